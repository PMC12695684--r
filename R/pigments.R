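# Spectrophotometric equation coefficients (96% ethanol extract,
# absorbances at 663, 646 and 470 nm), kept in one table for auditability.
pigment_coefficients <- function() {
  list(
    chl_a = c(a663 = 12.21, a646 = -2.81),
    chl_b = c(a663 = -5.1, a646 = 20.13),
    carotenoid = c(a470 = 1000, chl_a = -3.27, chl_b = -104, divisor = 227)
  )
}

#' Chlorophyll and carotenoid concentrations from absorbances
#'
#' Applies the spectrophotometric equations for 96% ethanol extracts to the
#' absorbance columns `a663`, `a646`, `a470`:
#'
#' * Chl a = 12.21 A663 - 2.81 A646
#' * Chl b = 20.13 A646 - 5.1 A663
#' * Chl total = Chl a + Chl b
#' * Carotenoid = (1000 A470 - 3.27 Chl a - 104 Chl b) / 227
#'
#' Results are in raw equation units (the extraction dilution factor is not
#' applied). Negative concentrations, which the linear equations can produce
#' for extreme absorbance ratios, are returned as computed and flagged with
#' a warning rather than clamped.
#'
#' @param absorbances A tibble with numeric columns `a663`, `a646`, `a470`
#'   (extra columns are carried through).
#'
#' @return The input tibble with columns `chl_a`, `chl_b`, `chl_total`,
#'   `carotenoid` appended.
#' @export
#'
#' @examples
#' compute_pigments(tibble::tibble(a663 = 0.8, a646 = 0.35, a470 = 0.5))
compute_pigments <- function(absorbances) {
  p <- tibble::as_tibble(absorbances)
  need <- c("a663", "a646", "a470")
  missing_cols <- setdiff(need, names(p))
  if (length(missing_cols) > 0) {
    stop("missing absorbance column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    if (any(!is.finite(p[[col]])) || any(p[[col]] < 0)) {
      stop("value error: ", col, " must be finite and >= 0", call. = FALSE)
    }
  }
  k <- pigment_coefficients()
  chl_a <- k$chl_a[["a663"]] * p$a663 + k$chl_a[["a646"]] * p$a646
  chl_b <- k$chl_b[["a646"]] * p$a646 + k$chl_b[["a663"]] * p$a663
  car <- (k$carotenoid[["a470"]] * p$a470 +
            k$carotenoid[["chl_a"]] * chl_a +
            k$carotenoid[["chl_b"]] * chl_b) / k$carotenoid[["divisor"]]
  p$chl_a <- chl_a
  p$chl_b <- chl_b
  p$chl_total <- chl_a + chl_b
  p$carotenoid <- car
  n_neg <- sum(chl_a < 0) + sum(chl_b < 0) + sum(car < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative pigment value(s) returned as computed",
            call. = FALSE)
  }
  p
}

#' Pigment concentration column names
#' @return Character vector of the four pigment columns.
#' @export
pigment_names <- function() c("chl_a", "chl_b", "chl_total", "carotenoid")
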