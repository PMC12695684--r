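#' @rdname classify_genotypes
#' @export
depth_levels <- function() c("superficial", "semi_deep", "deep")

#' @rdname classify_genotypes
#' @export
density_levels <- function() c("non_dense", "semi_dense", "dense")

# group index 1..9 from the two ordered class factors:
# 3 * (depth rank - 1) + density rank
group_index_of <- function(depth, density) {
  3L * (as.integer(depth) - 1L) + as.integer(density)
}

#' Confidence interval of the mean used as classification thresholds
#'
#' Student-t confidence interval of the mean of the per-genotype trait
#' values within one condition: mean +/- t(1 - alpha/2, n - 1) * sd/sqrt(n),
#' with the sample (n - 1) standard deviation. Its bounds are the cut
#' points that split genotypes into below / within / above classes.
#'
#' @param values Numeric vector of per-genotype trait values (n >= 2).
#' @param alpha Significance level; `0.05` gives the 95% interval.
#'
#' @return A one-row tibble: `mean`, `lower`, `upper`, `n`, `alpha`.
#' @export
#'
#' @examples
#' compute_ci(c(1, 2, 3))
compute_ci <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("domain error: need at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("domain error: values must be finite", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  m <- mean(values)
  half <- stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  tibble::tibble(mean = m, lower = m - half, upper = m + half,
                 n = n, alpha = alpha)
}

#' Classify genotypes into nine root-architecture groups
#'
#' Per condition, genotypes are split into three depth classes by root
#' length and three density classes by root tissue density, using the
#' 95% confidence interval of the condition mean as thresholds: values
#' strictly below the lower bound are `superficial` / `non_dense`, values
#' strictly above the upper bound are `deep` / `dense`, and values inside
#' the closed interval are `semi_deep` / `semi_dense`. The two class labels
#' combine into a group index 1-9
#' (`3 * (depth rank - 1) + density rank`), so that group 1 is
#' superficial non-dense and group 9 is deep dense.
#'
#' @param adjusted A tibble keyed by (`genotype_id`, `condition`) with the
#'   two classification trait columns, e.g. the output of
#'   [adjust_augmented()].
#' @param alpha Significance level of the interval (default 0.05).
#' @param length_trait,density_trait Names of the columns holding root
#'   length and root tissue density.
#'
#' @return A tibble with one row per genotype and condition: `genotype_id`,
#'   `condition`, `depth_class`, `density_class`, `group_index`.
#' @export
classify_genotypes <- function(adjusted, alpha = 0.05,
                               length_trait = "root_length",
                               density_trait = "root_tissue_density") {
  tab <- tibble::as_tibble(adjusted)
  for (col in c(length_trait, density_trait)) {
    if (!col %in% names(tab)) {
      stop("classification error: missing trait column ", col, call. = FALSE)
    }
    if (anyNA(tab[[col]])) {
      stop("classification error: missing ", col, " for genotype(s) ",
           paste(tab$genotype_id[is.na(tab[[col]])], collapse = ", "),
           call. = FALSE)
    }
  }
  three_way <- function(x, levels) {
    ci <- compute_ci(x, alpha)
    cls <- ifelse(x < ci$lower, levels[1],
                  ifelse(x > ci$upper, levels[3], levels[2]))
    factor(cls, levels = levels)
  }
  out <- tab |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(
      depth_class = three_way(.data[[length_trait]], depth_levels()),
      density_class = three_way(.data[[density_trait]], density_levels())
    ) |>
    dplyr::ungroup()
  tibble::tibble(
    genotype_id = out$genotype_id,
    condition = out$condition,
    depth_class = out$depth_class,
    density_class = out$density_class,
    group_index = group_index_of(out$depth_class, out$density_class)
  )
}

#' Tally genotype counts over the nine root groups
#'
#' @param assignments Output of [classify_genotypes()] (or
#'   [wild_barley_groups()]).
#' @param condition Condition to tally; `NULL` tallies each condition
#'   present.
#'
#' @return A tibble with one row per condition and group (always all nine
#'   groups, zero-filled): `condition`, `depth_class`, `density_class`,
#'   `group_index`, `n`.
#' @export
tally_groups <- function(assignments, condition = NULL) {
  a <- tibble::as_tibble(assignments)
  if (!is.null(condition)) {
    a <- a[a$condition %in% condition, ]
    conds <- condition
  } else {
    conds <- unique(a$condition)
  }
  grid <- tidyr::expand_grid(
    condition = conds,
    depth_class = factor(depth_levels(), levels = depth_levels()),
    density_class = factor(density_levels(), levels = density_levels())
  )
  counts <- a |>
    dplyr::count(.data$condition, .data$depth_class, .data$density_class)
  out <- grid |>
    dplyr::left_join(counts,
                     by = c("condition", "depth_class", "density_class")) |>
    dplyr::mutate(
      n = tidyr::replace_na(.data$n, 0L),
      group_index = group_index_of(.data$depth_class, .data$density_class),
      .before = "n"
    ) |>
    dplyr::arrange(.data$condition, .data$group_index)
  out
}

#' Marginal counts of a nine-group tally
#'
#' @param tally Output of [tally_groups()] for a single condition.
#'
#' @return A list with `depth` (named counts over depth classes), `density`
#'   (over density classes) and `total`.
#' @export
tally_margins <- function(tally) {
  stopifnot(length(unique(tally$condition)) == 1)
  margin <- function(cls, levels) {
    vapply(levels, function(l) sum(tally$n[cls == l]), numeric(1))
  }
  list(depth = margin(tally$depth_class, depth_levels()),
       density = margin(tally$density_class, density_levels()),
       total = sum(tally$n))
}

#' Per-genotype group stability across conditions
#'
#' Pairs each genotype's group under the two conditions and flags whether
#' the root architecture changed.
#'
#' @param assignments Output of [classify_genotypes()] covering both
#'   conditions.
#' @param conditions Length-2 character vector naming the reference and
#'   comparison condition.
#'
#' @return A tibble with one row per genotype: the group index and classes
#'   under each condition and a logical `changed`.
#' @export
stability_report <- function(assignments,
                             conditions = c("normal", "stress")) {
  a <- tibble::as_tibble(assignments)
  stopifnot(length(conditions) == 2)
  ref <- a[a$condition == conditions[1], ]
  cmp <- a[a$condition == conditions[2], ]
  only <- c(setdiff(ref$genotype_id, cmp$genotype_id),
            setdiff(cmp$genotype_id, ref$genotype_id))
  if (length(only) > 0) {
    stop("report error: genotype(s) present in only one condition: ",
         paste(only, collapse = ", "), call. = FALSE)
  }
  j <- dplyr::inner_join(
    ref[, c("genotype_id", "depth_class", "density_class", "group_index")],
    cmp[, c("genotype_id", "depth_class", "density_class", "group_index")],
    by = "genotype_id", suffix = paste0("_", conditions)
  )
  g1 <- paste0("group_index_", conditions[1])
  g2 <- paste0("group_index_", conditions[2])
  j$changed <- j[[g1]] != j[[g2]]
  dplyr::arrange(j, .data$genotype_id)
}
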