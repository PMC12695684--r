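#' Configuration for derived root-trait computation
#'
#' @param soil_volume Volume of growth medium per tube, in cm^3. Required:
#'   it is a physical property of the experiment with no sensible universal
#'   default.
#' @param pi_value Value of pi used in the area/diameter formulas. Defaults
#'   to `3.14`, the truncated constant conventionally used in the field's
#'   printed formulas; set to `base::pi` for full precision.
#' @param rtd_mode How root tissue density is computed from root dry weight
#'   (DW, g) and root volume (V, cm^3): `"product"` (DW * V, the convention
#'   followed by this pipeline's reference analysis) or `"quotient"`
#'   (DW / V, the physically standard density). See the package vignette.
#'
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(soil_volume, pi_value = 3.14,
                         rtd_mode = c("product", "quotient")) {
  if (missing(soil_volume)) {
    stop("soil_volume (cm^3 per tube) is required", call. = FALSE)
  }
  stopifnot(is.numeric(soil_volume), length(soil_volume) == 1,
            soil_volume > 0, is.numeric(pi_value), pi_value > 0)
  rtd_mode <- match.arg(rtd_mode)
  structure(list(soil_volume = soil_volume, pi_value = pi_value,
                 rtd_mode = rtd_mode),
            class = "trait_config")
}

# names of the derived trait columns, in output order
derived_trait_names <- function() {
  c("root_area", "root_diameter", "specific_root_length",
    "root_length_density", "root_specific_mass", "root_tissue_density",
    "root_mass_density", "root_fineness", "root_surface_area_density")
}

#' Trait columns produced by the derivation stage
#'
#' Primary traits first (renamed to unitless short names), then the nine
#' derived root traits, then the four pigment concentrations when present.
#'
#' @return Character vector of trait column names (without pigments).
#' @export
trait_names <- function() {
  c(unname(primary_trait_names()), derived_trait_names())
}

#' Derive root traits from primary tube measurements
#'
#' Computes the derived root-architecture traits from the primary per-tube
#' measurements, one row per input row (aggregation over the design happens
#' downstream). With root length L (cm), root fresh/dry weight FW/DW (g),
#' root volume V (cm^3) and tube soil volume S (cm^3):
#'
#' * root area = 2 * sqrt(V * pi * L)
#' * root diameter = sqrt(4 * FW / (L * pi))
#' * specific root length = L / DW
#' * root length density = L / S
#' * root specific mass = DW / S
#' * root tissue density = DW * V (`"product"` mode) or DW / V (`"quotient"`)
#' * root mass density = FW / S
#' * root fineness = L / V
#' * root surface area density = L * diameter * pi
#'
#' @param measurements A validated measurement tibble (see
#'   [read_measurements()]), or any tibble containing the primary
#'   measurement columns.
#' @param config A [trait_config()].
#'
#' @return A tibble with the design columns (`genotype_id`, `is_check`,
#'   `block`, `condition` when present), the primary traits under short
#'   names, and the derived traits.
#' @export
#'
#' @examples
#' m <- tibble::tibble(
#'   genotype_id = 1L, is_check = FALSE, block = 1L, condition = "normal",
#'   root_length_cm = 10, root_fresh_weight_g = 0.5, root_dry_weight_g = 0.1,
#'   root_volume_cm3 = 0.4, seedling_length_cm = 30,
#'   seedling_fresh_weight_g = 0.4, seedling_dry_weight_g = 0.05,
#'   a663 = 0.8, a646 = 0.35, a470 = 0.5
#' )
#' derive_traits(m, trait_config(soil_volume = 1000))
derive_traits <- function(measurements, config) {
  stopifnot(inherits(config, "trait_config"))
  m <- tibble::as_tibble(measurements)
  need <- c("root_length_cm", "root_fresh_weight_g", "root_dry_weight_g",
            "root_volume_cm3")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0) {
    stop("missing primary column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  L <- m$root_length_cm
  FW <- m$root_fresh_weight_g
  DW <- m$root_dry_weight_g
  V <- m$root_volume_cm3
  S <- config$soil_volume
  PI <- config$pi_value

  offending <- function(bad) {
    if ("genotype_id" %in% names(m)) {
      paste0(" (genotype ", paste(unique(m$genotype_id[bad]), collapse = ", "), ")")
    } else {
      paste0(" (row ", paste(which(bad), collapse = ", "), ")")
    }
  }
  if (any(bad <- c(L, FW, DW, V) < 0)) {
    stop("value error: negative primary measurement", call. = FALSE)
  }
  if (any(bad <- L <= 0)) {
    stop("domain error: root_length_cm must be > 0 for root_diameter and ",
         "specific_root_length", offending(bad), call. = FALSE)
  }
  if (any(bad <- DW <= 0)) {
    stop("domain error: root_dry_weight_g must be > 0 for specific_root_length",
         offending(bad), call. = FALSE)
  }
  if (any(bad <- V <= 0)) {
    stop("domain error: root_volume_cm3 must be > 0 for root_fineness",
         offending(bad), call. = FALSE)
  }

  diameter <- sqrt(4 * FW / (L * PI))
  out <- tibble::tibble(
    root_length = L,
    root_fresh_weight = FW,
    root_dry_weight = DW,
    root_volume = V,
    root_area = 2 * sqrt(V * PI * L),
    root_diameter = diameter,
    specific_root_length = L / DW,
    root_length_density = L / S,
    root_specific_mass = DW / S,
    root_tissue_density = if (config$rtd_mode == "product") DW * V else DW / V,
    root_mass_density = FW / S,
    root_fineness = L / V,
    root_surface_area_density = L * diameter * PI
  )
  for (col in c("seedling_length_cm", "seedling_fresh_weight_g",
                "seedling_dry_weight_g")) {
    if (col %in% names(m)) out[[primary_trait_names()[[col]]]] <- m[[col]]
  }
  id_cols <- intersect(c("genotype_id", "is_check", "block", "condition"),
                       names(m))
  dplyr::bind_cols(m[, id_cols], out)
}
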