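#' Read tube-level measurements from CSV
#'
#' Reads a comma-separated, UTF-8, period-decimal file with a mandatory
#' header matching the measurement schema, validates every row against the
#' design layout and returns a tibble with one row per tube.
#'
#' The schema columns are exactly:
#' `genotype_id,is_check,block,condition,root_length_cm,root_fresh_weight_g,`
#' `root_dry_weight_g,root_volume_cm3,seedling_length_cm,`
#' `seedling_fresh_weight_g,seedling_dry_weight_g,a663,a646,a470`.
#'
#' @param path Path to the CSV file.
#' @param layout A [design_layout()] describing the expected design.
#'
#' @return A validated tibble of measurements, row order preserved.
#' @export
read_measurements <- function(path, layout) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  m <- readr::read_csv(
    path,
    col_types = readr::cols(
      genotype_id = readr::col_integer(),
      is_check = readr::col_logical(),
      block = readr::col_integer(),
      condition = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_measurements(m, layout)
}

#' Write a trait table (or any tibble) to CSV
#'
#' Writes comma-separated, UTF-8, period-decimal CSV with a header row.
#' Numeric values are written with enough digits that a write/read
#' round trip reproduces them to better than 12 significant digits.
#'
#' @param table A tibble.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("I/O error: directory does not exist: ", dir, call. = FALSE)
  }
  tab <- tibble::as_tibble(table)
  num <- vapply(tab, is.numeric, logical(1)) & !vapply(tab, is.integer, logical(1))
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 15, format = "g"))
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Bundled reference classification of 114 wild barley genotypes
#'
#' A per-genotype depth/density classification of 114 wild barley
#' (*Hordeum vulgare* subsp. *spontaneum*) genotypes under normal and
#' water-stress moisture regimes, shipped with the package as a worked
#' reference for the nine-group tallying and stability machinery.
#'
#' @return A tibble of root-group assignments with columns `genotype_id`,
#'   `condition`, `depth_class`, `density_class`, `group_index` (two rows
#'   per genotype, one per condition).
#' @export
#'
#' @examples
#' tally_groups(wild_barley_groups(), condition = "normal")
wild_barley_groups <- function() {
  path <- system.file("extdata", "wild_barley_root_groups.csv",
                      package = "rootgroups", mustWork = TRUE)
  wide <- readr::read_csv(path, col_types = readr::cols(
    genotype_id = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE)
  long <- tidyr::pivot_longer(
    wide, -"genotype_id",
    names_to = c("condition", ".value"), names_sep = "_",
    names_transform = list(condition = as.character)
  )
  tibble::tibble(
    genotype_id = long$genotype_id,
    condition = long$condition,
    depth_class = factor(long$depth, levels = depth_levels()),
    density_class = factor(long$density, levels = density_levels()),
    group_index = group_index_of(
      factor(long$depth, levels = depth_levels()),
      factor(long$density, levels = density_levels())
    )
  )
}
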