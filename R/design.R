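#' Experimental design layout for an augmented block design
#'
#' Describes the layout of an augmented block design: a set of replicated
#' check genotypes that appear in every block, a set of unreplicated test
#' genotypes each assigned to exactly one block, and the moisture conditions
#' under which the whole layout is repeated.
#'
#' @param n_blocks Number of blocks per condition.
#' @param check_ids Integer vector of check (control) genotype labels.
#' @param test_ids Integer vector of test genotype labels.
#' @param conditions Character vector of condition names, ordered.
#'
#' @return An object of class `design_layout`: a list with the four fields
#'   plus `n_genotypes` and `tests_per_block`.
#' @export
#'
#' @examples
#' design_layout(2, check_ids = 1:2, test_ids = 3:8)
design_layout <- function(n_blocks, check_ids, test_ids,
                          conditions = c("normal", "stress")) {
  check_ids <- sort(as.integer(check_ids))
  test_ids <- sort(as.integer(test_ids))
  stopifnot(n_blocks >= 1, length(check_ids) >= 1, length(test_ids) >= 1)
  if (length(intersect(check_ids, test_ids)) > 0) {
    stop("check_ids and test_ids must be disjoint", call. = FALSE)
  }
  if (anyDuplicated(check_ids) || anyDuplicated(test_ids)) {
    stop("genotype labels must be unique", call. = FALSE)
  }
  if (length(test_ids) %% n_blocks != 0) {
    stop("number of test genotypes (", length(test_ids),
         ") is not divisible by n_blocks (", n_blocks, ")", call. = FALSE)
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      check_ids = check_ids,
      test_ids = test_ids,
      conditions = as.character(conditions),
      n_genotypes = length(check_ids) + length(test_ids),
      tests_per_block = length(test_ids) %/% n_blocks
    ),
    class = "design_layout"
  )
}

#' The wild barley seedling-tube layout
#'
#' The augmented block design used throughout this package's examples:
#' 114 wild barley genotypes of which 9 are replicated checks
#' (labels 1, 10, 24, 34, 35, 51, 74, 104, 113), 105 are unreplicated tests,
#' laid out in 5 blocks of 30 tubes per condition (21 tests + 9 checks per
#' block) under two soil-moisture regimes, for 150 tubes per condition and
#' 300 tubes in total.
#'
#' @return A [design_layout()] object.
#' @export
barley_layout <- function() {
  checks <- c(1L, 10L, 24L, 34L, 35L, 51L, 74L, 104L, 113L)
  design_layout(
    n_blocks = 5,
    check_ids = checks,
    test_ids = setdiff(1:114, checks),
    conditions = c("normal", "stress")
  )
}

#' @export
print.design_layout <- function(x, ...) {
  cat("<design_layout>\n")
  cat("  blocks per condition: ", x$n_blocks, "\n", sep = "")
  cat("  checks: ", length(x$check_ids), " (",
      paste(x$check_ids, collapse = ", "), ")\n", sep = "")
  cat("  tests:  ", length(x$test_ids), " (", x$tests_per_block,
      " per block)\n", sep = "")
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Column order of the measurement schema; shared by reader, writer and
# simulator.
measurement_columns <- function() {
  c("genotype_id", "is_check", "block", "condition",
    "root_length_cm", "root_fresh_weight_g", "root_dry_weight_g",
    "root_volume_cm3", "seedling_length_cm", "seedling_fresh_weight_g",
    "seedling_dry_weight_g", "a663", "a646", "a470")
}

# Short trait names used internally (schema column -> trait name).
primary_trait_names <- function() {
  c(root_length_cm = "root_length",
    root_fresh_weight_g = "root_fresh_weight",
    root_dry_weight_g = "root_dry_weight",
    root_volume_cm3 = "root_volume",
    seedling_length_cm = "seedling_length",
    seedling_fresh_weight_g = "seedling_fresh_weight",
    seedling_dry_weight_g = "seedling_dry_weight")
}

#' Validate a tibble of tube-level measurements against a design layout
#'
#' Checks value invariants (non-negative measurements, dry weight not
#' exceeding fresh weight) and design invariants (known genotype labels,
#' blocks within range, every check present in every block of each
#' condition, every test genotype in exactly one block per condition).
#' Rows with any missing primary measurement are dropped with a warning
#' rather than imputed.
#'
#' @param measurements A tibble in the measurement schema (see
#'   [read_measurements()]).
#' @param layout A [design_layout()].
#'
#' @return The validated tibble (invisibly identical to the input apart from
#'   dropped incomplete rows), with columns coerced to canonical types.
#' @export
validate_measurements <- function(measurements, layout) {
  m <- tibble::as_tibble(measurements)
  missing_cols <- setdiff(measurement_columns(), names(m))
  if (length(missing_cols) > 0) {
    stop("measurement schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- m[, measurement_columns()]
  m$genotype_id <- as.integer(m$genotype_id)
  m$block <- as.integer(m$block)
  m$is_check <- as.logical(m$is_check)
  m$condition <- as.character(m$condition)

  value_cols <- c("root_length_cm", "root_fresh_weight_g", "root_dry_weight_g",
                  "root_volume_cm3", "seedling_length_cm",
                  "seedling_fresh_weight_g", "seedling_dry_weight_g",
                  "a663", "a646", "a470")
  incomplete <- !stats::complete.cases(m[, value_cols])
  if (any(incomplete)) {
    warning(sum(incomplete), " row(s) with missing measurements dropped",
            call. = FALSE)
    m <- m[!incomplete, ]
  }

  bad_cond <- setdiff(unique(m$condition), layout$conditions)
  if (length(bad_cond) > 0) {
    stop("schema error: unknown condition(s): ",
         paste(bad_cond, collapse = ", "), call. = FALSE)
  }
  known <- c(layout$check_ids, layout$test_ids)
  if (!all(m$genotype_id %in% known)) {
    stop("schema error: unknown genotype id(s): ",
         paste(setdiff(m$genotype_id, known), collapse = ", "), call. = FALSE)
  }
  flag_should <- m$genotype_id %in% layout$check_ids
  if (!all(m$is_check == flag_should)) {
    stop("schema error: is_check flag inconsistent with layout for genotype(s) ",
         paste(unique(m$genotype_id[m$is_check != flag_should]), collapse = ", "),
         call. = FALSE)
  }
  if (any(m$block < 1 | m$block > layout$n_blocks)) {
    stop("design error: block outside 1..", layout$n_blocks, call. = FALSE)
  }
  for (col in value_cols) {
    if (any(m[[col]] < 0)) {
      stop("value error: negative ", col, call. = FALSE)
    }
  }
  if (any(m$root_dry_weight_g > m$root_fresh_weight_g)) {
    stop("value error: root_dry_weight_g exceeds root_fresh_weight_g",
         call. = FALSE)
  }
  if (any(m$seedling_dry_weight_g > m$seedling_fresh_weight_g)) {
    stop("value error: seedling_dry_weight_g exceeds seedling_fresh_weight_g",
         call. = FALSE)
  }

  # design occupancy: each check in every block, each test in exactly one
  for (cond in intersect(layout$conditions, unique(m$condition))) {
    mc <- m[m$condition == cond, ]
    for (chk in layout$check_ids) {
      blocks_seen <- sort(unique(mc$block[mc$genotype_id == chk]))
      if (!identical(blocks_seen, seq_len(layout$n_blocks))) {
        stop("design error: check ", chk, " missing from block(s) ",
             paste(setdiff(seq_len(layout$n_blocks), blocks_seen),
                   collapse = ", "),
             " under ", cond, call. = FALSE)
      }
    }
    test_counts <- table(mc$genotype_id[!mc$is_check])
    if (any(test_counts != 1)) {
      stop("design error: test genotype(s) ",
           paste(names(test_counts)[test_counts != 1], collapse = ", "),
           " observed more than once under ", cond, call. = FALSE)
    }
  }
  m
}
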