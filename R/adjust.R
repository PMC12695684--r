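# Identify the trait (numeric, non-design) columns of a trait table.
trait_columns_of <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("genotype_id", "block"))
}

#' Estimate block effects from replicated check genotypes
#'
#' In an augmented block design the unreplicated test genotypes are
#' confounded with blocks; the replicated checks are not. For every trait
#' and condition the block effect is estimated as
#' (mean of checks in the block) - (grand mean of checks over all blocks),
#' the classical check-based correction. Within each condition and trait the
#' estimated effects average to zero over blocks.
#'
#' @param table A per-tube trait tibble: design columns `genotype_id`,
#'   `is_check`, `block`, `condition` plus numeric trait columns.
#' @param layout A [design_layout()].
#' @param traits Character vector of trait columns to process; defaults to
#'   every numeric non-design column.
#'
#' @return A tibble with columns `condition`, `block`, `trait`, `effect`.
#' @export
estimate_block_effects <- function(table, layout, traits = NULL) {
  tab <- tibble::as_tibble(table)
  if (is.null(traits)) traits <- trait_columns_of(tab)
  checks <- tab[tab$is_check, c("genotype_id", "block", "condition", traits)]
  for (cond in unique(tab$condition)) {
    cc <- checks[checks$condition == cond, ]
    counts <- table(cc$genotype_id, cc$block)
    if (nrow(counts) < length(layout$check_ids) ||
        ncol(counts) < layout$n_blocks || any(counts < 1)) {
      stop("design error: missing check observation(s) under ", cond,
           call. = FALSE)
    }
  }
  long <- tidyr::pivot_longer(checks, dplyr::all_of(traits),
                              names_to = "trait", values_to = "value")
  long |>
    dplyr::group_by(.data$condition, .data$trait) |>
    dplyr::mutate(grand = mean(.data$value)) |>
    dplyr::group_by(.data$condition, .data$block, .data$trait) |>
    dplyr::summarise(effect = mean(.data$value) - .data$grand[1],
                     .groups = "drop") |>
    dplyr::arrange(.data$condition, .data$trait, .data$block)
}

#' Check-based adjustment of an augmented block design
#'
#' Removes the estimated block effects from every observation, then reduces
#' to one value per genotype and condition: test genotypes keep their single
#' corrected observation, check genotypes get the mean of their corrected
#' observations across blocks. On noise-free additive data
#' (value = genotype + block + condition) the adjusted differences between
#' any two genotypes within a condition equal the true genotype differences
#' exactly.
#'
#' @inheritParams estimate_block_effects
#' @param effects Output of [estimate_block_effects()]; computed from
#'   `table` if `NULL`.
#'
#' @return A tibble keyed by (`genotype_id`, `condition`) with a
#'   `provenance` column (`"check_mean"` or `"test_adjusted"`) and one
#'   column per trait.
#' @export
adjust_augmented <- function(table, layout, effects = NULL, traits = NULL) {
  tab <- tibble::as_tibble(table)
  if (is.null(traits)) traits <- trait_columns_of(tab)
  if (is.null(effects)) effects <- estimate_block_effects(tab, layout, traits)
  need <- tidyr::expand_grid(condition = unique(tab$condition),
                             block = sort(unique(tab$block)),
                             trait = traits)
  have <- dplyr::semi_join(need, effects,
                           by = c("condition", "block", "trait"))
  if (nrow(have) < nrow(need)) {
    stop("design error: effects table does not cover every ",
         "(condition, block, trait)", call. = FALSE)
  }
  present <- dplyr::distinct(tab, .data$genotype_id, .data$condition)
  expected <- tidyr::expand_grid(
    genotype_id = c(layout$check_ids, layout$test_ids),
    condition = intersect(layout$conditions, unique(tab$condition))
  )
  absent <- dplyr::anti_join(expected, present,
                             by = c("genotype_id", "condition"))
  if (nrow(absent) > 0) {
    stop("design error: genotype(s) with no observation: ",
         paste(utils::head(absent$genotype_id, 5), collapse = ", "),
         call. = FALSE)
  }

  long <- tidyr::pivot_longer(
    tab[, c("genotype_id", "is_check", "block", "condition", traits)],
    dplyr::all_of(traits), names_to = "trait", values_to = "value"
  )
  adj <- long |>
    dplyr::left_join(effects, by = c("condition", "block", "trait")) |>
    dplyr::mutate(corrected = .data$value - .data$effect) |>
    dplyr::group_by(.data$genotype_id, .data$is_check, .data$condition,
                    .data$trait) |>
    dplyr::summarise(adjusted = mean(.data$corrected), .groups = "drop")
  out <- tidyr::pivot_wider(adj, names_from = "trait",
                            values_from = "adjusted")
  out <- dplyr::mutate(
    out,
    provenance = ifelse(.data$is_check, "check_mean", "test_adjusted"),
    .after = "condition"
  )
  dplyr::arrange(dplyr::select(out, -"is_check"),
                 .data$condition, .data$genotype_id)[, c("genotype_id",
                                                         "condition",
                                                         "provenance",
                                                         traits)]
}

# significance stars at the 5% / 1% levels
stars_of <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Factorial ANOVA on the replicated check genotypes
#'
#' Two-way fixed-effects analysis of variance of tube-level check data with
#' factors genotype, stress condition, and their interaction; the design is
#' balanced (every check in every block of every condition), so sums of
#' squares are the classical sequential/orthogonal ones. If the trait has no
#' variation at all, sums of squares are 0 and the test is reported with
#' F = 0 and p = 1 by convention.
#'
#' @inheritParams estimate_block_effects
#' @param trait Name of a single trait column.
#'
#' @return A tibble with one row per term (`genotype`, `stress`,
#'   `genotype:stress`, `error`): `term`, `df`, `sumsq`, `meansq`, `f`,
#'   `p`, `stars`.
#' @export
factorial_check_anova <- function(table, layout, trait) {
  tab <- tibble::as_tibble(table)
  stopifnot(trait %in% names(tab))
  checks <- tab[tab$is_check, ]
  n_cell <- table(checks$genotype_id, checks$condition)
  if (nrow(n_cell) != length(layout$check_ids) ||
      ncol(n_cell) != length(layout$conditions) ||
      length(unique(as.vector(n_cell))) != 1) {
    stop("design error: check data unbalanced", call. = FALSE)
  }
  d <- data.frame(
    y = checks[[trait]],
    genotype = factor(checks$genotype_id),
    stress = factor(checks$condition)
  )
  if (stats::var(d$y) == 0 || isTRUE(all.equal(stats::var(d$y), 0))) {
    df <- c(nlevels(d$genotype) - 1L, nlevels(d$stress) - 1L,
            (nlevels(d$genotype) - 1L) * (nlevels(d$stress) - 1L),
            nrow(d) - nlevels(d$genotype) * nlevels(d$stress))
    return(tibble::tibble(
      term = c("genotype", "stress", "genotype:stress", "error"),
      df = df, sumsq = 0, meansq = 0,
      f = c(0, 0, 0, NA_real_), p = c(1, 1, 1, NA_real_),
      stars = c("ns", "ns", "ns", NA_character_)
    ))
  }
  fit <- stats::aov(y ~ genotype * stress, data = d)
  a <- stats::anova(fit)
  tibble::tibble(
    term = c("genotype", "stress", "genotype:stress", "error"),
    df = a$Df,
    sumsq = a$`Sum Sq`,
    meansq = a$`Mean Sq`,
    f = c(a$`F value`[1:3], NA_real_),
    p = c(a$`Pr(>F)`[1:3], NA_real_),
    stars = c(stars_of(a$`Pr(>F)`[1:3]), NA_character_)
  )
}
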