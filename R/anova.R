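#' One-way ANOVA of a trait across root groups
#'
#' Fixed-effects one-way decomposition of genotype-level trait values over
#' the nine root groups (or any grouping). At the reference scale of 114
#' genotypes in 9 groups the degrees of freedom are 8 between and 105
#' within. A trait with no variation is reported with all sums of squares
#' 0, F = 0 and p = 1 by convention.
#'
#' @param values A tibble with one row per genotype containing `trait`.
#' @param assignments Grouping: either a vector aligned with `values` rows
#'   or a tibble with `genotype_id` and `group_index` to be joined on.
#' @param trait Name of the trait column in `values`.
#'
#' @return A one-row tibble: `trait`, `df_between`, `df_within`,
#'   `ss_between`, `ss_within`, `ms_between`, `ms_within`, `f`, `p`,
#'   `stars`.
#' @export
oneway_group_anova <- function(values, assignments, trait) {
  v <- tibble::as_tibble(values)
  stopifnot(trait %in% names(v))
  if (is.data.frame(assignments)) {
    j <- dplyr::inner_join(v, assignments[, c("genotype_id", "group_index")],
                           by = "genotype_id")
    y <- j[[trait]]
    g <- factor(j$group_index)
  } else {
    stopifnot(length(assignments) == nrow(v))
    y <- v[[trait]]
    g <- factor(assignments)
  }
  g <- droplevels(g)
  k <- nlevels(g)
  n <- length(y)
  if (k < 2) stop("degenerate-design error: need >= 2 non-empty groups",
                  call. = FALSE)
  if (n <= k) stop("degenerate-design error: need n > number of groups",
                   call. = FALSE)
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) {
    return(tibble::tibble(trait = trait, df_between = k - 1L,
                          df_within = n - k, ss_between = 0, ss_within = 0,
                          ms_between = 0, ms_within = 0, f = 0, p = 1,
                          stars = "ns"))
  }
  a <- stats::anova(stats::lm(y ~ g))
  tibble::tibble(
    trait = trait,
    df_between = a$Df[1], df_within = a$Df[2],
    ss_between = a$`Sum Sq`[1], ss_within = a$`Sum Sq`[2],
    ms_between = a$`Mean Sq`[1], ms_within = a$`Mean Sq`[2],
    f = a$`F value`[1], p = a$`Pr(>F)`[1],
    stars = stars_of(a$`Pr(>F)`[1])
  )
}

#' LSD pairwise comparison of group means
#'
#' Least significant difference following a one-way ANOVA:
#' `LSD(i, j) = t(1 - alpha/2, df_within) * sqrt(ms_within * (1/n_i + 1/n_j))`;
#' a pair is declared different only when the absolute mean difference
#' strictly exceeds its LSD.
#'
#' @param values,assignments,trait As in [oneway_group_anova()].
#' @param anova Optional precomputed [oneway_group_anova()] row (recomputed
#'   if `NULL`).
#' @param alpha Significance level (0.05 or 0.01 in the reference analysis).
#'
#' @return A tibble with one row per unordered group pair: `group_i`,
#'   `group_j`, `mean_i`, `mean_j`, `diff`, `lsd`, `significant`.
#' @export
lsd_compare <- function(values, assignments, trait, anova = NULL,
                        alpha = 0.05) {
  v <- tibble::as_tibble(values)
  if (is.data.frame(assignments)) {
    j <- dplyr::inner_join(v, assignments[, c("genotype_id", "group_index")],
                           by = "genotype_id")
    y <- j[[trait]]
    g <- factor(j$group_index)
  } else {
    y <- v[[trait]]
    g <- factor(assignments)
  }
  g <- droplevels(g)
  if (is.null(anova)) anova <- oneway_group_anova(v, assignments, trait)
  if (anova$ms_within == 0) {
    stop("degenerate error: within-group mean square is 0", call. = FALSE)
  }
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  tcrit <- stats::qt(1 - alpha / 2, df = anova$df_within)
  pairs <- utils::combn(levels(g), 2)
  lsd <- tcrit * sqrt(anova$ms_within *
                        (1 / sizes[pairs[1, ]] + 1 / sizes[pairs[2, ]]))
  diff <- means[pairs[1, ]] - means[pairs[2, ]]
  tibble::tibble(
    group_i = pairs[1, ], group_j = pairs[2, ],
    mean_i = unname(means[pairs[1, ]]), mean_j = unname(means[pairs[2, ]]),
    diff = unname(diff), lsd = unname(lsd),
    significant = unname(abs(diff) > lsd)
  )
}

#' Pearson correlation matrix of traits with significance flags
#'
#' Pairwise Pearson correlations over genotype-level values, with two-sided
#' p-values from the t distribution on n - 2 degrees of freedom and
#' significance flags at the 5% and 1% levels (unadjusted; an optional
#' Benjamini-Hochberg column is available from [tidy()]). Zero-variance
#' traits yield `NA` correlations with a warning.
#'
#' @param values Tibble of genotype-level trait values (>= 3 rows).
#' @param traits Character vector of trait columns; defaults to all numeric
#'   non-design columns.
#'
#' @return An object of class `trait_correlations` holding matrices `r`,
#'   `p` and `n`; use [tidy()] for a long tibble or [autoplot()] for a
#'   heatmap.
#' @export
trait_correlations <- function(values, traits = NULL) {
  v <- tibble::as_tibble(values)
  if (is.null(traits)) traits <- trait_columns_of(v)
  x <- as.matrix(v[, traits])
  n <- nrow(x)
  if (n < 3) stop("need at least 3 genotypes", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance trait(s): ",
            paste(traits[sds == 0], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, traits = traits),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat("<trait_correlations> ", length(x$traits), " traits over ", x$n,
      " genotypes\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname trait_correlations
#' @param x A `trait_correlations` object.
#' @param ... Unused.
#' @export
tidy.trait_correlations <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  p <- x$p[idx]
  tibble::tibble(
    trait_1 = x$traits[idx[, 1]],
    trait_2 = x$traits[idx[, 2]],
    r = x$r[idx],
    p = p,
    stars = ifelse(is.na(p), NA_character_, stars_of(p)),
    p_bh = stats::p.adjust(p, method = "BH")
  )
}

#' @rdname trait_correlations
#' @param object A `trait_correlations` object.
#' @export
autoplot.trait_correlations <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait_1, y = .data$trait_2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$stars == "ns" | is.na(.data$stars), "",
                     .data$stars)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
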