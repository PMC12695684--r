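#' Canonical correlation implied by a discriminant-function eigenvalue
#'
#' In canonical discriminant analysis with the pooled within-group scatter
#' convention, each discriminant function's eigenvalue lambda (of
#' W^-1 B, within- and between-group scatter) maps to a canonical
#' correlation r = sqrt(lambda / (1 + lambda)).
#'
#' @param lambda Non-negative eigenvalue(s).
#'
#' @return Canonical correlation(s) in `[0, 1)`.
#' @export
#'
#' @examples
#' canonical_correlation(c(5.599, 7.173))
canonical_correlation <- function(lambda) {
  stopifnot(is.numeric(lambda), all(lambda >= 0))
  sqrt(lambda / (1 + lambda))
}

#' Canonical discriminant analysis of trait profiles over root groups
#'
#' Canonical (descriptive) linear discriminant analysis in the pooled
#' within-group scatter convention: eigen-decomposition of W^-1 B where W
#' is the pooled within-group scatter matrix and B the between-group
#' scatter. Returns eigenvalues, percent and cumulative percent of
#' variance, canonical correlations r_i = sqrt(lambda_i / (1 + lambda_i)),
#' raw and standardized coefficients, the structure matrix (pooled
#' within-group correlations between each variable and each canonical
#' score) and group centroids of the canonical scores (scores are centered
#' at the grand mean, so the size-weighted centroid mean is 0).
#'
#' A numerically singular within-group scatter is regularized by adding
#' `ridge * trace(W)/p` to the diagonal, with a warning.
#'
#' @param values Tibble of genotype-level trait values.
#' @param groups Group labels: a vector aligned with `values` rows, or a
#'   tibble with `genotype_id` and `group_index` joined on `genotype_id`.
#' @param traits Trait columns to use; defaults to all numeric non-design
#'   columns.
#' @param ridge Regularization factor for a singular within-group scatter.
#'
#' @return An object of class `canonical_lda` with elements `eigenvalues`,
#'   `pct_variance`, `cumulative_pct`, `canonical_correlation`, `coef_raw`,
#'   `coef_std`, `structure`, `centroids`, `scores`, `groups`, `n`, `p`,
#'   `k`, `ridged`. Use [tidy()] / [glance()] / [autoplot()].
#' @export
canonical_lda <- function(values, groups, traits = NULL, ridge = 1e-8) {
  v <- tibble::as_tibble(values)
  if (is.data.frame(groups)) {
    j <- dplyr::inner_join(v, groups[, c("genotype_id", "group_index")],
                           by = "genotype_id")
    g <- factor(j$group_index)
    v <- j
  } else {
    stopifnot(length(groups) == nrow(v))
    g <- factor(groups)
  }
  if (is.null(traits)) {
    traits <- setdiff(trait_columns_of(v), "group_index")
  }
  x <- as.matrix(v[, traits])
  storage.mode(x) <- "double"
  g <- droplevels(g)
  n <- nrow(x)
  p <- ncol(x)
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (n <= k) stop("need more observations than groups", call. = FALSE)

  grand <- colMeans(x)
  xc <- sweep(x, 2, grand)
  gm <- rowsum(x, g) / as.vector(table(g))
  xw <- x - gm[as.integer(g), , drop = FALSE]
  W <- crossprod(xw)
  sizes <- as.vector(table(g))
  dm <- sweep(gm, 2, grand)
  B <- crossprod(dm * sqrt(sizes))

  ridged <- FALSE
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R) || rcond(R) < 1e-12) {
    scale <- sum(diag(W)) / p
    if (scale <= 0) scale <- 1
    W <- W + diag(ridge * scale, p)
    ridged <- TRUE
    warning("within-group scatter singular; ridge regularization applied",
            call. = FALSE)
    R <- chol(W)
  }
  Rinv <- backsolve(R, diag(p))
  M <- crossprod(Rinv, B) %*% Rinv
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  s <- min(k - 1, p)
  lambda <- pmax(ee$values[seq_len(s)], 0)
  v_raw <- Rinv %*% ee$vectors[, seq_len(s), drop = FALSE]
  # scale so the pooled within-group variance of each score is 1
  v_raw <- v_raw * sqrt(n - k)
  # sign convention: largest-magnitude loading positive
  for (i in seq_len(s)) {
    top <- which.max(abs(v_raw[, i]))
    if (v_raw[top, i] < 0) v_raw[, i] <- -v_raw[, i]
  }
  scores <- xc %*% v_raw
  centroids <- rowsum(scores, g) / sizes
  within_sd <- sqrt(diag(W) / (n - k))
  coef_std <- v_raw * within_sd
  structure_m <- (W %*% v_raw) / (n - k) / within_sd
  fn <- paste0("LD", seq_len(s))
  dimnames(v_raw) <- dimnames(coef_std) <- dimnames(structure_m) <-
    list(traits, fn)
  dimnames(scores) <- list(NULL, fn)
  dimnames(centroids) <- list(levels(g), fn)
  total <- sum(lambda)
  pct <- if (total > 0) 100 * lambda / total else rep(0, s)
  structure(list(
    eigenvalues = lambda,
    pct_variance = pct,
    cumulative_pct = cumsum(pct),
    canonical_correlation = canonical_correlation(lambda),
    coef_raw = v_raw, coef_std = coef_std, structure = structure_m,
    centroids = centroids, scores = scores, groups = g,
    n = n, p = p, k = k, ridged = ridged
  ), class = "canonical_lda")
}

#' @export
print.canonical_lda <- function(x, ...) {
  cat("<canonical_lda> ", x$k, " groups, ", x$p, " traits, n = ", x$n,
      "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname canonical_lda
#' @param x A `canonical_lda` object.
#' @param ... Unused.
#' @export
tidy.canonical_lda <- function(x, ...) {
  tibble::tibble(
    fn = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    pct_variance = x$pct_variance,
    cumulative_pct = x$cumulative_pct,
    canonical_correlation = x$canonical_correlation
  )
}

#' @rdname canonical_lda
#' @export
glance.canonical_lda <- function(x, ...) {
  tibble::tibble(n = x$n, n_traits = x$p, n_groups = x$k,
                 n_functions = length(x$eigenvalues),
                 top3_cumulative_pct = x$cumulative_pct[min(3, length(x$cumulative_pct))],
                 ridged = x$ridged)
}

#' @rdname canonical_lda
#' @param object A `canonical_lda` object (for [autoplot()]).
#' @export
autoplot.canonical_lda <- function(object, ...) {
  d <- tibble::tibble(
    LD1 = object$scores[, 1],
    LD2 = if (ncol(object$scores) >= 2) object$scores[, 2] else 0,
    group = object$groups
  )
  cen <- tibble::as_tibble(object$centroids, rownames = "group")
  if (!"LD2" %in% names(cen)) cen$LD2 <- 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_label(data = cen,
                        ggplot2::aes(label = .data$group), show.legend = FALSE) +
    ggplot2::labs(x = "Canonical function 1", y = "Canonical function 2",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

# Wilks' lambda of a variable subset: det(W_S) / det(T_S)
wilks_lambda <- function(W, T, sel) {
  if (length(sel) == 0) return(1)
  dW <- det(W[sel, sel, drop = FALSE])
  dT <- det(T[sel, sel, drop = FALSE])
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  max(dW / dT, 0)
}

#' Stepwise variable selection by Wilks' lambda
#'
#' Greedy stepwise selection for discriminant analysis: at each step the
#' candidate variable with the largest partial F-to-enter joins the model
#' if its F is at least `f_enter`, then any selected variable whose partial
#' F-to-remove has fallen below `f_remove` is dropped. Entry requires a
#' strict improvement of Wilks' lambda, which guarantees termination and
#' keeps exact duplicates of an already selected variable out of the model.
#'
#' @inheritParams canonical_lda
#' @param f_enter,f_remove F thresholds to enter / remove (conventional
#'   defaults 3.84 and 2.71).
#' @param tol Minimum relative lambda improvement treated as real.
#'
#' @return Character vector of selected trait names, in entry order
#'   (possibly empty).
#' @export
stepwise_select <- function(values, groups, traits = NULL,
                            f_enter = 3.84, f_remove = 2.71, tol = 1e-10) {
  v <- tibble::as_tibble(values)
  if (is.data.frame(groups)) {
    j <- dplyr::inner_join(v, groups[, c("genotype_id", "group_index")],
                           by = "genotype_id")
    g <- factor(j$group_index)
    v <- j
  } else {
    g <- factor(groups)
  }
  if (is.null(traits)) {
    traits <- setdiff(trait_columns_of(v), "group_index")
  }
  x <- as.matrix(v[, traits])
  g <- droplevels(g)
  n <- nrow(x)
  k <- nlevels(g)
  gm <- rowsum(x, g) / as.vector(table(g))
  xw <- x - gm[as.integer(g), , drop = FALSE]
  W <- crossprod(xw)
  xc <- sweep(x, 2, colMeans(x))
  T <- crossprod(xc)

  partial_f <- function(lam_small, lam_big, q) {
    # F for the change from a q-variable model (lambda = lam_small) to a
    # (q+1)-variable model (lambda = lam_big)
    if (is.na(lam_big) || lam_big <= 0) return(Inf)
    ((n - k - q) / (k - 1)) * (lam_small / lam_big - 1)
  }

  sel <- integer(0)
  seen <- character(0)
  repeat {
    key <- paste(sort(sel), collapse = ",")
    if (key %in% seen) break  # a selection may never repeat
    seen <- c(seen, key)
    moved <- FALSE
    lam_cur <- wilks_lambda(W, T, sel)
    # entry scan
    cand <- setdiff(seq_along(traits), sel)
    if (length(cand) > 0) {
      lam_new <- vapply(cand, function(i) wilks_lambda(W, T, c(sel, i)),
                        numeric(1))
      improves <- !is.na(lam_new) & lam_new < lam_cur * (1 - tol)
      if (any(improves)) {
        fs <- rep(-Inf, length(cand))
        fs[improves] <- vapply(which(improves), function(ii) {
          partial_f(lam_cur, lam_new[ii], length(sel))
        }, numeric(1))
        best <- which.max(fs)
        if (fs[best] >= f_enter) {
          sel <- c(sel, cand[best])
          moved <- TRUE
        }
      }
    }
    # removal scan
    if (length(sel) > 1) {
      lam_cur <- wilks_lambda(W, T, sel)
      frem <- vapply(seq_along(sel), function(ii) {
        lam_wo <- wilks_lambda(W, T, sel[-ii])
        partial_f(lam_wo, lam_cur, length(sel) - 1)
      }, numeric(1))
      worst <- which.min(frem)
      if (frem[worst] < f_remove) {
        sel <- sel[-worst]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  traits[sel]
}
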