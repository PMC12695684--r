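test_that("eigenvalue-to-canonical-correlation map is exact", {
  expect_equal(canonical_correlation(0), 0)
  lam <- c(0.25, 1, 4)
  r <- canonical_correlation(lam)
  expect_equal(r^2 * (1 + lam), lam, tolerance = 1e-12)
  expect_error(canonical_correlation(-1))
})

test_that("two groups, one variable: eigenvalue equals the scatter ratio", {
  v <- tibble::tibble(x = c(0, 1, 2, 3))
  g <- c(1, 1, 2, 2)
  fit <- canonical_lda(v, g, traits = "x")
  # W = 0.5 + 0.5 = 1, B = 2*(0.5-1.5)^2 + 2*(2.5-1.5)^2 = 4
  expect_equal(fit$eigenvalues, 4, tolerance = 1e-10)
  expect_equal(fit$canonical_correlation, sqrt(4 / 5), tolerance = 1e-10)
})

test_that("identical group means give vanishing eigenvalues", {
  set.seed(40)
  x <- matrix(rnorm(40), 20, 2)
  x2 <- rbind(x, x)  # second group is an exact copy: equal means
  g <- rep(1:2, each = 20)
  fit <- canonical_lda(tibble::as_tibble(as.data.frame(x2)), g,
                       traits = c("V1", "V2"))
  expect_true(all(fit$eigenvalues <= 1e-12))
})

test_that("eigenvalues match the brute-force scatter oracle", {
  set.seed(41)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    p <- sample(2:5, 1)
    n <- sample((k * 3):40, 1)
    g <- c(1:k, sample(1:k, n - k, replace = TRUE))
    x <- matrix(rnorm(n * p), n, p) +
      matrix(rnorm(k * p, sd = 2), k, p)[g, ]
    v <- tibble::as_tibble(as.data.frame(x))
    fit <- canonical_lda(v, g, traits = names(v))
    oracle <- lda_scatter_oracle(x, g)[seq_len(min(k - 1, p))]
    expect_equal(fit$eigenvalues, oracle,
                 tolerance = 1e-8 * max(1, max(oracle)))
  }
})

test_that("model invariants hold on a structured dataset", {
  set.seed(42)
  sim <- simulate_dataset(simulation_config(seed = 99))
  tr <- derive_traits(sim$measurements, trait_config(1000))
  adj <- adjust_augmented(tr, sim$layout)
  cond <- adj[adj$condition == "normal", ]
  cls <- classify_genotypes(cond)
  traits <- c("root_length", "root_tissue_density", "root_fineness",
              "root_volume", "root_area", "root_diameter")
  fit <- canonical_lda(cond, cls, traits = traits)
  # eigenvalues descending, percentages summing to 100
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_equal(sum(fit$pct_variance), 100, tolerance = 0.1)
  # Table-style identity between eigenvalue and canonical correlation
  expect_equal(fit$canonical_correlation^2 * (1 + fit$eigenvalues),
               fit$eigenvalues, tolerance = 1e-9)
  # size-weighted centroid mean vanishes
  sizes <- as.vector(table(fit$groups))
  wmean <- colSums(fit$centroids * sizes) / sum(sizes)
  expect_lt(max(abs(wmean)), 1e-8)
  # within-group variance of every canonical score is 1
  xw <- fit$scores - fit$centroids[as.integer(fit$groups), ]
  expect_equal(colSums(xw^2) / (fit$n - fit$k),
               rep(1, length(fit$eigenvalues)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # tidy/glance surface the same numbers
  td <- tidy(fit)
  expect_equal(td$eigenvalue, fit$eigenvalues)
  expect_equal(glance(fit)$n_groups, fit$k)
})

test_that("structure matrix holds pooled within-group correlations", {
  set.seed(43)
  x <- matrix(rnorm(60), 20, 3)
  g <- rep(1:2, each = 10)
  x[g == 2, 1] <- x[g == 2, 1] + 3
  v <- tibble::as_tibble(as.data.frame(x))
  fit <- canonical_lda(v, g, traits = names(v))
  gm <- rowsum(x, g) / 10
  xw <- x - gm[g, ]
  sw <- fit$scores - fit$centroids[g, , drop = FALSE]
  manual <- cor(xw, sw)
  expect_equal(unname(fit$structure), unname(manual), tolerance = 1e-8)
})

test_that("singular within-group scatter falls back to ridge", {
  v <- tibble::tibble(x = c(1, 1, 2, 2, 3, 3), y = c(2, 2, 4, 4, 6, 6))
  expect_warning(fit <- canonical_lda(v, rep(1:3, each = 2),
                                      traits = c("x", "y")),
                 "ridge")
  expect_true(fit$ridged)
})

test_that("stepwise selection finds the separating variable", {
  set.seed(44)
  g <- rep(1:3, each = 10)
  v <- tibble::tibble(
    signal = g * 5 + rnorm(30, sd = 0.3),
    noise1 = rnorm(30),
    noise2 = rnorm(30)
  )
  sel <- stepwise_select(v, g, traits = c("noise1", "signal", "noise2"))
  expect_equal(sel[1], "signal")
  # infinite entry threshold selects nothing
  expect_length(stepwise_select(v, g, f_enter = Inf), 0)
  # an exact duplicate never enters
  v2 <- dplyr::mutate(v, signal_copy = signal)
  sel2 <- stepwise_select(v2, g,
                          traits = c("signal", "signal_copy", "noise1"))
  expect_false(all(c("signal", "signal_copy") %in% sel2))
})
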