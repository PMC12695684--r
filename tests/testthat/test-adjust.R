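test_that("equal check values give zero block effects", {
  lay <- tiny_layout()
  g <- stats::setNames(rep(5, 8), 1:8)
  tab <- additive_table(lay, g, b_effects = c(0, 0))
  eff <- estimate_block_effects(tab, lay, traits = "y")
  expect_true(all(eff$effect == 0))
})

test_that("two-block check means 10 and 12 give effects -1 and +1", {
  lay <- design_layout(2, check_ids = c(1, 2), test_ids = 3:4,
                       conditions = "normal")
  tab <- tibble::tibble(
    genotype_id = c(1, 2, 3, 1, 2, 4),
    is_check = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    block = c(1, 1, 1, 2, 2, 2),
    condition = "normal",
    y = c(9, 11, 7, 11, 13, 8)  # check means 10 (block 1) and 12 (block 2)
  )
  eff <- estimate_block_effects(tab, lay, traits = "y")
  expect_equal(eff$effect, c(-1, 1))
})

test_that("noise-free additive data recovers block and genotype effects", {
  set.seed(10)
  for (i in 1:10) {
    lay <- tiny_layout()
    g <- stats::setNames(rnorm(8, 10, 3), 1:8)
    b <- rnorm(2, 0, 2)
    tab <- additive_table(lay, g, b, cond_shift = rnorm(1))
    eff <- estimate_block_effects(tab, lay, traits = "y")
    for (cond in lay$conditions) {
      e <- eff$effect[eff$condition == cond]
      expect_equal(e, b - mean(b), tolerance = 1e-10)
    }
    adj <- adjust_augmented(tab, lay, traits = "y")
    for (cond in lay$conditions) {
      a <- adj[adj$condition == cond, ]
      ords <- match(a$genotype_id, as.integer(names(g)))
      # contrasts between genotypes equal true contrasts exactly
      expect_lt(max(abs((a$y - g[ords]) - mean(a$y - g[ords]))), 1e-10)
    }
  }
})

test_that("known block effects match spreadsheet-style subtraction", {
  b <- c(2, -1, 0, 3, -4)
  lay <- design_layout(5, check_ids = c(1, 2), test_ids = 3:12,
                       conditions = "normal")
  set.seed(11)
  g <- stats::setNames(rnorm(12, 20, 4), 1:12)
  tab <- additive_table(lay, g, b)
  eff <- estimate_block_effects(tab, lay, traits = "y")
  adj <- adjust_augmented(tab, lay, eff, traits = "y")
  # brute-force oracle: subtract the block's estimated effect row by row
  eff_lookup <- stats::setNames(eff$effect, eff$block)
  manual <- tab
  manual$adj <- manual$y - eff_lookup[as.character(manual$block)]
  expected <- tapply(manual$adj, manual$genotype_id, mean)
  expect_equal(adj$y, as.numeric(expected[as.character(adj$genotype_id)]),
               tolerance = 1e-12)
})

test_that("zero effects reduce adjustment to per-genotype means", {
  m <- tiny_measurements(seed = 31)
  tr <- derive_traits(m, trait_config(1000))
  lay <- tiny_layout()
  eff <- estimate_block_effects(tr, lay, traits = "root_length")
  eff$effect <- 0
  adj <- adjust_augmented(tr, lay, eff, traits = "root_length")
  raw_means <- tr |>
    dplyr::group_by(genotype_id, condition) |>
    dplyr::summarise(m = mean(root_length), .groups = "drop")
  j <- dplyr::inner_join(adj, raw_means, by = c("genotype_id", "condition"))
  expect_equal(j$root_length, j$m, tolerance = 1e-12)
  expect_setequal(unique(adj$provenance), c("check_mean", "test_adjusted"))
})

test_that("adding a constant to one block leaves contrasts invariant", {
  set.seed(12)
  lay <- tiny_layout()
  m <- tiny_measurements(seed = 33)
  tr <- derive_traits(m, trait_config(1000))
  adj1 <- adjust_augmented(tr, lay, traits = "root_length")
  tr2 <- tr
  shift <- tr2$block == 2 & tr2$condition == "normal"
  tr2$root_length[shift] <- tr2$root_length[shift] + 7.5
  adj2 <- adjust_augmented(tr2, lay, traits = "root_length")
  for (cond in lay$conditions) {
    d1 <- adj1$root_length[adj1$condition == cond]
    d2 <- adj2$root_length[adj2$condition == cond]
    expect_lt(max(abs((d1 - mean(d1)) - (d2 - mean(d2)))), 1e-10)
  }
})

test_that("missing observations raise design errors", {
  lay <- tiny_layout()
  m <- tiny_measurements(seed = 35)
  tr <- derive_traits(m, trait_config(1000))
  no_check <- tr[!(tr$genotype_id == 1 & tr$block == 1 &
                     tr$condition == "normal"), ]
  expect_error(estimate_block_effects(no_check, lay, traits = "root_length"),
               "design error")
  no_geno <- tr[tr$genotype_id != 5, ]
  expect_error(adjust_augmented(no_geno, lay, traits = "root_length"),
               "no observation")
})

test_that("factorial check ANOVA recovers a pure condition shift", {
  lay <- tiny_layout()
  delta <- 3
  g <- stats::setNames(rep(10, 8), 1:8)
  tab <- additive_table(lay, g, b_effects = c(0, 0), cond_shift = delta)
  # the noise-free fit is perfect: only the sums of squares are asserted
  a <- suppressWarnings(factorial_check_anova(tab, lay, "y"))
  # closed form for the balanced two-way layout on checks:
  # SS_stress = n_checks_total * delta^2 / 4 summed over the two halves
  n_half <- sum(tab$is_check) / 2
  expect_equal(a$sumsq[a$term == "stress"], 2 * n_half * (delta / 2)^2,
               tolerance = 1e-9)
  expect_equal(a$sumsq[a$term == "genotype:stress"], 0, tolerance = 1e-9)
  expect_equal(a$sumsq[a$term == "genotype"], 0, tolerance = 1e-9)
})

test_that("factorial ANOVA partitions total SS and handles degeneracy", {
  set.seed(13)
  lay <- tiny_layout()
  for (i in 1:10) {
    m <- tiny_measurements(seed = 100 + i)
    tr <- derive_traits(m, trait_config(1000))
    a <- factorial_check_anova(tr, lay, "root_length")
    y <- tr$root_length[tr$is_check]
    expect_equal(sum(a$sumsq), sum((y - mean(y))^2),
                 tolerance = 1e-9 * sum(a$sumsq))
    expect_equal(sum(a$df), length(y) - 1)
  }
  flat <- derive_traits(tiny_measurements(seed = 1), trait_config(1000))
  flat$root_length <- 5
  a0 <- factorial_check_anova(flat, lay, "root_length")
  expect_true(all(a0$sumsq == 0))
  expect_equal(a0$p[1:3], rep(1, 3))
})
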