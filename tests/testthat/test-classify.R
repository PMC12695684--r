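adjusted_fixture <- function(rl, rtd, condition = "normal") {
  tibble::tibble(genotype_id = seq_along(rl), condition = condition,
                 root_length = rl, root_tissue_density = rtd)
}

test_that("confidence interval matches the hand t-calculation", {
  ci <- compute_ci(c(1, 2, 3), alpha = 0.05)
  half <- qt(0.975, df = 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(ci$mean, 2)
  expect_equal(ci$upper - ci$mean, half, tolerance = 1e-12)
  expect_equal(ci$upper - ci$mean, 2.4841377, tolerance = 1e-6)
  expect_equal(ci$n, 3)
})

test_that("degenerate and scaled intervals behave as required", {
  ci0 <- compute_ci(c(5, 5, 5, 5))
  expect_equal(ci0$lower, 5)
  expect_equal(ci0$upper, 5)
  ci <- compute_ci(c(1, 4, 9, 12))
  ci2 <- compute_ci(2 * c(1, 4, 9, 12))
  expect_equal(unlist(ci2[c("mean", "lower", "upper")]),
               2 * unlist(ci[c("mean", "lower", "upper")]),
               tolerance = 1e-12)
  expect_error(compute_ci(3), "at least 2")
})

test_that("classification partitions genotypes with closed middle interval", {
  set.seed(20)
  for (i in 1:10) {
    n <- 30
    adj <- adjusted_fixture(rnorm(n, 20, 6), rnorm(n, 0.1, 0.04))
    cls <- classify_genotypes(adj)
    expect_equal(nrow(cls), n)
    expect_false(anyNA(cls$depth_class))
    expect_false(anyNA(cls$density_class))
    expect_equal(cls$group_index,
                 3 * (as.integer(cls$depth_class) - 1) +
                   as.integer(cls$density_class))
    # manual reclassification against the interval
    ci <- compute_ci(adj$root_length)
    manual <- ifelse(adj$root_length < ci$lower, "superficial",
                     ifelse(adj$root_length > ci$upper, "deep", "semi_deep"))
    expect_equal(as.character(cls$depth_class), manual)
  }
})

test_that("boundary values fall in the middle class (closed interval)", {
  vals <- c(1, 2, 3, 4, 10)
  ci <- compute_ci(vals)
  adj <- adjusted_fixture(c(vals, ci$lower, ci$upper),
                          rep(0.1, length(vals) + 2))
  # freeze the interval: boundary rows must not move it, so classify
  # against the enlarged cohort and check only the boundary rows
  cls <- classify_genotypes(adj)
  ci2 <- compute_ci(adj$root_length)
  at_bounds <- which(adj$root_length %in% c(ci2$lower, ci2$upper))
  expect_true(all(cls$depth_class[abs(adj$root_length - ci2$lower) < 1e-12 |
                                    abs(adj$root_length - ci2$upper) < 1e-12]
                  == "semi_deep"))
})

test_that("identical genotypes all land in the central group", {
  adj <- adjusted_fixture(rep(7, 10), rep(0.2, 10))
  cls <- classify_genotypes(adj)
  expect_true(all(cls$group_index == 5))
})

test_that("classification is invariant under positive affine maps", {
  set.seed(21)
  adj <- adjusted_fixture(rnorm(40, 25, 8), rnorm(40, 0.12, 0.05))
  base <- classify_genotypes(adj)
  for (i in 1:25) {
    a <- runif(2, 0.05, 20)
    b <- runif(2, -50, 50)
    mapped <- adj
    mapped$root_length <- a[1] * adj$root_length + b[1]
    mapped$root_tissue_density <- a[2] * adj$root_tissue_density + b[2]
    cls <- classify_genotypes(mapped)
    expect_identical(cls$depth_class, base$depth_class)
    expect_identical(cls$density_class, base$density_class)
  }
})

test_that("with a frozen interval, classification is monotone in the value", {
  vals <- c(2, 4, 6, 8, 20)
  ci <- compute_ci(vals)
  rank_of <- function(x) {
    ifelse(x < ci$lower, 1L, ifelse(x > ci$upper, 3L, 2L))
  }
  xs <- seq(0, 25, by = 0.25)
  expect_true(all(diff(rank_of(xs)) >= 0))
})

test_that("nine-group tally reproduces known marginals and cells", {
  wb <- wild_barley_groups()
  tn <- tally_groups(wb, condition = "normal")
  mn <- tally_margins(tn)
  expect_equal(unname(mn$depth), c(19, 63, 32))
  expect_equal(unname(mn$density), c(42, 53, 19))
  expect_equal(mn$total, 114)
  expect_equal(tn$n[tn$group_index == 9], 5)
  ts <- tally_groups(wb, condition = "stress")
  ms <- tally_margins(ts)
  expect_equal(unname(ms$depth)[2], 64)
  expect_equal(ts$n[ts$group_index == 9], 3)
})

test_that("empty assignments tally to zero", {
  wb <- wild_barley_groups()[0, ]
  t0 <- tally_groups(wb, condition = "normal")
  expect_equal(sum(t0$n), 0)
  expect_equal(nrow(t0), 9)
})

test_that("stability report flags transitions correctly", {
  wb <- wild_barley_groups()
  rep <- stability_report(wb)
  expect_equal(nrow(rep), 114)
  g111 <- rep[rep$genotype_id == 111, ]
  expect_false(g111$changed)
  expect_equal(g111$group_index_normal, 9)
  expect_equal(g111$group_index_stress, 9)

  # identical tables in both conditions: nothing changes
  same <- dplyr::bind_rows(
    adjusted_fixture(1:10, seq(0.1, 1, 0.1), condition = "normal"),
    adjusted_fixture(1:10, seq(0.1, 1, 0.1), condition = "stress")
  )
  cls <- classify_genotypes(same)
  expect_false(any(stability_report(cls)$changed))

  # shifting exactly one genotype above the upper bound flips exactly one
  shifted <- same
  i <- which(shifted$condition == "stress" & shifted$genotype_id == 5)
  ci <- compute_ci(same$root_length[same$condition == "stress"])
  shifted$root_length[i] <- ci$upper + 100
  cls2 <- classify_genotypes(shifted)
  ch <- stability_report(cls2)
  # genotype 5 moved; its removal from the middle may not move others
  expect_true(ch$changed[ch$genotype_id == 5])

  expect_error(stability_report(cls[cls$condition == "normal", ]),
               "report error")
})
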