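# Small design used by most unit tests: 2 checks + 6 tests in 2 blocks,
# two conditions (10 tubes per condition).
tiny_layout <- function() {
  design_layout(n_blocks = 2, check_ids = c(1, 2), test_ids = 3:8)
}

tiny_sim_config <- function(seed, ...) {
  simulation_config(seed = seed, n_tests = 6, check_ids = c(1, 2),
                    n_blocks = 2, ...)
}

tiny_measurements <- function(seed = 42) {
  simulate_dataset(tiny_sim_config(seed))$measurements
}

# Additive noise-free trait table y = genotype + block (+ condition shift),
# for exactness checks of the augmented-design adjustment.
additive_table <- function(layout, g_effects, b_effects, cond_shift = 0,
                           trait = "y") {
  conds <- layout$conditions
  rows <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    plan <- rbind(
      expand.grid(genotype_id = layout$check_ids,
                  block = seq_len(layout$n_blocks)),
      data.frame(genotype_id = layout$test_ids,
                 block = rep(seq_len(layout$n_blocks),
                             each = layout$tests_per_block))
    )
    plan$is_check <- plan$genotype_id %in% layout$check_ids
    plan$condition <- cond
    plan[[trait]] <- g_effects[as.character(plan$genotype_id)] +
      b_effects[plan$block] + (ci - 1) * cond_shift
    rows[[cond]] <- plan
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Brute-force within/between scatter matrices and the generalized
# eigenvalues of W^-1 B, written with explicit loops so it is independent
# of the canonical_lda implementation path.
lda_scatter_oracle <- function(x, g) {
  g <- factor(g)
  p <- ncol(x)
  grand <- colMeans(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lev in levels(g)) {
    xg <- x[g == lev, , drop = FALSE]
    mg <- colMeans(xg)
    for (i in seq_len(nrow(xg))) {
      d <- xg[i, ] - mg
      W <- W + outer(d, d)
    }
    dm <- mg - grand
    B <- B + nrow(xg) * outer(dm, dm)
  }
  ev <- eigen(solve(W) %*% B, only.values = TRUE)$values
  ev <- Re(ev[abs(Im(ev)) < 1e-8])
  sort(pmax(ev, 0), decreasing = TRUE)
}
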