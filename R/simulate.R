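# Gaussian sampler truncated below by resampling (no point mass at the
# bound). sd = 0 degenerates to the mean, which must respect the bound.
rnorm_trunc <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  if (all(sd == 0)) {
    if (any(mean < lower)) {
      stop("degenerate truncation: mean below lower bound with sd = 0",
           call. = FALSE)
    }
    return(mean)
  }
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- x <= lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd)
  }
  stop("truncated sampling failed to converge", call. = FALSE)
}

#' Configuration of the synthetic augmented-design generator
#'
#' Defines the simulated study conditions. Defaults emulate the reference
#' design: 105 unreplicated test genotypes plus 9 checks in 5 blocks of 30
#' tubes under two moisture regimes (300 tubes). Root length (cm) carries
#' the latent depth classes and root tissue density (g cm^3, product
#' convention) the latent density classes; adjacent class means are
#' separated by three measurement-noise standard deviations on each trait.
#'
#' @param seed Integer RNG seed (required).
#' @param n_tests Number of unreplicated test genotypes.
#' @param check_ids Labels of the replicated check genotypes.
#' @param n_blocks Blocks per condition.
#' @param conditions Condition names; the second one receives
#'   `stress_shift`.
#' @param block_sd SD of additive block effects on root length (cm);
#'   scaled onto root tissue density by the ratio of the two traits' class
#'   separations.
#' @param noise_sd SD of tube-level measurement noise on root length (cm);
#'   scaled onto root tissue density likewise.
#' @param depth_class_means Root-length means (cm) of the superficial /
#'   semi-deep / deep classes.
#' @param density_class_means Root-tissue-density means of the non-dense /
#'   semi-dense / dense classes.
#' @param class_proportions List with simplex vectors `depth` and
#'   `density`: latent class membership probabilities.
#' @param stress_shift Named list of additive shifts applied under the
#'   stress condition (root_length cm, root_tissue_density, seedling_length
#'   cm, a663 absorbance units).
#' @param trait_correlation Latent correlation between the depth and
#'   density class propensities.
#' @param genotype_sd_frac Within-class genotype effect SD as a fraction of
#'   `noise_sd`.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_tests = 105,
                              check_ids = c(1, 10, 24, 34, 35, 51, 74, 104, 113),
                              n_blocks = 5,
                              conditions = c("normal", "stress"),
                              block_sd = 2,
                              noise_sd = 3,
                              depth_class_means = c(15, 24, 33),
                              density_class_means = c(0.06, 0.12, 0.18),
                              class_proportions = list(
                                depth = c(0.44, 0.12, 0.44),
                                density = c(0.44, 0.12, 0.44)
                              ),
                              stress_shift = list(
                                root_length = -3,
                                root_tissue_density = -0.015,
                                seedling_length = -4,
                                a663 = -0.12
                              ),
                              trait_correlation = 0.3,
                              genotype_sd_frac = 0.2) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1,
            block_sd >= 0, noise_sd >= 0,
            length(depth_class_means) == 3, length(density_class_means) == 3,
            abs(sum(class_proportions$depth) - 1) < 1e-8,
            abs(sum(class_proportions$density) - 1) < 1e-8,
            all(class_proportions$depth >= 0),
            all(class_proportions$density >= 0),
            abs(trait_correlation) < 1, genotype_sd_frac >= 0,
            length(conditions) == 2)
  if (n_tests %% n_blocks != 0) {
    stop("config error: n_tests (", n_tests, ") not divisible by n_blocks (",
         n_blocks, "); leaves remainder ", n_tests %% n_blocks,
         " - choose counts that tile the blocks", call. = FALSE)
  }
  if (any(diff(depth_class_means) <= 0) || any(diff(density_class_means) <= 0)) {
    warning("class means not strictly increasing: latent classes are not ",
            "identifiable", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_tests = as.integer(n_tests),
    check_ids = sort(as.integer(check_ids)), n_blocks = as.integer(n_blocks),
    conditions = conditions, block_sd = block_sd, noise_sd = noise_sd,
    depth_class_means = depth_class_means,
    density_class_means = density_class_means,
    class_proportions = class_proportions, stress_shift = stress_shift,
    trait_correlation = trait_correlation, genotype_sd_frac = genotype_sd_frac
  ), class = "simulation_config")
}

#' Layout implied by a simulation config
#' @param config A [simulation_config()].
#' @return A [design_layout()].
#' @export
layout_of <- function(config) {
  max_id <- max(config$check_ids, config$n_tests + length(config$check_ids))
  design_layout(
    n_blocks = config$n_blocks,
    check_ids = config$check_ids,
    test_ids = setdiff(seq_len(config$n_tests + length(config$check_ids)),
                       config$check_ids),
    conditions = config$conditions
  )
}

#' Simulate an augmented-design seedling phenotyping dataset
#'
#' Draws a complete tube-level measurement table with the statistical
#' structure the analysis pipeline assumes: latent depth and density
#' classes per genotype (correlated propensities), additive genotype,
#' block and condition effects with Gaussian tube noise on root length and
#' root tissue density, and secondary traits (weights, volume, seedling
#' traits, absorbances) generated from documented linear maps with noise.
#' Root tissue density is induced by co-generating root volume and dry
#' weight so their product hits the latent target. All positive quantities
#' are truncated at plausible lower bounds by resampling. One value per
#' tube is emitted (the per-tube plant mean). Fully reproducible from
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#'
#' @return A list with `measurements` (tube-level tibble in the
#'   measurement schema), `truth` (list of `genotypes` and `blocks`
#'   tibbles with the latent classes and effects) and `layout`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  layout <- layout_of(cfg)
  ids <- c(layout$check_ids, layout$test_ids)
  n_geno <- length(ids)

  # latent correlated propensities -> classes by proportion quantiles
  rho <- cfg$trait_correlation
  z1 <- stats::rnorm(n_geno)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_geno)
  cutpoints <- function(p) stats::qnorm(cumsum(p)[1:2])
  classify_latent <- function(z, p, levels) {
    cp <- cutpoints(p)
    factor(levels[findInterval(z, cp) + 1], levels = levels)
  }
  depth <- classify_latent(z1, cfg$class_proportions$depth, depth_levels())
  density <- classify_latent(z2, cfg$class_proportions$density,
                             density_levels())

  sep_len <- mean(diff(cfg$depth_class_means))
  sep_den <- mean(diff(cfg$density_class_means))
  # map cm-scale sds onto the density scale; with flat class means fall
  # back to the ratio of the trait magnitudes
  den_scale <- if (sep_len > 0 && sep_den > 0) {
    sep_den / sep_len
  } else {
    mean(cfg$density_class_means) / mean(cfg$depth_class_means)
  }
  g_sd <- cfg$genotype_sd_frac * cfg$noise_sd

  geno <- tibble::tibble(
    genotype_id = ids,
    is_check = ids %in% layout$check_ids,
    depth_class = depth,
    density_class = density,
    length_effect = cfg$depth_class_means[as.integer(depth)] +
      stats::rnorm(n_geno, 0, g_sd),
    density_effect = cfg$density_class_means[as.integer(density)] +
      stats::rnorm(n_geno, 0, g_sd * den_scale)
  )

  blocks <- tidyr::expand_grid(condition = cfg$conditions,
                               block = seq_len(cfg$n_blocks))
  blocks$length_effect <- stats::rnorm(nrow(blocks), 0, cfg$block_sd)
  blocks$density_effect <- stats::rnorm(nrow(blocks), 0,
                                        cfg$block_sd * den_scale)

  rows <- list()
  for (cond in cfg$conditions) {
    stressed <- cond == cfg$conditions[2]
    sh <- function(name) if (stressed) cfg$stress_shift[[name]] else 0
    # tests randomized over blocks; checks in every block
    test_block <- rep(seq_len(cfg$n_blocks), each = layout$tests_per_block)
    test_block <- test_block[order(stats::runif(length(test_block)))]
    plan <- dplyr::bind_rows(
      tidyr::expand_grid(genotype_id = layout$check_ids,
                         block = seq_len(cfg$n_blocks)),
      tibble::tibble(genotype_id = layout$test_ids, block = test_block)
    )
    plan$condition <- cond
    plan <- dplyr::inner_join(plan, geno, by = "genotype_id")
    plan <- dplyr::inner_join(
      plan, blocks, by = c("condition", "block"),
      suffix = c("_geno", "_block")
    )
    nt <- nrow(plan)
    rl <- rnorm_trunc(nt,
                      plan$length_effect_geno + plan$length_effect_block +
                        sh("root_length"),
                      cfg$noise_sd, lower = 0.5)
    rtd <- rnorm_trunc(nt,
                       plan$density_effect_geno + plan$density_effect_block +
                         sh("root_tissue_density"),
                       cfg$noise_sd * den_scale, lower = 0.005)
    vol <- rnorm_trunc(nt, 0.25 + 0.01 * rl, 0.05, lower = 0.05)
    dw <- rtd / vol  # product-convention tissue density hits rtd exactly
    flesh <- rnorm_trunc(nt, 0.9 * vol, 0.05, lower = 0.01)
    fw <- dw + flesh
    sl <- rnorm_trunc(nt, 15 + 0.9 * rl + sh("seedling_length"), 2, lower = 1)
    sfw <- rnorm_trunc(nt, 0.15 + 0.012 * sl, 0.03, lower = 0.02)
    frac <- rnorm_trunc(nt, 0.13, 0.02, lower = 0.03)
    frac <- pmin(frac, 0.6)
    sdw <- frac * sfw
    a663 <- rnorm_trunc(nt, 0.85 + sh("a663"), 0.07, lower = 0.05)
    a646 <- rnorm_trunc(nt, 0.42 * a663, 0.03, lower = 0.01)
    a470 <- rnorm_trunc(nt, 0.55 * a663, 0.04, lower = 0.01)
    rows[[cond]] <- tibble::tibble(
      genotype_id = plan$genotype_id,
      is_check = plan$is_check,
      block = plan$block,
      condition = cond,
      root_length_cm = rl,
      root_fresh_weight_g = fw,
      root_dry_weight_g = dw,
      root_volume_cm3 = vol,
      seedling_length_cm = sl,
      seedling_fresh_weight_g = sfw,
      seedling_dry_weight_g = sdw,
      a663 = a663, a646 = a646, a470 = a470
    )
  }
  measurements <- dplyr::arrange(dplyr::bind_rows(rows),
                                 .data$condition, .data$block,
                                 .data$genotype_id)
  list(measurements = measurements,
       truth = list(genotypes = geno, blocks = blocks,
                    stress_shift = cfg$stress_shift),
       layout = layout)
}

#' Parameter-recovery benchmark of the full pipeline
#'
#' Runs simulate -> derive -> adjust -> classify over `n_reps` replicates
#' (seeds `config$seed`, `config$seed + 1`, ...) and reports, per
#' replicate, the fraction of genotype-condition pairs whose depth and
#' density classes match the latent ground truth, and the RMSE of the
#' recovered root-length block effects against the true (centered) ones.
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param soil_volume Tube soil volume handed to [trait_config()].
#'
#' @return A list with `reps` (per-replicate tibble: `rep`,
#'   `depth_recovery`, `density_recovery`, `recovery`, `block_rmse`) and
#'   `summary` (their means plus `non_identifiable`, flagged when adjacent
#'   latent class means are separated by less than one noise SD).
#' @export
recovery_benchmark <- function(config, n_reps, soil_volume = 1000) {
  stopifnot(inherits(config, "simulation_config"), n_reps >= 1)
  tc <- trait_config(soil_volume = soil_volume)
  out <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_dataset(cfg)
    traits <- derive_traits(sim$measurements, tc)
    adj <- adjust_augmented(traits, sim$layout,
                            traits = c("root_length", "root_tissue_density"))
    cls <- classify_genotypes(adj)
    truth <- sim$truth$genotypes[, c("genotype_id", "depth_class",
                                     "density_class")]
    j <- dplyr::inner_join(cls, truth, by = "genotype_id",
                           suffix = c("", "_true"))
    eff <- estimate_block_effects(traits, sim$layout,
                                  traits = "root_length")
    true_b <- sim$truth$blocks |>
      dplyr::group_by(.data$condition) |>
      dplyr::mutate(true_effect = .data$length_effect -
                      mean(.data$length_effect)) |>
      dplyr::ungroup()
    be <- dplyr::inner_join(eff, true_b[, c("condition", "block",
                                            "true_effect")],
                            by = c("condition", "block"))
    tibble::tibble(
      rep = r,
      depth_recovery = mean(j$depth_class == j$depth_class_true),
      density_recovery = mean(j$density_class == j$density_class_true),
      recovery = (mean(j$depth_class == j$depth_class_true) +
                    mean(j$density_class == j$density_class_true)) / 2,
      block_rmse = sqrt(mean((be$effect - be$true_effect)^2))
    )
  })
  min_sep <- min(diff(config$depth_class_means) /
                   max(config$noise_sd, .Machine$double.eps),
                 diff(config$density_class_means) /
                   max(config$noise_sd *
                         mean(diff(config$density_class_means)) /
                         mean(diff(config$depth_class_means)),
                       .Machine$double.eps))
  list(
    reps = out,
    summary = tibble::tibble(
      n_reps = n_reps,
      mean_depth_recovery = mean(out$depth_recovery),
      mean_density_recovery = mean(out$density_recovery),
      mean_recovery = mean(out$recovery),
      mean_block_rmse = mean(out$block_rmse),
      non_identifiable = !all(is.finite(min_sep)) || min_sep < 1
    )
  )
}
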