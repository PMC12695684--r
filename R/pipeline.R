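#' Configuration of a full pipeline run
#'
#' Collects everything a pipeline run needs: either an input measurement
#' CSV or a [simulation_config()], the trait and design configuration,
#' classification level and analysis toggles, and an output directory.
#'
#' @param input Path to a measurement CSV, or `NULL` to simulate.
#' @param simulate A [simulation_config()] used when `input` is `NULL`.
#' @param layout A [design_layout()]; defaults to [barley_layout()] (or the
#'   simulation layout).
#' @param traits A [trait_config()].
#' @param alpha Classification significance level, in (0, 1).
#' @param adjust Apply the check-based block adjustment before
#'   classification (default TRUE); FALSE classifies raw per-genotype
#'   means.
#' @param stepwise Run Wilks stepwise variable selection before the
#'   discriminant analysis (default FALSE: full-variable model).
#' @param correlation_scope `"genotypes"` (default) correlates the
#'   genotype-level adjusted values; `"group_means"` the nine group mean
#'   profiles.
#' @param out_dir Output directory (created if missing).
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, layout = NULL,
                            traits = trait_config(soil_volume = 1000),
                            alpha = 0.05, adjust = TRUE, stepwise = FALSE,
                            correlation_scope = c("genotypes", "group_means"),
                            out_dir = tempfile("rootgroups_run_")) {
  if (is.null(input) && is.null(simulate)) {
    stop("config error: either input or simulate must be given",
         call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("config error: input file does not exist: ", input, call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("config error: alpha must be in (0, 1)", call. = FALSE)
  }
  stopifnot(inherits(traits, "trait_config"))
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_config"))
  correlation_scope <- match.arg(correlation_scope)
  structure(list(
    input = input, simulate = simulate, layout = layout, traits = traits,
    alpha = alpha, adjust = adjust, stepwise = stepwise,
    correlation_scope = correlation_scope, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full root-group analysis pipeline
#'
#' Executes read (or simulate) -> derive traits -> pigments -> check-based
#' adjustment -> nine-group classification -> tallies and stability ->
#' per-trait group ANOVA -> canonical discriminant analysis -> trait
#' correlations -> Ward clustering of group profiles, writing every table
#' as CSV (dendrograms as Newick) plus a JSON run manifest. Rerunning with
#' an identical configuration and inputs reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#'
#' @return The manifest, invisibly: a list with the configuration echo,
#'   output file names and collected warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character(0)
  note <- function(w) warn_log <<- c(warn_log, conditionMessage(w))
  outputs <- character(0)
  emit <- function(tab, name) {
    path <- file.path(config$out_dir, name)
    write_table(tab, path)
    outputs <<- c(outputs, name)
  }

  withCallingHandlers({
    if (is.null(config$input)) {
      sim <- simulate_dataset(config$simulate)
      measurements <- sim$measurements
      layout <- sim$layout
      emit(measurements, "measurements.csv")
      emit(sim$truth$genotypes, "ground_truth_genotypes.csv")
    } else {
      layout <- if (is.null(config$layout)) barley_layout() else config$layout
      measurements <- read_measurements(config$input, layout)
    }

    traits <- derive_traits(measurements, config$traits)
    pig <- compute_pigments(measurements[, c("a663", "a646", "a470")])
    traits <- dplyr::bind_cols(traits, pig[, pigment_names()])
    emit(traits, "trait_table.csv")

    all_traits <- c(trait_names(), pigment_names())
    if (config$adjust) {
      effects <- estimate_block_effects(traits, layout, all_traits)
      adjusted <- adjust_augmented(traits, layout, effects, all_traits)
      emit(effects, "block_effects.csv")
    } else {
      adjusted <- traits |>
        tidyr::pivot_longer(dplyr::all_of(all_traits), names_to = "trait") |>
        dplyr::group_by(.data$genotype_id, .data$condition, .data$trait) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "trait", values_from = "value")
    }
    emit(adjusted, "adjusted_traits.csv")

    assignments <- classify_genotypes(adjusted, alpha = config$alpha)
    emit(assignments, "group_assignments.csv")
    tally <- tally_groups(assignments)
    emit(tally, "group_tally.csv")
    emit(stability_report(assignments, layout$conditions),
         "group_transitions.csv")

    root_traits <- setdiff(trait_names(),
                           c("seedling_length", "seedling_fresh_weight",
                             "seedling_dry_weight"))
    for (cond in layout$conditions) {
      vals <- adjusted[adjusted$condition == cond, ]
      asg <- assignments[assignments$condition == cond, ]
      anova_tab <- purrr::map_dfr(
        root_traits, \(tr) oneway_group_anova(vals, asg, tr))
      emit(anova_tab, paste0("group_anova_", cond, ".csv"))

      lda_traits <- root_traits
      if (config$stepwise) {
        sel <- stepwise_select(vals, asg, traits = root_traits)
        if (length(sel) >= 1) lda_traits <- sel
      }
      fit <- canonical_lda(vals, asg, traits = lda_traits)
      emit(tidy(fit), paste0("discriminant_eigen_", cond, ".csv"))
      emit(tibble::as_tibble(fit$structure, rownames = "trait"),
           paste0("discriminant_structure_", cond, ".csv"))
      emit(tibble::as_tibble(fit$centroids, rownames = "group"),
           paste0("discriminant_centroids_", cond, ".csv"))

      cor_scope <- if (config$correlation_scope == "genotypes") {
        vals
      } else {
        group_profiles(vals, asg)
      }
      emit(tidy(trait_correlations(
        cor_scope, traits = c(all_traits))),
        paste0("correlations_", cond, ".csv"))

      prof <- group_profiles(vals, asg)
      tree <- ward_cluster(prof)
      nwk_name <- paste0("dendrogram_", cond, ".nwk")
      as_newick(tree, file.path(config$out_dir, nwk_name))
      outputs <- c(outputs, nwk_name)
      emit(merge_table(tree), paste0("dendrogram_merges_", cond, ".csv"))
    }
  }, warning = function(w) {
    note(w)
    invokeRestart("muffleWarning")
  })

  manifest <- list(
    package = "rootgroups",
    version = as.character(utils::packageVersion("rootgroups")),
    seed = if (is.null(config$simulate)) NA else config$simulate$seed,
    alpha = config$alpha,
    adjust = config$adjust,
    stepwise = config$stepwise,
    correlation_scope = config$correlation_scope,
    rtd_mode = config$traits$rtd_mode,
    soil_volume = config$traits$soil_volume,
    input = if (is.null(config$input)) "simulated" else config$input,
    outputs = sort(outputs),
    warnings = warn_log
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Mean trait profile per root group
#'
#' @param values Genotype-level trait tibble for one condition.
#' @param assignments Matching classification tibble (joined on
#'   `genotype_id`).
#' @param traits Trait columns to average; defaults to all numeric
#'   non-design columns.
#'
#' @return A tibble with `group_index` and one mean column per trait;
#'   groups with no members are absent.
#' @export
group_profiles <- function(values, assignments, traits = NULL) {
  v <- tibble::as_tibble(values)
  if (is.null(traits)) traits <- trait_columns_of(v)
  j <- dplyr::inner_join(v, assignments[, c("genotype_id", "group_index")],
                         by = "genotype_id")
  j |>
    dplyr::group_by(.data$group_index) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$group_index)
}
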