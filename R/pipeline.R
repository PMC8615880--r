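#' Pipeline configuration
#'
#' Bundles everything one end-to-end synthetic run needs: the bands,
#' the three named networks plus their intersection, cohort sizes
#' (behavioral and neural cohorts may differ, e.g. 46 vs 40), the
#' planted effects that give the synthetic cohorts their signal, and
#' the inference settings (prior width, evidence gate, threshold grid,
#' null-model settings, seeds).
#'
#' @param region_labels atlas labels for the synthetic cortex.
#' @param networks named list of [network_definition()] objects; must
#'   contain `response_implementation`, `expectancy_implementation` and
#'   `expectancy_violation` (the intersection network is derived).
#' @param bands named list of [band_definition()] (default
#'   [canonical_bands()]).
#' @param n_behavioral,n_neural cohort sizes for behavioral and neural
#'   targets.
#' @param behavioral_targets,neural_targets target column names.
#' @param planted data frame (`band`, `network`, `region_a`,
#'   `region_b`, `target`, `beta`) of planted edge effects, or `NULL`
#'   for pure-noise cohorts.
#' @param noise_sd target noise sd in the cohort generator.
#' @param kappa stretched-beta prior width for all Bayes factors.
#' @param bf_gate evidence gate (default `sqrt(10)`).
#' @param p_grid retention-proportion grid for threshold selection.
#' @param n_nulls,rewires_per_edge null-model settings.
#' @param graph_side sidedness for nodal-metric correlations
#'   (`"two_sided"` by default; prediction accuracy is always
#'   one-sided positive).
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(region_labels,
                            networks,
                            bands = canonical_bands(),
                            n_behavioral = 46L,
                            n_neural = 40L,
                            behavioral_targets = c("delta_global_rt",
                                                   "delta_global_acc",
                                                   "delta_global_ies"),
                            neural_targets = c("cnv", "odp", "p3"),
                            planted = NULL,
                            noise_sd = 4 / 3,
                            kappa = 0.5,
                            bf_gate = sqrt(10),
                            p_grid = seq(0.1, 0.9, by = 0.05),
                            n_nulls = 20L,
                            rewires_per_edge = 10L,
                            graph_side = "two_sided",
                            seed = 1L) {
  required <- c("response_implementation", "expectancy_implementation",
                "expectancy_violation")
  if (!all(required %in% names(networks)))
    stop("networks must include: ", paste(required, collapse = ", "))
  stopifnot(all(vapply(networks, inherits, logical(1),
                       "network_definition")),
            all(vapply(bands, inherits, logical(1), "band_definition")))
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("bands must be a named list")
  for (net in networks) {
    miss <- setdiff(net$members, region_labels)
    if (length(miss))
      stop("network '", net$name, "' references unknown regions: ",
           paste(miss, collapse = ", "))
  }
  structure(list(region_labels = as.character(region_labels),
                 networks = networks, bands = bands,
                 n_behavioral = as.integer(n_behavioral),
                 n_neural = as.integer(n_neural),
                 behavioral_targets = behavioral_targets,
                 neural_targets = neural_targets,
                 planted = planted, noise_sd = noise_sd,
                 kappa = kappa, bf_gate = bf_gate,
                 p_grid = p_grid, n_nulls = as.integer(n_nulls),
                 rewires_per_edge = as.integer(rewires_per_edge),
                 graph_side = graph_side,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipeline_config()]; networks are
#' given as label lists (inline or as paths to one-label-per-line
#' files, resolved relative to the config file).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  nets <- lapply(names(raw$networks), function(nm) {
    val <- raw$networks[[nm]]
    if (length(val) == 1L && file.exists(file.path(dirname(path), val)))
      read_network_labels(file.path(dirname(path), val), name = nm)
    else network_definition(nm, unlist(val))
  })
  names(nets) <- names(raw$networks)
  raw$networks <- nets
  if (!is.null(raw$planted)) raw$planted <- as.data.frame(raw$planted)
  do.call(pipeline_config, raw)
}

# derive a stage seed from the master seed (kept < 2^31)
stage_seed <- function(seed, k) (seed * 1000L + k) %% 2147483647L

build_cohorts <- function(config, target_names, n_subjects, seed_offset) {
  cohorts <- list()
  targets_by_band <- list()
  for (bi in seq_along(config$bands)) {
    band <- names(config$bands)[bi]
    pe <- NULL
    if (!is.null(config$planted)) {
      pb <- config$planted[config$planted$band == band &
                             config$planted$target %in% target_names, ,
                           drop = FALSE]
      if (nrow(pb))
        pe <- pb[, c("region_a", "region_b", "target", "beta")]
    }
    spec <- cohort_spec(n_subjects = n_subjects,
                        region_labels = config$region_labels,
                        planted_edges = pe,
                        noise_sd = config$noise_sd,
                        target_names = target_names,
                        backbone = "small_world",
                        seed = stage_seed(config$seed, seed_offset + bi))
    sim <- simulate_cohort_connectivity(spec)
    cohorts[[band]] <- lapply(config$networks, function(net)
      lapply(sim$matrices, restrict_to_network, net = net))
    targets_by_band[[band]] <- sim$targets
  }
  list(cohorts = cohorts, targets = targets_by_band)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates per-band cohorts of connectivity matrices (behavioral and
#' neural cohorts separately), runs leave-one-subject-out SVR
#' prediction for every band x network x target, selects a per-band
#' retention threshold on the intersection network by the small-world
#' criterion, extracts nodal metrics and correlates them with every
#' index, gating all reports at `BF10 > sqrt(10)`. All stages are
#' seeded from the config seed; rerunning with the same config yields
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) `out_dir`. Files written: `manifest.json`,
#'   `predictions.json`, `thresholds.json`, `nodal_metrics.csv`,
#'   `nodal_correlations.csv`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("plvnet_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("[simulate] building behavioral (n=", config$n_behavioral,
          ") and neural (n=", config$n_neural, ") cohorts")
  beh <- build_cohorts(config, config$behavioral_targets,
                       config$n_behavioral, seed_offset = 100L)
  neu <- build_cohorts(config, config$neural_targets,
                       config$n_neural, seed_offset = 200L)

  message("[predict] LOSO SVR over ", length(config$bands), " bands x ",
          length(config$networks), " networks")
  svr_cfg <- svr_config(kappa = config$kappa)
  pred <- list()
  for (band in names(config$bands)) {
    pred <- c(pred,
              prediction_grid(stats::setNames(list(beh$cohorts[[band]]), band),
                              beh$targets[[band]], svr_cfg),
              prediction_grid(stats::setNames(list(neu$cohorts[[band]]), band),
                              neu$targets[[band]], svr_cfg))
  }
  pred_df <- do.call(rbind, lapply(pred, function(x)
    data.frame(band = x$band, network = x$network, target = x$target_name,
               r = x$accuracy$r, bf10 = x$accuracy$bf10,
               ci_low = x$accuracy$ci_low, ci_high = x$accuracy$ci_high,
               rmse = x$rmse, reported = x$reported)))
  rownames(pred_df) <- NULL

  message("[graph] intersection-network threshold selection and nodal metrics")
  inter <- intersection_network(config$networks$response_implementation,
                                config$networks$expectancy_implementation,
                                config$networks$expectancy_violation)
  if (length(inter$members) < 4)
    stop("graph stage: intersection network has fewer than 4 regions")
  thresholds <- list(); metrics_rows <- list(); corr_rows <- list()
  for (band in names(config$bands)) {
    # intersection members are a subset of the response network
    inter_mats <- lapply(beh$cohorts[[band]]$response_implementation,
                         restrict_to_network, net = inter)
    sel <- select_threshold(inter_mats, p_grid = config$p_grid,
                            n_nulls = config$n_nulls,
                            rewires_per_edge = config$rewires_per_edge,
                            seed = stage_seed(config$seed, 300L))
    thresholds[[band]] <- sel$p_star
    per_subj <- lapply(inter_mats, function(m)
      nodal_metrics(normalize_weights(proportional_threshold(m, sel$p_star))))
    for (s in seq_along(per_subj)) {
      df <- per_subj[[s]]
      df$subject <- beh$targets[[band]]$subject[s]
      df$band <- band
      metrics_rows[[paste(band, s)]] <- df
    }
    ct <- correlate_nodal_metrics(per_subj, beh$targets[[band]],
                                  kappa = config$kappa,
                                  side = config$graph_side,
                                  gate = config$bf_gate)
    ct$band <- band
    corr_rows[[band]] <- ct
  }
  metrics_df <- do.call(rbind, metrics_rows); rownames(metrics_df) <- NULL
  corr_df <- do.call(rbind, corr_rows); rownames(corr_df) <- NULL

  # outputs (deterministic content; manifest carries the config hash)
  write_json_out <- function(x, f)
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  write_json_out(pred_df, "predictions.json")
  write_json_out(thresholds, "thresholds.json")
  utils::write.csv(metrics_df, file.path(out_dir, "nodal_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(corr_df, file.path(out_dir, "nodal_correlations.csv"),
                   row.names = FALSE)
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config),
                                      c("networks", "bands"))],
                       cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("plvnet")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    bands = names(config$bands),
    networks = names(config$networks),
    n_tests_predictions = nrow(pred_df),
    n_tests_correlations = nrow(corr_df),
    n_reported = sum(pred_df$reported) + sum(corr_df$reported))
  write_json_out(manifest, "manifest.json")
  invisible(out_dir)
}

#' Correlate nodal graph metrics with subject indexes
#'
#' For each node, metric and index column, computes the Bayesian
#' correlation across subjects; rows passing the evidence gate get
#' `reported = TRUE` and (only those) a prior-width robustness summary
#' (minimum BF10 over the robustness grid).
#'
#' @param metrics_per_subject list (one per subject) of
#'   [nodal_metrics()] data frames, identical node order.
#' @param indexes data frame with a `subject` column and one numeric
#'   column per index; subject order must match.
#' @param kappa prior width.
#' @param side sidedness of the correlation test.
#' @param gate evidence threshold (default `sqrt(10)`).
#' @param robustness_grid prior widths for the robustness summary.
#' @return data frame with columns `node`, `metric`, `index`, `r`,
#'   `bf10`, `ci_low`, `ci_high`, `reported`, `min_bf10_robustness`.
#' @export
correlate_nodal_metrics <- function(metrics_per_subject, indexes,
                                    kappa = 0.5, side = "two_sided",
                                    gate = sqrt(10),
                                    robustness_grid = seq(0.1, 2, by = 0.1)) {
  ns <- length(metrics_per_subject)
  if (ns != nrow(indexes))
    stop("subjects misaligned: ", ns, " metric tables vs ",
         nrow(indexes), " index rows")
  nodes <- metrics_per_subject[[1]]$node
  for (m in metrics_per_subject)
    if (!identical(m$node, nodes)) stop("node order differs across subjects")
  metric_names <- c("degree", "strength", "clustering", "local_efficiency")
  index_names <- setdiff(names(indexes), "subject")
  rows <- list()
  for (v in seq_along(nodes)) for (mn in metric_names) {
    x <- vapply(metrics_per_subject, function(m) m[[mn]][v], numeric(1))
    for (ix in index_names) {
      y <- indexes[[ix]]
      r <- suppressWarnings(stats::cor(x, y))
      if (!is.finite(r)) next  # constant metric across cohort
      # a noiseless planted effect can give |r| = 1 exactly, where the
      # reduced likelihood degenerates; back off to the printable edge
      r_test <- sign(r) * min(abs(r), 0.9999)
      bc <- bayes_cor_test(r_test, ns, kappa = kappa, side = side)
      reported <- bc$bf10 > gate
      min_bf <- NA_real_
      if (reported)
        min_bf <- min(bf_robustness(r_test, ns, side = side,
                                    kappa_grid = robustness_grid)$bf10)
      rows[[length(rows) + 1L]] <-
        data.frame(node = nodes[v], metric = mn, index = ix, r = r,
                   bf10 = bc$bf10, ci_low = bc$ci_low, ci_high = bc$ci_high,
                   reported = reported, min_bf10_robustness = min_bf)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
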