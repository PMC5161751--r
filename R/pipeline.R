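## End-to-end orchestration: simulate -> ingest -> preprocess -> call ->
## fit -> classify -> score, with per-stage outputs and a machine-readable
## summary.

#' Build the experiment map for the simulated designs
#'
#' @param config a [sim_config()].
#' @return an [experiment_map()] covering the decay (mitosis and S phase),
#'   titration, cell-cycle (per genotype) and washout-rate samples generated
#'   by the simulators.
#' @export
simulated_experiment_map <- function(config) {
  maps <- list(
    experiment_map(paste0("M", time_code(config$decay_times)),
                   "decay_mitosis", "mitosis",
                   timepoint = config$decay_times),
    experiment_map(paste0("S", time_code(config$decay_times)),
                   "decay_sphase", "sphase",
                   timepoint = config$decay_times),
    experiment_map(sprintf("T%02d", seq_along(config$dose_grid) - 1L),
                   "titration", "AF",
                   dose = c(0, sort(config$dose_grid[config$dose_grid > 0]))))
  for (g in c("single_cyclin", "wt", "dCCP", "dCCP_rum1"))
    maps <- c(maps, list(
      experiment_map(sprintf("C%02d", seq_along(config$cycle_times)),
                     paste0("cycle_", g), g,
                     timepoint = config$cycle_times)))
  for (s in names(config$stage_activity))
    maps <- c(maps, list(
      experiment_map(sprintf("R%s_%d", s, seq_along(config$rate_times) - 1L),
                     paste0("rate_", s), s, timepoint = config$rate_times)))
  out <- do.call(rbind, maps)
  ## cycle genotypes share sample codes C01..C20; disambiguate
  dup <- duplicated(out$sample_code)
  out$sample_code[dup] <- paste0(out$sample_code[dup], ".",
                                 out$experiment_id[dup])
  experiment_map(out$sample_code, out$experiment_id, out$condition,
                 out$timepoint, out$dose, out$reference_channel)
}

## Fit the per-dose median titration of one site set; values normalized so
## the zero-dose control is 1.
fit_class_median_titration <- function(titration, doses, ids, ...) {
  m <- titration[intersect(ids, rownames(titration)), , drop = FALSE]
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  med <- med / med[doses == 0]
  fit_four_pl(doses, med, ...)
}

#' Run the full analysis pipeline on simulated data
#'
#' Generates a synthetic multi-design experiment with known ground truth,
#' writes and re-reads the MaxQuant-dialect tables, calls substrates from the
#' decay time courses, fits per-site dose-response thresholds, clusters and
#' classifies cell-cycle trajectories, estimates the stage activity profile
#' and the G1/S cyclin specificity scores, and writes per-stage tables plus
#' a JSON summary.
#'
#' @param config either a `list` or a path to a YAML/JSON file. Exactly one
#'   of `simulate` (arguments for [sim_config()]) or `input`
#'   (`site_table` + `map` paths) must be present; optional elements:
#'   `clusters` (flat cluster count, default 8) and `seed` (overrides the
#'   simulate block's seed).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage outputs and the `summary` list
#'   written to `summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("config must contain exactly one of 'simulate' or 'input'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  if (has_sim) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    log_stage("simulate: ", cfg$n_sites, " sites, seed ", cfg$seed)
    truth <- make_ground_truth(cfg)
    map <- simulated_experiment_map(cfg)
    mats <- list(
      simulate_decay_experiment(truth, cfg, "mitosis"),
      simulate_decay_experiment(truth, cfg, "sphase"),
      simulate_titration_experiment(truth, cfg))
    for (g in c("single_cyclin", "wt", "dCCP", "dCCP_rum1")) {
      m <- simulate_cell_cycle_experiment(truth, cfg, g)
      colnames(m) <- map$sample_code[map$experiment_id == paste0("cycle_", g)]
      mats <- c(mats, list(m))
    }
    for (s in names(cfg$stage_activity))
      mats <- c(mats, list(simulate_rate_experiment(truth, cfg, s)))
    site_table <- file.path(out_dir, "sites.tsv")
    map_path <- file.path(out_dir, "experiment_map.tsv")
    write_site_table(truth, mats, site_table, map)
    write_experiment_map(map, map_path)
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    site_table <- config$input$site_table
    map_path <- config$input$map
    map <- read_experiment_map(map_path)
    cfg <- NULL
  }

  log_stage("ingest: ", site_table)
  ing <- read_site_table(site_table, map)
  records <- ing$records; ratios <- ing$ratios

  log_stage("substrate calling")
  mito <- select_experiment(ratios, map, "decay_mitosis")
  sph <- select_experiment(ratios, map, "decay_sphase")
  calls <- call_substrates(mito, sph, records,
                           times = attr(mito, "times"))
  calls_m <- calls[calls$dataset == "mitosis", ]
  substrates <- calls_m$site_id[calls_m$is_substrate]
  utils::write.table(calls, file.path(out_dir, "substrate_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("temporal classification (", length(substrates), " substrates)")
  cyc_ref <- select_experiment(ratios, map, "cycle_dCCP")
  times_cyc <- attr(cyc_ref, "times")
  cyc_sub <- cyc_ref[intersect(substrates, rownames(cyc_ref)), ,
                     drop = FALSE]
  imp <- impute_knn(cyc_sub)
  sm <- smooth_nn(imp$matrix)
  k <- config$clusters %||% 8
  hc <- hierarchical_cluster(sm, k = k)
  trans <- list(g1s = 45, g2m = 60)
  classes <- assign_temporal_classes(sm, hc$clusters, times_cyc, trans,
                                     cycle_window = c(25, 110))
  utils::write.table(classes, file.path(out_dir, "temporal_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("dose-response fitting")
  tit <- select_experiment(ratios, map, "titration")
  doses <- attr(tit, "doses")
  tit_n <- normalize_to_condition(tit, colnames(tit)[doses == 0])
  fit_ids <- intersect(substrates, rownames(tit_n))
  fits <- lapply(fit_ids, function(id)
    fit_four_pl(doses, as.numeric(tit_n[id, ])))
  fit_df <- data.frame(
    site_id = fit_ids,
    protein_id = records$protein_id[match(fit_ids, records$site_id)],
    ic50 = vapply(fits, function(f) f$IC50 %||% NA_real_, numeric(1)),
    hill = vapply(fits, function(f) f$Hill %||% NA_real_, numeric(1)),
    r2 = vapply(fits, function(f) f$r2 %||% NA_real_, numeric(1)),
    accepted = vapply(fits, function(f) isTRUE(f$accepted), logical(1)),
    stringsAsFactors = FALSE)
  fit_df$label <- classes$label[match(fit_df$site_id, classes$site_id)]
  utils::write.table(fit_df, file.path(out_dir, "dose_response_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  acc <- fit_df[fit_df$accepted & !is.na(fit_df$label), ]
  ic50_by_class <- tapply(acc$ic50, acc$label, stats::median)

  log_stage("stage rate profile")
  stages <- c("G1", "S", "G2", "M")
  rate_times <- NULL
  stage_mats <- lapply(stages, function(s) {
    m <- select_experiment(ratios, map, paste0("rate_", s))
    rate_times <<- attr(m, "times")
    m[intersect(substrates, rownames(m)), , drop = FALSE]
  })
  names(stage_mats) <- stages
  rate_profile <- relative_rate_profile(stage_mats, times = rate_times,
                                        reference = "M")

  log_stage("specificity scores")
  class_ids <- split(classes$site_id, classes$label)
  spec <- NULL
  late_fit <- fit_class_median_titration(tit_n, doses,
                                         class_ids$late %||% character(0))
  s_times <- times_cyc[times_cyc >= 45 & times_cyc <= 60]
  if (isTRUE(late_fit$ok) && length(s_times)) {
    med_vals <- function(ids) {
      do.call(rbind, lapply(c("wt", "dCCP"), function(g) {
        m <- select_experiment(ratios, map, paste0("cycle_", g))
        tps <- attr(m, "times")
        m <- m[intersect(ids, rownames(m)), , drop = FALSE]
        data.frame(genotype = g, timepoint = tps,
                   value = apply(m, 2, stats::median, na.rm = TRUE))
      }))
    }
    late_v <- med_vals(class_ids$late)
    late_v <- late_v[late_v$timepoint %in% s_times, ]
    spec <- list()
    for (cl in c("early", "mid")) {
      ids <- class_ids[[cl]]
      if (is.null(ids) || length(ids) < 3) next
      cf <- fit_class_median_titration(tit_n, doses, ids)
      if (!isTRUE(cf$ok)) next
      cv <- med_vals(ids)
      cv <- cv[cv$timepoint %in% s_times, ]
      spec[[cl]] <- specificity_score(cf, late_fit, cv, late_v,
                                      pair = c("wt", "dCCP"))
    }
  }

  summary <- list(
    config_hash = config_hash(config),
    seed = if (has_sim) cfg$seed else NULL,
    n_sites = nrow(ratios),
    n_substrates_mitosis = length(substrates),
    median_half_life_min =
      stats::median(calls_m$half_life[calls_m$is_substrate], na.rm = TRUE),
    median_ic50_uM = as.list(ic50_by_class),
    rate_profile_pct = as.list(rate_profile),
    specificity_score = lapply(spec, function(d)
      stats::median(d$score, na.rm = TRUE)),
    class_counts = as.list(table(classes$label)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  log_stage("done (",
            round(as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                  1), " s)")
  invisible(list(truth = if (has_sim) truth else NULL, records = records,
                 ratios = ratios, calls = calls, classes = classes,
                 fits = fit_df, rate_profile = rate_profile,
                 specificity = spec, summary = summary))
}
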