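#' Simulation configuration for synthetic SILAC phosphoproteomics experiments
#'
#' Builds the configuration object consumed by [make_ground_truth()] and the
#' `simulate_*_experiment()` generators. Defaults describe a fission-yeast
#' style experiment: a seven-point kinase-inactivation decay time course, an
#' eleven-dose ATP-analog (1-NmPP1) titration plus a DMSO control, a 20-point
#' two-cycle release series and a five-point washout (re-phosphorylation rate)
#' assay.
#'
#' Noise is multiplicative (lognormal on the SILAC ratio, i.e. Gaussian on the
#' log2 ratio with standard deviation `noise_sd`); missing values are removed
#' completely at random at `missing_rate` (an optional low-value-biased mode
#' is available in the generators).
#'
#' @param n_sites number of phosphosites to simulate.
#' @param n_proteins number of distinct proteins the sites are placed on;
#'   defaults to roughly `n_sites / 2.5` so that some proteins carry several
#'   sites (needed for intra-protein threshold comparisons).
#' @param noise_sd standard deviation of Gaussian noise on the log2 ratio.
#' @param missing_rate fraction of measurements removed, in `[0, 1)`.
#' @param seed master integer seed; every generator derives an independent
#'   sub-stream from it so identical configurations give identical output.
#' @param class_proportions named numeric simplex over
#'   `early`, `mid`, `late`, `nonsubstrate`.
#' @param dose_grid inhibitor concentrations in micromolar, including a single
#'   zero-dose (DMSO) control.
#' @param decay_times,rate_times,cycle_times timepoint grids in minutes for
#'   the decay, washout-rate and cell-cycle designs.
#' @param stage_activity named relative kinase-to-phosphatase activity per
#'   cell-cycle stage, as a fraction of the mitotic level.
#' @param ic50_medians,hill_medians named per-class medians (micromolar and
#'   dimensionless) for the dose-response parameters of substrate sites.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [make_ground_truth()], [simulate_decay_experiment()]
#' @export
sim_config <- function(n_sites = 3000,
                       n_proteins = max(2L, round(n_sites / 2.5)),
                       noise_sd = 0.05,
                       missing_rate = 0.1,
                       seed = 1L,
                       class_proportions = c(early = 0.1, mid = 0.1,
                                             late = 0.4, nonsubstrate = 0.4),
                       dose_grid = c(0, 0.005, 0.015, 0.05, 0.15, 0.3,
                                     1, 2.5, 5, 7.5, 10, 20),
                       decay_times = c(0, 1, 3, 6, 9, 12, 24),
                       rate_times = c(0, 0.5, 1, 2, 10),
                       cycle_times = seq(0, 152, by = 8),
                       stage_activity = c(G1 = 0.017, S = 0.073,
                                          G2 = 0.36, M = 1),
                       ic50_medians = c(early = 3.7, mid = 1.7, late = 0.2),
                       hill_medians = c(early = -3.58, mid = -1.33,
                                        late = -1.41)) {
  cfg <- list(
    n_sites = as.integer(n_sites), n_proteins = as.integer(n_proteins),
    noise_sd = noise_sd, missing_rate = missing_rate,
    missing_mode = "mcar", seed = as.integer(seed),
    class_proportions = class_proportions, dose_grid = dose_grid,
    decay_times = decay_times, rate_times = rate_times,
    cycle_times = cycle_times, stage_activity = stage_activity,
    ic50_medians = ic50_medians, hill_medians = hill_medians,
    ## cell-cycle activity model: cycles delimited by mitotic-exit resets;
    ## within a cycle activity rises exponentially from `start_level` to the
    ## mitotic maximum (1) at `peak`, then holds until the next reset.
    cycle_model = list(
      starts = c(0, 25, 110), peaks = c(15, 90, 175),
      start_levels = c(0.36, 0.017, 0.017),
      g1s_time = 45, g2m_time = 75, cycle2 = c(25, 110),
      ## activity -> equivalent inhibitor dose mapping:
      ## dose = act_dose_scale / activity^act_dose_exponent (uM). The
      ## exponent > 1 reflects the ultrasensitive relation between inhibitor
      ## occupancy and net kinase activity in feedback-competent cells.
      act_dose_scale = 0.04, act_dose_exponent = 1.53,
      ## genotype effects, applied during interphase (before the G2/M point
      ## of each cycle): G1/S cyclins add generic activity in wt, plus a
      ## mid-substrate-specific specificity boost; rum1 deletion mildly
      ## advances activity in the G1/S-cyclin-less background.
      wt_generic_boost = 1.5, wt_mid_boost = 3, rum1_boost = 1.3),
    ## washout-rate model: sites start dephosphorylated at rate_y0 and
    ## re-phosphorylate linearly at rate_scale * stage_activity * sensitivity.
    rate_model = list(y0 = 0.2, cap = 1, rate_scale = 0.25),
    ## level of late-class sites in an S-phase decay experiment (they are not
    ## yet phosphorylated in S phase, so carry no decay signal there).
    sphase_late_level = 0.15)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$class_proportions
  if (is.null(names(p)) ||
      !setequal(names(p), c("early", "mid", "late", "nonsubstrate")))
    stop("class_proportions must be named early/mid/late/nonsubstrate",
         call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("class_proportions must be a simplex (non-negative, sum 1)",
         call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  dg <- cfg$dose_grid
  if (sum(dg == 0) != 1 || any(dg < 0))
    stop("dose_grid must hold exactly one zero-dose control and positive doses",
         call. = FALSE)
  if (any(cfg$decay_times < 0) || any(cfg$rate_times < 0) ||
      any(cfg$cycle_times < 0))
    stop("timepoints must be non-negative", call. = FALSE)
  if (cfg$n_sites < 1 || cfg$n_proteins < 1)
    stop("n_sites and n_proteins must be positive", call. = FALSE)
  invisible(cfg)
}
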