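## Synthetic SILAC experiment generators. All produce a "ratio matrix":
## sites x samples, values = relative phosphorylation (sample over common
## reference), with lognormal noise and optional missingness applied through
## a single seeded stream per experiment so output is fully reproducible.

## noise + missingness; `label` selects the reproducible sub-stream
apply_noise_missing <- function(mat, config, label) {
  set.seed(sub_seed(config$seed, label))
  if (config$noise_sd > 0)
    mat[] <- mat * 2^stats::rnorm(length(mat), 0, config$noise_sd)
  if (config$missing_rate > 0) {
    n <- length(mat)
    if (identical(config$missing_mode, "low_biased")) {
      w <- 2 * (1 - (rank(mat, ties.method = "first") - 0.5) / n)
      drop <- stats::runif(n) < pmin(config$missing_rate * w, 1)
    } else {
      drop <- stats::runif(n) < config$missing_rate
    }
    mat[drop] <- NA_real_
  }
  mat
}

empty_ratio_matrix <- function(truth, codes) {
  matrix(1, nrow = nrow(truth), ncol = length(codes),
         dimnames = list(truth$site_id, codes))
}

## sample code suffix for a timepoint: zero-padded integers for whole
## minutes (M00, M06, ...), plain decimal otherwise
time_code <- function(times) {
  ifelse(times == round(times), sprintf("%02d", as.integer(round(times))),
         as.character(times))
}

#' Simulate a kinase-inactivation decay time course
#'
#' Substrate sites decay from their initial level as
#' `y(t) = (y0 - plateau) * exp(-K * t) + plateau` with `y0 = 1`;
#' nonsubstrate sites stay flat at 1. In the S-phase version, late-class
#' substrates are not yet phosphorylated and sit flat at a low level
#' (`config$sphase_late_level`), which the downstream initial-value filter
#' is designed to remove.
#'
#' @param truth a [make_ground_truth()] data frame.
#' @param config a [sim_config()].
#' @param stage `"mitosis"` or `"sphase"`: cell-cycle stage at inactivation.
#' @param times timepoint grid in minutes (default the configured
#'   `0,1,3,6,9,12,24` grid).
#' @return sites x samples ratio matrix; columns named `M00`, `M01`, ... or
#'   `S00`, ... after the timepoint in minutes.
#' @export
simulate_decay_experiment <- function(truth, config,
                                      stage = c("mitosis", "sphase"),
                                      times = config$decay_times) {
  stage <- match.arg(stage)
  if (any(times < 0)) stop("negative timepoints are not allowed")
  prefix <- if (stage == "mitosis") "M" else "S"
  codes <- paste0(prefix, time_code(times))
  mat <- empty_ratio_matrix(truth, codes)
  sub <- truth$temporal_class_true != "nonsubstrate"
  decaying <- sub
  if (stage == "sphase") {
    late <- truth$temporal_class_true == "late"
    mat[late, ] <- config$sphase_late_level
    decaying <- sub & !late
  }
  if (any(decaying)) {
    K <- truth$K_true[decaying]
    pl <- truth$plateau_true[decaying]
    for (j in seq_along(times))
      mat[decaying, j] <- (1 - pl) * exp(-K * times[j]) + pl
  }
  apply_noise_missing(mat, config, paste0("decay_", stage))
}

#' Simulate an inhibitor titration experiment
#'
#' Substrate values follow the four-parameter logistic
#' `bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(dose)) * hill))`
#' with `hill < 0`; the zero-dose (DMSO) control equals `top` and
#' nonsubstrate sites stay at 1 throughout.
#'
#' @inheritParams simulate_decay_experiment
#' @param doses concentration grid in micromolar including exactly one
#'   zero-dose control.
#' @return ratio matrix with the control column first, then ascending doses;
#'   columns are named `T00` (control), `T01`, ...
#' @export
simulate_titration_experiment <- function(truth, config,
                                          doses = config$dose_grid) {
  if (sum(doses == 0) != 1 || any(doses < 0))
    stop("doses must contain exactly one zero-dose control; others positive")
  doses <- c(0, sort(doses[doses > 0]))
  codes <- sprintf("T%02d", seq_along(doses) - 1L)
  mat <- empty_ratio_matrix(truth, codes)
  sub <- truth$temporal_class_true != "nonsubstrate"
  if (any(sub)) {
    mat[sub, 1] <- truth$top_true[sub]
    for (j in 2:length(doses))
      mat[sub, j] <- four_pl(doses[j], truth$top_true[sub],
                             truth$bottom_true[sub],
                             log10(truth$ic50_true[sub]),
                             truth$hill_true[sub])
  }
  attr(mat, "doses") <- doses
  m <- apply_noise_missing(mat, config, "titration")
  attr(m, "doses") <- doses
  m
}

## Instantaneous CDK activity (fraction of mitotic maximum) at time t for the
## piecewise-exponential two-cycle model: rises from `start_levels[i]` at each
## cycle start to 1 at the cycle's peak, holds, and resets at mitotic exit.
cycle_activity <- function(t, model, boost = 1) {
  i <- findInterval(t, model$starts)
  t0 <- model$starts[i]; tp <- model$peaks[i]; lvl <- model$start_levels[i]
  frac <- pmin((t - t0) / (tp - t0), 1)
  act <- ifelse(frac >= 1, 1, lvl * (1 / lvl)^frac)
  ## genotype boosts act during interphase, i.e. before the cycle's G2/M point
  g2m_frac <- (model$g2m_time - model$cycle2[1]) /
    (model$peaks[2] - model$starts[2])
  pmin(act * ifelse(frac < g2m_frac, boost, 1), 1)
}

#' Simulate a synchronized two-cycle release experiment
#'
#' Each substrate site's trajectory is the occupancy of its dose-response
#' curve evaluated at the instantaneous CDK activity, using the equivalence
#' `dose = act_dose_scale / activity` between inhibitor dose and fractional
#' activity. Activity rises exponentially within each cycle and resets at
#' mitotic exit, so all classes dephosphorylate together at division.
#' Genotypes with G1/S cyclins (`wt`) add a generic interphase activity boost
#' plus a mid-substrate-specific boost; `dCCP_rum1` adds a smaller generic
#' boost; `single_cyclin` and `dCCP` are the baseline. The noise stream is
#' shared across genotypes (a paired design), so zero-boost genotypes give
#' byte-identical matrices.
#'
#' @inheritParams simulate_decay_experiment
#' @param genotype one of `"single_cyclin"`, `"wt"`, `"dCCP"`, `"dCCP_rum1"`.
#' @param times timepoints (minutes after release), default 20 points.
#' @return ratio matrix with columns `C01...C20`; timepoints in
#'   `attr(, "times")`.
#' @export
simulate_cell_cycle_experiment <- function(truth, config,
    genotype = c("single_cyclin", "wt", "dCCP", "dCCP_rum1"),
    times = config$cycle_times) {
  genotype <- match.arg(genotype)
  if (any(times < 0)) stop("negative timepoints are not allowed")
  mdl <- config$cycle_model
  gb <- switch(genotype, wt = mdl$wt_generic_boost,
               dCCP_rum1 = mdl$rum1_boost, 1)
  mb <- if (genotype == "wt") mdl$wt_mid_boost else 1
  codes <- sprintf("C%02d", seq_along(times))
  mat <- empty_ratio_matrix(truth, codes)
  sub <- truth$temporal_class_true != "nonsubstrate"
  mid <- truth$temporal_class_true == "mid"
  act_gen <- cycle_activity(times, mdl, boost = gb)
  act_mid <- cycle_activity(times, mdl, boost = gb * mb)
  for (j in seq_along(times)) {
    a <- ifelse(mid[sub], act_mid[j], act_gen[j])
    dose_eq <- mdl$act_dose_scale / a^mdl$act_dose_exponent
    mat[sub, j] <- four_pl(dose_eq, truth$top_true[sub],
                           truth$bottom_true[sub],
                           log10(truth$ic50_true[sub]), truth$hill_true[sub])
  }
  attr(mat, "times") <- times
  m <- apply_noise_missing(mat, config, "cycle")
  attr(m, "times") <- times
  m
}

#' Simulate a washout re-phosphorylation rate assay
#'
#' Sites start in the dephosphorylated state (relative phosphorylation
#' `rate_model$y0`, below the 0.5 eligibility bound) and re-phosphorylate
#' linearly with initial slope `rate_scale * stage_activity * sensitivity`,
#' saturating at `rate_model$cap`. Nonsubstrate sites stay flat at 1.
#'
#' @inheritParams simulate_decay_experiment
#' @param stage cell-cycle stage, one of `names(config$stage_activity)`
#'   (default `G1`, `S`, `G2`, `M`).
#' @param times timepoint grid in minutes after washout.
#' @return ratio matrix with columns `R<stage>_<i>`; timepoints in
#'   `attr(, "times")`.
#' @export
simulate_rate_experiment <- function(truth, config, stage,
                                     times = config$rate_times) {
  if (!stage %in% names(config$stage_activity))
    stop("unknown stage: ", stage)
  act <- config$stage_activity[[stage]]
  rm_ <- config$rate_model
  codes <- sprintf("R%s_%d", stage, seq_along(times) - 1L)
  mat <- empty_ratio_matrix(truth, codes)
  sub <- truth$temporal_class_true != "nonsubstrate"
  slope <- rm_$rate_scale * act * truth$sensitivity_true[sub]
  for (j in seq_along(times))
    mat[sub, j] <- pmin(rm_$y0 + slope * times[j], rm_$cap)
  attr(mat, "times") <- times
  m <- apply_noise_missing(mat, config, paste0("rate_", stage))
  attr(m, "times") <- times
  m
}
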