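## One-phase exponential decay fitting, phosphorylation half-lives and the
## four-criteria substrate-calling workflow with anomaly screening.

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `y = (Y0 - Plateau) * exp(-K * t) + Plateau` under
#' the constraints `K > 0` and `Plateau > 0`. The half-life is `ln(2) / K`
#' and the dephosphorylation rate is reported as `K` itself (per minute).
#' Fitting uses `nls` (port algorithm, box constraints) started from
#' `Y0 = first value`, `Plateau = min value`, `K = 0.3`, with a constrained
#' quasi-Newton fallback for degenerate series.
#'
#' @param t timepoints in minutes (non-negative).
#' @param y relative phosphorylation values (`NA` allowed; pairs dropped).
#' @return an object of class `decay_fit`: a list with `Y0`, `Plateau`, `K`,
#'   `half_life`, `r2`, `n_used`, `non_decaying` and `ok` (FALSE when fewer
#'   than 4 points or the optimiser failed).
#' @examples
#' t <- c(0, 1, 3, 6, 9, 12, 24)
#' f <- fit_one_phase_decay(t, exp(-log(2) / 2.2 * t))
#' f$half_life  # 2.2
#' @export
fit_one_phase_decay <- function(t, y) {
  if (any(t < 0, na.rm = TRUE)) stop("timepoints must be non-negative")
  keep <- !is.na(t) & !is.na(y)
  t <- t[keep]; y <- y[keep]
  failed <- list(ok = FALSE, Y0 = NA_real_, Plateau = NA_real_, K = NA_real_,
                 half_life = NA_real_, r2 = NA_real_, n_used = length(t),
                 non_decaying = NA)
  class(failed) <- "decay_fit"
  if (length(t) < 4) return(failed)

  start <- c(Y0 = y[which.min(t)], Plateau = max(min(y), 1e-3), K = 0.3)
  lower <- c(0, 1e-9, 1e-6); upper <- c(Inf, Inf, 100)
  par <- tryCatch({
    fit <- suppressWarnings(
      stats::nls(y ~ (Y0 - Plateau) * exp(-K * t) + Plateau,
                 start = as.list(start), algorithm = "port",
                 lower = lower, upper = upper,
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE)))
    stats::coef(fit)
  }, error = function(e) NULL)
  if (is.null(par)) {
    obj <- function(p) sum(((p[1] - p[2]) * exp(-p[3] * t) + p[2] - y)^2)
    o <- tryCatch(stats::optim(start, obj, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(factr = 1e4, maxit = 500)),
                  error = function(e) NULL)
    if (is.null(o)) return(failed)
    par <- o$par
  }
  yhat <- (par[1] - par[2]) * exp(-par[3] * t) + par[2]
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-300) 0 else 1 - ss_res / ss_tot
  out <- list(ok = TRUE, Y0 = unname(par[1]), Plateau = unname(par[2]),
              K = unname(par[3]), half_life = log(2) / unname(par[3]),
              r2 = r2, n_used = length(t),
              non_decaying = unname(par[1] - par[2]) <
                0.05 * max(unname(par[1]), 1e-12))
  class(out) <- "decay_fit"
  out
}

## Evaluate substrate-calling criteria i-iv on one series.
## i  : initial-value bounds (per-dataset);
## ii : at least `min_present` measured timepoints;
## iii: at least one of t in {1,3,6,9,12} below half the 0-min value;
## iv : decay fit with r2 > 0.9 and Plateau < 0.5.
## The fit (criterion iv) is only attempted when i-iii hold.
eval_decay_criteria <- function(t, y, dataset = c("mitosis", "sphase"),
                                min_present = 4,
                                mitosis_bounds = c(0.5, 2),
                                sphase_lower = 0.25,
                                iii_times = c(1, 3, 6, 9, 12)) {
  dataset <- match.arg(dataset)
  y0 <- if (any(t == 0)) y[t == 0][1] else NA_real_
  p_i <- if (is.na(y0)) FALSE else if (dataset == "mitosis")
    y0 > mitosis_bounds[1] && y0 < mitosis_bounds[2] else y0 > sphase_lower
  p_ii <- sum(!is.na(y)) >= min_present
  p_iii <- !is.na(y0) &&
    any(y[t %in% iii_times] < 0.5 * y0, na.rm = TRUE)
  fit <- NULL; p_iv <- FALSE
  if (p_i && p_ii && p_iii) {
    fit <- fit_one_phase_decay(t, y)
    p_iv <- isTRUE(fit$ok) && fit$r2 > 0.9 && fit$Plateau < 0.5
  }
  list(pass_i = p_i, pass_ii = p_ii, pass_iii = p_iii, pass_iv = p_iv,
       fit = fit, pass = p_i && p_ii && p_iii && p_iv)
}

#' Anomaly screening of a failed substrate-calling series
#'
#' Removes each non-zero timepoint in turn (the 0-min anchor is never
#' removed), re-evaluates criteria i-iv on the reduced series, and accepts
#' the site if any single removal makes it pass. Where several removals
#' pass, the one with the highest decay-fit R-squared wins; the half-life is
#' taken from the reduced fit.
#'
#' @inheritParams fit_one_phase_decay
#' @param dataset `"mitosis"` or `"sphase"` (selects criterion-i bounds).
#' @param ... further arguments for the criteria evaluation.
#' @return `NULL` if no removal rescues the site, otherwise a list with the
#'   criteria flags, the `decay_fit` and `removed_timepoint` (minutes).
#' @export
anomaly_screen <- function(t, y, dataset = "mitosis", ...) {
  cand <- t[t != 0 & !is.na(y)]
  best <- NULL
  for (tp in cand) {
    keep <- t != tp
    res <- eval_decay_criteria(t[keep], y[keep], dataset, ...)
    if (res$pass && (is.null(best) || res$fit$r2 > best$fit$r2)) {
      res$removed_timepoint <- tp
      best <- res
    }
  }
  best
}

#' Call CDK substrates from inactivation time courses
#'
#' Applies the four-criteria workflow independently to the mitosis and
#' S-phase decay datasets: (i) the 0-min value must lie within the
#' dataset-specific bounds (mitosis: between 0.5 and 2, the replicate
#' comparison; S phase: above 0.25); (ii) at least 4 of the 7 timepoints
#' measured; (iii) at least one of the 1-12-min timepoints below half the
#' 0-min value; (iv) a one-phase decay fit with R-squared > 0.9 and plateau
#' below 0.5. Sites failing a plain pass are sent through
#' [anomaly_screen()]. Only sites at the minimal CDK consensus (central S/T
#' with +1 P in the sequence window) are considered.
#'
#' @param mitosis,sphase ratio matrices on the same timepoint grid (either
#'   may be `NULL` to call on one dataset only).
#' @param records site annotation with `site_id` and `window` columns, used
#'   for the consensus prefilter; pass `NULL` to skip prefiltering.
#' @param times timepoint grid in minutes matching the matrix columns.
#' @param ... criterion parameters passed to the evaluator.
#' @return a `data.frame` with one row per site and dataset: criteria flags,
#'   `is_substrate`, fitted `K`, `half_life`, `plateau`, `r2`,
#'   `removed_timepoint` (NA unless rescued) and `rescued`.
#' @export
call_substrates <- function(mitosis, sphase = NULL, records = NULL,
                            times = c(0, 1, 3, 6, 9, 12, 24), ...) {
  mats <- Filter(Negate(is.null),
                 list(mitosis = mitosis, sphase = sphase))
  if (!length(mats)) stop("at least one dataset required")
  for (m in mats)
    if (ncol(m) != length(times))
      stop("timepoint grid mismatch: matrix has ", ncol(m),
           " columns for ", length(times), " timepoints")
  rows <- list()
  for (ds in names(mats)) {
    m <- mats[[ds]]
    ids <- rownames(m)
    if (!is.null(records)) {
      calls <- classify_cdk_consensus(records$window)
      ok_ids <- records$site_id[calls != "none"]
      ids <- intersect(ids, ok_ids)
    }
    for (id in ids) {
      y <- as.numeric(m[id, ])
      res <- eval_decay_criteria(times, y, ds, ...)
      rescued <- FALSE; removed <- NA_real_
      if (!res$pass) {
        asr <- anomaly_screen(times, y, ds, ...)
        if (!is.null(asr)) {
          res <- asr; rescued <- TRUE; removed <- asr$removed_timepoint
        }
      }
      f <- res$fit
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = id, dataset = ds, pass_i = res$pass_i,
        pass_ii = res$pass_ii, pass_iii = res$pass_iii,
        pass_iv = res$pass_iv, is_substrate = res$pass,
        K = if (!is.null(f) && f$ok) f$K else NA_real_,
        half_life = if (!is.null(f) && f$ok) f$half_life else NA_real_,
        plateau = if (!is.null(f) && f$ok) f$Plateau else NA_real_,
        r2 = if (!is.null(f) && f$ok) f$r2 else NA_real_,
        removed_timepoint = removed, rescued = rescued,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(site_id = character(0), dataset = character(0),
                      pass_i = logical(0), pass_ii = logical(0),
                      pass_iii = logical(0), pass_iv = logical(0),
                      is_substrate = logical(0), K = numeric(0),
                      half_life = numeric(0), plateau = numeric(0),
                      r2 = numeric(0), removed_timepoint = numeric(0),
                      rescued = logical(0)))
  do.call(rbind, rows)
}

#' Compare half-lives between biological repeats
#'
#' Recomputes half-lives from two repeat experiments using only timepoints
#' up to and including `t_max` minutes, for sites passing criteria i-iv in
#' both repeats (no anomaly screening). Pairs where either half-life falls
#' below `min_half_life` minutes (15 s by default) are excluded.
#'
#' @param matrix_a,matrix_b ratio matrices of the two repeats.
#' @param times timepoint grid shared by both matrices.
#' @param dataset criterion-i flavour, default `"mitosis"`.
#' @param t_max last timepoint used (minutes).
#' @param min_half_life exclusion bound for the pair comparison (minutes).
#' @return `data.frame(site_id, half_life_a, half_life_b)`.
#' @export
halflife_repeat_comparison <- function(matrix_a, matrix_b,
                                       times = c(0, 1, 3, 6, 9, 12, 24),
                                       dataset = "mitosis", t_max = 12,
                                       min_half_life = 0.25) {
  sel <- times <= t_max
  tt <- times[sel]
  ids <- intersect(rownames(matrix_a), rownames(matrix_b))
  out <- list()
  for (id in ids) {
    ya <- as.numeric(matrix_a[id, sel]); yb <- as.numeric(matrix_b[id, sel])
    ra <- eval_decay_criteria(tt, ya, dataset)
    if (!ra$pass) next
    rb <- eval_decay_criteria(tt, yb, dataset)
    if (!rb$pass) next
    hla <- ra$fit$half_life; hlb <- rb$fit$half_life
    if (hla < min_half_life || hlb < min_half_life) next
    out[[length(out) + 1L]] <- data.frame(site_id = id, half_life_a = hla,
                                          half_life_b = hlb,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site_id = character(0), half_life_a = numeric(0),
                      half_life_b = numeric(0)))
  do.call(rbind, out)
}
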