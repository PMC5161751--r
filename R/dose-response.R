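## Constrained four-parameter-logistic (4PL) dose-response fitting with
## robust-regression outlier removal, acceptance gating, inverse
## interpolation and intra- vs inter-protein threshold comparisons.

#' Four-parameter logistic forward model
#'
#' `y = Bottom + (Top - Bottom) / (1 + 10^((logIC50 - log10(dose)) * Hill))`.
#' With `Hill < 0` the curve decreases monotonically in dose; at
#' `dose = IC50` it passes through the midpoint `(Top + Bottom) / 2`.
#'
#' @param dose dose(s), strictly positive, in the same units as `10^logic50`.
#' @param top,bottom upper and lower asymptotes (`top > bottom > 0`).
#' @param logic50 log10 of the half-maximal dose.
#' @param hill Hill slope (negative for inhibition curves).
#' @export
four_pl <- function(dose, top, bottom, logic50, hill) {
  bottom + (top - bottom) / (1 + 10^((logic50 - log10(dose)) * hill))
}

fit_4pl_ls <- function(ld, y, w = NULL, start, multistart = FALSE) {
  if (is.null(w)) w <- rep(1, length(y))
  lower <- c(1e-9, 1e-9, -12, -50)
  upper <- c(Inf, Inf, 6, -1e-6)
  obj <- function(p)
    sum(w * (p[2] + (p[1] - p[2]) / (1 + 10^((p[3] - ld) * p[4])) - y)^2)
  starts <- list(start)
  if (multistart) {
    base <- c(stats::quantile(y, 0.95, names = FALSE),
              max(min(y), 1e-3), stats::median(ld), -1)
    starts <- c(starts, list(base, replace(base, 4, -3)))
  }
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(stats::optim(s0, obj, method = "L-BFGS-B", lower = lower,
                               upper = upper,
                               control = list(factr = 1e4, maxit = 1000)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("4PL optimisation failed")
  par <- best$par
  ## Gauss-Newton polish for full precision on clean data
  pol <- tryCatch({
    fit <- suppressWarnings(
      stats::nls(y ~ Bottom + (Top - Bottom) /
                   (1 + 10^((logIC50 - ld) * Hill)),
                 start = list(Top = par[1], Bottom = par[2],
                              logIC50 = par[3], Hill = par[4]),
                 weights = w, algorithm = "port",
                 lower = lower, upper = upper,
                 control = stats::nls.control(maxiter = 100,
                                              warnOnly = TRUE)))
    stats::coef(fit)
  }, error = function(e) NULL)
  if (!is.null(pol) && obj(pol) <= obj(par)) par <- pol
  names(par) <- c("Top", "Bottom", "logIC50", "Hill")
  par
}

#' Fit a constrained four-parameter logistic dose-response curve
#'
#' Ordinary least squares under the constraints `Hill < 0` and `Bottom > 0`,
#' preceded by robust outlier removal in the ROUT style: an iteratively
#' reweighted fit with Lorentzian weights yields a robust residual scale
#' (the 68.27th percentile of absolute residuals, inflated by `n / (n - 4)`);
#' two-sided t-tail p-values of the scaled residuals are then gated by
#' Benjamini-Hochberg at false-discovery rate `rout_q` and flagged points are
#' excluded from the final ordinary fit. R-squared is computed on retained
#' points only.
#'
#' @param dose doses in micromolar, optionally including one zero-dose
#'   control. By default the control is excluded from the fit; with
#'   `control = "pseudo_dose"` it is assigned a dose one log10 below the
#'   lowest tested concentration instead.
#' @param y relative phosphorylation, normalized so the control equals 1.
#' @param rout_q outlier false-discovery rate (default 0.10).
#' @param control `"exclude"` or `"pseudo_dose"`.
#' @return an object of class `dose_response_fit`: `Top`, `Bottom`,
#'   `logIC50`, `IC50`, `Hill`, `r2`, `outliers_removed` (doses),
#'   `n_used`, `accepted` and `ok`.
#' @export
fit_four_pl <- function(dose, y, rout_q = 0.1,
                        control = c("exclude", "pseudo_dose")) {
  control <- match.arg(control)
  stopifnot(rout_q > 0, rout_q < 1)
  keep <- !is.na(dose) & !is.na(y)
  dose <- dose[keep]; y <- y[keep]
  if (any(dose < 0)) stop("doses must be non-negative")
  failed <- structure(list(ok = FALSE, accepted = FALSE),
                      class = "dose_response_fit")
  if (sum(dose > 0) < 6) return(failed)
  is0 <- dose == 0
  if (any(is0)) {
    if (control == "exclude") { dose <- dose[!is0]; y <- y[!is0] }
    else dose[is0] <- min(dose[dose > 0]) / 10
  }
  ld <- log10(dose)
  n <- length(y)
  start <- c(max(y), max(min(y), 1e-3),
             ld[which.min(abs(y - (max(y) + min(y)) / 2))], -1)
  par <- tryCatch(fit_4pl_ls(ld, y, start = start, multistart = TRUE),
                  error = function(e) NULL)
  if (is.null(par)) return(failed)

  pred <- function(p) p["Bottom"] + (p["Top"] - p["Bottom"]) /
    (1 + 10^((p["logIC50"] - ld) * p["Hill"]))
  rsdr_of <- function(r)
    stats::quantile(abs(r), 0.6827, names = FALSE) * n / max(n - 4, 1)

  ## robust IRLS with Lorentzian weights
  for (it in seq_len(6)) {
    r <- y - pred(par)
    s <- rsdr_of(r)
    if (s < 1e-12) break
    w <- 1 / (1 + (r / s)^2)
    new <- tryCatch(fit_4pl_ls(ld, y, w, start = par),
                    error = function(e) NULL)
    if (is.null(new)) break
    if (max(abs(new - par) / pmax(abs(par), 1e-6)) < 1e-6) { par <- new; break }
    par <- new
  }
  r <- y - pred(par)
  s <- rsdr_of(r)
  out_idx <- integer(0)
  if (s > 1e-12) {
    p_res <- 2 * stats::pt(-abs(r) / s, df = max(n - 4, 1))
    out_idx <- which(stats::p.adjust(p_res, "BH") < rout_q)
  }
  keep_idx <- setdiff(seq_len(n), out_idx)
  if (length(keep_idx) < 6) return(failed)
  par <- tryCatch(fit_4pl_ls(ld[keep_idx], y[keep_idx], start = par,
                             multistart = length(out_idx) > 0),
                  error = function(e) NULL)
  if (is.null(par)) return(failed)
  yk <- y[keep_idx]
  resid <- yk - (par["Bottom"] + (par["Top"] - par["Bottom"]) /
                   (1 + 10^((par["logIC50"] - ld[keep_idx]) * par["Hill"])))
  ss_tot <- sum((yk - mean(yk))^2)
  r2 <- if (ss_tot < 1e-300) 0 else 1 - sum(resid^2) / ss_tot
  fit <- structure(list(ok = TRUE, Top = unname(par["Top"]),
                        Bottom = unname(par["Bottom"]),
                        logIC50 = unname(par["logIC50"]),
                        IC50 = unname(10^par["logIC50"]),
                        Hill = unname(par["Hill"]), r2 = r2,
                        outliers_removed = dose[out_idx],
                        n_used = length(keep_idx), accepted = FALSE),
                   class = "dose_response_fit")
  fit$accepted <- accept_fit(fit)
  fit
}

#' Acceptance gate for a dose-response fit
#'
#' A fit is accepted when `r2 > 0.9`, `Bottom < 0.5` and
#' `Top / Bottom > 2` (the Hill slope is negative by construction).
#'
#' @param fit a `dose_response_fit`.
#' @return logical flag.
#' @export
accept_fit <- function(fit) {
  isTRUE(fit$ok) && fit$r2 > 0.9 && fit$Bottom < 0.5 &&
    fit$Top / fit$Bottom > 2
}

#' Invert a four-parameter logistic fit
#'
#' Returns the unique dose at which the fitted curve equals `y`. Values at
#' or outside the open interval `(Bottom, Top)` have no finite preimage:
#' with `strict = TRUE` (default) this is an error, otherwise `NA` is
#' returned so the caller can flag the point.
#'
#' @param fit an accepted `dose_response_fit` (or any list with `Top`,
#'   `Bottom`, `logIC50`, `Hill`).
#' @param y target response value(s).
#' @param strict error on out-of-range values instead of returning `NA`.
#' @return dose(s) in the fit's units.
#' @export
invert_four_pl <- function(fit, y, strict = TRUE) {
  bad <- y <= fit$Bottom | y >= fit$Top
  if (any(bad) && strict)
    stop("value outside the open interval (Bottom, Top)")
  out <- rep(NA_real_, length(y))
  ok <- !bad
  ratio <- (fit$Top - y[ok]) / (y[ok] - fit$Bottom)
  out[ok] <- 10^(fit$logIC50 - log10(ratio) / fit$Hill)
  out
}

#' Intra- versus inter-protein differences in activity thresholds
#'
#' For proteins carrying at least two accepted IC50 values, computes the
#' absolute pairwise IC50 differences within proteins (intra) and across all
#' site pairs of those proteins, and tests intra against inter pairs with a
#' two-sided Mann-Whitney U test (exact for small samples without ties,
#' normal approximation with tie correction otherwise).
#'
#' @param fits `data.frame` with columns `site_id`, `protein_id`, `ic50`
#'   and `accepted`.
#' @return list with `intra` and `all_pairs` difference vectors, the U
#'   `statistic`, two-sided `p_value` (`NA` when degenerate) and pair counts.
#' @export
delta_ic50_analysis <- function(fits) {
  f <- fits[fits$accepted & !is.na(fits$ic50), , drop = FALSE]
  multi <- names(which(table(f$protein_id) >= 2))
  f <- f[f$protein_id %in% multi, , drop = FALSE]
  if (!nrow(f)) stop("no proteins with multiple accepted IC50 values")
  pairs <- utils::combn(nrow(f), 2)
  delta <- abs(f$ic50[pairs[1, ]] - f$ic50[pairs[2, ]])
  same <- f$protein_id[pairs[1, ]] == f$protein_id[pairs[2, ]]
  intra <- delta[same]; inter <- delta[!same]
  if (!length(intra)) stop("no intra-protein pairs")
  degenerate <- stats::var(delta) == 0
  if (degenerate || !length(inter)) {
    stat <- NA_real_; p <- NA_real_
  } else {
    wt <- suppressWarnings(stats::wilcox.test(intra, inter,
                                              alternative = "two.sided"))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  list(intra = intra, all_pairs = delta, statistic = stat, p_value = p,
       n_intra = length(intra), n_all = length(delta),
       degenerate = degenerate)
}
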