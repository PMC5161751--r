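## Imputation, smoothing and condition-anchored normalization applied before
## clustering, AUC and heatmap-style analyses.

#' k-nearest-neighbour imputation of a ratio matrix
#'
#' Rows with fewer than `min_valid_fraction` valid values are dropped; every
#' missing cell of a retained row is replaced by the `exp(-d)`-weighted mean
#' of the `k` nearest complete rows, where `d` is the Euclidean distance over
#' the row's observed columns (computed on column-standardised values when
#' `standardize = TRUE`, mirroring the documented defaults of the classic
#' `knnImputation` routine). Observed values are never altered.
#'
#' @param mat sites x samples matrix, `NA` for missing.
#' @param k number of neighbours (default 10).
#' @param min_valid_fraction minimum fraction of observed values for a row to
#'   be retained (default 0.5).
#' @param standardize standardise columns before computing distances.
#' @return `list(matrix = <complete matrix>, report = <list>)`; the report
#'   holds input/dropped row counts and the fraction of cells imputed.
#' @export
impute_knn <- function(mat, k = 10, min_valid_fraction = 0.5,
                       standardize = TRUE) {
  assert_matrix(mat)
  stopifnot(k >= 1)
  frac <- rowMeans(!is.na(mat))
  kept <- mat[frac >= min_valid_fraction, , drop = FALSE]
  n_lowvalid <- nrow(mat) - nrow(kept)
  complete <- !rowSums(is.na(kept))
  if (sum(complete) < 2) stop("need at least 2 complete rows to impute from")
  donors <- kept[complete, , drop = FALSE]
  sc <- if (standardize) {
    mu <- colMeans(kept, na.rm = TRUE)
    sd_ <- apply(kept, 2, stats::sd, na.rm = TRUE)
    sd_[!is.finite(sd_) | sd_ == 0] <- 1
    list(mu = mu, sd = sd_)
  } else list(mu = rep(0, ncol(kept)), sd = rep(1, ncol(kept)))
  donors_sc <- sweep(sweep(donors, 2, sc$mu), 2, sc$sd, "/")

  out <- kept
  dropped <- character(0)
  n_imputed <- 0L
  for (i in which(!complete)) {
    obs <- which(!is.na(kept[i, ]))
    if (!length(obs)) { dropped <- c(dropped, rownames(kept)[i]); next }
    xi <- (kept[i, obs] - sc$mu[obs]) / sc$sd[obs]
    d <- sqrt(colSums((t(donors_sc[, obs, drop = FALSE]) - xi)^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    w <- exp(-d[nn])
    if (!sum(w)) w <- rep(1, length(nn))
    miss <- which(is.na(kept[i, ]))
    out[i, miss] <- colSums(donors[nn, miss, drop = FALSE] * w) / sum(w)
    n_imputed <- n_imputed + length(miss)
  }
  if (length(dropped)) {
    warning("dropped rows with no usable neighbours: ",
            paste(dropped, collapse = ", "))
    out <- out[setdiff(rownames(out), dropped), , drop = FALSE]
  }
  list(matrix = out,
       report = list(n_input = nrow(mat), n_dropped_low_valid = n_lowvalid,
                     n_dropped_no_neighbour = length(dropped),
                     imputed_fraction = n_imputed / length(out)))
}

#' Nearest-neighbour smoothing of trajectories
#'
#' Replaces each row by the unweighted mean of its `n_smooth` nearest rows
#' (Euclidean distance, self excluded). All means are computed from the
#' input matrix, so no smoothed value feeds into another (the operation is
#' a single pass and is deliberately not idempotent).
#'
#' @param mat complete sites x samples matrix.
#' @param n_smooth number of neighbours averaged (default 5).
#' @return the smoothed matrix.
#' @export
smooth_nn <- function(mat, n_smooth = 5) {
  assert_matrix(mat)
  if (anyNA(mat)) stop("smooth_nn requires a complete matrix (impute first)")
  if (nrow(mat) < n_smooth + 1)
    stop("need at least n_smooth + 1 rows")
  d <- as.matrix(stats::dist(mat))
  diag(d) <- Inf
  out <- mat
  for (i in seq_len(nrow(mat))) {
    nn <- order(d[i, ])[seq_len(n_smooth)]
    out[i, ] <- colMeans(mat[nn, , drop = FALSE])
  }
  out
}

#' Normalize each row to an anchor sample
#'
#' Divides every row by its value in `anchor_sample` (so the anchor column
#' becomes 1), e.g. to express a titration relative to the DMSO control.
#' Rows with a missing anchor value are dropped with a warning.
#'
#' @param mat sites x samples matrix.
#' @param anchor_sample column name of the anchor.
#' @return the normalized matrix with an `n_dropped` attribute.
#' @export
normalize_to_condition <- function(mat, anchor_sample) {
  assert_matrix(mat)
  if (!anchor_sample %in% colnames(mat))
    stop("anchor sample not present: ", anchor_sample)
  anchor <- mat[, anchor_sample]
  bad <- is.na(anchor)
  if (any(bad))
    warning(sum(bad), " rows dropped: missing anchor value")
  out <- mat[!bad, , drop = FALSE] / anchor[!bad]
  attr(out, "n_dropped") <- sum(bad)
  out
}
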