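## Hierarchical clustering of cell-cycle trajectories, early/mid/late class
## assignment, the G1/S cyclin-specificity score and the genotype comparison
## screen.

#' Hierarchical clustering of trajectories
#'
#' Agglomerative clustering of matrix rows with Euclidean distance and (by
#' default) average linkage, with an optional flat cut.
#'
#' @param mat complete sites x samples matrix.
#' @param k optional number of flat clusters to cut the tree into.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with the `hclust` `tree`, the leaf `order` and, when `k` is
#'   given, a named `clusters` vector.
#' @export
hierarchical_cluster <- function(mat, k = NULL, linkage = "average") {
  assert_matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows to cluster")
  if (anyNA(mat)) stop("matrix must be complete (impute first)")
  tree <- stats::hclust(stats::dist(mat), method = linkage)
  res <- list(tree = tree, order = tree$order, clusters = NULL)
  if (!is.null(k)) res$clusters <- stats::cutree(tree, k = k)
  res
}

#' Assign early/mid/late temporal classes to clustered sites
#'
#' Classifies each cluster by its mean trajectory, normalized to its maximum
#' within the analysed cycle window: `early` when the level at the G1/S
#' transition reaches at least `early_frac` (0.5) of the cycle maximum;
#' `late` when the G1/S level is below `late_frac` (0.25) of the maximum and
#' half-maximum is first crossed after the G2/M transition; `mid` otherwise.
#' Clusters whose trajectory is essentially flat (range below `flat_frac`
#' of the maximum) are `unassigned`. A manual override table relabels
#' individual sites (`source` becomes `manual_override`).
#'
#' @param mat complete sites x samples matrix (same rows as `clusters`).
#' @param clusters named cluster assignment from [hierarchical_cluster()].
#' @param times timepoints (minutes) for the matrix columns.
#' @param transitions `list(g1s = , g2m = )` transition times in minutes.
#' @param cycle_window analysis window `c(t_start, t_end)`; defaults to the
#'   full grid.
#' @param early_frac,late_frac,flat_frac classification thresholds as
#'   fractions of the in-window maximum.
#' @param override optional `data.frame(site_id, label)` of manual calls.
#' @return `data.frame(site_id, label, cluster_id, source)`.
#' @export
assign_temporal_classes <- function(mat, clusters, times, transitions,
                                    cycle_window = range(times),
                                    early_frac = 0.5, late_frac = 0.25,
                                    flat_frac = 0.2, override = NULL) {
  if (is.null(transitions$g1s) || is.null(transitions$g2m))
    stop("transitions must supply g1s and g2m times")
  assert_matrix(mat)
  stopifnot(length(times) == ncol(mat))
  sel <- times >= cycle_window[1] & times <= cycle_window[2]
  tt <- times[sel]
  lab_of <- function(traj) {
    y <- traj[sel]
    ymax <- max(y); ymin <- min(y)
    if (ymax <= 0 || (ymax - ymin) < flat_frac * ymax) return("unassigned")
    g1s_level <- stats::approx(tt, y, xout = transitions$g1s)$y / ymax
    yn <- y / ymax
    cross <- which(yn >= 0.5)
    t_half <- if (length(cross)) {
      i <- cross[1]
      if (i == 1) tt[1] else {
        stats::approx(yn[(i - 1):i], tt[(i - 1):i], xout = 0.5)$y
      }
    } else Inf
    if (g1s_level >= early_frac) "early"
    else if (g1s_level < late_frac && t_half > transitions$g2m) "late"
    else "mid"
  }
  out <- data.frame(site_id = names(clusters),
                    label = NA_character_,
                    cluster_id = unname(clusters),
                    source = "automatic", stringsAsFactors = FALSE)
  for (cl in unique(clusters)) {
    rows <- names(clusters)[clusters == cl]
    traj <- colMeans(mat[rows, , drop = FALSE])
    out$label[out$cluster_id == cl] <- lab_of(traj)
  }
  if (!is.null(override)) {
    m <- match(override$site_id, out$site_id)
    ok <- !is.na(m)
    out$label[m[ok]] <- override$label[ok]
    out$source[m[ok]] <- "manual_override"
  }
  out
}

#' In vivo G1/S cyclin specificity score
#'
#' For each timepoint, the class's median phosphorylation in each genotype is
#' mapped back through the class's median dose-response curve to an
#' equivalent inhibitor concentration, normalized to the concentration
#' interpolated for the late-substrate median, inverted, and expressed as a
#' ratio between the two genotypes. A class phosphorylated at a lower
#' equivalent inhibitor concentration (higher kinase activity) in the
#' numerator genotype scores above 1; genotype-identical inputs score
#' exactly 1.
#'
#' @param class_fit accepted `dose_response_fit` of the class-median
#'   titration (early or mid).
#' @param late_fit accepted `dose_response_fit` of the late-class median.
#' @param class_values `data.frame(genotype, timepoint, value)` of the
#'   class's median relative phosphorylation per genotype and timepoint.
#' @param late_values same structure for the late class.
#' @param pair `c(numerator, denominator)` genotype names, e.g.
#'   `c("wt", "dCCP")`.
#' @return `data.frame(timepoint, score, flagged)`; `flagged` marks
#'   timepoints where any median fell outside its curve's open
#'   `(Bottom, Top)` range (score `NA`, never silently clamped).
#' @export
specificity_score <- function(class_fit, late_fit, class_values, late_values,
                              pair) {
  stopifnot(length(pair) == 2)
  inv_ratio <- function(genotype, tp) {
    cv <- class_values$value[class_values$genotype == genotype &
                               class_values$timepoint == tp]
    lv <- late_values$value[late_values$genotype == genotype &
                              late_values$timepoint == tp]
    if (length(cv) != 1 || length(lv) != 1) return(NA_real_)
    c_class <- invert_four_pl(class_fit, cv, strict = FALSE)
    c_late <- invert_four_pl(late_fit, lv, strict = FALSE)
    c_late / c_class   # inverted normalized concentration
  }
  tps <- sort(intersect(
    class_values$timepoint[class_values$genotype == pair[1]],
    class_values$timepoint[class_values$genotype == pair[2]]))
  score <- vapply(tps, function(tp)
    inv_ratio(pair[1], tp) / inv_ratio(pair[2], tp), numeric(1))
  data.frame(timepoint = tps, score = score, flagged = is.na(score))
}

#' Screen for genotype-specific phosphorylation losses
#'
#' Compares per-site ratios between a test genotype pair after excluding
#' sites whose ratio in a self-versus-self control deviates more than
#' twofold (outside `[0.5, 2]`), restricting to minimal-consensus sites, and
#' flags sites at least as decreased as the least-decreased positive-control
#' site (or an explicit threshold).
#'
#' @param test_ratios named vector of test-genotype ratios per site.
#' @param control_ratios named vector of control (self vs self) ratios.
#' @param records site annotation with `site_id` and `window` (or `NULL` to
#'   skip the consensus filter).
#' @param positive_controls site ids whose decrease defines the threshold.
#' @param threshold explicit ratio threshold (used when no positive
#'   controls are given).
#' @param control_bounds admissible control-ratio interval.
#' @return `data.frame(site_id, test_ratio, flagged)` over retained sites,
#'   positive controls excluded from the report.
#' @export
genotype_ratio_screen <- function(test_ratios, control_ratios, records = NULL,
                                  positive_controls = NULL, threshold = NULL,
                                  control_bounds = c(0.5, 2)) {
  ids <- intersect(names(test_ratios), names(control_ratios))
  if (!length(ids)) stop("no matched site ids between test and control")
  ctrl <- control_ratios[ids]
  ids <- ids[!is.na(ctrl) & ctrl >= control_bounds[1] &
               ctrl <= control_bounds[2]]
  if (!is.null(records)) {
    calls <- classify_cdk_consensus(records$window)
    ids <- intersect(ids, records$site_id[calls != "none"])
  }
  if (is.null(threshold)) {
    if (is.null(positive_controls))
      stop("supply positive_controls or an explicit threshold")
    pc <- test_ratios[intersect(positive_controls, names(test_ratios))]
    if (!length(pc)) stop("no positive-control sites found")
    threshold <- max(pc, na.rm = TRUE)
  }
  ids <- setdiff(ids, positive_controls)
  tv <- test_ratios[ids]
  data.frame(site_id = ids, test_ratio = unname(tv),
             flagged = !is.na(tv) & tv <= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
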