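## Shared fixture builders. Everything is generated in code; no stored data.

## A hand-specified ground-truth table with full control over every kinetic
## parameter; `class_params` rows are recycled over `n` sites per class.
manual_truth <- function(classes, K = 0.3151, plateau = 0.05, ic50 = 1,
                         hill = -1.4, top = 1, bottom = 0.1,
                         sensitivity = 1, window = NULL) {
  n <- length(classes)
  is_sub <- classes != "nonsubstrate"
  if (is.null(window)) {
    base <- strrep("A", 15)
    window <- ifelse(is_sub, paste0(base, "SPAK", strrep("A", 12)),
                     paste0(base, "S", strrep("A", 15)))
  }
  val <- function(x) rep_len(x, n)
  data.frame(
    site_id = sprintf("P%03d_S%d", seq_len(n), seq_len(n) * 10),
    protein_id = sprintf("P%03d", seq_len(n)),
    position = seq_len(n) * 10, residue = "S", window = window,
    temporal_class_true = classes,
    K_true = ifelse(is_sub, val(K), NA_real_),
    plateau_true = ifelse(is_sub, val(plateau), NA_real_),
    ic50_true = ifelse(is_sub, val(ic50), NA_real_),
    hill_true = ifelse(is_sub, val(hill), NA_real_),
    top_true = ifelse(is_sub, val(top), NA_real_),
    bottom_true = ifelse(is_sub, val(bottom), NA_real_),
    sensitivity_true = ifelse(is_sub, val(sensitivity), NA_real_),
    localization_prob = 0.99, stringsAsFactors = FALSE)
}

noiseless_config <- function(..., n_sites = 10, seed = 1) {
  sim_config(n_sites = n_sites, seed = seed, noise_sd = 0,
             missing_rate = 0, ...)
}

## Exhaustive two-sided Mann-Whitney p-value by enumeration of all
## assignments of the pooled values to the two groups (tie-free inputs).
mw_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_stat(x, y)
  idx <- utils::combn(length(pooled), m)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Quadratic-time reference implementation of average-linkage agglomeration
## (Lance-Williams update); returns merge heights and the flat k-cluster
## partition as a membership vector.
brute_average_linkage <- function(mat, k) {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat))
  diag(d) <- Inf
  groups <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  heights <- numeric(0)
  membership <- seq_len(n)
  while (sum(active) > k) {
    dd <- d
    dd[!active, ] <- Inf; dd[, !active] <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, d[i, j])
    ## average-linkage update of row/col i; deactivate j
    for (kk in which(active)) {
      if (kk == i || kk == j) next
      d[i, kk] <- (sizes[i] * d[i, kk] + sizes[j] * d[j, kk]) /
        (sizes[i] + sizes[j])
      d[kk, i] <- d[i, kk]
    }
    groups[[i]] <- c(groups[[i]], groups[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
  }
  for (g in which(active)) membership[groups[[g]]] <- g
  list(membership = membership, heights = heights)
}

## partition equality up to label permutation
same_partition <- function(a, b) {
  identical(unname(tapply(seq_along(a), a, paste, collapse = ",")) |> sort(),
            unname(tapply(seq_along(b), b, paste, collapse = ",")) |> sort())
}
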