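## Sequence-context classification (minimal/full CDK consensus, RxL cyclin
## docking motifs), positional amino-acid profiles and Fisher-exact
## annotation enrichment with Benjamini-Hochberg FDR control.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Classify sequence windows against the CDK consensus
#'
#' `minimal` requires a central S or T followed by proline (+1 P);
#' `full` additionally requires lysine or arginine at position +3.
#'
#' @param windows character vector of odd-length amino-acid windows centred
#'   on the phosphosite (terminal padding `_` allowed; every full call is
#'   also a minimal call).
#' @return factor with levels `none`, `minimal`, `full`.
#' @export
classify_cdk_consensus <- function(windows) {
  n <- nchar(windows)
  if (any(n %% 2 == 0)) stop("windows must have odd length")
  if (length(unique(n)) > 1) stop("windows must share one length")
  center <- (n[1] + 1) / 2
  cen <- substr(windows, center, center)
  if (!all(cen %in% c("S", "T", "Y")))
    stop("window centre must be S, T or Y")
  p1 <- substr(windows, center + 1, center + 1)
  p3 <- substr(windows, center + 3, center + 3)
  minimal <- cen %in% c("S", "T") & p1 == "P"
  full <- minimal & p3 %in% c("K", "R")
  factor(ifelse(full, "full", ifelse(minimal, "minimal", "none")),
         levels = c("none", "minimal", "full"))
}

#' Find RxL cyclin-docking motifs in a protein sequence
#'
#' Matches the full motif `[RK] x L x{0,1} [FYLIVMP]` with standard greedy
#' regular-expression semantics (the one-residue spacer is preferred where
#' both forms match a start position); overlapping matches at different
#' start positions are all reported.
#'
#' @param sequence amino-acid string (standard 20-letter alphabet).
#' @return `data.frame(start, match)` with 1-based start positions.
#' @export
find_rxl_motifs <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% AA_ALPHABET))
    stop("sequence contains non-amino-acid characters")
  phi <- c("F", "Y", "L", "I", "V", "M", "P")
  n <- length(chars)
  starts <- integer(0); matches <- character(0)
  for (i in seq_len(max(n - 3, 0))) {
    if (!chars[i] %in% c("R", "K") || chars[i + 2] != "L") next
    hit <- NULL
    if (i + 4 <= n && chars[i + 4] %in% phi)        # greedy: spacer first
      hit <- paste0(chars[i:(i + 4)], collapse = "")
    else if (chars[i + 3] %in% phi)
      hit <- paste0(chars[i:(i + 3)], collapse = "")
    if (!is.null(hit)) {
      starts <- c(starts, i); matches <- c(matches, hit)
    }
  }
  data.frame(start = starts, match = matches, stringsAsFactors = FALSE)
}

#' Positional amino-acid frequency profile
#'
#' Tallies residue frequencies at each window position; terminal padding
#' (`_`) is excluded from the denominators, so every column is a frequency
#' distribution over the residues actually observed at that position.
#'
#' @param windows equal-length character vector of sequence windows.
#' @return residues x positions matrix of frequencies (columns sum to 1).
#' @export
aa_frequency_profile <- function(windows) {
  n <- unique(nchar(windows))
  if (length(n) != 1) stop("windows must share one length")
  m <- matrix(0, nrow = length(AA_ALPHABET), ncol = n,
              dimnames = list(AA_ALPHABET,
                              as.character(seq_len(n) - (n + 1) / 2)))
  for (j in seq_len(n)) {
    res <- substr(windows, j, j)
    res <- res[res != "_"]
    if (!length(res)) next
    tab <- table(factor(res, levels = AA_ALPHABET))
    m[, j] <- as.numeric(tab) / length(res)
  }
  m
}

#' Fisher-exact annotation enrichment with BH FDR control
#'
#' For every annotation term, builds the 2x2 table of term membership against
#' target membership over the universe (target plus background), computes a
#' two-sided Fisher exact p-value (summation of tables at most as probable as
#' the observed one), adjusts across terms by Benjamini-Hochberg, and flags
#' terms with adjusted p below `fdr` (default 0.02).
#'
#' @param target ids of the foreground set (must lie in the universe).
#' @param background ids of the rest of the universe.
#' @param annotation_map named list: term -> character vector of ids.
#' @param fdr significance cutoff on the BH-adjusted p-value.
#' @return `data.frame(term, a, b, c, d, odds_ratio, p, q, significant)`,
#'   where `a` counts term-and-target ids and `b` term-and-background ids.
#' @export
fisher_enrichment <- function(target, background, annotation_map,
                              fdr = 0.02) {
  universe <- union(target, background)
  if (!length(universe) || !length(annotation_map))
    stop("empty universe or annotation map")
  if (!all(target %in% universe)) stop("target must be within the universe")
  background <- setdiff(universe, target)
  rows <- lapply(names(annotation_map), function(term) {
    ids <- intersect(annotation_map[[term]], universe)
    if (!length(ids))
      stop("annotation term absent from universe: ", term)
    a <- length(intersect(ids, target))
    b <- length(intersect(ids, background))
    c_ <- length(target) - a
    d <- length(background) - b
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                             alternative = "two.sided")
    data.frame(term = term, a = a, b = b, c = c_, d = d,
               odds_ratio = (a * d) / max(b * c_, .Machine$double.xmin),
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet`, returning a plain named
#' character vector for motif scanning.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required to read FASTA files")
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}
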