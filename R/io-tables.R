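## Reading/writing MaxQuant-dialect phosphosite and protein-group tables and
## the experiment map that links sample codes to designs. The canonical
## internal quantity is "relative phosphorylation" = sample / reference: the
## stored H:L ratio is inverted wherever the reference is the heavy channel,
## so downstream code never sees the mixed H:L / L:H orientation of the raw
## tables.

#' Build an experiment map
#'
#' The experiment map links each ratio column (sample code) of a table to its
#' experiment, condition and coordinate (timepoint in minutes or dose in
#' micromolar), and records which SILAC channel held the common reference.
#'
#' @param sample_code character vector of sample codes (column identifiers).
#' @param experiment_id experiment each sample belongs to.
#' @param condition free-text condition label.
#' @param timepoint timepoint in minutes (`NA` for titrations).
#' @param dose dose in micromolar (`NA` for time courses).
#' @param reference_channel `"heavy"` or `"light"` per sample.
#' @return a `data.frame` of class `experiment_map`.
#' @export
experiment_map <- function(sample_code, experiment_id, condition = "",
                           timepoint = NA_real_, dose = NA_real_,
                           reference_channel = "heavy") {
  m <- data.frame(sample_code = as.character(sample_code),
                  experiment_id = as.character(experiment_id),
                  condition = condition, timepoint = timepoint, dose = dose,
                  reference_channel = reference_channel,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$sample_code))
    stop("duplicate sample codes in experiment map")
  if (!all(m$reference_channel %in% c("heavy", "light")))
    stop("reference_channel must be 'heavy' or 'light'")
  class(m) <- c("experiment_map", "data.frame")
  m
}

#' Read or write an experiment map (TSV or YAML)
#'
#' @param path file path; `.yaml`/`.yml` selects YAML, anything else
#'   tab-separated text.
#' @return for the reader, an [experiment_map()].
#' @export
read_experiment_map <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    lst <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(lst, function(e)
      data.frame(sample_code = e$sample_code,
                 experiment_id = e$experiment_id,
                 condition = e$condition %||% "",
                 timepoint = e$timepoint %||% NA_real_,
                 dose = e$dose %||% NA_real_,
                 reference_channel = e$reference_channel %||% "heavy",
                 stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  experiment_map(df$sample_code, df$experiment_id, df$condition,
                 as.numeric(df$timepoint), as.numeric(df$dose),
                 df$reference_channel)
}

#' @rdname read_experiment_map
#' @param map an [experiment_map()] to serialise.
#' @export
write_experiment_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

ratio_col <- function(code) paste("Ratio H/L normalized", code)

## relative phosphorylation -> stored H:L for a sample given its reference
to_hl <- function(values, reference) {
  if (reference == "heavy") 1 / values else values
}

#' Write a phosphosite table in the MaxQuant dialect
#'
#' Serialises ground-truth site annotation plus one or more ratio matrices
#' into a tab-separated table with the column conventions of a
#' `Phospho (STY)Sites.txt` subset: `id`, `Protein`, `Position`,
#' `Amino acid`, `Sequence window`, `Localization prob`, `Reverse`,
#' `Potential contaminant` (marked `+`), and one
#' `Ratio H/L normalized <code>` column per sample. Relative phosphorylation
#' is converted back to the stored H:L orientation using each sample's
#' reference channel, so the table round-trips losslessly through
#' [read_site_table()].
#'
#' @param truth a [make_ground_truth()] data frame (or any data frame with
#'   the same identity columns).
#' @param matrices one ratio matrix or a list of them (shared site ids).
#' @param path output file.
#' @param map an [experiment_map()] covering every sample code.
#' @param decoys number of reverse-flagged decoy rows to append (for QC
#'   tests; default 0).
#' @return the path, invisibly.
#' @export
write_site_table <- function(truth, matrices, path, map, decoys = 0L) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  ids <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), ids)) stop("matrices must share site ids")
  if (!identical(truth$site_id, ids))
    truth <- truth[match(ids, truth$site_id), ]
  out <- data.frame(id = truth$site_id, Protein = truth$protein_id,
                    Position = truth$position, `Amino acid` = truth$residue,
                    `Sequence window` = truth$window,
                    `Localization prob` = truth$localization_prob,
                    Reverse = "", `Potential contaminant` = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (m in matrices) {
    for (code in colnames(m)) {
      ref <- map$reference_channel[map$sample_code == code]
      if (length(ref) != 1) stop("sample code not in map: ", code)
      out[[ratio_col(code)]] <- signif(to_hl(m[, code], ref), 10)
    }
  }
  if (decoys > 0) {
    dec <- out[rep(1, decoys), ]
    dec$id <- paste0("REV__", seq_len(decoys))
    dec$Reverse <- "+"
    out <- rbind(out, dec)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a phosphosite table, apply QC filters and orient ratios
#'
#' Applies the standard post-search filters: rows flagged reverse or
#' potential contaminant are dropped, as are rows with localization
#' probability not exceeding `min_localization` (default 0.9, i.e. a row at
#' 0.89 is excluded) or with zero valid ratio values. Remaining ratios are
#' oriented to relative phosphorylation (sample / reference), inverting the
#' stored H:L values for samples whose reference is the heavy channel.
#'
#' @param path tab-separated site table.
#' @param map an [experiment_map()]; every ratio column's sample code must
#'   resolve to exactly one entry.
#' @param min_localization localization-probability cutoff (exclusive).
#' @param ratio_pattern regular expression with one capture group extracting
#'   the sample code from a ratio column name.
#' @return `list(records = <site annotation data.frame>, ratios = <matrix>)`.
#' @export
read_site_table <- function(path, map, min_localization = 0.9,
                            ratio_pattern = "^Ratio H/L normalized (.+)$") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("id", "Protein", "Position", "Amino acid", "Sequence window",
            "Localization prob", "Reverse", "Potential contaminant")
  if (!all(need %in% names(tab)))
    stop("missing required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  rcols <- grep(ratio_pattern, names(tab), value = TRUE)
  if (!length(rcols)) stop("no ratio columns matching pattern")
  codes <- sub(ratio_pattern, "\\1", rcols)
  if (!all(codes %in% map$sample_code))
    stop("unmapped sample codes: ",
         paste(setdiff(codes, map$sample_code), collapse = ", "))

  keep <- !(tab$Reverse %in% "+") & !(tab$`Potential contaminant` %in% "+") &
    tab$`Localization prob` > min_localization
  tab <- tab[keep, , drop = FALSE]
  ratios <- as.matrix(tab[, rcols, drop = FALSE])
  colnames(ratios) <- codes
  rownames(ratios) <- tab$id
  for (j in seq_along(codes)) {
    ref <- map$reference_channel[map$sample_code == codes[j]]
    if (ref == "heavy") ratios[, j] <- 1 / ratios[, j]
  }
  valid <- rowSums(!is.na(ratios)) > 0
  ratios <- ratios[valid, , drop = FALSE]
  tab <- tab[valid, , drop = FALSE]
  records <- data.frame(site_id = tab$id, protein_id = tab$Protein,
                        position = tab$Position, residue = tab$`Amino acid`,
                        window = tab$`Sequence window`,
                        localization_prob = tab$`Localization prob`,
                        stringsAsFactors = FALSE)
  list(records = records, ratios = ratios)
}

#' Read or write a protein-group ratio table
#'
#' As [read_site_table()] but without the localization filter: contaminant
#' and reverse rows are dropped, all-missing rows are dropped, and ratios
#' are oriented to sample / reference.
#'
#' @inheritParams read_site_table
#' @return a proteins x samples ratio matrix.
#' @export
read_protein_table <- function(path, map,
                               ratio_pattern = "^Ratio H/L normalized (.+)$") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("Protein IDs", "Reverse", "Potential contaminant")
  if (!all(need %in% names(tab)))
    stop("missing required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  rcols <- grep(ratio_pattern, names(tab), value = TRUE)
  if (!length(rcols)) stop("no ratio columns matching pattern")
  codes <- sub(ratio_pattern, "\\1", rcols)
  if (!all(codes %in% map$sample_code))
    stop("unmapped sample codes: ",
         paste(setdiff(codes, map$sample_code), collapse = ", "))
  keep <- !(tab$Reverse %in% "+") & !(tab$`Potential contaminant` %in% "+")
  tab <- tab[keep, , drop = FALSE]
  ratios <- as.matrix(tab[, rcols, drop = FALSE])
  colnames(ratios) <- codes
  rownames(ratios) <- tab$`Protein IDs`
  for (j in seq_along(codes)) {
    ref <- map$reference_channel[map$sample_code == codes[j]]
    if (ref == "heavy") ratios[, j] <- 1 / ratios[, j]
  }
  ratios[rowSums(!is.na(ratios)) > 0, , drop = FALSE]
}

#' @rdname read_protein_table
#' @param protein_ids,matrix protein identifiers and their ratio matrix.
#' @export
write_protein_table <- function(protein_ids, matrix, path, map) {
  out <- data.frame(`Protein IDs` = protein_ids, Reverse = "",
                    `Potential contaminant` = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (code in colnames(matrix)) {
    ref <- map$reference_channel[map$sample_code == code]
    if (length(ref) != 1) stop("sample code not in map: ", code)
    out[[ratio_col(code)]] <- signif(to_hl(matrix[, code], ref), 10)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Select and order the columns of one experiment
#'
#' Restricts a ratio matrix to the samples of one experiment and orders the
#' columns ascending by timepoint or dose, with a zero-dose control first.
#'
#' @param matrix sites x samples ratio matrix.
#' @param map an [experiment_map()].
#' @param experiment_id experiment to extract.
#' @return the column-subset matrix, with the matching coordinate vector in
#'   `attr(, "times")` or `attr(, "doses")`.
#' @export
select_experiment <- function(matrix, map, experiment_id) {
  sel <- map[map$experiment_id == experiment_id, , drop = FALSE]
  if (!nrow(sel)) stop("unknown experiment id: ", experiment_id)
  sel <- sel[sel$sample_code %in% colnames(matrix), , drop = FALSE]
  if (!nrow(sel)) stop("no columns of this experiment present in matrix")
  by_dose <- all(!is.na(sel$dose))
  key <- if (by_dose) sel$dose else sel$timepoint
  if (anyNA(key)) stop("experiment mixes timepoints and doses or has gaps")
  sel <- sel[order(key), , drop = FALSE]
  out <- matrix[, sel$sample_code, drop = FALSE]
  if (by_dose) attr(out, "doses") <- sort(key) else
    attr(out, "times") <- sort(key)
  out
}
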