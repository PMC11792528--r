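# Reading peptide-level search-engine output (MaxQuant peptides.txt or a
# generic TSV), decoy/contaminant filtering, and microbial/host/ambiguous
# origin classification.

.parse_intensity_cols <- function(tab, cols, path) {
  out <- matrix(0, nrow(tab), length(cols))
  for (j in seq_along(cols)) {
    raw <- as.character(tab[[cols[j]]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(raw) & raw != "NA")
    if (length(bad))
      stop("non-numeric intensity in column '", cols[j], "' of '", path,
           "' at data row(s): ", .comma_list(bad), call. = FALSE)
    val[is.na(val)] <- 0
    out[, j] <- val
  }
  out
}

.plus_flag <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  x <- as.character(x)
  !is.na(x) & (x == "+" | toupper(x) %in% c("TRUE", "1"))
}

#' Read peptide-level search results
#'
#' Parses a MaxQuant `peptides.txt` (tab-separated; columns `Sequence`,
#' `Proteins`, one or more `Intensity`/`Intensity <sample>` columns,
#' optional `Reverse` and `Potential contaminant` flags with value `"+"`)
#' or a generic TSV (`sequence`, `proteins`, `intensity_<sample>` columns,
#' optional `is_decoy`/`is_contaminant`). Semicolon-separated protein
#' groups are split; rows with an empty protein group are dropped with a
#' message stating the count. Sequences must be plain uppercase residue
#' strings — whitespace or modification annotations are rejected, not
#' stripped.
#'
#' @param path File path.
#' @param dialect `"maxquant"` or `"generic"`.
#' @return A [PeptideSet-class].
#' @seealso [filterObservations()], [classifyOrigin()], [writePeptides()]
#' @export
readPeptides <- function(path, dialect = c("maxquant", "generic")) {
  dialect <- match.arg(dialect)
  tab <- .read_tsv(path, colClasses = "character")
  if (dialect == "maxquant") {
    seq_col <- "Sequence"; prot_col <- "Proteins"
    int_cols <- grep("^Intensity( .+)?$", colnames(tab), value = TRUE)
    samples <- ifelse(int_cols == "Intensity", "Intensity",
                      sub("^Intensity ", "", int_cols))
    decoy <- .plus_flag(tab[["Reverse"]], nrow(tab))
    contam <- .plus_flag(
      if ("Potential contaminant" %in% colnames(tab))
        tab[["Potential contaminant"]] else tab[["Contaminant"]], nrow(tab))
  } else {
    seq_col <- "sequence"; prot_col <- "proteins"
    int_cols <- grep("^intensity_", colnames(tab), value = TRUE)
    samples <- sub("^intensity_", "", int_cols)
    decoy <- .plus_flag(tab[["is_decoy"]], nrow(tab))
    contam <- .plus_flag(tab[["is_contaminant"]], nrow(tab))
  }
  for (col in c(seq_col, prot_col))
    if (!col %in% colnames(tab))
      stop("required column: ", col, call. = FALSE)
  if (length(int_cols) == 0L)
    stop("required column: at least one intensity column", call. = FALSE)

  seqs <- as.character(tab[[seq_col]])
  bad_seq <- which(!.is_aa(seqs))
  if (length(bad_seq))
    stop("invalid peptide sequence(s) (must be plain uppercase residues) ",
         "at data row(s): ", .comma_list(bad_seq), call. = FALSE)
  inten <- .parse_intensity_cols(tab, int_cols, path)
  colnames(inten) <- samples

  prot_raw <- .blank_to_na(tab[[prot_col]])
  keep <- !is.na(prot_raw)
  if (any(!keep))
    message("readPeptides: dropped ", sum(!keep),
            " row(s) with an empty protein group")
  groups <- strsplit(prot_raw[keep], ";", fixed = TRUE)
  groups <- lapply(groups, function(g) g[nzchar(g)])
  if (anyDuplicated(seqs[keep]))
    stop("duplicate peptide sequence row(s): ",
         .comma_list(seqs[keep][duplicated(seqs[keep])]), call. = FALSE)
  PeptideSet(sequence = seqs[keep], proteinGroup = groups,
             intensities = inten[keep, , drop = FALSE],
             isDecoy = decoy[keep], isContaminant = contam[keep])
}

#' Write a PeptideSet back to disk
#'
#' The generic dialect round-trips losslessly through [readPeptides()].
#'
#' @param ps A [PeptideSet-class].
#' @param path Output file path.
#' @param dialect `"generic"` or `"maxquant"`.
#' @return `path`, invisibly.
#' @export
writePeptides <- function(ps, path, dialect = c("generic", "maxquant")) {
  dialect <- match.arg(dialect)
  inten <- intensityMatrix(ps)
  groups <- vapply(as.list(proteinGroups(ps)), paste, "", collapse = ";")
  if (dialect == "generic") {
    df <- data.frame(sequence = peptideSequences(ps), proteins = groups,
                     is_decoy = isDecoy(ps), is_contaminant = isContaminant(ps),
                     check.names = FALSE)
    icol <- paste0("intensity_", colnames(inten))
  } else {
    df <- data.frame(Sequence = peptideSequences(ps), Proteins = groups,
                     Reverse = ifelse(isDecoy(ps), "+", ""),
                     check.names = FALSE)
    df[["Potential contaminant"]] <- ifelse(isContaminant(ps), "+", "")
    icol <- ifelse(colnames(inten) == "Intensity", "Intensity",
                   paste("Intensity", colnames(inten)))
  }
  for (j in seq_along(icol)) df[[icol[j]]] <- inten[, j]
  .write_tsv(df, path)
  invisible(path)
}

#' Remove decoy and contaminant observations
#'
#' Surviving rows are untouched; the numbers removed are recorded in
#' `metadata(ps)$removed` and reported with a message.
#'
#' @param ps A [PeptideSet-class].
#' @return The filtered [PeptideSet-class].
#' @export
filterObservations <- function(ps) {
  stopifnot(is(ps, "PeptideSet"))
  n_decoy <- sum(isDecoy(ps))
  n_contam <- sum(isContaminant(ps) & !isDecoy(ps))
  out <- ps[!isDecoy(ps) & !isContaminant(ps), ]
  metadata(out)$removed <- c(decoy = n_decoy, contaminant = n_contam)
  message("filterObservations: removed ", n_decoy, " decoy and ",
          n_contam, " contaminant row(s)")
  out
}

#' Classify peptides as microbial, host or ambiguous
#'
#' A peptide whose protein group is entirely covered by `microbialIds` is
#' microbial; entirely by `hostIds`, host; a group touching both is
#' ambiguous and is excluded from microbial profiling and from the
#' microbe/host ratio downstream (it would otherwise be double counted).
#'
#' @param ps A [PeptideSet-class].
#' @param microbialIds,hostIds Character vectors of protein ids. Every
#'   protein-group member must occur in one of the two.
#' @return `ps` with `originClass(ps)` set.
#' @export
classifyOrigin <- function(ps, microbialIds, hostIds) {
  stopifnot(is(ps, "PeptideSet"))
  groups <- as.list(proteinGroups(ps))
  all_ids <- unique(unlist(groups))
  unknown <- setdiff(all_ids, c(microbialIds, hostIds))
  if (length(unknown))
    stop("protein id(s) neither microbial nor host: ", .comma_list(unknown),
         call. = FALSE)
  cls <- vapply(groups, function(g) {
    mic <- any(g %in% microbialIds)
    hst <- any(g %in% hostIds)
    if (mic && hst) "ambiguous" else if (mic) "microbial" else "host"
  }, "")
  rowData(ps)$originClass <- cls
  ps
}
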