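# Peptide-centric taxonomic annotation: every retained microbial peptide
# gets the LCA of its protein group's lineages. Protein ids retired by
# deduplication are resolved through dedupMap first, so results searched
# against the pre-deduplication database still annotate. By construction
# every resolvable peptide receives an assignment — at worst the
# uninformative "Root" — so there is no unannotated state.

.resolve_ids <- function(ids, db) {
  dmap <- db@dedupMap
  resolved <- ifelse(ids %in% names(dmap), unname(dmap[ids]), ids)
  unknown <- setdiff(resolved, names(db@proteins))
  if (length(unknown))
    stop("protein id(s) absent from the reference database: ",
         .comma_list(unknown), call. = FALSE)
  unique(resolved)
}

#' Taxonomic LCA for one peptide's protein group
#'
#' @param proteinGroup Character vector of protein ids (pre- or
#'   post-deduplication ids; retired ids resolve through `dedupMap(db)`).
#' @param db A [ReferenceDb-class] supplying the lineages.
#' @return A [TaxonomicAssignment-class].
#' @examples
#' \dontrun{annotatePeptide(c("s1_P1", "s2_P4"), db)}
#' @seealso [annotateTaxonomy()] for whole tables, [lca()] for the
#'   underlying operation.
#' @export
annotatePeptide <- function(proteinGroup, db) {
  stopifnot(is(db, "ReferenceDb"))
  ids <- .resolve_ids(proteinGroup, db)
  idx <- match(ids, db@taxonomy$protein_id)
  linmat <- as.matrix(as.data.frame(db@taxonomy[idx, .RANKS, drop = FALSE]))
  mode(linmat) <- "character"
  res <- .lca_core(linmat)
  TaxonomicAssignment(res$taxon, res$rank, res$lineage)
}

#' Annotate a peptide table with taxonomic LCAs
#'
#' One output row per peptide: the resolved rank and taxon, the lineage
#' prefix (both pipe-joined and as one column per rank, `NA` below the LCA
#' rank), and one intensity column per sample (`intensity_<sample>`). Rows
#' are ordered by peptide sequence. If origin classes are present only
#' microbial peptides are annotated; ambiguous and host peptides are left
#' out.
#'
#' @param ps A filtered [PeptideSet-class].
#' @param db A [ReferenceDb-class].
#' @return A data.frame with columns `sequence`, `rank`, `taxon`,
#'   `rankLadder(FALSE)`, `lineage`, then `intensity_<sample>` columns.
#' @export
annotateTaxonomy <- function(ps, db) {
  stopifnot(is(ps, "PeptideSet"), is(db, "ReferenceDb"))
  if (any(!is.na(originClass(ps))))
    ps <- ps[!is.na(originClass(ps)) & originClass(ps) == "microbial", ]
  seqs <- peptideSequences(ps)
  samples <- colnames(intensityMatrix(ps))
  empty <- data.frame(sequence = character(0), rank = character(0),
                      taxon = character(0))
  if (length(seqs) == 0L) {
    for (r in .RANKS) empty[[r]] <- character(0)
    empty$lineage <- character(0)
    for (s in samples) empty[[paste0("intensity_", s)]] <- numeric(0)
    return(empty)
  }
  groups <- as.list(proteinGroups(ps))
  tax_ids <- db@taxonomy$protein_id
  linmat_all <- as.matrix(as.data.frame(db@taxonomy[, .RANKS, drop = FALSE]))
  mode(linmat_all) <- "character"
  dmap <- db@dedupMap
  res <- lapply(groups, function(g) {
    g <- ifelse(g %in% names(dmap), unname(dmap[g]), g)
    idx <- match(unique(g), tax_ids)
    if (anyNA(idx))
      stop("protein id(s) absent from the reference database: ",
           .comma_list(unique(g)[is.na(idx)]), call. = FALSE)
    .lca_core(linmat_all[idx, , drop = FALSE])
  })
  out <- data.frame(sequence = seqs,
                    rank = vapply(res, `[[`, "", "rank"),
                    taxon = vapply(res, `[[`, "", "taxon"))
  for (r in .RANKS)
    out[[r]] <- vapply(res, function(x)
      if (r %in% names(x$lineage)) x$lineage[[r]] else NA_character_, "")
  out$lineage <- vapply(res, function(x) paste(x$lineage, collapse = "|"), "")
  inten <- intensityMatrix(ps)
  for (j in seq_along(samples))
    out[[paste0("intensity_", samples[j])]] <- inten[, j]
  out <- out[.radix_order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distribution of LCA ranks
#'
#' Fraction of the annotated table at each rank of the ladder, either by
#' peptide count or by total intensity (summed over samples).
#'
#' @param annotated Output of [annotateTaxonomy()]; must be non-empty.
#' @param weight `"count"` or `"intensity"`.
#' @return Named numeric vector over `rankLadder()`, summing to 1.
#' @export
rankDistribution <- function(annotated, weight = c("count", "intensity")) {
  weight <- match.arg(weight)
  if (nrow(annotated) == 0L) stop("empty annotated table")
  w <- if (weight == "count") {
    rep(1, nrow(annotated))
  } else {
    icols <- grep("^intensity_", colnames(annotated), value = TRUE)
    rowSums(as.matrix(annotated[, icols, drop = FALSE]))
  }
  tot <- tapply(w, factor(annotated$rank, levels = rankLadder()), sum,
                default = 0)
  stats::setNames(as.vector(tot / sum(tot)), rankLadder())
}
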