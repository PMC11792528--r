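# S4 classes: ReferenceDb (non-redundant protein reference),
# PeptideSet (peptide x sample observations), TaxonomicAssignment (one LCA).

#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData rowData<- colData assayNames
NULL

#' ReferenceDb: a protein reference database with taxonomy and KO lookups
#'
#' Holds one [Biostrings::AAStringSet] of protein sequences (names are
#' protein ids), a parallel taxonomy table (strain plus the rank ladder),
#' an optional KEGG-ortholog assignment per protein, and a map from
#' protein ids retired during exact deduplication to their retained
#' representative. Build one with [mergeProteomes()] or [ReferenceDb()].
#'
#' @slot proteins [Biostrings::AAStringSet], names = protein ids (unique).
#' @slot taxonomy [S4Vectors::DataFrame] with columns `protein_id`,
#'   `strain_id` and the ranks of `rankLadder(FALSE)`, one row per protein,
#'   aligned with `proteins`.
#' @slot ko Named character vector (protein id -> KO, `NA` when absent).
#' @slot dedupMap Named character vector: removed protein id ->
#'   representative protein id present in `proteins`.
#' @aliases ReferenceDb
#' @export
setClass("ReferenceDb",
  slots = c(proteins = "AAStringSet",
            taxonomy = "DataFrame",
            ko = "character",
            dedupMap = "character"))

setValidity("ReferenceDb", function(object) {
  ids <- names(object@proteins)
  msgs <- character(0)
  if (length(object@proteins)) {
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      msgs <- c(msgs, "all proteins must be named by a protein id")
    if (anyDuplicated(ids))
      msgs <- c(msgs, paste0("duplicate protein ids: ",
                             .comma_list(ids[duplicated(ids)])))
    if (any(Biostrings::width(object@proteins) == 0L))
      msgs <- c(msgs, "empty protein sequence(s)")
  }
  needed <- c("protein_id", "strain_id", .RANKS)
  if (!all(needed %in% colnames(object@taxonomy)))
    msgs <- c(msgs, paste0("taxonomy must have columns: ",
                           paste(needed, collapse = ", ")))
  else if (nrow(object@taxonomy) != length(object@proteins) ||
           (length(ids) && !identical(object@taxonomy$protein_id, ids)))
    msgs <- c(msgs, "taxonomy rows must align with proteins")
  if (length(object@ko) != length(object@proteins) ||
      (length(ids) && !identical(names(object@ko), ids)))
    msgs <- c(msgs, "ko must be named by and aligned with protein ids")
  bad_ko <- !is.na(object@ko) & !grepl("^K[0-9]{5}$", object@ko)
  if (any(bad_ko))
    msgs <- c(msgs, paste0("malformed KO id(s): ",
                           .comma_list(object@ko[bad_ko])))
  if (length(object@dedupMap) &&
      !all(object@dedupMap %in% ids))
    msgs <- c(msgs, "dedupMap values must be protein ids present in the collection")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReferenceDb
#'
#' @param proteins Named [Biostrings::AAStringSet] (or named character
#'   vector) of protein sequences; names are protein ids.
#' @param taxonomy data.frame with columns `protein_id`, `strain_id`
#'   (optional, `NA` allowed) and the ranks `rankLadder(FALSE)`; one row per
#'   protein. Rows are matched to `proteins` by `protein_id`.
#' @param ko Optional named character vector or two-column data.frame
#'   (`protein_id`, `ko`) of KEGG-ortholog assignments.
#' @param dedupMap Named character vector of retired id -> representative id.
#' @return A [ReferenceDb-class] object.
#' @export
ReferenceDb <- function(proteins, taxonomy, ko = NULL,
                        dedupMap = character(0)) {
  if (!is(proteins, "AAStringSet")) proteins <- AAStringSet(proteins)
  ids <- names(proteins)
  if (is.null(ids)) ids <- character(0)
  taxonomy <- as.data.frame(taxonomy)
  if (!"strain_id" %in% colnames(taxonomy)) taxonomy$strain_id <- NA_character_
  idx <- match(ids, taxonomy$protein_id)
  if (anyNA(idx)) {
    stop("no taxonomy row for protein id(s): ", .comma_list(ids[is.na(idx)]))
  }
  taxonomy <- taxonomy[idx, , drop = FALSE]
  for (r in .RANKS) taxonomy[[r]] <- .blank_to_na(taxonomy[[r]])
  taxonomy$phylum <- normalizePhylumName(taxonomy$phylum)
  tax <- DataFrame(protein_id = ids,
                   strain_id = .blank_to_na(taxonomy$strain_id))
  for (r in .RANKS) tax[[r]] <- taxonomy[[r]]
  kovec <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(ko)) {
    if (is.data.frame(ko)) ko <- stats::setNames(.blank_to_na(ko$ko), ko$protein_id)
    hit <- intersect(names(ko), ids)
    kovec[hit] <- unname(ko[hit])
  }
  new("ReferenceDb", proteins = proteins, taxonomy = tax,
      ko = kovec, dedupMap = dedupMap)
}

setMethod("show", "ReferenceDb", function(object) {
  cat("ReferenceDb with", length(object@proteins), "protein sequence(s)\n")
  cat("  strains:", length(unique(stats::na.omit(object@taxonomy$strain_id))),
      " species:", length(unique(stats::na.omit(object@taxonomy$species))),
      " KO-annotated:", sum(!is.na(object@ko)), "\n")
  if (length(object@dedupMap))
    cat("  dedupMap:", length(object@dedupMap),
        "retired id(s) resolved to representatives\n")
})

#' TaxonomicAssignment: the LCA result for one peptide
#'
#' @slot taxon Taxon name at the resolved rank (`"Root"` when the protein
#'   group agrees on nothing below superkingdom).
#' @slot rank Rank of the assignment, one of `rankLadder()`.
#' @slot lineage Named character vector: the lineage prefix ending at
#'   `taxon`.
#' @aliases TaxonomicAssignment
#' @export
setClass("TaxonomicAssignment",
  slots = c(taxon = "character", rank = "character", lineage = "character"))

setValidity("TaxonomicAssignment", function(object) {
  if (length(object@taxon) != 1L || length(object@rank) != 1L)
    return("taxon and rank must be length-1")
  if (!object@rank %in% rankLadder())
    return(paste0("unknown rank: ", object@rank))
  deepest <- names(object@lineage)[length(object@lineage)]
  if (!identical(deepest, object@rank))
    return("rank must equal the deepest rank of the lineage")
  TRUE
})

#' @rdname TaxonomicAssignment-class
#' @param taxon,rank,lineage See slots.
#' @export
TaxonomicAssignment <- function(taxon, rank, lineage) {
  new("TaxonomicAssignment", taxon = taxon, rank = rank, lineage = lineage)
}

setMethod("show", "TaxonomicAssignment", function(object) {
  cat("TaxonomicAssignment:", object@taxon, sprintf("[%s]\n", object@rank))
  cat(" ", paste(object@lineage, collapse = " | "), "\n")
})

#' PeptideSet: peptide-level search results as a SummarizedExperiment
#'
#' Rows are identified peptides, columns are samples; the single assay
#' `"intensity"` carries non-negative MS intensities (0 = not quantified in
#' that sample). Row metadata holds the protein group each peptide maps to,
#' decoy/contaminant flags from the search engine, and the origin class
#' (`"microbial"`, `"host"` or `"ambiguous"`) once [classifyOrigin()] has
#' run. Build one with [readPeptides()] or [PeptideSet()].
#'
#' @aliases PeptideSet
#' @export
setClass("PeptideSet", contains = "SummarizedExperiment")

setValidity("PeptideSet", function(object) {
  msgs <- character(0)
  if (!"intensity" %in% assayNames(object))
    return("PeptideSet needs an 'intensity' assay")
  rd <- rowData(object)
  needed <- c("proteinGroup", "isDecoy", "isContaminant", "originClass")
  if (!all(needed %in% colnames(rd)))
    return(paste0("rowData must have columns: ", paste(needed, collapse = ", ")))
  seqs <- rownames(object)
  if (nrow(object)) {
    if (is.null(seqs) || !all(.is_aa(seqs)))
      msgs <- c(msgs, "row names must be plain uppercase peptide sequences")
    if (any(lengths(rd$proteinGroup) == 0L))
      msgs <- c(msgs, "every peptide needs a non-empty protein group")
    if (any(assay(object, "intensity") < 0, na.rm = TRUE))
      msgs <- c(msgs, "intensities must be non-negative")
    bad <- !(rd$originClass %in% c("microbial", "host", "ambiguous")) &
      !is.na(rd$originClass)
    if (any(bad)) msgs <- c(msgs, "originClass must be microbial/host/ambiguous or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PeptideSet
#'
#' @param sequence Character vector of plain uppercase peptide sequences.
#' @param proteinGroup List (or [IRanges::CharacterList]) of protein-id
#'   vectors, one per peptide.
#' @param intensities Numeric matrix, peptides x samples (column names are
#'   sample ids). `NA` is replaced by 0 (not quantified).
#' @param isDecoy,isContaminant Logical flags per peptide.
#' @param originClass Optional per-peptide class; usually left `NA` until
#'   [classifyOrigin()].
#' @return A [PeptideSet-class] object.
#' @export
PeptideSet <- function(sequence, proteinGroup, intensities,
                       isDecoy = FALSE, isContaminant = FALSE,
                       originClass = NA_character_) {
  n <- length(sequence)
  intensities <- as.matrix(intensities)
  intensities[is.na(intensities)] <- 0
  rd <- DataFrame(proteinGroup = CharacterList(proteinGroup),
                  isDecoy = rep_len(as.logical(isDecoy), n),
                  isContaminant = rep_len(as.logical(isContaminant), n),
                  originClass = rep_len(as.character(originClass), n))
  se <- SummarizedExperiment(assays = list(intensity = intensities),
                             rowData = rd)
  rownames(se) <- sequence
  new("PeptideSet", se)
}

setMethod("show", "PeptideSet", function(object) {
  cat("PeptideSet:", nrow(object), "peptide(s) x", ncol(object), "sample(s)\n")
  rd <- rowData(object)
  cat("  decoys:", sum(rd$isDecoy), " contaminants:", sum(rd$isContaminant), "\n")
  oc <- rd$originClass
  if (any(!is.na(oc))) {
    tb <- table(factor(oc, c("microbial", "host", "ambiguous")))
    cat("  origin:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})
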