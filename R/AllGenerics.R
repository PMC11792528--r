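# Accessor generics. Slot access stays internal; user code goes through
# these.

#' @describeIn ReferenceDb-class Protein ids (FASTA-order).
#' @param x,object A `ReferenceDb` or `PeptideSet`.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname ReferenceDb-class
#' @export
setMethod("proteinIds", "ReferenceDb", function(x) names(x@proteins))

#' @describeIn ReferenceDb-class Protein sequences as an
#'   [Biostrings::AAStringSet].
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ReferenceDb-class
#' @export
setMethod("sequences", "ReferenceDb", function(x) x@proteins)

#' @describeIn ReferenceDb-class Per-protein taxonomy as a data.frame
#'   (`protein_id`, `strain_id`, then the rank ladder).
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname ReferenceDb-class
#' @export
setMethod("taxonomyTable", "ReferenceDb", function(x) as.data.frame(x@taxonomy))

#' @describeIn ReferenceDb-class Named KO vector (protein id -> KO, `NA`
#'   when unannotated).
#' @export
setGeneric("koAssignments", function(x) standardGeneric("koAssignments"))

#' @rdname ReferenceDb-class
#' @export
setMethod("koAssignments", "ReferenceDb", function(x) x@ko)

#' @describeIn ReferenceDb-class Retired id -> representative id map built
#'   by [deduplicateExact()].
#' @export
setGeneric("dedupMap", function(x) standardGeneric("dedupMap"))

#' @rdname ReferenceDb-class
#' @export
setMethod("dedupMap", "ReferenceDb", function(x) x@dedupMap)

#' @rdname ReferenceDb-class
#' @export
setMethod("length", "ReferenceDb", function(x) length(x@proteins))

#' @describeIn PeptideSet-class Protein groups as an
#'   [IRanges::CharacterList], one element per peptide.
#' @param x A `PeptideSet`.
#' @export
setGeneric("proteinGroups", function(x) standardGeneric("proteinGroups"))

#' @rdname PeptideSet-class
#' @export
setMethod("proteinGroups", "PeptideSet",
          function(x) rowData(x)$proteinGroup)

#' @describeIn PeptideSet-class Peptide sequences (row names).
#' @export
setGeneric("peptideSequences", function(x) standardGeneric("peptideSequences"))

#' @rdname PeptideSet-class
#' @export
setMethod("peptideSequences", "PeptideSet", function(x) rownames(x))

#' @describeIn PeptideSet-class Decoy flags.
#' @export
setGeneric("isDecoy", function(x) standardGeneric("isDecoy"))

#' @rdname PeptideSet-class
#' @export
setMethod("isDecoy", "PeptideSet", function(x) rowData(x)$isDecoy)

#' @describeIn PeptideSet-class Contaminant flags.
#' @export
setGeneric("isContaminant", function(x) standardGeneric("isContaminant"))

#' @rdname PeptideSet-class
#' @export
setMethod("isContaminant", "PeptideSet", function(x) rowData(x)$isContaminant)

#' @describeIn PeptideSet-class Origin class (`NA` until
#'   [classifyOrigin()] has run).
#' @export
setGeneric("originClass", function(x) standardGeneric("originClass"))

#' @rdname PeptideSet-class
#' @export
setMethod("originClass", "PeptideSet", function(x) rowData(x)$originClass)

#' @describeIn PeptideSet-class Intensity assay (peptides x samples).
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname PeptideSet-class
#' @export
setMethod("intensityMatrix", "PeptideSet",
          function(x) assay(x, "intensity"))
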