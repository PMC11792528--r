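# Building the non-redundant protein reference from per-strain proteome
# FASTAs. Deduplication is exact full-length string equality: at 100%
# identity with full-length coverage, sequence clustering reduces to exact
# duplicate removal, so no external clustering tool is involved.

.parse_fasta_headers <- function(headers) {
  toks <- strsplit(headers, "[ \t]+")
  list(protein_id = vapply(toks, `[`, "", 1L),
       strain_id = vapply(toks, function(t)
         if (length(t) >= 2L) t[2L] else NA_character_, ""))
}

#' Merge per-strain proteome FASTAs into one reference collection
#'
#' Reads every FASTA in `fastaPaths` (file order, then record order — the
#' order is deterministic and preserved), attaches a lineage to every
#' protein from `taxonomyTable`, and a KEGG ortholog where `koTable` has
#' one. The result is the pre-deduplication reference; follow with
#' [deduplicateExact()].
#'
#' FASTA headers are `protein_id` optionally followed by whitespace and a
#' `strain_id`. `taxonomyTable` may be keyed per protein (`protein_id`
#' column) or per strain (`strain_id` column, expanded to all of the
#' strain's proteins); per-protein keys win when both resolve.
#'
#' @param fastaPaths Character vector of FASTA file paths.
#' @param taxonomyTable data.frame (or TSV path) with a `protein_id` and/or
#'   `strain_id` key column plus the rank columns `rankLadder(FALSE)`.
#' @param koTable Optional data.frame (or TSV path) with columns
#'   `protein_id`, `ko`; empty cells mean no KO.
#' @return A [ReferenceDb-class] (not yet deduplicated).
#' @seealso [deduplicateExact()], [censusTaxa()], [writeReferenceDb()]
#' @export
mergeProteomes <- function(fastaPaths, taxonomyTable, koTable = NULL) {
  if (is.character(taxonomyTable)) taxonomyTable <- .read_tsv(taxonomyTable)
  if (is.character(koTable)) koTable <- .read_tsv(koTable)
  taxonomyTable <- as.data.frame(taxonomyTable)
  if (!any(c("protein_id", "strain_id") %in% colnames(taxonomyTable)))
    stop("taxonomyTable needs a 'protein_id' or 'strain_id' key column")
  missing_ranks <- setdiff(.RANKS, colnames(taxonomyTable))
  if (length(missing_ranks))
    stop("taxonomyTable is missing rank column(s): ",
         paste(missing_ranks, collapse = ", "))

  aa_list <- vector("list", length(fastaPaths))
  for (i in seq_along(fastaPaths)) {
    p <- fastaPaths[i]
    aa <- tryCatch(Biostrings::readAAStringSet(p), error = function(e)
      stop("malformed FASTA '", p, "': ", conditionMessage(e), call. = FALSE))
    if (length(aa) == 0L)
      stop("malformed FASTA '", p, "': no records (line 1)")
    aa_list[[i]] <- aa
  }
  aa <- do.call(c, aa_list)
  hd <- .parse_fasta_headers(names(aa))
  if (anyDuplicated(hd$protein_id))
    stop("duplicate protein id(s) across files: ",
         .comma_list(hd$protein_id[duplicated(hd$protein_id)]))
  names(aa) <- hd$protein_id

  # resolve lineages: per-protein key first, strain key as fallback
  n <- length(aa)
  row_idx <- rep(NA_integer_, n)
  if ("protein_id" %in% colnames(taxonomyTable))
    row_idx <- match(hd$protein_id, taxonomyTable$protein_id)
  strain <- hd$strain_id
  if ("strain_id" %in% colnames(taxonomyTable)) {
    fallback <- match(strain, taxonomyTable$strain_id)
    row_idx[is.na(row_idx)] <- fallback[is.na(row_idx)]
    # strain recorded in the table wins over a missing header token
    strain[is.na(strain)] <-
      as.character(taxonomyTable$strain_id[row_idx])[is.na(strain)]
  }
  if (anyNA(row_idx)) {
    bad <- which(is.na(row_idx))
    lab <- ifelse(is.na(strain[bad]), hd$protein_id[bad],
                  paste0(hd$protein_id[bad], " (strain ", strain[bad], ")"))
    stop("unresolvable taxonomy for: ", .comma_list(lab), call. = FALSE)
  }
  tax <- data.frame(protein_id = hd$protein_id, strain_id = strain)
  for (r in .RANKS) tax[[r]] <- .blank_to_na(taxonomyTable[[r]][row_idx])

  ko <- NULL
  if (!is.null(koTable)) {
    ko <- stats::setNames(.blank_to_na(as.character(koTable$ko)),
                          koTable$protein_id)
    ko <- ko[!is.na(ko)]
    bad_ko <- !grepl("^K[0-9]{5}$", ko)
    if (any(bad_ko))
      stop("malformed KO id(s): ", .comma_list(ko[bad_ko]))
  }
  ReferenceDb(aa, tax, ko = ko)
}

#' Remove exact duplicate sequences
#'
#' Retains exactly one representative per distinct sequence string — the
#' record whose protein id sorts first in the C locale, for determinism —
#' and records every removed id in `dedupMap(db)` so that search results
#' referring to a retired id still resolve. Raw strings are compared
#' (residue `X` kept verbatim, no I/L equivalence). Idempotent.
#'
#' @param db A non-empty [ReferenceDb-class].
#' @return A deduplicated [ReferenceDb-class]; record order is the input
#'   order restricted to the representatives.
#' @export
deduplicateExact <- function(db) {
  stopifnot(is(db, "ReferenceDb"))
  if (length(db) == 0L) stop("cannot deduplicate an empty collection")
  seqs <- as.character(db@proteins)
  ids <- names(db@proteins)
  rep_of_class <- vapply(split(ids, seqs), function(v) .radix_sort(v)[1L], "")
  reps <- unname(rep_of_class[seqs])
  keep <- ids == reps
  newmap <- stats::setNames(reps[!keep], ids[!keep])
  resolve <- function(x) ifelse(x %in% names(newmap), unname(newmap[x]), x)
  old <- db@dedupMap
  combined <- c(newmap,
                if (length(old)) stats::setNames(resolve(unname(old)), names(old))
                else character(0))
  new("ReferenceDb",
      proteins = db@proteins[keep],
      taxonomy = db@taxonomy[keep, , drop = FALSE],
      ko = db@ko[keep],
      dedupMap = combined)
}

#' Census of distinct taxa per rank
#'
#' Counts the distinct taxon names at each rank over all records' lineages
#' (unfilled ranks are skipped).
#'
#' @param db A [ReferenceDb-class].
#' @return Named integer vector over `rankLadder(FALSE)`.
#' @export
censusTaxa <- function(db) {
  stopifnot(is(db, "ReferenceDb"))
  vapply(.RANKS, function(r)
    length(unique(stats::na.omit(as.character(db@taxonomy[[r]])))),
    integer(1))
}

#' Write / read a reference database
#'
#' `writeReferenceDb()` writes `<prefix>.fasta` (60-character wrapped,
#' headers `protein_id strain_id`), `<prefix>.taxonomy.tsv`,
#' `<prefix>.ko.tsv` (empty cell = no KO) and, when non-empty,
#' `<prefix>.dedup.tsv`. `readReferenceDb()` round-trips them losslessly.
#'
#' @param db A [ReferenceDb-class]; must be non-empty.
#' @param prefix Output path prefix.
#' @return `writeReferenceDb()` returns the written paths invisibly;
#'   `readReferenceDb()` returns a [ReferenceDb-class].
#' @export
writeReferenceDb <- function(db, prefix) {
  stopifnot(is(db, "ReferenceDb"))
  if (length(db) == 0L) stop("refusing to write an empty database")
  aa <- db@proteins
  strain <- as.character(db@taxonomy$strain_id)
  names(aa) <- ifelse(is.na(strain), names(aa), paste(names(aa), strain))
  paths <- c(fasta = paste0(prefix, ".fasta"),
             taxonomy = paste0(prefix, ".taxonomy.tsv"),
             ko = paste0(prefix, ".ko.tsv"))
  Biostrings::writeXStringSet(aa, paths[["fasta"]], width = 60L)
  .write_tsv(as.data.frame(db@taxonomy), paths[["taxonomy"]])
  .write_tsv(data.frame(protein_id = names(db@ko), ko = unname(db@ko)),
             paths[["ko"]])
  if (length(db@dedupMap)) {
    paths <- c(paths, dedup = paste0(prefix, ".dedup.tsv"))
    .write_tsv(data.frame(removed_id = names(db@dedupMap),
                          representative_id = unname(db@dedupMap)),
               paths[["dedup"]])
  }
  invisible(paths)
}

#' @rdname writeReferenceDb
#' @export
readReferenceDb <- function(prefix) {
  db <- mergeProteomes(paste0(prefix, ".fasta"),
                       paste0(prefix, ".taxonomy.tsv"),
                       paste0(prefix, ".ko.tsv"))
  dedup_path <- paste0(prefix, ".dedup.tsv")
  if (file.exists(dedup_path)) {
    dd <- .read_tsv(dedup_path)
    db@dedupMap <- stats::setNames(as.character(dd$representative_id),
                                   dd$removed_id)
    validObject(db)
  }
  db
}
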