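# Intensity-weighted taxonomic composition, headline ratios and peptide-set
# overlaps. Composition keeps an explicit "Unannotated-at-rank" bin for
# peptides whose LCA is coarser than the requested rank, so total intensity
# is conserved and fractions always sum to 1.

.intensity_col <- function(annotated, sample) {
  col <- paste0("intensity_", sample)
  if (!col %in% colnames(annotated))
    stop("no intensity column for sample '", sample, "'", call. = FALSE)
  annotated[[col]]
}

#' Taxonomic composition at a rank
#'
#' Aggregates peptide intensities by the taxon each peptide's lineage
#' carries at `rank`. Peptides whose LCA is coarser than `rank` contribute
#' to an explicit `"Unannotated-at-rank"` entry; taxa below
#' `othersThreshold` (fraction of the sample's summed microbial intensity)
#' are merged into `"others"`.
#'
#' @param annotated Output of [annotateTaxonomy()].
#' @param rank A rank from `rankLadder(FALSE)`.
#' @param sample Sample id (an `intensity_<sample>` column must exist).
#' @param othersThreshold Relative-abundance cutoff below which taxa merge
#'   into `"others"`; default 0.02 (2%).
#' @return data.frame with columns `sample`, `rank`, `taxon`, `fraction`;
#'   fractions sum to 1. The sample's total intensity is attached as
#'   `attr(, "total_intensity")`.
#' @export
compositionAtRank <- function(annotated, rank, sample,
                              othersThreshold = 0.02) {
  if (!rank %in% .RANKS)
    stop("unknown rank: ", rank, call. = FALSE)
  inten <- .intensity_col(annotated, sample)
  if (nrow(annotated) == 0L || sum(inten) <= 0)
    stop("no intensity for sample '", sample, "'", call. = FALSE)
  taxon <- as.character(annotated[[rank]])
  taxon[is.na(taxon)] <- "Unannotated-at-rank"
  tot <- tapply(inten, taxon, sum)
  frac <- tot / sum(tot)
  small <- names(frac)[frac < othersThreshold &
                         names(frac) != "Unannotated-at-rank"]
  if (length(small)) {
    frac <- c(frac[!names(frac) %in% small], others = sum(frac[small]))
  }
  keep <- setdiff(names(frac), c("others", "Unannotated-at-rank"))
  nm <- c(keep[.radix_order(-frac[keep])],
          intersect(c("others", "Unannotated-at-rank"), names(frac)))
  out <- data.frame(sample = sample, rank = rank, taxon = nm,
                    fraction = as.vector(frac[nm]))
  attr(out, "total_intensity") <- sum(inten)
  out
}

.phylum_intensity <- function(annotated, sample, phylum) {
  inten <- .intensity_col(annotated, sample)
  phy <- normalizePhylumName(as.character(annotated$phylum))
  sum(inten[!is.na(phy) & phy == phylum])
}

#' Bacillota/Bacteroidota (Firmicutes/Bacteroidetes) intensity ratio
#'
#' Summed intensity of peptides whose lineage contains phylum Bacillota
#' divided by the same for Bacteroidota, after synonym normalization, for
#' one sample. A classical gut-microbiome summary statistic.
#'
#' @inheritParams compositionAtRank
#' @return Positive numeric ratio.
#' @export
fbRatio <- function(annotated, sample) {
  num <- .phylum_intensity(annotated, sample, "Bacillota")
  den <- .phylum_intensity(annotated, sample, "Bacteroidota")
  if (den <= 0)
    stop("zero Bacteroidota intensity in sample '", sample,
         "': ratio undefined", call. = FALSE)
  num / den
}

#' Microbe/host intensity ratio
#'
#' Summed intensity of microbial peptides divided by that of host peptides
#' for one sample; ambiguous peptides are excluded from both.
#'
#' @param ps A [PeptideSet-class] with origin classes set (see
#'   [classifyOrigin()]).
#' @param sample Sample id (a column of the intensity assay).
#' @return Positive numeric ratio.
#' @export
mhRatio <- function(ps, sample) {
  stopifnot(is(ps, "PeptideSet"))
  if (all(is.na(originClass(ps))))
    stop("run classifyOrigin() first", call. = FALSE)
  inten <- intensityMatrix(ps)
  if (!sample %in% colnames(inten))
    stop("no such sample: ", sample, call. = FALSE)
  x <- inten[, sample]
  cls <- originClass(ps)
  num <- sum(x[cls == "microbial"])
  den <- sum(x[cls == "host"])
  if (den <= 0)
    stop("zero host intensity in sample '", sample, "': ratio undefined",
         call. = FALSE)
  num / den
}

#' Venn-region counts for named peptide sets
#'
#' Partitions the union of the sets into exclusive membership regions and
#' counts each, e.g. comparing the peptides identified against two
#' databases. Region names join the member set names with `"&"`.
#'
#' @param resultSets Named list (>= 2 elements) of character vectors of
#'   peptide sequences.
#' @return Named integer vector over all non-empty set combinations
#'   (zero counts included); the counts sum to the size of the union.
#' @examples
#' peptideOverlap(list(A = c("x", "y", "z"), B = c("y", "z", "w")))
#' @export
peptideOverlap <- function(resultSets) {
  if (length(resultSets) < 2L || is.null(names(resultSets)) ||
      any(!nzchar(names(resultSets))))
    stop("need >= 2 named peptide sets")
  resultSets <- lapply(resultSets, unique)
  universe <- unique(unlist(resultSets))
  member <- vapply(resultSets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(resultSets)))
  nm <- names(resultSets)
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  if (length(universe)) {
    key <- apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
    tab <- table(key)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
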