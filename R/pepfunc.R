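# Functional annotation: strict-consensus peptide -> KEGG-ortholog mapping,
# pathway peptide sets, a rank-based per-sample enrichment score in the
# GSVA family, and group-contrast significance.

#' Strict-consensus KO for one peptide
#'
#' A peptide inherits a KEGG ortholog only when every member of its protein
#' group carries the same KO. Any disagreement, any member without a KO,
#' or an empty group yields no annotation (`NA`): the conservative reading
#' of "annotate only when all KOs in the group are identical". The result
#' is invariant to protein-group order and duplication.
#'
#' @param proteinGroup Character vector of protein ids.
#' @param ko Either a [ReferenceDb-class] (ids resolve through its
#'   `dedupMap`) or a named character vector protein id -> KO (`NA` =
#'   none).
#' @return A single KO id, or `NA_character_`.
#' @examples
#' consensusKO(c("p1", "p2"), c(p1 = "K00001", p2 = "K00001"))
#' consensusKO(c("p1", "p2"), c(p1 = "K00001", p2 = "K00002"))
#' @export
consensusKO <- function(proteinGroup, ko) {
  if (is(ko, "ReferenceDb")) {
    ids <- .resolve_ids(proteinGroup, ko)
    kos <- unname(koAssignments(ko)[ids])
  } else {
    kos <- unname(ko[unique(proteinGroup)])
  }
  if (length(kos) == 0L || anyNA(kos)) return(NA_character_)
  u <- unique(kos)
  if (length(u) == 1L) u else NA_character_
}

#' Build a peptide-to-KO database
#'
#' Applies the strict-consensus rule to every peptide and returns the
#' mappable subset as a two-column table (peptide, KO) in deterministic
#' (C-locale sequence) order, optionally written as TSV for use as a
#' custom peptide-to-KEGG table.
#'
#' @param ps A filtered [PeptideSet-class].
#' @param db A [ReferenceDb-class] (or named KO vector).
#' @param file Optional TSV output path.
#' @return data.frame with columns `peptide`, `ko` (only mapped peptides).
#' @export
buildPeptideKoDb <- function(ps, db, file = NULL) {
  stopifnot(is(ps, "PeptideSet"))
  groups <- as.list(proteinGroups(ps))
  kos <- vapply(groups, consensusKO, "", ko = db)
  out <- data.frame(peptide = peptideSequences(ps), ko = kos)
  out <- out[!is.na(out$ko), , drop = FALSE]
  out <- out[.radix_order(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) .write_tsv(out, file)
  out
}

#' Pathway peptide sets
#'
#' Joins a peptide-to-KO map with a KO-to-pathway membership table: a
#' peptide joins every pathway containing its KO. Pathways with fewer than
#' `minSize` peptides are dropped.
#'
#' @param koMap data.frame from [buildPeptideKoDb()] (columns `peptide`,
#'   `ko`).
#' @param koToPathway data.frame (or TSV path) with columns `ko`,
#'   `pathway_id` (optionally `pathway_name`).
#' @param minSize Minimum peptides per pathway set (default 5).
#' @return Named list: pathway id -> character vector of peptides.
#' @export
pathwayPeptideSets <- function(koMap, koToPathway, minSize = 5L) {
  if (is.character(koToPathway)) koToPathway <- .read_tsv(koToPathway)
  joined <- merge(koMap, koToPathway[, c("ko", "pathway_id")], by = "ko")
  sets <- lapply(split(joined$peptide, joined$pathway_id), unique)
  sets <- sets[lengths(sets) >= minSize]
  sets[.radix_sort(names(sets))]
}

# per-sample rank walk shared by gsvaScores; x = one sample's intensities
.sample_walk <- function(e, setMask, tau, scoreType) {
  n <- length(e)
  m <- sum(setMask)
  if (m == 0L || m == n) return(0)
  rk <- rank(e, ties.method = "average")
  ord <- .radix_order(-e, names(e))
  inset <- setMask[ord]
  w <- abs(rk[ord])^tau
  steps <- ifelse(inset, w / sum(w[inset]), -1 / (n - m))
  v <- cumsum(steps)
  if (scoreType == "maxdev") {
    v[which.max(abs(v))]
  } else {
    max(0, max(v)) + min(0, min(v))
  }
}

#' Per-sample pathway enrichment scores (GSVA-style rank walk)
#'
#' For each sample, peptide intensities are log2(x+1)-transformed and
#' ranked; walking down the list ordered by decreasing expression, in-set
#' peptides step the running sum up proportionally to `|rank|^tau` and
#' out-of-set peptides step it down uniformly — a Kolmogorov-Smirnov-like
#' random walk. The score is the signed maximum deviation from zero
#' (`scoreType = "maxdev"`, default) or the sum of the largest positive
#' and negative deviations (`"diff"`); either is bounded in [-1, 1].
#' Because only ranks enter, scores are invariant to any strictly
#' monotone per-sample transform of the intensities. A set spanning the
#' whole matrix has an empty complement and scores 0; a set sharing no
#' peptide with the matrix is skipped with a warning.
#'
#' @param x Peptide x sample intensity matrix (row names = peptides), or a
#'   [PeptideSet-class] (its intensity assay is used). At least 3 samples.
#' @param pathwaySets Named list from [pathwayPeptideSets()].
#' @param tau Rank-weight exponent for in-set steps (default 1).
#' @param scoreType `"maxdev"` or `"diff"`.
#' @param logTransform log2(x+1)-transform intensities first (default
#'   TRUE); ranks are unchanged by it, it only documents the scale.
#' @return Numeric matrix, pathway x sample.
#' @export
gsvaScores <- function(x, pathwaySets, tau = 1,
                       scoreType = c("maxdev", "diff"),
                       logTransform = TRUE) {
  scoreType <- match.arg(scoreType)
  if (is(x, "PeptideSet")) x <- intensityMatrix(x)
  x <- as.matrix(x)
  if (ncol(x) < 3L) stop("need at least 3 samples")
  if (is.null(rownames(x))) stop("x needs peptide row names")
  e <- if (logTransform) log2(x + 1) else x
  keep <- vapply(pathwaySets, function(s) any(rownames(x) %in% s),
                 logical(1))
  if (any(!keep))
    warning("skipping pathway set(s) sharing no peptide with the matrix: ",
            .comma_list(names(pathwaySets)[!keep]))
  pathwaySets <- pathwaySets[keep]
  scores <- matrix(NA_real_, length(pathwaySets), ncol(x),
                   dimnames = list(names(pathwaySets), colnames(x)))
  for (j in seq_len(ncol(e))) {
    ej <- stats::setNames(e[, j], rownames(x))
    for (p in names(pathwaySets)) {
      mask <- rownames(x) %in% pathwaySets[[p]]
      scores[p, j] <- .sample_walk(ej, mask, tau, scoreType)
    }
  }
  scores
}

#' Group-contrast significance of enrichment scores
#'
#' Per pathway, a one-way ANOVA F-test of the enrichment scores across
#' group labels, followed by Benjamini-Hochberg adjustment. Pathways whose
#' scores carry no variance at all (identical across groups) get p = 1.
#'
#' @param scores Pathway x sample matrix from [gsvaScores()].
#' @param groups Group label per sample: a (optionally named) vector
#'   aligned with `colnames(scores)`. At least 2 groups with at least 2
#'   samples each.
#' @param alpha Adjusted-p threshold for the `significant` flag (default
#'   `1e-6`).
#' @return data.frame with columns `pathway`, `p`, `p_adj`, `significant`.
#' @export
enrichmentSignificance <- function(scores, groups, alpha = 1e-6) {
  scores <- as.matrix(scores)
  if (!is.null(names(groups))) {
    if (!all(colnames(scores) %in% names(groups)))
      stop("groups must cover every sample")
    groups <- groups[colnames(scores)]
  }
  g <- factor(as.character(groups))
  if (length(g) != ncol(scores))
    stop("one group label per sample is required")
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  p <- apply(scores, 1L, function(y) {
    if (stats::var(y) < 1e-24) return(1)
    pv <- stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1L]
    if (is.na(pv)) 1 else pv
  })
  data.frame(pathway = rownames(scores), p = unname(p),
             p_adj = stats::p.adjust(unname(p), method = "BH"),
             significant = stats::p.adjust(unname(p), method = "BH") < alpha)
}
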