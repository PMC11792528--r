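# Flat rank-ladder taxonomy and lowest-common-ancestor resolution.
#
# Lineages live on a fixed eight-level ladder (root, then superkingdom down
# to species). A lineage may terminate early (unranked below some level) but
# never has gaps: every rank above its terminal rank is filled. The LCA of a
# set of lineages is the deepest rank at which all of them carry the same
# taxon name; agreement only at superkingdom (or nothing at all) reports as
# the uninformative "Root", so superkingdom never appears as an LCA rank.

.RANKS <- c("superkingdom", "phylum", "class", "order", "family",
            "genus", "species")

#' The taxonomic rank ladder
#'
#' Ordered rank names used throughout the package, from coarse to fine.
#'
#' @param includeRoot Prepend `"root"` to the ladder.
#' @return Character vector of rank names.
#' @examples
#' rankLadder()
#' @export
rankLadder <- function(includeRoot = TRUE) {
  if (includeRoot) c("root", .RANKS) else .RANKS
}

.synonym_cache <- new.env(parent = emptyenv())

.phylum_synonym_map <- function() {
  if (is.null(.synonym_cache$map)) {
    path <- system.file("extdata", "phylum_synonyms.tsv", package = "metapep")
    tab <- .read_tsv(path)
    .synonym_cache$map <- stats::setNames(tab$canonical, tab$name)
  }
  .synonym_cache$map
}

#' Normalize legacy phylum names
#'
#' Maps legacy/current phylum synonym pairs onto one canonical vocabulary
#' (Firmicutes/Bacillota, Bacteroidetes/Bacteroidota,
#' Actinobacteria/Actinomycetota, Tenericutes/Mycoplasmatota). Names without
#' a synonym entry pass through unchanged. Normalization is applied before
#' any LCA computation so that a legacy and a current spelling of the same
#' phylum can never split a protein group.
#'
#' @param name Character vector of phylum names (`NA` allowed).
#' @param synonyms Optional replacement table with columns `name` and
#'   `canonical`; defaults to the table shipped in
#'   `system.file("extdata", "phylum_synonyms.tsv", package = "metapep")`.
#' @return Character vector of canonical names.
#' @examples
#' normalizePhylumName(c("Firmicutes", "Bacillota", "Verrucomicrobia"))
#' @export
normalizePhylumName <- function(name, synonyms = NULL) {
  map <- if (is.null(synonyms)) {
    .phylum_synonym_map()
  } else {
    stats::setNames(synonyms$canonical, synonyms$name)
  }
  hit <- match(name, names(map))
  out <- ifelse(is.na(hit), name, unname(map)[hit])
  out[is.na(name)] <- NA_character_
  out
}

# Coerce lineages (data.frame / matrix with rank columns, or list of named
# character vectors) to an n x 7 character matrix with columns .RANKS.
.as_lineage_matrix <- function(lineages) {
  if (is.list(lineages) && !is.data.frame(lineages)) {
    lineages <- do.call(rbind, lapply(lineages, function(l) {
      row <- stats::setNames(rep(NA_character_, length(.RANKS)), .RANKS)
      keep <- intersect(names(l), .RANKS)
      row[keep] <- as.character(l[keep])
      row
    }))
  }
  lineages <- as.matrix(lineages)
  mode(lineages) <- "character"
  missing_cols <- setdiff(.RANKS, colnames(lineages))
  if (length(missing_cols)) {
    pad <- matrix(NA_character_, nrow(lineages), length(missing_cols),
                  dimnames = list(NULL, missing_cols))
    lineages <- cbind(lineages, pad)
  }
  lineages <- lineages[, .RANKS, drop = FALSE]
  lineages[!is.na(lineages) & !nzchar(lineages)] <- NA_character_
  # contiguity: once a rank is unfilled, everything deeper must be too
  filled <- !is.na(lineages)
  gap <- apply(filled, 1L, function(f) any(diff(as.integer(f)) > 0L))
  if (any(gap)) {
    stop("lineage with a gap above its terminal rank at row(s): ",
         .comma_list(which(gap)))
  }
  lineages
}

# core LCA over a lineage matrix; returns list(rank, taxon, depth) where
# depth indexes .RANKS (0 = no agreement below root). Superkingdom-level
# agreement is reported as root.
.lca_core <- function(linmat) {
  linmat[, "phylum"] <- normalizePhylumName(linmat[, "phylum"])
  depth <- 0L
  for (k in seq_along(.RANKS)) {
    col <- linmat[, k]
    if (anyNA(col)) break
    u <- unique(col)
    if (length(u) != 1L) break
    depth <- k
  }
  if (depth <= 1L) {
    list(rank = "root", taxon = "Root",
         lineage = stats::setNames("Root", "root"))
  } else {
    list(rank = .RANKS[depth], taxon = unname(linmat[1L, depth]),
         lineage = stats::setNames(unname(linmat[1L, seq_len(depth)]),
                                   .RANKS[seq_len(depth)]))
  }
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the deepest (rank, taxon) pair shared by all lineages. Lineages
#' that agree on nothing below superkingdom collapse to the uninformative
#' `("root", "Root")` assignment: a peptide matching proteins from two
#' phyla is still annotated, just without taxonomic information. Phylum
#' names are synonym-normalized (see [normalizePhylumName()]) before
#' comparison.
#'
#' @param lineages A data.frame/matrix with rank-named columns (any subset
#'   of `rankLadder(FALSE)`), one row per lineage, or a list of named
#'   character vectors. Must be non-empty.
#' @return A [TaxonomicAssignment-class] object.
#' @examples
#' lin <- data.frame(
#'   superkingdom = "Bacteria", phylum = c("Bacillota", "Bacillota"),
#'   class = "Clostridia", order = c("Eubacteriales", "Lachnospirales")
#' )
#' lca(lin)
#' @export
lca <- function(lineages) {
  linmat <- .as_lineage_matrix(lineages)
  if (nrow(linmat) == 0L) stop("lca() needs at least one lineage")
  res <- .lca_core(linmat)
  TaxonomicAssignment(taxon = res$taxon, rank = res$rank,
                      lineage = res$lineage)
}
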