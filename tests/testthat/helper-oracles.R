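# Independent oracles used to cross-check the implementation, written as
# plainly as possible and kept separate from the package's own code paths.

# longest-common-prefix walk over the rank-name vectors
oracle_lca <- function(linmat) {
  linmat <- as.matrix(linmat)
  linmat[, "phylum"] <- normalizePhylumName(linmat[, "phylum"])
  depth <- 0L
  for (j in seq_len(ncol(linmat))) {
    col <- linmat[, j]
    if (any(is.na(col)) || !all(col == col[1L])) break
    depth <- j
  }
  if (depth <= 1L) list(rank = "root", taxon = "Root")
  else list(rank = colnames(linmat)[depth], taxon = unname(linmat[1L, depth]))
}

# exhaustive enumeration of tryptic fragments: split into minimal segments
# with a regex, then emit every contiguous run of <= mm+1 segments
oracle_digest <- function(seq, mm, range = NULL) {
  segs <- strsplit(gsub("(?<=[KR])(?!P)", "\r", seq, perl = TRUE),
                   "\r", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(segs)) {
    for (k in 0:mm) {
      if (i + k > length(segs)) break
      out <- c(out, paste(segs[i:(i + k)], collapse = ""))
    }
  }
  if (!is.null(range))
    out <- out[nchar(out) >= range[1] & nchar(out) <= range[2]]
  out
}

# naive step-by-step recomputation of the rank random walk
oracle_gsva <- function(mat, sets, tau = 1, type = "maxdev") {
  e <- log2(mat + 1)
  out <- matrix(NA_real_, length(sets), ncol(mat),
                dimnames = list(names(sets), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    rk <- rank(e[, j], ties.method = "average")
    names(rk) <- rownames(mat)
    ord <- rownames(mat)[order(-e[, j], rownames(mat), method = "radix")]
    for (s in names(sets)) {
      hits <- ord %in% sets[[s]]
      m <- sum(hits); n <- length(ord)
      if (m == 0 || m == n) { out[s, j] <- 0; next }
      wsum <- sum(abs(rk[ord[hits]])^tau)
      running <- 0; trail <- numeric(n)
      for (i in seq_len(n)) {
        running <- running +
          if (hits[i]) abs(rk[[ord[i]]])^tau / wsum else -1 / (n - m)
        trail[i] <- running
      }
      out[s, j] <- if (type == "maxdev") trail[which.max(abs(trail))]
                   else max(0, max(trail)) + min(0, min(trail))
    }
  }
  out
}

# --- fixtures -------------------------------------------------------------

toy_taxonomy <- function() {
  data.frame(
    strain_id = c("st1", "st2", "st3", "st4"),
    superkingdom = "Bacteria",
    phylum = c("Bacillota", "Bacillota", "Bacteroidota", "Bacillota"),
    class = c("Cl1", "Cl1", "Cl2", "Cl1"),
    order = c("Or1", "Or1", "Or2", "Or1"),
    family = c("Fa1", "Fa1", "Fa2", "Fa1"),
    genus = c("Ge1", "Ge1", "Ge2", "Ge2"),
    species = c("Sp1", "Sp2", "Sp3", "Sp4"))
}

# p1/p3 are exact sequence duplicates in different phyla; p4 lacks a KO
toy_db <- function() {
  prot <- c(p1 = "MKTAYIAKQRPLMNR", p2 = "AAAKPBBBRCCCK",
            p3 = "MKTAYIAKQRPLMNR", p4 = "GGGKRHHHK")
  strain <- c("st1", "st2", "st3", "st4")
  tx <- toy_taxonomy()
  tax <- cbind(data.frame(protein_id = names(prot), strain_id = strain),
               tx[match(strain, tx$strain_id), -1])
  ReferenceDb(prot, tax, ko = c(p1 = "K00001", p2 = "K00001", p3 = "K00002"))
}

# lineages drawn from small per-rank pools; tree consistency is irrelevant
# for prefix-comparison properties
random_lineage <- function(maxDepth = 7L) {
  pools <- list(superkingdom = "Bacteria",
                phylum = c("Bacillota", "Bacteroidota", "Firmicutes"),
                class = paste0("C", 1:2), order = paste0("O", 1:2),
                family = paste0("F", 1:2), genus = paste0("G", 1:3),
                species = paste0("S", 1:3))
  depth <- sample(seq_len(maxDepth), 1L)
  l <- rep(NA_character_, 7L)
  names(l) <- rankLadder(FALSE)
  for (j in seq_len(depth)) l[j] <- sample(pools[[j]], 1L)
  l
}

.fixture_cache <- new.env(parent = emptyenv())

# shared end-to-end simulation, built once per test run
get_sim <- function(seed = 11L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- simulationConfig(seed = seed)
    ref <- simulateReference(cfg)
    db <- deduplicateExact(ref$db)
    sim <- simulatePeptideTable(ref, cfg)
    path <- tempfile(fileext = ".txt")
    metapep:::.write_tsv(sim$table, path)
    ps <- suppressMessages(readPeptides(path, dialect = "maxquant"))
    ps <- suppressMessages(filterObservations(ps))
    ps <- classifyOrigin(ps, microbialIds = proteinIds(ref$db),
                         hostIds = sim$host_ids)
    ann <- annotateTaxonomy(ps, db)
    .fixture_cache[[key]] <- list(cfg = cfg, ref = ref, db = db, sim = sim,
                                  ps = ps, ann = ann)
  }
  .fixture_cache[[key]]
}

write_toy_fastas <- function(dir, n_files = 2L, per_file = 3L,
                             prefix = "prot") {
  paths <- character(n_files)
  k <- 0L
  for (i in seq_len(n_files)) {
    paths[i] <- file.path(dir, sprintf("strain%d.fasta", i))
    lines <- character(0)
    for (j in seq_len(per_file)) {
      k <- k + 1L
      lines <- c(lines, sprintf(">%s%d st%d", prefix, k, i),
                 paste(sample(c("A", "G", "K", "M", "T", "R"), 24,
                              replace = TRUE), collapse = ""))
    }
    writeLines(lines, paths[i])
  }
  paths
}
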