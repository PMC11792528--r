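# Synthetic fixture generator: a miniature cultivated-reference collection
# (taxonomy tree over the 8-rank ladder, per-strain proteomes with planted
# exact duplicates and KOs) and matching MaxQuant-dialect peptide tables
# with full ground truth, so every pipeline stage is testable without any
# download. Ground-truth LCA and KO are computed here by code paths
# independent of lca()/consensusKO().

.PHYLUM_POOL <- c("Bacillota", "Bacteroidota", "Actinomycetota",
                  "Pseudomonadota", "Verrucomicrobiota", "Fusobacteriota",
                  "Desulfobacterota", "Mycoplasmatota")

# uniform residue model with elevated K/R so tryptic peptide yields are
# realistic (~8% each vs ~4.7% for the other 18 residues)
.AA_CHARS <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
.AA_PROBS <- c(rep((1 - 0.16) / 18, 18), 0.08, 0.08)
.AA_ALPHABET <- c(.AA_CHARS, "K", "R")

.random_protein <- function(len) {
  paste(sample(.AA_ALPHABET, len, replace = TRUE, prob = .AA_PROBS),
        collapse = "")
}

# n point substitutions, each guaranteed to change the residue
.mutate_protein <- function(seq, n = 2L) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), min(n, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(.AA_ALPHABET, ch[p]), 1L)
  paste(ch, collapse = "")
}

.check_fraction <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(nm, " must be a fraction in [0, 1]")
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic workflow; the seed fixes every
#' downstream draw. Defaults give a miniature gut-community reference
#' (4 phyla, 64 species/strains, ~1,900 proteins) and a peptide table of
#' 1,000 identifications across 8 samples in two groups — large enough to
#' exercise LCA collapse, deduplication and enrichment, small enough to
#' run in seconds.
#'
#' @param n_phyla Number of phyla (<= 8; drawn from a fixed pool of real
#'   gut phylum names so phylum-level statistics are meaningful).
#' @param classes_per_phylum,orders_per_class,families_per_order,genera_per_family,species_per_genus
#'   Branching factors of the taxonomy tree.
#' @param strains_per_species Strains per species.
#' @param proteins_per_strain Proteins generated per strain.
#' @param protein_length_range Protein length range (residues).
#' @param shared_protein_fraction Fraction of proteins copied into another
#'   strain so that tryptic peptides are shared across strains. A copy is
#'   an exact duplicate with probability `shared_exact_fraction`
#'   (exercising deduplication and retired-id resolution) and otherwise
#'   carries `n_mutations` point substitutions — a near-identical homolog
#'   that survives exact deduplication, shares most tryptic peptides with
#'   its donor, and therefore drives genuine LCA coarsening.
#' @param shared_exact_fraction Fraction of shared copies that are exact
#'   (default 0.5).
#' @param n_mutations Point substitutions per inexact copy (default 2).
#' @param missed_cleavages_max Maximum missed tryptic cleavages (default 2,
#'   the usual search setting).
#' @param peptide_length_range Peptide length filter (default 7-30
#'   residues, MaxQuant-typical).
#' @param n_peptides Total identified peptides (microbial + host).
#' @param n_samples Number of samples; `group_labels` (default: first half
#'   "A", second half "B") drive the enrichment contrast.
#' @param group_labels Optional character vector of length `n_samples`.
#' @param host_fraction Fraction of identified peptides of host origin.
#' @param host_proteins Size of the synthetic host proteome.
#' @param decoy_rate,contaminant_rate Rates of injected decoy/contaminant
#'   rows (relative to real rows).
#' @param missing_rate Probability an intensity is 0 (not quantified).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity
#'   parameters (meanlog 16, sdlog 1.5: median ~9e6, the scale of typical
#'   MS1 peptide intensities).
#' @param ko_pool_size Number of distinct KOs in the pool.
#' @param ko_missing_rate Probability a protein has no KO.
#' @param ko_agreement Probability a copied protein keeps its donor's KO
#'   (controls consensus-rule agreement within protein groups).
#' @param seed Integer seed.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(n_phyla = 4L,
                             classes_per_phylum = 1L,
                             orders_per_class = 2L,
                             families_per_order = 2L,
                             genera_per_family = 2L,
                             species_per_genus = 2L,
                             strains_per_species = 1L,
                             proteins_per_strain = 30L,
                             protein_length_range = c(120L, 300L),
                             shared_protein_fraction = 0.15,
                             shared_exact_fraction = 0.5,
                             n_mutations = 2L,
                             missed_cleavages_max = 2L,
                             peptide_length_range = c(7L, 30L),
                             n_peptides = 1000L,
                             n_samples = 8L,
                             group_labels = NULL,
                             host_fraction = 0.10,
                             host_proteins = 20L,
                             decoy_rate = 0.05,
                             contaminant_rate = 0.02,
                             missing_rate = 0.20,
                             intensity_meanlog = 16,
                             intensity_sdlog = 1.5,
                             ko_pool_size = 40L,
                             ko_missing_rate = 0.10,
                             ko_agreement = 0.80,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_phyla", "classes_per_phylum", "orders_per_class",
              "families_per_order", "genera_per_family", "species_per_genus",
              "strains_per_species", "proteins_per_strain", "n_peptides",
              "n_samples", "host_proteins", "ko_pool_size",
              "missed_cleavages_max", "n_mutations")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop(nm, " must be a non-negative integer")
    cfg[[nm]] <- as.integer(v)
  }
  if (cfg$n_phyla < 1L || cfg$n_phyla > length(.PHYLUM_POOL))
    stop("n_phyla must be between 1 and ", length(.PHYLUM_POOL))
  for (nm in c("shared_protein_fraction", "shared_exact_fraction",
               "host_fraction", "decoy_rate", "contaminant_rate",
               "missing_rate", "ko_missing_rate", "ko_agreement"))
    .check_fraction(cfg[[nm]], nm)
  for (nm in c("protein_length_range", "peptide_length_range")) {
    v <- cfg[[nm]]
    if (length(v) != 2L || v[1] > v[2] || v[1] < 1)
      stop(nm, " must be an increasing pair of positive lengths")
  }
  if (is.null(cfg$group_labels))
    cfg$group_labels <- rep(c("A", "B"),
                            times = c(ceiling(cfg$n_samples / 2),
                                      floor(cfg$n_samples / 2)))
  if (length(cfg$group_labels) != cfg$n_samples)
    stop("group_labels must have one label per sample")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "SimulationConfig")
}

.build_strain_tree <- function(cfg) {
  phyla <- .PHYLUM_POOL[seq_len(cfg$n_phyla)]
  rows <- list()
  ci <- oi <- fi <- gi <- si <- ti <- 0L
  for (p in phyla)
    for (c_ in seq_len(cfg$classes_per_phylum)) {
      ci <- ci + 1L; cl <- sprintf("Class%02d", ci)
      for (o in seq_len(cfg$orders_per_class)) {
        oi <- oi + 1L; od <- sprintf("Order%02d", oi)
        for (f in seq_len(cfg$families_per_order)) {
          fi <- fi + 1L; fa <- sprintf("Family%02d", fi)
          for (g in seq_len(cfg$genera_per_family)) {
            gi <- gi + 1L; ge <- sprintf("Genus%03d", gi)
            for (s in seq_len(cfg$species_per_genus)) {
              si <- si + 1L; sp <- sprintf("Species%03d", si)
              for (t in seq_len(cfg$strains_per_species)) {
                ti <- ti + 1L
                rows[[ti]] <- data.frame(
                  strain_id = sprintf("s%03d", ti),
                  superkingdom = "Bacteria", phylum = p, class = cl,
                  order = od, family = fa, genus = ge, species = sp)
              }
            }
          }
        }
      }
    }
  do.call(rbind, rows)
}

#' Simulate a reference collection with ground truth
#'
#' Generates the taxonomy tree, per-strain proteomes, per-protein KOs, and
#' plants `shared_protein_fraction` exact cross-strain duplicates (recorded
#' in the truth tables). Deterministic under `cfg$seed`: the generator
#' seeds the RNG itself, so the same config yields byte-identical output.
#'
#' @param cfg A [simulationConfig()].
#' @param dir Optional directory: writes the reference files via
#'   [writeReferenceDb()] (prefix `reference`).
#' @return List with elements `db` (pre-deduplication
#'   [ReferenceDb-class]), `taxonomy` (strain-level table), `ko`
#'   (protein-level table), `truth` (list: `duplicates` and `homologs`
#'   data.frames with columns `copy_id`, `donor_id`; `tree_counts` named
#'   integer vector), and `config`.
#' @export
simulateReference <- function(cfg = simulationConfig(), dir = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  strains <- .build_strain_tree(cfg)
  n_strain <- nrow(strains)
  lens <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                 n_strain * cfg$proteins_per_strain, replace = TRUE)
  ids <- as.vector(vapply(strains$strain_id, function(s)
    sprintf("%s_P%04d", s, seq_len(cfg$proteins_per_strain)),
    character(cfg$proteins_per_strain)))
  strain_of <- rep(strains$strain_id, each = cfg$proteins_per_strain)
  seqs <- vapply(lens, .random_protein, "")
  ko_pool <- sprintf("K%05d", seq_len(cfg$ko_pool_size))
  draw_ko <- function(n) ifelse(stats::runif(n) < cfg$ko_missing_rate,
                                NA_character_,
                                sample(ko_pool, n, replace = TRUE))
  kos <- draw_ko(length(ids))

  n_shared <- round(cfg$shared_protein_fraction * length(ids))
  empty_pairs <- data.frame(copy_id = character(0), donor_id = character(0))
  dup_truth <- hom_truth <- empty_pairs
  if (n_shared > 0 && n_strain > 1L) {
    donors <- sample(length(ids), n_shared)
    # half the copies stay within the donor's genus (shared peptides then
    # collapse to genus, as dominates real gut data); the rest go anywhere
    tgt <- vapply(strain_of[donors], function(s) {
      genus <- strains$genus[strains$strain_id == s]
      near <- setdiff(strains$strain_id[strains$genus == genus], s)
      pool <- if (length(near) && stats::runif(1) < 0.5) near
              else setdiff(strains$strain_id, s)
      sample(pool, 1L)
    }, "")
    copy_ids <- sprintf("%s_D%04d", tgt, seq_len(n_shared))
    exact <- stats::runif(n_shared) < cfg$shared_exact_fraction
    copy_seqs <- seqs[donors]
    copy_seqs[!exact] <- vapply(copy_seqs[!exact], .mutate_protein, "",
                                n = cfg$n_mutations)
    keep_ko <- stats::runif(n_shared) < cfg$ko_agreement
    copy_kos <- ifelse(keep_ko, kos[donors], draw_ko(n_shared))
    dup_truth <- data.frame(copy_id = copy_ids[exact],
                            donor_id = ids[donors][exact])
    hom_truth <- data.frame(copy_id = copy_ids[!exact],
                            donor_id = ids[donors][!exact])
    ids <- c(ids, copy_ids)
    seqs <- c(seqs, copy_seqs)
    strain_of <- c(strain_of, tgt)
    kos <- c(kos, copy_kos)
  }

  tax <- cbind(data.frame(protein_id = ids, strain_id = strain_of),
               strains[match(strain_of, strains$strain_id),
                       .RANKS, drop = FALSE])
  rownames(tax) <- NULL
  db <- ReferenceDb(stats::setNames(seqs, ids), tax,
                    ko = stats::setNames(kos, ids))
  tree_counts <- vapply(.RANKS, function(r)
    length(unique(strains[[r]])), integer(1))
  out <- list(db = db,
              taxonomy = strains,
              ko = data.frame(protein_id = ids, ko = kos),
              truth = list(duplicates = dup_truth, homologs = hom_truth,
                           tree_counts = tree_counts),
              config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeReferenceDb(db, file.path(dir, "reference"))
    .write_tsv(strains, file.path(dir, "taxonomy_strains.tsv"))
    .write_tsv(out$ko, file.path(dir, "ko.tsv"))
  }
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' emits every fragment carrying 0..`missedMax` missed cleavage sites,
#' filtered to `lengthRange`, ordered by start position then span.
#'
#' @param sequence One amino-acid string.
#' @param missedMax Maximum missed cleavages (default 2).
#' @param lengthRange Length filter `c(min, max)` in residues, or `NULL`
#'   for no filter.
#' @return Character vector of peptides (possibly with repeats when the
#'   protein repeats itself). An empty sequence digests to nothing.
#' @examples
#' digestTryptic("MKTAYIAKQRPK", missedMax = 1, lengthRange = NULL)
#' @export
digestTryptic <- function(sequence, missedMax = 2L, lengthRange = c(7L, 30L)) {
  stopifnot(length(sequence) == 1L, missedMax >= 0)
  sequence <- as.character(sequence)
  if (is.na(sequence) || !nzchar(sequence)) return(character(0))
  if (!.is_aa(sequence)) stop("invalid amino-acid sequence")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cleav <- if (n > 1L)
    which(chars[-n] %in% c("K", "R") & chars[-1L] != "P") else integer(0)
  bounds <- c(0L, cleav, n)
  nb <- length(bounds)
  out <- vector("list", nb - 1L)
  for (a in seq_len(nb - 1L)) {
    bs <- (a + 1L):min(a + 1L + missedMax, nb)
    out[[a]] <- substring(sequence, bounds[a] + 1L, bounds[bs])
  }
  out <- unlist(out)
  if (!is.null(lengthRange)) {
    len <- nchar(out)
    out <- out[len >= lengthRange[1] & len <= lengthRange[2]]
  }
  out
}

# ground-truth LCA: plain element-wise prefix walk over the rank columns,
# deliberately separate from .lca_core()
.truth_lca <- function(linmat) {
  depth <- 0L
  for (j in seq_len(ncol(linmat))) {
    vals <- linmat[, j]
    if (any(is.na(vals)) || any(vals != vals[1L])) break
    depth <- j
  }
  if (depth <= 1L) c(rank = "root", taxon = "Root")
  else c(rank = colnames(linmat)[depth], taxon = unname(linmat[1L, depth]))
}

# ground-truth consensus KO: independent re-application of the rule
.truth_ko <- function(kos) {
  if (length(kos) == 0L || any(is.na(kos))) return(NA_character_)
  if (all(kos == kos[1L])) kos[1L] else NA_character_
}

#' Simulate a MaxQuant-dialect peptide table with ground truth
#'
#' Digests every reference protein, samples identified microbial peptides
#' (each peptide's protein group is the full set of reference proteins
#' whose digest contains it, under pre-deduplication ids), adds peptides
#' from a synthetic host proteome, log-normal intensities with dropout,
#' and injects decoy and contaminant rows at the configured rates. The
#' truth table records each real peptide's origin, source strains, LCA
#' (rank + taxon) and consensus KO, computed by code independent of the
#' annotation path.
#'
#' @param ref Output of [simulateReference()].
#' @param cfg The same [simulationConfig()]; defaults to `ref$config`.
#' @param dir Optional directory: writes `peptides.txt` (MaxQuant dialect)
#'   and `truth_peptides.tsv`.
#' @return List with `table` (data.frame in MaxQuant `peptides.txt`
#'   layout), `truth` (data.frame: `peptide`, `origin`, `true_strains`,
#'   `true_rank`, `true_taxon`, `true_ko`), `counts` (named integer
#'   vector: microbial, host, decoy, contaminant), `host_ids`, `samples`
#'   and `groups`.
#' @export
simulatePeptideTable <- function(ref, cfg = ref$config, dir = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 1L)
  db <- ref$db
  ids <- proteinIds(db)
  seqs <- as.character(sequences(db))

  uq <- unique(seqs)
  dig <- lapply(uq, function(s)
    unique(digestTryptic(s, cfg$missed_cleavages_max,
                         cfg$peptide_length_range)))
  pep2seq <- split(rep(uq, lengths(dig)), unlist(dig))
  seq2ids <- split(ids, seqs)
  micro_pool <- names(pep2seq)

  n_micro <- min(round(cfg$n_peptides * (1 - cfg$host_fraction)),
                 length(micro_pool))
  micro_peps <- .radix_sort(sample(micro_pool, n_micro))
  pep_groups <- lapply(pep2seq[micro_peps], function(sq)
    .radix_sort(unname(unlist(seq2ids[sq]))))

  # synthetic host proteome; host peptide sequences must not collide with
  # the microbial pool, or origin would be ambiguous by construction
  host_ids <- sprintf("HOST_P%03d", seq_len(cfg$host_proteins))
  host_seqs <- vapply(sample(
    cfg$protein_length_range[1]:cfg$protein_length_range[2],
    cfg$host_proteins, replace = TRUE), .random_protein, "")
  host_dig <- lapply(host_seqs, function(s)
    unique(digestTryptic(s, cfg$missed_cleavages_max,
                         cfg$peptide_length_range)))
  host_map <- split(rep(host_ids, lengths(host_dig)), unlist(host_dig))
  host_pool <- setdiff(names(host_map), micro_pool)
  n_host <- min(cfg$n_peptides - n_micro, length(host_pool))
  host_peps <- .radix_sort(sample(host_pool, n_host))

  real_peps <- c(micro_peps, host_peps)
  real_groups <- c(pep_groups, lapply(host_map[host_peps], .radix_sort))
  n_real <- length(real_peps)

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  make_intensity <- function(n) {
    m <- matrix(stats::rlnorm(n * cfg$n_samples, cfg$intensity_meanlog,
                              cfg$intensity_sdlog), n, cfg$n_samples)
    m[matrix(stats::runif(n * cfg$n_samples) < cfg$missing_rate,
             n, cfg$n_samples)] <- 0
    m
  }
  inten <- make_intensity(n_real)

  # decoys: reversed real sequences under REV__ ids
  n_decoy <- round(cfg$decoy_rate * n_real)
  rev_str <- function(x) vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), "")
  decoy_cand <- unique(rev_str(sample(real_peps)))
  decoy_cand <- setdiff(decoy_cand, real_peps)
  decoy_peps <- utils::head(decoy_cand, n_decoy)
  n_decoy <- length(decoy_peps)
  decoy_groups <- paste0("REV__D", seq_len(n_decoy))

  n_con <- round(cfg$contaminant_rate * n_real)
  con_peps <- character(0)
  while (length(con_peps) < n_con) {
    cand <- vapply(sample(8:20, n_con, replace = TRUE), .random_protein, "")
    con_peps <- utils::head(
      setdiff(unique(c(con_peps, cand)), c(real_peps, decoy_peps)), n_con)
  }
  con_groups <- sprintf("CON__P%05d", seq_len(n_con))

  all_seq <- c(real_peps, decoy_peps, con_peps)
  all_groups <- c(vapply(real_groups, paste, "", collapse = ";"),
                  decoy_groups, con_groups)
  all_inten <- rbind(inten, make_intensity(n_decoy + n_con))
  tab <- data.frame(Sequence = all_seq, Proteins = all_groups,
                    Reverse = c(rep("", n_real), rep("+", n_decoy),
                                rep("", n_con)),
                    check.names = FALSE)
  tab[["Potential contaminant"]] <- c(rep("", n_real + n_decoy),
                                      rep("+", n_con))
  for (j in seq_along(samples))
    tab[[paste("Intensity", samples[j])]] <- all_inten[, j]

  # Ground truth via independent code paths. Exact sequence duplicates are
  # resolved the way the annotation sees them after deduplication: one
  # representative (lexicographically smallest id) per distinct sequence;
  # every id sharing a sequence necessarily shares all its tryptic
  # peptides, so each duplicate class lies entirely inside the group.
  tax <- taxonomyTable(db)
  linmat_all <- as.matrix(tax[, .RANKS, drop = FALSE])
  ko_all <- koAssignments(db)
  truth <- data.frame(peptide = real_peps,
                      origin = rep(c("microbial", "host"),
                                   c(n_micro, n_host)),
                      true_strains = "host",
                      true_rank = NA_character_,
                      true_taxon = NA_character_,
                      true_ko = NA_character_)
  for (i in seq_len(n_micro)) {
    g <- real_groups[[i]]
    gs <- seqs[match(g, ids)]
    reps <- vapply(split(g, gs), function(v) .radix_sort(v)[1L], "",
                   USE.NAMES = FALSE)
    idx <- match(reps, tax$protein_id)
    res <- .truth_lca(linmat_all[idx, , drop = FALSE])
    truth$true_strains[i] <- paste(unique(tax$strain_id[idx]),
                                   collapse = ";")
    truth$true_rank[i] <- res[["rank"]]
    truth$true_taxon[i] <- res[["taxon"]]
    truth$true_ko[i] <- .truth_ko(unname(ko_all[reps]))
  }

  out <- list(table = tab, truth = truth,
              counts = c(microbial = n_micro, host = n_host,
                         decoy = n_decoy, contaminant = n_con),
              host_ids = host_ids, samples = samples,
              groups = stats::setNames(cfg$group_labels, samples))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(tab, file.path(dir, "peptides.txt"))
    .write_tsv(truth, file.path(dir, "truth_peptides.tsv"))
  }
  out
}

#' Simulate a KO-to-pathway membership table
#'
#' Assigns each KO of the pool to one or two synthetic pathways, giving a
#' membership table of the shape a user would otherwise supply from KEGG.
#'
#' @param cfg A [simulationConfig()].
#' @param nPathways Number of synthetic pathways (default 12).
#' @return data.frame with columns `ko`, `pathway_id`, `pathway_name`.
#' @export
simulatePathwayTable <- function(cfg = simulationConfig(), nPathways = 12L) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 2L)
  kos <- sprintf("K%05d", seq_len(cfg$ko_pool_size))
  paths <- sprintf("path%03d", seq_len(nPathways))
  rows <- lapply(kos, function(k) {
    p <- sample(paths, 1L + stats::rbinom(1L, 1L, 0.5))
    data.frame(ko = k, pathway_id = p,
               pathway_name = paste0("Synthetic pathway ", sub("path", "", p)))
  })
  do.call(rbind, rows)
}
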