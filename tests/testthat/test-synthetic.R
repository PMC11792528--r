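small_cfg <- function(...) {
  simulationConfig(proteins_per_strain = 8L,
                   protein_length_range = c(80L, 150L),
                   n_peptides = 200L, ...)
}

test_that("simulateReference is deterministic under its seed", {
  cfg <- small_cfg(seed = 5L)
  a <- simulateReference(cfg)
  b <- simulateReference(cfg)
  expect_identical(as.character(sequences(a$db)), as.character(sequences(b$db)))
  expect_identical(proteinIds(a$db), proteinIds(b$db))
  expect_identical(koAssignments(a$db), koAssignments(b$db))
  expect_identical(a$truth, b$truth)

  ta <- simulatePeptideTable(a, cfg)
  tb <- simulatePeptideTable(b, cfg)
  expect_identical(ta$table, tb$table)
  expect_identical(ta$truth, tb$truth)
})

test_that("the taxonomy census matches the configured tree", {
  cfg <- small_cfg(seed = 6L)
  ref <- simulateReference(cfg)
  cs <- censusTaxa(ref$db)
  expect_equal(cs, ref$truth$tree_counts)
  expect_equal(cs[["phylum"]], cfg$n_phyla)
  expect_equal(cs[["species"]],
               cfg$n_phyla * cfg$classes_per_phylum * cfg$orders_per_class *
                 cfg$families_per_order * cfg$genera_per_family *
                 cfg$species_per_genus)
  # planted exact duplicates + homologs account for the extra records
  n_base <- cs[["species"]] * cfg$strains_per_species *
    cfg$proteins_per_strain
  expect_equal(length(ref$db),
               n_base + nrow(ref$truth$duplicates) +
                 nrow(ref$truth$homologs))
  dd <- deduplicateExact(ref$db)
  expect_equal(length(dd), length(ref$db) - nrow(ref$truth$duplicates))
})

test_that("without shared proteins every peptide resolves to species", {
  cfg <- small_cfg(seed = 8L, shared_protein_fraction = 0)
  ref <- simulateReference(cfg)
  sim <- simulatePeptideTable(ref, cfg)
  micro <- sim$truth[sim$truth$origin == "microbial", ]
  expect_true(all(micro$true_rank == "species"))
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  # no cleavage site at all: the whole chain or nothing
  expect_equal(digestTryptic("MAAAAAA", lengthRange = NULL), "MAAAAAA")
  expect_equal(digestTryptic("MAAAAAA", lengthRange = c(1, 3)), character(0))
  expect_equal(digestTryptic(""), character(0))

  # K followed by P is protected
  expect_equal(digestTryptic("AAAKPGGG", lengthRange = NULL), "AAAKPGGG")
  expect_equal(digestTryptic("AAAKGGG", missedMax = 0, lengthRange = NULL),
               c("AAAK", "GGG"))

  # fragments ordered by start, then span; missed cleavages included
  expect_equal(digestTryptic("AKCKDK", missedMax = 2, lengthRange = NULL),
               c("AK", "AKCK", "AKCKDK", "CK", "CKDK", "DK"))
})

test_that("zero-missed-cleavage fragments concatenate to the protein", {
  set.seed(61)
  for (i in 1:20) {
    prot <- paste(sample(c("A", "C", "D", "K", "R", "P", "M"), 150,
                         replace = TRUE), collapse = "")
    frags <- digestTryptic(prot, missedMax = 0, lengthRange = NULL)
    expect_equal(paste(frags, collapse = ""), prot)
  }
})

test_that("digestion equals the exhaustive segment-run oracle", {
  set.seed(62)
  for (i in 1:10) {
    prot <- metapep:::.random_protein(200L)
    for (mm in 0:2) {
      expect_equal(digestTryptic(prot, mm, lengthRange = NULL),
                   oracle_digest(prot, mm))
      expect_equal(digestTryptic(prot, mm, c(7, 30)),
                   oracle_digest(prot, mm, c(7, 30)))
    }
  }
})

test_that("the annotation pipeline recovers the generator's ground truth", {
  fx <- get_sim()
  micro <- fx$sim$truth[fx$sim$truth$origin == "microbial", ]
  idx <- match(micro$peptide, fx$ann$sequence)
  expect_false(anyNA(idx))
  expect_equal(fx$ann$rank[idx], micro$true_rank)
  expect_equal(fx$ann$taxon[idx], micro$true_taxon)

  # consensus KOs equal the planted truth, including the unmappable ones
  mic_ps <- fx$ps[originClass(fx$ps) == "microbial", ]
  km <- buildPeptideKoDb(mic_ps, fx$db)
  got <- stats::setNames(rep(NA_character_, nrow(micro)), micro$peptide)
  got[km$peptide] <- km$ko
  expect_identical(unname(got), micro$true_ko)
})

test_that("decoy and contaminant bookkeeping matches the planted counts", {
  fx <- get_sim()
  counts <- fx$sim$counts
  raw_path <- tempfile()
  metapep:::.write_tsv(fx$sim$table, raw_path)
  raw <- suppressMessages(readPeptides(raw_path, "maxquant"))
  expect_equal(sum(isDecoy(raw)), unname(counts[["decoy"]]))
  expect_equal(sum(isContaminant(raw)), unname(counts[["contaminant"]]))
  filtered <- suppressMessages(filterObservations(raw))
  expect_equal(nrow(filtered),
               unname(counts[["microbial"]] + counts[["host"]]))
  expect_equal(sum(originClass(fx$ps) == "host"),
               unname(counts[["host"]]))
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(host_fraction = 1.2), "fraction")
  expect_error(simulationConfig(n_phyla = 50), "n_phyla")
  expect_error(simulationConfig(peptide_length_range = c(30, 7)),
               "increasing")
  expect_error(simulationConfig(n_samples = 3, group_labels = c("A", "B")),
               "label per sample")
})
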