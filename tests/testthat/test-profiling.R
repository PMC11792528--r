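two_phylum_table <- function() {
  data.frame(sequence = c("AAAK", "CCCR"),
             rank = "species", taxon = c("SpA", "SpB"),
             superkingdom = "Bacteria",
             phylum = c("Bacillota", "Bacteroidota"),
             class = c("ClA", "ClB"), order = c("OrA", "OrB"),
             family = c("FaA", "FaB"), genus = c("GeA", "GeB"),
             species = c("SpA", "SpB"),
             lineage = "x", intensity_s1 = c(3, 1), intensity_s2 = c(2, 2))
}

test_that("compositionAtRank aggregates intensity by taxon", {
  comp <- compositionAtRank(two_phylum_table(), "phylum", "s1",
                            othersThreshold = 0)
  expect_equal(comp$fraction[comp$taxon == "Bacillota"], 0.75)
  expect_equal(comp$fraction[comp$taxon == "Bacteroidota"], 0.25)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
  expect_equal(attr(comp, "total_intensity"), 4)

  root_only <- data.frame(sequence = "AAAK", rank = "root", taxon = "Root",
                          superkingdom = NA, phylum = NA, class = NA,
                          order = NA, family = NA, genus = NA, species = NA,
                          lineage = "Root", intensity_s1 = 5)
  comp2 <- compositionAtRank(root_only, "family", "s1")
  expect_equal(comp2$taxon, "Unannotated-at-rank")
  expect_equal(comp2$fraction, 1)

  expect_error(compositionAtRank(two_phylum_table(), "kingdom", "s1"),
               "unknown rank")
  expect_error(compositionAtRank(two_phylum_table(), "phylum", "s9"),
               "s9")
})

test_that("low-abundance taxa merge into 'others' exactly as summed by hand", {
  set.seed(31)
  n_fam <- 30L
  fams <- sprintf("Fam%02d", seq_len(n_fam))
  inten <- stats::rlnorm(n_fam, 3, 2)
  tab <- data.frame(sequence = sprintf("PEP%02dK", seq_len(n_fam)),
                    rank = "family", taxon = fams,
                    superkingdom = "Bacteria", phylum = "Bacillota",
                    class = "Cl", order = "Or", family = fams,
                    genus = NA, species = NA, lineage = "x",
                    intensity_s1 = inten)
  comp <- compositionAtRank(tab, "family", "s1", othersThreshold = 0.02)
  frac <- inten / sum(inten)
  manual_others <- sum(frac[frac < 0.02])
  if (manual_others > 0) {
    expect_equal(comp$fraction[comp$taxon == "others"], manual_others,
                 tolerance = 1e-12)
  }
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
  kept <- setdiff(comp$taxon, "others")
  expect_true(all(comp$fraction[comp$taxon %in% kept] >= 0.02))
})

test_that("composition conserves intensity on simulated data", {
  fx <- get_sim()
  for (s in fx$sim$samples[1:3]) {
    comp <- compositionAtRank(fx$ann, "family", s)
    expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
    expect_equal(attr(comp, "total_intensity"),
                 sum(fx$ann[[paste0("intensity_", s)]]),
                 tolerance = 1e-6 * attr(comp, "total_intensity"))
  }
})

test_that("fbRatio divides Bacillota by Bacteroidota intensity", {
  tab <- two_phylum_table()
  expect_equal(fbRatio(tab, "s1"), 3)
  expect_equal(fbRatio(tab, "s2"), 1)

  # invariant under uniform rescaling
  scaled <- tab
  scaled$intensity_s1 <- scaled$intensity_s1 * 1e4
  expect_equal(fbRatio(scaled, "s1"), fbRatio(tab, "s1"))

  # invariant under legacy phylum labels
  legacy <- tab
  legacy$phylum <- c("Firmicutes", "Bacteroidetes")
  expect_equal(fbRatio(legacy, "s1"), fbRatio(tab, "s1"))

  no_bact <- tab[tab$phylum == "Bacillota", ]
  expect_error(fbRatio(no_bact, "s1"), "Bacteroidota")
})

test_that("mhRatio sums microbial over host, excluding ambiguous", {
  ps <- PeptideSet(sequence = c("AAAK", "CCCR", "DDDK", "EEEK"),
                   proteinGroup = list("M1", "H1", c("M1", "H1"), "M2"),
                   intensities = matrix(c(6, 3, 100, 0), 4, 1,
                                        dimnames = list(NULL, "s1")))
  ps <- classifyOrigin(ps, c("M1", "M2"), "H1")
  expect_equal(mhRatio(ps, "s1"), 2)

  # the ambiguous peptide contributes to neither side
  drop_amb <- ps[originClass(ps) != "ambiguous", ]
  expect_equal(mhRatio(drop_amb, "s1"), mhRatio(ps, "s1"))

  only_m <- ps[originClass(ps) == "microbial", ]
  expect_error(mhRatio(only_m, "s1"), "host")
  expect_error(mhRatio(PeptideSet("AAAK", list("M1"),
                                  matrix(1, 1, 1,
                                         dimnames = list(NULL, "s1"))),
                       "s1"), "classifyOrigin")
})

test_that("peptideOverlap partitions the union into exclusive regions", {
  counts <- peptideOverlap(list(A = c("x", "y", "z"), B = c("y", "z", "w")))
  expect_equal(counts[["A"]], 1L)
  expect_equal(counts[["B"]], 1L)
  expect_equal(counts[["A&B"]], 2L)
  expect_equal(sum(counts), 4L)

  same <- peptideOverlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same[["A&B"]], 2L)
  expect_equal(same[["A"]] + same[["B"]], 0L)

  three <- peptideOverlap(list(A = c("x", "y"), B = c("y", "z"),
                               C = c("z", "q", "y")))
  expect_equal(sum(three), 4L)  # union x,y,z,q
  expect_equal(three[["A&B&C"]], 1L)

  expect_error(peptideOverlap(list(c("x"))), "named")
})
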