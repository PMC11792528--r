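test_that("consensusKO requires unanimous agreement", {
  ko <- c(p1 = "K00001", p2 = "K00001", p3 = "K00002", p4 = NA)
  expect_equal(consensusKO(c("p1", "p2"), ko), "K00001")
  expect_equal(consensusKO(c("p1", "p3"), ko), NA_character_)
  expect_equal(consensusKO(c("p1", "p4"), ko), NA_character_)
  expect_equal(consensusKO(character(0), ko), NA_character_)

  # invariant to order and duplication
  expect_equal(consensusKO(c("p2", "p1", "p1"), ko),
               consensusKO(c("p1", "p2"), ko))

  # through a ReferenceDb, retired ids resolve first: p3 (K00002) resolves
  # to representative p1 (K00001), so the group agrees
  dd <- deduplicateExact(toy_db())
  expect_equal(consensusKO(c("p1", "p3"), dd), "K00001")
  expect_equal(consensusKO("p4", dd), NA_character_)  # no KO
})

test_that("buildPeptideKoDb keeps only consensus-mappable peptides, sorted", {
  ko <- c(a = "K00001", b = "K00001", c = "K00002", d = NA)
  ps <- PeptideSet(sequence = c("EEEK", "AAAK", "CCCR", "DDDK", "FFFK"),
                   proteinGroup = list("c", c("a", "b"), c("a", "c"),
                                       "d", "a"),
                   intensities = matrix(1, 5, 1,
                                        dimnames = list(NULL, "s1")))
  out <- buildPeptideKoDb(ps, ko)
  expect_equal(out$peptide, c("AAAK", "EEEK", "FFFK"))
  expect_equal(out$ko, c("K00001", "K00002", "K00001"))

  file <- tempfile()
  buildPeptideKoDb(ps, ko, file = file)
  expect_equal(read.delim(file)$peptide, out$peptide)

  none <- buildPeptideKoDb(ps[4, ], ko)
  expect_equal(nrow(none), 0L)
  expect_equal(colnames(none), c("peptide", "ko"))
})

test_that("pathwayPeptideSets joins KOs to pathways and applies minSize", {
  koMap <- data.frame(peptide = sprintf("PEP%dK", 1:6),
                      ko = c("K00001", "K00001", "K00002", "K00002",
                             "K00002", "K00003"))
  k2p <- data.frame(ko = c("K00001", "K00001", "K00002", "K00003"),
                    pathway_id = c("pwA", "pwB", "pwA", "pwB"))
  sets <- pathwayPeptideSets(koMap, k2p, minSize = 1L)
  # relational-join oracle
  want <- merge(koMap, k2p, by = "ko")
  for (p in names(sets))
    expect_setequal(sets[[p]], unique(want$peptide[want$pathway_id == p]))
  expect_equal(lengths(sets)[["pwA"]], 5L)

  # a KO in two pathways puts its peptides in both sets
  expect_true(all(c("PEP1K", "PEP2K") %in% sets$pwA))
  expect_true(all(c("PEP1K", "PEP2K") %in% sets$pwB))

  dropped <- pathwayPeptideSets(koMap, k2p, minSize = 4L)
  expect_equal(names(dropped), "pwA")
})

test_that("gsvaScores equals the brute-force random walk", {
  set.seed(51)
  peps <- sprintf("PEP%02dK", 1:20)
  mat <- matrix(stats::rlnorm(20 * 4, 10, 1), 20, 4,
                dimnames = list(peps, sprintf("s%d", 1:4)))
  mat[sample(80, 10)] <- 0
  sets <- list(pw1 = peps[1:6], pw2 = peps[c(3, 9:14)], pw3 = peps[15:20])
  for (type in c("maxdev", "diff")) {
    got <- gsvaScores(mat, sets, scoreType = type)
    want <- oracle_gsva(mat, sets, type = type)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_true(all(abs(gsvaScores(mat, sets)) <= 1))
})

test_that("gsvaScores is rank-based and handles degenerate sets", {
  set.seed(52)
  peps <- sprintf("PEP%02dK", 1:15)
  mat <- matrix(stats::rlnorm(15 * 3, 8, 1), 15, 3,
                dimnames = list(peps, sprintf("s%d", 1:3)))
  sets <- list(pw1 = peps[1:5], pw2 = peps[6:15])
  base <- gsvaScores(mat, sets)
  # strictly monotone transforms leave the ranks, hence scores, unchanged
  expect_equal(gsvaScores(mat * 1e3, sets), base)
  expect_equal(gsvaScores(mat^1.7, sets), base)

  # a set spanning every peptide has an empty complement: no signal
  whole <- gsvaScores(mat, list(all = peps))
  expect_true(all(whole == 0))

  # a sample whose top ranks are exactly one pathway scores it highest
  mat2 <- mat
  mat2[sets$pw1, 1] <- max(mat) * (2 + seq_len(5))
  sc <- gsvaScores(mat2, sets)
  expect_gt(sc["pw1", 1], 0)
  expect_equal(unname(which.max(sc[, 1])), 1L)

  expect_warning(gsvaScores(mat, c(sets, list(alien = "NOTAPEPTIDE"))),
                 "alien")
  expect_error(gsvaScores(mat[, 1:2], sets), "3 samples")
})

test_that("enrichmentSignificance ranks an injected group shift first", {
  set.seed(53)
  scores <- matrix(stats::rnorm(30 * 8, 0, 0.1), 30, 8,
                   dimnames = list(sprintf("pw%02d", 1:30),
                                   sprintf("s%d", 1:8)))
  groups <- rep(c("A", "B"), each = 4)
  scores["pw07", groups == "B"] <- scores["pw07", groups == "B"] + 2
  sig <- enrichmentSignificance(scores, groups, alpha = 0.01)
  expect_equal(sig$pathway[which.min(sig$p_adj)], "pw07")
  expect_true(all(sig$p_adj >= sig$p - 1e-15))
  expect_true(all(sig$p_adj >= 0 & sig$p_adj <= 1))

  # BH is monotone: adjusted ordering preserves raw ordering
  ord <- order(sig$p)
  expect_true(all(diff(sig$p_adj[ord]) >= -1e-15))

  # scores identical across groups carry no evidence
  flat <- matrix(1, 3, 8, dimnames = list(paste0("pw", 1:3), colnames(scores)))
  sigf <- enrichmentSignificance(flat, groups)
  expect_true(all(sigf$p_adj == 1))

  expect_error(enrichmentSignificance(scores, rep("A", 8)), "2 groups")
  expect_error(enrichmentSignificance(scores, c(rep("A", 7), "B")),
               "2 samples")
})
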