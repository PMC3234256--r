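test_that("the distance term normalizes by the reference distance", {
  expect_equal(distanceTerm(c(0, 0, 0), c(4, 6, 8)), 0)
  # a 1 A deviation weighs more over a 4 A pair than over an 8 A pair
  expect_equal(distanceTerm(1, 4), 0.25)
  expect_equal(distanceTerm(1, 8), 0.125)
  # additive over pairs
  expect_equal(distanceTerm(c(1, 1), c(4, 8)), 0.25 + 0.125)
  # scale consistency: scaling query and reference together changes nothing
  dev <- c(0.3, 0.9, 0.2); ref <- c(3.5, 7.1, 5.2)
  expect_equal(distanceTerm(dev * 4, ref * 4), distanceTerm(dev, ref))
  # strictly monotone in every component
  bumped <- dev + c(0.5, 0, 0)
  expect_gt(distanceTerm(bumped, ref), distanceTerm(dev, ref))
  expect_error(distanceTerm(1, 0), class = "claspScoreError")
  expect_error(distanceTerm(c(1, 2), 1), class = "claspScoreError")
})

test_that("the PD term floors denominators and ignores near-zero pairs", {
  expect_equal(pdTerm(c(-201.7, 22.3), c(-201.7, 22.3)), 0)
  # both-near-zero ignore band
  expect_equal(pdTerm(3, 2, epsZero = 25), 0)
  # band requires BOTH sides near zero
  expect_gt(pdTerm(3, 200, epsZero = 25), 0)
  # higher reference PDs are more loosely constrained
  expect_lt(pdTerm(250, 200), pdTerm(100, 50))
  expect_equal(pdTerm(250, 200), 50 / 200)
  # denominator floor for small references outside the band
  expect_equal(pdTerm(80, 30), 50 / 50)
  expect_error(pdTerm(1, c(1, 2)), class = "claspScoreError")
})

test_that("probing a motif in its own reference yields exactly zero", {
  for (kind in c("trypsin-1a0j", "blactamase")) {
    s <- fixtureStructure(kind)
    grid <- fixtureGrid(kind)
    m <- fixtureMotif(kind, withPD = TRUE)
    sc <- scoreMatches(enumerateCandidates(s, m), m, grid = grid)
    expect_identical(min(claspScores(sc)), 0)
    best <- bestMatch(sc)
    expect_true(best$matched)
    expect_identical(best$best$S, 0)
    expect_identical(best$best$D, 0)
    expect_identical(best$best$P, 0)
  }
})

test_that("weights decompose the score and wp = 0 is purely spatial", {
  set <- makeLabeledScoreset(seed = 3L)
  s0 <- scoreLabeledSet(set, wp = 0)
  s1 <- scoreLabeledSet(set)
  sD <- scoreLabeledSet(set, wd = 1, wp = 0)
  sP <- scoreLabeledSet(set, wd = 0, wp = 1)
  expect_equal(s1, sD + sP)
  expect_identical(s0, sD)
  expect_true(all(s1 >= 0))
  # doubling a weight doubles its term
  expect_equal(scoreLabeledSet(set, wd = 2, wp = 0), 2 * sD)
})

test_that("the best match wins on score with deterministic tie-breaks", {
  # planted perfect copy plus a perturbed decoy copy: the copy must win
  sites <- fixtureSites("trypsin-1a0j")
  decoy <- sites
  decoy$x <- decoy$x + c(0.8, -0.5, 0.6)   # distorted geometry
  s <- mergeStructures(
    readPDB(makeToyStructure(sites), sourceId = "copy+decoy"),
    transformStructure(readPDB(makeToyStructure(decoy, seed = 2L)),
                       t = c(0, 25, 0)))
  m <- buildMotif(s, c("A:10", "A:20", "A:30"),
                  labels = c("Sergrp", "Hisgrp", "Aspgrp"))
  sc <- scoreMatches(enumerateCandidates(s, m, tol = 3), m, wp = 0)
  expect_gte(matchCount(sc), 2L)
  best <- bestMatch(sc)
  expect_equal(unname(best$best$S), 0)
  expect_match(best$best$residues, "A:SER:10")
  # alternates retained in the report, sorted by (S, D, residues)
  expect_gte(nrow(best$report), 2L)
  expect_true(!is.unsorted(best$report$S))

  # no-match is distinguishable from a zero score
  empty <- scoreMatches(
    enumerateCandidates(readPDB(makeToyStructure(
      data.frame(resid = "ALA", x = 0, y = 0, z = 0))), m),
    m, wp = 0)
  nm <- bestMatch(empty)
  expect_false(nm$matched)
  expect_null(nm$best)
})

test_that("library ranking is ascending with self-motifs first at zero", {
  kinds <- c("trypsin-1a0j", "sap-1k7h", "blactamase")
  motifs <- lapply(kinds, fixtureMotif)
  expect_equal(nrow(rankLibrary(fixtureStructure("trypsin-1a0j"),
                                list())), 0L)
  for (kind in kinds) {
    tab <- rankLibrary(fixtureStructure(kind), motifs, wp = 0)
    expect_equal(tab$motif[1], kind)
    expect_equal(tab$S[1], 0)
    matched <- tab$S[tab$matched]
    expect_true(!is.unsorted(matched))
    # no-match motifs are listed last without a sentinel score
    if (any(!tab$matched))
      expect_true(all(which(!tab$matched) > which(tab$matched)))
  }
})

test_that("confusion metrics follow their definitions and flag 0/0", {
  perfect <- confusionMetrics(TP = 10, TN = 90, FP = 0, FN = 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fpr, 0)
  m <- confusionMetrics(TP = 9, TN = 90, FP = 10, FN = 1)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$fpr, 0.1)
  expect_length(m$undefined, 0L)
  u <- confusionMetrics(TP = 0, TN = 5, FP = 0, FN = 0)
  expect_true(is.na(u$sensitivity))
  expect_equal(u$undefined, "sensitivity")
})

test_that("ROC sweeps are stepwise, reach (1, 1), and match pROC's AUC", {
  # perfectly separated scores pass through (fpr 0, sens 1)
  sep <- rocSweep(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  expect_true(any(sep$curve$fpr == 0 & sep$curve$sensitivity == 1))
  expect_equal(sep$auc, 1)
  # identical scores: origin plus the single (1, 1) point
  same <- rocSweep(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(nrow(same$curve), 2L)
  expect_equal(same$curve$fpr, c(0, 1))
  expect_equal(same$curve$sensitivity, c(0, 1))
  # monotone curve
  r <- rocSweep(c(3, 1, 4, 1, 5, 9, 2, 6), c(1, 1, 0, 1, 0, 0, 1, 0))
  expect_true(!is.unsorted(r$curve$fpr))
  expect_true(!is.unsorted(r$curve$sensitivity))
  expect_error(rocSweep(1:3, c(1, 1, 1)), class = "claspScoreError")

  skip_if_not_installed("pROC")
  set.seed(42)
  scores <- c(rnorm(30, 1), rnorm(30, 2))
  labels <- rep(c(1, 0), each = 30)
  ours <- rocSweep(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, direction = ">",
    levels = c(0, 1), quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("PD scoring sharpens discrimination on family-consistent sets", {
  # paired comparison on the synthetic family fixture: adding the PD term
  # must not reduce the area under the sensitivity/FPR sweep
  aucD <- aucC <- numeric(10)
  for (i in seq_len(10)) {
    set <- makeLabeledScoreset(seed = 100 + i)
    aucD[i] <- rocSweep(scoreLabeledSet(set, wp = 0), set$positive)$auc
    aucC[i] <- rocSweep(scoreLabeledSet(set), set$positive)$auc
  }
  expect_true(all(aucC >= aucD))
  expect_gt(mean(aucC), mean(aucD))
})
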