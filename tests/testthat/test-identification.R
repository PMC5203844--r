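# a small db reused across identification tests
id_db <- function() {
  mono <- buildMonomerDb(searchConfig(c("AEm", "AEmA", "AEmG", "AEmI")))
  d33 <- crosslinkedSpecies(list(muropeptide("AEm", gm),
                                 muropeptide("AEmAA", gm)), donorPos = 3L)
  d43 <- crosslinkedSpecies(list(muropeptide("AEmA", gm),
                                 muropeptide("AEmA", gm)), donorPos = 4L)
  murosearch:::.makeDb(c(mono@species, list(d33, d43)))
}

# noise-free MS2 spectrum built from a species' own predictions
synth_ms2 <- function(sp, activation, z = 2L, charges = seq_len(min(z, 2L))) {
  fr <- predictFragments(sp, activation, charges = charges)
  spectrum(1L, 10, 2L, mz = fr$mz, intensity = rep(100, nrow(fr)),
           precursorMz = mzFromNeutral(neutralMass(sp), z),
           precursorCharge = z, activation = activation)
}

test_that("precursor matching respects the ppm tolerance", {
  db <- id_db()
  sp <- muropeptide("AEmA", gm)
  obs <- mzFromNeutral(neutralMass(sp), 2L)
  hit <- matchPrecursor(obs, 2L, db, tolPpm = 5)
  expect_equal(hit$label[1], "GlcN-MurNAc-AEmA")
  expect_lt(abs(hit$ppmError[1]), 1e-6)
  # the 38-ppm pair resolves at 5 ppm: querying one never returns the other
  obs2 <- mzFromNeutral(neutralMass(muropeptide("AEmA", "GlcNAc-MurNAc")), 2L)
  hit2 <- matchPrecursor(obs2, 2L, db, tolPpm = 5)
  expect_true("GlcNAc-MurNAc-AEmA" %in% hit2$label)
  expect_false("GlcN-MurNAc-AEmI" %in% hit2$label)
  # the exactly-isobaric 4-3/3-3 dimer pair comes back together, equal ppm
  d <- db@table$label[db@table$nUnits == 2]
  obs3 <- mzFromNeutral(db@table$neutralMass[db@table$nUnits == 2][1], 2L)
  hit3 <- matchPrecursor(obs3, 2L, db, tolPpm = 5)
  expect_setequal(intersect(hit3$label, d), d)
  expect_equal(diff(abs(hit3$ppmError[hit3$label %in% d])), 0)
  expect_error(matchPrecursor(500, 0L, db), "positive integer")
})

test_that("widening the precursor tolerance never drops candidates", {
  db <- id_db()
  obs <- mzFromNeutral(neutralMass(muropeptide("AEmA", gm)) * (1 + 3e-6), 3L)
  for (tol in c(5, 10, 20, 50)) {
    narrow <- matchPrecursor(obs, 3L, db, tolPpm = tol)
    wide <- matchPrecursor(obs, 3L, db, tolPpm = tol * 2)
    expect_true(all(narrow$index %in% wide$index))
  }
})

test_that("fragment matching uses ppm for HCD and Da for ETD", {
  fr <- data.frame(series = "b", site = "x", charge = 1L, mz = 800,
                   content = 0, unitsCovered = "1", diagnosticFor = "none")
  mkSpec <- function(act) spectrum(1L, 5, 2L, mz = 800.4, intensity = 10,
                                   precursorMz = 500, precursorCharge = 2L,
                                   activation = act)
  # 0.4 Da off: inside 0.5 Da (ETD), far outside 20 ppm (HCD)
  expect_equal(nrow(matchFragments(mkSpec("ETD"), fr)), 1)
  expect_equal(nrow(matchFragments(mkSpec("HCD"), fr)), 0)
  # empty spectrum -> empty match list
  empty <- spectrum(1L, 5, 2L, precursorMz = 500, precursorCharge = 2L,
                    activation = "ETD")
  expect_equal(nrow(matchFragments(empty, fr)), 0)
  # each observed peak is used at most once
  fr2 <- rbind(fr, transform(fr, mz = 800.1))
  m <- matchFragments(mkSpec("ETD"), fr2)
  expect_equal(nrow(m), 1)
  expect_equal(m$mz, 800.1)  # nearest prediction wins the peak
})

test_that("scoring spans [0, 2] with the expected anchors", {
  db <- id_db()
  idx <- match("GlcN-MurNAc-AEmA", db@table$label)
  sp <- db@species[[idx]]
  spec <- synth_ms2(sp, "HCD", z = 2L)
  cand <- matchPrecursor(spec@precursorMz, 2L, db)
  ranked <- scoreAndRank(spec, cand, db)
  # a noise-free spectrum of its own candidate scores the maximum 2.0
  expect_equal(ranked$score[ranked$index == idx], 2.0)
  expect_equal(ranked$index[1], idx)
  # a spectrum sharing no peaks with the candidate scores 0
  frAll <- predictFragments(sp, "HCD", charges = 1:2)
  off <- c(333.333, 777.777)
  expect_gt(min(abs(outer(frAll$mz, off, `-`))), 1)
  blank <- spectrum(2L, 10, 2L, mz = off, intensity = c(5, 5),
                    precursorMz = spec@precursorMz, precursorCharge = 2L,
                    activation = "HCD")
  fakeCand <- data.frame(index = idx, label = db@table$label[idx],
                         neutralMass = neutralMass(sp),
                         theoreticalMz = 1, ppmError = 0)
  expect_equal(scoreAndRank(blank, fakeCand, db)$score, 0)
})

test_that("half the primary fragments carrying 80 % of intensity scores 1.3", {
  sp <- asSpecies(muropeptide("AEmA", gm))
  fr <- predictFragments(sp, "HCD", charges = 1L)
  primary <- fr[fr$series %in% c("b", "y"), ]
  take <- primary[seq_len(nrow(primary) / 2), ]   # half of b/y predictions
  # one decoy peak far from every prediction carries the other 20 %
  decoy <- 250
  while (min(abs(fr$mz - decoy)) < 1) decoy <- decoy + 1.7
  tot <- 1000
  spec <- spectrum(1L, 5, 2L,
                   mz = c(take$mz, decoy),
                   intensity = c(rep(0.8 * tot / nrow(take), nrow(take)),
                                 0.2 * tot),
                   precursorMz = mzFromNeutral(neutralMass(sp), 2L),
                   precursorCharge = 1L, activation = "HCD")
  cand <- data.frame(index = 1L, label = "x",
                     neutralMass = neutralMass(sp), theoreticalMz = 1,
                     ppmError = 0)
  db1 <- murosearch:::.makeDb(list(sp))
  got <- scoreAndRank(spec, cand, db1)
  expect_equal(got$score, 0.5 + 0.8, tolerance = 1e-6)
})

test_that("score is monotone in matched-fragment inclusion", {
  sp <- asSpecies(muropeptide("AEm", gm))
  db1 <- murosearch:::.makeDb(list(sp))
  fr <- predictFragments(sp, "ETD", charges = 1L)
  cand <- data.frame(index = 1L, label = "x",
                     neutralMass = neutralMass(sp), theoreticalMz = 1,
                     ppmError = 0)
  prev <- -Inf
  for (k in seq_len(nrow(fr))) {
    spec <- spectrum(1L, 5, 2L, mz = fr$mz[seq_len(k)],
                     intensity = rep(10, k),
                     precursorMz = mzFromNeutral(neutralMass(sp), 2L),
                     precursorCharge = 1L, activation = "ETD")
    s <- scoreAndRank(spec, cand, db1)$score
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("isobaric grouping separates resolvable masses and joins true isomers", {
  db <- id_db()
  g <- isobaricGroups(db, tolPpm = 5)
  lab <- function(x) g$group[match(x, g$label)]
  # the exactly-isobaric dimer interpretations share a group
  dimers <- g[g$label %in% db@table$label[db@table$nUnits == 2], ]
  expect_equal(length(unique(dimers$group)), 1)
  expect_true(all(dimers$groupSize >= 2))
  expect_match(dimers$annotation[1], "\\[")
  # the 38-ppm pair lands in different groups
  expect_false(lab("GlcNAc-MurNAc-AEmA") == lab("GlcN-MurNAc-AEmI"))
  # a singleton db forms one group of one
  solo <- murosearch:::.makeDb(list(asSpecies(muropeptide("AEm", gm))))
  gs <- isobaricGroups(solo)
  expect_equal(gs$groupSize, 1L)
})

test_that("run search recovers generating compositions", {
  fx <- makeFixtureSuite()
  run <- simulateRun(fx$mixTruth, cycleTime = 0.1, seed = 3)
  stems <- c("AEm", "AEmA", "AEmG")
  mono <- buildMonomerDb(searchConfig(stems))
  suppressMessages({
    db2 <- buildMultimerDb(searchConfig(stems, maxUnits = 2),
                           acceptorStems = stems)
    db3 <- buildMultimerDb(searchConfig(stems, maxUnits = 3),
                           acceptorStems = stems)
  })
  db <- murosearch:::.combineDbs(mono, db2, db3)
  ids <- searchRun(run, db)
  top <- ids[ids$rank == 1L, ]
  truthLabels <- vapply(fx$mixTruth@species, speciesLabel, character(1))
  # noise-free: every MS2 spectrum's top hit is its generating composition
  expect_gte(mean(top$label %in% truthLabels), 0.99)
  expect_setequal(unique(top$label), truthLabels)
  # with spurious peaks and dropout the recovery stays >= 95 %
  runN <- simulateRun(fx$mixTruth, cycleTime = 0.1, seed = 4,
                      noise = list(dropout = 0.1, spurious = 0.2))
  topN <- subset(searchRun(runN, db), rank == 1L)
  expect_gte(mean(topN$label %in% truthLabels), 0.95)
})
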