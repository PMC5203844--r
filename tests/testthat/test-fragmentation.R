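# fixtures shared across fragmentation tests
frag_fixtures <- function() {
  list(
    d33 = crosslinkedSpecies(list(muropeptide("AEm", gm),
                                  muropeptide("AEmA", gm)), donorPos = 3L),
    d43 = crosslinkedSpecies(list(muropeptide("AEmA", gm),
                                  muropeptide("AEm", gm)), donorPos = 4L),
    f4_43 = crosslinkedSpecies(list(muropeptide("AEmA", gm),
                                    muropeptide("AEmA", gm)), donorPos = 4L),
    f4_33 = crosslinkedSpecies(list(muropeptide("AEm", gm),
                                    muropeptide("AEmAA", gm)), donorPos = 3L))
}

test_that("the donor-splitting c/z pair reproduces the annotated ETD masses", {
  fx <- frag_fixtures()
  fr <- predictFragments(fx$d33, "ETD", charges = 1L)
  xl <- fr[grepl("^xlink", fr$site), ]
  cIon <- xl$mz[xl$series == "c"]
  zIon <- xl$mz[xl$series == "z"]
  # published theoretical values for the tripeptide 3-3 dimer: 828.38 / 884.39
  expect_equal(round(cIon, 2), 828.38)
  expect_equal(round(zIon, 2), 884.39)
  # independent oracle: donor blocks = monomer minus its terminal water
  donorBlocks <- ora_mass(ora_monomer_comp("AEm", c("GlcN", "MurNAc"))) -
    ora_mass(ORA_WATER)
  expect_equal(cIon, ora_c_ion(donorBlocks), tolerance = 1e-6)
  accBlocks <- ora_mass(ora_monomer_comp("AEmA", c("GlcN", "MurNAc"))) -
    ora_mass(ORA_WATER)
  expect_equal(zIon, ora_zdot_ion(accBlocks), tolerance = 1e-6)
  # 4-3 counterpart: the c-ion carries the whole tetrapeptide donor
  fr43 <- predictFragments(fx$f4_43, "ETD", charges = 1L)
  xl43 <- fr43[grepl("^xlink", fr43$site), ]
  expect_equal(xl43$mz[xl43$series == "c"], ora_c_ion(accBlocks),
               tolerance = 1e-6)  # ~899.42, near the observed 899.45
  expect_equal(round(xl43$mz[xl43$series == "z"], 2), 884.39)
})

test_that("HCD b-ions and glycosidic Y ions come out right", {
  frB <- predictFragments(muropeptide("AEm"), "HCD", charges = 1L)
  b2 <- frB$mz[frB$series == "b" & frB$site == "u1:E2-m3"]
  expect_equal(b2, 201.087, tolerance = 1e-3)   # A + E residues + proton
  # glycosidic cleavages: bare-peptide Y (lactyl|Ala1) and GlcN loss
  fr <- predictFragments(muropeptide("AEm", gm), "ETD", charges = 1L)
  yPep <- fr$mz[fr$series == "Y" & grepl("lactyl\\|A1", fr$site)]
  expect_equal(yPep, ora_mass(ora_monomer_comp("AEm")) + ORA_PROTON,
               tolerance = 1e-6)
  yGlcN <- fr$mz[fr$series == "Y" & grepl("GlcN\\|MurNAc", fr$site)]
  expect_equal(yGlcN,
               ora_mass(ora_monomer_comp("AEm", "MurNAc")) + ORA_PROTON,
               tolerance = 1e-6)
  # all three named glycan bonds are cleaved in both modes
  for (act in c("HCD", "ETD")) {
    f <- predictFragments(muropeptide("AEmA", gm), act, charges = 1L)
    expect_setequal(unique(f$site[f$series == "Y"]),
                    c("u1:GlcN|MurNAc", "u1:MurNAc|lactyl", "u1:lactyl|A1"))
  }
})

test_that("complementarity identities hold on every linear prediction", {
  proton <- 1.00727646677
  for (stem in c("AEm", "AEmA", "AEmG", "AEmAA"))
    for (gf in c("none", gm, "GlcNAc-MurNAc")) {
      mp <- muropeptide(stem, gf)
      M <- neutralMass(mp)
      hcd <- predictFragments(mp, "HCD", charges = 1L)
      amide <- grepl("^u1:[A-Za-z]", hcd$site)
      for (s in unique(hcd$site[amide & hcd$series %in% c("b", "y")])) {
        b <- hcd$mz[hcd$series == "b" & hcd$site == s]
        y <- hcd$mz[hcd$series == "y" & hcd$site == s]
        expect_equal(b + y, M + 2 * proton, tolerance = 1e-3)
      }
      etd <- predictFragments(mp, "ETD", charges = 1L)
      for (s in unique(etd$site[etd$series == "c"])) {
        cc <- etd$mz[etd$series == "c" & etd$site == s]
        zz <- etd$mz[etd$series == "z" & etd$site == s]
        # c + z-dot = M + H + 2 protons; the z+1 variant adds one more H
        expect_equal(cc + zz, M + 1.0078250319 + 2 * proton,
                     tolerance = 1e-3)
        z1 <- etd$mz[etd$series == "z+1" & etd$site == s]
        expect_equal(z1 - zz, 1.0078250319, tolerance = 1e-6)
      }
    }
})

test_that("a monomer passed as a species predicts identical fragments", {
  mp <- muropeptide("AEmA", gm)
  a <- predictFragments(mp, "HCD", charges = 1:2)
  b <- predictFragments(asSpecies(mp), "HCD", charges = 1:2)
  expect_identical(a, b)
})

test_that("fragment masses are invariant under relabeling equivalent donors", {
  # swapping two identical donor units relabels the same molecule
  tri1 <- crosslinkedSpecies(list(muropeptide("AEm", gm),
                                  muropeptide("AEm", gm),
                                  muropeptide("AEmA", gm)))
  tri2 <- crosslinkedSpecies(list(muropeptide("AEm", gm),
                                  muropeptide("AEm", gm),
                                  muropeptide("AEmA", gm))[c(2, 1, 3)])
  expect_equal(neutralMass(tri1), neutralMass(tri2))
  for (act in c("HCD", "ETD")) {
    f1 <- sort(predictFragments(tri1, act, charges = 1L)$mz)
    f2 <- sort(predictFragments(tri2, act, charges = 1L)$mz)
    expect_equal(f1, f2, tolerance = 1e-9)
  }
  # permuting distinct donors changes the chain but never the neutral mass
  triA <- crosslinkedSpecies(list(muropeptide("AEm", gm),
                                  muropeptide("AEm", "MurNAc"),
                                  muropeptide("AEmA", gm)))
  triB <- crosslinkedSpecies(list(muropeptide("AEm", "MurNAc"),
                                  muropeptide("AEm", gm),
                                  muropeptide("AEmA", gm)))
  expect_equal(neutralMass(triA), neutralMass(triB))
  # database enumeration canonicalises donor order, so the db-level fragment
  # sets are order-independent even for distinct donors
  suppressMessages({
    dbA <- buildMultimerDb(searchConfig(c("AEm"), glycoforms = c(gm, "MurNAc"),
                                        maxUnits = 3), acceptorStems = "AEmA")
    dbB <- buildMultimerDb(searchConfig(c("AEm"), glycoforms = c("MurNAc", gm),
                                        maxUnits = 3), acceptorStems = "AEmA")
  })
  expect_identical(dbA@table$label, dbB@table$label)
})

test_that("diagnostic internal fragments separate 3-3 from 4-3", {
  fx <- frag_fixtures()
  di <- diagnosticInternalFragments(fx$f4_33, fx$f4_43)
  # the two-mDAP internal proves a 3-3 link: residue sum 344.170
  twoMdap <- di[abs(di$content - 344.170) < 2e-3, ]
  expect_equal(nrow(twoMdap), 1)
  expect_identical(twoMdap$diagnosticFor, "3-3")
  expect_equal(twoMdap$mz, 344.170 + 1.00728, tolerance = 2e-3)
  # Ala + 2 mDAP (415.207) arises under either topology: excluded
  expect_false(any(abs(di$content - (344.170 + 71.037)) < 2e-3))
  # non-isobaric pairs are rejected
  expect_error(diagnosticInternalFragments(fx$d33, fx$f4_43),
               "not isobaric")
})

test_that("flagged ETD diagnostics differ by more than the tolerance by construction", {
  fx <- frag_fixtures()
  tol <- 0.5
  di <- diagnosticFragments(fx$f4_33, fx$f4_43, "ETD", charges = 1:2,
                            tol = tol)
  dA <- di$a[di$a$diagnosticFor == "3-3", ]
  expect_gt(nrow(dA), 0)
  for (i in seq_len(nrow(dA))) {
    other <- di$b$mz[di$b$charge == dA$charge[i]]
    expect_true(all(abs(other - dA$mz[i]) > tol))
  }
  dB <- di$b[di$b$diagnosticFor == "4-3", ]
  expect_gt(nrow(dB), 0)
  # the 4-3 diagnostics include the published donor/acceptor-splitting pair
  # (899.42 c / 884.39 z); the tripeptide c at 828.38 is NOT diagnostic for
  # this composition because the 4-3 donor's m3-A4 c-ion has the same content
  expect_true(any(abs(dB$mz - 899.42) < 0.01))
  expect_true(any(abs(dB$mz - 884.39) < 0.01))
  expect_false(any(abs(c(dA$mz, dB$mz) - 828.38) < 0.01))

  # tripeptide/tetrapeptide composition: under full topology-aware
  # prediction the 828.38/884.39 pair is common to both interpretations
  # (the 4-3 donor's m3-A4 cleavage has the same content), so the exclusive
  # evidence is the donor-spanning c at 1638.73 (3-3) versus the
  # cross-link-splitting 899.42 c / 813.35 z (4-3)
  fx5 <- frag_fixtures()
  di5 <- diagnosticFragments(fx5$d33, fx5$d43, "ETD", charges = 1:2,
                             tol = tol)
  dA5 <- di5$a[di5$a$diagnosticFor == "3-3", ]
  dB5 <- di5$b[di5$b$diagnosticFor == "4-3", ]
  expect_true(any(abs(dA5$mz - 1638.73) < 0.01))
  expect_true(any(abs(dB5$mz - 899.42) < 0.01))
  expect_true(any(abs(dB5$mz - 813.35) < 0.01))
  expect_false(any(abs(c(dA5$mz, dB5$mz) - 884.39) < 0.01))
})
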