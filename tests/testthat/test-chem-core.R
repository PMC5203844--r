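test_that("residue masses reproduce the published mDAP value and elemental sums", {
  expect_equal(residueMass("m"), 172.0848, tolerance = 1e-4)
  # mDAP equals the legacy Met + 41.0443 encoding
  expect_equal(residueMass("m"), residueMass("M") + 41.0443,
               tolerance = 1e-4)
  expect_equal(residueMass("A"), 71.0371, tolerance = 1e-4)
  expect_equal(residueMass("G"), 57.0215, tolerance = 1e-4)
  for (code in names(ORA_RES))
    expect_equal(residueMass(code), ora_mass(ORA_RES[[code]]),
                 tolerance = 1e-9)
  expect_error(residueMass("B"), "B")
  expect_error(residueMass(c("A", "z")), "z")
})

test_that("the five standard glycoform masses match the printed values", {
  expect_equal(glycanMass(glycoform("MurNAc")), 277.116, tolerance = 1e-3)
  expect_equal(glycanMass(glycoform("GlcN-deacetyl-MurNAc")), 396.174,
               tolerance = 1e-3)
  expect_equal(glycanMass(glycoform("GlcN-anhydro-MurNAc")), 420.174,
               tolerance = 1e-3)
  expect_equal(glycanMass(glycoform("GlcN-MurNAc")), 438.185,
               tolerance = 1e-3)
  expect_equal(glycanMass(glycoform("GlcNAc-MurNAc")), 480.196,
               tolerance = 1e-3)
  expect_identical(glycanMass(glycoform("none")), 0)
})

test_that("glycoform chemistry constraints hold", {
  # reduction adds exactly H2
  expect_equal(glycanMass(glycoform("GlcN-MurNAc", reduced = TRUE)) -
                 glycanMass(glycoform("GlcN-MurNAc", reduced = FALSE)),
               2 * 1.0078250319, tolerance = 1e-9)
  # anhydro is 18.011 below the reduced convention and cannot be reduced
  expect_equal(glycanMass(glycoform("MurNAc")) -
                 glycanMass(glycoform("anhydro-MurNAc")),
               18.0106, tolerance = 1e-3)
  expect_error(new("Glycoform", sugars = c("GlcN", "anhydro-MurNAc"),
                   reduced = TRUE) |> validObject(), "anhydro")
  expect_error(glycoform("GlcX-MurNAc"), "GlcX|parse")
})

test_that("muropeptide masses agree with the independent elemental oracle", {
  cases <- expand.grid(stem = c("AEm", "AEmA", "AEmG", "AEmAA", "AEmF"),
                       gf = c("none", "MurNAc", "GlcN-MurNAc",
                              "GlcNAc-MurNAc", "GlcN-anhydro-MurNAc",
                              "GlcN-deacetyl-MurNAc"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    mp <- muropeptide(cases$stem[i], cases$gf[i])
    sugars <- if (cases$gf[i] == "none") character(0)
              else mp@glycoform@sugars
    expect_equal(neutralMass(mp),
                 ora_mass(ora_monomer_comp(cases$stem[i], sugars,
                                           mp@glycoform@reduced)),
                 tolerance = 2e-3, label = paste(cases$stem[i], cases$gf[i]))
  }
})

test_that("amidation is -0.984 and restricted to E and mDAP", {
  md <- stemModification("amidation", 2)
  expect_equal(md$delta, -0.984, tolerance = 1e-3)
  mp <- muropeptide("AEm", "GlcN-MurNAc", md)
  expect_equal(neutralMass(mp),
               neutralMass(muropeptide("AEm", "GlcN-MurNAc")) - 0.984,
               tolerance = 1e-3)
  expect_error(muropeptide("AEm", mods = stemModification("amidation", 1)),
               "E or mDAP")
  expect_error(muropeptide("AEm", mods = stemModification("wildcard", 3,
                                                          delta = 500)),
               "wildcard")
})

test_that("cross-linked species masses are unit sums minus one water per link", {
  u1 <- muropeptide("AEm", gm); u2 <- muropeptide("AEmA", gm)
  d <- crosslinkedSpecies(list(u1, u2))
  expect_equal(neutralMass(d), 1709.747, tolerance = 2e-3)
  expect_equal(neutralMass(d), neutralMass(u1) + neutralMass(u2) - 18.0106,
               tolerance = 1e-3)
  expect_identical(topology(d), "3-3")
  # a monomer wrapped as a species keeps its mass
  expect_equal(neutralMass(asSpecies(u1)), neutralMass(u1))
  # oracle path: trimer from elemental composition
  tri <- crosslinkedSpecies(list(muropeptide("AEm", gm),
                                 muropeptide("AEm", gm),
                                 muropeptide("AEmA", gm)))
  expect_equal(neutralMass(tri),
               ora_species_mass(list("AEm", "AEm", "AEmA"),
                                list(c("GlcN", "MurNAc"),
                                     c("GlcN", "MurNAc"),
                                     c("GlcN", "MurNAc"))),
               tolerance = 2e-3)
  # a 3-3 donor must be a tripeptide, a 4-3 donor at least a tetrapeptide
  expect_error(crosslinkedSpecies(list(u2, u2), donorPos = 3L),
               "tripeptide")
  expect_error(crosslinkedSpecies(list(u1, u2), donorPos = 4L),
               "four stem residues")
  # link count must be units - 1
  expect_error(new("CrosslinkedSpecies", units = list(u1, u2),
                   links = murosearch:::.emptyLinks()) |> validObject(),
               "units - 1")
})

test_that("the 4-3/3-3 dimer pair is exactly isobaric", {
  d43 <- crosslinkedSpecies(list(muropeptide("AEmA", gm),
                                 muropeptide("AEmA", gm)), donorPos = 4L)
  d33 <- crosslinkedSpecies(list(muropeptide("AEm", gm),
                                 muropeptide("AEmAA", gm)), donorPos = 3L)
  expect_equal(neutralMass(d43), neutralMass(d33), tolerance = 1e-12)
})

test_that("m/z arithmetic and ppm differences behave", {
  expect_equal(mzFromNeutral(1000, 1), 1000 + 1.00728, tolerance = 1e-5)
  expect_equal(mzFromNeutral(2520.096, 3), 841.039, tolerance = 1e-3)
  expect_error(mzFromNeutral(1000, 0), "positive integer")
  expect_equal(neutralFromMz(mzFromNeutral(1234.5, 3), 3), 1234.5)
  # symmetry and non-negativity over random mass pairs
  set.seed(42)
  a <- runif(50, 300, 3000); b <- a * (1 + runif(50, -1e-4, 1e-4))
  expect_identical(ppmDiff(a, b), ppmDiff(b, a))
  expect_true(all(ppmDiff(a, b) >= 0))
  expect_identical(ppmDiff(a, a), rep(0, 50))
})

test_that("the GlcNAc-MurNAc-AEmA / GlcN-MurNAc-AEm(I/L) pair sits near 38 ppm", {
  m1 <- neutralMass(muropeptide("AEmA", "GlcNAc-MurNAc"))
  m2 <- neutralMass(muropeptide("AEmI", gm))
  # oracle check of both masses, then of the separation
  expect_equal(m1, ora_mass(ora_monomer_comp("AEmA", c("GlcNAc", "MurNAc"))),
               tolerance = 1e-9)
  expect_equal(m2, ora_mass(ora_monomer_comp("AEmI", c("GlcN", "MurNAc"))),
               tolerance = 1e-9)
  expect_equal(ppmDiff(m1, m2), 38.65, tolerance = 0.01)
  # far beyond a 5 ppm precursor tolerance
  expect_gt(ppmDiff(m1, m2), 5 * 7)
})
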