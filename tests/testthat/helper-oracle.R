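# Independent mass oracle: recomputes neutral masses from elemental
# compositions with its own frozen element masses and formula tables,
# checked against pyteomics. Deliberately does not call the package's mass
# arithmetic: species masses are assembled as element-count vectors
# (residues + glycan residues + n*H2O - links*H2O) and summed at the end,
# exercising a different path than the package's per-block mass additions.

ORA_EL <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069)
ORA_PROTON <- 1.00727646677

ora_formula <- function(...) {
  x <- c(...)
  v <- c(H = 0, C = 0, N = 0, O = 0, S = 0)
  v[names(x)] <- v[names(x)] + x
  v
}

ORA_RES <- list(
  G = ora_formula(C = 2, H = 3, N = 1, O = 1),
  A = ora_formula(C = 3, H = 5, N = 1, O = 1),
  E = ora_formula(C = 5, H = 7, N = 1, O = 3),
  m = ora_formula(C = 7, H = 12, N = 2, O = 3),
  I = ora_formula(C = 6, H = 11, N = 1, O = 1),
  F = ora_formula(C = 9, H = 9, N = 1, O = 1),
  S = ora_formula(C = 3, H = 5, N = 1, O = 2))

ORA_SUGAR <- list(
  "GlcN"            = ora_formula(C = 6, H = 11, N = 1, O = 4),
  "GlcNAc"          = ora_formula(C = 8, H = 13, N = 1, O = 5),
  "MurNAc"          = ora_formula(C = 11, H = 17, N = 1, O = 7),
  "deacetyl-MurNAc" = ora_formula(C = 9, H = 15, N = 1, O = 6),
  "anhydro-MurNAc"  = ora_formula(C = 11, H = 17, N = 1, O = 6))

ORA_WATER <- ora_formula(H = 2, O = 1)
ORA_H2 <- ora_formula(H = 2)

ora_mass <- function(v) sum(ORA_EL[names(v)] * v)

# elemental composition of a monomer: residues + water + glycan residues
# (+H2 if the reducing end is reduced, i.e. MurNAc or deacetyl-MurNAc)
ora_monomer_comp <- function(stem, sugars = character(0), reduced = TRUE) {
  v <- ORA_WATER
  for (r in strsplit(stem, "")[[1]]) v <- v + ORA_RES[[r]]
  for (s in sugars) v <- v + ORA_SUGAR[[s]]
  if (reduced && length(sugars) &&
      sugars[length(sugars)] %in% c("MurNAc", "deacetyl-MurNAc"))
    v <- v + ORA_H2
  v
}

# cross-linked species: sum of unit compositions minus one water per link
ora_species_mass <- function(stemList, sugarList, nLinks = length(stemList) - 1) {
  v <- 0 * ORA_WATER
  for (i in seq_along(stemList))
    v <- v + ora_monomer_comp(stemList[[i]], sugarList[[i]])
  v <- v - nLinks * ORA_WATER
  ora_mass(v)
}

ora_mz <- function(M, z) (M + z * ORA_PROTON) / z

# c-ion: N-side blocks + NH3 + proton; z-dot: C-side blocks + H2O - NH3 +
# H + proton (frozen, independent of the package's offset table)
ora_c_ion <- function(blocks)
  blocks + 17.02654910 + ORA_PROTON
ora_zdot_ion <- function(blocks)
  blocks + 18.01056468 - 17.02654910 + 1.0078250319 + ORA_PROTON

# small helpers used across test files
gm <- "GlcN-MurNAc"
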