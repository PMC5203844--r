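## Monoisotopic element masses and residue/glycan building-block tables.
## All downstream masses are sums over these full-precision values; the
## rounded literature values (172.0848, 438.185, 18.0106, ...) are only ever
## used as expectations in tests, never as internal constants.

.ELEMENTS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

.PROTON   <- 1.00727646688
.ELECTRON <- 0.00054857991

#' Monoisotopic mass of an elemental formula
#'
#' @param formula named numeric vector of element counts, e.g.
#'   \code{c(C = 3, H = 5, N = 1, O = 1)}.
#' @return Monoisotopic mass in Da.
#' @examples
#' formulaMass(c(H = 2, O = 1))  # water
#' @export
formulaMass <- function(formula) {
  el <- names(formula)
  bad <- setdiff(el, names(.ELEMENTS))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  sum(.ELEMENTS[el] * as.numeric(formula))
}

## Residue (dehydrated) elemental formulas: 20 standard amino acids plus the
## reserved lower-case 'm' for meso-diaminopimelic acid (mDAP), the stem
## residue that carries the cross-linking amine in most Gram-positive rods.
.RESIDUE_FORMULAS <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  m = c(C = 7,  H = 12, N = 2, O = 3)   # mDAP
)

.RESIDUE_MASSES <- vapply(.RESIDUE_FORMULAS, formulaMass, numeric(1))

## Glycan building blocks (residue formulas, i.e. already dehydrated for the
## glycosidic/amide condensations). Borohydride reduction of the MurNAc
## reducing end (muramitol) adds H2; the 1,6-anhydro ring is not reducible.
.SUGAR_FORMULAS <- list(
  "GlcN"            = c(C = 6,  H = 11, N = 1, O = 4),
  "GlcNAc"          = c(C = 8,  H = 13, N = 1, O = 5),
  "MurNAc"          = c(C = 11, H = 17, N = 1, O = 7),
  "deacetyl-MurNAc" = c(C = 9,  H = 15, N = 1, O = 6),
  "anhydro-MurNAc"  = c(C = 11, H = 17, N = 1, O = 6)
)
.SUGAR_MASSES <- vapply(.SUGAR_FORMULAS, formulaMass, numeric(1))

.MURNAC_VARIANTS <- c("MurNAc", "deacetyl-MurNAc", "anhydro-MurNAc")
.REDUCIBLE      <- c("MurNAc", "deacetyl-MurNAc")

## Lactyl bridge inside MurNAc (MurNAc = GlcNAc + lactyl ether); needed for
## the MurNAc|lactyl glycosidic cleavage seen prominently in ETD spectra.
.LACTYL_FORMULA <- c(C = 3, H = 4, O = 2)

#' Physical constants used in m/z arithmetic
#'
#' Water (the amide condensation loss), the proton and hydrogen masses, and
#' the amidation delta (OH -> NH2 on a side-chain carboxyl).
#'
#' @return Named numeric vector in Da.
#' @export
physicalConstants <- function() {
  c(
    water     = formulaMass(c(H = 2, O = 1)),
    proton    = .PROTON,
    hydrogen  = .ELEMENTS[["H"]],
    ammonia   = formulaMass(c(N = 1, H = 3)),
    electron  = .ELECTRON,
    reduction = formulaMass(c(H = 2)),
    amidation = formulaMass(c(N = 1, H = 2)) - formulaMass(c(O = 1, H = 1)),
    lactyl    = formulaMass(.LACTYL_FORMULA)
  )
}

.WATER     <- formulaMass(c(H = 2, O = 1))
.AMMONIA   <- formulaMass(c(N = 1, H = 3))
.HYDROGEN  <- .ELEMENTS[["H"]]
.AMIDATION <- formulaMass(c(N = 1, H = 2)) - formulaMass(c(O = 1, H = 1))
.LACTYL    <- formulaMass(.LACTYL_FORMULA)

## Offset of the legacy "methionine + delta" import convention, in which a
## modified M stands in for mDAP in FASTA databases.
.MDAP_AS_MET_OFFSET <- .RESIDUE_MASSES[["m"]] - .RESIDUE_MASSES[["M"]]

#' Residue table
#'
#' @return data.frame with columns \code{code}, \code{formula} (character,
#'   Hill-ish), \code{mass} (monoisotopic residue mass in Da).
#' @export
residueTable <- function() {
  data.frame(
    code = names(.RESIDUE_FORMULAS),
    formula = vapply(.RESIDUE_FORMULAS, function(f)
      paste0(names(f), ifelse(f > 1, f, ""), collapse = ""), character(1)),
    mass = unname(.RESIDUE_MASSES),
    row.names = NULL
  )
}

#' Monoisotopic residue mass
#'
#' Dehydrated (in-chain) residue mass for a single-letter code. The reserved
#' code \code{m} is mDAP (meso-diaminopimelic acid, 172.0848 Da).
#'
#' @param code character vector of single-letter residue codes.
#' @return numeric vector of masses in Da.
#' @examples
#' residueMass("m")                 # mDAP
#' residueMass(c("A", "E", "m"))
#' @export
residueMass <- function(code) {
  bad <- setdiff(code, names(.RESIDUE_MASSES))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  unname(.RESIDUE_MASSES[code])
}

#' Residue masses of a peptide stem string
#'
#' @param stem character scalar such as \code{"AEmA"}.
#' @return numeric vector, one mass per residue.
#' @keywords internal
stemResidueMasses <- function(stem) {
  stopifnot(is.character(stem), length(stem) == 1L, nzchar(stem))
  residueMass(strsplit(stem, "")[[1]])
}
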