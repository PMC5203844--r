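#' @import methods
NULL

#' Glycoform: the glycan chain attached to a peptide stem
#'
#' Zero, one or two monosaccharides. The reducing-end position (last) must be
#' a MurNAc variant; a non-reducing GlcN/GlcNAc may precede it. Reduction
#' (borohydride, +H2) and the 1,6-anhydro ring are mutually exclusive.
#'
#' @slot sugars ordered character vector (N-terminal to reducing end), each
#'   one of \code{GlcN}, \code{GlcNAc}, \code{MurNAc}, \code{deacetyl-MurNAc},
#'   \code{anhydro-MurNAc}; may be empty (no glycan).
#' @slot reduced logical; reducing-end MurNAc reduced to muramitol.
#' @exportClass Glycoform
setClass("Glycoform",
  representation(sugars = "character", reduced = "logical"),
  prototype(sugars = character(0), reduced = TRUE))

setValidity("Glycoform", function(object) {
  s <- object@sugars
  msg <- character(0)
  if (length(s) > 2L)
    msg <- c(msg, "at most two monosaccharides are supported")
  bad <- setdiff(s, names(.SUGAR_FORMULAS))
  if (length(bad))
    msg <- c(msg, paste("unsupported monosaccharide:", paste(bad, collapse = ", ")))
  if (length(s) >= 1L && !length(bad)) {
    if (!(s[length(s)] %in% .MURNAC_VARIANTS))
      msg <- c(msg, "reducing-end (last) sugar must be a MurNAc variant")
    if (length(s) == 2L && !(s[1L] %in% c("GlcN", "GlcNAc")))
      msg <- c(msg, "non-reducing sugar must be GlcN or GlcNAc")
    if (isTRUE(object@reduced) && "anhydro-MurNAc" %in% s)
      msg <- c(msg, "anhydro-MurNAc cannot be reduced")
  }
  if (length(object@reduced) != 1L || is.na(object@reduced))
    msg <- c(msg, "'reduced' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Muropeptide: one glycan chain plus one peptide stem
#'
#' @slot glycoform a \linkS4class{Glycoform} (possibly empty).
#' @slot stem character scalar of single-letter residue codes, \code{m} =
#'   mDAP (e.g. \code{"AEmA"}).
#' @slot mods data.frame of stem modifications with columns \code{kind}
#'   (\code{amidation}, \code{anhydro}, \code{wildcard}), \code{delta} (Da)
#'   and \code{position} (1-based stem index).
#' @exportClass Muropeptide
setClass("Muropeptide",
  representation(glycoform = "Glycoform", stem = "character",
                 mods = "data.frame"))

.emptyMods <- function()
  data.frame(kind = character(0), delta = numeric(0), position = integer(0))

setValidity("Muropeptide", function(object) {
  msg <- character(0)
  if (length(object@stem) != 1L || !nzchar(object@stem))
    return("stem must be a non-empty character scalar")
  res <- strsplit(object@stem, "")[[1]]
  bad <- setdiff(res, names(.RESIDUE_MASSES))
  if (length(bad))
    msg <- c(msg, paste("unknown residue code(s):", paste(bad, collapse = ", ")))
  md <- object@mods
  need <- c("kind", "delta", "position")
  if (!all(need %in% names(md)))
    return("mods must have columns kind, delta, position")
  if (nrow(md)) {
    if (!all(md$kind %in% c("amidation", "anhydro", "wildcard")))
      msg <- c(msg, "mod kind must be amidation, anhydro or wildcard")
    if (any(md$position < 1L | md$position > length(res)))
      msg <- c(msg, "mod position outside the stem")
    ami <- md$kind == "amidation"
    if (any(ami)) {
      if (!all(res[md$position[ami]] %in% c("E", "m")))
        msg <- c(msg, "amidation is only allowed on E or mDAP")
      if (any(abs(md$delta[ami] - .AMIDATION) > 1e-3))
        msg <- c(msg, "amidation delta must be -0.984")
    }
    wc <- md$kind == "wildcard"
    if (any(wc) && any(md$delta[wc] < -130 | md$delta[wc] > 210))
      msg <- c(msg, "wildcard delta outside [-130, +210] Da")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-linked species: an ordered chain of muropeptide units
#'
#' Units are ordered donor-to-acceptor: the first k-1 units are donors, the
#' last is the terminal acceptor. Each link is an amide between the donor
#' stem (position 3 = mDAP side-chain carboxyl, a 3-3 link; position 4 =
#' d-Ala carboxyl, a 4-3 link) and the acceptor mDAP amine (position 3),
#' condensing out one water.
#'
#' @slot units list of \linkS4class{Muropeptide}.
#' @slot links data.frame with columns \code{donorUnit}, \code{donorPos}
#'   (3 or 4), \code{acceptorUnit}, \code{acceptorPos} (always 3).
#' @exportClass CrosslinkedSpecies
setClass("CrosslinkedSpecies",
  representation(units = "list", links = "data.frame"))

.emptyLinks <- function()
  data.frame(donorUnit = integer(0), donorPos = integer(0),
             acceptorUnit = integer(0), acceptorPos = integer(0))

setValidity("CrosslinkedSpecies", function(object) {
  msg <- character(0)
  k <- length(object@units)
  if (k < 1L) return("at least one unit is required")
  if (!all(vapply(object@units, is, logical(1), "Muropeptide")))
    return("units must all be Muropeptide objects")
  lk <- object@links
  need <- c("donorUnit", "donorPos", "acceptorUnit", "acceptorPos")
  if (!all(need %in% names(lk)))
    return("links must have columns donorUnit, donorPos, acceptorUnit, acceptorPos")
  if (nrow(lk) != k - 1L)
    msg <- c(msg, sprintf("links (%d) must number units - 1 (%d)", nrow(lk), k - 1L))
  if (nrow(lk)) {
    if (any(lk$donorUnit < 1L | lk$donorUnit > k) ||
        any(lk$acceptorUnit < 1L | lk$acceptorUnit > k))
      msg <- c(msg, "link unit index out of range")
    if (!all(lk$donorPos %in% c(3L, 4L)))
      msg <- c(msg, "donorPos must be 3 (3-3 link) or 4 (4-3 link)")
    if (!all(lk$acceptorPos == 3L))
      msg <- c(msg, "acceptorPos must be 3 (mDAP)")
    for (i in seq_len(nrow(lk))) {
      dlen <- nchar(object@units[[lk$donorUnit[i]]]@stem)
      if (lk$donorPos[i] == 3L && dlen != 3L)
        msg <- c(msg, "a 3-3 donor must carry a tripeptide stem")
      if (lk$donorPos[i] == 4L && dlen < 4L)
        msg <- c(msg, "a 4-3 donor needs at least four stem residues")
      astem <- strsplit(object@units[[lk$acceptorUnit[i]]]@stem, "")[[1]]
      if (length(astem) < 3L || astem[3L] != "m")
        msg <- c(msg, "acceptor position 3 must be mDAP")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Candidate database for precursor search
#'
#' Deduplicated candidate species with a mass-sorted index for ppm-window
#' lookup.
#'
#' @slot species list of \linkS4class{CrosslinkedSpecies}, in mass order.
#' @slot table data.frame, one row per species: \code{label}, \code{stems},
#'   \code{glycans}, \code{topology}, \code{nUnits}, \code{nMods},
#'   \code{neutralMass} (ascending).
#' @exportClass CandidateDb
setClass("CandidateDb", representation(species = "list", table = "data.frame"))

setValidity("CandidateDb", function(object) {
  if (length(object@species) != nrow(object@table))
    return("species list and table must have the same length")
  if (is.unsorted(object@table$neutralMass))
    return("table must be sorted by neutralMass")
  TRUE
})

#' One MS1 or MS2 spectrum
#'
#' @slot scan integer scan number.
#' @slot rt retention time in minutes.
#' @slot msLevel 1 or 2.
#' @slot precursorMz,precursorCharge precursor fields (MS2; NA for MS1).
#' @slot activation \code{"HCD"}, \code{"ETD"} or NA (MS1).
#' @slot mz,intensity centroided peak list, mz ascending.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(scan = "integer", rt = "numeric", msLevel = "integer",
                 precursorMz = "numeric", precursorCharge = "integer",
                 activation = "character", mz = "numeric",
                 intensity = "numeric"))

setValidity("Spectrum", function(object) {
  msg <- character(0)
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (is.unsorted(object@mz))
    msg <- c(msg, "peaks must be sorted by mz")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (!object@msLevel %in% c(1L, 2L))
    msg <- c(msg, "msLevel must be 1 or 2")
  if (object@msLevel == 2L &&
      (is.na(object@precursorMz) || is.na(object@precursorCharge)))
    msg <- c(msg, "MS2 spectra need precursorMz and precursorCharge")
  if (object@msLevel == 2L && !object@activation %in% c("HCD", "ETD"))
    msg <- c(msg, "MS2 activation must be HCD or ETD")
  if (length(msg)) msg else TRUE
})

#' An LC-MS/MS run: an ordered collection of spectra
#'
#' @slot spectra list of \linkS4class{Spectrum}, RT-ordered.
#' @slot metadata free-form list (source file, simulation ground truth, ...).
#' @exportClass MsRun
setClass("MsRun", representation(spectra = "list", metadata = "list"),
  prototype(spectra = list(), metadata = list()))

setValidity("MsRun", function(object) {
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    return("spectra must all be Spectrum objects")
  rt <- vapply(object@spectra, function(s) s@rt, numeric(1))
  if (is.unsorted(rt)) return("spectra must be in retention-time order")
  TRUE
})

#' Ground truth for a simulated run
#'
#' @slot species list of \linkS4class{CrosslinkedSpecies}.
#' @slot info data.frame, one row per species: \code{abundance} (total
#'   monoisotopic ion count, summed over charge states), \code{rtCenter},
#'   \code{rtWidth} (Gaussian sigma, minutes), \code{isdParent} (index of the
#'   in-source-decay parent, or NA for genuine species).
#' @slot charges list of named numeric vectors (charge state -> fraction).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(species = "list", info = "data.frame", charges = "list"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  n <- length(object@species)
  if (nrow(object@info) != n || length(object@charges) != n)
    return("species, info and charges must have equal length")
  need <- c("abundance", "rtCenter", "rtWidth", "isdParent")
  if (!all(need %in% names(object@info)))
    return("info needs columns abundance, rtCenter, rtWidth, isdParent")
  if (any(object@info$abundance <= 0))
    msg <- c(msg, "abundances must be positive")
  if (any(object@info$rtWidth <= 0))
    msg <- c(msg, "rtWidth must be positive")
  ip <- object@info$isdParent
  if (any(!is.na(ip) & (ip < 1 | ip > n)))
    msg <- c(msg, "isdParent index out of range")
  if (length(msg)) msg else TRUE
})
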