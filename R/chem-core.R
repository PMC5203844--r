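## Constructors, accessors and mass arithmetic for muropeptide species.

#' Construct a glycoform
#'
#' @param sugars character vector of monosaccharides, N-terminal first (e.g.
#'   \code{c("GlcN", "MurNAc")}), or a hyphen-joined name such as
#'   \code{"GlcN-MurNAc"}, \code{"GlcN-anhydro-MurNAc"} or \code{"none"}.
#' @param reduced reduce the MurNAc reducing end to muramitol (+2.0157 Da)?
#'   Defaults to TRUE: after mutanolysin digestion and borohydride treatment
#'   every disaccharide carries a reduced reducing end.
#' @return A \linkS4class{Glycoform}.
#' @examples
#' glycoform("GlcN-MurNAc")
#' glycanMass(glycoform("GlcNAc-MurNAc"))
#' @export
glycoform <- function(sugars = character(0), reduced = TRUE) {
  if (length(sugars) == 1L && (sugars == "none" || sugars == ""))
    sugars <- character(0)
  if (length(sugars) == 1L && grepl("-", sugars) &&
      !sugars %in% names(.SUGAR_FORMULAS))
    sugars <- .parseGlycoName(sugars)
  if ("anhydro-MurNAc" %in% sugars) reduced <- FALSE
  new("Glycoform", sugars = as.character(sugars), reduced = reduced)
}

## "GlcN-anhydro-MurNAc" -> c("GlcN", "anhydro-MurNAc"), etc.
.parseGlycoName <- function(name) {
  for (v in c("anhydro-MurNAc", "deacetyl-MurNAc", "MurNAc")) {
    if (name == v) return(v)
    pre <- paste0("-", v)
    if (endsWith(name, pre)) {
      head <- substr(name, 1L, nchar(name) - nchar(pre))
      return(c(head, v))
    }
  }
  stop("cannot parse glycoform name: ", name)
}

#' Glycan modification mass
#'
#' The mass added to a bare peptide stem by its N-terminal glycan chain.
#' Reduction adds H2 to a reducible reducing end (MurNAc or
#' deacetyl-MurNAc); the 1,6-anhydro ring is 18.011 Da below the reduced
#' convention.
#'
#' @param x a \linkS4class{Glycoform}.
#' @return Mass in Da (0 for the empty glycoform).
#' @export
glycanMass <- function(x) {
  stopifnot(is(x, "Glycoform"))
  validObject(x)
  if (!length(x@sugars)) return(0)
  m <- sum(.SUGAR_MASSES[x@sugars])
  if (x@reduced && x@sugars[length(x@sugars)] %in% .REDUCIBLE)
    m <- m + 2 * .HYDROGEN
  m
}

#' Construct a muropeptide (one glycan chain + one peptide stem)
#'
#' @param stem character scalar of single-letter codes; \code{m} is mDAP
#'   (e.g. \code{"AEm"}, \code{"AEmA"}).
#' @param glycoform a \linkS4class{Glycoform}, or a name accepted by
#'   \code{\link{glycoform}} (default \code{"none"}).
#' @param mods data.frame of stem modifications (columns \code{kind},
#'   \code{delta}, \code{position}); see \code{\link{stemModification}}.
#' @return A \linkS4class{Muropeptide}.
#' @examples
#' mp <- muropeptide("AEmA", "GlcN-MurNAc")
#' neutralMass(mp)
#' @export
muropeptide <- function(stem, glycoform = "none", mods = NULL) {
  if (!is(glycoform, "Glycoform"))
    glycoform <- glycoform(glycoform)
  if (is.null(mods)) mods <- .emptyMods()
  new("Muropeptide", glycoform = glycoform, stem = stem, mods = mods)
}

#' Describe a stem modification
#'
#' @param kind \code{"amidation"} (-0.984 on E or mDAP), \code{"anhydro"}
#'   (-18.011 water loss) or \code{"wildcard"} (any delta in [-130, +210]).
#' @param position 1-based stem position.
#' @param delta mass delta in Da; filled in automatically for amidation and
#'   anhydro.
#' @return one-row data.frame suitable for \code{mods} in
#'   \code{\link{muropeptide}}; rbind rows to combine.
#' @export
stemModification <- function(kind = c("amidation", "anhydro", "wildcard"),
                             position, delta = NULL) {
  kind <- match.arg(kind)
  if (is.null(delta))
    delta <- switch(kind,
      amidation = .AMIDATION,
      anhydro   = -.WATER,
      stop("wildcard modifications need an explicit delta"))
  data.frame(kind = kind, delta = delta, position = as.integer(position))
}

#' Assemble a cross-linked species from muropeptide units
#'
#' Units are given donor-to-acceptor; consecutive units are joined by one
#' amide cross-link each (losing one water). The donor position decides the
#' topology: 3 = mDAP-to-mDAP (3-3, l,d-transpeptidase), 4 = d-Ala-to-mDAP
#' (4-3, d,d-transpeptidase).
#'
#' @param units list of \linkS4class{Muropeptide} (1 to 3).
#' @param donorPos integer vector of donor positions, one per link
#'   (length(units) - 1); defaults to 3 for tripeptide donors and 4
#'   otherwise.
#' @return A \linkS4class{CrosslinkedSpecies}.
#' @examples
#' dimer <- crosslinkedSpecies(list(muropeptide("AEm", "GlcN-MurNAc"),
#'                                  muropeptide("AEmA", "GlcN-MurNAc")))
#' neutralMass(dimer)
#' @export
crosslinkedSpecies <- function(units, donorPos = NULL) {
  if (is(units, "Muropeptide")) units <- list(units)
  k <- length(units)
  if (k > 1L) {
    if (is.null(donorPos))
      donorPos <- vapply(units[seq_len(k - 1L)], function(u)
        if (nchar(u@stem) == 3L) 3L else 4L, integer(1))
    links <- data.frame(donorUnit = seq_len(k - 1L),
                        donorPos = as.integer(donorPos),
                        acceptorUnit = 2:k, acceptorPos = 3L)
  } else links <- .emptyLinks()
  new("CrosslinkedSpecies", units = units, links = links)
}

#' @describeIn crosslinkedSpecies a monomer wrapped as a species.
#' @param x a \linkS4class{Muropeptide}.
#' @export
asSpecies <- function(x) crosslinkedSpecies(list(x))

#' Neutral monoisotopic mass
#'
#' For a muropeptide: sum of residue masses + water + glycan modification
#' mass + stem modification deltas. For a cross-linked species: sum of unit
#' masses minus one water (18.0106 Da) per cross-link.
#'
#' @param x a \linkS4class{Muropeptide} or \linkS4class{CrosslinkedSpecies}.
#' @return Mass in Da.
#' @export
setGeneric("neutralMass", function(x) standardGeneric("neutralMass"))

#' @rdname neutralMass
#' @export
setMethod("neutralMass", "Muropeptide", function(x) {
  sum(stemResidueMasses(x@stem)) + .WATER + glycanMass(x@glycoform) +
    sum(x@mods$delta)
})

#' @rdname neutralMass
#' @export
setMethod("neutralMass", "CrosslinkedSpecies", function(x) {
  sum(vapply(x@units, neutralMass, numeric(1))) - nrow(x@links) * .WATER
})

#' Cross-link topology of a species
#'
#' @param x a \linkS4class{CrosslinkedSpecies}.
#' @return character vector, one of \code{"3-3"}/\code{"4-3"} per link
#'   (empty for a monomer).
#' @export
topology <- function(x) {
  stopifnot(is(x, "CrosslinkedSpecies"))
  if (!nrow(x@links)) return(character(0))
  ifelse(x@links$donorPos == 3L, "3-3", "4-3")
}

#' Accessors for muropeptide species
#'
#' \code{speciesUnits} returns the list of units; \code{stems} the stem
#' strings; \code{glycoforms} the glycoform names; \code{speciesLabel} a
#' compact human-readable label.
#'
#' @param x a \linkS4class{CrosslinkedSpecies} (or, where sensible, a
#'   \linkS4class{Muropeptide}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
speciesUnits <- function(x) x@units

#' @rdname accessors
#' @export
stems <- function(x) {
  if (is(x, "Muropeptide")) return(x@stem)
  vapply(x@units, function(u) u@stem, character(1))
}

#' @rdname accessors
#' @export
glycoformName <- function(x) {
  gf <- if (is(x, "Muropeptide")) x@glycoform else x
  if (!length(gf@sugars)) "none" else paste(gf@sugars, collapse = "-")
}

#' @rdname accessors
#' @export
glycoforms <- function(x) {
  if (is(x, "Muropeptide")) return(glycoformName(x))
  vapply(x@units, glycoformName, character(1))
}

#' @rdname accessors
#' @export
speciesLabel <- function(x) {
  if (is(x, "Muropeptide")) x <- asSpecies(x)
  us <- vapply(seq_along(x@units), function(i) {
    u <- x@units[[i]]
    g <- glycoformName(u)
    lab <- if (g == "none") u@stem else paste0(g, "-", u@stem)
    if (nrow(u@mods)) {
      tag <- paste0(substr(u@mods$kind, 1, 2), u@mods$position,
                    collapse = ",")
      lab <- paste0(lab, "[", tag, "]")
    }
    lab
  }, character(1))
  top <- topology(x)
  if (!length(top)) return(us)
  paste0(paste(mapply(function(u, t) paste0(u, " =", t, "= "),
                      us[-length(us)], top), collapse = ""),
         us[length(us)])
}

setMethod("show", "Glycoform", function(object) {
  cat("Glycoform:", glycoformName(object),
      if (object@reduced && length(object@sugars)) "(reduced)" else "", "\n")
})

setMethod("show", "Muropeptide", function(object) {
  cat(sprintf("Muropeptide %s | stem %s | %d mod(s) | M = %.4f Da\n",
              glycoformName(object), object@stem, nrow(object@mods),
              neutralMass(object)))
})

setMethod("show", "CrosslinkedSpecies", function(object) {
  cat(sprintf("CrosslinkedSpecies (%d unit%s): %s\n  M = %.4f Da\n",
              length(object@units),
              if (length(object@units) > 1) "s" else "",
              speciesLabel(object), neutralMass(object)))
})

#' m/z of a neutral mass at a given charge
#'
#' @param M neutral mass in Da.
#' @param z positive integer charge.
#' @return (M + z * proton) / z.
#' @examples
#' mzFromNeutral(2520.096, 3)
#' @export
mzFromNeutral <- function(M, z) {
  if (any(z < 1) || any(z != round(z)))
    stop("charge must be a positive integer")
  if (any(M <= 0)) stop("mass must be positive")
  (M + z * .PROTON) / z
}

#' Neutral mass from an observed m/z and charge
#'
#' @param mz observed m/z.
#' @param z positive integer charge.
#' @export
neutralFromMz <- function(mz, z) {
  if (any(z < 1) || any(z != round(z)))
    stop("charge must be a positive integer")
  mz * z - z * .PROTON
}

#' Relative mass difference in parts per million
#'
#' 1e6 * |m1 - m2| / min(m1, m2); symmetric and non-negative.
#'
#' @param m1,m2 masses (or m/z values) in Da.
#' @export
ppmDiff <- function(m1, m2) {
  1e6 * abs(m1 - m2) / pmin(m1, m2)
}
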