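## Candidate enumeration: monomer, dimer and trimer databases, and the
## wildcard (open delta) search used to surface unanticipated stem variants.

#' Search configuration
#'
#' @param stems character vector of stem sequences (\code{m} = mDAP).
#' @param glycoforms character vector of glycoform names; may include
#'   \code{"none"}. Defaults to the five states searched for monomers:
#'   MurNAc, GlcN-deacetyl-MurNAc, GlcN-anhydro-MurNAc, GlcN-MurNAc and
#'   GlcNAc-MurNAc, plus the bare peptide.
#' @param amidation enumerate -0.984 amidation on E and mDAP sites?
#' @param wildcardRange numeric length-2 delta window in Da (default off =
#'   NULL). A wildcard pass may not be combined with amidation: the two are
#'   run as separate searches.
#' @param donorStems stems allowed on donor (non-terminal) units of
#'   multimers; only tripeptide (3-3 donors) and tetrapeptide (4-3 donors)
#'   stems make chemical sense.
#' @param maxUnits 1 (monomers), 2 (dimers) or 3 (trimers).
#' @param chargeRange integer charges considered when matching precursors.
#' @param reduced are reducing ends borohydride-reduced?
#' @return a list of class \code{SearchConfig}.
#' @export
searchConfig <- function(stems,
                         glycoforms = c("none", "MurNAc",
                                        "GlcN-deacetyl-MurNAc",
                                        "GlcN-anhydro-MurNAc",
                                        "GlcN-MurNAc", "GlcNAc-MurNAc"),
                         amidation = FALSE,
                         wildcardRange = NULL,
                         donorStems = c("AEm", "AEmA"),
                         maxUnits = 1L,
                         chargeRange = 1:4,
                         reduced = TRUE) {
  if (!is.null(wildcardRange)) {
    stopifnot(length(wildcardRange) == 2L, wildcardRange[1] < wildcardRange[2])
    if (amidation)
      stop("a wildcard pass may not be combined with amidation; ",
           "run two searches")
  }
  if (maxUnits > 1L) {
    badlen <- nchar(donorStems)
    if (!all(badlen %in% c(3L, 4L)))
      stop("donor stems must be tri- or tetrapeptides")
  }
  structure(list(stems = stems, glycoforms = glycoforms,
                 amidation = amidation, wildcardRange = wildcardRange,
                 donorStems = donorStems, maxUnits = as.integer(maxUnits),
                 chargeRange = as.integer(chargeRange), reduced = reduced),
            class = "SearchConfig")
}

## All amidation-state mod tables for a stem: the E and mDAP sites each
## independently on or off (at most the two such sites per stem).
.amidationStates <- function(stem, enabled) {
  if (!enabled) return(list(.emptyMods()))
  res <- strsplit(stem, "")[[1]]
  sites <- which(res %in% c("E", "m"))
  if (!length(sites)) return(list(.emptyMods()))
  states <- list(.emptyMods())
  for (s in sites) {
    withS <- lapply(states, function(md)
      rbind(md, stemModification("amidation", s)))
    states <- c(states, withS)
  }
  states
}

.makeDb <- function(speciesList) {
  if (!length(speciesList)) {
    return(new("CandidateDb", species = list(),
               table = data.frame(label = character(0), stems = character(0),
                                  glycans = character(0),
                                  topology = character(0),
                                  nUnits = integer(0), nMods = integer(0),
                                  neutralMass = numeric(0))))
  }
  tab <- data.frame(
    label = vapply(speciesList, speciesLabel, character(1)),
    stems = vapply(speciesList, function(s)
      paste(stems(s), collapse = ","), character(1)),
    glycans = vapply(speciesList, function(s)
      paste(glycoforms(s), collapse = ","), character(1)),
    topology = vapply(speciesList, function(s)
      paste(topology(s), collapse = ","), character(1)),
    nUnits = vapply(speciesList, function(s)
      length(s@units), integer(1)),
    nMods = vapply(speciesList, function(s)
      sum(vapply(s@units, function(u) nrow(u@mods), integer(1))), integer(1)),
    neutralMass = vapply(speciesList, neutralMass, numeric(1)))
  o <- order(tab$neutralMass, tab$label)
  new("CandidateDb", species = speciesList[o], table = tab[o, , drop = FALSE])
}

#' Number of candidates in a database
#' @param db a \linkS4class{CandidateDb}.
#' @export
dbSize <- function(db) nrow(db@table)

#' @rdname dbSize
#' @export
dbTable <- function(db) db@table

#' @rdname dbSize
#' @param i index
#' @export
dbSpecies <- function(db, i) db@species[[i]]

setMethod("show", "CandidateDb", function(object) {
  n <- nrow(object@table)
  cat(sprintf("CandidateDb: %d candidates, %d distinct masses (1 mDa bins)\n",
              n, length(unique(round(object@table$neutralMass, 3)))))
  if (n) cat(sprintf("  mass range %.3f - %.3f Da\n",
                     min(object@table$neutralMass),
                     max(object@table$neutralMass)))
})

#' Build the monomer candidate database
#'
#' One candidate per stem x glycoform x allowed modification state, as in a
#' monomer search over a small FASTA of stem sequences with variable
#' N-terminal glycan and amidation modifications.
#'
#' @param config a \code{\link{searchConfig}} with \code{maxUnits = 1}.
#' @return a \linkS4class{CandidateDb} of single-unit species.
#' @examples
#' db <- buildMonomerDb(searchConfig(c("AEm", "AEmA", "AEmG")))
#' dbSize(db)  # 18
#' @export
buildMonomerDb <- function(config) {
  stopifnot(inherits(config, "SearchConfig"))
  if (config$maxUnits != 1L)
    stop("buildMonomerDb requires maxUnits = 1")
  if (!length(config$stems)) {
    warning("empty stem list: returning an empty database")
    return(.makeDb(list()))
  }
  out <- list()
  for (st in config$stems)
    for (gf in config$glycoforms)
      for (md in .amidationStates(st, config$amidation))
        out[[length(out) + 1L]] <- asSpecies(
          muropeptide(st, glycoform(gf, reduced = config$reduced), md))
  .makeDb(out)
}

## Dedup key: unordered donor multiset + terminal acceptor (stems, glycans,
## mods), plus the link topology multiset.
.speciesKey <- function(sp) {
  k <- length(sp@units)
  ustr <- vapply(sp@units, function(u) {
    md <- if (nrow(u@mods)) paste(u@mods$kind, u@mods$position, round(u@mods$delta, 4),
                                  sep = ":", collapse = ";") else ""
    paste(u@stem, glycoformName(u), md, sep = "|")
  }, character(1))
  top <- topology(sp)
  paste(paste(sort(ustr[-k]), collapse = "+"), ustr[k],
        paste(sort(top), collapse = "+"), sep = " // ")
}

#' Build the dimer or trimer candidate database
#'
#' Donor (non-terminal) units are drawn from \code{config$donorStems}
#' (tripeptides form 3-3 links, tetrapeptides 4-3 links), the terminal
#' acceptor from \code{acceptorStems} (typically the stems discovered in the
#' monomer pass), and each unit independently takes any configured
#' glycoform. Adjacent units are joined by one cross-link losing 18.0106 Da.
#' Entries identical up to donor order are deduplicated.
#'
#' @param config a \code{\link{searchConfig}} with \code{maxUnits} 2 or 3.
#' @param acceptorStems character vector of terminal acceptor stems.
#' @return a \linkS4class{CandidateDb}; attribute \code{orderedCount} holds
#'   the pre-deduplication count of ordered donor combinations.
#' @export
buildMultimerDb <- function(config, acceptorStems) {
  stopifnot(inherits(config, "SearchConfig"))
  if (!config$maxUnits %in% c(2L, 3L))
    stop("buildMultimerDb requires maxUnits of 2 or 3")
  if (!length(acceptorStems))
    stop("acceptor stem list is empty")
  nDonor <- config$maxUnits - 1L
  gfs <- config$glycoforms
  donorChoice <- expand.grid(rep(list(seq_along(config$donorStems)), nDonor),
                             KEEP.OUT.ATTRS = FALSE)
  gfChoice <- expand.grid(rep(list(seq_along(gfs)), config$maxUnits),
                          KEEP.OUT.ATTRS = FALSE)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  ordered <- 0L
  for (acc in acceptorStems) {
    accStates <- .amidationStates(acc, config$amidation)
    for (di in seq_len(nrow(donorChoice))) {
      dstems <- config$donorStems[as.integer(donorChoice[di, ])]
      donorStates <- lapply(dstems, .amidationStates, config$amidation)
      stateGrid <- expand.grid(c(lapply(donorStates, seq_along),
                                 list(seq_along(accStates))),
                               KEEP.OUT.ATTRS = FALSE)
      for (gi in seq_len(nrow(gfChoice))) {
        gnames <- gfs[as.integer(gfChoice[gi, ])]
        for (si in seq_len(nrow(stateGrid))) {
          ordered <- ordered + 1L
          mods <- c(lapply(seq_len(nDonor), function(j)
                      donorStates[[j]][[stateGrid[si, j]]]),
                    list(accStates[[stateGrid[si, nDonor + 1L]]]))
          units <- lapply(seq_len(config$maxUnits), function(j) {
            st <- if (j <= nDonor) dstems[j] else acc
            muropeptide(st, glycoform(gnames[j], reduced = config$reduced),
                        mods[[j]])
          })
          ## canonical donor order: the retained representative of an
          ## unordered donor multiset is the same whatever the input order
          if (nDonor > 1L) {
            dkey <- vapply(units[seq_len(nDonor)], function(u)
              paste(u@stem, glycoformName(u),
                    paste(u@mods$kind, u@mods$position, collapse = ";"),
                    sep = "|"), character(1))
            units[seq_len(nDonor)] <- units[order(dkey)]
          }
          sp <- crosslinkedSpecies(units)
          key <- .speciesKey(sp)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            out[[length(out) + 1L]] <- sp
          }
        }
      }
    }
  }
  db <- .makeDb(out)
  attr(db, "orderedCount") <- ordered
  message(sprintf(
    "multimer db: %d ordered combinations, %d after deduplication, %d distinct masses (1 mDa bins)",
    ordered, dbSize(db), length(unique(round(db@table$neutralMass, 3)))))
  db
}

#' Look up database entries within a ppm window of a neutral mass
#'
#' @param db a \linkS4class{CandidateDb}.
#' @param neutral neutral mass in Da.
#' @param tolPpm tolerance in ppm.
#' @return integer indices into the database, sorted by |ppm error|.
#' @export
dbLookup <- function(db, neutral, tolPpm = 5) {
  m <- db@table$neutralMass
  if (!length(m)) return(integer(0))
  w <- neutral * tolPpm * 1e-6
  lo <- findInterval(neutral - w, m) + 1L
  hi <- findInterval(neutral + w, m)
  if (hi < lo) return(integer(0))
  idx <- lo:hi
  idx[order(abs(m[idx] - neutral))]
}

#' Open (wildcard) delta search against a monomer database
#'
#' For an observed neutral mass, report every base candidate whose mass
#' difference falls inside the wildcard window and outside the precursor
#' tolerance, with the implied single-residue interpretation where the delta
#' matches a residue substitution, a residue addition at the stem C-terminus,
#' or a water loss (anhydro).
#'
#' @param observedNeutral observed neutral mass in Da.
#' @param baseDb monomer \linkS4class{CandidateDb}.
#' @param tolPpm precursor tolerance used both to exclude trivial deltas and
#'   to match residue interpretations.
#' @param range wildcard window in Da.
#' @return data.frame with columns \code{base}, \code{baseMass},
#'   \code{delta}, \code{annotation} (semicolon-joined interpretations,
#'   possibly empty).
#' @export
resolveWildcard <- function(observedNeutral, baseDb, tolPpm = 5,
                            range = c(-130, 210)) {
  if (any(baseDb@table$nUnits != 1L))
    stop("wildcard resolution expects a monomer database")
  tab <- baseDb@table
  tolDa <- observedNeutral * tolPpm * 1e-6
  out <- list()
  for (i in seq_len(nrow(tab))) {
    delta <- observedNeutral - tab$neutralMass[i]
    if (delta < range[1] || delta > range[2] || abs(delta) <= tolDa) next
    stem <- strsplit(stems(baseDb@species[[i]])[1], "")[[1]]
    ann <- character(0)
    rm <- .RESIDUE_MASSES
    for (p in seq_along(stem)) {
      d2 <- delta + rm[[stem[p]]]
      hit <- names(rm)[abs(rm - d2) <= tolDa]
      hit <- setdiff(hit, stem[p])
      ## collapse I/L isobars
      if (all(c("I", "L") %in% hit)) hit <- c(setdiff(hit, c("I", "L")), "I/L")
      if (length(hit))
        ann <- c(ann, sprintf("position-%d %s->%s substitution",
                              p, stem[p], paste(hit, collapse = "|")))
    }
    add <- names(rm)[abs(rm - delta) <= tolDa]
    if (all(c("I", "L") %in% add)) add <- c(setdiff(add, c("I", "L")), "I/L")
    if (length(add))
      ann <- c(ann, sprintf("C-terminal +%s addition",
                            paste(add, collapse = "|")))
    if (abs(delta + .WATER) <= max(tolDa, 2e-3))
      ann <- c(ann, "water loss (anhydro residue)")
    out[[length(out) + 1L]] <- data.frame(
      base = tab$label[i], baseMass = tab$neutralMass[i], delta = delta,
      annotation = paste(ann, collapse = "; "))
  }
  if (!length(out))
    return(data.frame(base = character(0), baseMass = numeric(0),
                      delta = numeric(0), annotation = character(0)))
  do.call(rbind, out)
}

#' Read peptide stems from a FASTA file
#'
#' @param path FASTA of stem sequences.
#' @param convention \code{"mdap"}: the file uses the reserved lower-case
#'   \code{m} for mDAP directly; \code{"met41"}: the legacy convention in
#'   which (modified) methionine \code{M} stands for mDAP, converted on
#'   import.
#' @return character vector of stems.
#' @export
readStems <- function(path, convention = c("mdap", "met41")) {
  convention <- match.arg(convention)
  seqs <- as.character(Biostrings::readBStringSet(path))
  out <- unname(seqs)
  if (convention == "met41") out <- gsub("M", "m", out, fixed = TRUE)
  bad <- out[!vapply(out, function(s)
    all(strsplit(s, "")[[1]] %in% names(.RESIDUE_MASSES)), logical(1))]
  if (length(bad))
    stop("stem(s) with unknown residue codes: ", paste(bad, collapse = ", "))
  out
}

#' Export a candidate database to TSV
#'
#' Columns: units, stems, glycoforms, links, neutral_mass.
#'
#' @param db a \linkS4class{CandidateDb}.
#' @param path output file.
#' @export
exportCandidates <- function(db, path) {
  tab <- db@table
  out <- data.frame(units = tab$nUnits, stems = tab$stems,
                    glycoforms = tab$glycans, links = tab$topology,
                    neutral_mass = sprintf("%.5f", tab$neutralMass))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
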