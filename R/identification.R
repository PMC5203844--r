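## Spectrum-to-candidate matching: mzML ingestion, precursor lookup at ppm
## tolerance, fragment matching per activation mode, scoring and ranking,
## and isobaric grouping.

#' Construct a Spectrum
#'
#' @param scan integer scan number.
#' @param rt retention time (minutes).
#' @param msLevel 1 or 2.
#' @param mz,intensity centroided peaks (sorted by \code{mz}; re-sorted here).
#' @param precursorMz,precursorCharge,activation MS2 precursor annotation.
#' @return a \linkS4class{Spectrum}.
#' @export
spectrum <- function(scan, rt, msLevel, mz = numeric(0),
                     intensity = numeric(0), precursorMz = NA_real_,
                     precursorCharge = NA_integer_,
                     activation = NA_character_) {
  o <- order(mz)
  new("Spectrum", scan = as.integer(scan), rt = as.numeric(rt),
      msLevel = as.integer(msLevel), precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      activation = as.character(activation),
      mz = mz[o], intensity = intensity[o])
}

#' Construct an MsRun from a list of spectra
#'
#' @param spectra list of \linkS4class{Spectrum}, any order (RT-sorted here).
#' @param metadata free-form list.
#' @export
msRun <- function(spectra, metadata = list()) {
  rt <- vapply(spectra, function(s) s@rt, numeric(1))
  new("MsRun", spectra = spectra[order(rt)], metadata = metadata)
}

#' @rdname msRun
#' @param x an \linkS4class{MsRun}.
#' @param msLevel optional filter (1 or 2).
#' @export
runSpectra <- function(x, msLevel = NULL) {
  sp <- x@spectra
  if (!is.null(msLevel))
    sp <- sp[vapply(sp, function(s) s@msLevel == msLevel, logical(1))]
  sp
}

setMethod("show", "MsRun", function(object) {
  lev <- vapply(object@spectra, function(s) s@msLevel, integer(1))
  rt <- vapply(object@spectra, function(s) s@rt, numeric(1))
  cat(sprintf("MsRun: %d spectra (%d MS1, %d MS2), RT %.2f - %.2f min\n",
              length(lev), sum(lev == 1L), sum(lev == 2L),
              if (length(rt)) min(rt) else NA, if (length(rt)) max(rt) else NA))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum scan %d | MS%d | RT %.2f | %d peaks",
              object@scan, object@msLevel, object@rt, length(object@mz)))
  if (object@msLevel == 2L)
    cat(sprintf(" | %s precursor %.4f (%d+)", object@activation,
                object@precursorMz, object@precursorCharge))
  cat("\n")
})

## Activation cvParam accessions (PSI-MS controlled vocabulary).
.ACTIVATION_CV <- c(
  "MS:1000422" = "HCD",   # beam-type collision-induced dissociation
  "MS:1000598" = "ETD",
  "MS:1000133" = "HCD"    # plain CID: treat as collisional
)

## Per-spectrum activation from the mzML XML (mzR's header omits it).
.readActivations <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  sp <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  idx <- as.integer(xml2::xml_attr(sp, "index"))
  act <- vapply(sp, function(s) {
    a <- xml2::xml_find_first(s, ".//m:activation/m:cvParam", ns)
    if (inherits(a, "xml_missing")) return(NA_character_)
    acc <- xml2::xml_attr(a, "accession")
    if (acc %in% names(.ACTIVATION_CV)) .ACTIVATION_CV[[acc]]
    else NA_character_
  }, character(1))
  act[order(idx)]
}

#' Read a centroided mzML run
#'
#' Peaks and scan headers are read with mzR; the HCD/ETD activation of each
#' MS2 scan is taken from the activation cvParams in the file.
#'
#' @param path mzML file.
#' @return an \linkS4class{MsRun} (retention times in minutes).
#' @export
readMsRun <- function(path) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (!nrow(hd)) stop("no spectra in ", path)
  act <- .readActivations(path)
  sp <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    pk <- mzR::peaks(fh, i)
    sp[[i]] <- spectrum(
      scan = hd$acquisitionNum[i], rt = hd$retentionTime[i] / 60,
      msLevel = hd$msLevel[i],
      mz = pk[, 1], intensity = pk[, 2],
      precursorMz = if (hd$msLevel[i] == 2L) hd$precursorMZ[i] else NA_real_,
      precursorCharge = if (hd$msLevel[i] == 2L) hd$precursorCharge[i]
                        else NA_integer_,
      activation = if (hd$msLevel[i] == 2L) act[i] else NA_character_)
  }
  msRun(sp, metadata = list(source = path))
}

#' Match an observed precursor against the candidate database
#'
#' @param observedMz observed precursor m/z.
#' @param z precursor charge (>= 1).
#' @param db a \linkS4class{CandidateDb}.
#' @param tolPpm precursor tolerance in ppm (default 5).
#' @return data.frame of matching entries sorted by |ppm error|: columns
#'   \code{index} (into the db), \code{label}, \code{neutralMass},
#'   \code{theoreticalMz}, \code{ppmError} (signed, observed - theoretical).
#' @export
matchPrecursor <- function(observedMz, z, db, tolPpm = 5) {
  if (z < 1 || z != round(z)) stop("charge must be a positive integer")
  neutral <- neutralFromMz(observedMz, z)
  idx <- dbLookup(db, neutral, tolPpm * 1.5)  # widened, refined on m/z below
  if (!length(idx))
    return(data.frame(index = integer(0), label = character(0),
                      neutralMass = numeric(0), theoreticalMz = numeric(0),
                      ppmError = numeric(0)))
  theo <- mzFromNeutral(db@table$neutralMass[idx], z)
  ppm <- 1e6 * (observedMz - theo) / theo
  keep <- abs(ppm) <= tolPpm
  out <- data.frame(index = idx[keep], label = db@table$label[idx[keep]],
                    neutralMass = db@table$neutralMass[idx[keep]],
                    theoreticalMz = theo[keep], ppmError = ppm[keep])
  out[order(abs(out$ppmError)), , drop = FALSE]
}

#' Match predicted fragments to the peaks of a spectrum
#'
#' Greedy nearest-pair assignment: candidate (fragment, peak) pairs within
#' tolerance are accepted in order of increasing mass error, each observed
#' peak and each predicted fragment used at most once. HCD tolerance is in
#' ppm (Orbitrap readout); ETD in Da (ion-trap readout), which automatically
#' accepts the z/z+1 hydrogen-transfer ambiguity at 0.5 Da.
#'
#' @param spec a \linkS4class{Spectrum} (MS2).
#' @param fragments fragment table from \code{\link{predictFragments}}.
#' @param hcdTolPpm fragment tolerance for HCD spectra (default 20 ppm).
#' @param etdTolDa fragment tolerance for ETD spectra (default 0.5 Da).
#' @return the fragment table rows that matched, with \code{obsMz},
#'   \code{obsIntensity}, \code{peak} (index) and \code{error} columns.
#' @export
matchFragments <- function(spec, fragments, hcdTolPpm = 20, etdTolDa = 0.5) {
  stopifnot(is(spec, "Spectrum"))
  empty <- cbind(fragments[0, , drop = FALSE],
                 data.frame(obsMz = numeric(0), obsIntensity = numeric(0),
                            peak = integer(0), error = numeric(0)))
  if (!nrow(fragments) || !length(spec@mz)) return(empty)
  tolOf <- function(mz) {
    if (identical(spec@activation, "ETD")) rep(etdTolDa, length(mz))
    else mz * hcdTolPpm * 1e-6
  }
  tol <- tolOf(fragments$mz)
  pairs <- list()
  for (i in seq_len(nrow(fragments))) {
    lo <- findInterval(fragments$mz[i] - tol[i], spec@mz) + 1L
    hi <- findInterval(fragments$mz[i] + tol[i], spec@mz)
    if (hi >= lo)
      for (p in lo:hi)
        pairs[[length(pairs) + 1L]] <- c(i, p,
                                         abs(spec@mz[p] - fragments$mz[i]))
  }
  if (!length(pairs)) return(empty)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 3]), , drop = FALSE]
  usedFrag <- logical(nrow(fragments))
  usedPeak <- logical(length(spec@mz))
  keep <- logical(nrow(pm))
  for (r in seq_len(nrow(pm))) {
    f <- pm[r, 1]; p <- pm[r, 2]
    if (!usedFrag[f] && !usedPeak[p]) {
      usedFrag[f] <- TRUE; usedPeak[p] <- TRUE; keep[r] <- TRUE
    }
  }
  pm <- pm[keep, , drop = FALSE]
  out <- fragments[pm[, 1], , drop = FALSE]
  out$obsMz <- spec@mz[pm[, 2]]
  out$obsIntensity <- spec@intensity[pm[, 2]]
  out$peak <- as.integer(pm[, 2])
  out$error <- out$obsMz - out$mz
  out[order(out$mz), , drop = FALSE]
}

## Primary-series fragment keys (z/z+1 variants collapse to one key).
.primaryKeys <- function(fragments, activation) {
  primary <- if (identical(activation, "ETD")) c("c", "z", "z+1")
             else c("b", "y")
  fr <- fragments[fragments$series %in% primary, , drop = FALSE]
  if (!nrow(fr)) return(character(0))
  ser <- sub("^z\\+1$", "z", fr$series)
  unique(paste(ser, fr$site, fr$charge))
}

#' Score candidates against an MS2 spectrum and rank them
#'
#' Score = (fraction of predicted primary-series fragments matched) +
#' (fraction of total observed intensity explained by any predicted
#' fragment), in [0, 2]. All candidates with score >= 0 are retained (the
#' manual score cut of zero); ranking is by descending score with ties
#' broken by fewer modifications, then fewer units, then label.
#'
#' @param spec an MS2 \linkS4class{Spectrum}.
#' @param candidates data.frame from \code{\link{matchPrecursor}}.
#' @param db the \linkS4class{CandidateDb} the candidates index into.
#' @param hcdTolPpm,etdTolDa fragment tolerances.
#' @param cache optional environment memoising fragment predictions across
#'   spectra of one run.
#' @return candidates with \code{score}, \code{nMatched}, \code{rank}
#'   columns, best first.
#' @export
scoreAndRank <- function(spec, candidates, db, hcdTolPpm = 20,
                         etdTolDa = 0.5, cache = NULL) {
  if (!nrow(candidates)) {
    candidates$score <- numeric(0)
    candidates$nMatched <- integer(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  zmax <- max(1L, min(spec@precursorCharge, 2L))
  totInt <- sum(spec@intensity)
  score <- nm <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    sp <- db@species[[candidates$index[i]]]
    key <- paste0(candidates$index[i], ":", spec@activation, ":", zmax)
    fr <- if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE))
      get(key, envir = cache)
    else {
      f <- predictFragments(sp, spec@activation, charges = seq_len(zmax))
      if (!is.null(cache)) assign(key, f, envir = cache)
      f
    }
    mt <- matchFragments(spec, fr, hcdTolPpm, etdTolDa)
    pk <- .primaryKeys(fr, spec@activation)
    mk <- .primaryKeys(mt, spec@activation)
    fracFrag <- if (length(pk)) length(intersect(mk, pk)) / length(pk) else 0
    fracInt <- if (totInt > 0) sum(spec@intensity[unique(mt$peak)]) / totInt
               else 0
    score[i] <- fracFrag + fracInt
    nm[i] <- nrow(mt)
  }
  candidates$score <- score
  candidates$nMatched <- as.integer(nm)
  nMods <- db@table$nMods[candidates$index]
  nUnits <- db@table$nUnits[candidates$index]
  o <- order(-candidates$score, nMods, nUnits, candidates$label)
  candidates <- candidates[o, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  candidates
}

#' Partition a candidate database into isobaric groups
#'
#' Single-linkage grouping of entries whose neighbouring masses are within
#' \code{tolPpm}; entries in the same group cannot be told apart by
#' precursor mass. Groups of size > 1 are annotated in bracket notation.
#'
#' @param db a \linkS4class{CandidateDb}.
#' @param tolPpm grouping tolerance (default 5 ppm).
#' @return data.frame with one row per entry: \code{index}, \code{label},
#'   \code{neutralMass}, \code{group}, \code{groupSize}, \code{annotation}.
#' @export
isobaricGroups <- function(db, tolPpm = 5) {
  tab <- db@table
  n <- nrow(tab)
  if (!n)
    return(data.frame(index = integer(0), label = character(0),
                      neutralMass = numeric(0), group = integer(0),
                      groupSize = integer(0), annotation = character(0)))
  m <- tab$neutralMass
  grp <- integer(n); grp[1] <- 1L
  for (i in seq_len(n - 1L))
    grp[i + 1L] <- if (ppmDiff(m[i], m[i + 1L]) <= tolPpm) grp[i]
                   else grp[i] + 1L
  size <- as.integer(table(grp)[as.character(grp)])
  ann <- rep("", n)
  for (g in unique(grp[size > 1L])) {
    members <- tab$label[grp == g]
    ann[grp == g] <- paste0("[", paste(members, collapse = " | "), "]")
  }
  data.frame(index = seq_len(n), label = tab$label, neutralMass = m,
             group = grp, groupSize = size, annotation = ann)
}

#' Search every MS2 spectrum of a run against a candidate database
#'
#' For each MS2 spectrum: precursor lookup at \code{tolPpm}, fragment
#' matching and scoring of all precursor candidates, and -- when the best
#' candidates form an isobaric group containing both cross-link topologies
#' -- an automated 3-3/4-3 topology call from the diagnostic fragments.
#'
#' @param run an \linkS4class{MsRun}.
#' @param db a \linkS4class{CandidateDb}.
#' @param tolPpm precursor tolerance (5 ppm).
#' @param hcdTolPpm,etdTolDa fragment tolerances (20 ppm / 0.5 Da).
#' @return data.frame of identifications (best candidate per spectrum first
#'   by rank): \code{scan}, \code{rt}, \code{activation}, \code{z},
#'   \code{precursorMz}, \code{index}, \code{label}, \code{stems},
#'   \code{glycans}, \code{topology}, \code{ppmError}, \code{score},
#'   \code{rank}, \code{group}, \code{topologyCall}.
#' @export
searchRun <- function(run, db, tolPpm = 5, hcdTolPpm = 20, etdTolDa = 0.5) {
  ms2 <- runSpectra(run, msLevel = 2L)
  if (!length(ms2)) stop("run contains no MS2 spectra to search")
  groups <- isobaricGroups(db, tolPpm)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  rows <- list()
  for (spec in ms2) {
    cand <- matchPrecursor(spec@precursorMz, spec@precursorCharge, db, tolPpm)
    if (!nrow(cand)) next
    cand <- scoreAndRank(spec, cand, db, hcdTolPpm, etdTolDa, cache = cache)
    g <- groups$group[cand$index]
    call <- "n/a"
    top <- db@table$topology[cand$index]
    ## exactly-isobaric cross-linked interpretations with differing topology
    multi <- which(db@table$nUnits[cand$index] > 1L)
    if (length(multi) > 1L) {
      iso <- multi[abs(cand$neutralMass[multi] -
                       cand$neutralMass[multi[1]]) <= 1e-6]
      isoClass <- ifelse(grepl("4-3", top[iso], fixed = TRUE), "4-3", "3-3")
      if (length(unique(isoClass)) > 1L) {
        tc <- tryCatch(
          classifyCrosslink(spec, db@species[cand$index[iso]],
                            hcdTolPpm = hcdTolPpm, etdTolDa = etdTolDa),
          error = function(e) NULL)
        if (!is.null(tc)) call <- tc$call
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scan = spec@scan, rt = spec@rt, activation = spec@activation,
      z = spec@precursorCharge, precursorMz = spec@precursorMz,
      index = cand$index, label = cand$label,
      stems = db@table$stems[cand$index],
      glycans = db@table$glycans[cand$index],
      topology = top, ppmError = cand$ppmError, score = cand$score,
      rank = cand$rank, group = g,
      topologyCall = ifelse(cand$rank == 1L, call, "n/a"))
  }
  if (!length(rows))
    return(data.frame(scan = integer(0), rt = numeric(0),
                      activation = character(0), z = integer(0),
                      precursorMz = numeric(0), index = integer(0),
                      label = character(0), stems = character(0),
                      glycans = character(0), topology = character(0),
                      ppmError = numeric(0), score = numeric(0),
                      rank = integer(0), group = integer(0),
                      topologyCall = character(0)))
  do.call(rbind, rows)
}

#' Write an identifications table to TSV
#' @param ids data.frame from \code{\link{searchRun}}.
#' @param path output file.
#' @export
exportIdentifications <- function(ids, path) {
  utils::write.table(ids, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
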