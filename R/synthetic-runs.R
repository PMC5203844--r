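## Ground-truth LC-MS/MS run simulation: Gaussian elution over a ~50-min
## gradient, 3-point isotope envelopes per charge state, data-dependent
## MS2 alternating HCD/ETD on the top-N multiply charged precursors with
## dynamic exclusion, optional in-source-decay satellites sharing the
## parent's exact elution profile, and standard mzML output.

#' Assemble a simulation ground truth
#'
#' Abundance is the total monoisotopic MS1 ion count of a species, summed
#' over charge states -- exactly the quantity XIC quantification reports --
#' so recovery can be checked against the injected values. A species with
#' \code{isdParent} set is an in-source-decay satellite: it inherits the
#' parent's elution center and width exactly (decay happens after the
#' column).
#'
#' @param species list of \linkS4class{CrosslinkedSpecies} (or
#'   \linkS4class{Muropeptide}s, wrapped automatically).
#' @param abundance numeric vector of total monoisotopic ion counts.
#' @param rtCenter,rtWidth Gaussian elution center and sigma (minutes).
#' @param charges optional list of named numeric vectors (charge ->
#'   fraction, normalised here); defaults by class: monomers 1+/2+, dimers
#'   2+/3+, trimers 2+/3+/4+.
#' @param isdParent integer index of the decay parent or NA.
#' @return a \linkS4class{GroundTruth}.
#' @export
groundTruth <- function(species, abundance, rtCenter, rtWidth = 0.15,
                        charges = NULL, isdParent = NA_integer_) {
  species <- lapply(species, function(s)
    if (is(s, "Muropeptide")) asSpecies(s) else s)
  n <- length(species)
  rtWidth <- rep_len(rtWidth, n)
  isdParent <- rep_len(as.integer(isdParent), n)
  if (is.null(charges)) {
    charges <- lapply(species, function(s)
      switch(min(length(s@units), 3L),
             c(`1` = 0.3, `2` = 0.7),
             c(`2` = 0.6, `3` = 0.4),
             c(`2` = 0.3, `3` = 0.5, `4` = 0.2)))
  }
  charges <- lapply(charges, function(p) p / sum(p))
  for (i in seq_len(n))
    if (!is.na(isdParent[i])) {
      rtCenter[i] <- rtCenter[isdParent[i]]
      rtWidth[i] <- rtWidth[isdParent[i]]
    }
  new("GroundTruth", species = species,
      info = data.frame(abundance = abundance, rtCenter = rtCenter,
                        rtWidth = rtWidth, isdParent = isdParent),
      charges = charges)
}

#' @rdname groundTruth
#' @param x a \linkS4class{GroundTruth}.
#' @export
truthTable <- function(x) {
  cbind(data.frame(label = vapply(x@species, speciesLabel, character(1)),
                   neutralMass = vapply(x@species, neutralMass, numeric(1))),
        x@info)
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d species, RT %.1f - %.1f min\n",
              length(object@species), min(object@info$rtCenter),
              max(object@info$rtCenter)))
})

## Approximate 3-point isotope envelope: relative intensities of the M+1 and
## M+2 isotopologues grow with mass (Poisson in the number of heavy
## isotopes, lambda ~ 5.5e-4 per Da -- adequate below 3 kDa).
.isotopeRatios <- function(M) {
  lam <- 5.5e-4 * M
  c(1, lam, lam^2 / 2)
}

#' Simulate an LC-MS/MS run from a ground truth
#'
#' MS1 scans on a fixed cycle carry Gaussian elution profiles with 3-point
#' isotope envelopes per charge state; after each MS1 scan the top-N most
#' intense multiply charged (2+ and higher) precursors not under dynamic
#' exclusion trigger MS2 scans with alternating HCD/ETD activation, peaks
#' drawn from the theoretical fragment predictions. Noise-free simulation
#' is exactly reproducible and its XIC integrals equal the injected
#' abundances; the noise model adds per-point intensity dispersion, fragment
#' dropout and spurious fragment peaks.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param rtStart,rtEnd simulated acquisition window (minutes); default
#'   covers every species at +/- 5 sigma.
#' @param cycleTime MS1 cycle in minutes (default 0.02).
#' @param topN data-dependent precursors per cycle (default 5).
#' @param dynamicExclusion exclusion after selection, minutes (default 0.5).
#' @param noise list: \code{dropout} (probability a predicted fragment peak
#'   is missing), \code{spurious} (spurious peaks as a fraction of predicted
#'   peaks), \code{intensityCv} (lognormal CV on MS1 points),
#'   \code{mzJitterPpm} (Gaussian m/z jitter on fragment peaks).
#' @param seed RNG seed; runs are bit-reproducible for a fixed seed.
#' @return an \linkS4class{MsRun}; the ground truth and per-species injected
#'   totals are kept in \code{metadata}.
#' @export
simulateRun <- function(truth, rtStart = NULL, rtEnd = NULL,
                        cycleTime = 0.02, topN = 5, dynamicExclusion = 0.5,
                        noise = list(), seed = 1) {
  stopifnot(is(truth, "GroundTruth"))
  validObject(truth)
  noise <- utils::modifyList(
    list(dropout = 0, spurious = 0, intensityCv = 0, mzJitterPpm = 0), noise)
  set.seed(as.integer(seed))
  info <- truth@info
  if (is.null(rtStart)) rtStart <- min(info$rtCenter - 5 * info$rtWidth)
  if (is.null(rtEnd)) rtEnd <- max(info$rtCenter + 5 * info$rtWidth)
  times <- seq(rtStart, rtEnd, by = cycleTime)
  nScan <- length(times)
  nSp <- length(truth@species)
  masses <- vapply(truth@species, neutralMass, numeric(1))
  labels <- vapply(truth@species, speciesLabel, character(1))

  ## per-species elution weights, normalised so the summed monoisotopic ion
  ## count over all MS1 scans equals the injected abundance exactly
  weights <- matrix(0, nSp, nScan)
  for (i in seq_len(nSp)) {
    w <- stats::dnorm(times, info$rtCenter[i], info$rtWidth[i])
    w[w < max(w) * 1e-12] <- 0
    weights[i, ] <- info$abundance[i] * w / sum(w)
  }
  if (noise$intensityCv > 0) {
    jit <- matrix(exp(stats::rnorm(nSp * nScan, 0, noise$intensityCv)),
                  nSp, nScan)
    weights <- weights * jit
  }

  chargeTabs <- lapply(seq_len(nSp), function(i) {
    z <- as.integer(names(truth@charges[[i]]))
    data.frame(z = z, frac = as.numeric(truth@charges[[i]]),
               mz = mzFromNeutral(masses[i], z))
  })
  iso <- lapply(masses, .isotopeRatios)
  neutron <- 1.003355  # C13 - C12 spacing of the isotope envelope

  spectra <- list()
  scanNo <- 0L
  ms2Count <- 0L
  exclusion <- new.env(hash = TRUE, parent = emptyenv())
  fragCache <- new.env(hash = TRUE, parent = emptyenv())

  for (j in seq_len(nScan)) {
    t <- times[j]
    mzs <- numeric(0); ints <- numeric(0)
    precs <- list()
    for (i in seq_len(nSp)) {
      base <- weights[i, j]
      if (base <= 0) next
      ct <- chargeTabs[[i]]
      for (r in seq_len(nrow(ct))) {
        mono <- base * ct$frac[r]
        if (mono <= 0) next
        mzs <- c(mzs, ct$mz[r] + (0:2) * neutron / ct$z[r])
        ints <- c(ints, mono * iso[[i]])
        if (ct$z[r] >= 2L)
          precs[[length(precs) + 1L]] <- list(i = i, z = ct$z[r],
                                              mz = ct$mz[r], int = mono)
      }
    }
    scanNo <- scanNo + 1L
    spectra[[length(spectra) + 1L]] <-
      spectrum(scanNo, t, 1L, mzs, ints)

    if (!length(precs)) next
    pint <- vapply(precs, function(p) p$int, numeric(1))
    keyOf <- vapply(precs, function(p) paste0(p$i, ":", p$z), character(1))
    open <- vapply(keyOf, function(k) {
      until <- if (exists(k, envir = exclusion, inherits = FALSE))
        get(k, envir = exclusion) else -Inf
      t >= until
    }, logical(1))
    ord <- order(-pint)
    sel <- utils::head(ord[open[ord]], topN)
    for (k in seq_along(sel)) {
      s <- sel[k]
      p <- precs[[s]]
      assign(keyOf[s], t + dynamicExclusion, envir = exclusion)
      ms2Count <- ms2Count + 1L
      act <- if (ms2Count %% 2L == 1L) "HCD" else "ETD"
      ck <- paste0(p$i, ":", act, ":", min(p$z, 2L))
      fr <- if (exists(ck, envir = fragCache, inherits = FALSE))
        get(ck, envir = fragCache)
      else {
        f <- predictFragments(truth@species[[p$i]], act,
                              charges = seq_len(max(1L, min(p$z, 2L))))
        assign(ck, f, envir = fragCache)
        f
      }
      fmz <- fr$mz
      fint <- p$int * stats::runif(length(fmz), 0.2, 1)
      if (noise$dropout > 0) {
        keep <- stats::runif(length(fmz)) >= noise$dropout
        if (!any(keep)) keep[which.max(fint)] <- TRUE
        fmz <- fmz[keep]; fint <- fint[keep]
      }
      if (noise$mzJitterPpm > 0)
        fmz <- fmz * (1 + stats::rnorm(length(fmz), 0, noise$mzJitterPpm * 1e-6))
      if (noise$spurious > 0) {
        nspur <- round(noise$spurious * length(fmz))
        if (nspur > 0) {
          smz <- stats::runif(nspur, 150, max(fmz) * 1.05)
          sint <- stats::runif(nspur, 0.05, 0.6) * max(fint)
          fmz <- c(fmz, smz); fint <- c(fint, sint)
        }
      }
      scanNo <- scanNo + 1L
      spectra[[length(spectra) + 1L]] <- spectrum(
        scanNo, t + cycleTime * k / (topN + 1), 2L, fmz, fint,
        precursorMz = p$mz, precursorCharge = p$z, activation = act)
    }
  }
  msRun(spectra, metadata = list(
    truth = truth, labels = labels,
    injected = stats::setNames(info$abundance, labels), seed = seed))
}

## header columns required by mzR's mzML writer
.mzrHeader <- function(run) {
  sp <- run@spectra
  n <- length(sp)
  g <- function(f, def) vapply(sp, f, def)
  ms2 <- g(function(s) s@msLevel, integer(1)) == 2L
  data.frame(
    seqNum = seq_len(n), acquisitionNum = g(function(s) s@scan, integer(1)),
    msLevel = g(function(s) s@msLevel, integer(1)), polarity = 1L,
    peaksCount = g(function(s) length(s@mz), integer(1)),
    totIonCurrent = g(function(s) sum(s@intensity), numeric(1)),
    retentionTime = g(function(s) s@rt, numeric(1)) * 60,
    basePeakMZ = g(function(s)
      if (length(s@mz)) s@mz[which.max(s@intensity)] else 0, numeric(1)),
    basePeakIntensity = g(function(s)
      if (length(s@intensity)) max(s@intensity) else 0, numeric(1)),
    collisionEnergy = ifelse(ms2, ifelse(
      g(function(s) identical(s@activation, "ETD"), logical(1)), 35, 25), 0),
    ionisationEnergy = 0, lowMZ = g(function(s)
      if (length(s@mz)) min(s@mz) else 0, numeric(1)),
    highMZ = g(function(s) if (length(s@mz)) max(s@mz) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(ms2, g(function(s) s@precursorMz, numeric(1)), 0),
    precursorCharge = ifelse(ms2,
                             g(function(s) s@precursorCharge, integer(1)), 0L),
    precursorIntensity = ifelse(ms2, 1, 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", g(function(s) s@scan, integer(1))),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(ms2, g(function(s) s@precursorMz,
                                            numeric(1)), NA_real_),
    isolationWindowLowerOffset = ifelse(ms2, 1.5, NA_real_),
    isolationWindowUpperOffset = ifelse(ms2, 1.5, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
}

#' Write a run to mzML 1.1
#'
#' Peaks and headers are written with mzR; the HCD/ETD activation of each
#' MS2 scan is then stamped into the activation cvParams (mzR's writer
#' emits plain CID).
#'
#' @param run an \linkS4class{MsRun}.
#' @param path output mzML file.
#' @return the path, invisibly.
#' @export
writeRunMzML <- function(run, path) {
  hdr <- .mzrHeader(run)
  pks <- lapply(run@spectra, function(s)
    cbind(mz = s@mz, intensity = s@intensity))
  mzR::writeMSData(pks, file = path, header = hdr)
  ## stamp activation types
  acts <- vapply(run@spectra, function(s) s@activation, character(1))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  spNodes <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  idx <- as.integer(xml2::xml_attr(spNodes, "index"))
  for (k in seq_along(spNodes)) {
    a <- acts[idx[k] + 1L]
    if (is.na(a)) next
    cv <- xml2::xml_find_first(spNodes[[k]], ".//m:activation/m:cvParam", ns)
    if (inherits(cv, "xml_missing")) next
    if (a == "ETD") {
      xml2::xml_set_attr(cv, "accession", "MS:1000598")
      xml2::xml_set_attr(cv, "name", "electron transfer dissociation")
    } else {
      xml2::xml_set_attr(cv, "accession", "MS:1000422")
      xml2::xml_set_attr(cv, "name",
                         "beam-type collision-induced dissociation")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a ground-truth sidecar TSV
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output file.
#' @export
exportTruth <- function(truth, path) {
  utils::write.table(truthTable(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Table-style trimer builder: stems and glycoform names, donors first.
.trimer <- function(stems, glycans, reduced = TRUE) {
  crosslinkedSpecies(mapply(function(s, g)
    muropeptide(s, glycoform(g, reduced = reduced)), stems, glycans,
    SIMPLIFY = FALSE))
}

#' Canonical small fixtures for end-to-end testing
#'
#' A fixed set of species and scenarios exercising every stage: the
#' isobaric dimer pair (two tetrapeptide units 4-3 linked versus a
#' tripeptide 3-3 linked to a pentapeptide), the tripeptide-tetrapeptide
#' 3-3 dimer with its 4-3 counterpart, a verified set of trimer
#' compositions, a wildcard sequence variant (AEmF), a monomer search
#' scenario over AEm/AEmA/AEmG, and a mixed ground truth with
#' monomer/dimer/trimer ion counts split 29.2/57.4/13.4 plus an
#' in-source-decay satellite.
#'
#' @param seed seed recorded into the ground truths.
#' @return named list of fixtures.
#' @export
makeFixtureSuite <- function(seed = 1) {
  gm <- "GlcN-MurNAc"
  fig4Pair <- list(
    d43 = crosslinkedSpecies(list(muropeptide("AEmA", gm),
                                  muropeptide("AEmA", gm)), donorPos = 4L),
    d33 = crosslinkedSpecies(list(muropeptide("AEm", gm),
                                  muropeptide("AEmAA", gm)), donorPos = 3L))
  fig5Pair <- list(
    d33 = crosslinkedSpecies(list(muropeptide("AEm", gm),
                                  muropeptide("AEmA", gm)), donorPos = 3L),
    d43 = crosslinkedSpecies(list(muropeptide("AEmA", gm),
                                  muropeptide("AEm", gm)), donorPos = 4L))
  table3Trimers <- list(
    .trimer(c("AEm", "AEm", "AEmA"), c(gm, gm, gm)),          # 2520.096
    .trimer(c("AEm", "AEmA", "AEmA"), c(gm, gm, gm)),         # 2591.133
    .trimer(c("AEm", "AEm", "AEm"), c(gm, gm, gm)),           # 2449.059
    .trimer(c("AEmA", "AEmA", "AEmA"), c(gm, gm, gm)),        # 2662.170
    .trimer(c("AEm", "AEm", "AEmG"), c(gm, gm, gm)),          # 2506.080
    .trimer(c("AEm", "AEm", "AEmA"), c(gm, "MurNAc", gm)),    # 2359.027
    .trimer(c("AEm", "AEm", "AEmA"), c(gm, gm, "none")),      # 2081.911
    .trimer(c("AEm", "AEm", "AEmA"), c(gm, "none", "none")),  # 1643.726
    .trimer(c("AEm", "AEmA", "AEmG"), c(gm, gm, gm)))         # 2577.117
  ## clean class mixture at the headline monomer/dimer/trimer ion-count split
  mix <- groundTruth(
    species = list(
      asSpecies(muropeptide("AEmA", gm)),                     # monomer
      fig5Pair$d33,                                           # dimer
      table3Trimers[[1]]),                                    # trimer
    abundance = c(29.2e6, 57.4e6, 13.4e6),
    rtCenter = c(22, 28.6, 34.7),
    rtWidth = 0.15)
  ## in-source-decay scenario: a satellite co-eluting exactly with its
  ## parent, and a control pair shifted by 2 min (a genuine species)
  isd <- groundTruth(
    species = list(
      asSpecies(muropeptide("AEmA", gm)),            # parent
      asSpecies(muropeptide("AEmA", "MurNAc")),      # true ISD satellite
      asSpecies(muropeptide("AEmG", gm)),            # second parent-like
      asSpecies(muropeptide("AEmG", "MurNAc"))),     # shifted: genuine
    abundance = c(40e6, 8e6, 30e6, 6e6),
    rtCenter = c(22, 22, 25, 27),
    rtWidth = 0.15,
    isdParent = c(NA, 1L, NA, NA))
  list(
    fig4Pair = fig4Pair,
    fig5Pair = fig5Pair,
    table3Trimers = table3Trimers,
    wildcardVariant = muropeptide("AEmF", gm),
    monomerConfig = searchConfig(c("AEm", "AEmA", "AEmG")),
    mixTruth = mix,
    isdTruth = isd,
    seed = seed)
}
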