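## Extracted-ion-chromatogram quantification: per-species XIC integrals with
## charge-state summation, class percentages, and in-source-decay flagging
## by exact co-elution.

#' Extracted ion chromatogram
#'
#' @slot targetMz target m/z.
#' @slot tolPpm extraction tolerance.
#' @slot rt,intensity trace points (per MS1 scan, RT in minutes).
#' @exportClass XicTrace
setClass("XicTrace",
  representation(targetMz = "numeric", tolPpm = "numeric",
                 rt = "numeric", intensity = "numeric"))

setValidity("XicTrace", function(object) {
  if (length(object@rt) != length(object@intensity))
    return("rt and intensity lengths differ")
  if (is.unsorted(object@rt)) return("trace must be RT-sorted")
  TRUE
})

#' @rdname extractXic
#' @param x an \linkS4class{XicTrace}.
#' @export
xicIntegral <- function(x) sum(x@intensity)

#' @rdname extractXic
#' @export
xicApex <- function(x) {
  if (!length(x@rt) || all(x@intensity == 0)) return(NA_real_)
  x@rt[which.max(x@intensity)]
}

setMethod("show", "XicTrace", function(object) {
  cat(sprintf(
    "XicTrace m/z %.4f (+/- %g ppm): %d scans, apex %.2f min, integral %.3g\n",
    object@targetMz, object@tolPpm, length(object@rt), xicApex(object),
    xicIntegral(object)))
})

#' Extract an ion chromatogram from the MS1 scans of a run
#'
#' Per MS1 scan, intensities of all peaks within +/- \code{tolPpm} of
#' \code{targetMz} are summed. The XIC integral is the plain sum of the
#' per-scan ion counts (not a trapezoid over RT), matching the
#' summed-ion-count definition of the quantities reported here; it is
#' therefore proportional to the MS1 scan rate, which is constant within a
#' run.
#'
#' @param run an \linkS4class{MsRun} containing MS1 scans.
#' @param targetMz target m/z.
#' @param tolPpm extraction tolerance in ppm (default 10).
#' @param rtWindow optional numeric length-2 RT window (minutes).
#' @return an \linkS4class{XicTrace}.
#' @export
extractXic <- function(run, targetMz, tolPpm = 10, rtWindow = NULL) {
  ms1 <- runSpectra(run, msLevel = 1L)
  if (!length(ms1)) stop("run contains no MS1 scans")
  rt <- vapply(ms1, function(s) s@rt, numeric(1))
  if (!is.null(rtWindow)) {
    keep <- rt >= rtWindow[1] & rt <= rtWindow[2]
    ms1 <- ms1[keep]; rt <- rt[keep]
  }
  w <- targetMz * tolPpm * 1e-6
  ii <- vapply(ms1, function(s) {
    lo <- findInterval(targetMz - w, s@mz) + 1L
    hi <- findInterval(targetMz + w, s@mz)
    if (hi >= lo) sum(s@intensity[lo:hi]) else 0
  }, numeric(1))
  new("XicTrace", targetMz = targetMz, tolPpm = tolPpm, rt = rt,
      intensity = ii)
}

.className <- function(nUnits)
  c("monomer", "dimer", "trimer")[pmin(nUnits, 3L)]

#' Quantify identified species by XIC
#'
#' One row per distinct identified species (rank-1 identifications). The
#' integral is the monoisotopic XIC ion count summed over the charge states
#' the species was identified at; percentages are per class (monomer, dimer,
#' trimer) over the identified total.
#'
#' @param ids identification table from \code{\link{searchRun}}.
#' @param run the \linkS4class{MsRun}.
#' @param db the \linkS4class{CandidateDb} used for the search.
#' @param tolPpm XIC extraction tolerance (default 10 ppm).
#' @param rtHalfWindow half-width (minutes) of the RT window around the
#'   identifying scans used for extraction (default 2.5).
#' @param chargeRange charge states probed for XIC signal (default 1:4;
#'   identification only selects multiply charged precursors, but e.g.
#'   singly charged monomers still carry MS1 ion count that belongs in the
#'   charge-state sum).
#' @return data.frame: \code{label}, \code{index}, \code{stems},
#'   \code{glycans}, \code{class}, \code{charges}, \code{neutralMass},
#'   \code{apexRt}, \code{integral}, \code{percentOfClass},
#'   \code{isdParent} (NA until \code{\link{flagInSourceDecay}}). The
#'   per-species traces are attached as attribute \code{traces}.
#' @export
quantifySpecies <- function(ids, run, db, tolPpm = 10, rtHalfWindow = 2.5,
                            chargeRange = 1:4) {
  if (!nrow(ids)) stop("no identifications to quantify")
  top1 <- ids[ids$rank == 1L, , drop = FALSE]
  out <- list(); traces <- list()
  for (d in split(top1, top1$index)) {
    idx <- d$index[1]
    sp <- db@species[[idx]]
    M <- db@table$neutralMass[idx]
    win <- c(min(d$rt) - rtHalfWindow, max(d$rt) + rtHalfWindow)
    probe <- sort(unique(c(d$z, chargeRange)))
    perZ <- lapply(probe, function(z)
      extractXic(run, mzFromNeutral(M, z), tolPpm, win))
    hasSignal <- vapply(perZ, function(x) xicIntegral(x) > 0, logical(1))
    zz <- probe[hasSignal | probe %in% d$z]
    perZ <- perZ[hasSignal | probe %in% d$z]
    rt <- perZ[[1]]@rt
    summed <- Reduce(`+`, lapply(perZ, function(x) x@intensity))
    tr <- new("XicTrace", targetMz = mzFromNeutral(M, min(zz)),
              tolPpm = tolPpm, rt = rt, intensity = summed)
    traces[[db@table$label[idx]]] <- tr
    out[[length(out) + 1L]] <- data.frame(
      label = db@table$label[idx], index = idx,
      stems = db@table$stems[idx], glycans = db@table$glycans[idx],
      class = .className(db@table$nUnits[idx]),
      charges = paste(zz, collapse = ","), neutralMass = M,
      apexRt = xicApex(tr), integral = xicIntegral(tr))
  }
  q <- do.call(rbind, out)
  q$percentOfClass <- NA_real_
  for (cl in unique(q$class)) {
    sel <- q$class == cl
    tot <- sum(q$integral[sel])
    q$percentOfClass[sel] <- if (tot > 0) 100 * q$integral[sel] / tot else NA
  }
  q$isdParent <- NA_character_
  rownames(q) <- NULL
  attr(q, "traces") <- traces
  q
}

#' Class-level composition summary
#'
#' @param quant table from \code{\link{quantifySpecies}}.
#' @return data.frame with \code{class}, \code{integral},
#'   \code{percentOfTotal} over the identified XIC total.
#' @export
classSummary <- function(quant) {
  agg <- stats::aggregate(integral ~ class, quant, sum)
  agg$percentOfTotal <- 100 * agg$integral / sum(agg$integral)
  agg[order(match(agg$class, c("monomer", "dimer", "trimer"))), ]
}

## sugar multiset of a species, e.g. c(GlcN=2, MurNAc=3)
.sugarCounts <- function(sp) {
  s <- unlist(lapply(sp@units, function(u) u@glycoform@sugars))
  table(factor(s, levels = names(.SUGAR_FORMULAS)))
}

## is `child` the same peptide content as `parent` but missing >= 1 sugars?
.isGlycanSubset <- function(child, parent) {
  if (paste(sort(stems(child)), collapse = ",") !=
      paste(sort(stems(parent)), collapse = ",")) return(FALSE)
  if (paste(sort(topology(child)), collapse = ",") !=
      paste(sort(topology(parent)), collapse = ",")) return(FALSE)
  cc <- .sugarCounts(child); pc <- .sugarCounts(parent)
  all(cc <= pc) && sum(cc) < sum(pc)
}

#' Flag in-source-decay satellites by exact co-elution
#'
#' A species that lacks one or more monosaccharides relative to a fuller
#' glycoform of the same peptide content is flagged as produced by in-source
#' decay of that parent iff the two XICs co-elute exactly: apex difference
#' at most \code{apexTol} minutes and Pearson correlation of the overlapping
#' trace points at least \code{minCor}. A satellite shifted in RT is a
#' genuine species and is never flagged.
#'
#' @param quant table from \code{\link{quantifySpecies}} (with its
#'   \code{traces} attribute).
#' @param db the \linkS4class{CandidateDb}.
#' @param apexTol apex RT tolerance in minutes (default 0.1).
#' @param minCor minimum Pearson correlation (default 0.95).
#' @return \code{quant} with \code{isdParent} filled in with the parent
#'   label for flagged rows.
#' @export
flagInSourceDecay <- function(quant, db, apexTol = 0.1, minCor = 0.95) {
  traces <- attr(quant, "traces")
  if (is.null(traces)) stop("quant table lacks its traces attribute")
  n <- nrow(quant)
  for (i in seq_len(n)) {
    child <- db@species[[quant$index[i]]]
    best <- NA_character_; bestInt <- -Inf
    for (j in seq_len(n)) {
      if (i == j) next
      parent <- db@species[[quant$index[j]]]
      if (!.isGlycanSubset(child, parent)) next
      ti <- traces[[quant$label[i]]]; tj <- traces[[quant$label[j]]]
      if (is.na(xicApex(ti)) || is.na(xicApex(tj))) next
      if (abs(xicApex(ti) - xicApex(tj)) > apexTol) next
      ov <- intersect(round(ti@rt, 6), round(tj@rt, 6))
      if (length(ov) < 3L) next
      a <- ti@intensity[match(ov, round(ti@rt, 6))]
      b <- tj@intensity[match(ov, round(tj@rt, 6))]
      keep <- a > 0 | b > 0
      if (sum(keep) < 3L || stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0)
        next
      if (stats::cor(a[keep], b[keep]) < minCor) next
      if (quant$integral[j] > bestInt) {
        best <- quant$label[j]; bestInt <- quant$integral[j]
      }
    }
    quant$isdParent[i] <- best
  }
  quant
}

#' Merge in-source-decay satellites into their parents
#'
#' Either reports satellites separately (as identified) or merges their
#' integrals into the parent row; the total integral is conserved exactly
#' in both reports.
#'
#' @param quant flagged table from \code{\link{flagInSourceDecay}}.
#' @param merge merge satellite integrals into parents?
#' @return quant table with recomputed class percentages.
#' @export
mergeInSourceDecay <- function(quant, merge = TRUE) {
  q <- quant
  if (merge) {
    sat <- which(!is.na(q$isdParent))
    for (i in sat) {
      j <- match(q$isdParent[i], q$label)
      if (!is.na(j)) q$integral[j] <- q$integral[j] + q$integral[i]
    }
    if (length(sat)) q <- q[-sat, , drop = FALSE]
  }
  for (cl in unique(q$class)) {
    sel <- q$class == cl
    tot <- sum(q$integral[sel])
    q$percentOfClass[sel] <- if (tot > 0) 100 * q$integral[sel] / tot else NA
  }
  rownames(q) <- NULL
  q
}

#' Export a quantification table to TSV
#'
#' Columns mirror the standard muropeptide report: peptides, charges,
#' glycans, neutral mass, elution time, XIC integral, percent of class.
#'
#' @param quant table from \code{\link{quantifySpecies}}.
#' @param path output file.
#' @export
exportQuant <- function(quant, path) {
  out <- data.frame(
    Peptides = quant$stems, Charges = quant$charges,
    Glycans = quant$glycans, NeutralMass = sprintf("%.3f", quant$neutralMass),
    ElutionTime = sprintf("%.2f", quant$apexRt),
    XicIntegral = sprintf("%.4g", quant$integral),
    PercentOfClass = sprintf("%.2f", quant$percentOfClass),
    Class = quant$class, InSourceDecayOf = quant$isdParent)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Total ion chromatogram of the MS1 scans
#'
#' @param run an \linkS4class{MsRun}.
#' @return data.frame \code{rt}, \code{tic} for plotting.
#' @export
ticTrace <- function(run) {
  ms1 <- runSpectra(run, msLevel = 1L)
  data.frame(rt = vapply(ms1, function(s) s@rt, numeric(1)),
             tic = vapply(ms1, function(s) sum(s@intensity), numeric(1)))
}
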