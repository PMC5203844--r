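## Automated 3-3 vs 4-3 cross-link topology decisions from diagnostic
## fragments, replacing the manual inspection step.

#' Decide the cross-link topology of an isobaric candidate group
#'
#' ETD spectra are interrogated with the c/z pair splitting donor from
#' acceptor (plus any other topology-exclusive c/z ion, including z+1
#' hydrogen-transfer variants); HCD spectra use only the unambiguous
#' internal-fragment rule (an internal fragment weighing two mDAP residues
#' proves a 3-3 link; the shared Ala + 2 mDAP fragment is never used). A
#' diagnostic peak must be strong: at or above the \code{strongQuantile}
#' intensity quantile of the spectrum. If diagnostics of both or neither
#' topology are matched the call is ambiguous.
#'
#' @param spec an MS2 \linkS4class{Spectrum}.
#' @param candidates list of isobaric \linkS4class{CrosslinkedSpecies}
#'   containing at least two cross-link topologies.
#' @param hcdTolPpm,etdTolDa fragment tolerances (20 ppm / 0.5 Da).
#' @param strongQuantile intensity quantile defining a "strong" peak
#'   (default 0.5: the top half of peaks).
#' @return list with \code{call} (\code{"3-3"}, \code{"4-3"} or
#'   \code{"ambiguous"}), \code{evidence} (matched diagnostic fragments with
#'   errors), \code{activation}, \code{candidates} (labels).
#' @export
classifyCrosslink <- function(spec, candidates, hcdTolPpm = 20,
                              etdTolDa = 0.5, strongQuantile = 0.5) {
  stopifnot(is(spec, "Spectrum"), spec@msLevel == 2L)
  if (length(candidates) < 2L)
    stop("need at least two isobaric candidates")
  masses <- vapply(candidates, neutralMass, numeric(1))
  if (max(masses) - min(masses) > 1e-6)
    stop("candidates are not isobaric")
  tops <- vapply(candidates, .majorTopology, character(1))
  if (length(unique(tops)) < 2L)
    stop("candidates must include both cross-link topologies")
  spA <- candidates[[match("3-3", tops)]]
  spB <- candidates[[match("4-3", tops)]]
  zmax <- max(1L, min(spec@precursorCharge, 2L, na.rm = TRUE))
  if (identical(spec@activation, "HCD")) {
    di <- diagnosticInternalFragments(spA, spB)
    dA <- di[di$diagnosticFor == "3-3", , drop = FALSE]
    dB <- di[di$diagnosticFor == "4-3", , drop = FALSE]
  } else {
    di <- diagnosticFragments(spA, spB, "ETD", charges = seq_len(zmax),
                              tol = etdTolDa)
    dA <- di$a[di$a$diagnosticFor == "3-3", , drop = FALSE]
    dB <- di$b[di$b$diagnosticFor == "4-3", , drop = FALSE]
  }
  ## a diagnostic must land on a strong peak
  strong <- spec
  if (length(spec@intensity)) {
    thr <- stats::quantile(spec@intensity, strongQuantile, names = FALSE)
    keep <- spec@intensity >= thr
    strong <- spectrum(spec@scan, spec@rt, 2L, spec@mz[keep],
                       spec@intensity[keep], spec@precursorMz,
                       spec@precursorCharge, spec@activation)
  }
  mA <- matchFragments(strong, dA, hcdTolPpm, etdTolDa)
  mB <- matchFragments(strong, dB, hcdTolPpm, etdTolDa)
  call <- if (nrow(mA) && !nrow(mB)) "3-3"
          else if (nrow(mB) && !nrow(mA)) "4-3"
          else "ambiguous"
  list(call = call, evidence = rbind(mA, mB),
       activation = spec@activation,
       candidates = vapply(candidates, speciesLabel, character(1)))
}

#' Consensus topology calls per isobaric composition
#'
#' Aggregates the per-spectrum topology calls of \code{\link{searchRun}}
#' (rank-1 identifications of cross-linked species) by isobaric group:
#' majority call, with disagreeing spectra counted as conflicts. A group
#' whose spectra are all ambiguous stays ambiguous.
#'
#' @param ids identification table from \code{\link{searchRun}}.
#' @return data.frame: \code{group}, \code{composition} (label of the called
#'   interpretation, or the group annotation), \code{call},
#'   \code{nSpectra}, \code{n33}, \code{n43}, \code{nAmbiguous},
#'   \code{nConflicts}, \code{note}.
#' @export
batchCall <- function(ids) {
  top1 <- ids[ids$rank == 1L & ids$topology != "" &
              ids$topologyCall != "n/a", , drop = FALSE]
  if (!nrow(top1))
    return(data.frame(group = integer(0), composition = character(0),
                      call = character(0), nSpectra = integer(0),
                      n33 = integer(0), n43 = integer(0),
                      nAmbiguous = integer(0), nConflicts = integer(0),
                      note = character(0)))
  out <- lapply(split(top1, top1$group), function(d) {
    n33 <- sum(d$topologyCall == "3-3")
    n43 <- sum(d$topologyCall == "4-3")
    call <- if (n33 > n43) "3-3" else if (n43 > n33) "4-3" else "ambiguous"
    conf <- if (call == "3-3") n43 else if (call == "4-3") n33 else 0L
    cls <- ifelse(grepl("4-3", d$topology, fixed = TRUE), "4-3", "3-3")
    comp <- if (call %in% cls) d$label[match(call, cls)] else d$label[1]
    data.frame(group = d$group[1], composition = comp, call = call,
               nSpectra = nrow(d), n33 = n33, n43 = n43,
               nAmbiguous = sum(d$topologyCall == "ambiguous"),
               nConflicts = as.integer(conf),
               note = "co-eluting minor topology cannot be excluded")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write topology calls to TSV
#' @param calls data.frame from \code{\link{batchCall}}.
#' @param path output file.
#' @export
exportCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
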