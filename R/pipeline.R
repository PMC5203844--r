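## End-to-end orchestration: build-db -> search -> quantify -> call-links ->
## report, driven by a key-value (YAML) config.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Default pipeline configuration
#'
#' @return a list of defaults: the standard tolerances (5 ppm precursor,
#'   20 ppm HCD, 0.5 Da ETD fragments), the five glycoforms plus the bare
#'   peptide, amidation on, trimer search on, wildcard pass off.
#' @export
defaultConfig <- function() {
  list(
    mzml = NULL,
    stems_fasta = NULL,
    stems = NULL,
    stem_convention = "mdap",
    glycoforms = c("none", "MurNAc", "GlcN-deacetyl-MurNAc",
                   "GlcN-anhydro-MurNAc", "GlcN-MurNAc", "GlcNAc-MurNAc"),
    amidation = FALSE,
    max_units = 3L,
    donor_stems = c("AEm", "AEmA"),
    precursor_ppm = 5,
    hcd_ppm = 20,
    etd_da = 0.5,
    xic_ppm = 10,
    wildcard = FALSE,
    wildcard_range = c(-130, 210),
    merge_isd = TRUE,
    output_dir = NULL)
}

#' Read a pipeline configuration file
#'
#' @param path YAML key-value file; unknown keys are rejected.
#' @return config list (defaults filled in).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- defaultConfig()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(def, cfg)
}

## combine candidate databases into one mass-sorted db
.combineDbs <- function(...) {
  dbs <- list(...)
  .makeDb(do.call(c, lapply(dbs, function(d) d@species)))
}

#' Run the full identification-quantification pipeline
#'
#' Stages: read stems, build the monomer database, read the run, search
#' monomers, build dimer/trimer databases using the monomer stems actually
#' identified as terminal acceptors, search everything, quantify by XIC with
#' in-source-decay flagging, call cross-link topologies, optionally run the
#' wildcard pass on unidentified precursors, and assemble a report. Stage
#' failures propagate with the stage name.
#'
#' @param config a config list (see \code{\link{defaultConfig}}), a YAML
#'   path, or a list with \code{run} (an \linkS4class{MsRun}) instead of
#'   \code{mzml}.
#' @return a \code{RunReport} list: \code{classSummary},
#'   \code{classSummaryMerged}, \code{quant}, \code{quantMerged},
#'   \code{calls}, \code{identifications}, \code{isobaric},
#'   \code{unidentified}, \code{sequenceVariants} (wildcard pass only),
#'   \code{log}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- utils::modifyList(defaultConfig(), config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log <<- c(log, msg)
  }

  stems <- .stage("stems", {
    if (!is.null(config$stems)) unlist(config$stems)
    else if (!is.null(config$stems_fasta))
      readStems(config$stems_fasta, config$stem_convention)
    else stop("config needs 'stems' or 'stems_fasta'")
  })

  run <- .stage("read-run", {
    if (!is.null(config$run)) config$run else readMsRun(config$mzml)
  })

  monoCfg <- searchConfig(stems, glycoforms = config$glycoforms,
                          amidation = isTRUE(config$amidation), maxUnits = 1L,
                          donorStems = config$donor_stems)
  monoDb <- .stage("build-db", buildMonomerDb(monoCfg))
  say("monomer db: %d candidates, %d distinct masses", dbSize(monoDb),
      length(unique(round(monoDb@table$neutralMass, 3))))

  monoIds <- .stage("search", searchRun(run, monoDb, config$precursor_ppm,
                                        config$hcd_ppm, config$etd_da))
  ## terminal acceptors: the monomer stems actually identified, plus the
  ## donor stems themselves (which occur cross-linked far more often than
  ## free, and are needed so both isobaric topology interpretations of a
  ## composition enter the candidate space)
  acceptors <- unique(c(unlist(strsplit(
    monoIds$stems[monoIds$rank == 1L], ",")), config$donor_stems))
  if (!length(acceptors)) acceptors <- stems
  say("monomer pass: %d spectra identified; %d acceptor stems",
      length(unique(monoIds$scan)), length(acceptors))

  db <- monoDb
  if (config$max_units >= 2L) {
    db <- .stage("build-db", {
      multi <- lapply(2:config$max_units, function(k)
        buildMultimerDb(searchConfig(stems, glycoforms = config$glycoforms,
                                     amidation = isTRUE(config$amidation),
                                     maxUnits = k,
                                     donorStems = config$donor_stems),
                        acceptorStems = acceptors))
      do.call(.combineDbs, c(list(monoDb), multi))
    })
    say("combined db: %d candidates, %d distinct masses", dbSize(db),
        length(unique(round(db@table$neutralMass, 3))))
  }

  ids <- .stage("search", searchRun(run, db, config$precursor_ppm,
                                    config$hcd_ppm, config$etd_da))
  say("search: %d/%d MS2 spectra identified",
      length(unique(ids$scan)), length(runSpectra(run, msLevel = 2L)))

  quant <- .stage("quantify", {
    q <- quantifySpecies(ids, run, db, tolPpm = config$xic_ppm)
    flagInSourceDecay(q, db)
  })
  quantMerged <- mergeInSourceDecay(quant, merge = isTRUE(config$merge_isd))
  calls <- .stage("call-links", batchCall(ids))

  grp <- isobaricGroups(db, config$precursor_ppm)
  isoAnn <- grp[grp$groupSize > 1L & grp$index %in% ids$index, , drop = FALSE]

  ## MS2 precursors matching nothing: listed by neutral mass only
  ms2 <- runSpectra(run, msLevel = 2L)
  idScans <- unique(ids$scan)
  unid <- unique(round(vapply(
    ms2[!vapply(ms2, function(s) s@scan %in% idScans, logical(1))],
    function(s) neutralFromMz(s@precursorMz, s@precursorCharge),
    numeric(1)), 3))

  variants <- NULL
  if (isTRUE(config$wildcard)) {
    variants <- .stage("wildcard", {
      baseCfg <- searchConfig(stems, glycoforms = config$glycoforms,
                              amidation = FALSE, maxUnits = 1L)
      baseDb <- buildMonomerDb(baseCfg)
      out <- lapply(unid, function(M)
        resolveWildcard(M, baseDb, config$precursor_ppm,
                        config$wildcard_range))
      res <- if (length(out)) do.call(rbind, out)
             else data.frame(base = character(0), baseMass = numeric(0),
                             delta = numeric(0), annotation = character(0))
      res[nzchar(res$annotation), , drop = FALSE]
    })
    say("wildcard pass: %d annotated sequence-variant interpretations",
        nrow(variants))
  }

  report <- list(
    classSummary = classSummary(quant),
    classSummaryMerged = classSummary(quantMerged),
    quant = quant, quantMerged = quantMerged,
    calls = calls, identifications = ids,
    isobaric = isoAnn, unidentified = unid,
    sequenceVariants = variants, log = log)
  class(report) <- "RunReport"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    exportQuant(quantMerged, file.path(config$output_dir, "quant.tsv"))
    exportIdentifications(ids, file.path(config$output_dir,
                                         "identifications.tsv"))
    exportCalls(calls, file.path(config$output_dir, "crosslink_calls.tsv"))
    utils::write.table(ticTrace(run), file.path(config$output_dir, "tic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("== muropeptide run report ==\n\nClass composition (% of identified XIC total):\n")
  cs <- x$classSummary
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-8s %6.1f %%\n", cs$class[i], cs$percentOfTotal[i]))
  cat(sprintf("\n%d quantified species; %d cross-link topology calls\n",
              nrow(x$quant), nrow(x$calls)))
  if (nrow(x$calls)) {
    for (i in seq_len(nrow(x$calls)))
      cat(sprintf("  %s -> %s (%d spectra, %d conflicts)\n",
                  x$calls$composition[i], x$calls$call[i],
                  x$calls$nSpectra[i], x$calls$nConflicts[i]))
  }
  if (length(x$unidentified))
    cat("Unidentified precursor neutral masses:",
        paste(format(x$unidentified, nsmall = 3), collapse = ", "), "\n")
  if (!is.null(x$sequenceVariants) && nrow(x$sequenceVariants)) {
    cat("Sequence variants (wildcard pass):\n")
    for (i in seq_len(nrow(x$sequenceVariants)))
      cat(sprintf("  %s %+0.3f Da: %s\n", x$sequenceVariants$base[i],
                  x$sequenceVariants$delta[i],
                  x$sequenceVariants$annotation[i]))
  }
  invisible(x)
}
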