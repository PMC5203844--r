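## Theoretical fragment prediction for linear and cross-linked muropeptides.
##
## A species is modelled as a graph of mass blocks: glycan sugars (the
## reducing-end MurNAc split into ring and lactyl), stem residues, and amide
## edges (backbone bonds and cross-links). Any neutral amide-bonded assembly
## weighs sum(blocks) + H2O, so cleaving one bond splits the species into two
## block sums F_N and F_C with F_N + F_C = M - H2O, and the usual ion-type
## offsets apply uniformly to backbone and cross-link amides:
##   b/B: F + z*H+           y/Y: F + H2O + z*H+
##   c:   F + NH3 + z*H+     z.:  F + H2O - NH3 + H + z*H+   (z+1: + H)

.fragOffset <- function(series) {
  switch(series,
    b = 0, B = 0, internal = 0,
    y = .WATER, Y = .WATER,
    c = .AMMONIA,
    "z" = .WATER - .AMMONIA + .HYDROGEN,
    "z+1" = .WATER - .AMMONIA + 2 * .HYDROGEN,
    stop("unknown series: ", series))
}

#' Ion m/z from a fragment block sum
#'
#' @param content sum of block (residue/sugar/mod) masses in the fragment.
#' @param series one of \code{b}, \code{y}, \code{c}, \code{z}, \code{z+1},
#'   \code{B}, \code{Y}, \code{internal}.
#' @param z charge.
#' @return m/z.
#' @keywords internal
fragmentMz <- function(content, series, z = 1L) {
  (content + .fragOffset(series) + z * .PROTON) / z
}

## Build the block graph of a species. Nodes carry masses; edges carry a
## cleavage type and, for amides, the id of the N-terminal-side node.
.speciesGraph <- function(sp) {
  nodes <- list()   # id -> mass
  unitOf <- character(0)
  edges <- list()   # list(a, b, type, site, nSide)
  addNode <- function(id, mass, unit) {
    nodes[[id]] <<- mass
    unitOf[[id]] <<- as.character(unit)
  }
  for (u in seq_along(sp@units)) {
    mp <- sp@units[[u]]
    res <- strsplit(mp@stem, "")[[1]]
    rmass <- residueMass(res)
    if (nrow(mp@mods))
      for (j in seq_len(nrow(mp@mods)))
        rmass[mp@mods$position[j]] <- rmass[mp@mods$position[j]] +
          mp@mods$delta[j]
    rid <- sprintf("u%d.r%d", u, seq_along(res))
    for (i in seq_along(res)) addNode(rid[i], rmass[i], u)
    if (length(res) > 1L)
      for (i in seq_len(length(res) - 1L))
        edges[[length(edges) + 1L]] <- list(
          a = rid[i], b = rid[i + 1L], type = "amide",
          site = sprintf("u%d:%s%d-%s%d", u, res[i], i, res[i + 1L], i + 1L),
          nSide = rid[i])
    gf <- mp@glycoform
    if (length(gf@sugars)) {
      ring <- gf@sugars[length(gf@sugars)]
      ringMass <- .SUGAR_MASSES[[ring]] - .LACTYL
      if (gf@reduced && ring %in% .REDUCIBLE)
        ringMass <- ringMass + 2 * .HYDROGEN
      ringId <- sprintf("u%d.ring", u)
      lacId <- sprintf("u%d.lac", u)
      addNode(ringId, ringMass, u)
      addNode(lacId, .LACTYL, u)
      edges[[length(edges) + 1L]] <- list(
        a = ringId, b = lacId, type = "glyco",
        site = sprintf("u%d:MurNAc|lactyl", u), nSide = ringId)
      edges[[length(edges) + 1L]] <- list(
        a = lacId, b = rid[1L], type = "glyco",
        site = sprintf("u%d:lactyl|%s1", u, res[1L]), nSide = lacId)
      if (length(gf@sugars) == 2L) {
        s1 <- sprintf("u%d.s1", u)
        addNode(s1, .SUGAR_MASSES[[gf@sugars[1L]]], u)
        edges[[length(edges) + 1L]] <- list(
          a = s1, b = ringId, type = "glyco",
          site = sprintf("u%d:%s|%s", u, gf@sugars[1L], ring), nSide = s1)
      }
    }
  }
  if (nrow(sp@links))
    for (l in seq_len(nrow(sp@links))) {
      d <- sp@links$donorUnit[l]; a <- sp@links$acceptorUnit[l]
      dn <- sprintf("u%d.r%d", d, sp@links$donorPos[l])
      an <- sprintf("u%d.r%d", a, sp@links$acceptorPos[l])
      edges[[length(edges) + 1L]] <- list(
        a = dn, b = an, type = "amide",
        site = sprintf("xlink:u%d(%d)-u%d(3)", d, sp@links$donorPos[l], a),
        nSide = dn)
    }
  list(nodes = nodes, edges = edges, unitOf = unitOf)
}

## Connected component containing `start` after removing edge `drop`.
.component <- function(graph, start, drop) {
  adj <- list()
  for (i in seq_along(graph$edges)) {
    if (i == drop) next
    e <- graph$edges[[i]]
    adj[[e$a]] <- c(adj[[e$a]], e$b)
    adj[[e$b]] <- c(adj[[e$b]], e$a)
  }
  seen <- character(0)
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, setdiff(adj[[v]], seen))
  }
  seen
}

#' Predict theoretical fragments of a (possibly cross-linked) muropeptide
#'
#' Emits, for every backbone and cross-link amide, b/y ions (HCD) or c and
#' both z-radical and hydrogen-transfer z+1 ions (ETD); for every glycosidic
#' bond (GlcN|MurNAc, MurNAc|lactyl, lactyl|Ala1) B and Y ions in both
#' activation modes; and, for HCD, internal fragments of 2-4 residues
#' (b-type offset). Fragments carry every unit still covalently attached
#' through the cross-link graph.
#'
#' @param x a \linkS4class{CrosslinkedSpecies} or \linkS4class{Muropeptide}.
#' @param activation \code{"HCD"} or \code{"ETD"}.
#' @param charges integer vector of fragment charges (default 1, or
#'   1:min(precursor z, 2) at match time).
#' @return data.frame: \code{series}, \code{site}, \code{charge}, \code{mz},
#'   \code{content} (block sum, Da), \code{unitsCovered},
#'   \code{diagnosticFor}.
#' @examples
#' fr <- predictFragments(muropeptide("AEm", "GlcN-MurNAc"), "ETD")
#' head(fr)
#' @export
predictFragments <- function(x, activation = c("HCD", "ETD"), charges = 1L) {
  activation <- match.arg(activation)
  if (is(x, "Muropeptide")) x <- asSpecies(x)
  stopifnot(is(x, "CrosslinkedSpecies"))
  validObject(x)
  g <- .speciesGraph(x)
  allNodes <- names(g$nodes)
  total <- sum(unlist(g$nodes))
  rows <- list()
  emit <- function(series, site, content, unitsCovered) {
    for (z in charges)
      rows[[length(rows) + 1L]] <<- data.frame(
        series = series, site = site, charge = z,
        mz = fragmentMz(content, series, z), content = content,
        unitsCovered = unitsCovered, diagnosticFor = "none")
  }
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    nComp <- .component(g, e$nSide, i)
    if (length(nComp) == length(allNodes)) next   # ring: not cleavable alone
    cComp <- setdiff(allNodes, nComp)
    fN <- sum(unlist(g$nodes[nComp]))
    fC <- total - fN
    uN <- paste(sort(unique(g$unitOf[nComp])), collapse = ",")
    uC <- paste(sort(unique(g$unitOf[cComp])), collapse = ",")
    if (e$type == "amide") {
      if (activation == "HCD") {
        emit("b", e$site, fN, uN)
        emit("y", e$site, fC, uC)
      } else {
        emit("c", e$site, fN, uN)
        emit("z", e$site, fC, uC)
        emit("z+1", e$site, fC, uC)
      }
    } else {
      emit("B", e$site, fN, uN)
      emit("Y", e$site, fC, uC)
    }
  }
  if (activation == "HCD") {
    intr <- .internalFragments(x, maxLen = 4L)
    for (j in seq_len(nrow(intr)))
      emit("internal", intr$site[j], intr$content[j], intr$units[j])
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(series = character(0), site = character(0),
                      charge = integer(0), mz = numeric(0),
                      content = numeric(0), unitsCovered = character(0),
                      diagnosticFor = character(0))
  out[order(out$mz), , drop = FALSE]
}

## Contiguous residue stretches of 2..maxLen residues, walking backbone and
## cross-link amides; deduplicated by site label.
.internalFragments <- function(sp, maxLen = 4L) {
  g <- .speciesGraph(sp)
  resNodes <- grep("\\.r\\d+$", names(g$nodes), value = TRUE)
  adj <- list()
  for (e in g$edges) {
    if (e$type != "amide") next
    adj[[e$a]] <- c(adj[[e$a]], e$b)
    adj[[e$b]] <- c(adj[[e$b]], e$a)
  }
  paths <- list()
  walk <- function(path) {
    if (length(path) >= 2L) paths[[length(paths) + 1L]] <<- path
    if (length(path) >= maxLen) return()
    last <- path[length(path)]
    for (nxt in setdiff(adj[[last]], path)) walk(c(path, nxt))
  }
  for (v in resNodes) walk(v)
  if (!length(paths))
    return(data.frame(site = character(0), content = numeric(0),
                      units = character(0)))
  lab <- vapply(paths, function(p)
    paste(sort(p), collapse = "+"), character(1))
  keep <- !duplicated(lab)
  paths <- paths[keep]; lab <- lab[keep]
  data.frame(
    site = paste0("int:", lab),
    content = vapply(paths, function(p) sum(unlist(g$nodes[p])), numeric(1)),
    units = vapply(paths, function(p)
      paste(sort(unique(g$unitOf[p])), collapse = ","), character(1)))
}

#' Fragments that discriminate two isobaric cross-link interpretations
#'
#' Given two candidate species of identical composition (e.g. the 4-3 dimer
#' of two tetrapeptide units versus the 3-3 dimer of a tripeptide and a
#' pentapeptide), returns each candidate's predicted fragments flagged with
#' the topology they are exclusive to: a fragment is diagnostic when no
#' fragment of the other interpretation lies within \code{tol} of it.
#'
#' @param spA,spB isobaric \linkS4class{CrosslinkedSpecies} candidates.
#' @param activation \code{"HCD"} or \code{"ETD"}.
#' @param charges fragment charges.
#' @param tol mass tolerance in Da used to declare two predictions
#'   indistinguishable (use the fragment-match tolerance).
#' @return list with elements \code{a} and \code{b}: fragment tables whose
#'   \code{diagnosticFor} column is set to that candidate's topology for
#'   exclusive fragments.
#' @export
diagnosticFragments <- function(spA, spB, activation = c("HCD", "ETD"),
                                charges = 1L, tol = 0.5) {
  activation <- match.arg(activation)
  if (abs(neutralMass(spA) - neutralMass(spB)) > 1e-6)
    stop("candidates are not isobaric")
  fa <- predictFragments(spA, activation, charges)
  fb <- predictFragments(spB, activation, charges)
  if (activation == "HCD") {
    ## only the internal-fragment rule is topology-safe in HCD
    fa <- .flagExclusive(fa, fb, tol, .majorTopology(spA), "internal")
    fb <- .flagExclusive(fb, fa, tol, .majorTopology(spB), "internal")
  } else {
    fa <- .flagExclusive(fa, fb, tol, .majorTopology(spA))
    fb <- .flagExclusive(fb, fa, tol, .majorTopology(spB))
  }
  list(a = fa, b = fb)
}

## topology class of a species: "4-3" if any link is 4-3, else "3-3"
## (for multimers the operative question is whether d,d-transpeptidation
## contributed any link); "none" for monomers
.majorTopology <- function(sp) {
  top <- topology(sp)
  if (!length(top)) "none"
  else if (any(top == "4-3")) "4-3"
  else "3-3"
}

.flagExclusive <- function(fr, other, tol, label, seriesOnly = NULL) {
  if (!nrow(fr)) return(fr)
  cand <- rep(TRUE, nrow(fr))
  if (!is.null(seriesOnly)) cand <- fr$series %in% seriesOnly
  ## an exclusive diagnostic may not coincide with ANY predicted m/z of the
  ## other interpretation, whatever that ion's charge: the observed peak
  ## list carries no charge information
  for (i in which(cand))
    if (any(abs(other$mz - fr$mz[i]) <= tol)) cand[i] <- FALSE
  fr$diagnosticFor <- ifelse(cand, label, "none")
  fr
}

#' Topology-unambiguous internal fragments of an isobaric candidate pair
#'
#' Internal fragments (2-4 contiguous residues, b-type ion offset) whose
#' residue composition is achievable under exactly one of the two cross-link
#' interpretations. The classic case: an internal fragment weighing two mDAP
#' residues proves a 3-3 link (the two mDAPs are adjacent through the
#' cross-link), while Ala + 2 mDAP arises under either topology and is
#' excluded.
#'
#' @param spA,spB isobaric candidates with different topology.
#' @param tol Da tolerance for considering two internal masses equal.
#' @return data.frame of internal fragments with \code{diagnosticFor} set
#'   to the topology each proves; ambiguous ones are dropped.
#' @export
diagnosticInternalFragments <- function(spA, spB, tol = 0.01) {
  if (abs(neutralMass(spA) - neutralMass(spB)) > 1e-6)
    stop("candidates are not isobaric")
  ia <- .internalFragments(spA)
  ib <- .internalFragments(spB)
  exA <- ia[!vapply(ia$content, function(m)
    any(abs(ib$content - m) <= tol), logical(1)), , drop = FALSE]
  exB <- ib[!vapply(ib$content, function(m)
    any(abs(ia$content - m) <= tol), logical(1)), , drop = FALSE]
  mk <- function(d, lab) {
    if (!nrow(d))
      return(data.frame(series = character(0), site = character(0),
                        charge = integer(0), mz = numeric(0),
                        content = numeric(0), unitsCovered = character(0),
                        diagnosticFor = character(0)))
    data.frame(series = "internal", site = d$site, charge = 1L,
               mz = fragmentMz(d$content, "internal", 1L),
               content = d$content, unitsCovered = d$units,
               diagnosticFor = lab)
  }
  rbind(mk(exA, .majorTopology(spA)), mk(exB, .majorTopology(spB)))
}

#' Export a fragment table to TSV
#' @param fragments a fragment data.frame from \code{\link{predictFragments}}.
#' @param path output file.
#' @export
exportFragments <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
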