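---
title: "murosearch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{murosearch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murosearch)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open. The companion README shows the worked
examples; the test suite computes every empirical claim made here.

## 1. The mass model

Muropeptides are modelled as a glycan chain (0–2 monosaccharides) attached
N-terminally to a peptide stem. All arithmetic is additive over
full-precision monoisotopic element masses; the rounded values found in the
muropeptide literature (mDAP 172.0848, GlcN-MurNAc 438.185, cross-link
−18.0106, amidation −0.984) are *surfaces* that the model reproduces within
2 mDa, never constants it stores. This matters for trimers: three rounded
glycoform masses and two rounded water losses would otherwise compound to
several mDa of bias, which at 5 ppm precursor tolerance (±13 mDa at 2.5 kDa)
would consume a third of the error budget.

mDAP (meso-diaminopimelic acid, C7H12N2O3) is a first-class residue with
the reserved lower-case code `m`. The historical workaround of encoding it
as methionine plus a +41.0443 fixed modification — a concession to
protein-centric search engines — is supported only as a FASTA import
convention (`readStems(..., convention = "met41")`).

Glycoforms are built from monosaccharide residue blocks. Two conventions
are worth stating explicitly because they differ across the literature:

* **Reduction.** After borohydride treatment every reducing-end MurNAc is
  muramitol; the package therefore reduces reducing ends *by default*
  (+2.0157 Da), toggleable per glycoform. The 1,6-anhydro ring cannot be
  reduced and sits 18.011 Da below the reduced convention.
* **De-N-acetylation.** GlcN is simply GlcNAc − C2H2O; the dominant state
  in *C. difficile* walls.

A cross-linked species is an ordered chain of units, donors first. Each
link is an amide from the donor stem (position 3 = mDAP side-chain
carboxyl, topology 3–3; position 4 = d-Ala carboxyl, topology 4–3) to the
acceptor's mDAP amine, and condenses out one water. Validity methods
enforce the chemistry: a 3–3 donor must be a tripeptide, a 4–3 donor at
least a tetrapeptide, and the acceptor's position 3 must be mDAP.

Amidation (−0.984 Da, OH→NH2) is enumerated on at most the E and mDAP
sites of each stem, each independently on or off — the two sites chemically
available on these stems.

## 2. Fragment prediction on the block graph

A species is a graph whose nodes are mass blocks — stem residues, the
non-reducing sugar, the MurNAc ring, and the lactyl bridge — and whose
edges are the cleavable bonds: backbone amides, cross-link amides, and the
three glycosidic bonds that electron-transfer spectra of muropeptides
cleave prominently (GlcN|MurNAc, MurNAc|lactyl, lactyl|Ala1). Any neutral
amide-bonded assembly weighs Σ blocks + H2O, so deleting one edge splits
the species into two block sums `F_N` and `F_C` with
`F_N + F_C = M − H2O`, and one offset table serves every cleavage,
backbone or cross-link alike:

| ion | m/z at charge z |
|----|----|
| b, B, internal | (F + z·p)/z |
| y, Y | (F + H2O + z·p)/z |
| c | (F + NH3 + z·p)/z |
| z• | (F + H2O − NH3 + H + z·p)/z |
| z+1 | z• + H |

ETD z-ions are emitted in both the radical (z•) and hydrogen-transfer
(z+1) variants, since the transfer is routine at precursor charge 2+. HCD
prediction adds internal fragments — contiguous stretches of 2–4 residues
walked along backbone *and* cross-link edges — because collisional spectra
of muropeptides are dominated by them; the length cap bounds the
combinatorics at trimer size. Internal ions use the b-type offset (residue
sum + proton); the annotating literature does not state the ion type, so
this is a package convention, configurable at the call site in principle
but fixed in practice. Fragment charges default to 1..min(precursor z, 2),
appropriate for the sub-1 kDa fragments these species produce.

### What topology-aware prediction changes

Because prediction walks the real link graph, every fragment carries
whatever units remain covalently attached — the behaviour search engines
built on concatenated linear sequences can only approximate. One
consequence, found by the package's own exclusivity computation and worth
recording: for the isobaric dimer pairs, the celebrated "splitting" c/z
pair (828.38/884.39 for a tripeptide donor) is *predicted by both
interpretations* — the 4–3 alternative's donor m3–A4 cleavage yields
fragments of identical content. The ions that are genuinely exclusive are,
for the tripeptide⋈tetrapeptide composition, the donor-spanning c at
1638.73 (3–3) versus the cross-link-splitting c 899.42 / z 813.35 (4–3).
`diagnosticFragments()` therefore computes exclusivity mechanically — a
fragment is diagnostic only if no fragment of the other interpretation, at
*any* charge, lies within the match tolerance — rather than hard-coding
annotated ions. Manual annotations remain correct as evidence *for* their
topology; they are just not all evidence *against* the alternative.

## 3. Search, scoring and the absence of decoys

Precursor matching is at 5 ppm (the instrument class this models), with
candidates sorted by |ppm error|. Fragment matching is greedy
nearest-pair: candidate (fragment, peak) pairs within tolerance are
accepted in order of increasing error, each peak and each fragment used at
most once — 20 ppm for HCD (Orbitrap readout), 0.5 Da for ETD (ion-trap
readout, which also absorbs the z/z+1 ambiguity).

The score is deliberately transparent rather than probabilistic:

    score = (fraction of predicted primary-series fragments matched)
          + (fraction of observed total intensity explained)   ∈ [0, 2]

with primary series b/y (HCD) or c/z (ETD, the two z variants collapsing
to one prediction). All candidates with score ≥ 0 are retained — the
"score cut of zero" policy — with ties broken by fewer modifications, then
fewer units, then label. Reversed-sequence decoy FDR is *not* implemented:
with a search space of a few thousand candidates and most information in
the precursor mass, reversed stems produce near-identical masses and
fragments, and the decoy premise fails. In its place the package reports
per-identification ppm error and explicit isobaric-group annotations
(bracket notation), so ambiguity is visible rather than hidden behind a
rate.

Monoisotopic precursor assignment is trusted as given; a ±1-isotope rescue
was considered and left out (off by default would be its only safe
setting, and the simulator never mis-assigns).

## 4. Topology calling

`classifyCrosslink()` matches each interpretation's exclusive diagnostics
against the spectrum and calls the topology whose diagnostics — and only
whose — are present. Two thresholds are the package's own quantifications
of qualitative language:

* a diagnostic peak must be **strong**: at or above the 0.5 intensity
  quantile of the spectrum's peaks (configurable). This makes calls
  invariant to intensity rescaling and robust to the low-level spurious
  peaks the noise model injects;
* HCD spectra are interrogated *only* with the unambiguous
  internal-fragment rule — an internal fragment weighing two mDAP residues
  (344.170 Da content) proves adjacency of the two mDAPs and hence a 3–3
  link, while Ala + 2×mDAP can arise under either topology and is never
  used. In practice HCD can prove 3–3 or abstain; it cannot prove 4–3.

`batchCall()` aggregates per-spectrum calls by isobaric group into a
majority consensus with conflicts counted, and every consensus row carries
the caveat that a co-eluting minority topology cannot be excluded by MS2
evidence alone.

## 5. Quantification

The XIC of a species is extracted per charge state at the monoisotopic
m/z ± 10 ppm over the MS1 scans near its identifications (±2.5 min), and
the reported integral is the **plain sum of per-scan ion counts, summed
over charge states** — not a trapezoid over time. This matches the
summed-ion-count definition of the reference tables; it is proportional to
the MS1 scan rate, which is constant within a run (the documented caveat
is that integrals are not comparable across runs with different cycle
times). Charge states are probed over 1–4 even though data-dependent
selection only fires on 2+ and higher: singly charged monomer signal
belongs in the sum.

In-source decay is recognised structurally plus chromatographically: a
species lacking one or more monosaccharides relative to a fuller glycoform
of the *same peptide content* is flagged as a decay satellite iff its XIC
apex is within 0.1 min of the parent's and the Pearson correlation of the
overlapping trace points is ≥ 0.95. Both thresholds are the package's
quantification of "exact co-elution"; the published account gives none.
The monosaccharide-loss deltas (GlcN 161.069, GlcNAc 203.079, whole
reduced disaccharide 438.185) derive from the component tables, not from
hard-coded constants. Satellites can be reported separately or merged into
their parents; the two reports conserve the total integral exactly, which
the tests assert.

## 6. The simulator: what it emulates and what it does not

`simulateRun()` generates the statistical structure the pipeline assumes:
Gaussian elution profiles over a configurable gradient (defaults mimic a
~50-min nano-LC run), a 0.02-min MS1 cycle, 3-point isotope envelopes
(Poisson in the heavy-isotope count, λ ≈ 5.5×10⁻⁴ per Da — adequate below
3 kDa; no averagine model is needed at these masses), charge-state
fractions per species (monomers 1+/2+, dimers 2+/3+, trimers 2+/3+/4+ by
default), data-dependent top-5 selection of multiply charged precursors
with 30-s-scale dynamic exclusion, alternating HCD/ETD activation, and
MS2 peaks drawn from the package's own fragment predictions with uniform
random intensities, optional dropout, spurious peaks and m/z jitter.
In-source-decay satellites share the parent's elution parameters *exactly*
(decay happens after the column), which is the property the flagging rule
keys on.

A species' `abundance` is defined as its total monoisotopic MS1 ion count
summed over charge states — precisely the quantity XIC quantification
reports — so noise-free recovery is exact by construction and the
round-trip tests check the pipeline, not the generator's bookkeeping. The
canonical `makeFixtureSuite()` mixture injects the monomer/dimer/trimer
classes at the 29.2/57.4/13.4 ion-count split of the reference analysis.

Deliberately not emulated: profile-mode peaks, chromatographic tailing,
chimeric MS2 spectra, charge-state-dependent fragmentation efficiency, and
intensity-dependent m/z error. Passing round trips therefore demonstrate
correctness of the identification/quantification logic under the model's
assumptions, not robustness to every pathology of real chromatography;
fragment *intensities* in particular carry no chemical information here,
so scoring thresholds tuned on simulated data should not be read as
instrument-calibrated.

Because MS2 spectra are simulated from the same fragment generator the
search uses, identification round trips share that model; the mass
arithmetic itself is guarded against circularity by a separate
elemental-composition oracle in the test suite, written with its own
frozen tables.

## 7. Numerical choices and degenerate inputs

* Candidate databases deduplicate on the unordered donor multiset plus
  terminal acceptor plus topology multiset; donor order is canonicalised
  at build time so enumeration is order-independent. Ordered and
  deduplicated counts are both logged (for the full reference-scale trimer
  space, 2×2×20 stems × 5³ glycoforms = 10,000 ordered; deduplication
  merges permuted donor pairs to 5,500).
* Mass-window lookups run on a sorted index via `findInterval`
  (O(log n)); the ppm window is computed on the neutral mass with a 1.5×
  guard band, then refined on m/z.
* The pipeline's multimer acceptors are the monomer stems actually
  identified in the first pass, *unioned with the donor stems*: donors
  occur cross-linked far more often than free (so a first pass may miss
  them as monomers), and without them one interpretation of an isobaric
  composition would be absent from the candidate space and topology
  calling would silently have nothing to compare.
* For multimers, a species counts as class 4–3 if *any* of its links is
  4–3; a topology call on a multimer composition therefore answers whether
  d,d-transpeptidation contributed at all, which is what pairwise
  diagnostics can support.
* The wildcard (open) search is a separate pass with variable
  modifications off, mirroring two-pass practice; deltas inside the
  precursor tolerance are not wildcard matches, and interpretations
  (substitution at a position, C-terminal addition, water loss) collapse
  I/L isobars.
* Isobaric grouping is single-linkage over the sorted mass list: adjacent
  entries within 5 ppm join. Single linkage can chain, but at the density
  of this search space (≤ a few thousand candidates over ~2 kDa) chaining
  beyond a true group was not observed.
* Empty inputs fail loudly and early: an empty stem list warns and returns
  an empty database; a run without MS1 scans cannot be quantified; a run
  without MS2 spectra fails the search stage by name.
* Problem sizes in the shipped tests are scaled to the structure being
  exercised: three-stem databases (~1,600 candidates with dimers and
  trimers), simulated runs of 300–1,000 spectra, 25–60 ETD spectra per
  topology round trip. These sizes already make every failure mode the
  tests guard against observable; the full reference-scale search space
  differs only by constant factors.

## 8. Known limitations

* Tetramers and higher oligomers are out of scope, as are O-acetylation
  and other remodelling chemistries not represented in the glycoform
  table (the tables are extendable through the configuration surface).
* Topology calls for trimers rest on pairwise diagnostics; a trimer with
  one 3–3 and one 4–3 link is callable only insofar as its pairwise
  exclusive ions survive in the spectrum.
* Stereochemical isomers (distinct elution peaks with identical MS2) are
  reported as one species; chromatography alone cannot name them.
* XIC extraction assumes well-separated isotope envelopes; co-eluting
  species within 10 ppm of each other's monoisotopic m/z would merge, a
  situation the isobaric-group report flags at the precursor level but
  quantification does not deconvolve.
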