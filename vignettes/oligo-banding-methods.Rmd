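---
title: "Oligo-banding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligo-banding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoband)
```

# The method in brief

Oligo-banding karyotypes a genome with a small panel of oligonucleotide
FISH probes. Each probe is a pool of 1500-3000 synthetic oligos tiling a
genomic window of roughly half a megabase; each oligo carries a
genome-homologous 39mer flanked by orthogonal 20mer segments for
amplification and for hybridization of a dye-labelled detection oligo.
Detected through three fluorophores used singly or in pairs, every probe
appears as one band in one of six colours, and each chromosome's ordered
band colours form its *banding pattern*. Karyotyping then reduces to
reading these patterns along traced chromosomes; structural rearrangements
appear as edited patterns.

This vignette records the models behind each module, the tunable
parameters with their defaults and rationale, the synthetic world the
generators emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite and the
acceptance script do not themselves compute.

# Panel design

Probe windows are runs of `n_oligo = 3000` consecutive candidate 39mers.
Constraints, all in base pairs:

* `min_resolvable_bp = 8e6`. Two bands closer than roughly 7-8 Mb are not
  optically separable on a metaphase chromosome, so inter-probe gaps must
  be at least this large.
* `termini_margin_bp = 6e6`. Probe edges keep at least 6 Mb from the
  chromosome ends (the smallest distance-from-ends value in the published
  panel rounds down to this).

The published rules say *which* criteria windows must satisfy (density,
spacing, termini distance) but not *how* to search. Our placement
heuristic anchors one window per probe at equal genomic quantiles of the
designable region and snaps each anchor to the densest (smallest-span)
feasible candidate run whose midpoint lies within half an inter-anchor
width; ties go to the run closest to the anchor, then leftmost. This is a
documented package choice, not an inferred original algorithm.

Single-colour probes keep 1500 of their 3000 oligos: exactly three
index-defined groups are evaluated (first half, middle half, second half)
and the group with the smallest genomic span is retained, earliest group
on ties — deterministic, and exactly the three groups the design
describes. Paired-colour probes keep all 3000 oligos, alternating odd and
even indices between the two fluorophores so both sub-probes tile the
same window.

Panel summaries follow the convention that reproduces the published
table's Total row: per-chromosome means first, then an unweighted mean
and a sample (n-1) standard deviation across chromosomes; interprobe
distance is the gap between consecutive probe boundaries (end of previous
to start of next) — at the ~28 Mb scale of real gaps the ~0.5 Mb probe
span makes the boundary-vs-midpoint choice negligible, and the boundary
convention reproduces the printed values. "Distance from termini" uses
the probe edge nearest each terminus; the source leaves this ambiguous
and the choice is flagged here.

# Colour scheme optimization

Schemes are drawn uniformly: every band of every chromosome gets one of
the six tokens independently. The optimizer draws `n_candidates = 1000`
schemes (sub-seeded `seed + i - 1`, so enlarging the candidate set never
changes earlier candidates) and keeps the lexicographic best by
(minimum pairwise Levenshtein distance, then sum). The published account
says only "best set based on Levenshtein distance"; we maximize the
*minimum* because it directly encodes unambiguous identification — the
worst pair of chromosomes is the one that causes misassignment.
Distances are computed in the p->q orientation only; orientation
ambiguity on spreads is handled at matching time, not design time.
Whether the original script also penalized within-chromosome colour
repetition is unknown; an optional adjacency constraint exists and is off
by default.

# Oligo assembly

`filter_39mers()` is an explicit, deterministic stand-in for an
alignment-backed mining pipeline: soft-masked bases are excluded, GC and
nearest-neighbor Tm must fall in configurable windows, homopolymers are
capped, and a hash-based k-mer screen (`k = 18`, max count 1) stands in
for genome-wide uniqueness alignment. It is not a re-implementation of
the original mining stack and is documented as such.

Dimerization free energy uses the unified nearest-neighbor dinucleotide
parameters at 37 C (initiation +1.96 kcal/mol), scanning all ungapped
antiparallel registers of the two strands and summing stack terms over
adjacent complementary pairs; the minimum over registers is compared
against the published -9 kcal/mol threshold. The published work names the
threshold but not the parameter set; the parameter table is frozen in
`R/thermo.R`. Compatible-set selection is greedy in input order (the
cited maximal-clique algorithms are replaced; an exact search is provided
for candidate sets up to 30), and role attribution prefers 3'-terminal
G/C dinucleotides (GC clamps) for primers.

Two oligo layouts ship. The four-segment layout (reverse-binding 20 +
homology 39 + forward-binding 20 + handle 20) totals 99 nt; the published
synthesis length is 79 nt. Which segment the real 79mers omit is not
documented, so the default `79nt` layout drops the forward-binding
segment and the layout validator *reports* (never silently fixes) any
declared-total mismatch.

# Signature analysis

Band calling had to be designed from scratch (the original plugin's rule
is not published). The rule, chosen for robustness on uneven FISH
backgrounds:

1. smooth each fluorophore profile with a moving average matched to the
   nominal band width (`smooth_k = 5` samples);
2. estimate background level and scale by iterative sigma clipping
   (median/MAD recomputed on samples below level + 3 x scale, five
   rounds) — necessary because a derivative chromosome's bands can cover
   over a third of its trace, which inflates naive median/MAD estimates;
3. threshold at `bg + 4.5 sigma`; keep above-threshold runs of at least
   3 samples (`min_band_frac = 0.01`); split runs at valleys dipping
   below half the lower flanking peak; trim extents to full width at
   half maximum (threshold-based extents grow with brightness, FWHM
   extents do not);
4. fuse cross-channel bands with >= 50% reciprocal overlap into
   paired-colour tokens; fuse calls with centre separation below
   `merge_frac = 0.02` of the trace (sub-resolution neighbours appear as
   a single band, as the published SSC13 panel's probes 4 and 5 do).

Matching tries both orientations (spread chromosomes have no polarity)
against every reference pattern and reports the minimum edit distance
(the `Err` of the original plugin's output table; its exact metric is
unpublished, token-level Levenshtein is our choice, consistent with the
design objective).

Rearrangement explanation ranks three hypotheses for an anomalous
signature: (a) it is a reference pattern within measurement error; (b)
one token was inserted into a reference pattern (`add`-type material);
(c) it decomposes into a prefix of one donor's pattern plus a suffix of
another's (a derivative chromosome). Decompositions are accepted only at
total edit cost `<= max_err` (default 1) *and* strictly below the best
single-chromosome error (parsimony guard), and a valid insertion beats a
decomposition at equal edit penalty — one breakpoint is a smaller claim
than two. Equal-cost decompositions are common when band colours collide
(with six colours and ~100 bands, identical adjacent tokens across
chromosomes are expected); they are resolved by fitting each candidate's
predicted band fractions (panel geometry with breaks at inter-probe
interval midpoints) to the observed band centres. Breakpoints map to the
gap between the last retained and first lost probe; splits beyond a
terminal probe yield an open interval flagged "reciprocity
undetermined" — exchange distal to the last probe is invisible to the
method.

Spread-level reports demand recurrence: a rearrangement is reported only
when seen in at least `majority_frac = 0.8` of at least `min_spreads = 5`
spreads, and complementary derivative calls merge into one reciprocal
translocation; isolated single-spread near-misses (edit cost <= 1) are
demoted as artefacts (chromosome piling, twisting, folding).

# Segregation model

A reciprocal-translocation heterozygote forms a quadrivalent {A, B, derA,
derB} at meiosis I. All six 2-subsets are enumerated and labelled:
alternate ({A,B}, {derA,derB}; balanced), adjacent-I ({A,derB}, {derA,B})
and adjacent-II ({A,derA}, {B,derB}). Breakpoints live in inter-band gaps
(probe granularity — the method cannot resolve within-band breaks), so
exactly the two alternate classes are balanced, and the two balanced
classes carry identical expected signal multisets — which is why the
classifier merges them into a single `"balanced"` label, mirroring what
FISH can actually distinguish. 3:1 and 4:0 segregations are out of model.
Observed sperm heads are classified to the nearest class by total
absolute difference of signal counts, with a tolerance (default 1) for
decondensation-artefact signal duplication; no published class
frequencies exist for the studied carrier, so the classifier is validated
against the simulator only.

# The synthetic world

The generators state one concrete world; its parameters are not test
dials.

* Candidate 39mers: homogeneous Poisson at 1/150 bp (optional dense
  clusters for snapping tests).
* Profiles: 256 arc-length samples per trace; Gaussian background (mean
  100, sd 10); band amplitude `snr x background_sd` with `snr = 5` as
  default — the lower edge of reliable reading; bands as Gaussian bumps
  at the genomic midpoints of their probes, FWHM 3.5% of the trace
  (a ~0.5 um spot on a chromosome of a few um; floored at 3 rendered
  pixels since the genomic span itself is sub-resolution); a smooth DAPI
  envelope; orientation flipped with probability 0.5 and recorded.
* Spread images: chromosomes as smooth random curves with Gaussian band
  spots, plus the true traces as analyzer input.
* Sperm heads: class mixture draws; signal duplication with probability
  `duplication_prob x decondensation`; head widths around the 5 um
  decondensation optimum.
* The pig-like fixture uses rounded public assembly lengths, the
  published per-chromosome probe counts (configuration, not derived), and
  fixed *irregular* interprobe spacing (+-30% deterministic pattern):
  evenly spaced probes would make distinct derivative decompositions
  geometrically indistinguishable, and real panels are irregular.

What a green round-trip establishes: that band calling, matching,
decomposition and breakpoint mapping invert the stated generative model
at the stated noise level. What it does not establish: performance on
real microscopy (uneven hybridization, autofluorescence, chromosome
piling and twisting, spectral bleed-through between real filter sets),
none of which the generators model beyond an optional linear crosstalk
term (default 0).

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; 1-based closed only on
  explicitly flagged TSV export.
* Ties: densest-1500 group by group order; equal-span windows by anchor
  distance then position; matching by forward orientation then reference
  order; decompositions additionally by positional fit then largest
  retained prefix.
* Empty signatures match the shortest reference at its full length and
  are flagged low-confidence. All-zero profiles yield zero bands, not an
  error. A zero-probe chromosome is an error in summaries; single-probe
  chromosomes contribute no interprobe value.
* All randomness is seed-parameterized; schemes record their seed, and
  the optimizer's sub-seeding makes its score non-decreasing in the
  number of candidates.

# Known limitations

* Chromosome tracing is an input, as in the original plugin; no
  segmentation is attempted.
* Unlabelled material is invisible: terminal additions are reported only
  as "reciprocity undetermined", and sub-band rearrangements are out of
  model.
* The genome-orthogonality screen for 20mers is a k-mer containment
  check, not an aligner; an external alignment report can be supplied
  instead.
* Images are exchanged as plain-text channel matrices; no TIFF reader is
  available in the supported R stack.
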