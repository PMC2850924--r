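---
title: "Detecting small heat shock proteins and slicing their monomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small heat shock proteins and slicing their monomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdscan)
```

## The problem

Small heat shock proteins (sHSPs) are ATP-independent chaperones that bind
misfolded proteins and prevent their irreversible aggregation.  The family
is defined by a single conserved region, the Alpha Crystallin Domain (ACD):
a beta-sandwich of roughly 80-100 residues, delimited here from strand
beta2 to strand beta9.  Outside the ACD, sHSP sequences are heterogeneous:
a variable, often disordered N-terminal region, and a C-terminal region
carrying a short aliphatic anchoring motif (I/V/L-X-I/V/L) that docks into
a neighbouring subunit's hydrophobic groove during oligomerisation.

Because family members share little overall sequence identity while the
ACD is structurally tight, single multiple alignments of thousands of
sHSPs are impractical.  `acdscan` instead implements a structure-seeded,
iteratively enriched profile hidden Markov model: a small, high-quality
seed alignment of reference ACDs (annotated with beta-strand landmarks) is
compiled into a profile HMM, the profile scans a databank, confident hits
are realigned onto the profile's columns and used to rebuild it, and the
E-value acceptance threshold is relaxed one order of magnitude per
iteration.  The final hit set is curated and each monomer is sliced into
N-terminal region, ACD zones, C-terminal Anchoring Module (CAM) and
C-terminal tail.

## The model

### Profile architecture and glocal scoring

The profile is the classic match/insert/delete HMM: match states
`M_1..M_M` carry per-column emission distributions, insert states
`I_0..I_M` emit at background frequencies, delete states `D_1..D_M` skip a
column.  Scoring is *glocal*: every profile column must be visited (as
match or delete) while the alignment is local in the target sequence.
This is a deliberate modelling decision, not a convenience: the ACD is
delimited beta2 to beta9, and a partial domain should never qualify as a
hit, so whole-model alignment is the correct semantics.  Unaligned target
flanks cost nothing because emissions are scored as log2-odds against the
background, making the flanking null and model contributions cancel.

The Viterbi score of a sequence is

    S = log2 [ P(best path) / P_bg(aligned subsequence) ]   (bits)

and the forward score sums over all glocal paths (so forward >= Viterbi
always).  Viterbi is the scorer used for detection and iteration because
its traceback yields the column map -- the explicit correspondence between
profile columns and target positions -- which every downstream slicing
operation consumes.  Ties in the traceback are broken match > delete >
insert for determinism.

### Profile construction

Alignment columns with gap fraction strictly below 0.5 become match
states.  Match emissions are observed counts plus background-proportional
pseudocounts of total weight 20; transitions are counted per row path and
Laplace-smoothed (+1 on each structurally allowed transition).  Sequence
weighting is off by default (Henikoff position-based weighting is
available).  These are conventional, documented choices: the historical
procedure this reimplements used its profile software's standard
parameters, which are not recoverable in detail.

### E-values and calibration

Bit scores are converted to E-values with the Gumbel (type-I extreme
value) tail,

    E = N * (1 - exp(-exp(-lambda * (S - mu)))),

where `N` is the number of sequences scanned.  `mu` and `lambda` are
fitted to the Viterbi scores of `n` random background sequences (default
`n = 200`, length 150): method-of-moments initialisation
(`lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda`) followed by
maximum-likelihood refinement.  Calibration is re-run after every rebuild
with a sub-seed derived from the master seed and the iteration index, so a
whole run is reproducible from one integer.

### The iteration

Thresholds run from `10^-10` to `10^-5`, one order of magnitude per
iteration (at most 10 iterations), followed by a final selection pass at
`10^-5`.  The exponents are configuration, not fixed facts: the source
procedure's exponents were typeset as placeholders and are unrecoverable,
so this package makes them explicit `iterationConfig()` arguments with the
defaults above.  Two further rules are fixed by the method: detected ACD
envelopes longer than 100 residues are discarded before realignment, and
previously accepted sequences are re-evaluated against each new profile
(no grandfathering).  Insert-state residues are kept in the re-training
alignment as dedicated insert columns (`keepInserts = FALSE` discards
them); columns promoted from insert to match inherit the structural label
of the nearest preceding labelled column, which keeps the zone landmarks
propagating through rebuilds.

Curation then keeps records that are not fragments, have protein-existence
evidence level at most 3, and carry exactly one qualifying envelope
(a second non-overlapping envelope is detected by masking the first hit to
`X` and rescanning).

### Architecture slicing

The ACD envelope is `[acd_start, acd_end]`; the N-terminal region precedes
it and the C-terminal region follows it, so the three regions partition
the monomer by construction.  Inside the ACD, the landmark map divides
profile columns into the beta2-beta5 zone, the L57 loop and the
beta7-beta9 zone.  Every envelope residue is assigned to exactly one zone:
matched residues to their column's zone, inserted residues to the zone of
the preceding column (boundary insertions therefore go to the *preceding*
zone -- a deterministic rule that preserves zone-length additivity);
deletions contribute zero length.

The anchoring motif is searched in the C-terminal region with
`[IV].[IV]` or the extended `[IVL].[IVL]` regular expression.  When
several occurrences exist the *leftmost* wins: the source analysis did not
state an occurrence rule, and leftmost is deterministic and yields the
shortest CAM, matching the tight CAM length distribution seen in the
family (an alternative that picks the occurrence with CAM length nearest
14 can be selected in code).  The CAM runs from the residue after the ACD
to the motif's last residue; the remainder is the C-terminal tail.  The
extended motif defines the CAM; whether the basic `[IV].[IV]` form is also
present is reported separately so both motif statistics come from one
pass.  Zone hydropathy is the mean Kyte-Doolittle index, with `X`
contributing zero.

### Groups and logos

Records are grouped by lineage (Metazoa, Viridiplantae, Fungi, Archaea,
other Eukaryota), and bacteria are split into the two described classes by
best global-alignment percent identity against per-class reference sets
(BLOSUM62, gap open 10, extend 1, threshold 40% -- all configurable,
because the historical class membership and cutoff are unstated; the
packaged reference TSV is synthetic and user-replaceable, so group-level
class sizes are approximate by design).  Sequence logos are computed
gap-aware: a deleted column counts as an explicit 21st symbol, information
content is `I(c) = log2(21) - H(c)`, and letter heights `freq * I(c)` are
drawn for the 20 amino acids only.  The small-sample correction is off by
default (the modified logo tool this mirrors did not document its fate);
`correction = "smallsample"` subtracts `20 / (2 ln 2 n)`.

## The synthetic benchmark

Real databank reproduction requires downloading millions of sequences, so
the package ships a generator whose defaults are the study conditions used
by the tests and the acceptance script:

* The packaged seed is a deterministic synthetic 12-row, 83-column
  ungapped alignment (zones 38 / 14 / 31) carrying the family's canonical
  conservation patterns: the P-G doublet in loop L34, a charged L57 loop,
  F-X-R in strand beta7, and a D/E-L close to strand beta9.  It stands in
  for a curated structural seed and is clearly labelled synthetic.
* ACDs are sampled from a *sharpened* profile of that seed (emission
  pseudocount weight 1, no transition smoothing), so sampled domains
  follow the seed's exact ungapped geometry -- every planted ACD spans the
  83 columns with zone lengths 38/14/31, like the alpha-crystallin
  subfamily whose ACD length is exactly 83 residues.  All sequence-level
  noise comes from the per-site mutation rate (default 0.2).  This choice
  makes the architecture checks sharp: planted boundaries and CAM lengths
  are exact by construction, so any disagreement is attributable to the
  detector, not to the fixture.
* Region lengths: N-terminal ~ truncN(53, 35, min 0) and CAM ~
  truncN(14, 3, min 3) follow the family statistics; the tail uses
  truncN(5, 4, min 0), consistent with most tails being shorter than 5
  residues.  Lengths are rounded to the nearest integer and floored at
  the stated minima.
* The CAM is written so the planted motif is provably leftmost: interior
  CAM residues are drawn from the background *excluding* I, V and L, and
  the final three residues realise the motif (flanks I/V/L with weights
  .55/.30/.15, centre drawn from background).
* Metadata defaults emulate the curated study set (no fragments,
  existence levels 1-3); `fragmentFraction` and `existenceProbs` exist to
  exercise curation, and the group mix follows the family's taxonomic
  proportions (animals .15, plants .18, bacteria .58, fungi .03,
  archaea .04, other .02).
* Decoys are background-only sequences with matched length structure.

What passing tests on this generator do *not* show: robustness to the
length and indel heterogeneity of real ACDs (real zone lengths vary by
group; the default generator holds them fixed), to fragmented or
low-evidence database entries beyond the curation rules, or to
phylogenetic correlation between family members (sampled sequences are
independent draws).  The bacterial class assignment is only as meaningful
as the reference sets supplied.

## Numerical choices and degenerate inputs

* Probability-zero transitions score `-Inf`; the scorer guards them and a
  sequence with no admissible glocal path returns `-Inf` rather than an
  error.  Paths that emit nothing are excluded.
* `X` residues score as background (zero log-odds) in both match and
  insert states and contribute zero to hydropathy; they are skipped in
  emission counting and logo counts.
* Emission and transition groups must renormalise to 1 within `1e-9`
  (class validity); the Gumbel fit refuses score samples with degenerate
  variance or fewer than 100 points.
* E-values saturate at the double-precision floor of
  `1 - exp(-x) ~ x`; scores far above `mu` report `E = 0`.
* All coordinates are 1-based inclusive everywhere (sequence positions
  and alignment columns); the BED export converts to 0-based half-open
  explicitly.

## Problem sizes used by the packaged checks

The test-suite benchmark and the acceptance script run the full pipeline
on a 50-positive + 50-decoy databank (mutation rate 0.2), with
calibration samples of 200 random sequences of length 150 per iteration
and six enrichment iterations plus the final pass.  These sizes give
stable statistics for a desk-scale benchmark while keeping a full run in
seconds; larger databanks only change the `dbSize` factor in E-values.

## A worked run

```{r pipeline}
seed <- syntheticSeedAlignment()
ds <- generateDataset(syntheticSeedProfile("sampling"),
                      synthesisParams(seed = 42L))
run <- iterateProfile(seed$alignment, seed$annotation, ds$bank,
                      config = iterationConfig(), seed = 42L)
run$trace
curated <- curateHits(run$hits, ds$bank)
arch <- annotateArchitecture(curated, ds$bank, run$profile)
head(arch[, c("accession", "nterm_len", "acd_len", "l57_len",
              "cam_len", "tail_len")])
```

```{r stats}
lengthDistribution(arch$acd_len)$mode
lengthDistribution(arch$cam_len)$mean
logo <- logoCounts(curated, ds$bank, run$profile)
round(logo@info[1:10], 2)
```

## Known limitations

* Single-domain reporting: one best envelope per sequence; additional
  envelopes only set the multi-ACD flag (they are not emitted as separate
  hits), which suffices for curation but not for tandem-ACD architecture
  analysis.
* The N-terminal region is delineated but not sub-annotated; it resists
  meaningful profile alignment.
* Plan7-style multi-hit scoring, HMMER binary file compatibility and DNA
  alphabets are out of scope; profiles serialise to a versioned JSON text
  format instead.
* E-value calibration assumes i.i.d. background residues; compositionally
  biased targets will have optimistic E-values, as with any
  Gumbel-calibrated profile search.
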