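# acdscan

Detection of small heat shock proteins (sHSPs) and structural annotation
of their monomers with an iteratively enriched, structure-seeded profile
hidden Markov model.

sHSPs are ATP-independent chaperones that bind misfolded proteins under
stress.  The family's hallmark is the Alpha Crystallin Domain (ACD), a
beta-sandwich of ~80-100 residues delimited from strand beta2 to strand
beta9; the flanking N- and C-terminal regions are heterogeneous, and the
C-terminal region carries a short aliphatic anchoring motif
(I/V/L-X-I/V/L) used in oligomer assembly.  `acdscan` is for sequence
analysts who want to find complete ACDs in a protein databank, delineate
each monomer's architecture, and summarise the family group by group.

## The method

1. **Seed profile.**  A structure-annotated seed alignment of reference
   ACDs (Stockholm with a `#=GC ACD_elements` landmark line, or aligned
   FASTA plus a landmark TSV) is compiled into a profile HMM: match
   columns by gap fraction < 0.5, background-proportional emission
   pseudocounts (total weight 20), Laplace-smoothed transitions.
2. **Glocal scoring.**  A sequence is scored by aligning the *entire*
   profile (deletions allowed) to one contiguous subsequence — partial
   ACDs never match.  The Viterbi bit score is
   `S = log2 P(best path) / P_bg(aligned subsequence)`; a forward scorer
   is available.
3. **E-values.**  Scores of random background sequences are fitted with a
   Gumbel law (moments + maximum likelihood), giving
   `E = N (1 - exp(-exp(-lambda (S - mu))))` for a databank of `N`
   sequences.
4. **Iterative enrichment.**  Scan at threshold `10^-10`, keep envelopes
   of at most 100 residues, realign hits onto profile columns, rebuild
   and recalibrate, then relax the threshold one order of magnitude per
   iteration up to `10^-5`, and finish with a curation pass (no
   fragments, protein-existence level <= 3, exactly one ACD envelope).
5. **Architecture.**  Each monomer is sliced into N-terminal region, ACD
   zones (beta2-beta5 / L57 loop / beta7-beta9, via the landmark map and
   the Viterbi column map), the C-terminal Anchoring Module (from the ACD
   end to the end of the leftmost anchoring motif) and the C-terminal
   tail; per-zone Kyte-Doolittle hydropathy is reported.
6. **Group statistics.**  Taxonomic grouping, bacterial class A/B
   assignment by global-alignment identity, gap-aware sequence logos
   (gap as an explicit 21st symbol, `I(c) = log2(21) - H(c)`), length
   distributions and annotation-overlap percentages.

A deterministic synthetic benchmark generator (planted ACDs, exact CAM
lengths, ground-truth tables) makes every stage testable without any
download.

## A worked example

```r
library(acdscan)

seed <- syntheticSeedAlignment()                 # packaged synthetic seed
ds   <- generateDataset(syntheticSeedProfile("sampling"),
                        synthesisParams(seed = 42L))   # 50 + 50 databank
run  <- iterateProfile(seed$alignment, seed$annotation, ds$bank,
                       config = iterationConfig(), seed = 42L)
run$trace
#>   iteration exponent threshold nHits nNew checksum
#> 1         1      -10     1e-10    48   48 7b28d8fd
#> 2         2       -9     1e-09    49    1 254b8d56
#> 3         3       -8     1e-08    50    1 4ded1214
#> 4         4       -7     1e-07    50    0 4ded1214
#> 5         5       -6     1e-06    50    0 4ded1214
#> 6         6       -5     1e-05    50    0 4ded1214

curated <- curateHits(run$hits, ds$bank)
arch <- annotateArchitecture(curated, ds$bank, run$profile)
nrow(curated); mean(arch$acd_len); mean(arch$cam_len)
#> [1] 50
#> [1] 83
#> [1] 14.54
```

The trace shows the enrichment converging: 48 of the 50 planted domains
pass the strictest threshold immediately, and the remaining two enter as
the threshold relaxes; no background decoy ever qualifies.  Each curated
monomer is then sliced — the mean ACD length of 83 residues reproduces
the planted alpha-crystallin-like geometry (zones 38/14/31), and the mean
CAM length ~14.5 matches the planted truncated-normal CAM lengths
exactly, record by record (`arch$cam_len` vs the generator's truth
table).

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/acdscan synth   --n-pos 50 --n-neg 50 --seed 42 --out fixtures/
Rscript inst/scripts/acdscan iterate --seed-aln inst/extdata/synthetic_seed.sto \
    --db fixtures/db.fasta --meta fixtures/meta.tsv --seed 42 --out run/
Rscript inst/scripts/acdscan annotate --profile run/profile.json \
    --hits run/hits.tsv --db fixtures/db.fasta --out arch.tsv
```

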