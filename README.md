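# riboqueue

Codon-level analysis of ribosome profiling (ribo-seq) data, built around
three questions that arise when a stress slows the decoding of a specific
codon:

1. **Which codons are decoded slowly?** Per-codon *normalized ribosome
   occupancy* — the fraction of a gene's ribosome-protected fragments (RPFs)
   whose A-site sits on a codon identity, divided by that identity's
   compositional frequency in the gene.
2. **Do ribosomes queue behind the slow codon?** *Metagene density
   profiles* around every occurrence of a target codon, with peak calling:
   stalled ribosomes appear as a peak at offset 0, and queued ribosomes as
   peaks at one-footprint spacings (−10, −20 codons for 30-nt footprints).
3. **Does the slowdown show at the gene level?** *Translation efficiency*
   (TE; RPF counts normalized by mRNA counts) changes between conditions,
   binned by a gene's content of the slow codon.

The motivating biology is the fission-yeast oxidative-stress response, where
H₂O₂ exposure lowers charged tRNA-Trp levels, ribosomes stall on the single
tryptophan codon (UGG) and up to three ribosomes stack behind the stall; the
package ships a stochastic footprint simulator that reproduces exactly this
situation with known ground truth, so every stage of the pipeline is
testable at desk scale.

## The statistics

For one coding sequence, over the eligible codon positions (1-based codon
index > 90, stop codon excluded):

- *f(c)* = RPFs whose A-site is on codons of identity *c* / total eligible
  RPFs,
- *a(c)* = positions with identity *c* / total eligible positions,
- occupancy *o(c) = f(c)/a(c)*, so Σ_c a(c)·o(c) = 1 per gene.

Profiles average *o(c)* across genes (unweighted), giving a 61-entry table
(one per sense codon) where 1 means average dwell time and >1 slow decoding.
A-sites come from the footprint 5′ end plus a per-read-length offset (15 nt
for 27–31-nt reads, calibratable from initiation metagenes). Metagene
profiles normalize each occurrence window by its mean before averaging, so
highly expressed genes do not dominate. TE is `log2((rpf + 0.5)/(rna + 0.5))`,
median-centred; gene-list overlaps use the one-sided hypergeometric
(Fisher) test.

## Worked example

Simulate the stress and control conditions (200 genes, 10⁶ footprints
each), then ask the three questions:

```r
library(riboqueue)
library(dplyr)

stress  <- simulate_experiment(make_scenario("h2o2",    overrides = list(seed = 42)))
control <- simulate_experiment(make_scenario("control", overrides = list(seed = 42)))

tr_s <- build_count_tracks(stress$footprints,  default_offsets(), stress$transcripts)
tr_c <- build_count_tracks(control$footprints, default_offsets(), control$transcripts)

ratio <- occupancy_ratio(occupancy_profile(tr_s, stress$transcripts),
                         occupancy_profile(tr_c, control$transcripts))
ratio |> arrange(rank) |> head(3)
#>   codon amino_acid occupancy_stress occupancy_control log2_ratio  rank
#> 1 TGG   W                     6.64              0.988     2.75       1
#> 2 CAG   Q                     0.904             0.959    -0.0861     2
#> 3 GTC   V                     0.909             0.976    -0.102      3
```

TGG (tryptophan) stands alone: its occupancy rises almost 7-fold under
stress (log2 ratio 2.75) while every other codon stays near 1 — the
signature of codon-specific stalling.

```r
mg    <- metagene_profile(tr_s, stress$transcripts, "TGG")
peaks <- detect_peaks(mg, min_ratio = 1.5)
filter(peaks, passes_threshold)
#>   position height passes_threshold
#> 1        0   6.77 TRUE
#> 2      -10   3.03 TRUE
#> 3      -20   1.60 TRUE
queue_summary(peaks)
#> [1] 3
```

RPF density piles up on the UGG codon itself (offset 0) and at 10 and 20
codons upstream — trailing ribosomes stacked at one-footprint (30 nt = 10
codon) spacing behind the stalled one; `queue_summary()` reads this as a
stack of three ribosomes. Under the `"h2o2_trp"` scenario (tryptophan
supplementation rescues tRNA charging) both the UGG excess and the upstream
peaks disappear.

`autoplot()` methods draw the occupancy and metagene profiles;
`compute_te()`, `te_change()`, `bin_by_content()` and `bin_trend()` carry
the TE-by-Trp-content analysis, and `overlap_test()` the gene-list
enrichment test.

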