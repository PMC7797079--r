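---
title: "Methods: codon occupancy, ribosome queuing and TE analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon occupancy, ribosome queuing and TE analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and numerical choices behind
`riboqueue`, in the spirit of a methods section: what each statistic
assumes, which knobs matter, and what the synthetic data generator does and
does not emulate.

## Coordinate conventions

All footprint coordinates are 0-based half-open nucleotide positions
relative to the first nucleotide of the start codon (the natural BED frame
for transcript-coordinate alignments); codon indices are 0-based
internally. The one place a 1-based convention appears is the occupancy
cutoff, which is stated as "codons after 90" counting the start codon as
codon 1: internally this is codon index >= 90. Transcript-coordinate
footprints are strandless by construction (mRNA sense); a "-" strand BED
row is dropped with a warning, or raises in strict mode.

A CDS record must start with ATG, end with a stop codon, contain no
internal stop and have length divisible by 3. The default validation
policy is skip-with-warning, because real annotation sets contain
stragglers; `strict = TRUE` escalates to errors and is what the test suite
uses.

## A-site assignment

The reported frame is the ribosomal A-site (the codon being decoded). The
default offset is 15 nt from the 5′ end for 27–31-nt reads — the canonical
12-nt P-site offset plus one codon — applied as a fallback to other
lengths where it fits inside the read. `calibrate_offsets()` recovers
per-length offsets from initiating-ribosome reads: the modal 5′-end
distance to the start codon puts the P-site on codon 0, so the A-site
offset is that mode plus 3 nt. Ties take the smaller offset
(determinism); length classes with fewer than 500 usable reads fall back
to the default table. Note that calibration reads necessarily begin
upstream of the ATG, so the calibration routine accepts negative start
coordinates that the BED loader would reject.

Reads whose A-site would land on the stop codon or outside the CDS are
*unassigned* — a value, not an error — and tallied so that assigned +
unassigned always equals the input read count. Reads assigned to the start
codon are kept; the occupancy cutoff removes them downstream.

## Normalized codon occupancy

Per gene, over eligible positions (codon index > cutoff, stop excluded):
`f(c)` is the fraction of eligible A-site reads on codon identity `c`,
`a(c)` the fraction of eligible positions with identity `c`, and
`o(c) = f(c)/a(c)`. The identity `sum_c a(c) * o(c) = 1` holds exactly per
gene (tested at 1e-9). Codons absent from a gene's eligible region are
*undefined* for that gene, not zero — a 0/0 must not contaminate the
average.

Tunable parameters:

* `codon_cutoff` (default 90 codons): excludes the initiation ramp, where
  elongation speed is atypical. The plain reading — strictly greater than
  90, start codon counted as 1 — is used, so a 100-codon gene contributes
  positions 91..99.
* `min_gene_rpf` (default 64 reads): a gene's `f` is a multinomial
  estimate; with fewer than ~64 eligible reads its per-codon occupancies
  are noise-dominated. The value is a package choice (configurable), set
  to bound per-gene relative error at roughly 1/8.

Averaging across genes is **unweighted** (each contributing gene counts
once); a read-weighted pooled mode (`weighted = TRUE`) exists for
sensitivity analysis. Whether the original codon-enrichment averages were
unweighted or pooled is ambiguous in the literature this follows; both are
implemented and unweighted is the default because it matches a
per-sequence-then-average description and is robust to expression
outliers.

## Metagene profiles and peak calling

For every occurrence of a target codon whose ±`window` (default 30 codons)
window lies inside the CDS (stop excluded), the A-site counts are
normalized by the window mean and averaged position-wise. Per-occurrence
normalization stops high-expression genes from dominating the average; an
expression-weighted mode is deliberately absent because its behaviour is
dominated by a handful of genes. Occurrences are accounted exhaustively:
total = used + boundary-dropped + zero-read-dropped. Occurrences of the
target codon inside another occurrence's window are retained (each is its
own center); an isolation filter exists for sensitivity checks, since
excluding them would bias against codon-dense genes. The occupancy cutoff
is *not* applied to metagene windows: it belongs to the codon-usage
statistic only.

Peak calling: a position is a candidate if it is a strict local maximum
within ±2 codons; candidates are visited from highest density down and
called when density >= `min_ratio` (default 1.5) times the median density
over the search range, masking ±2 codons around already-called peaks so a
tall stall peak does not inflate the background. Ties in the local-maximum
test fail it (a plateau is not a peak); an all-equal profile yields no
candidates. `queue_summary()` counts consecutive peaks at
0, −w, −2w, ... (±1 codon) and returns the inferred stack size; a peak at
−w without one at 0 is not a queue.

## The synthetic footprint generator

The generator is *occupancy-weighted positional sampling*, not a
mechanistic TASEP simulation: the evidence it must reproduce is density
(peaks and enrichments), not kinetics, and positional sampling keeps every
expectation in closed form for test oracles.

* A gene receives footprints in proportion to `expression × total codon
  dwell` — the steady-state ribosome load. Under uniform dwell this
  reduces to expression × length; under stalling it makes Trp-rich genes
  gain apparent TE, which is the gene-level signature the TE-binning
  analysis looks for (a slow codon increases the number of ribosomes per
  transcript, not protein output).
* Within a gene the A-site codon is drawn proportionally to per-codon
  dwell over non-stop codons; stop codons never receive A-site footprints
  (the occupancy statistic covers the 61 sense codons).
* The 5′ end is placed so the A-site (under the default offset table)
  falls on the drawn codon; draws whose 5′ end would leave the CDS are
  skipped and counted, never resampled — so emitted + skipped equals the
  requested read number. This depletes roughly the first 5 and last ~10
  codons, a crude stand-in for real coverage edge effects; it also means
  closed-form expectations that ignore boundaries are only approximate
  near the CDS ends (the tests use exact enumeration including the skip
  rule where precision matters).
* Queuing is an explicit emission rule: each primary footprint on the
  stall codon seeds a queued footprint exactly one ribosome width
  (default 10 codons = 30 nt) upstream with probability `q`, and that one
  seeds a second with probability `q` again (geometric decay `q^k`,
  capped at depth 2 — consistent with stacks of at most three ribosomes).
  Spacing follows the footprint length: a 27-nt fixed-length scenario
  gives 9-codon spacing.
* Footprint lengths: discrete triangular on 26–30 nt peaking at 30 (90%
  of mass) plus a uniform 17–25-nt tail (10%), emulating a gel-purified
  ~17–30-nt fragment pool with canonical 30-nt protection.
* Expression is lognormal (sdlog 1) unless fixed explicitly — a standard
  stand-in for the heavy-tailed mRNA abundance distribution.

Scenario presets encode the study conditions: `control` (uniform dwell, no
queuing), `h2o2` (TGG dwell ×8, `q = 0.3`, depth 2) and `h2o2_trp`
(identical to control — the charging rescue). The stall magnitude and
queue probability are not measured quantities; they are preset so that the
stall peak, the −10/−20 peaks and the occupancy excess are unambiguous at
10⁶ reads, and are fully configurable. Default problem sizes (200 genes of
250–600 codons, ~2% TGG, 10⁶ footprints per condition) are the package's
chosen desk-scale study conditions; the TE-trend analyses run at 5×10⁵
reads per condition, where the planted content-dependent effect is still
far above counting noise.

What the generator does **not** emulate: UTRs and uORFs, initiation ramps,
sequencing error, PCR duplicates/UMIs, multimapping, disome (57-nt)
classes, positional biases from ligation or nuclease preference. Passing
tests therefore demonstrate the correctness of the pipeline's arithmetic
and its sensitivity under idealized sampling — not robustness to every
artefact of real libraries.

## Seeding and reproducibility

One master seed per scenario; per-stage child seeds (transcriptome,
expression, footprints, RNA counts) are derived deterministically from it,
so each stage is individually reproducible and two runs with the same seed
are byte-identical. All seeds stay below 2³¹.

## TE, binning and the trend test

TE uses the simple pseudocounted ratio `log2((rpf + 0.5)/(rna + 0.5))`;
0.5 keeps zero-count genes finite while flagging them. Differential-TE
inference (negative-binomial modelling) is out of scope — the ratio feeds
descriptive analyses only. TE changes are median-centred; the median of a
centred column is exactly 0 for odd n (mean-of-middle-two convention for
even n).

`bin_by_content()` uses the sense-codon count (start included, stop
excluded) as denominator. Bin 0 is exactly the zero-content genes and may
legitimately be empty for codon-rich transcriptomes; the trend statistic
never uses it, so `bin_trend()` errors only when a *nonzero* bin is empty.
Ties in content are broken by gene id — deterministic, and immaterial at
realistic gene counts.

The trend statistic is the Spearman correlation between bin index (1..k)
and bin median TE change, with a two-sided permutation p-value (gene-to-
bin assignment permuted, 999 permutations, seeded). In the test suite the
null check runs over five seeds; significance there is judged at a
family-wise 0.05 level (Bonferroni: per-seed 0.01), since five independent
null tests at 0.05 each would be expected to fail spuriously about one
time in four.

`overlap_test()` is the one-sided hypergeometric upper tail
(`P(X >= overlap)`), identical to the one-sided Fisher exact test on the
2×2 membership table; the zero-overlap case correctly returns 1.

## Known limitations

* Occupancy is not corrected for queuing: a queued ribosome inflates the
  occupancy of whatever codon sits one footprint upstream of a stall.
  This is faithful to the descriptive statistic, but means occupancy and
  dwell time diverge in heavily queued regimes.
* The A-site offset is codon-accurate only if the true offset is within
  ±1 nt of the configured one *within* a codon; an offset wrong by a full
  codon shifts every profile by one position. Calibration from initiation
  metagenes is provided for exactly this reason.
* Single-gene pause-site calling (as opposed to codon-identity metagenes)
  is out of scope; per-gene tracks can be exported, but no per-site
  statistics are computed.
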