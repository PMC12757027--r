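---
title: "castworks: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{castworks: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

castworks implements the computational side of a host-factor study of
CRISPR-associated transposase (CAST) genome editing in Gram-negative
bacteria: calling activators and inhibitors of integration from a
differential RB-TnSeq screen, profiling integration outcomes from Nanopore
long reads, designing safe-site guides, and quantifying editing efficiency
from serial-dilution spot plates. Every analysis step is paired with a
synthetic-data generator that plants known truth, so the whole pipeline is
testable by parameter recovery. This vignette explains the models behind
each step, the parameters that matter, and the choices made where the
design was genuinely open.

## The screen model

The screen contrasts a CAST condition against a *mariner* transposase
control (controlling for delivery and selection effects unrelated to CAST
itself), in two independently selected screens, over a barcoded
transposon-mutant library.

**Strain fitness.** For each barcoded mutant,
`log2((post + c) / (t0 + c))` with pseudocount `c = 1`, median-centred over
strains with sufficient time-zero counts so a typical (null) strain scores
0. The upstream published fitness pipeline for RB-TnSeq uses a
weighted-variance model with several normalisations; castworks deliberately
implements only the parts the downstream decision rule consumes — pseudocount
log-ratios, median centring, and central-region gene averaging — and makes no
claim of numerical equivalence with that pipeline. The decision rule operates
on fitness *differences* thresholded at 1, which are insensitive to the
refinements omitted.

**Gene fitness.** Unweighted mean over *usable* strains: time-zero count at
least `min_t0 = 3` and insertion within the central window
`[0.1, 0.9]` of the gene (insertions near gene ends often leave function
intact and dilute the signal). A gene with no usable strains in a screen is
"nd" (no data) and is excluded from calling in that screen — this reproduces
how a gene absent from the starting library in one screen is reported
separately rather than called.

**Candidate calling.** Per screen, replicate gene fitnesses are averaged
within condition and the mariner mean is subtracted from the CAST mean. A
gene is called an inhibitor when this differential exceeds +1 in *both*
screens, an activator when below −1 in both (mutating an inhibitor helps
CAST, so positive differentials mean inhibition of CAST by the wild-type
gene). The two-screen consistency requirement is the main false-positive
control; the null-screen property test measures the empirical false-positive
rate and checks it decreases with sequencing depth.

**What the generator emulates.** `make_screen_design()` /
`simulate_barseq()` model a 3,744-gene library with 10 barcoded insertion
mutants per gene by default (the real library has ~40; 10 keeps the
per-gene central-window strain count comfortably above zero at desk scale),
lognormal time-zero abundance variation, per-screen *independent*
`N(0, 0.3)` null CAST effects (two screens share biology but not their
noise; a shared large null effect would defeat the consistency rule by
construction), exactly neutral mariner effects, negative-binomial counts
(size 50 — mild overdispersion, a choice, since count tables alone do not
pin down a noise model), and optional per-screen dropout genes with zero time-zero counts.
Planted hits use effect magnitudes uniform in [2, 4]: a hit is defined by
exceeding 1 in both screens, and hits that replicate across screens sit
well beyond the threshold, so the planted magnitudes emulate a clean hit
set rather than borderline cases. Not emulated: strain-level position-dependent effects,
PCR jackpotting, cross-contamination, or correlated replicate structure —
recovery results on synthetic data bound what the pipeline can do, not what
any particular wet experiment achieves.

## Long-read insertion profiling

The filter chain applies the analysis rules in order, and its counts are
asserted monotone on every run:

1. **Read QC** — mean Phred > 20 and length ≥ 150 bp.
2. **Analysis subset** — length > 10,000 bp, so a read can span the full
   cargo plus junction context.
3. **Cargo location** — the full transposon is locally aligned to the read
   (both strands); reads covering less than 80% of the annotated right-end
   interval are dropped. The right-end interval is taken from the vector
   annotation — the rule needs a reference length, and making it explicit
   vector metadata avoids guessing one.
4. **Flank classification** — the cargo-proximal 600 bp (configurable) of
   each flank is aligned to the reference genome and to the plasmid
   backbone; a flank is `genomic`/`plasmid` when > 100 bp maps to that
   reference, `both` when both do, `unmapped` otherwise. Capping the flank
   keeps alignment cost linear in read count and does not affect any rule
   downstream: the 100-bp threshold, the junction coordinate (read from the
   cargo-proximal end) and cointegrate detection (backbone adjacent to
   cargo) all live inside the capped window.
5. **Insertion call** — the junction is the first genomic base downstream
   of the inserted sequence, mapped from the genomic flank's alignment
   endpoint, preferring the PAM-proximal flank. Orientation is RL when the
   transposon right end is the PAM-proximal end. The offset counts the
   bases between the protospacer 3′ end and the insertion gap — the
   "downstream of the PAM/guide" distance, measured from the protospacer 3′
   end, the convention under which the expected integration distance is
   ~49 bp. On-target means the junction falls within a 100-bp window on the
   PAM-downstream side of the target 3′ end (one-sided by default; a
   symmetric ±100 window is available via `window_mode`, since either
   reading of a “100-bp window of the target 3′ end” is defensible).
6. **Cointegrate** — read-level: any plasmid-bearing flank contiguous with
   the cargo (the duplicated-transposon/backbone structure places backbone
   directly next to one transposon copy). When reads carry clone
   identifiers (always true for simulated data), a clone-level estimate by
   majority vote per clone is reported alongside: a cointegrate rate can
   be quoted per read or per clone, and the two differ when clones
   contribute uneven read numbers.

**Alignment.** All span decisions use an internal seed-and-extend local
aligner (exact-word seeds on clustered diagonals, banded affine-gap
Smith-Waterman extension; BLASTn-like scoring: match +2, mismatch −3, gap
open 5, extend 2). This removes any external-binary dependency; the test
suite holds its scores and accept/reject decisions to an independent full
Smith-Waterman oracle (`Biostrings::pairwiseAlignment`) on randomized
instances. Ties between equal-scoring placements resolve to the leftmost
subject coordinate.

**What the read generator emulates.** Events are iid: on-target events at a
configurable offset downstream of the protospacer 3′ end (point mass at
49 bp by default, with a Gaussian `offset_sd` available; no particular
empirical spread is claimed),
orientation RL/LR at 0.9/0.1, cointegrates carrying
transposon–backbone–transposon, off-target events uniform outside the
window. Reads span the junction with ≥ 500 bp flanks, on a random strand,
with iid errors (60% substitutions, 20% insertions, 20% deletions) and flat
quality strings. Not emulated: homopolymer-dependent Nanopore error
structure, chimeras, fragmented reads that only partly span the cargo.
Recovery at 5% error (orientation, cointegrate and on-target labels; modal
offset exact) therefore demonstrates the pipeline's rules are correctly
implemented and robust to generic indel noise — not performance on any
particular flow cell.

## Safe-site and guide design

Safe sites are intergenic regions between converging genes (`+` then `-`)
of 300–600 nt, excluded when overlapping mobile-element or ncRNA masks or
flanked by essential genes. Mask and essentiality information is consumed
as user-supplied intervals: the original selection consulted curated
databases by hand, which is out of scope here, and every rejected site is
kept in the output with its exclusion flags for audit.

Within a site, every 5′-CN-3′ PAM on either strand yields the 32 nt
immediately 3′ of the PAM as a candidate protospacer. Filters: GC within
40–60%; the predicted insertion locus — 45–55 bp downstream of the
protospacer 3′ end, bracketing the ~49 bp expected distance — must stay
inside the intergenic region and clear of terminator masks.

Off-target risk is scored by the same seed-and-extend aligner at word size
4 with no complexity filtering, both strands, the on-target locus excluded.
E-values are *not* reproduced: on genomes this small the e-value is
monotone in the raw score, so ranking uses (seed-region matches of the best
hit, best hit score), ascending. The seed region is the 10 PAM-proximal
nucleotides; its match count is computed on the best hit's seed diagonal
(ungapped), which is exact whenever the seed region aligns without indels —
in particular for the verbatim-duplicate cases the rule exists to catch.
Hits are counted above a score floor of 32 (a 16-bp perfect core), a
documented default since no floor is prescribed. Full ties rank by
protospacer sequence, then genomic coordinate: a sequence tie-break keeps
the selected guide set invariant under reverse-complementing the genome,
which a coordinate-only tie-break cannot. Three guides per accepted site
are returned, and an audit pass re-checks PAM, length, GC and locus
containment on everything emitted.

## Efficiency statistics

**Titers.** Each countable spot (counts within [3, 30] by default; lawns
excluded) estimates `count × dilution factor × (1000 / volume µl)` CFU/ml;
spots are pooled as total colonies over total plated volume. This pooled
form is the standard plate-count estimator and is preferred over averaging
per-spot estimates, which is biased upward by the inclusion-truncation of
spots near the countable minimum. All-zero series are censored at the
detection limit — one colony at the least-diluted plating, which for 10 µl
spots of a 10³ dilution is 10⁵ CFU/ml — and censored values propagate as
upper bounds, never as imputed zeros (exports flag them explicitly).

**Fold changes and testing.** Efficiency is transconjugant over total
titer; each treatment is normalised to the same-day control (day-to-day
efficiency variation makes cross-day pooling invalid, so a missing same-day
control is an error, never silently pooled); significance against the
normalised control uses a one-sample, one-tailed t test with hypothetical
mean 1, the direction chosen by the prior hypothesis (activator or
inhibitor).

**Fold-recovery conditions.** The recovery experiment
(`experiment_fold()`) plants a 55.2-fold treatment effect over three
simulated days at the study's scale: control efficiency 10⁻³ of a
2.5×10⁹ CFU/ml total population. One design choice deserves
justification: a 55.2-fold estimate with a replicate spread of ±6.9 (a CV
of about 12%) implies per-titer counting noise of a few percent, i.e. of order 10² colonies informing each titer. Single ≤30-colony
spots cannot deliver that (four ~25-colony counts alone give a per-day fold
CV above 20%), so the emulation titers each sample from duplicate spots
over a 10²–10⁸ series counted up to 300 colonies per spot. With that
counting effort the recovered mean fold is unbiased to within ~2% with a
seed-to-seed SD of about 3 folds, consistent with the reported spread. The
package default countable range stays (3, 30).

## Numerical conventions and degenerate inputs

* All internal coordinates are 0-based half-open; FASTA/GFF3 and reported
  junctions are 1-based per their standards.
* Every generator takes a `seed` and is byte-identical under it (RNG state
  is scoped with `withr`, never leaked).
* Empty call sets summarise to an explicit empty sentinel, not NA
  arithmetic; zero-variance or n < 2 t tests, infeasible genome
  configurations, pairing without a same-day control, and totals below
  detection are explicit errors.
* Alignment tie-breaks: leftmost subject coordinate; guide-ranking ties:
  protospacer sequence, then coordinate.

## Problem sizes

The bundled experiments run at desk scale, chosen so the full suite and the
acceptance script each complete in minutes on one core: 3,744 genes × 10
strains at 10⁶ reads per sample for the screen; 500 reads (guide-directed
run) and 1,000 reads (cointegrate run) of ~15 kb at 5% error for the
profiler; 50-kb genomes for design; three days of duplicate spot series for
the efficiency statistics. All are parameters, not limits.

## Known limitations

* The simplified fitness model is a documented substitute for the full
  published RB-TnSeq pipeline, adequate for thresholded differentials.
* The read simulator's error model is generic iid; Nanopore-specific error
  structure is out of scope, so error-rate robustness results transfer only
  qualitatively.
* Off-target seed-match counting is ungapped along the best hit's diagonal.
* Essentiality, ncRNA, mobile-element and terminator annotations must be
  supplied; no databases are queried.
* Cointegrate detection relies on backbone sequence adjacent to the cargo
  within the analysed flank window; rearranged cointegrates beyond that
  window would be missed (none are simulated).
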