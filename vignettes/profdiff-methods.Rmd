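---
title: "Calling differential ChIP-seq enrichment from coverage profiles"
author: "profdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential ChIP-seq enrichment from coverage profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profdiff)
```

## The problem

A transcription factor tagged and immunoprecipitated in one genotype
("case", e.g. a tagged-factor strain) is compared against the identical
protocol in a control genotype. Rather than calling peaks per sample and
intersecting, `profdiff` works on *coverage profiles*: it asks, window by
window, where the depth-normalized, input-corrected case signal differs from
the control signal, and then tests each merged differential region for
statistical significance. The approach suits sharp transcription-factor
binding (tens to hundreds of bp) with a modest number of true sites.

## The model and procedure

Per ChIP replicate, with one input sample per condition:

1. **Extension.** Each single-end read (default 50 bp) is extended to the
   original fragment length (default 200 bp) from its 5' end: a plus-strand
   read starting at $s$ covers $[s, s+200)$; a minus-strand read ending at
   $e$ covers $[e-200, e)$. Fragments are clamped at chromosome ends.
2. **Depth normalization.** Every base value is divided by the sample's
   total read count and multiplied by $10^6$ (reads-per-million scaling), so
   replicates of different depth are comparable.
3. **Input subtraction.** The condition's normalized input profile is
   subtracted base-wise from each of the condition's normalized ChIP
   replicates. Negative values (input excess) are *retained*: the next step
   absorbs the offset, and clamping would discard information about
   input-dominated regions.
4. **Unit scaling.** Each subtracted replicate is min–max scaled into
   $[0,1]$, one transform per replicate over all chromosomes jointly. A
   degenerate (constant) profile maps to all zeros.
5. **Discretization.** The base profile is averaged over a sliding window
   (default 50 bp — the scale of a transcription-factor footprint) shifted by
   half a window (25 bp). The grid is anchored at coordinate 0; the trailing
   clipped window is kept and averaged over its actual span, so chromosome
   tails stay tracked.
6. **Replicate combination.** Windows are averaged across replicates of the
   same condition.
7. **Difference profile.** Per window, the signed difference case − control.
   Because inputs are unit-scaled the difference lies in $[-1, 1]$; under
   the null it is approximately normal with mean near 0.
8. **Noise filter.** All windows within $k\sigma$ (default $k=4$) of the
   global mean are discarded; mean and the sample standard deviation are
   computed over *all* windows of all chromosomes, zeros included, because
   the null distribution is the genome-wide one. Retention uses $\ge$ at the
   boundary (ties there are measure-zero in floating point). A zero-variance
   difference profile retains nothing.
9. **Merging and size filter.** Retained windows whose spans overlap or abut
   *and* share sign are merged; merged regions shorter than one window
   (50 bp) are discarded.
10. **Testing.** Each candidate region is tested by a two-sided two-sample
    Kolmogorov–Smirnov test of the case vs control window values overlapping
    the region. The p-value is exact (tie-aware, conditional on the pooled
    sample) when $n_\text{case} \cdot n_\text{control} \le 10^4$, asymptotic
    otherwise. p-values are Benjamini–Hochberg corrected; regions with
    $q < 0.05$ enriched in the case condition are the accepted peaks.

Design choices where the procedure was genuinely open:

* **Signed, not Euclidean, difference.** The workflow is sometimes described
  with a "Euclidean difference", but sign is indispensable — values span
  $[-1,1]$, merging is sign-aware, and only case-enriched regions are
  accepted — so the difference is implemented as the signed
  case − control.
* **KS sample.** By default the KS test uses the replicate-*combined* window
  values (the same profiles the difference was computed from);
  `pipeline_config(ks_per_replicate = TRUE)` instead pools per-replicate
  window values, tripling the sample size at the cost of treating replicates
  as exchangeable draws.
* **BH family.** Whether correction should run over candidates of both signs
  or case-enriched candidates only is ambiguous; the default corrects over
  *all* candidates (conservative for the case-enriched set), with
  `bh_family = "case_only"` as the alternative.
* **Degenerate regions.** Candidates with very few windows are still tested
  (a 1-vs-1 KS has exact $p = 1$), never silently dropped; the q-threshold
  removes them.
* **Blacklisting.** Regions overlapping supplied blacklist intervals (e.g. a
  transgene-source BAC) are discarded after acceptance, except those
  assigned to explicitly whitelisted genes.

## Downstream annotation

Accepted peaks are assigned to a gene when they overlap the gene body or a
strand-aware window 1 kb upstream of the TSS (the TSS of a minus-strand gene
is its right edge; its upstream window extends rightward). Overlap of one
base suffices; nested or dense genes yield multiple associations, all of
which are reported — no prioritization is attempted. Genome-wide motif hits
are related to genes with a wider window, 5 kb upstream to 1 kb downstream,
matching common peak-annotation practice.

## Motif scanning

The binding motif is a 12-column position probability matrix (MEME minimal
format in and out). Scoring is FIMO-style log-odds in bits with a
pseudocount of $0.01 \times$ background; the p-value of a score is the exact
probability that a background word scores at least as high. For widths up to
10 the dynamic program carries the exact support of the score distribution,
so p-values are exact to floating-point precision; wider motifs use a
discretized lattice with a 1e-3-bit step — two orders of magnitude below any
decision boundary at the default scan threshold $p \le 10^{-4}$. Scanning
computes word scores on the same lattice, so scan p-values are internally
consistent. Both strands are scanned; a match whose word is its own reverse
complement is reported on both strands and flagged `palindromic` (peak-level
counting is unaffected: a peak either contains a hit or not). The default
background is uniform; genome-trained frequencies can be supplied on the
`pwm`.

The reporter-element helpers mirror the synthetic response-element design:
four concatenated 22-bp genomic segments, each carrying one binding site
with the CRE-like core `TGACGTCA`; `validate_atre()` checks each segment for
the core (or its reverse complement) and for a PWM hit, and a mutant segment
with three or more substitutions in the core fails the core check.

## Auxiliary statistics

* `ddct_fold_change()` — relative qPCR quantification: per group
  $\Delta C_t = \overline{C_t^{target} - C_t^{normalizer}}$, fold change
  $2^{-\Delta\Delta C_t}$. Group means of $\Delta C_t$ are used; the
  confidence-interval construction for replicate fold changes is not pinned
  down, so per-replicate folds are available behind `per_replicate = TRUE`
  and interval construction is left to the caller.
* `filter_de_list()` — fold-change list filter with the boundary *included*
  (a gene at exactly the 1.5-fold default cutoff is kept).
* `overlap_fisher()` — one-tailed Fisher exact test of two-list overlap,
  enrichment tail $P(\text{overlap} \ge \text{observed})$.

## The simulator and what it does (not) emulate

`sim_config()` describes the emulated design: two conditions, three ChIP
replicates plus one input each, 50 bp single-end reads from 200 bp
fragments. Background fragment starts are uniform over the genome; inside a
spiked region of fold $f$, the case-condition ChIP sampling density is
$f\times$ background; control ChIP and all inputs are spike-free. Reads are
emitted as already-aligned intervals (the pipeline's entry point is uniquely
mapped reads, so simulating FASTQ and a mapper would add nothing
verifiable). Fragments overhanging a chromosome end are truncated, keeping
read counts exact. Each sample is generated from its own deterministically
derived random stream in a fixed role order, so adding samples never
perturbs earlier ones and a fixed seed gives byte-identical outputs.

Depth is a free parameter: no sequencing depth is prescribed by the design,
so the default is 100,000 reads per sample on a 100 kb genome (~200×
fragment coverage), a realistic per-base depth for a fly-scale ChIP
experiment shrunk to desk scale. The default spike-recovery scenario plants
three 500 bp regions at fold 8.

The simulator does **not** model sequencing error, PCR duplicates,
mappability bias, GC bias, chromatin accessibility structure, or paired
ends. Passing recovery tests therefore demonstrates the correctness of the
pipeline's arithmetic, error control and power under idealized sampling —
not robustness to the artefacts of real libraries.

## Numerical choices and problem sizes

* Exact KS via the tie-aware conditional distribution; asymptotic Kolmogorov
  series (100 terms) above the $n_1 n_2 > 10^4$ crossover.
* Noise-filter SD is the sample estimator (n − 1); the estimator is not
  prescribed and at genome-window counts the difference is negligible.
* Window grids anchored at 0; no anchor is prescribed and results shift by
  at most one window either way.
* Test and verification runs use a 100 kb single-chromosome genome, 100k
  reads per sample, 20 null replications for the false-positive check —
  sizes at which every stage is exercised and full runs finish in seconds.

## Known limitations

Single-end only; dense per-base vectors bound memory by the longest
chromosome (fine for desk-scale and fly-scale genomes, wasteful for human);
no summit calling, no IDR, no fragment-length estimation; scan hits carry
p-values but not q-values; the KS test treats windows as exchangeable
observations and ignores their spatial autocorrelation from the half-window
overlap — the 4σ pre-filter and the window-size minimum are what keep this
approximation honest, and the simulated null false-positive check is the
empirical evidence that it holds under the emulated design.
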