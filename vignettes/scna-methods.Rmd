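---
title: "Methods: copy-number calling for chromosomally unstable tumour genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number calling for chromosomally unstable tumour genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinscna)
```

## The problem

Chromosomally unstable (CIN) tumours continually mis-segregate and rearrange
chromosomes, producing somatic copy number alterations (SCNAs) that range
from whole-chromosome aneuploidies to ~2 Mb focal amplicons. Low-pass (~3x)
whole-genome sequencing is the standard readout: read counts in fixed
genomic bins are proportional to local copy number, so a tumour profile
normalized to a matched normal control reveals gains and losses without
deep coverage. This package implements that analysis end to end for
mouse-like genomes — simulation of ground-truthed profiles, normalization,
segmentation, event classification, cohort recurrence, and the digital-PCR
and FISH statistics used to validate candidate amplifications — with the
motivating application being cohorts of Kras-driven mammary tumours that
escape oncogene withdrawal by amplifying the *Met* locus on chromosome 6.

## Coverage model and normalization

Binned counts are modelled per bin $i$ as negative binomial with mean
$\mu_i = d \cdot c_i / 2$, where $d$ is the expected diploid depth per bin
and $c_i$ the integer copy number. The default $d = 30{,}000$ is the
arithmetic consequence of the targeted study conditions: 3x coverage of
50 bp single-end reads in 500 kb bins ($3 \times 500000 / 50$). The default
overdispersion (inverse size) of 0.01 puts the per-bin log2-ratio SD near
0.15, a realistic figure for low-pass data; 0 gives pure Poisson counts.

`log2_normalize()` computes
$\log_2\!\left(\frac{t_i + pc}{c_i + pc}\right) - m$
with pseudocount $pc = 1$ (guarding zero-count bins at shallow coverage)
and $m$ the median over autosomal bins. Median centring anchors the modal
(diploid) state at 0 and makes the profile invariant to global scale —
library size differences cancel. Whether the original analyses centred
their profiles is not documented anywhere we could rely on; centring is
this package's own choice, as is the absence of GC/mappability correction,
which the normalization deliberately omits to stay minimal. The X
chromosome is treated as a diploid autosome (all-female cohorts) but is
still excluded from the centring median so that convention can be changed
independently.

## Segmentation: circular binary segmentation from first principles

Each chromosome's log2 values are partitioned by recursive arc splitting.
For a piece $x_1..x_n$, every arc (contiguous window) of width
$m \le k \le n - m$ is scored with

$$T = \frac{|\bar{x}_{in} - \bar{x}_{out}|}{s\sqrt{1/k + 1/(n-k)}}$$

where $s$ is the piece's overall sample SD (a difference-based SD was
considered and rejected as an unnecessary elaboration at these bin sizes;
the simple estimator keeps the statistic interpretable). The maximizing arc
is tested by permutation: the piece's bins are shuffled `n_perm = 1000`
times and the split is accepted when
$(1 + \#\{T^{perm} \ge T^{obs}\}) / (n_{perm} + 1) < \alpha = 0.01$.
An accepted interior arc yields three pieces, a boundary arc two, and
recursion continues until nothing splits. Permutation counting stops early
once the exceedance count already guarantees $p \ge \alpha$, which cannot
change any decision but makes flat chromosomes cheap.

Numerical choices worth recording:

* **Minimum arc width 2 bins.** Blocks single-bin noise segments at 500 kb
  resolution while keeping ~2 Mb amplicons (4 bins) splittable.
* **Tie-breaking.** Among equal statistics the smallest start, then the
  smallest end wins. An arc and its complement have *identical* statistics
  in exact arithmetic, so the implementation treats values within a
  relative $10^{-9}$ as tied; otherwise last-ulp float noise would pick
  sides platform-dependently.
* **Degenerate pieces.** A constant piece (SD 0) or one shorter than twice
  the minimum width is returned unsplit and flagged; this is also the fast
  path for noise-free profiles.
* **Determinism.** One seed in `cbs_params()` drives all permutations, so
  a segmentation is bit-reproducible.
* **Pruning off by default.** `undo_splits()` (merge adjacent segments
  whose means differ by less than `k` MADs of the bin values) is provided
  but not applied unless requested, since the target analysis does not
  describe pruning.

The arc search is validated in the test suite against exhaustive
enumeration of all arcs for short profiles, and the permutation test is
calibrated on pure-noise chromosomes (false-split rate at most twice
$\alpha$).

## Event classification

Segment means are discretized with inclusive thresholds at $\pm 0.25$:
`GAIN` at or above $+0.25$, `LOSS` at or below $-0.25$. The cutoffs sit
well below a clonal single-copy gain ($\log_2 3/2 \approx 0.585$) and above
segmentation noise at 3x; they are configurable because the original
analysis does not print its values. Classification then applies the
category rules per chromosome:

1. Count state switches between adjacent segments. More than
   `switch_max = 10` switches calls the whole chromosome a single gross
   chromosomal rearrangement (GCR), which supersedes any other call there
   and counts as one SCNA.
2. Otherwise maximal runs of adjacent same-sign non-neutral segments are
   merged into candidate events (a sub-threshold neutral sliver keeps two
   gains apart — no gap bridging, the simplest deterministic reading).
   Each event's span fraction of the chromosome decides its category:
   whole-chromosome gain/loss (WCG/WCL) at $\ge 0.95$, partial gain/loss
   (PCG/PCL) at $\ge 0.2$ ("at least one-fifth"), focal
   amplification/deletion (AMP/DEL) below that. All boundaries inclusive.

`whole_fraction = 0.95` rather than 1.0 lets a chromosome-wide shift
tolerate edge-bin artefacts; it, too, is a configurable package decision.

## The simulator and what it does (not) emulate

`simulate_karyotype()` plants events uniformly at random on a diploid
baseline, rejecting and resampling overlapping placements so ground truth
stays unambiguous. Defaults are fixed study conditions, not tuning knobs:
a 19-autosome + X mouse-like layout with approximate mm10 lengths, 500 kb
bins (~5,450 bins genome-wide), and per-genome Poisson event counts with
means WCG 0.5, WCL 0.2, PCG 0.25, PCL 0.3, AMP 0.8, DEL 0.35, GCR 0.1 —
about 2.5 SCNAs per tumour, matching the reference cohort's mean burden
(2.48) with focal amplification the most frequent kind. Focal events span
4–12 bins (2–6 Mb); 30% of amplicons are generated as
breakage-fusion-bridge-like stepped profiles: 3–8 nested +1 gain steps
centred on a focal locus, rising monotonically to a peak of at least 4
copies and falling again. BFB is modelled phenomenologically — by the
copy-number *shape* such cycles leave behind — not by simulating
fusion-bridge mechanics, because shape is all a read-depth analysis can
see. A GCR is realized as six interior gain blocks (twelve switches).

Event coordinates snap to bin boundaries, and each event's ground-truth
label is derived from its *realized* span via the same boundaries the
classifier uses. Recovery tests therefore measure the fidelity of
normalize–segment–classify, not label bookkeeping.

What the simulator does **not** emulate: GC and mappability bias, read-level
artefacts, subclonal mixtures and tumour purity below 1, and germline CNVs.
Passing recovery tests consequently show that the pipeline is correct for
clonal events under count noise — not that it is robust to the platform
biases or subclonality of real libraries.

Problem sizes in the shipped tests are the package's chosen desk scale:
recovery is demonstrated on 200-tumour cohorts (noise-free must be exact;
Poisson-noise accuracy at least 90%), CBS calibration on 200 noise
chromosomes, and the oracle comparison on 500 short profiles.

## Cohort aggregation

`per_chromosome_frequency()` reports the fraction of tumours per genotype
carrying each category on each chromosome, with genotype cohort sizes as
denominators. `minimal_common_region()` sweeps interval endpoints and
returns the leftmost highest-support run — with full support this is the
mutual intersection, the operation that pinpoints a shared driver gene
(here *Met*) inside recurrent amplicons. SCNA burden between genotypes is
compared with the two-sided pooled-variance Student t-test (Welch optional);
the pooled form is the package default because it reproduces the reference
cohort's printed P = 0.34 from the bundled per-tumour counts. A
permutation cross-check in the test suite agrees with the analytic p to
about 0.06 — ties among small discrete counts make the exact permutation
null slightly heavier-tailed, so exact agreement to 0.05 is not attainable
on these data and the test documents the measured gap.

One interpretive decision in the bundled cohort deserves note: eleven of
the sixteen sequenced KM tumours carry a cMet amplification by sequencing,
but exactly one of them (KM15) owes it to a whole-chromosome-6 gain rather
than the recurrent ~2 Mb focal amplicon; the published 62.5% figure counts
the focal events only, and the fixture's `chr6_category` column encodes
that distinction so both quantities are computable.

## Validation assays

**Digital PCR.** Poisson partition statistics give
$\hat\lambda = -\ln(n_{neg}/n)$ per dye; the copy ratio is
$\hat\lambda_t/\hat\lambda_r$. Channels are modelled as independent
binomials with positive probability $1 - e^{-\lambda}$, the standard
single-dye quantification model; double-positive joint modelling is
deliberately out of scope. The 95% interval comes from the delta method on
the log scale with
$\mathrm{var}(\log\hat\lambda) \approx (e^{\lambda} - 1)/(n\lambda^2)$;
a chip is called amplified when the interval's lower bound exceeds 1.
Saturated chips (no negative partitions) are an explicit error — the
estimator is undefined there. Coverage of the interval is verified by
simulation (93–97% at the nominal 95%), and the trisomy expectation — a
target concentration 1.5x a disomic reference recovering a ratio of 1.5 —
is the quantity `scripts/acceptance.R` recomputes.

**FISH.** Per-cell spot counts are summarized after discarding cells with
at least 3 target *and* at least 3 reference copies, the genome-doubling
exclusion: such cells inflate both channels and would mask a true
target-specific gain. Over retained cells the ratio of mean counts and the
fraction of cells at or above 3 target copies are reported; the
conventional secondary positivity call (at least 5 copies in more than 15%
of nuclei) is available as `fish_positive()`.

## Known limitations

* Absolute copy number, purity and ploidy are not inferred; calls are
  relative to the profile's modal state.
* Segmentation is single-sample; no joint multi-sample breakpoints.
* The GCR rule is a count heuristic on state switches, so a chromosome
  with many genuine independent events and a complex one are not
  distinguished.
* The permutation test's discreteness means achievable p-values are
  multiples of $1/(n_{perm}+1)$; with the defaults the effective level is
  just under 0.01.
* `minimal_common_region()` reports a single interval; multi-modal support
  profiles (two disjoint equally-supported cores) surface only the
  leftmost.
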