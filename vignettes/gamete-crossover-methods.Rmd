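---
title: "Methods: crossover detection and recombination analysis from single-gamete sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover detection and recombination analysis from single-gamete sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocross)
```

## The problem

A single heterozygous plant produces thousands of haploid gametes, each
carrying one recombined chromatid per chromosome. Sequencing pollen nuclei
with droplet scRNA-seq genotypes every gamete at a sparse subset of
haplotype-diagnostic SNP markers, and each haplotype switch along a
chromosome marks one meiotic crossover (CO). From one plant and one
sequencing run this yields a genome-wide recombination landscape that would
otherwise require a large segregating population. The approach is
especially informative in holocentric species, where hundreds of
repeat-based centromeric units (Tyba-like tandem arrays carrying CENH3) are
scattered along every chromosome and the classical "centromere effect" on
recombination can be interrogated unit by unit.

`holocross` implements the full analysis: marker selection from a variant
table, cell-level quality control, a smoothing genotyper that emits CO
intervals, windowed recombination landscapes and Marey maps, interference
statistics, permutation-based feature association, and the merging rules
that turn raw repeat/ChIP annotations into centromeric units. A synthetic
gamete generator with known ground truth exercises every stage.

## The synthetic generator defines the study conditions

The generator is first-class, tested code, not a fixture. Its defaults are
the conditions of the emulated study system:

* **Genome**: five chromosomes, haplotype-specific SNP markers at ~1 per
  449 bp, centromeric arrays of mean 20 kb spaced ~400 kb apart.
  Chromosomes default to 2 Mb so that cohorts of thousands of cells stay
  desk-sized; every density is per-bp and scale-free, and tests that need
  chromosome-scale physics (e.g. coincidence curves) use a 90 Mb
  chromosome instead.
* **Meiosis**: each chromosome carries 60 cM (300 cM genome-wide), so a
  gamete averages 3 COs and a chromatid 0.6. Chiasmata are placed on the
  genetic scale by a *stationary gamma-renewal process* with shape
  `nu` and rate `2 nu` per Morgan — the standard interference model —
  and each chiasma is inherited by the sampled chromatid with probability
  1/2. `nu = 1` is exactly Poisson; larger `nu` gives the underdispersed
  counts and sub-unity coincidence typical of strong interference. The
  stationary start is sampled exactly from the closed-form equilibrium
  (forward-recurrence) distribution of the gamma gap, so no burn-in is
  needed and seeds reproduce byte-identically.
* **Interference strength**: the study system shows strong interference
  (coincidence below 1 out to ~60 Mb separations) but no single generative
  interference strength follows from that observation. We default to
  `nu = 5`, chosen once as qualitatively consistent with such a curve,
  and expose it everywhere.
* **Distal bias**: the genetic-to-physical map can be warped by a U-shaped
  intensity `((s + 0.02)(1 - s + 0.02))^-w` on the scaled chromosome. The
  0.02 guard keeps the intensity integrable for any `w >= 0`. `w = 0`
  (uniform) is used wherever a test's oracle assumes uniformity; the
  cohort default `w = 0.5` reproduces a distally biased landscape.
* **Observation**: cells report a log-normal number of markers (median
  380, so cohorts straddle the 400-marker QC cut, as the real
  pre-processing did), one read per marker by default (transcript
  sparsity), haplotype error 1%, and 5% of emitted cells are doublets.
* **Offspring**: selfed offspring take the union of two gametes' COs and
  report each as an interval with log-normal width (median 334 bp,
  sdlog 1.892 so the mean is ~2 kb), the resolution scale of low-coverage
  whole-genome offspring sequencing.

What the generator does **not** emulate: expression levels, barcode
chemistry and ambient RNA, mapping bias, structural variation between
haplotypes, and fine-scale CO placement preferences (promoter enrichment,
suppression inside centromeric units). Passing tests therefore demonstrate
the correctness and calibration of the analysis machinery under the
stated statistical structure, not the biological claims themselves.

## The crossover caller

Per cell and chromosome, with markers ordered by position:

1. **Allele-frequency smoothing.** `af = hap2 / (hap1 + hap2)` is replaced
   by its mean over the two markers ahead and behind (window truncated at
   ends). An isolated wrong-haplotype read, e.g. `(0, 0, 1, 0, 0)`,
   smooths to 0.2 and is absorbed.
2. **Genotype assignment and majority smoothing.** Genotype is H1 below
   0.5, H2 above, NA at exactly 0.5; then each genotype is replaced by the
   majority over the same window (NAs excluded; ties keep the marker's own
   call — determinism over cleverness, never random).
3. **Blocks and qualification.** Maximal runs of equal genotype become
   blocks. A block is *qualified* — allowed to carry genotype state — when
   it has at least 5 markers of which some 5 consecutive span at most
   1 Mb. A "5 markers within 1 Mb" rule leaves open whether the span
   constraint applies to the whole block or to a core; we require a dense
   5-marker core, which rejects sparse spurious runs
   while letting long dense blocks qualify regardless of total span.
4. **Calls.** Unqualified blocks are ignored for state: adjacent qualified
   groups with equal genotype merge (no CO); a genotype conversion emits
   one CO interval from the last marker of the upstream group to the first
   marker of the downstream group (BED, 0-based half-open).
5. **Close double COs.** Manual review of double-CO cells does not
   reproduce, so the package applies a deterministic surrogate: consecutive COs on a chromatid
   whose interval midpoints are closer than 2 Mb are flagged; a flagged
   pair is kept only when all three flanking qualified groups have at
   least 10 markers, otherwise both calls are dropped. Both parameters are
   exposed (`co_params()`), and the policy can be disabled.

Quality control precedes calling: cells need more than 5,000 reads
(strict) and at least 400 markers (inclusive — "fewer than 400" is
discarded); the genotype switch rate (raw majority genotypes, switches
never counted across chromosome boundaries, divided by total observed
markers) flags doublets above 0.07. The switch rate uses *raw* genotypes
because the doublet screen runs before any smoothing; a cell with fewer
than two markers gets NA and fails open as a singleton. Species assignment
from dual-reference alignment rates calls a cell ambiguous when the rates
differ by fewer than 10 percentage points (the delta is a judgement call and
is exposed) and discards
winners below 25%.

Note on defaults: the 5,000-read cut refers to raw barcode read counts in
the real pre-processing; synthetic cells carry ~1 read per marker, so
synthetic pipelines pass an explicit lower `min_reads`.

## Landscapes, maps, counts

The windowed rate is
`rate(w) = 100 * sum(overlap_fraction(CO, w)) / n_cells / |w in Mb|`,
with each CO's mass spread uniformly over its interval. Sparse-marker CO
intervals are of megabase scale, and assigning each to its midpoint
creates step artifacts at window edges; uniform spreading is the default
and midpointing is available by passing point intervals. With
non-overlapping windows the track conserves mass exactly:
`sum(rate * |w|) * n_cells / 100` equals the CO count.

The Marey map evaluates, at any physical position, the expected per-gamete
number of COs to its left (in cM); by construction the total map length
equals `100 *` mean COs per gamete, and the curve is monotone. Genetic
lengths involve no mapping function — gamete data count COs directly, so
no double-counting correction applies. Markers are thinned for map
construction by taking the lower-median marker by index in consecutive
500 kb windows from the first present marker.

## Interference statistics

* `poisson_gof()` merges Poisson expectation bins below 5 into the upper
  tail and uses `bins - 2` degrees of freedom.
* `dispersion_test()` uses the variance-ratio statistic
  `(n - 1) * var / mean ~ chi-squared(n - 1)` with a two-sided p-value —
  a closed-form classic that is exactly recomputable in tests.
* `coc_curve()` divides a chromosome into `k` equal intervals (15 by
  default; analyses of this kind sometimes use more intervals for the
  longest chromosome, which the `k` argument accommodates) and computes `f_ij / (f_i f_j)` from per-gamete presence frequencies.
  Because a CO is only localised to an interval, each round resamples a
  uniform point per CO; the default of 100 rounds
  brings the resampling error below 1% on fixtures. Pair separation is
  measured between interval midpoints. Pairs with `f_i f_j = 0` are
  skipped and counted.

## Feature association

The permutation null re-places, per round, the observed per-chromosome CO
counts with interval widths drawn from the empirical width pool, starts
uniform on `[0, L - width]` (clamped by construction; pseudo-COs may
overlap each other). Overlap counts use
half-open semantics, each CO counted at most once per track, and
`Z = (obs - mean) / sd` with positive Z meaning enrichment; no
multiple-testing correction is applied, matching how such Z-scores are
conventionally reported.

The relative-distance profile uses CO interval midpoints (with a median
offspring resolution of a few hundred bp the midpoint is faithful) and
normalises the
position between the end of the left flanking unit and the start of the
right one to [0, 1]; COs inside units or beyond the terminal units are
excluded and counted. The smooth curve is a span-0.75, degree-1 loess —
tri-cube weighted local linear regression — with its pointwise standard
error; the exact smoother is presentation-level. Metagene profiles scale
feature bodies to [0, 1] with absolute-bp flanks, orienting stranded
features so the TSS is always left. Window correlation matrices are plain
Pearson coefficients on aligned 1 Mb / 250 kb windows; zero-variance
tracks yield NA entries rather than spurious values.

## Centromeric-unit annotation

The two merging rules deliberately differ at the boundary: repeat monomers merge at gaps **up to and including**
25 kb ("a maximum distance of 25 kb") after dropping fragments under
500 bp, with merged arrays under 2 kb discarded; ChIP peaks merge at gaps
**strictly less than** 25 kb ("less than 25 kb"), with domains under 1 kb
discarded. Both operations are idempotent and produce sorted disjoint
intervals.

Cross-haplotype comparison scales array midpoints to relative positions
within syntenic blocks and pairs arrays greedily by increasing relative
offset, one-to-one; greedy nearest-offset pairing is
deterministic and recovers jittered copies exactly in tests. The test battery (Shapiro, F, t, Mann-Whitney,
Kolmogorov-Smirnov, linear regression of offset on position) reports NA
with a reason when a test cannot run.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed per operation through a
  scoped Mersenne-Twister; cohort wrappers derive per-cell seeds by
  counter, so any cell can be re-observed in isolation.
* Ties resolve deterministically everywhere: allele frequency exactly 0.5
  gives NA, genotype-vote ties keep the marker's own call, even-count
  thinning windows take the lower median.
* Zero-width CO intervals behave as points in overlap and rate
  computations.
* Empty inputs are legal wherever the result is well-defined (empty
  marker lists, cells with zero markers, zero COs); operations whose
  result is undefined fail loudly (zero markers genome-wide, zero cells,
  a permutation width larger than its chromosome — named in the error).
* Obligate-CO mode rejection-samples chromatids with zero COs; it is
  skipped with a warning for a zero-length map, where it can never
  terminate. It defaults off so that count expectations stay exact.

## Problem sizes used by the test suite

The suite simulates at the sizes the checks need, chosen once: 20,000
chromatids for dispersion and coincidence calibration (Monte-Carlo error
on var/mean ~1%, on mean CoC ~2%), 10,000 gametes for count means (0.7%
error on a mean of 3), 2,000 dense noiseless cells for end-to-end map
recovery, 500 cells at 2% error for caller accuracy, and 200 replicates
of 1,000 permutation rounds for Z calibration. At these sizes the whole
suite runs in a few minutes on one core.

## Known limitations

* The caller cannot see COs outside the observed marker span or closer to
  a chromosome end than five markers; recovered map lengths are therefore
  biased low by the terminal marker gap (about 1–3% at the test marker
  densities). This matches the confident-region convention of the
  landscape track (windows only between the first and last marker).
* Chromatid thinning of the chiasma process attenuates interference
  relative to the bivalent scale, as in any thinned renewal model; `nu`
  is the bivalent-scale shape, not the chromatid-scale one.
* The pseudo-CO null conditions on per-chromosome counts and widths but
  not on marker density; with strongly non-uniform markers the null is
  conservative near marker deserts.
* Diploid (F1 offspring) genotyping is out of scope; offspring CO sets
  enter as interval tables.
* The package exposes its functionality as an R API; shell-based
  workflows can drive `run_pipeline()` through `Rscript` with a YAML
  configuration (`read_pipeline_config()`).
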