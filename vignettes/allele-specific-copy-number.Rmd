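---
title: "Allele-specific copy number from tumor SNP-array signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number from tumor SNP-array signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnladder)
```

## The problem

Tumor genomes are aneuploid, admixed with genetically normal cells, and
often heterogeneous from cell to cell. A SNP array measures, per marker,
a total-intensity **Log-ratio** (log2 against a diploid reference,
median-centered per sample) and a **B-allele frequency** (BAF,
`B/(A+B)`). Conventional analysis thresholds the Log-ratio around zero,
which fails badly when the average tumor ploidy is not 2 (the
median-centering then centers some other copy number at zero) or when
normal-cell admixture compresses all signals toward their diploid values.

`cnladder` addresses this with two ideas:

1. **The allelic imbalance ratio.** Within a segment, fold BAF about 0.5
   (`|BAF - 0.5|`) so that germline phase is irrelevant, and cluster the
   folded values on two means. The inner center `d_het` tracks the
   heterozygous SNPs, which any allelic imbalance pushes away from 0.5;
   the outer center `d_hom` tracks the homozygous SNPs near 0.5
   deviation. The ratio `d_het/d_hom` runs from about 0.1 (balanced
   variant, typical array noise) to near 1 (LOH in a nearly pure tumor).
   No genotype calls, allele-frequency cutoffs, or matched normals are
   needed.

2. **The copy number ladder.** In the (mean Log-ratio, allelic imbalance
   ratio) plane, segments cluster at one point per allele-specific state
   `(c, m)` (total and minor copy number). The geometry of these points is
   sample-specific — it depends on purity and ploidy — but its *relative*
   structure is predictable: Log-ratio spacing between successive copy
   numbers shrinks slowly; states with the same minor copy number line up
   diagonally; balanced states (`c = 2m`) share one imbalance level. The
   caller therefore anchors itself at copy number 2 and works upward
   rung by rung, predicting each next coordinate from the rungs below and
   snapping the prediction to observed segment clusters. No global
   purity/ploidy grid search is performed, which keeps the method robust
   for samples (heterogeneous, very aneuploid) that do not fit a single
   closed-form model.

## The calling procedure

Given segments annotated with `mean_lr` and `ai_ratio`:

* **Anchor (cn2).** Among Log-ratio clusters of long autosomal segments
  (default `long_min = 2000` markers), take the two lowest-intensity
  clusters and pick the one with the lower length-weighted median
  imbalance: unaltered cn2m1 regions are more balanced than deletions or
  LOH. If the two candidates are not separable (imbalance medians within
  0.05) the estimate *fails loudly* and a `manual_seed()` — the analyst's
  reading of the scatter plot — must be provided. Genome-wide LOH is the
  canonical case where this happens.
* **Low-copy imbalance levels.** Near the cn2 Log-ratio, the imbalance
  values are split into a balanced and (if present) an LOH mode by a
  weighted two-means threshold; one spacing lower sits cn1. A gap-based
  split is deliberately avoided here: a single under-segmented segment
  with intermediate imbalance would chain the two modes together,
  whereas the two-means split tolerates such bridges. Missing modes are
  extrapolated (cn2m0 at `cn2m1 + 0.45`, capped at 1; cn1 midway) and
  marked as such.
* **Rungs upward.** With spacing decay `rho = 0.9`, the next rung is
  predicted at `lr(c-1) + rho * step`, and any sufficiently heavy
  observed cluster in the window `step * [0.5, 1.4]` above the previous
  rung replaces the prediction (lowest such cluster: the next copy
  number is by definition the nearest state above). The window is wide
  and asymmetric because the true log2 spacing shrinks faster than a
  fixed decay in near-pure samples (`log2(4/3)/log2(3/2) ≈ 0.71`) and
  slower in heavily admixed ones (≈ 0.9); a narrow symmetric window
  around the prediction would skip the true rung and lock onto the one
  above it.
* **Imbalance levels per rung.** The `m = 0` diagonal is extended from
  its two lower points with slope decay `rho_ai = 0.9`; balanced states
  reuse the cn2m1 level; a minor copy number first appearing at
  `c = 2m + 1` is interpolated between the balanced level and the
  `m = 0` level by the imbalance fraction `(c - 2m)/c`, which is
  independent of the (unknown) purity. Each predicted level is snapped
  to the weighted median of matching observed segments.
* **Assignment.** Each segment takes the state minimizing a scaled
  squared distance, the scales being the local inter-copy spacing and
  the local gap between adjacent minor-copy levels (floor 0.05), so one
  rung of error costs comparably in either axis. Exact ties go to the
  larger minor copy number — the less drastic interpretation, avoiding
  spurious LOH calls. Homozygous deletions (cn0) sit a full spacing
  below cn1 with the balanced imbalance level (only normal-cell DNA
  remains at such loci).
* **Heterogeneity.** A segment whose distance to its nearest state
  exceeds `het_frac = 0.3` of the distance between its two nearest
  states, over at least `long_het = 500` markers, is flagged: its copy
  number is most simply explained as an average over a mixed cell
  population (subclonal events, double minutes). Tumor cell fraction
  itself is deliberately *not* estimated numerically; it is assessed
  visually from the scatter plot, and exists in this package only as
  simulator ground truth.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `long_min` | 2000 markers | segment length admitted to the cn2 search |
| `gap_lr` | 0.1 | Log-ratio gap opening a new segment cluster |
| `rho`, `rho_ai` | 0.9 | per-copy decay of spacing / diagonal slope |
| `match_frac` | 0.25 | fraction of local spacing for observation matching |
| `step_lo`, `step_hi` | 0.5, 1.4 | acceptance window for the next rung |
| `min_cluster_markers` | 1000 | evidence needed before a cluster moves the ladder |
| `s_ai_floor` | 0.05 | floor of the imbalance distance scale |
| `het_frac`, `long_het` | 0.3, 500 | heterogeneity flag threshold and length |
| `max_cn` | 8 | highest rung built |

`min_cluster_markers` doubles as protection against subclonal regions:
a several-hundred-marker cluster stranded between rungs must not pull a
rung onto itself. The flip side is a known limitation — a *large*
subclonal cluster (thousands of markers) could still be mistaken for a
rung, as in any cluster-driven ladder construction; the heterogeneity
flag and the scatter plot are the safeguards.

The two-means clustering itself is solved exactly: in one dimension the
optimal 2-means partition is a threshold in sorted order, found by
scanning all splits with prefix sums. Each cluster must hold at least
`min_frac = 5%` of the values — a genuine heterozygous cluster holds a
substantial share of SNPs, and without the constraint a handful of
markers bleeding across an imperfect breakpoint into an LOH segment can
masquerade as the inner cluster and wreck the ratio. Segments with fewer
than `min_snps = 20` SNPs report no imbalance and are excluded from
model fitting. Degenerate input (all folded values equal, the noiseless
LOH limit) collapses both centers onto the common value and the ratio is
defined as 1.

## Segmentation

Changepoints are found by penalized recursive binary segmentation of the
Log-ratio (threshold `alpha * sigma^2 * log(n)`, default `alpha = 2`,
noise scale from root-mean-square successive differences), unioned with
the same search on folded BAF of SNP markers clipped at 0.3 — without
the BAF channel, copy-neutral LOH boundaries are invisible. Clipping
turns the uninformative homozygous SNPs into a constant, roughly
tripling the signal-to-noise of heterozygous-SNP shifts. Nearby
breakpoints from the two channels are merged to their median; segments
never drop below `min_markers = 100`. Segmentation is deterministic
given the track, and a pre-computed segment table can be supplied
instead (`run_pipeline(segments = ...)`), since the caller is agnostic
to the segmenter. Hidden-Markov segmentation is deliberately not
offered: subclonal regions with non-integer copy number make an HMM
oscillate between neighboring integer states.

For fine structure — double-minute amplifications whose copy number
varies cell to cell — `split_short_segments()` re-partitions segments
into pieces of 200–400 markers (piece count chosen so the mean size is
nearest 300, ties toward fewer/longer pieces for more stable imbalance
estimates; statistics are recomputed per piece, since each piece is its
own point in the scatter plot).

## The simulator and what it does (not) emulate

`simulate_sample()` generates marker tracks with ground truth under the
standard DNA-mixture model. At tumor cell fraction `f` and average tumor
ploidy `psi`, a state `(c, m)` has

    LR  = log2( (f*c + 2*(1-f) + b0) / (f*psi + 2*(1-f)) ) + N(0, sd_lr)
    BAF = (f*b + (1-f)) / (f*c + 2*(1-f)) + N(0, sd_baf_het)   (het SNPs)

with `b` the B-carrying copy count, a final per-sample median-centering
of LR, and homozygous BAF at 0/1 displaced inward by `|N(0,
sd_baf_hom)|`. The small background term `b0 = 0.05` (diploid-DNA
units) keeps homozygous deletions at a deep but finite Log-ratio, as
array background fluorescence does. Subclonality is a two-clone mixture
per region: `clone_fraction` of tumor cells carry `(c, m)`, the rest the
cn2m1 background, giving non-integer effective states. The average
ploidy is always recomputed from the region table, never free, and the
DNA-vs-cell mixing arithmetic (`dna_fraction_from_cell_fraction()`)
reproduces the practice of compensating for higher tumor DNA content
when constructing dilution series by mass.

Noise defaults (`sd_lr = 0.20`, `sd_baf_het = 0.06`, `sd_baf_hom =
0.03`, heterozygosity rate 1/3, 1 marker/kb on three chromosomes of
18,000–22,000 markers) were chosen once to mimic modern high-density
arrays at desk scale; in particular they make the balanced-segment
imbalance ratio come out near 0.1, the value typical of real balanced
segments under this statistic. Presets cover the validation designs: a
near-triploid genome (average ploidy 3.35) with 35 aberrations of which
14 carry LOH, used as the base of a 30–100% dilution series; an exactly
diploid genome with balanced gains and losses; a 50%-subclonal deletion;
and a run of three 250-marker amplicons (cn 4, 6, 8).

The simulator does **not** emulate probe-level A/B intensities, GC
waves, wave artifacts, batch effects, marker-density variation, or
genotyping-oriented BAF compression. Passing the simulated benchmarks
therefore demonstrates the correctness and the admixture/aneuploidy
robustness of the *method*, not performance on any particular array
platform; on real data the segmentation penalty and the noise-dependent
defaults may need adjustment.

## Evaluation protocol

A truth aberration counts as detected when more than half of its marker
span is covered by calls with exactly the right `(c, m)`; breakpoint
placement is ignored (different segmenters place them differently).
Specificity is the percentage of the truly unaltered (clonal cn2m1)
marker span reported as cn2m1. Spans are measured in markers, not base
pairs: markers are what calls and truth share, and at uniform simulated
density the two coincide. Strict minor-copy matching is the default; a
`total_only` mode exists for debugging. On the simulated dilution
series the caller reaches full sensitivity at tumor fractions 0.5 and
above and stays above 94% at 0.3, with specificity above 98%
throughout; the test suite asserts the (looser) floors of 95% at
`f = 1`, 80% at `f = 0.3`, and 95% specificity.

## Numerical choices and edge cases

* Weighted medians implement every "weighted on length" step; marker
  count proxies genomic length (exact at uniform density).
* All internal coordinates are 1-based inclusive (probe-annotation
  convention); only BED export is 0-based half-open.
* Markers with non-finite Log-ratio are dropped (and counted) at read
  time; missing-BAF markers contribute to `mean_lr` and `n_markers` but
  not to the imbalance clustering.
* Sex chromosomes are read but excluded from model fitting by default,
  since their Log-ratio baseline depends on sex rather than aberration.
* Non-polymorphic copy-number probes are weighted equally with SNP
  probes in `mean_lr`.
* Ladder invariants (Log-ratio strictly increasing in `c`, imbalance
  strictly decreasing in `m`) are enforced after observation updates;
  ties in the splitter go to fewer pieces; the rung acceptance takes the
  *lowest* admissible cluster, never the nearest.
* Test problem sizes: 60,000-marker genomes for the dilution and ploidy
  checks (3 or 10 seeds), 9,000–10,000-marker single chromosomes for the
  subclone and double-minute scenarios — small enough that the whole
  suite runs in well under a minute, large enough that every copy number
  rung rests on thousands of markers.

## Worked example

```{r example}
r <- run_pipeline(preset = "dilution", tumor_fraction = 0.5, seed = 1)
head(subset(r$calls,
            select = c(chrom, start, end, n_markers, mean_lr, ai_ratio,
                       cn, minor_cn, loh)))
r$avg_ploidy
r$report
```

The scatter-plot coordinates for plotting come from
`write_scatter_table(r$calls, highlight_chrom = "chr2")`; the ladder
itself (`r$ladder`) can be overlaid to show the expected position of
every state.
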