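---
title: "Two-axis methylome analysis: CpG-island methylation and backbone demethylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-axis methylome analysis: CpG-island methylation and backbone demethylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Cancer methylomes deviate from normal tissue in two broad, largely
independent directions: focal hypermethylation of CpG islands (CGIs) and
diffuse loss of methylation across gene-poor, repressive chromatin.
`backbonemeth` reduces a probe-level beta-value matrix to two per-sample
summary axes:

* **average CGI methylation** — the arithmetic mean beta over all retained
  CGI CpGs in a sample;
* **average backbone methylation** — the mean beta over CpGs in the
  *backbone*, defined as the genome complement of every annotated
  functional class: CGIs, their 2 kb shores, promoters (1.5 kb upstream of
  the TSS), the first 10% of each gene body, exons, DNase hypersensitive
  sites, TF-binding sites, enhancers, and repeats.

In normal tissue both axes are tightly constrained: CGIs are hypomethylated
(average ~0.18–0.24) and the backbone is hypermethylated (~0.78–0.82).
Samples are classified against the edges of those windows: **HC** (high CGI
methylation) when the CGI average exceeds 0.24, otherwise **NC**; **LB**
(low backbone methylation) when the backbone average falls below 0.78,
otherwise **NB**. The boundary values belong to the normal classes. Both
cutoffs are arguments, not constants, and `calibrate_cutoffs()` re-derives
them from any normal cohort the same way (max normal CGI average, min
normal backbone average), since they are empirical edges rather than
theoretical quantities.

Downstream of the two axes the package provides:

* per-sample differential-CpG calls against the mean of normal tissues
  (change strictly greater than 0.2 in either direction), and for each TF
  the **enrichment rate**

  $$\mathrm{rate} = \frac{\text{DM CpGs inside TF sites}/\text{CpGs inside TF sites}}
                          {\text{DM CpGs outside TF sites}/\text{CpGs outside TF sites}},$$

* sliding-window methylation-change tracks (2 Mb bins advancing by 1 Mb)
  and inside-vs-outside contrasts against lamina-associated domains (LADs),

* an association battery: Wilcoxon rank-sum for binary variables,
  Kruskal–Wallis for categorical ones, Kendall rank correlation (tau-b) for
  continuous ones, a linear model adjusted for age and sex for clinical
  variables, Benjamini–Hochberg correction within each declared family, a
  gene-level copy-number (SCNA) scan, and a cross-tumor-type percentile
  summary of scan p-values.

## Probe-level quality control

Probes are removed globally when a common SNP lies within 10 bp of the
interrogated CpG, when a repeat element lies within 15 bp (both encoded as
manifest columns, so no SNP or repeat database is needed at run time), or
when the CpG is on a sex chromosome. Both distance rules are inclusive
(distance <= threshold removes). Per sample, any cell whose detection
p-value is strictly greater than 0.05 is masked. Masked cells are stored as
`NA` in the beta matrix — there is no separate mask object — which makes
masking trivially monotone and all averaging pairwise-complete. An average
is only reported for a sample when at least `min_probes` (default 100)
unmasked probes of the class remain; the guard exists because tiny
synthetic genomes can otherwise produce averages over a handful of CpGs.

A probe may carry several functional labels (a CGI probe can also sit in a
TF site); CGI averaging uses CGI membership regardless of other overlaps.
The backbone label is exclusive by construction since the backbone is the
complement of everything else.

## Numerical conventions

* Coordinates are 0-based half-open (BED convention) everywhere; interval
  membership of a probe is `start <= pos < end`. Conversion to the 1-based
  closed convention happens only at the GenomicRanges boundary inside the
  interval algebra.
* `region_normalize()` merges overlapping *and bookended* intervals and
  returns rows ordered by chromosome name then start, so normalization is
  idempotent and independent of input order.
* The 5'-body length is `floor(0.1 * gene length)` with a minimum of 1 bp —
  rounding toward the 5' end, so the 5'-body never spills past the stated
  fraction.
* Shores exclude CGI bases: shores and islands are disjoint classes.
* Promoters and 5'-bodies are computed per input transcript row; genes with
  several transcripts contribute several intervals, deduplicated by
  normalization.
* Sliding windows are anchored at 0 on every chromosome; the final partial
  window is retained; a probe at a window boundary belongs to the window by
  half-open membership, so with `step = bin` each probe is counted exactly
  once.
* Percentiles across tumor types use linear interpolation between closest
  ranks (`quantile(type = 7)`). With 21 tumor types the 10th percentile
  therefore interpolates around the 3rd order statistic — a locus must be
  recurrently significant in several tumor types before the low percentiles
  move, which is exactly the screening behaviour the summary is for.
* `bh_adjust()` defaults its family size to the number of non-missing
  p-values; the SCNA scan instead declares the family as the number of
  genes attempted, the genome-wide convention for gene-level scans.
* Degenerate association designs are reported as missing with a diagnostic
  note, never silently dropped: constant variables, binary groups with
  fewer than 2 members, and clinical variables collinear with an adjustment
  covariate (detected as any aliased coefficient in the fitted model,
  regardless of which term R drops).
* An enrichment rate with zero outside calls is reported as missing rather
  than infinite; the four counts always accompany it.

## The synthetic cohort generator

Every stage is testable without external data because
`simulate_annotations()` and `simulate_cohort()` build a complete toy study
deterministically from a seed: a ~21 Mb four-chromosome genome (one sex
chromosome), genes with exons, CGIs at 60% of promoters plus intergenic
ones, eight TF factors of which the first ("POLYCOMB") has its sites parked
on 70% of CGIs, scattered repeats, DNase sites, enhancers, and megabase LAD
blocks covering about 30% of each autosome.

Beta values are drawn from a mean-parameterized Beta distribution,
`Beta(mu * kappa, (1 - mu) * kappa)`, the natural two-parameter family on
[0, 1]; `kappa = 80` gives per-cell noise of about 0.04 sd at the
compartment means. The mean `mu` for probe *i* in sample *j* combines:

* a probe baseline drawn once per probe around its compartment mean
  (CGI 0.21, backbone 0.80, other 0.50 — the CGI and backbone values are
  the midpoints of the normal windows; concentration 200);
* a per-sample offset (sd 0.005 per axis), the between-subject variation
  that gives normal cohorts their narrow ranges — chosen so that
  essentially all normal samples (far more than 99%) fall inside
  0.18–0.24 / 0.78–0.82;
* the planted tumor shifts.

A tumor block plants a CGI shift $\delta_C$ and a backbone shift
$\delta_B$, each scaled per tumor by a heterogeneity factor centred at 1
(sd 0.15), so cohorts spread along the axes as real tumor types do. Two
deliberate design choices keep parameter recovery exact:

* **Weights redistribute, they do not inflate.** The CGI shift is
  concentrated (weight 2) at CGIs inside polycomb-like TF sites and the
  backbone shift is concentrated (factor 1.5) inside LADs, but the weights
  are normalized to mean 1 over the probes of the class. A planted
  $\delta_B = 0.10$ therefore moves the cohort-mean backbone average by
  exactly 0.10 (to ~0.70) while still producing a measurable
  inside-vs-outside LAD contrast. An additional `lad_extra_shift` is
  available as an *uncentred* inside-LAD effect for contrast experiments.
* **Planted associations are centred.** Clinical slopes (stage on the CGI
  axis, age on the backbone axis), mutation effects and the copy-number
  coupling are applied as `effect * (x - mean(x))`, so they create
  recoverable associations without moving cohort means.

The copy-number coupling converts a target Kendall tau into a linear
coefficient through the Gaussian relation $\rho = \sin(\pi\tau/2)$ and the
known sample-level noise components. The paired "WGBS-like" table is the
realized per-sample average plus Gaussian noise whose sd is calibrated per
axis as `sd(avg) * sqrt(1/r^2 - 1)` with target r = 0.84, i.e. so the
theoretical attenuated array-vs-WGBS correlation matches the concordance
expected between platforms; at 200 samples the sample correlation then sits
within about ±0.1 of the target. Detection failures are injected in 0.5%
of cells.

What the generator does **not** emulate: array batch structure, tumor
purity mixtures, type I/II probe chemistry differences (the design type is
metadata only), realistic CpG spacing, or biologically structured
backgrounds of differential methylation outside the planted compartments.
Passing tests therefore demonstrate that the estimators recover what was
planted under a clean noise model — not that the pipeline is robust to the
technical artefacts of real array data, which are assumed to be handled by
upstream normalization (the pipeline consumes pre-normalized betas by
contract).

One consequence of the clean background is worth naming: in CIMP-like
blocks nearly all hypermethylation calls land inside polycomb-like sites,
so the enrichment rate's denominator is a small count and the raw ratio is
noisy from sample to sample even though it is large; the quantity that
tracks a sample's CGI methylation tightly is the inside-site DM fraction.
The test suite asserts the monotone relationship on that fraction and the
magnitude/sign of the ratio, at the precision each supports.

## Problem sizes and defaults

The default study conditions are 100 normal samples and two 100-tumor
blocks ("CIMP_like": $\delta_C = 0.10$, $\delta_B = 0.03$, with a planted
MUT1 effect of +0.08 on the CGI average at 30% prevalence;
"Demethylated": $\delta_C = 0.03$, $\delta_B = 0.10$, with a copy-number
coupling of tau 0.4 to the backbone average), over 5 400 probes (2 000
CGI, 2 000 backbone, 1 000 other, 400 destined for QC removal). Property
tests use reduced cohorts (~1 000 probes, 30+30 samples) and toy genomes of
at most 10^5 bp for the per-base oracles; statistical calibration uses
1 000 null replicates per test. These sizes were chosen so the whole suite
exercises cohort-scale behaviour while remaining quick to run on a laptop.

## Worked example

```{r, eval = FALSE}
library(backbonemeth)

cohort <- simulate_cohort(cohort_spec(seed = 1))
retained <- filter_probes(cohort$manifest)
beta <- mask_detection(
  cohort$beta[retained$probe_id, ],
  cohort$detection_p[retained$probe_id, ]
)
assignment <- assign_regions(retained, cohort$taxonomy)
summary <- summarize_samples(beta, assignment, sample_info = cohort$clinical)

table(summary$tumor_type, paste(summary$cgi_class, summary$backbone_class))
plot_methylation_density(summary, color = "tumor_type")

glance(concordance(summary, cohort$wgbs))
```

Or as one reproducible run writing every stage output plus a JSON manifest:

```{r, eval = FALSE}
run_pipeline(run_config(seed = 1, out_dir = "run1"))
```

## Known limitations

* The concordance check pools the CGI and backbone axes into one Pearson
  correlation (per-axis values are reported alongside); because the two
  axes sit at opposite ends of [0, 1], the pooled correlation is dominated
  by the between-axis separation and is optimistic relative to either axis
  alone.
* The linear clinical model assumes an approximately linear ordinal effect
  coding; ordinal conversion tables are the caller's responsibility.
* Tumor purity is accepted only as an optional covariate column; no
  deconvolution is attempted.
* Survival modelling, normalization (BMIQ), and batch correction (ComBat)
  are out of scope by design; the pipeline consumes their outputs.
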