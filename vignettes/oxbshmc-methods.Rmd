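---
title: "Methods: locus-specific 5hmC analysis from paired BS/OxBS arrays"
author: "oxbshmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-specific 5hmC analysis from paired BS/OxBS arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxbshmc)
```

## The measurement model

Bisulfite (BS) conversion leaves both 5-methylcytosine (5mC) and
5-hydroxymethylcytosine (5hmC) unconverted, so a BS-channel beta-value at a
probe measures the sum of the two marks. Oxidative bisulfite (OxBS)
chemistry first oxidises 5hmC so that only 5mC survives conversion. For a
probe $g$ and sample $s$ measured on both channels,

$$\hat\beta^{5hmC}_{gs} = \beta^{BS}_{gs} - \beta^{OxBS}_{gs}, \qquad
  \hat\beta^{5mC}_{gs} = \beta^{OxBS}_{gs}.$$

Because the two channels are measured on separate aliquots with independent
technical noise, the difference can be negative even though true 5hmC
cannot be. `compute_5hmc()` treats strictly negative differences as
technical artifact and clamps them to $10^{-7}$ (a stand-in for zero that
keeps the value strictly positive); exact zeros are left at 0. A
consequence worth stating: a *genuine* positive difference may also be
arbitrarily small, so the 5hmC container enforces nonnegativity rather
than a hard floor. Conservation holds at machine precision: wherever
$\beta^{BS} \ge \beta^{OxBS}$, the reconstructed
$\hat\beta^{5mC} + \hat\beta^{5hmC}$ agrees with $\beta^{BS}$ to within
one unit in the last place (bitwise identity is not attainable in floating
point), and the number of clamped cells equals the number of negative
differences exactly.

## Probe filtering and top-fraction selection

Probes overlapping SNPs and probes on sex chromosomes are removed before
analysis (`filter_probes()`); with two cohorts of mixed sex, sex-chromosome
methylation would otherwise confound the comparison. "Top 1%" probe sets
rank probes by cohort-mean 5hmC and keep the top
$\lceil 0.01\,n \rceil$; ties at the selection boundary are broken by
probe-id order and the result records whether a tie was cut, since the
choice is otherwise arbitrary.

## Volcano statistics: moderated t

Per-probe differential hydroxymethylation between cohorts (MT minus WT) is
tested with an empirical-Bayes moderated t-statistic, mirroring the
limma-style `lmFit`/`eBayes` analysis used with methylation arrays. The
pooled residual variance $s_g^2$ (with $d = n_1 + n_2 - 2$ df) is shrunk
towards a prior:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

with $(d_0, s_0^2)$ fitted by the method of moments on
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$ (solving
$\psi'(d_0/2) = \mathrm{Var}(e) - \psi'(d/2)$ by Newton iteration), and the
two-sided p-value referred to a t distribution with $d_0 + d$ df. When the
observed log-variances are *less* dispersed than a chi-square allows, the
prior df is infinite and all probes share $s_0^2$. Setting `prior_df = 0`
disables moderation and reproduces the ordinary pooled t-test exactly,
which the tests verify probe-by-probe; the moderated fit is cross-checked
against limma's independent implementation. On null synthetic data the
type-I error at $\alpha = 0.05$ lands within $0.05 \pm 0.01$.

## Region detection (bump hunting)

Differentially (hydroxy)methylated regions are found by the bump-hunting
recipe: probes are grouped into gap-clusters (consecutive probes on one
chromosome at most `max_gap` = 1000 bp apart), per-probe effects
$\bar\beta_{MT} - \bar\beta_{WT}$ are smoothed within clusters by a
truncated centered running mean (width 3; width 1 disables smoothing — a
running mean was preferred over loess for determinism and speed at
array scale), and candidate regions are maximal same-sign runs of smoothed
effects beyond a cutoff with at least `min_probes = 7` probes. The cutoff
is the 0.99 genome-wide quantile of the absolute smoothed effects by
default; an absolute cutoff is also accepted.

Significance comes from cohort-label permutations (250 by default; all
distinct assignments are enumerated when fewer exist, with a warning).
Null areas are collected from **every** beyond-cutoff run of the permuted
effects, with no length filter — the convention of the Bumphunter package
itself. This makes the family-wise adjusted p
$$\text{adj}p = \frac{1 + \#\{\text{permutations whose max null area} \ge A\}}
                      {1 + n_{perm}}$$
strictly conservative for the length-filtered observed regions; with
length-filtered nulls instead, the false-detection rate on null data sits
exactly at $\alpha$ and zero-detection runs become a coin flip across
seeds. The pooled per-region p uses the +1-corrected rank among all null
areas and equals 1 when no permutation yields any candidate — selection is
therefore based on adj-p, which behaves correctly in that regime.

In the packaged recovery experiment (20 planted regions of 10 probes,
$\Delta\beta^{5hmC} = 0.15$, channel noise sd 0.03, 12 vs 9 samples,
20,000 probes), the detection cutoff is set at the 0.95 quantile rather
than the default 0.99: the planted probes are exactly 1% of the array, so
a 0.99 quantile falls *inside* the planted effect distribution by
construction and would split regions. This is an analysis choice for that
dataset, made on that argument, not a tuned constant.

## Enrichment statistics

Enhancer enrichment of a probe set is summarised per annotation source as
an odds ratio with a Woolf (log-scale Wald) 95% interval, with the
Haldane–Anscombe 0.5 correction when a cell is empty, and tested by
Cochran–Mantel–Haenszel across strata (CpG-island feature by default; the
strata choice is recorded in the output). The CMH statistic is used
without continuity correction; the common odds ratio is the
Mantel–Haenszel estimator with a Robins–Breslow–Greenland interval. Exact
gene-set overlaps use the upper-tail hypergeometric probability computed
in log space against a universe of 20,345 protein-coding genes (GRCh37).
Fisher's exact test serves small tables; Pearson chi-square serves large
ones; "adjusted p" always means Benjamini–Hochberg unless stated.

## Consensus clustering

Sample clustering stability is assessed by consensus clustering: 1000
resampling steps, each drawing 80% of the probes without replacement
(the resampling proportion is applied to probes — items — matching the
common consensus-clustering convention for an 0.8 subsampling parameter),
Pearson dissimilarity $1 - r$ between samples, Ward linkage
(`ward.D`-style Lance–Williams update on the non-Euclidean dissimilarity;
variants differ, so the choice is recorded). Because every sample pair is
co-sampled in every probe-resample, the consensus denominator is the
resample count. Final assignments cut a Ward tree on
$1 - \text{consensus}$; per-k CDF areas and mean silhouette widths are
reported, and the advisory `chosen_k` maximises the silhouette without
hiding the per-k diagnostics.

## Expression coupling

Expression is quantile-normalised (limma's implementation; ties receive
the mean of their would-be quantiles). Differential expression uses the
two-group pooled t (equivalently one-way ANOVA with two groups) on log2
values — the package resolves an ambiguity in its motivating analysis
description, which names both ANOVA and a log-rank test, in favour of the
two-group ANOVA — with selection requiring both adjusted p < 0.05 and
linear fold change > 2. Probe–gene coupling uses Spearman correlation
(average ranks on ties, t-approximation p with $n-2$ df). Probes whose
genes are differentially expressed and whose 5hmC–expression correlation
satisfies $|r_s| \ge 0.5$ are classified by correlation sign crossed with
expression direction (Group 1: positive/up-in-MT; 2: negative/up; 3:
positive/down; 4: negative/down), and the sign-by-direction table is
tested by Fisher's exact test for small expected counts, chi-square
otherwise.

The 5hmC share of a gene set's methylation is
$100 \cdot \bar\beta^{5hmC} / (\bar\beta^{5hmC} + \bar\beta^{5mC})$ per
gene (probe means first, then per sample or per cohort — both levels are
provided because the quantity is reported ambiguously in the field);
genes with total methylation below 0.3 are excluded from percentage
summaries, as a share of a near-zero total is unstable.

## The synthetic study

The generator emulates a paired BS/OxBS two-cohort study at its published
scale: 20,000 probes, 1,000 genes, 12 MT vs 9 WT samples. Defaults were
fixed once, as the study conditions:

* baseline mean 5hmC beta 0.04 (right-skewed Beta; observed cohort means
  are near 0.046/0.044, matching the reported 0.046/0.037 scale), over a
  CpG-feature-dependent 5mC background;
* channel-independent Gaussian technical noise (sd 0.02) on BS and OxBS,
  which produces the negative-difference artifact at a realistic rate;
* 20 planted regions of 10 probes gaining 0.15 5hmC beta in MT, laid out
  as isolated gap-clusters; per-region magnitudes vary by a uniform 0.5–1.5
  multiplier because homogeneous shifts are invisible to correlation-based
  clustering (a location change does not alter Pearson distance) — the
  heterogeneity is what makes cohort profiles separable, as in real data;
* a 50-gene methylator-phenotype signature hypermethylated (+0.3 5mC) at
  promoters in MT, whose probes also carry appreciable 5hmC (Beta mean
  0.08) so that planted per-gene 5hmC shares fall in the reported 7–18%
  range rather than being dominated by clamp bias near zero;
* 25 positively coupled genes (4 body probes each = 100 Group-1 probes,
  target Spearman 0.9) and 5 negatively coupled, down-in-MT genes that
  populate Group 4; a gene's probes share one latent per-sample 5hmC
  signal (sd 0.05), because independent per-probe noise would attenuate
  probe-level coupling below the 0.5 retention threshold by construction;
* planted fold change 4 for DE genes (comfortably above the >2 selection
  cut) with residual log2 noise sd 0.5;
* optional three-group structure: an intermediate cluster (2 MT + 3 WT
  samples) carrying half the planted effect, mirroring a mixed cluster
  between the pure cohort clusters;
* hMeDIP reads drawn per probe with Poisson rates proportional to true
  5hmC times a log-normal per-sample spike-in recovery factor.

What the generator does *not* emulate: realistic probe-level manifest
structure (neighbouring-probe correlation, Infinium type chemistry),
beta-value heteroskedasticity near the boundaries, batch effects, or
sequence-level reads. Passing recovery tests therefore demonstrate the
*arithmetic and inferential machinery*, not robustness to array
artefacts that normalisation handles upstream.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at the study scale above;
region recovery uses 250 permutations and 20 null repeats, clustering 1000
resamples over 320 signal probes, calibration 10,000 null probes. The
Newton solve for the variance-prior trigamma inverse iterates to relative
tolerance 1e-10. Degenerate inputs are refused loudly: empty sample
sheets, cohorts with fewer than two samples for two-group statistics,
constant vectors in correlations, zero spike-in enrichment, windows with
zero library size.

## Known limitations

* The permutation p for a region is undefined in a useful sense when no
  permutation produces any null candidate (it equals 1 by the +1
  convention); adj-p carries the inference there.
* Ward-on-Pearson clustering is a Lance–Williams approximation, not a
  centroid method in a metric space; different Ward variants can split
  borderline samples differently.
* The moderated-t prior fit assumes exchangeable probe variances; strong
  variance structure (e.g. bimodal probe types) would call for stratified
  moderation, which is not implemented.
* hMeDIP modelling stops at interval arithmetic: no CpG-density coupling,
  no enrichment-efficiency estimation beyond the spike-in ratio.
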