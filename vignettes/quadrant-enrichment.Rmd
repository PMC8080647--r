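---
title: "Quadrant enrichment of TREX/NCT gene-set scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant enrichment of TREX/NCT gene-set scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senquad)
```

## The question and the method

Cellular senescence has been associated with transcriptional downregulation
of the machinery that moves macromolecules across the nuclear envelope: the
mRNA export apparatus (the THO/TREX complex, TREX-2, and the NXF/NXT
transporter factors, collectively "TREXes") and the classical NLS-dependent
trafficking system (nuclear pore complex, karyopherin transport receptors,
and the Ran GTPase cycle, collectively "NCTFs"). Because individual genes in
these functional units move subtly and in a strongly correlated way, the
analysis works at the gene-set level:

1. **Score.** For each study stratum, each gene's log2 expression is
   z-standardized (mean 0, sample sd 1, `n − 1` denominator) across that
   study's samples. A sample's score on a gene set is the arithmetic mean of
   the available member-gene z-values. Standardizing per study removes
   platform and batch location/scale differences, which is what makes
   pooling samples from many small studies meaningful.
2. **Classify.** Each sample is placed in the (TREXes score, NCTFs score)
   plane, split into quadrants Q1 (high/high), Q2, Q3 (low/low), Q4 at the
   per-axis medians over all included samples. Ties (`value <= split`) go to
   the low side, so the rule is deterministic and total.
3. **Test.** For a quadrant of interest (Q3 for senescence contrasts),
   the 2x2 table of group membership against quadrant membership is analyzed
   with the exact conditional test: one-sided hypergeometric tail p-value,
   conditional maximum-likelihood odds ratio, and exact one-sided lower
   confidence bound, so results print in the conventional
   "OR; CI lower–Inf; p" form.

The same machinery applies to tissue cohorts after deterministic grouping
rules: age-decade dichotomy (20–40 young vs 50–70 old), median-age
dichotomy, age quartiles, and the two tumor-stage dichotomies (stage I vs
II–IV, or I–II vs III–IV, after normalizing substage annotations such as
"Stage IIIB").

## Exact inference for the 2x2 table

Conditional on both margins of the table `(a, b / c, d)`, the first cell
follows Fisher's noncentral hypergeometric distribution with odds-ratio
parameter $\psi$:

$$P_\psi(X = x) \propto \binom{K}{x}\binom{n-K}{t-x}\,\psi^x,$$

with $n$ the table total, $K = a + b$ the target-group size and $t = a + c$
the quadrant size. The package implements this likelihood directly
(log-scale, normalized by log-sum-exp):

* the one-sided p-value is the central ($\psi = 1$) tail $P(X \ge a)$;
* the odds-ratio estimate is the conditional MLE, found by solving the
  monotone score equation $E_\psi[X] = a$ with root-finding on
  $\log\psi$ (0 or $\infty$ when $a$ sits at the support boundary);
* the exact one-sided lower bound solves $P_\psi(X \ge a) = \alpha$, again
  monotone in $\psi$; the upper bound is $\infty$ for the "greater"
  alternative. The two-sided p-value (point-probability method) and
  two-sided bounds are available for completeness, but the one-sided test is
  the default throughout because the reported confidence intervals are of
  the one-sided `lower–Inf` form.

Numerical choices: roots are bracketed by doubling on the $\log\psi$ scale
and refined with `uniroot` at tolerances of 1e-12 (estimate) and 1e-14
(bounds), so the returned lower bound satisfies its defining equation to
about 1e-10. The test suite checks the p-values against exhaustive
enumeration of binomial-coefficient sums for every informative table with
$n \le 30$, the conditional MLE against a dense log-grid likelihood search,
and both against `stats::fisher.test` as an independent implementation
(whose looser internal root tolerance is the only source of disagreement,
at the 1e-3 level). A table with an empty margin carries no information
about $\psi$: p = 1 and an undefined OR are reported with a warning rather
than an arbitrary number.

## The curated registry

Category sizes are fixed by the analysis design — TREX 16, TREX-2 5,
TREX-associated factors 8, NPC 31, NTR 11, Ran 4, and the two senescence
markers CDKN1A/CDKN2A — with supergroups TREXes (29) and NCTFs (46) derived
as unions. The exact member lists bundled here are curated from the
standard mRNA-export and nucleocytoplasmic-transport literature under those
size constraints, and the NPC set carries structural subclasses (Y complex,
central/nuclear/cytoplasmic FG, transmembrane, basket) plus the extremely
long-lived nucleoporins (ELLPs) as an orthogonal, deliberately overlapping
classification. Because reasonable curations differ at the margins, the
registry is fully replaceable via a GMT file, and `resolve_symbols()`
reports per-set coverage against any expression matrix. Symbol matching is
exact case-insensitive HGNC; alias and probe-level resolution are out of
scope by design, which is the main practical limitation when scoring older
array platforms.

## The synthetic cohort generator

`simulate_cohort()` draws log2-scale expression
$$x_{gi} = \mu_g + b_{s(i)} + \rho\,L_g f_{i,c(g)} + \delta_g(\mathrm{grp}_i)
 + \sigma\sqrt{1-\rho^2}\,e_{gi}$$
with baseline $\mu_g \sim N(8, 1)$, per-study batch shifts
$b_s \sim N(0, \tau)$, one standard-normal latent factor per sample and
functional category (loading 1 for that category's genes), a group effect of
$-\delta\sigma$ on target genes and $+\delta_{\mathrm{marker}}\sigma$ on
marker genes in senescent samples, and independent Gaussian residuals. With
$\sigma = 1$ every set gene has unit total variance and within-category
correlation $\rho^2$, reproducing the block-multicollinearity structure of
real functional units; markers are deliberately factor-free so their
counter-movement (senescent samples in Q1 of the CDKN2A x CDKN1A plane) is
driven purely by the mean shift.

Defaults were chosen once to describe a typical pooled in-vitro design:
5 studies of 6 + 6 samples, 200 background genes, $\delta = 1$,
$\delta_{\mathrm{marker}} = 1$, $\rho = 0.7$ (strong within-unit
correlation), $\tau = 1$, $\sigma = 1$. The published analyses report no
effect-size estimate for the downregulation (only that it is small but
clearly significant), so the validation harness spans
$\delta \in \{0, 0.5, 1, 2\}$; the end-to-end demonstration cohort uses 17
studies of 3 + 3 samples at $\delta = 0.5$, which lands the Q3 odds ratio
in the single-digit-to-low-double-digit range typical of the real pooled
analysis.

What the generator does **not** emulate: probe-level microarray artifacts,
platform mixing, missing-value patterns of real arrays, non-Gaussian
(count-like) noise, or realistic clinical covariate distributions. Passing
tests therefore demonstrate the pipeline's statistical correctness under
its own model assumptions, not robustness to every flavor of real data.

## Effect recovery and the attenuation correction

After per-study z-standardization of a balanced two-group study, a raw mean
shift of $u = \delta\sigma$ appears as a standardized difference of
approximately $D = -u/\sqrt{v + u^2/4}$ with
$v = \rho^2 + \sigma^2(1-\rho^2)$, because the pooled per-gene standard
deviation absorbs part of the group separation. `recovery_experiment()`
therefore reports both the raw standardized score difference and the
attenuation-corrected estimate
$\hat\delta = -D\sqrt{v}/(\sigma\sqrt{1 - D^2/4})$, which recovers
$\delta$ without the compression (a few percent of small-sample bias
remains from the $n-1$ standard-deviation correction). The uncorrected
difference is the right quantity when one only wants the z-scale effect;
the corrected one is the right quantity for parameter recovery, and it is
what the acceptance checks assert.

## Design choices that were genuinely open

* **Per-study vs pooled standardization.** Scores default to per-study
  z-standardization (the only scale on which pooling heterogeneous array
  platforms is meaningful); `zstandardize(by_study = FALSE)` provides the
  pooled alternative for single-platform cohorts.
* **One-sided vs two-sided.** The exact test defaults to one-sided with
  $\alpha = 0.05$ (the reported intervals are one-sided `lower–Inf`);
  `alternative = "two.sided"` is available.
* **Tie rules.** `<= split` goes low in the quadrant assignment,
  `<= median` is young in the age dichotomy, `<= boundary` takes the lower
  age quartile — one consistent convention, so degenerate inputs
  (all-identical scores or ages) have well-defined output.
* **Coverage handling.** Sets scoring below 50% symbol coverage warn but
  are not dropped; zero-variance genes become missing rather than zero, so
  they cannot shrink a set score toward 0. Samples missing a score on
  either axis are excluded listwise from the quadrant analysis.
* **No multiplicity correction** is applied across quadrants or set pairs,
  matching the analysis convention this package reproduces; users scanning
  many contrasts should adjust externally.
* **Group handling in the 2x2 construction.** With more than two group
  labels the comparison group must be named explicitly (remaining labels
  are excluded with a warning) instead of being lumped silently.

## Problem sizes used in validation

The bundled checks run entirely on synthetic data: exhaustive exact-test
verification over all informative tables with $n \le 30$ plus 1,000 random
tables for the odds-ratio estimate; 1,000 null replicates (5 studies x
6 + 6) for the type-I error of the Q3 test, which stays below the nominal
0.05 because the exact test is conservative at these sample sizes; and a
$\delta$-grid with 200 pooled samples per replicate for power monotonicity
and effect recovery. The end-to-end demonstration uses the 17-study
simulated cohort described above. Reproducing the published real-data odds
ratio requires the original public expression series and external RMA
preprocessing, which is deliberately outside this package's scope: it
consumes normalized matrices and never downloads or renormalizes data.
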