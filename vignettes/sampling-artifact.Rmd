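---
title: "Lopsided sampling and rare-variant tallies: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lopsided sampling and rare-variant tallies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lopsided)
```

## The problem

Public allele-frequency resources (gnomAD-style per-population AC/AN
tables) pool samples of very different sizes: tens of thousands of people
for some labeled populations, a few hundred for others. Because a variant
at true allele frequency $p$ is observed at least once in $n$ sampled gene
copies with probability $1 - (1-p)^n$, a deeply sampled population will
"have" many more rare variants than a shallowly sampled one **even when
every population draws from an identical variant pool**. Per-population
counts of rare (especially functionally shortlisted) variants are therefore
largely a readout of sampling depth, not of biology. This package provides
the computations needed to diagnose, quantify, and demonstrate that
artifact for a two-gene setting with one X-linked and one autosomal gene,
where allele numbers additionally depend on karyotype composition.

## The model

All estimators share one model: alleles are exchangeable binomial draws.

* **Discovery.** The detection probability of a variant is
  $d(p, n) = 1 - (1-p)^n$, and the expected tally of a pool
  $\{p_1, \dots, p_k\}$ at depth $n$ is $\sum_i d(p_i, n)$
  (`expected_tally()`). Both are monotone in $n$ and in each $p_i$ — the
  discovery-curve fact the artifact rests on.
* **Tally regression.** Per-population tallies of shortlisted variants are
  regressed on per-population sample size through the origin:
  $\hat\beta = \sum x_i y_i / \sum x_i^2$. Fit quality is the *uncentered*
  coefficient of determination
  $r^2 = (\sum x_i y_i)^2 / (\sum x_i^2 \sum y_i^2)$,
  the squared cosine between the $x$ and $y$ vectors. The centered $r^2$
  is ill-defined for a forced-origin fit (it can go negative and depends
  on an intercept the model denies); the uncentered form is the standard
  defensible choice, and we document it prominently because a reported
  "origin-rooted $r^2$" does not pin down a formula by itself.
* **Absence confidence.** If a variant truly had frequency $p$, the
  smallest $n$ with $d(p, n) \ge c$ (`min_alleles_for_confidence()`) is
  the number of additional alleles one must sample so that continued
  absence would be surprising at level $c$. The closed form
  $\lceil \ln(1-c)/\ln(1-p) \rceil$ is bracketed and verified by direct
  evaluation at $n$ and $n-1$, because floating-point ceilings can
  overshoot exact thresholds ($p = 0.5$, $c = 0.75$ must give 2, not 3).
* **Carrier-free probability.** Assuming variants assort independently at
  their sampled frequencies, an individual of karyotype $k$ carries none
  of a set with probability $\prod_i (1 - p_i)^{c_{ik}}$, where
  $c_{ik}$ is 2 for autosomal variants and for X-linked variants in XX
  individuals, and 1 for X-linked variants in XY individuals. The reported
  population percentage averages XX and XY (default 1:1 mix, configurable
  via `xx_fraction`). Any positive linkage between variants would *raise*
  the true carrier-free fraction, so the independence estimate is a
  conservative floor in that respect; linkage is documented, not modeled.

## Tunable parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| true frequency spectrum | `spectrum_*()` | point mass $10^{-5}$ (experiment); constraint-skewed on $[10^{-6}, 10^{-3}]$ (two-gene fixture) | "many equally rare variants" is the cleanest null for the artifact; the skewed spectrum proxies selective constraint |
| number of shared variants | `experiment_config()` | 131 | size of the motivating shortlist (130 rare + 1 common) |
| allele numbers | `population_spec()` | {72000, 46000, 30000, 28000, 21000, 10000, 3324, 3134, 900} | two deep samples (36,000 and 23,000 people doubled), three small groups at their stated person counts doubled, four mid-sized fixture choices under a 15,000-person ceiling |
| replicates | `experiment_config()` | 200 | enough for a stable mean $r^2$ (its replicate SD is about 0.012) in seconds |
| karyotype mix | `xx_fraction` | 0.5 | half-XX/half-XY populace |
| confidence level | `min_alleles_for_confidence()` | 0.9 in the CLI | conventional detection-power target |

## What the generator emulates — and what it does not

`draw_truth()` + `sample_table()` produce per-variant, per-population AC/AN
tables with: (i) i.i.d. true frequencies from a chosen spectrum, optionally
identical across populations (`shared = TRUE`, the null in which any
tally-vs-sample-size relationship is pure artifact); (ii) allele numbers
derived from karyotype composition, so X-linked AN $= 2\,n_{XX} + n_{XY}$
is properly smaller than autosomal AN $= 2(n_{XX} + n_{XY})$; and (iii)
binomial allele counts. Deliberately **not** emulated: diploid structure
and Hardy–Weinberg pairing (allele draws are exchangeable, matching the
allele-level arithmetic of every estimator; individuals exist only in the
Monte-Carlo test oracle), linkage disequilibrium, coalescent ancestry,
demography, selection dynamics, per-site coverage variation, and
sequencing error. A green simulation test therefore establishes that the
*estimators implement the stated binomial model correctly* and that the
artifact follows from that model; it does not establish that any real
dataset satisfies the model, and real shared ancestry or correlated
coverage would change quantitative details (though not the monotone
depth–discovery relationship that drives the artifact).

The constraint-skewed spectrum tilts a log-uniform density by
$p^{-\text{skew}}$ over a discrete grid of $10^4$ log-spaced points. It is
a qualitative proxy only — it reproduces "mass shifted toward rarer
variants", which is all the near-linear-accrual comparison needs, and
makes no population-genetic claim.

## Numerical choices and degenerate inputs

* AN = 0 means **no data**, never absence: `frequency()` returns `NA`,
  `presence_status()` returns `"no_data"`, carrier-free estimation skips
  (and counts) such variants, and a population whose AN is 0 for every
  shortlisted record is dropped from the regression with a warning. The
  motivating absence claims are about *sampled* data; treating silence as
  zero would manufacture absences exactly where sampling is thinnest.
* A through-origin fit with all $y = 0$ returns slope 0 and an `NA`
  $r^2$ with a warning — a flat fit through zeros carries no evidence of
  proportionality, and reporting $r^2 = 1$ there would be misleading.
* Detection probabilities use `-expm1(n * log1p(-p))`, accurate for the
  $p \sim 10^{-5}$, $n \sim 10^4$ regime where `1 - (1-p)^n` loses
  precision.
* Replicate seeds derive from the master seed by the fixed rule
  `(master*1009 + replicate*7919 + stage) mod (2^31 - 1)` (stage 0 =
  truth draw, stage 1 = table sampling), so any replicate is reproducible
  in isolation and all seeds stay valid 32-bit integers.
* Variant-set membership for carrier-free estimates defaults to
  shortlisted variants that are *population-distinctive* (present in at
  least one population's sample, absent in at least one other), keeping
  ubiquitous common variants out of a rare-distinctive-variant claim;
  `distinctive_only = FALSE` includes everything.

## Design choices where the design was open

* **Uncentered $r^2$** for the origin-rooted fit, as argued above.
* **Absence requires AN > 0.** Whether the original tallies treated
  uncovered sites as absences is unknowable from summary descriptions; we
  adopt the sampled-absence rule and surface it everywhere.
* **Exclusion lists are configuration.** Record-keeping corrections to a
  published shortlist (variants to drop or add) are expressed as explicit
  `exclude` arguments to `tally_per_population()`, not edits to data files,
  so analyses remain auditable.
* **Alleles are the unit of the absence calculator**; conversion to people
  (`alleles_to_people()`) lives beside it because X-linkage makes the
  conversion karyotype-dependent (1.5 copies per person at a 1:1 mix).

## Known limitations

Independence across variants (no linkage) and across populations
(independent, not cumulative, discovery) are assumptions, both conservative
for the artifact argument but unverified for any particular dataset. The
VCF reader handles one dialect (suffix-keyed `AC_*`/`AN_*` INFO fields,
pre-split multi-allelics) and is a convenience, not a VCF toolkit.
External-data reproductions (real shortlists against gnomAD releases) are
supported by the same functions through the TSV/VCF readers but ship no
data; all bundled defaults are synthetic and labeled as such.
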