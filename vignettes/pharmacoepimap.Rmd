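---
title: "Calling drug-associated methylation regions and tracing their regulatory evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling drug-associated methylation regions and tracing their regulatory evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacoepimap)
library(dplyr)
```

## The problem

Large cancer cell-line screens measure, for hundreds of lines, both a
genome-wide DNA methylation profile (beta-values per CpG probe) and the
response to hundreds of compounds (area under the dose-response curve,
AUC; low AUC means sensitive). `pharmacoepimap` implements a layered
discovery pipeline over such data:

1. **dDMR calling** — per-CpG linear models of AUC on methylation,
   combined across spatially correlated neighbouring probes into *drug
   differentially methylated regions*.
2. **Expression linking** — regions whose methylation also associates
   with the expression of a proximal gene, classified into four
   mechanism cases by the signs of the drug effect and the
   methylation-expression correlation.
3. **Tumour generalisation** — links re-tested in an independent cohort
   without drug data (primary tumours); sign-consistent replicated links
   are *tgdDMRs*.
4. **Network evidence** — tgdDMR genes connected to the corresponding
   drug targets on a directed protein signalling network with Yen's
   K-shortest loopless paths, with a reverse-direction fallback.

A synthetic-cohort generator produces data with the statistical
structure each stage assumes, so the whole pipeline is testable without
any external downloads.

## The per-CpG model

Within one cancer type and for one drug, each probe's beta-value $m$
enters

$$y = \beta_0 + \beta_1 m + \beta_2 c_1 + \beta_3 c_2 + \beta_4 c_3
      + \beta_5\,\mathrm{pc}_1 + \beta_6\,\mathrm{pc}_2 + \varepsilon,$$

where $y$ is the AUC, $c_1$–$c_3$ are screening medium, growth property
and MSI status (one-hot encoded against the lexicographically first
level; constant columns dropped), and $\mathrm{pc}_1,\mathrm{pc}_2$ are
the first two principal components of the cancer type's beta matrix,
which absorb global methylation patterns so that $\beta_1$ captures the
local effect. The p-value is the two-sided t-test on $\beta_1$ at
residual degrees of freedom; probes with fewer than 8 complete
(beta, AUC) pairs are skipped. Only drugs with at least three partial
responders (AUC $\le$ 0.7) and cancer types with more than 15 lines are
scanned.

## From sites to regions

Neighbouring CpG sites are correlated, so per-site p-values are not
independent. The pipeline:

* estimates a distance-binned autocorrelation function (ACF) of the
  signed association z-scores (bins of 250 bp up to 1000 bp; bins with
  fewer than 10 pairs inherit the previous bin; estimates clipped to
  $[0, 0.99]$ — negative estimates carry no usable signal and clipping
  keeps the combination conservative);
* applies the Stouffer–Liptak–Kechris correction per site over its
  $\pm$1000 bp neighbourhood: $z_i = \Phi^{-1}(1-p_i)$, combined as
  $\sum_i z_i / \sqrt{\sum_{ij} C_{ij}}$ with $C$ looked up from the
  ACF (the denominator is floored at the site count, which guards
  against non-positive-definite lookups);
* extracts regions: seeds at corrected $p < 0.05$, extension over sites
  with corrected $p < 0.05$, peaks within 1000 bases merged;
* computes a region-level Stouffer–Liptak over the constituent sites'
  *raw* p-values and applies a Šidák adjustment
  $1-(1-p)^{n_\mathrm{eff}}$ with
  $n_\mathrm{eff} = \max(1, \lfloor n_\mathrm{total}/n_\mathrm{region}\rfloor)$.
  The effective-test count uses probe counts rather than base-pair
  coverage: array probes are single-base, so a probe-count dialect is
  well defined on sparse designs (this is a documented dialect choice,
  not asserted equivalent to coverage-based counting);
* reports a region as a dDMR only if the Šidák-adjusted p is below
  $10^{-6}$, every constituent probe has raw $p < 0.01$ (the strictest
  reading of the per-site filter), and at least 4 samples sit in each
  aberrant state (region-mean beta below 0.3 and above 0.7), so both
  methylation modes are populated. The effect size is the mean
  per-probe slope $\beta_1$; a negative effect size means
  hypermethylated lines are sensitive.

P-values are clipped to $[10^{-300}, 1-10^{-16}]$ before any normal
transform, and tail quantities use `log1p`/`expm1` and upper-tail
`qnorm` so nothing overflows at extreme significance.

## Expression linking and the four cases

For each dDMR, candidate genes come either from strand-aware promoter
windows (2000 bp upstream to 200 bp downstream of the TSS) or, in
distal mode, the 20 nearest genes (10 per side where available). The
samples are split into U (unmethylated) and M (methylated) groups of
size $g=\max(4, \lfloor 0.2\,n\rfloor)$ by region-mean beta, and each
candidate gene is tested with a two-sided Mann–Whitney U test (exact
when both groups have $\le 8$ samples — via the exact rank-sum
distribution without ties and full assignment enumeration with ties — a
tie-corrected normal approximation otherwise). The reported direction
is the sign of the smaller one-sided tail.

Raw p-values below 0.05 enter a permutation stage: the same M/U groups
are applied to genes drawn uniformly with replacement from the rest of
the expression matrix (default 50000 draws; the examples here use
2000–4000 to keep the vignette and tests desk-sized), giving
$\mathrm{emp}_p = (1+\#\{p_\mathrm{null}\le p_\mathrm{obs}\})/(N+1)$,
followed by Benjamini–Hochberg adjustment across links; significance
requires adjusted empirical $p < 0.001$. The "empirical adjusted p" is
implemented as this two-stage construction because the raw (0.05) and
adjusted (0.001) thresholds imply an aggregation step after the
per-link empirical p.

Significant links receive a mechanism case from the sign pair
(dDMR effect size, Pearson correlation of region-mean beta with
expression, computed on **all** samples, not only the M/U tails): Case 1
$(-,-)$, Case 2 $(-,+)$, Case 3 $(+,-)$, Case 4 $(+,+)$. The U test
itself is reported two-sided with the direction as a separate field,
since one- versus two-sided usage in comparable pipelines is
version-dependent.

## Tumour generalisation and concordance

`replicate_links()` re-derives M/U groups from the tumour cohort's own
region-mean beta quantiles (rather than reusing cell-line cutoffs),
reruns the rank test and the permutation adjustment, and flags a link
as a tgdDMR only when it is significant in both cohorts **with the same
direction** — replication by significance alone would accept
sign-flipped regulation. Tumour cohorts below 8 samples are skipped
with a warning. No drug data and no covariate correction are used on
the tumour side. `effect_concordance()` summarises paired effect sizes
from two screens by sign-consistency fraction and a Pearson correlation
test (correlation left unset below 3 pairs).

## Network evidence

Signalling networks are directed edge lists; self-loops are dropped and
duplicate edges keep the minimum weight. `yen_k_shortest()` is a full
implementation of Yen's K-shortest loopless paths with an unweighted
(hop-count) metric by default, honouring weights when present, and a
deterministic lexicographic tie-break among equal-weight paths so runs
are reproducible. `connect_biomarker_to_targets()` searches forward
paths first and falls back to the reverse direction only when no
forward path exists; paths may traverse other drug targets (nothing in
the procedure forbids it, and excluding them would need an extra,
undocumented rule).

## The synthetic generator

`simulate_pharmaco_cohort()` emulates the features the pipeline relies
on, with defaults chosen once as a realistic desk-scale screen:

* 40 cell lines, 500 probes. Probes are placed in dense clusters of ~8
  at 30–80 bp spacing separated by multi-kilobase gaps, mirroring the
  CpG-island-centred seeding of methylation arrays; a planted region
  occupies one whole cluster.
* Beta-values are bimodal (modes near 0.1 and 0.9, shared within a
  cluster) on the logit scale, with AR(1) spatial noise (correlation
  0.7 per adjacent probe, SD 0.5), independent per-cell noise (SD 0.3),
  and two strong global latent factors (SD 1.5, loadings on every
  probe). The factors emulate lineage- and CIMP-like cohort-wide
  methylation gradients: they dominate the top principal components the
  way global patterns do on full-size arrays, which is what makes the
  model's PC correction meaningful at 500 probes.
* AUC = 0.8 + effect $\times$ region-mean beta + covariate offsets +
  Gaussian noise (SD 0.03, at the well-replicated end of the
  reproducibility reported for large screens), clipped to $(0,1]$.
  The default planted region shifts 10 of 40 samples to the opposite
  beta mode with effect $-0.15$ AUC per beta unit.
* The linked gene's expression is linear in region-mean beta with the
  slope sign set by the requested case; a concordant (or sign-flipped)
  tumour cohort can be regenerated from the stored truth record.

What the generator does **not** emulate: probe chemistry and
measurement error structure of real arrays, copy-number-driven
methylation artefacts, heterogeneous cluster sizes of the real
manifest, and realistic gene density. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated
under the stated model, not that the pipeline's power on real cohorts
matches the synthetic power.

Two scale-related behaviours are worth knowing. First, with 500 probes
a planted region contributes a visible share of the methylation
covariance, so the global factors must be strong for the PCs to stay
global; on 450k-scale data this is automatic. Second, the ACF estimator
pools probe pairs across the scan, so a scan's own signal (and any
factor component not captured by two PCs) inflates the estimated
correlations; the inflation enlarges the Stouffer denominator and is
therefore conservative.

## A worked run

```{r pipeline}
sim <- simulate_pharmaco_cohort(sim_config(seed = 1))
sim$cohort

res <- call_ddmrs(sim$cohort)
tidy(res)

links <- link_dmr_expression(res, sim$cohort, n_permutations = 2000,
                             seed = 2)
tidy(links) |> select(region_id, gene, mwu_p, emp_adj_p, pearson_r, case)

tum <- simulate_tumour_cohort(sim$truth, n_tumours = 60, seed = 3)
rep <- replicate_links(links, tum, n_permutations = 2000, seed = 4)
glance(rep)

net <- make_toy_network("GENE_PL1", "DRUG_TARGET", path_length = 5,
                        decoys = 10)
connect_biomarker_to_targets(net, "GENE_PL1", "DRUG_TARGET")
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(links)
```

## Numerical and design notes

* OLS is solved by QR; coefficients, standard errors and t-tests agree
  with the normal equations to $10^{-8}$ (enforced by tests).
* PC sign convention: the largest-magnitude loading of each component
  is positive, so scores are reproducible across platforms.
* PCs are computed per cancer type on the filtered probe set, once per
  type.
* M/U ties break by stable input order; pairs with constant beta or
  $2g>n$ are untestable sentinels, not errors.
* The empirical-p convention $(1+k)/(N+1)$ keeps p-values positive and
  unbiased under the null; its floor means very small `n_permutations`
  cannot reach stringent thresholds — at the default threshold of
  0.001 at least 1000 (and in practice several thousand) permutations
  are needed.
* Simulation sizes in tests (500 probes, 20-seed recovery batches,
  2000–4000 permutations) are desk-scale choices; the pipeline defaults
  (50000 permutations) match the published procedure it follows.
* A probe matching several removal reasons in `filter_probes()` is
  counted once, in the order cross-reactive, blacklist, sex chromosome.
* Multi-gene probe annotations are not resolved specially: the manifest
  carries a single `gene` string and downstream code treats it as the
  first listed gene.
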