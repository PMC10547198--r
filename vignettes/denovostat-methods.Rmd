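---
title: "Models and methods behind denovostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind denovostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(denovostat)
```

This vignette explains the statistical models the package implements, the
parameters that matter and how their defaults were chosen, what the
synthetic generator does and does not emulate, and the numerical and
design choices that were genuinely open. The running example throughout
is the pCMS (primary complex motor stereotypies) trio study the package
is calibrated to: 118 case and 750 control trios, 54 damaging de novo
variants in cases, and one gene (*KDM5B*) hit twice.

## Variant classification

Annotated de novo calls are reduced to a fixed effect vocabulary and then
to a finest class: synonymous; missense split by PolyPhen2-HDIV score
into probably damaging (`mis_d`, score >= 0.957), possibly damaging
(`mis_p`, in [0.453, 0.957)) and benign (`mis_b`); likely gene disrupting
(LGD) split into stopgain (stoploss is also a stop-codon alteration and
is grouped here), canonical splice site, and frameshift indel;
non-frameshift indel; unknown; non-coding. Aggregate classes are sums of
finest classes, so hierarchy identities (`damaging = lgd + mis_d` etc.)
hold on every tabulation by construction. Two deliberate conventions:

* a missense call without a PolyPhen prediction counts toward "all
  missense" (and thus nonsynonymous/coding) but toward no sub-class, so
  sub-class counts never invent a prediction;
* a variant with no population-frequency entry is treated as novel and
  passes the rare-variant filter (default threshold 0.001). An observed
  germline de novo absent from a large population reference is the
  expected case, not a missing-data problem.

Gene symbols are compared case-sensitively after whitespace trimming; no
alias resolution is attempted, because inputs are assumed to come from a
single annotation source.

## Burden: exact conditional rate-ratio test

The de novo rate of a class is `x / B`, with `B` the cohort's haploid
*callable* bases summed over trios — callable meaning every family member
had the depth and quality required to call a de novo variant at the
locus. Normalizing by callable bases rather than trio counts is the guard
against batch differences in depth between the case and control
sequencing.

Two Poisson processes with exposures `B_case`, `B_ctrl` are compared
conditionally: given the total `T = x_case + x_ctrl`, the case count is
`Binomial(T, p0)` with `p0 = B_case / (B_case + B_ctrl)` under equal
rates, and the one-sided p-value is the exact binomial tail. The test is
exact and conservative on the discrete grid; `adjust = "mid"` or
`"randomized"` provide the standard discreteness corrections (the
randomized version is exactly uniform under the null and is what the
calibration tests use). The default confidence interval is the Katz
log-normal interval `exp(log rr ± z sqrt(1/x_case + 1/x_ctrl))`; an exact
conditional interval (inverting the binomial interval for `p0`) is
available, and is the automatic fallback when a zero cell makes the
log-normal interval undefined.

Per-individual estimates multiply the per-bp rate by the coding exome
size (33,828,798 bp) *and by 2*: rates are per haploid base, individuals
are diploid. The factor is explicit in `exome_constants()` because
published tables are sometimes ambiguous about it; with the factor of 2
the package reproduces the pCMS per-individual values (1.37 coding per
case, 1.18 per control) from the printed counts and rates.

## TADA-Denovo: Poisson-Gamma Bayes factors

For gene `g` and class `c` (LGD and damaging missense), the de novo count
over `N` trios is `Poisson(q0)`, `q0 = 2 N mu_gc`, under the null. Under
the risk hypothesis the rate is inflated by a relative risk `gamma` with
prior `Gamma(shape = gamma_bar * beta, rate = beta)`, so the marginal
likelihood is negative binomial and the Bayes factor is closed-form; it
is evaluated in log space, and per-gene class counts above 50 are
rejected as input errors rather than propagated into overflow territory.
The gene-level Bayes factor is the product over classes.

With a prior fraction `pi` of risk genes, the posterior probability of
association is `pi BF / (pi BF + 1 - pi)`. Genes are ranked by
decreasing BF (ties broken by symbol; tied BFs share the q of the worst
tied rank) and the direct-posterior q at rank `i` is the running mean of
`1 - posterior` over the top `i` genes — the Bayesian expected FDR of the
list cut at `i`. Thresholds q < 0.1 ("high confidence") and q < 0.3
("probable") follow the conventions of the de novo literature.

Hyperparameter defaults are derived from the data rather than fixed:
`estimate_gamma_from_burden` spreads the class's excess burden
(observed minus expected-null count) uniformly over `k` risk genes,
`gamma_bar = 1 + (x - E0) G / (E0 k)`, with `beta = 1` and
`pi = k / G`. For the pCMS calibration (k = 184, G = 18,665) this gives
`gamma_bar` of about 98 for LGD and 27 for damaging missense. The
expected null count `E0` is the control count scaled by the
callable-base ratio, which keeps the calibration on the study's callable
territory.

Empirical p-values simulate null counts from `Poisson(2 N mu)` and rank
the observed BF in the simulated BF distribution, pooled across genes by
default (one genome-wide null distribution) with an add-one estimator. A
pooled p compares a gene against the genome, so a zero-count gene with an
unusually small mutation rate can receive p < 1; per-gene nulls
(`pooled = FALSE`) compare each gene only against itself and give p near
1 for zero counts. Both are useful; the pooled default keeps the cost at
desk scale.

## Estimating the number of risk genes

The estimator asks: how many risk genes `k` make the observed recurrence
most probable? Each Monte-Carlo replicate splits the `M` observed
damaging variants into an excess part `C ~ Binomial(M, C_bar / M)`
(`C_bar = max(0, M - E0)`; the binomial redraw avoids bias from rounding
the expected excess) placed in `k` risk genes drawn uniformly from the
universe — rate-weighted within the set, since even among risk genes a
longer gene is a bigger target — and a null part `M - C` placed over all
genes with probability proportional to their damaging rate.

The likelihood statistic was a genuinely open choice, and the package
ships both:

* `statistic = "profile"` (default): the probability that the simulated
  multiset of per-gene hit counts among recurrent genes equals the
  observed one (for pCMS: exactly one gene hit exactly twice).
* `statistic = "count"`: the probability that the *number* of genes with
  two or more hits equals the observed number.

The count statistic is degenerate when the excess is appreciable: at
`k = 1` all ~14 excess pCMS mutations stack in a single gene, which still
counts as "one recurrent gene", so the count likelihood is maximized at
k = 1 while predicting a 14-fold-hit gene that looks nothing like the
data. The profile statistic uses the multiplicity information and
excludes the pile-up; on the pCMS inputs its likelihood curve rises
steeply to ~150 and stays flat (within Monte-Carlo error at 2,000
simulations per grid point) to roughly 400, with the argmax in the
150–250 region — consistent with the study-scale estimate of 184, which
sits on the plateau. Because the curve is flat, the result object
reports, besides the argmax: the `support` interval (likelihood within
`e^-2` of the maximum) and the `plateau` interval (within two Monte-Carlo
standard errors of the maximum). At 50,000 simulations per point the
plateau would shrink accordingly; 2,000 per point with one refinement
pass around the argmax is the package default and keeps a full curve
under half a minute.

## Projection of discovery versus cohort size

Cohorts of `n` trios are simulated with the calibrated relative risks
planted in `k` risk genes (`Poisson(2 n mu_c gamma_c)` per gene and
class, `gamma_c = gamma_bar_c` in risk genes, 1 elsewhere), run through
the TADA step with the same priors, and the genes under each q threshold
are counted; 200 replicates per cohort size is the default. `pi` is held
fixed at `k / G` across cohort sizes rather than re-estimated per
simulated cohort — the projection asks what a bigger cohort finds under
the *current* calibration.

Two properties are structural and tested: q < 0.1 counts never exceed
q < 0.3 counts, and mean discoveries grow with cohort size. The absolute
counts, however, depend strongly on the hyperparameters. Under this
package's burden-derived calibration the projection yields roughly 16
high-confidence genes at 500 trios and 40 at 1,000 — about twice the
study-scale projections (7 and 26), whose exact prior settings are not
recoverable from the published summary. Generic TADA-style priors
(relative risks near 20/5) move the projection well below those values
instead. The shape is robust; the level is a statement about the priors,
and the projection should be read comparatively (how much more a cohort
of 1,000 finds than one of 500), not as an absolute promise. The
acceptance suite keeps the published-level comparison as a failing check
rather than adjusting the calibration to meet it.

## Gene-set overlap by weighted permutation

Each observed damaging mutation is reassigned, independently, to a gene
with probability proportional to a placement weight; the default weight
is the gene's damaging mutation rate, which subsumes the gene-length and
sequence-context effects that dedicated tools model explicitly
(class-specific weights can be supplied, in which case LGD and missense
mutations permute under their own rates). The observed overlap with a
gene set — mutation-level by default, gene-level optionally — is compared
with the permutation distribution: fold = observed / permutation mean,
p = add-one one-sided tail. A scan over many sets shares one permutation
stream, so set-to-set differences are not permutation noise. The
closed-form expectation `n_mutations * (set weight share)` is used as a
cross-check on the permutation mean throughout the tests.

## The synthetic generator

`scenario_config()` describes a study; defaults describe the pCMS pilot:
G = 18,665 genes, 118 case and 750 control trios, 184 risk genes, and
relative risks from the burden calibration. Per-gene total coding rates
are lognormal with log-sd 0.8 (about half an order of magnitude spread,
the scale of coding-length variation between genes), rescaled so a fully
callable individual carries 1.18 coding de novos; class rates are fixed
fractions of the total, anchored to the control class distribution
(damaging fraction 0.42/1.18). Per-trio callable bases are normal
(means reproduce the cohort callable totals; sd 4 Mb) and enter as an
exposure multiplier `callable / (2 * exome)` on every rate, so the
callable-base normalization in the burden module is actually exercised.
A configurable fraction of extra variants receives a population
frequency above the filter threshold.

With these defaults the case cohort carries ~54 damaging de novos and at
least one doubly-hit gene in roughly two-thirds of seeds, matching the
calibration anchors. Everything flows from one scenario seed through a
seed splitter, so a scenario is exactly reproducible.

What the generator does *not* emulate: sequence context (no
trinucleotide model, no per-variant positions), annotation noise
(effects are generated clean), relatedness and QC artifacts, and any
correlation between a gene's mutation rate and its risk status (risk
genes are drawn uniformly). Passing tests on synthetic data therefore
demonstrate the statistical machinery, not robustness to annotation or
calling errors in real tables.

`pcms_fixture()` is different in kind: a deterministic reconstruction of
the pCMS study's variant tables whose per-class tabulations equal the
published counts exactly, with the damaging case variants placed in the
published case-exclusive gene list (*KDM5B* doubly hit, two further genes
shared with damaged control genes), and callable totals recovered as
count / rate from the published coding row. Per-variant details the
summary tables do not determine (PolyPhen scores within a class band,
proband assignments, background gene identities) are synthetic. The
published list of case-exclusive genes prints 52 entries but contains
*KDM5B* twice; the package's set operation returns the 51 unique symbols
and the fixture reproduces exactly that structure. Likewise
`pcms_gene_sets()` provides synthetic stand-ins for the curated disorder
lists, with sizes typical of their literatures and planted overlaps
matching the published fold enrichments — so recovering those folds tests
the permutation machinery against an analytic target, not the curation
of the real lists.

## Numerical choices

* All Bayes factors in log space; the closed form is verified in the
  test suite against a quadrature oracle (coarse peak scan + fine
  Simpson rule on the log scale) to 1e-6 relative error. Naive adaptive
  quadrature fails here when the likelihood peak sits far from the prior
  mass, which is why the oracle locates the peak first.
* Exact binomial tails come from `stats::pbinom`; nothing distributional
  is hand-rolled.
* Weighted placement in hot Monte-Carlo loops uses precomputed
  cumulative weights with `findInterval` (O(log G) per draw) instead of
  per-call weight tables.
* Ties in the BF ranking share the q of the worst tied rank; ranking
  ties are broken by gene symbol so results are order-invariant.
* Zero cells in the rate-ratio test: `x_case = 0` returns rr 0 with
  p = 1 (one-sided greater); `x_ctrl = 0` returns rr Inf with the exact
  conditional interval; division by zero never occurs.
* Problem sizes in the shipped tests and acceptance script: 2,000
  simulations per MLE grid point, 200 projection replicates per cohort
  size, 20,000 permutations per enrichment scan — chosen so a full run
  of each stage completes in seconds to a few minutes on one core while
  keeping Monte-Carlo standard errors well inside the tolerances being
  checked.

## Known limitations

* The projection's absolute discovery counts inherit the prior
  calibration (see above); treat levels as calibration-dependent.
* The MLE likelihood is flat over a wide k range at desk-scale
  simulation depth; report the support/plateau intervals, not just the
  argmax.
* The mutability weighting in the enrichment module approximates
  context-aware placement; fold enrichments against real curated lists
  should be read with that approximation in mind.
* No multiplicity correction is applied across gene sets in a scan
  (nominal p-values, matching the descriptive use of such scans).
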