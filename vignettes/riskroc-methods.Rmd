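---
title: "riskroc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riskroc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskroc)
```

## 1. The model

`riskroc` treats risk prediction from SNP genotypes as a ranking problem.
A *risk group* is a set of multilocus genotypes; its likelihood ratio

$$LR_j = \frac{P(G_j \mid D)}{P(G_j \mid \bar D)}$$

is, by the Neyman-Pearson argument, the optimal ranking score: among all
orderings of a fixed set of groups, ordering by decreasing $LR$ maximizes
the area under the ROC curve, and the resulting curve (the *optimal ROC*)
is concave. Both halves of the package reduce to this construction; they
differ only in where the group masses come from.

* **Design stage**: masses are theoretical, computed from published
  per-SNP information and the disease prevalence.
* **Build stage**: masses are empirical counts of a fitted partition of
  the case-control sample.

The shared core (`group_table()`, `lr_order()`, `roc_from_groups()`,
`auc_from_groups()`) orders groups, merges exactly tied LRs (the optimal
ROC is defined on LR level sets, so a tie is a single curve segment), and
accumulates masses. The AUC identity
$AUC = P(LR_{case} > LR_{control}) + \tfrac12 P(LR_{case} = LR_{control})$
is verified in the test suite against a brute-force pairwise oracle to
1e-12, and LR-optimality is verified exhaustively over all permutations
of up to six groups.

## 2. Design stage

### From published inputs to conditional frequencies

A SNP may arrive with case/control genotype frequencies directly, or with
population genotype frequencies $f_g$ (or a single risk-allele frequency,
expanded under Hardy-Weinberg as $(1-q)^2, 2q(1-q), q^2$) plus genotype
relative risks $r_g$ (baseline genotype fixed at 1). With prevalence
$\rho$, the baseline penetrance is $k = \rho / \sum_g f_g r_g$ and

$$P(g \mid D) = \frac{f_g r_g}{\sum_h f_h r_h}, \qquad
  P(g \mid \bar D) = \frac{f_g (1 - k r_g)}{1 - \rho}.$$

The combination $k \cdot \max_g r_g > 1$ means some genotype would need a
penetrance above one; it is rejected as an input error rather than
clipped. The transform is exactly invertible
(`rr_from_conditional()`), which the tests use as a round-trip check.

### Combining loci

Design-stage inputs are per-marker, so the joint case and control
distributions are taken as products of the per-SNP conditional margins:
linkage equilibrium between markers *and* multiplicative joint effects
within each disease class. This is the only computable default from
per-marker inputs; it is an assumption, not a theorem, and markers in LD
or with strong epistasis will violate it. One group is formed per
multilocus genotype ($3^L$ of them); a hard guard at $L = 15$ refuses
combinatorial explosions instead of approximating.

### Power and sample size

The AUC is tested one-sided against a threshold $A_0$ ("is the model's
accuracy above $A_0$?") with the asymptotic normal test

$$\text{power} = \Phi\!\left(\frac{A_1 - A_0 - z_{1-\alpha}\,sd_0}{sd_1}\right),$$

where $sd_i$ is the standard deviation of the empirical AUC under each
hypothesis. The variance formula is **a genuinely open design choice**:
the underlying sample-size methodology for this test is not fully
specified by its public description. We adopt the Hanley-McNeil form

$$\widehat{\mathrm{Var}}(\hat A) = \frac{A(1-A) + (n_D - 1)(Q_1 - A^2)
  + (n_{\bar D} - 1)(Q_2 - A^2)}{n_D\, n_{\bar D}},
  \quad Q_1 = \frac{A}{2 - A},\; Q_2 = \frac{2A^2}{1 + A},$$

the standard textbook choice, validated in the tests against a
Monte-Carlo estimate of the sampling variance under a binormal score
model (10% relative tolerance) and against a Monte-Carlo check that the
test's realized size is $\alpha$. Any alternative of the same signature
can be supplied via `variance_fn`. Users comparing against sample sizes
computed by other tools should expect disagreement exactly here: with
$A_1 = 0.61$, $A_0 = 0.60$, $\alpha = 0.05$, power $0.95$, this
formula requires 17,071 cases per arm; published figures for the same
scenario computed with other variance estimators can differ by a factor
of about two.

The smallest adequate integer sample size is found by doubling then
bisection on `power_at_n()`, which is monotone in $n$; controls are
`ceiling(ratio * cases)`.

## 3. Build stage: F-ROC forward selection

Starting from one root group containing everyone, each step:

1. for every candidate SNP, splits every current group by that SNP's
   genotype categories (0/1/2, plus "missing" as a fourth category under
   `missing = "own_category"`), dropping empty categories;
2. **merges** statistically indistinguishable groups (below);
3. scores the partition by the AUC of its empirical-LR ordering;
4. keeps the candidate with the highest training AUC, ties broken by
   original column order (fully deterministic).

Selection stops at `max_predictors`, when no candidate improves the
training AUC by more than 1e-9, or — with `stop_rule = "cv"` — the
returned model is truncated to the cross-validated-AUC-maximizing size.
Training AUC per step is non-decreasing by construction (each step
optimizes over refinements).

### The merge rule

Splitting every group by every new SNP would triple the group count per
step and overfit immediately; distinct genotypes frequently carry
indistinguishable risk and should form a single risk group. The
collapsing criterion is another open design point (the behaviour —
e.g. three genotypes forming two risk groups — is observable in the
method's public examples, the rule is not). `riskroc` uses LR-adjacent
agglomerative merging: groups are sorted by empirical LR, and the
adjacent pair whose 2×2 case/control table has the largest association
p-value (chi-square with continuity correction; Fisher's exact test
whenever any expected count is below 5) is merged, repeatedly, while that
p-value is at least `alpha_merge`. The default `alpha_merge = 0.05`
merges whatever the data cannot distinguish at the 5% level;
`alpha_merge = 0` disables merging (special-cased, since every p-value is
$\ge 0$). Merging only adjacent-in-LR pairs keeps the partition ordered
and the procedure $O(G)$ per round.

A merged group is represented by the explicit set of genotype paths it
covers, not by per-SNP category products: merging groups that descend
from different parents produces sets that are not rectangular, so the
product representation would silently change the model. Per-SNP category
sets are still derived for display (DOT labels, `risk_node$path`). After
such cross-parent merges the "tree" is really a layered directed graph;
with `alpha_merge = 0` it is a proper tree and parent counts equal the
sum of child counts (asserted in the tests).

### Empirical LR, zero cells, smoothing

$LR = \frac{(n_{case} + c)/(N_D + cG)}{(n_{control} + c)/(N_{\bar D} + cG)}$
with pseudo-count $c$ (`smoothing`, default 0) over the $G$ current
groups. With $c = 0$ a pure-case group has $LR = \infty$ and ranks first
— a vertical ROC segment at FPR 0. Whether to smooth is left to the user
because the reference behaviour is unspecified; the default reproduces
the unsmoothed ranking, and the merge step usually absorbs tiny groups
before they matter.

### Cross-validation and external validation

Folds are stratified by case status with a seeded shuffle (default
`k_folds = 10`); each fold's model is refit from scratch (selection
included) on the remaining folds, and held-out samples are scored by
their matched group's *training* LR. Unseen genotype paths — at CV or
external validation — score $LR = 1$: a sample the model has never seen
carries no evidence either way, so it sits exactly at chance. External
validation (`apply_model()`) routes new samples through the frozen
partition the same way; imputation fill values are reused from training.

`fit_froc(k_folds = 0)` additionally skips the CV trace entirely (the
contract otherwise requires $2 \le k \le$ smaller class count); this
keeps large simulation studies and the fold-internal refits affordable.

## 4. The simulator: what it emulates, what it does not

`sim_config()` + `simulate_case_control()` emulate *retrospective
case-control sampling*: exact case and control joint genotype
distributions are computed from the penetrance model (HWE genotypes,
multiplicative relative risks across loci, optional epistatic multipliers
on genotype pairs, baseline penetrance scaled to hit the prevalence
exactly), and fixed numbers of cases and controls are drawn i.i.d. from
each. Missingness is masked completely at random. Defaults in the test
suite use common-variant scenarios (MAF 0.2-0.3, per-allele relative
risks around 2, prevalence 0.01) — the scale of effect sizes at which
single-SNP models are detectable at a few thousand samples, which is what
the recovery criteria exercise.

`truth_spec()` returns the exact generating distributions and their
theoretical optimal-ROC AUC, so simulation tests compare against closed
truth, not against another estimate.

Deliberately **not** emulated: linkage disequilibrium between SNPs,
population stratification, genotyping error correlated with case status,
informative missingness, quantitative traits, covariates. A green test on
this generator therefore establishes correctness of the algorithms under
the stated sampling model — not robustness of risk prediction to the
confounders of real GWAS data.

## 5. Numerical choices

* Probability masses must sum to 1 within `riskroc_tol$mass_tol = 1e-9`;
  input triples off by at most 1e-6 are renormalized with a warning
  (reader tolerance for rounded published frequencies), larger deviations
  are rejected.
* LRs equal within relative `riskroc_tol$lr_tol = 1e-12` are treated as
  exact ties and merged; infinite-LR groups sort first and merge
  together.
* Forward-step improvements below 1e-9 count as "no improvement"; AUC
  ties between candidates fall back to original column order.
* Sample-size search: doubling then bisection, `ceiling` rounding for
  cases and controls.
* All randomness (fold shuffles, simulation draws) flows from explicit
  integer seeds; identical inputs and seed give byte-identical file
  outputs (no timestamps in any data file).

## 6. Known limitations

* The design stage assumes inter-locus independence within each class;
  no LD modelling, no design-stage interactions.
* The Hanley-McNeil variance makes the sample size formula-sensitive (see
  §2); it is a documented, swappable default, not a claim of uniqueness.
* The merge rule is this package's reconstruction of an unpublished
  criterion; different gates give different group counts (the default is
  validated behaviourally: indistinguishable genotypes collapse,
  strongly distinct ones never do).
* Continuous environmental predictors must be pre-binned to at most a few
  categories; the package will not bin automatically.
* Candidate-pool pre-screening (e.g. by marginal p-value) is out of
  scope: the fitter consumes whatever columns it is given.
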