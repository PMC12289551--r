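---
title: "Supervised admixture projection and continental classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised admixture projection and continental classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixclass)
library(dplyr)
```

## The problem

Clinical sequencing rarely comes with the germline, genome-wide SNP data
that classical ancestry tools expect. Tumour-derived whole-exome or
RNA-Seq call sets carry only hundreds to a few tens of thousands of
usable bi-allelic SNPs, the set of markers differs from sample to sample
and caller to caller, and somatic mutations add noise. `admixclass`
implements a pipeline built for exactly this regime: genotypes are
projected onto a fixed reference of gene-pool allele frequencies to get a
per-individual ancestry profile, and a shrinkage linear discriminant
classifier maps profiles to continental groups. Because the profile is a
low-dimensional summary (a point on the K-simplex), classification
remains possible even when the underlying SNP set is tiny, and the
package ships the robustness experiments — SNP down-sampling,
foreign-SNP perturbation, synthetic two-way admixture — that quantify
how far that claim stretches.

## The admixture model

An individual's genome is modelled as a mixture of K gene pools. Pool k
is a vector of alternate-allele frequencies $p_{kj}$ over the panel SNPs
j; the individual's ancestry is a simplex vector $q$ with
$\sum_k q_k = 1$. At site j the expected alternate-allele frequency is
$f_j = \sum_k q_k\, p_{kj}$, and a diploid dosage
$g_j \in \{0, 1, 2\}$ contributes

$$\ell_j(q) = g_j \log f_j + (2 - g_j)\log(1 - f_j)$$

to the log-likelihood. Missing sites are skipped; the binomial
coefficient $\binom{2}{g_j}$ is constant in $q$ and omitted, so traces
from this package are comparable with each other but offset from tools
that include it. All frequencies are clamped into
$[10^{-6}, 1 - 10^{-6}]$ so no term is ever infinite.

**Supervised projection** (`fit_supervised_q()`) holds P fixed and
maximises the likelihood over $q$ with the multiplicative EM update

$$q_k \leftarrow \frac{q_k}{2M_{\text{obs}}}\sum_j\left[
  \frac{g_j\,p_{kj}}{f_j} + \frac{(2-g_j)(1-p_{kj})}{1-f_j}\right],$$

starting from the uniform vector and stopping when the log-likelihood
improves by less than `tol` (default $10^{-6}$) or after `max_iter`
iterations (default 2000). The objective is concave in $q$, so the EM
fixed point is the global maximiser; the test suite verifies this
against an exhaustive simplex grid search. Individuals are independent,
so sample order cannot affect results; the inner loop is compiled (C++)
because a boundary optimum — an individual drawn purely from one pool —
makes plain EM converge slowly and the per-site work dominates.

Note the stopping rule bounds the *per-iteration* improvement, not the
distance to the optimum: when a fit must agree with an external optimum
to high precision (as in the oracle tests), a tighter `tol` is the right
knob.

**Unsupervised fitting** (`fit_unsupervised()`) alternates the same
Q-update with the frequency update

$$p_{kj} \leftarrow \frac{\sum_i a_{ikj}}{\sum_i a_{ikj} + \sum_i b_{ikj}},
\qquad
a_{ikj} = \frac{g_{ij} q_{ik} p_{kj}}{f_{ij}},\quad
b_{ikj} = \frac{(2-g_{ij}) q_{ik} (1-p_{kj})}{1-f_{ij}},$$

both taken from the same E-step, so the total log-likelihood is
non-decreasing (a property the tests check on random instances). Q rows
are initialised from flat Dirichlet draws and P from per-site observed
frequencies jittered with seed-controlled noise. Components come out
anonymous (`pool1 ... poolK`); attaching geographic names is a
deliberate post-hoc human step done by inspecting population-mean
profiles of reference cohorts, and the package never auto-names them.
Choosing K is likewise left to the analyst: run the fit over a range of
K and inspect `glance()` summaries and profiles; no automatic
K-selection statistic is invented.

**Synthetic reference individuals** (`generate_synthetic_individuals()`)
are drawn per pool with dosage $\sim \text{Binomial}(2, p_{kj})$. They
are the anchors that let supervised projection run against a frequency
table rather than against controlled-access reference genotypes, with 15
individuals per pool as the default.

## Thresholded profiles and continental groups

Raw ancestry vectors on small SNP sets carry spurious minor components.
`threshold_normalize()` zeroes components strictly below
$\tau = 0.1$ and renormalises; a component exactly at the threshold
survives. If *every* component falls below the threshold, $\tau$ is
lowered by 0.01 and the rule re-applied until at least one survives; the
applied threshold is recorded per sample so the adaptive rule is
auditable downstream (the run log of `run_infer()` keeps it). The
threshold never drops below the step; in the degenerate case where even
that keeps nothing (possible only when K exceeds 1/step), the maximal
component survives. The operation is idempotent, which the tests assert
on random simplex vectors.

`collapse_to_groups()` sums components within continental groups under a
two-column mapping. The shipped default maps the twelve components
(Africa A/B; Central, South and Western Europe; Scandinavia; East, Far
East and Southeast Asia; Central Asia; India; Native America) onto five
groups (Africa, Europe, East Asia, Central Asia, America). The mapping
is configuration, not code: it lives in
`inst/extdata/component_groups.tsv` and any mapping can be passed in.
The classifier itself uses the full component profile as features —
components carry more information than the five collapsed sums — and
collapsing is exposed as an explicit, optional step.

## The classifier

`fit_lda()` is a Gaussian equal-covariance discriminant: class means
$\mu_c$, pooled within-class covariance S, shrunk toward a scaled
identity,

$$\Sigma = (1-\gamma)\,S + \gamma\,\frac{\mathrm{tr}(S)}{K}\,I,$$

with $\gamma$ estimated by a Ledoit–Wolf rule when
`shrinkage = "auto"`. Shrinkage is not cosmetic here: thresholded
profiles contain many exact zeros and classes can be small, so S is
often ill-conditioned or singular; the shrunk covariance is always
invertible and the fitted $\gamma$ is reported in the model object.
Three numerical edge cases are handled explicitly: at $\gamma = 0$ a
singular S is an error instructing the user to shrink (tolerance
`tol = 1e-4` on the relative eigenvalue); when classes are internally
constant (S numerically zero) the identity target is rescaled from the
total scatter so the classifier degrades to nearest class mean; and when
S is already a multiple of the identity the auto rule returns
$\gamma = 1$ since the shrinkage direction is a no-op. Posteriors are
the softmax of the discriminant scores
$d_c(x) = x^\top\Sigma^{-1}\mu_c - \tfrac12 \mu_c^\top\Sigma^{-1}\mu_c +
\log\pi_c$, which is exactly the Gaussian posterior under equal
covariance. Exact posterior ties break by lexicographic class order so
predictions are deterministic. At $\gamma = 0$ the posteriors match a
classical LDA reference to $10^{-6}$, and on two-class Gaussian data the
test-set error sits within 0.02 of the closed-form Bayes rate
$\Phi(-\Delta/2)$ — both are asserted in the tests.

Evaluation uses stratified k-fold cross-validation (default k = 5; each
validation fold is then a 0.2 fraction, which is why no separate holdout
fraction parameter exists), pooling out-of-fold predictions into one
metric report: confusion matrix, accuracy, balanced accuracy,
support-weighted precision/recall/F1, multi-class MCC, Cohen's kappa, a
two-cell chi-squared test of the correct/incorrect split against a 50%
null, and per-class one-vs-rest AUROC. `ovr_curves()` adds ROC and
precision–recall curves with 95% bootstrap bands (default 1000
resamples); a class absent from the truth is flagged undefined rather
than silently scored. `compare_classifiers()` runs standard baselines
(multinomial logistic, ridge, random forest, naive Bayes — delegated to
their canonical packages) under the same folds; only the shrinkage LDA
is this package's own implementation. Class imbalance is handled by
stratification only; no reweighting is applied.

## Robustness experiments

*Down-sampling* (`downsample_correlation_experiment()`): ancestry is
re-estimated on random SNP subsets and correlated per component with the
full-set estimate across samples; p-values use Student's t with n − 2
degrees of freedom. A constant component (e.g. with a single pool) has
no defined correlation and is flagged, never silently dropped. The
full-size row is identically r = 1 because the EM is deterministic.

*Foreign-SNP perturbation* (`build_union_snp_list()`,
`perturb_sample()`, `perturbation_sweep_evaluate()`): a cohort-wide
union of sites is built, duplicates resolved by highest QUAL (ties keep
the first-encountered donor, in cohort order). For each sample and level
f ∈ {1%, …, 10%}, `round(f × sites-on-chromosome)` foreign sites
(round-half-up, per chromosome) are drawn from the union excluding the
sample's own sites and appended with the donor's genotype — the donor
call is the only genotype information available for an uncalled site.
Original sites are never altered, a level that rounds to zero added
sites returns the input bit-exactly, and an exhausted pool is taken
whole with a warning. The sweep re-runs projection, thresholding and
classification per level against the *baseline* model (robustness of a
trained classifier is the question; retraining per level would answer a
different one) and reports the full metric trajectory. Levels are
labelled `f0 … f9` for 1%–10%; the unperturbed run is reported
separately as level `"orig"` rather than being conflated with `f0`.
Specific classes (e.g. groups absent from training) can be excluded from
evaluation via `exclude_classes`.

*Synthetic admixture* (`make_synthetic_admixed()`,
`admixture_classification_report()`): two-way admixed profiles are the
component-wise average of two source individuals' profiles — exactly the
midpoint of the segment between the parents, still on the simplex — and
are labelled with the canonical (alphabetically sorted) unordered pair
of the sources' groups. A model trained on pair categories then reports
top-1/top-2 labels and probabilities, flagging calls whose top-1
posterior falls below 0.85 as low-confidence. The pair list is taken
from configuration, since which pairs are of interest depends on the
cohort.

## The synthetic-data generator

Real reference cohorts are large and access-controlled, so the test bed
is simulated. `simulate_panel()` draws Balding–Nichols gene pools: an
ancestral frequency $p_{0j} \sim U(0.05, 0.95)$ per site and pool
frequencies

$$p_{kj} \sim \mathrm{Beta}\!\left(p_{0j}\frac{1-F}{F},\;
  (1-p_{0j})\frac{1-F}{F}\right),$$

so $E[p_{kj}] = p_{0j}$ and $\mathrm{Var}[p_{kj}] = p_{0j}(1-p_{0j})F$.
`simulate_cohort()` draws individuals with vertex truth (or Dirichlet
admixture via `alpha`), dosages $\sim \mathrm{Binomial}(2, q^\top p)$,
optional missingness, and synthetic QUAL values in $U(40, 99)$ so that
the PASS/QUAL filters are genuinely exercised on emitted VCF fixtures;
`emit_fixture()` can also append deliberately failing records
(multi-allelic, low-QUAL, non-PASS). All randomness flows from the one
seed in `sim_config()` and fixtures regenerate byte-identically.

Defaults are K = 5 pools, M = 2000 SNPs, F = 0.15, 40 individuals per
group: F in the 0.1–0.2 range is the scale of differentiation between
continental human populations, M = 2000 matches the low end of RNA-Seq
call sets where the method is meant to operate, and five pools mirror
the five continental groups. The experiments in the tests and in
`scripts/acceptance.R` run at these sizes (down to M = 500 for the
perturbation sweep, whose cost is multiplied by eleven evaluation
levels).

What the generator deliberately does **not** emulate: linkage
disequilibrium (sites are independent), realistic site-frequency
spectra beyond Balding–Nichols, caller-specific genotype error, somatic
mutation burden, or the uneven group sizes of real cohorts. Passing
tests on this bed therefore demonstrate the correctness and internal
robustness of the machinery — recovery of known ancestry, stability
under perturbation and down-sampling — not field accuracy on any real
population, which depends on the quality of the reference panel
supplied at analysis time.

## Numerical choices, in one place

- Frequency clamp $\varepsilon = 10^{-6}$ everywhere a log or ratio is
  taken.
- EM convergence: absolute log-likelihood improvement below `tol`
  (default $10^{-6}$); supervised default `max_iter = 2000`,
  unsupervised 500.
- Threshold rule: strict `<` at $\tau$; fallback decrement exactly 0.01
  computed as $\tau - i \cdot \text{step}$ to avoid floating-point
  drift; floor at one step.
- LDA: `tol = 1e-4` as the relative-eigenvalue bound; ties in posterior
  break lexicographically; priors empirical unless fixed.
- Perturbation counts: round-half-up per chromosome.
- Variant identity: exact `(chrom, pos, ref, alt)` string match,
  1-based positions. No strand flipping or ref/alt swap recovery is
  attempted — between-caller strand reconciliation is genuinely
  ambiguous, and silent flipping corrupts dosages; mismatches are
  counted and surfaced instead. Half-calls (`./1`) become missing
  rather than guessing a dosage. Duplicate records keep the
  highest-QUAL copy.
- Missing QUAL fails a positive QUAL threshold; `FILTER` must be
  exactly `PASS` when the PASS filter is on (a `.` is not a pass).
  Both filters are configurable because RNA-Seq callers differ.

## Worked end-to-end example

```{r pipeline, fig.width = 7, fig.height = 3}
cfg <- sim_config(K = 5, M = 1000, F = 0.15, n_per_group = 20, seed = 42)
panel <- simulate_panel(cfg)
cohort <- simulate_cohort(panel, cfg)

profiles <- cohort$genotypes |>
  fit_supervised_q(panel) |>
  threshold_normalize()

cv <- stratified_kfold_cv(profiles[attr(profiles, "components")],
                          cohort$truth$group, k = 5, seed = 1)
glance(cv)
```

```{r barplot, fig.width = 7, fig.height = 3}
plot_ancestry(profiles[c(1:10, 41:50, 81:90), ])
```

## Known limitations

- Dosage-only input: genotype likelihoods (low-coverage workflows) are
  out of scope; upstream callers must commit to genotypes.
- Plain EM, no quasi-Newton acceleration: correctness over speed at
  desk scale; the compiled inner loop keeps fixture-scale runs in
  seconds.
- Exact-match variant keys mean panels and call sets must share a
  reference build and allele orientation.
- The classifier is linear with a shared covariance; strongly
  non-Gaussian profile clouds (e.g. heavy multi-way admixture) are
  better read through the profiles and posteriors themselves than
  through the hard labels, and the top-2 reporting exists for exactly
  that reason.
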