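---
title: "Sensitivity-based epistatic analysis: model, significance and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity-based epistatic analysis: model, significance and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensepi)
```

## The problem

Quantitative genetic interaction mapping asks whether the phenotype of a
double deletion mutant departs from what the two single deletions predict
independently. When the same library is grown in two environments — here a
reference medium (E1) and the same medium plus a perturbation such as a
DNA-damaging drug (E2) — a second question arises: *which interactions are
remodelled by the environmental change?* A per-environment fitness analysis
cannot answer this cleanly: an interaction significant only under the drug
may simply have slipped under the significance threshold in the other
environment (replicate variance is typically larger under drug), and an
interaction significant in both environments may still be exactly the
response machinery one is after.

`sensepi` implements three score families that together resolve this.

## Scores

Let $m(\cdot, E)$ be the exponential growth rate of a strain in environment
$E$, with $wt$ the wildtype and $X$, $Y$, $(X,Y)$ the deletion strains.

**F-score** (per environment). Multiplicative neutrality expects
$m(X,Y) = m(X)\,m(Y)/m(wt)$, and the relative deviation

$$\varepsilon_{fit} = \frac{m(X,Y)\,m(wt)}{m(X)\,m(Y)} - 1$$

is the conventional fitness-based epistasis score: negative = aggravating,
positive = alleviating, symmetric in $X$ and $Y$
(`expected_double_rate()`, `f_score()`).

**Sensitivity and the ES-score** (cross-environment, per gene). Define a
strain's environmental sensitivity as $S = m(E1)/m(E2)$; a strain hurt by
the perturbation has $S > 1$. Treating the environmental change as one more
"mutation", the same independence argument yields the environmental
sensitivity score

$$\varepsilon_{env}(X) = \frac{S(wt)}{S(X)} - 1,$$

zero when deleting $X$ leaves sensitivity unchanged and negative for
hypersensitive mutants (`sensitivity()`, `es_score()`). The same formula
with the $Y$ single mutant as reference scores deletion of $X$ in a
$Y$-deleted background.

**S-score** (cross-environment, per pair). Imposing that
$\varepsilon_{env}(X)$ be preserved across genetic backgrounds gives a
multiplicative neutrality on sensitivities,
$S(X,Y)\,S(wt) = S(X)\,S(Y)$, and the sensitivity-based epistasis score

$$\varepsilon_{sen} = \frac{S(X,Y)\,S(wt)}{S(X)\,S(Y)} - 1
  = \frac{1+\varepsilon_{fit}(E1)}{1+\varepsilon_{fit}(E2)} - 1 .$$

The right-hand identity (exact when all scores come from the same mean
rates; `s_score()` and the test suite verify it numerically) is the crux:
a pair whose fitness interaction is *identical* in both environments has
$\varepsilon_{sen} = 0$ however strong the interaction, while any
environment-modulated interaction shows up with a sign that says in which
direction the drug reshapes it. Under our orientation ($E1$ = reference),
drug-enhanced alleviation among functionally linked genes appears as
negative S-scores.

## Growth-rate estimation

Rates come from OD600 time courses by ordinary least squares of
$\log OD$ on time (`fit_growth_rate()`), restricted conjunctively to OD in
$[0.1, 0.4]$ and time in $[60, 360]$ min — the exponential window of a
typical microplate run — with at least 10 qualifying points; replicates
failing the window are rejected as records, not errors, and an $R^2 < 0.95$
fit warns (a stand-in for manual curve inspection, which no rule can fully
reproduce). Replicates are summarised as mean, CV and count
(`summarize_replicates()`); a single surviving replicate yields an
*unestimable* CV, never 0, and the significance layer substitutes the
library median.

When many single mutants carry genuine fitness defects, directly measured
single rates can be biased by strain-construction artefacts. The pooled
alternative (`estimate_single_from_doubles()`) estimates $m(X)$ from each
partner as $\mu_i = m(X,Y_i)\,m(wt)/m(Y_i)$ and takes the median, which
tolerates a minority of true interactions among the partners; estimates
deviating more than 5% from the measured value are flagged, and
`apply_estimated_singles()` substitutes estimates only for an explicit
override list — substitution is never automatic.

## Significance: parametric bootstrap

Each score is tested against simulated data drawn from normal distributions
with the observed means and variances, with the double mutant forced to the
null: its trial rate is drawn around the multiplicative expectation $m_0$
with variance $m_0^2(cv_1^2 + cv_2^2)$, where $cv_1$ is the CV of that
pair's measured double-mutant rate and $cv_2$ the library-median CV over
all double mutants in the same environment (a robustifier for the
few-replicate per-pair CV). The two-sided P-value is the add-one-corrected
fraction of trials at least as extreme as observed, so no P is ever 0 (the
floor is $1/(n_{trials}+1)$; default 300000 trials). Draws that land
non-positive are redrawn up to 100 times, then the trial is discarded.

Two design points deserve explanation:

* **CVs describe the mean estimates.** The bootstrap emulates the sampling
  distribution of the *measured mean* rates, so `score_significance()`
  passes $cv/\sqrt{n}$ for every strain. Feeding replicate-level CVs
  instead would test each mean as if it were a single replicate and make
  every test drastically conservative.
* **Null-mean mode.** For the F- and S-scores the default recomputes $m_0$
  per trial from that trial's drawn single/wildtype rates. An algebraic
  subtlety: with a per-trial $m_0$ the single/wildtype draws cancel exactly
  from the trial statistic, leaving it distributed as the double-mutant
  noise term alone, $\mathcal N(0,\, cv_1^2+cv_2^2)$; the
  `null_mean_mode = "fixed"` alternative (null mean from the observed
  means) leaves them in, giving a wider null. Which sits closer to the true
  sampling variance of the observed score depends on the replicate design;
  under the default design (19 wildtype/single and 4 double replicates)
  the per-trial null is the closer match and is the default. For the
  ES-score the situation inverts: its null constrains only *one* of the
  four measured rates (the mutant's E2 rate, centred on
  $m_0 = m(X,E1)\,m(wt,E2)/m(wt,E1)$), so a per-trial $m_0$ would cancel
  all but that single draw and understate the null variance severely; the
  ES default is therefore `"fixed"`, which is first-order exact.

Measured on independent null pairs simulated under the default replicate
design (`simulate_null_pair_tests()`, which the acceptance checks run at
5000 pairs), all three families reject at close to nominal rates, the
F family running slightly hot at $\alpha = 0.05$ because its null variance
inherits the 3-degree-of-freedom sample CV of the 4-replicate doubles.

Single mutants are compared to wildtype by a Welch T-test
(`ttest_single_vs_wt()`), and F-interactions are assigned to environments
by the four-way rule on per-environment P-values
(`assign_environment()`: significant in E1 only, E2 only, both, none).
Raw P thresholds are used throughout, matching screen practice of
calibrated per-test error; Benjamini–Hochberg can be applied by the caller
(`p.adjust`) but is deliberately not a default.

## Downstream analyses

* `call_by_threshold()` / `call_top_k()` build call sets; "most likely"
  ranking is by P with deterministic ties (larger $|\varepsilon|$, then
  pair name). `compare_call_sets()` partitions two sets;
  `delta_f_vs_s()` tabulates $|\varepsilon_{sen}|$ against
  $|\varepsilon_{fit}(E2)-\varepsilon_{fit}(E1)|$, the empirical face of
  the identity above.
* `enrichment_test()` scores evidence enrichment of a call set by the
  upper-tail hypergeometric test including the observed count; the
  `"any"` category counts a pair once however many evidence lines support
  it. `cobinding_test()` applies the same tail to two regulators' shared
  targets within a differentially-expressed universe.
  `predictive_value_curve()` sweeps thresholds for predictive value and
  TPR/FPR, with false positives defined as called pairs outside the
  evidence set.
* **Phenotypic masking** (`masking_delta()`, `detect_masking()`,
  `recovery_curve()`): within a positively ordered pathway, deleting the
  upstream gene hides the downstream deletion's phenotype, so the double
  resembles the upstream single. On sensitivities this is
  $\varepsilon_{sen} = \varepsilon_{env}(Y)$ (masked gene $Y$); on fitness,
  $\varepsilon_{fit} = W_{wt}/W_Y - 1$. A directed pair is called masking
  when the interaction is alleviating (negative S-score within complexes;
  positive F-score — both sign conventions overridable), significant at
  $\alpha$, and the equivalence statistic falls below $\Delta_{thr}$.
  Both directions of every pair are always evaluated; unassayed directions
  are excluded from numerator and denominator, and the FPR background is
  all other assayed directions (within-complex non-expected directions are
  not exempted).
* **Profile clustering** (`build_profile_matrix()`,
  `cluster_profiles()`): signed S-score profiles, correlation-based
  dissimilarity $1-r$ over shared scored partners with the mutual cells
  excluded (so two genes' distance is driven by third parties), average
  linkage. Missing pairs are handled pairwise-complete; pairs sharing
  fewer than 3 partners are flagged unstable, and an undefined
  dissimilarity is an error naming the pair. Optional support values come
  from plain column resampling — deliberately not a multiscale/AU
  correction, since support is used qualitatively. Trees export to Newick
  with merge heights as branch lengths.

## The synthetic library generator

`synthetic_library_spec()` / `generate_library()` emulate the screen the
package targets: a wildtype (doubling time ~90 min in E1,
$m = 0.0077\,\mathrm{min}^{-1}$; ~10% slower in E2), 26 single deletions
with graded relative fitness 0.75–1.0, all pairwise doubles following
multiplicative neutrality perturbed by planted $\varepsilon_{fit}$ per
environment, replicate noise multiplicative normal (lognormal by flag) with
CV 0.03, and replicate counts 19/19/4 for wildtype/singles/doubles — the
replicate floors of the emulated screen design. 2.8% of doubles are dropped
as unassayed (absent rows, the "grey squares"). The planted truth table
carries $\varepsilon_{fit}$ per environment and the implied
$\varepsilon_{sen}$ and $\varepsilon_{env}$, satisfying the identity
exactly by construction. `generate_od_curves()` adds the raw-OD layer for
testing the fitter.

`standard_scenarios()` fixes five study designs: `"null"` (no
interactions), `"static"` (20 pairs, $\varepsilon = \pm 0.3$ equal in both
environments — F's territory, invisible to S), `"modulated"` (the same
pairs with $\varepsilon$ only in E2 — S's territory), `"complex"` (three
complexes of 3/4/3 genes whose members share a common sensitivity ratio
and whose doubles inherit the single-mutant sensitivity: co-equivalent
masking planted on sensitivity, with the member fitness values 0.80–0.90
chosen so that the corresponding *fitness* equivalence fails by ~0.15–0.3),
and `"modules"` (two 4-gene modules, within/between S-scores −0.4/+0.3,
CV 0.02, the clustering benchmark).

What the generator does *not* emulate: plate spatial effects, lag and
stationary phases, evaporation, strain-construction artefacts, or
correlated replicate structure. Passing the validation suite therefore
demonstrates correctness of the inferential machinery under the stated
noise model, not robustness to everything real plates do.

## Numerical and statistical choices

* Scores are computed from mean rates; replicate CVs travel alongside and
  enter only the significance layer.
* One library has one wildtype estimate, so all of a library's S-scores
  share its noise — an O($cv/\sqrt{n_{wt}}$) library-wide offset (~1–3%).
  Quantities about central tendency or false-call *rates* are therefore
  estimated over replicate simulated libraries (24 for null-score medians,
  5 for call rates) in the validation suite and acceptance script; a
  single library's median is one draw of that offset, not an estimate of
  the method's centring.
* Validation problem sizes: 1000 random rate sets for the identity (checked
  in relative terms, since extreme rate ratios push scores to magnitudes
  where an absolute $10^{-12}$ is below double resolution); 5000 null pairs
  at $10^4$ bootstrap trials for calibration; $10^4$ trials for all
  power/recovery runs (the production default stays 300000).
* Degenerate inputs: zero CVs are legal (the bootstrap degenerates
  gracefully; an exactly-zero score gets P = 1); `n = 1` replicates get the
  library-median CV; missing rates make a score undefined and skipped with
  a report, never silently zero.

## Limitations

* The bootstrap normality assumption is untested for heavy-tailed replicate
  noise; the lognormal generator flag exists to probe this.
* The F-family test is mildly anti-conservative at loose thresholds under
  few-replicate designs (sample-CV noise in the null variance); rankings
  are unaffected, but exact error control at $\alpha = 0.05$ is at the
  band edge.
* Masking direction cannot distinguish upstream-of from
  physically-complexed-with; co-equivalence is expected for complexes and
  the statistic treats both directions symmetrically in that case.
* Profile clustering needs enough shared partners per gene pair; sparse
  libraries degrade the correlation estimates before they degrade the
  scores.
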