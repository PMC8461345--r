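---
title: "Latent profiles of brain structure: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent profiles of brain structure: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainprofiles)
```

## The problem and the model

Univariate brain-structure studies relate one region at a time to
psychopathology. This package takes the person-centered alternative:
identify subgroups of children whose *pattern* across many regions is
similar, then ask whether subgroup membership carries information about
concurrent and future psychopathology beyond global head size.

The measurement model is a latent profile analysis (LPA): for subject $i$
with standardized indicator vector $z_i \in \mathbb{R}^{18}$ (14 ICV-residualized
subcortical volumes, 4 orbitofrontal thicknesses),

$$f(z_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{18}
  \mathcal{N}(z_{ij};\, \mu_{kj},\, \sigma_j^2),$$

with class-varying means, a class-invariant diagonal covariance, and free
mixing proportions, giving $18K + 18 + (K-1)$ free parameters
(`count_parameters()`). This structure — local independence with shared
indicator variances — is the default LPA parameterization in the mixture
software this field predominantly uses, and it is corroborated by the
parameter counts such software prints for 18 indicators
($19K + 17$; e.g. 112 at $K=5$). Sampling weights $w_i$ enter as a
pseudo-likelihood: EM maximizes $\sum_i w_i \log f(z_i)$.

Estimation (`fit_lpa()`) uses multi-start EM: initial class means are
drawn from randomly chosen observations, all starts run a 15-iteration
burn-in, the best `n_final` continue to a relative log-likelihood
tolerance of `1e-7` (at most 500 iterations), and the fit is flagged
*replicated* when the two best distinct converged log-likelihoods agree
within `1e-4` — the operational version of "enough random starts to
replicate the maximum". All densities are computed in the log domain with
log-sum-exp, so posteriors remain finite for $|z|$ up to at least 40.
Residual variances are floored at `1e-4`; a fit that touches the floor is
flagged inadmissible downstream. Profiles are reported in descending
mixing-proportion order (ties broken lexicographically on the mean
vectors) so that repeated runs and the characterization stage agree;
profile numbering carries no substantive meaning.

## Preprocessing

Subcortical volumes are residualized on intracranial volume by ordinary
least squares (unweighted, pooled across sexes) and then standardized over
the full analysis sample; cortical thicknesses are standardized but not
residualized. Standardization uses the $n-1$ SD. Both choices are recorded
in the stored transform parameters, which replay bit-for-bit on the
fitting sample. Subjects with any missing indicator are excluded before
fitting and counted. A constant ICV is an error rather than a silent
centering fallback: it signals a broken covariate, not a degenerate
analysis request.

## Model selection

For each $K$ in the configured range (default 2–9) the solution table
reports AIC, BIC, sample-size-adjusted BIC (penalty computed at
$(n+2)/24$, the convention of the field's mixture software), AICC,
relative entropy
$E = 1 - \sum_i \sum_k -p_{ik}\log p_{ik} / (n \log K)$, and screening
flags: profiles holding under 3% of the sample by modal assignment,
non-convergence or a floored variance, and non-replicated maxima. BIC is
weighted most strongly; `selected_K` is set only when BIC attains a strict
interior minimum over the fitted range — when every criterion keeps
falling as $K$ grows (the situation the synthetic default reproduces),
selection is explicitly left to substantive judgment, and the pipeline
characterizes a preferred solution (default $K=5$) while saying so.

Two tests of $K$ vs $K-1$ are provided. `lmr_lrt()` implements the
approximate likelihood-ratio test: $2(LL_K - LL_{K-1})$ referred to a
weighted sum of $\chi^2_1$ variables whose weights are eigenvalues of the
Vuong matrix assembled from both fits' per-observation analytic scores
(outer-product estimate of $B$) and a finite-difference derivative of the
analytic score vector (estimate of $A$); tail probabilities come from
Imhof-type numerical inversion, integrated piecewise over oscillation
periods. An adjusted variant divides the statistic by $1 + 1/(d \log n)$,
the ad hoc Bartlett-style small-sample correction, where $d$ is the
parameter difference. `bootstrap_lrt()` is the parametric bootstrap
alternative: refit both models on data simulated from the smaller one,
$p = (1 + \#\{LR_b \ge LR\})/(B+1)$.

**Known limitation.** The weighted-chi-square approximation expands both
likelihoods quadratically around their fitted values. The global
multi-start maximum of an overfitted mixture is a supremum over many
spurious local optima, which a local expansion understates: in our null
calibration (single 18-dimensional Gaussian, $n = 1000$), the statistic
concentrates around 36 while the estimated reference distribution centers
near 24, so the approximate test rejects a true one-class model more often
than its nominal level. This is the known weakness of this family of
approximations for mixtures and the reason the parametric bootstrap is
generally preferred; the package ships both, and the solution-table
p-values should be read as heuristic screening information, exactly as
the surrounding fit indices are.

## Profile characterization

`characterize_profiles()` describes each profile by model-estimated means
at least 0.30 SD above or below the grand mean (the indicators are
standardized, so the grand mean is 0). Deviations within 0.05 SD below
threshold are reported as near-threshold notes rather than flags —
a mean of 0.27 is *not* flagged at threshold 0.30. Labels are assembled
from a fixed region-group map: striatal = caudate, putamen, pallidum,
accumbens; limbic = amygdala, hippocampus; thalamus grouped with the
subcortical set; OFC thickness separately. "Bilateral" wording requires
both hemispheres flagged; when at least 80% of subcortical indicators move
together the label collapses to "subcortical volume". The threshold is
monotone by construction: raising it can only remove flags.

`stability_check()` matches profiles between two fits by exact assignment
(minimum summed squared mean distance over permutations — exhaustive
search is exact for $K \le 9$) and reports per-profile modal agreement on
the common subjects, the quantity behind "membership > 95% consistent"
claims.

## Comparing profiles on outcomes: the manual three-step

Treating modal class as known attenuates outcome contrasts toward zero,
because misclassified subjects drag class means together. The package's
default estimator follows the three-step logic with pseudo-class draws:

1. Fit the LPA and keep the posterior matrix $p_{ik}$.
2. Draw $M = 20$ independent label sets $s_i^{(m)} \sim p_{i\cdot}$.
3. For each draw, fit the weighted outcome regression (linear for
   dimensional scores, logistic for lifetime diagnoses) on profile
   indicators plus a priori covariates (age, sex at birth, ICV; plus the
   baseline score for follow-up outcomes), with a cluster-robust (CR0)
   sandwich over the 21 sites; listwise deletion over outcome and
   covariates, with the retained $n$ recorded.
4. Undo the draw classification error: adjusted per-drawn-class estimates
   $a$ satisfy $a = D\mu$ with
   $D[s,k] = P(\text{true}=k \mid \text{drawn}=s)$ computable from the
   posteriors, so $\hat\mu = D^{-1}a$ (for diagnoses the correction mixes
   probabilities, so it is applied on the response scale). Without this
   correction the pseudo-draw estimator is *more* attenuated than modal
   assignment — drawing adds classification noise; `correct = FALSE`
   exposes the naive variant for exactly that demonstration.
5. Pool across draws by the combination rules (mean estimate; total
   variance = within + $(1+1/M)$ between), Wald-test the $K-1$ profile
   contrasts, BH-adjust the omnibus p-values within the three outcome
   families (baseline dimensional, baseline diagnoses, follow-up
   dimensional — the child-report prodromal scores travel with the
   dimensional family of their wave), and report pairwise z-tests at raw
   $\alpha = 0.05$ with grouping letters only where the adjusted omnibus
   test is significant.

`bch_correction()` implements the classification-error-corrected
alternative built on modal assignment: subjects carry the row of the
inverted average classification matrix indexed by their modal class, and
weighted class means of the outcome are then consistent. The two
estimators agree within Monte-Carlo error across the entropy range the
synthetic cohorts span.

Because the draws are made from the step-1 posteriors alone — they do not
condition on the outcome — they are improper imputations in Rubin's
sense, and the pooled variance errs on the conservative side; in null
simulations at entropy 0.75 the omnibus test's type-I error sits at or
slightly below the nominal 5%. This is a property of the published
procedure itself, not of this implementation, and we document it rather
than re-derive a different estimator.

Effect sizes: Cohen's $d$ is the adjusted mean difference over the pooled
within-profile SD of the raw outcome; for diagnoses the adjusted log-odds
difference is converted by $\sqrt{3}/\pi$ (the logistic latent-scale
convention, used because the source analyses print $d$ for binary
outcomes without defining a conversion). $\omega^2$ uses the ANOVA
decomposition $(SS_B - df_B \cdot MS_W)/(SS_T + MS_W)$ on the
covariate-residualized outcome, truncated at zero and averaged over
draws; for binary outcomes a latent-scale analogue (between-profile
variance of adjusted log-odds over that plus $\pi^2/3$) is reported and
flagged approximate.

## What the synthetic cohort emulates — and what it does not

The generator (`cohort_config()`, `generate_cohort()`) produces the
structure every stage assumes: 21 sites; families contributing a second
child with probability 0.25 and one participant per family kept at
random; lognormal sampling weights (sdlog 0.35) normalized to mean 1;
47.8% female; age uniform on 9–11 years; ICV $1500 \pm 100$ cm³ with a
0.7 SD male–female difference; 18 indicators drawn from a $K=5$ mixture
with an ICV loading of 0.4 SD on the volume indicators; dimensional
outcomes with very small profile effects (differences of 0.05–0.15 SD,
chosen so $\omega^2 < 0.01$ at study scale), site intercepts of 0.05 SD,
an autoregressive baseline-to-follow-up correlation of 0.55, an optional
nonnegative count-like scale for the checklist scores, and lifetime
diagnosis prevalences between 0.06 and 0.42 with small class log-odds
shifts. Outcome cells go missing independently at 5%.

The default class-mean preset encodes the five published profile
patterns (reduced subcortical; reduced OFC thickness; reduced limbic /
elevated striatal; elevated OFC / reduced striatal; elevated OFC and
subcortical). The within-profile SD is $c\sqrt{1 - B_j}$ with a single
factor $c = 1.08$ fixed once so that the true-model relative entropy on
the standardized scale is approximately 0.75, the classification quality
reported for five-profile solutions of this kind; with that choice the
mixture-implied standardized means (`true_standardized_means()`) preserve
the published pattern of which indicators cross the 0.30 SD threshold.
Indicator correlations with ICV and between-region residual correlations
beyond the profile structure are free parameters of the generator, not
estimates — the source tables do not report them.

What passing tests on these cohorts shows: the estimation, selection,
characterization, and comparison machinery recovers known structure under
the stated design. What it does not show: anything about real
morphometry — real ROI volumes have within-class covariance beyond ICV,
site effects on the indicators themselves, non-Gaussian tails, and
QC-correlated missingness, none of which are simulated.

## Numerical choices and degenerate inputs

* EM tolerance `1e-7` (relative), max 500 iterations, variance floor
  `1e-4`; the floor doubles as the admissibility screen.
* Modal ties break toward the lowest profile index; profile order is
  descending $\pi$ with a lexicographic tie-break.
* The BCH and draw-mixing matrices are rejected when their condition
  number exceeds `1e6` (advice: use the pseudo-draw estimator, or accept
  that entropy is too low for any three-step correction).
* Logistic separation is detected (non-convergence or a profile
  coefficient beyond 10 on the logit scale) and handled by Haldane-style
  half-weight pseudo-observations, flagged in the result.
* A single site falls back to the unclustered HC0 sandwich — with one
  cluster the clustered "meat" would collapse to an outer product of one
  summed score.
* Imhof integration proceeds in steps of one oscillation period with a
  moment-matching fallback if a piece fails to integrate.

## Problem sizes used by the test suite

The suite exercises the pipeline at the largest sizes that keep the whole
run comfortably reproducible on a single CPU: parameter recovery on a
9000-subject cohort (100 starts); BIC consistency over 50 seeds at
$n = 2000$; LMR null calibration over 200 replicates at $n = 1000$ with a
20-dataset bootstrap cross-check at $B = 99$; three-step type-I
calibration over 300 replicates at $n \approx 700$ with known-model
posteriors (isolating the comparison machinery from estimation noise);
and bias checks at $n = 20000$. The analysis scripts under `analysis/`
run a 3000-family cohort through the full 2–9 profile workflow.

## Known limitations

* The LMR-type approximation is anticonservative for overfitted mixtures
  (see above); prefer the bootstrap test when the decision matters.
* Pseudo-class-draw pooling is mildly conservative for the omnibus test
  (improper imputation), so borderline omnibus effects may be missed.
* The $\omega^2$ for binary outcomes is a latent-scale approximation.
* Sampling weights enter the mixture fit as a pseudo-likelihood and the
  outcome models as regression weights; no design-based variance for the
  mixture parameters themselves is attempted (the engine reports point
  estimates and posteriors only).
* With fewer than ~20 sites the CR0 sandwich can under-cover; the
  package does not implement small-cluster corrections.
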