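---
title: "Methods: design-based CSMF comparison and facility-to-population projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design-based CSMF comparison and facility-to-population projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaproj)
```

## The problem

Verbal autopsy (VA) surveys assign each under-5 death a cause from a
short fixed scheme (10 neonatal, 12 child causes) and record where the
death occurred. Deaths in hospitals or other health facilities could in
principle be medically certified; deaths at home, en route, or elsewhere
cannot. If facility and community deaths had similar cause distributions
— or if their differences could be adjusted away using covariates
available in routine surveys — facility causes could be projected to the
whole population. `vaproj` provides the estimation, testing, projection
and simulation machinery for that question, for data with a stratified,
clustered, weighted survey design.

## Data model and place classification

A record set is one row per death with a cause label, the raw place of
death, demographic covariates, and design columns (stratum, PSU, weight;
each PSU belongs to exactly one stratum and weights are positive).
The binary place class is a pure function of the raw place: hospital
deaths and deaths at another health provider *seen at a facility* are
facility deaths; home, en-route and other deaths are community deaths.
Finer facility sub-categories (health centre, health post, private
doctor/clinic) are accepted in input but collapsed before
classification, because every analysis uses only the binary split. A
death at an "other provider" whose setting was never resolved is a
validation error rather than a silent guess — the data, not the code,
must resolve it. Missing covariates are kept as missing at load (an
explicit `"missing"` level at model-fitting time); imputation is out of
scope because it would silently alter the CSMF denominators.

## Estimation and the accuracy statistic

The CSMF for cause $j$ in a subset is the weighted proportion
$\sum_i w_i 1\{c_i = j\} / \sum_i w_i$; in census mode all weights are
1. Causes absent from a subset keep fraction 0 so vectors stay
conformable. Agreement between a predicted and a reference distribution
is summarized by CSMF accuracy

$$\mathrm{acc}(p, r) = 1 - \frac{\sum_j |r_j - p_j|}{2\,(1 - \min_j r_j)},$$

which is 1 iff $p = r$ and 0 when all predicted mass sits on a
minimum-fraction cause of $r$ with disjoint support (the maximal
divergence attainable given $r$). The statistic is asymmetric; this
package's convention is that the reference is the quantity being
estimated: the community distribution when comparing facility to
community deaths, the observed population distribution when scoring
projections. The reference role is an explicit argument so the opposite
convention is one flag away.

## Design-based uncertainty

Confidence intervals use a percentile bootstrap resampling PSUs: each
replicate redraws, independently within each stratum, the original
number of PSUs with replacement, carrying all records of a drawn PSU
(k draws contribute the records k times). Weights are not rescaled
after resampling — the plain with-replacement reading of PSU
resampling; Rao–Wu rescaling would be the alternative and is documented
as such. In census mode each record is its own resampling unit. The
default replicate count is 1000 for plain statistics and 200 for
projections whose replicates refit models. Replicates on which a
statistic is undefined (for instance a resample that loses one place
class) are dropped with a logged count; more than 10% dropped is an
error. Percentile endpoints necessarily stay inside the statistic's
range; no BCa correction is applied, matching the simple description of
the procedure this package follows.

## The Rao-Scott corrected chi-square

No survey-analysis dependency is used; the correction is implemented
directly. For a place-by-category table the Pearson statistic $X^2$ is
computed from weighted cell proportions scaled by the raw sample size.
The design-effect matrix of the independence contrasts is estimated by
linearization: the influence of record $i$ on the cell-proportion vector
is $(w_i/W)(\delta_i - \hat p)$, summed to PSU totals and combined with
the stratified with-replacement covariance estimator; the null
(multinomial) covariance is evaluated at $\hat p$ with the matching
$n - 1$ small-sample factor. With eigenvalues $\lambda_1, \dots,
\lambda_d$ of the generalized design-effect matrix ($d$ = number of
independence contrasts), the second-order corrected statistic is
$X^2 / (\bar\lambda (1 + a^2))$ with $a$ the coefficient of variation of
the $\lambda$'s, referred to an F distribution with Satterthwaite
numerator degrees of freedom $d/(1+a^2)$ and denominator degrees of
freedom proportional to (PSUs − strata). A first-order variant
($\bar\lambda$ only) is available.

Two numerical conventions matter. First, the matched small-sample
factors make the design effect *exactly* 1 under a degenerate iid design
(every record its own PSU, equal weights), so the corrected statistic
reduces exactly to the Pearson chi-square. Second, the F reference at
finite denominator degrees of freedom cannot reproduce the chi-square
p-value exactly, so the reference is exposed as an option
(`p_reference = "F"` or `"chisq"`); census-mode data use the ordinary
Pearson test outright, since there is no design to correct for.

Per-cause comparisons fall back to the Fisher exact test (two-sided, by
summing hypergeometric probabilities not exceeding the observed table's)
when any raw cell is zero or any expected raw count is below 5. That
trigger is this package's decision — published tables mark *which* tests
were exact but not the rule. Fisher operates on raw unweighted counts,
because exactness is undefined for non-integer weighted counts; a
message flags the approximation whenever weights are non-uniform. No
multiplicity adjustment is applied to the per-cause p-values, matching
the analysis this package reproduces.

## Projections A-E

All five schemes use only facility deaths to learn about causes.
Projection A substitutes the observed facility CSMF for the community.
Projections B-E fit a cause model among facility deaths — B a
multinomial logit on age band and mother's education (plus any formal
antenatal care for neonates); C a random forest adding sex, facility
birth and wealth quintile; D a random forest on B's covariates; E on B's
covariates plus facility birth — and predict each community death's
cause probabilities. The default aggregation is *soft* (survey-weighted
average of predicted probability vectors); *hard* assignment (top cause
per record, scheme-order tie-break) is a flag, since the source analyses
do not say which was used and soft aggregation has lower variance. The
population prediction is the exact mixture
$p_{\text{fac}} \cdot \widehat{f} + (1 - p_{\text{fac}}) \cdot \widehat{c}$
and is scored against the observed population CSMF.

Numerical choices: the multinomial logit carries a small ridge penalty
(`decay = 1e-4`, intercept-free in effect for the separation problem it
solves) so that sparse cause-by-covariate cells cannot produce divergent
coefficients while the covariate sets stay exactly as specified; the
random forest uses 500 trees, minimum node size 1,
$\lfloor\sqrt{p}\rfloor$ candidate features per split, probability
estimation, a fixed seed, and single-threaded prediction for exact
reproducibility. Survey weights enter both model kinds as observation
weights by default (`weighted = FALSE` gives the unweighted reading;
the sources are silent on this). Training rows are sorted by record id
before fitting so results cannot depend on input order. Causes with no
facility deaths are structurally unprojectable — they receive predicted
community fraction 0 and are listed in the result rather than hidden.
"Other" and "unspecified" are ordinary model classes. Bootstrap
intervals for model-based projections refit the model on every
replicate, so they carry full-pipeline uncertainty.

The facility-share sweep holds both place-specific distributions fixed
and varies the facility share $w$; the numerator of the accuracy
statistic then shrinks exactly linearly,
$\sum_j |f_j - m_j(w)| = (1-w)\sum_j |f_j - c_j|$, and accuracy reaches
1 at $w = 1$.

## The synthetic-data generator

Every stage is testable without the archived study data through a
generator whose truth is known exactly. A scenario fixes: the survey
design (default 10 strata of 6 PSUs; unit-mean log-normal weights with
sd 0.3 clamped to [0.2, 5], a DHS-like dispersion without extremes);
independent covariate marginals (with small missingness where real
studies have it); a logistic place-of-death model (per-covariate-level
log-odds); and a cause model — per-place baseline CSMF plus optional
covariate log-odds offsets *shared by both places*. Shared offsets make
the cause-given-covariates law transportable, the assumption under
which covariate adjustment can recover the community CSMF; setting them
to zero with different baselines gives non-transportable divergence;
zero offsets with equal baselines give an exact null. True place-specific
CSMFs and the true facility share are obtained by enumeration over the
finite covariate grid, never by sampling, and satisfy the mixture
identity by construction.

Country presets emulate the four published studies: the preset
population CSMF equals the printed cause-specific proportions
(renormalized after rounding), the true facility share equals the
observed share (the place-model intercept is solved by root finding
over the enumerated grid), Cameroon is census-mode, and the covariate
effects on place of death reproduce the observed direction of imbalance
(facility deaths younger, far more often facility-born, wealthier, more
educated mothers). Because true place-specific CSMFs were never
published, presets derive them from the population CSMF by a facility
log-odds tilt ($f \propto m\,e^{\tau}$, community solving the mixture
identity); the default tilt follows the direction of the significant
published differences (facility toward birth asphyxia/injury, preterm
and pneumonia in neonates, meningitis and malaria in children;
community toward sepsis and ill-defined causes) with magnitudes that
are free scenario parameters. Presets keep cause-covariate offsets at
zero: cause depends on place only, covariates on place, which
reproduces the demographic imbalance without disturbing the targeted
place-specific CSMFs.

What the generator does *not* emulate: within-PSU correlation of causes
or covariates (records are exchangeable within PSUs, so the design
correction is exercised mechanically rather than stressed),
informative weights, recall error in cause assignment, and any
dependence structure among covariates. Passing tests therefore show the
pipeline's correctness and calibration under a clean design, not VA
misclassification behaviour on real interviews.

## Problem sizes in the test suite

The operating-characteristic tests use sizes chosen to give stable Monte
Carlo estimates at desk scale: type-I error from 200 simulated null
studies of 800 deaths; bootstrap coverage from 200 studies of 1200
deaths with 200 replicates each (the coverage scenario puts a tilt on
every cause so no per-cause difference is null — with many null causes
the plug-in accuracy estimator's |noise| bias pushes percentile
intervals below the truth); projection recovery from 10 studies of 5000
deaths; the birthplace comparison from 100 studies of 1200 deaths.

## Known limitations

* The accuracy statistic's denominator depends on the reference's
  minimum fraction; with 10-12 causes the minimum is usually near 0 and
  the statistic behaves like $1 - \tfrac12 L_1$.
* Facility-based projection cannot recover causes that never occur in
  facilities (they are reported as unprojectable, not imputed).
* Model-based community predictions inherit the facility sample's
  sampling noise: their expected $L_1$ error from the truth is bounded
  below by roughly $\sqrt{2/\pi}\,\sum_j\sqrt{p_j(1-p_j)\,/\,n_{\text{fac}}}$
  even when the model is correctly specified, so a few thousand facility
  deaths cannot pin the community CSMF much below $L_1 \approx 0.03$-$0.05$.
* The bootstrap treats first-stage sampling as with-replacement and does
  not rescale weights; designs with high sampling fractions would need
  the rescaled variant.
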