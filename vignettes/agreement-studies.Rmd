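---
title: "Scoring distal radius fractures and measuring observer agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring distal radius fractures and measuring observer agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idealclass)
```

## The IDEAL score

The IDEAL classification grades a distal radius fracture at first
presentation from five binary items, each worth one point:

* **I**ncongruity — an articular step or gap of at least 2 mm;
* **D**isplacement — the fracture requires reduction, either stated
  explicitly or derived from radiographic thresholds (radial shortening
  > 3 mm, loss of volar tilt > 10°, or loss of radial inclination > 5°,
  all strict);
* **E**nergy — a high-energy mechanism (anything beyond a fall from
  standing height);
* **A**ge — 60 years or older;
* **L**esions — any associated lesion (radiocarpal dislocation or
  subluxation, carpal fracture, carpal or distal radioulnar instability,
  neurovascular injury, open fracture, distal ulnar fracture).

The total (0–5) maps to three types: 0–1 points Type I (stable,
conservative treatment, good prognosis), 2–3 points Type II (potentially
unstable, pins / external fixation / plating, intermediate prognosis),
4–5 points Type III (complex, associated fixation methods and possibly
bone graft, poor prognosis).

Two boundaries are printed inconsistently in the system's published
descriptions: the incongruity cut-off appears both as "> 2 mm" and as
"≥ 2 mm", and the age cut-off both as "≥ 60" and as "> 60 / < 60"
(leaving exactly 60 undefined). This package fixes both inclusively — a
step of exactly 2 mm scores, and age exactly 60 scores — as deliberate,
documented design choices rather than guesses at intent
(`ideal_thresholds()` records them). The three displacement thresholds
are strict, matching their printed form. Units are fixed to millimetres
and degrees; no auto-detection is attempted.

`ideal_score_space()` enumerates all 32 component vectors: the
0–1 / 2–3 / 4–5 bands partition the score range with no gaps or
overlaps, and raising any single component can never lower the type —
both properties are asserted in the test suite rather than assumed.

```{r}
fracture <- radiographic_findings(articular_step_mm = 2.0,
                                  radial_shortening_mm = 4)
patient <- case_context(age_years = 66, energy = "low",
                        lesions_present = FALSE)
ideal_classify(fracture, patient)
```

## Agreement statistics

Reproducibility studies of classification systems rate the same cases
several times and summarise concordance with chance-corrected kappas.

**Cohen's kappa** (two raters) is $(p_o - p_e)/(1 - p_e)$ with observed
agreement $p_o$ and chance agreement $p_e$ from the product of marginal
label distributions. Its standard error is the large-sample delta-method
estimate of Fleiss, Cohen and Everitt, and intervals are normal
approximations clipped to $[-1, 1]$.

**Fleiss's kappa** generalises to $m$ raters per subject from a
subjects-by-categories count matrix: per-subject agreement is the
fraction of concordant rater pairs, chance agreement the sum of squared
pooled category shares. The reported standard error is Fleiss's
large-sample formula; note it is derived under the no-agreement null, so
intervals far from zero are first-order approximations (a caveat shared
by most software implementing this estimator).

Intraobserver reproducibility across the repeated sessions T1, T2, T3 is
computed by treating one observer's sessions as interchangeable
replicate raters and applying Fleiss's kappa; the method is named in
study reports without specifying the arrangement, and sessions-as-raters
is the natural one. Pairwise Cohen kappas between consecutive sessions
(`session_drift()`) are reported separately because they answer a
different question — whether familiarity with a system improves
consistency over time.

Interobserver agreement at a session applies Fleiss's kappa with
observers as raters; `pairwise_mean_kappa()` additionally reports the
unweighted mean Cohen kappa over all observer pairs, a summary some
study reports print alongside.

**Interpretation bands** follow the convention used in fracture
classification studies: below 0.5 unsatisfactory, 0.5–0.75 satisfactory,
above 0.75 excellent. "Between 0.5 and 0.75" is read as the closed
interval, so both boundary values are satisfactory.

**Degeneracy.** When both raters assign one identical constant label,
$p_e = 1$ and the kappa ratio is undefined; such estimates are returned
as 1 with zero standard error and an explicit `degenerate` flag, and
degenerate pairs are excluded (with a warning) from pairwise means —
never silently turned into `NaN`.

**Cross-system comparison.** Published comparisons of kappa values
across systems cite an F test without further specification. Here
`compare_kappa_sets()` performs a one-way analysis of variance on
unit-level kappas — the units being observers (intraobserver) or
sessions (interobserver) — plus all pairwise two-group F tests, and
optionally a permutation p-value obtained by permuting group membership.
The parametric test treats the unit-level kappas as exchangeable
observations and ignores their pairing across systems; with only a
handful of units it is indicative rather than powerful, which is why the
permutation alternative is offered. The method name is recorded in the
output.

**Missing ratings** are handled by dropping subjects that lack a
complete rater/session panel for the analysis at hand, with a logged
count; no imputation is attempted.

## Sample size by expected CI width

`required_n()` implements the expected-width planning approach of
Giraudeau and Mary: choose the smallest number of subjects such that the
anticipated two-sided confidence interval for kappa is acceptably
narrow. The variance model is the common-correlation binary
(intraclass) model with two replicates per subject,

$$\mathrm{var}(\hat\kappa) = \frac{1-\kappa}{n}\Big[(1-\kappa)(1-2\kappa)
  + \frac{\kappa(2-\kappa)}{2\pi(1-\pi)}\Big],$$

with prevalence $\pi$ defaulting to 0.5 (the least favourable and the
usual planning default when the case mix is unknown). For more than two
replicates no comparably standard closed form exists; the two-replicate
variance is divided by $m - 1$ as a clearly-labelled approximation, and
the package's own analyses use the two-replicate design throughout.

A frequently quoted planning point — expected kappa 0.70 at 90%
confidence needing about 50 subjects — omits the assumed width and
prevalence. At $\pi = 0.5$ the width that makes $n = 50$ exactly
sufficient is:

```{r}
w50 <- kappa_ci_width(0.70, n = 50, prevalence = 0.5, conf = 0.90)
w50
required_n(0.70, max_expected_width = w50, conf = 0.90)
```

so (π = 0.5, width ≈ `r round(kappa_ci_width(0.70, 50, 0.5, 0.90), 3)`)
is one combination reproducing it; smaller prevalences pair with larger
widths. The package documents these combinations rather than asserting
any one of them as the original assumption.

## The rating simulator

Because reproducibility studies rarely deposit their raw ratings, the
package ships a simulator that generates complete studies with known
ground truth, so every estimator can be validated against analytic
expectations.

**Cases.** `generate_cases()` draws a case mix from a two-component
displacement mixture (an essentially undisplaced and a displaced
component, truncated at zero), a truncated-normal adult age
distribution, and Bernoulli high-energy/lesion indicators. The defaults
(60 cases; mean age 62, SD 18; 25% high-energy; 15% lesions; 65%
displaced; articular involvement in 50% of displaced and 10% of
undisplaced fractures) are chosen to resemble an unselected adult
distal-radius-fracture series — predominantly older, low-energy,
moderately displaced injuries — since no published case-mix table exists
for such convenience samples; they are documented defaults, not an
empirical case mix. True IDEAL labels are obtained by actually scoring
the true findings; true Frykman/Fernandez/AO labels are sampled from
configurable category distributions (uniform by default) because those
systems' internal morphological logic is out of scope — only their label
alphabets (8, 5 and 9 main-subgroup categories) matter for agreement
statistics.

**Observers.** An `observer_profile()` carries Gaussian measurement
noise per continuous finding (IDEAL ratings arise by perturbing the true
measurements and re-scoring — negative perceived values are clamped at
zero), flip probabilities for the binary items, and a row-stochastic
confusion matrix per categorical system. The default confusion model
places `accuracy` on the true label and spreads the rest uniformly
(`uniform_confusion()`): the simplest model, chosen deliberately because
observed and chance agreement then have closed forms
(`analytic_cohen_kappa()`, `analytic_fleiss_kappa()`), which the test
suite exploits for parameter-recovery checks. The default six-observer
panel spans a low-noise specialist down to two high-noise students.

**Session correlation.** Within-observer consistency beyond what truth
induces is modelled by a single parameter $\rho$: at sessions after the
first, with probability $\rho$ the observer reuses their session-1
perception of the case, otherwise they perceive it afresh. $\rho = 1$
forces identical labels across sessions (intraobserver kappa exactly 1);
$\rho = 0$ gives conditionally independent sessions. One consequence of
this anchoring construction is asymmetry: for $\rho > 0$ the expected
T1-vs-T2 agreement, $\rho + (1-\rho)\bar S$, exceeds the T2-vs-T3
agreement, $\rho^2 + (1-\rho^2)\bar S$ (where $\bar S$ is the expected
fresh-redraw agreement), so null learning-effect checks are run at
$\rho = 0$. `analytic_intraobserver_kappa()` gives the closed-form
sessions-as-raters kappa under this model. Optional per-session error
multipliers shrink or inflate an observer's error at chosen sessions to
model a learning effect.

**Randomness.** A single global seed expands into labelled substreams
(`substream_seed()`): case generation, each observer-by-system rating
stream and each presentation order draw from their own stream, so adding
an observer never perturbs the cases or the other observers' ratings.
`randomize_presentation()` produces the blinded randomized reading order
per observer and session.

What the simulator does **not** emulate: real radiographic measurement
physics, correlated errors between systems rated by the same observer,
case-difficulty heterogeneity (some radiographs being intrinsically
ambiguous), and truth labels for the established systems that derive
from morphology. Passing parameter-recovery tests therefore demonstrates
the correctness of the estimators and pipeline under a known error
model, not the field reliability of any classification system.

## The study pipeline

`agreement_study()` runs the full analysis on a validated long-format
rating table: per-observer intraobserver kappas, per-session
interobserver kappas, pairwise means, drift pairs, interpretation bands
and cross-system comparisons, with metadata recording dropped subjects
and skipped analyses. Report CSVs round to 3 decimals (half-even, base
R's `round`); the JSON report keeps full precision. Two aggregations of
the per-observer intraobserver column are reported — the arithmetic mean
and a pooled Fleiss kappa over all observers' subject-by-session
panels — because published study tables are ambiguous about which
aggregation their overall row uses (printed overall values there do not
equal the arithmetic means of the printed columns, e.g. an overall 0.771
against a column mean of 0.7745). Neither is asserted to be "the"
published aggregation. Similarly, interobserver per-session values
reported in running text and tables occasionally differ in the third
decimal (0.653 vs 0.654); full-precision JSON output avoids introducing
such discrepancies downstream. The AO alphabet defaults to the nine main
subgroups A1–C3; whether a given study used the 27 full subgroups is
often unstated, so the alphabet is configurable.

```{r}
cases <- generate_cases(case_config(n_cases = 60, seed = 11))
ratings <- simulate_ratings(cases, default_observer_panel(),
                            n_sessions = 3, seed = 11)
fit <- agreement_study(ratings)
summary(fit)
```

## Numerical choices and problem sizes

Degenerate chance agreement is detected at `1 - p_e < 1e-12`; kappa
oracle-equivalence tests require agreement to `1e-12` over all label
configurations with up to 4 subjects, 3 categories and 3 raters.
Stochastic validation uses 500 subjects for within-suite
parameter-recovery checks and 1000 subjects for the headline
recovery tests, with acceptance at three standard errors — sizes at
which the analytic standard errors are small enough to be informative
while the whole suite stays fast. Monte-Carlo validation of the
sample-size variance formula uses 500 replicate two-replicate studies of
50 subjects. The cross-system F test's type-I error is checked over 400
null simulations at the study's own scale (four groups of six).

## Limitations

* The Fleiss standard error is a null-based approximation; bootstrap
  intervals would be preferable for small panels but are out of scope.
* The comparison F test ignores the pairing of units across systems and
  the sampling error of each kappa; it mirrors common practice in
  classification-reproducibility reports rather than best possible
  inference.
* Sample-size planning covers the binary two-replicate intraclass model
  only; multi-category planning formulas are not implemented.
* Weighted kappa and agreement on continuous measurements are
  deliberately absent.
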