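---
title: "SSMD decision statistics for multiplexed organoid screens"
author: "organoidScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSMD decision statistics for multiplexed organoid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidScreen)
```

# The screen and its statistical model

A multiplexed phenotypic organoid screen measures, for every well of a
384-well plate, three quantities: basal lysozyme secretion (`LYZ.NS`),
secretagogue-stimulated lysozyme secretion (`LYZ.S`), and cellular ATP
(`ATP`, a viability proxy). Wells hold either a compound at one of four
doses, a vehicle (DMSO) control in one of four stimulation-order roles
A–D, or no cells (assay background). The screen is replicated across
biological donors, and the analysis question is which treatment–dose
combinations increase lysozyme secretion in *both* assays with a
well-powered effect size.

The signal model the pipeline assumes (and the synthetic generator
implements) is additive on the log10 scale:

$$x_{ij} = \mu_{\text{assay}} + \text{plate} + f(i,j) +
  \theta_{\text{treat}}(\text{dose}) + \varepsilon_{ij},$$

where $f(i,j)$ is a smooth spatial plate artifact over rows and columns,
$\theta$ the treatment effect with a Hill dose–response, and
$\varepsilon$ well noise. Each stage of the pipeline removes or quantifies
one term of this model.

## Spatial LOESS correction

Raw values are log10-transformed (positivity is enforced at the door — the
data container rejects non-positive values by validity), and each plate ×
assay is corrected with a two-predictor local regression over integer
(row, column) positions: tricube weights, span 1, local polynomial degree
2, no robustness iterations — the defaults of the R `loess` function the
method is anchored to. The corrected value is

$$\hat x_{ij} = x_{ij} - (\text{fit}_{ij} - \mathrm{median}(\text{fit})),$$

which removes the spatial trend while preserving the plate's central
tendency exactly: a constant plate is returned unchanged and adding a
constant shifts the output by that constant (both are exact identities in
the test suite). No-cell wells are excluded from the fit and the
downstream plate median — their background signal would drag both — but
still receive corrected values by surface evaluation. Missing wells are
omitted, never imputed. The surface is evaluated with `surface = "direct"`
so masked wells and plate corners are predicted exactly rather than by
interpolation.

Fold changes stay on the log10 scale throughout (they are differences of
logs); `10^FC` is only a reporting convenience. The primary screen uses
the plate median as its reference (`plateFoldChange`), so its implicit
assumption is that most of the library is inert — the test suite probes
what happens when that assumption is strained (see Limitations). The
validation screen instead references vehicle-control medians
(`controlFoldChange`) with assay-specific control selection: all vehicle
wells for ATP; the vehicle wells basal in the non-stimulated phase (roles
A and B) for LYZ.NS; and for LYZ.S the wells that were basal first and
stimulated second (role A), i.e. the wells that experienced exactly what a
compound well experiences.

## Replicate SSMD and its decision theory

Each treatment–dose–assay group of $n$ replicate fold changes (one per
donor in the primary screen, $n = 3$; one per well in the validation
screen, $n = 8$) with mean $\bar d$ and variance $s^2$ is scored with the
UMVUE of the strictly standardized mean difference:

$$\mathrm{SSMD} = c_n \frac{\bar d}{\sqrt{w_i s^2 + w_0 s_0^2}},
\qquad c_n = \frac{\Gamma(\tfrac{n-1}{2})}{\Gamma(\tfrac{n-2}{2})}
\sqrt{\tfrac{2}{n-1}},$$

with $s_0^2$ the median of all group variances in the assay and
$w_i = w_0 = 0.5$. The $c_n$ factor makes $c_n \bar d / s$ exactly
unbiased for the true standardized effect under normality (verified
empirically at $10^5$ groups in the suite). Two deliberate properties of
this estimator deserve note:

* **Shrinkage vs unbiasedness.** The pooled $s_0^2$ term stabilizes the
  denominator at small $n$, but because the median of $\chi^2$-distributed
  variances sits below their mean, the shrunken denominator is slightly
  small on average and large effects are amplified (at $n = 3$ and a true
  SSMD of 3, the mean estimate is noticeably above 3). The pipeline keeps
  0.5/0.5 as the operational default because ranking, not unbiased
  estimation, is what hit calling needs; calibration analyses use
  $w_i = 1$ to isolate the theory.
* **Theory scale.** The FPL/FNL error curves below are built on the plain
  mean/SD $t$ statistic; the decision statistic carries the extra $c_n$.
  The package therefore evaluates the noncentral-$t$ CDF at
  $\beta/(c_n k)$, equivalently reports $\beta_{\alpha_1} = c_n k t^*$.
  This mapping was confirmed numerically before being frozen: it
  reproduces both of the workflow's anchor critical values (0.997 at
  $n = 3$ and 0.889 at $n = 8$), whereas the raw-scale reading
  ($\beta = k t^*$) gives 1.767 and 1.001. The raw scale remains available via
  `decisionParams(..., scale = "raw")`.

The error curves for an upregulation decision at threshold $\beta$ are

$$\mathrm{FPL}(\beta) = 1 - F_{t(n-1,\sqrt n \beta_2)}\!\left(
  \frac{\beta}{c_n k}\right), \qquad
\mathrm{FNL}(\beta) = F_{t(n-1,\sqrt n \beta_1)}\!\left(
  \frac{\beta}{c_n k}\right), \qquad k = \sqrt{1/n},$$

with $\beta_2 = 0.25$ ("at least very weak effect", the false-positive
bound) and $\beta_1 = 3$ ("at least strong effect", the false-negative
bound). FPL is strictly decreasing and FNL strictly increasing in
$\beta$, so the balanced threshold is the unique root of
$\mathrm{FNL} = \mathrm{FPL}$:

```{r decision}
optimalCriticalValue(decisionParams(n = 3))
optimalCriticalValue(decisionParams(n = 8, fpl = 0.05, mode = "fpl_only"))
```

Root finding uses a bracketed solver on $(10^{-6}, 20]$ with tolerance
$10^{-6}$ in $\beta$ and an explicit error when the bracket shows no sign
change; monotonicity of both curves makes the root unique and the result
bracket-independent. The noncentral-$t$ CDF is delegated to `stats::pt`
and validated in the suite against the integral representation
$E[\Phi(x\sqrt{V/\nu} - \delta)]$ with $V \sim \chi^2_\nu$.

## Gates and refinement

A primary hit must have SSMD strictly greater than $\beta_{\alpha_1}$ in
both LYZ assays; ATP is always scored and reported but never gates (hits
are called "without regard to viability"). Refined hits additionally
require a fold-change z-score strictly above $\Phi^{-1}(0.9) = 1.282$ in
both LYZ assays, where the z-score standardizes each group's mean fold
change by the sample (n−1) SD of all group means in that assay; the method
definition leaves the SD estimator open, and the sample SD is the
conventional default. Comparisons are strict (`>`), matching the "greater
than" phrasing of both hit definitions. Optimal doses are ranked by the
conservative minimum of the two LYZ SSMDs in the primary screen (a
both-assay reading of the dose rule) and by mean LYZ fold change in the
validation screen (its explicitly stated rule); exact ties break toward
the lower dose, and per-target deduplication breaks ties by lexicographic
treatment id so outputs are deterministic.

# The synthetic generator: what it emulates, and what it does not

`simulatePrimaryScreen` emulates the screen's statistical structure with
known ground truth: 433 compounds against 184 annotated targets at doses
0.08/0.4/2/10 µM, randomly placed across five 384-well plates, replicated
over three donors, with per-plate smooth spatial artifacts (low-order
polynomial ramp plus an optional edge-row/column offset,
`spatialEdgeWeight`), per-plate offsets, vehicle wells in the four
stimulation-order roles and no-cell background wells. Default per-plate
control counts (24 vehicle + 8 no-cell) are a design choice, not fixed by
the assay layout, and plates are completed with additional vehicle
wells when the library does not fill them.

Choices worth flagging:

* **Stimulation semantics of roles A–D** are reconstructed from the
  reported control contrasts: A = basal then stimulated (the compound-well
  scheme), B = basal/basal, C = stimulated/stimulated, D = stimulated then
  basal. They are exposed via `stimulatedRoles()` so the convention is
  reconfigurable in one place.
* **Effect scale.** A spiked hit with true SSMD $\beta$ shifts the log10
  signal by $\beta \cdot \texttt{effectSdLog10}$ with a Hill
  dose–response; `effectSdLog10` defaults to the well-noise SD so that
  $\beta$ is the effect in noise units, but is decoupled so the
  noise-free limit can be probed with non-vanishing effects. Abundance
  hits perturb both LYZ assays with the same latent effect (correlation
  1); secretion-only hits perturb LYZ.S alone.
* **Latent background bioactivity.** A target-selective inhibitor library
  is broadly bioactive, so every compound draws a latent effect
  $\eta \sim N(0, 1.5)$ (SSMD units) shared by both LYZ assays and coupled
  into ATP at half strength. This term was chosen to place donor-pair
  replicate correlations of group fold changes in the 0.5–0.75 band
  reported for screens of this design; setting it to 0 yields a library
  of exact nulls plus the spiked hits, which is what the calibration
  tests use.
* **Validation layout.** "4-plate replicates with 8 well replicates per
  dose" is read as 2 wells per dose per plate × 4 plate replicates, which
  is the only reading that fits 13 treatments × 4 doses plus 100 vehicle
  wells on one 384-well plate. Vehicle wells default to 25 per role
  (100 total for ATP normalization).
* **Composition counts.** Treated fractions are derived from control
  fractions by multiplying each type's (type vs rest) odds by its designed
  odds ratio. When the designed ORs are jointly inconsistent the fractions
  are renormalised and the *realized* ORs (recomputed from the final
  fractions) are reported as ground truth; consistent designs are
  unaffected. Coverage tests use consistent two-type designs.
* **Randomness.** One seeded stream per dataset, drawn in a fixed
  documented order (placement, latent effects, then per plate × assay:
  surface, offset, noise), so identical configs are byte-identical.

What the generator does **not** emulate: organoid-to-organoid biological
heterogeneity beyond a single noise term, plate-reader saturation,
cross-well contamination, dose-dependent toxicity in the LYZ channels,
batch drift across donors beyond plate offsets, or any mechanistic
dose–response shape beyond the Hill family. Passing tests therefore show
that the *statistical machinery* behaves as designed under the stated
model — not that real screens satisfy that model.

# Numerical choices and degenerate inputs

* LOESS needs at least $(\text{degree}+1)^2$ non-missing wells; span must
  lie in (0, 1].
* Groups with fewer than 2 replicates, zero denominators, or undefined
  z-scores are emitted with status flags (`too_few_replicates`,
  `zero_denominator`, `zscore_undefined`), never silently dropped. The
  UMVUE factor requires $n \ge 3$.
* Fisher enrichment: two-sided p by hypergeometric small-p summation with
  the customary $1 + 10^{-7}$ relative slack against floating-point ties
  (and capped at 1); odds ratio as the sample cross-product with a
  Haldane–Anscombe +0.5 applied only when a zero cell occurs; 95 % CI by
  the Woolf log-normal interval; conditional-MLE OR available via
  `orMethod = "cmle"`. One-sidedness is not assumed anywhere.
* The exceedance cutoff is the inverse-ECDF (type 1) percentile so integer
  count data yield integer cutoffs; exceedance is strictly greater than
  the cutoff.
* FDR defaults to Benjamini–Hochberg for enrichment; Bonferroni is exposed
  because differential-expression conventions differ.
* QC contrasts use Welch's unequal-variance t test on log10 values
  (Wilcoxon available); degenerate contrasts (a side with fewer than two
  wells, or both sides constant at different values) are flagged
  unavailable rather than failing the report.

# Problem sizes in the test suite

The suite validates calibration with 10,000 simulated replicate groups per
error-rate check and $10^5$ groups for unbiasedness; the exhaustive Fisher
cross-check enumerates all 2×2 tables with totals up to 16 plus a sampled
set with margins up to 30; CI coverage uses 150–200 seeded replicates at
10,000 cells per sample; and end-to-end recovery runs screens of up to 500
compounds × 4 doses across 18 plates. These sizes were chosen so each
check's Monte-Carlo error is small against the tolerance it asserts while
the whole suite stays comfortably interactive (~20 s).

# Known limitations

* Plate-median normalization assumes a mostly inert library. When a large
  fraction of compounds is active in one direction, the plate median
  absorbs part of the common effect and error rates drift from their
  design values; the end-to-end calibration test documents this by using a
  symmetric spike design. Control-median normalization (the validation
  mode) is the remedy when control wells are plentiful.
* The FPL/FNL theory describes the plain $t$ denominator, while the
  default pipeline denominator is shrunken (w = 0.5 with $s_0^2$); this
  estimator/theory mismatch is inherited from the method definition and
  is kept deliberately. Its practical effect at the operating point
  ($\beta \approx 1$) is small but it inflates very large effect
  estimates.
* The anchor critical values are reproduced to their quoted precision at
  the stated n; for other designs the solver is exact to its tolerance
  but has no external anchor to compare against.
* Replicate correlations are computed on group mean fold changes, the
  quantities the screen analyzes; well-level correlations would be lower
  and are not reported.
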