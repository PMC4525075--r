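---
title: "Methods: quantifying magnetic orientation in C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying magnetic orientation in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcompass)
```

wormcompass implements the statistical pipeline for studying magnetic
orientation (magnetotaxis) in *C. elegans*: geometric predictions from the
local geomagnetic field, circular statistics on migration headings,
two-choice behavioral indices, cross-isolate correlation with field
parameters, and quantification of stimulus-evoked calcium responses in the
AFD sensory neurons. Because the raw behavioral and imaging data behind
this kind of study are rarely deposited, the package pairs every analysis
stage with a seeded synthetic generator that has the statistical structure
the stage assumes; the test suite demonstrates that each stage recovers its
generator's parameters. This vignette records the models, the parameter
choices, and the design decisions that were genuinely open.

## Geomagnetic geometry

A site's field is described by its horizontal component $H \ge 0$ and
signed vertical component $V$ (Gauss; positive = pointing into the ground,
the northern-hemisphere sense), with total intensity $F = \sqrt{H^2 + V^2}$
and inclination (dip) $I = \operatorname{atan2}(V, H)$ in degrees.
Declination is carried for bookkeeping only: in a coil assay the imposed
field vector defines the reference frame, so only angles *relative to the
field* matter.

A worm on a plate that wants to translate straight up must move at angle
$\theta_{up} = 90^\circ + I$ to the field vector: within the vertical plane
containing the field, a movement at angle $\theta$ from the field has
elevation $\theta - I$, and elevation $+90^\circ$ gives $\theta = 90 + I$.
A flat assay cannot distinguish a rotation of $+\theta$ from $-\theta$
about the field axis, so the mirror candidate $(270 - I) \bmod 360$ is
always reported alongside; both attain the same maximal vertical
translation in three dimensions (the test suite checks this against a
brute-force maximization over the movement cone). Downward candidates are
the antipodes. We expose both candidates rather than resolving the
ambiguity silently; `select_candidate()` resolves it against an observed
mean heading, breaking exact ties toward the $90 + I$ branch. At $I = 0$
(magnetic equator) up and down candidate sets coincide and the prediction
is flagged degenerate — the geometric reason equatorial isolates cannot
use dip for vertical navigation.

For Bristol, England ($I \approx 66.3^\circ$) this yields up at
$156.3^\circ$ and down at $336.3^\circ$:

```{r}
optimal_vertical_headings(66.3)
```

Angle conventions: degrees everywhere, normalized to $[0, 360)$; $0^\circ$
is the plate-plane projection of the imposed field's north direction, with
compass-style (clockwise) positive rotation. Since every statistic in the
package depends only on angle differences, the convention merely has to be
applied consistently. Inclination sign follows "north pointing down"
positive; the southern hemisphere gets negative dips, which mirrors the
candidate sets (tested as a reflection identity).

## Circular statistics

A heading sample of $n$ worms $\theta_1 \dots \theta_n$ is summarized by
the mean resultant vector: $\bar C = \tfrac1n \sum \cos\theta_i$,
$\bar S = \tfrac1n \sum \sin\theta_i$, resultant length
$R = \sqrt{\bar C^2 + \bar S^2} \in [0, 1]$ and mean direction
$\hat\mu = \operatorname{atan2}(\bar S, \bar C)$. When $R$ is numerically
zero (below $10^{-12}$, e.g. exact antipodes) the mean is reported as
undefined rather than an arbitrary angle, and a downstream V statistic is
set to 0.

*Rayleigh test.* Uniformity is tested with $z = nR^2$ and Zar's corrected
approximation
$$p = e^{-z}\left[1 + \frac{2z - z^2}{4n}
  - \frac{24z - 132z^2 + 76z^3 - 9z^4}{288 n^2}\right],$$
clamped to $(0, 1]$. This is the formula behind the standard circular
toolboxes; Monte Carlo calibration at $n = 20$ (10,000 uniform replicates
in the acceptance suite) shows the p-values are uniform to
Kolmogorov–Smirnov distance $< 0.02$ and the size at $\alpha = 0.05$ is
within $\pm 0.01$.

*V test.* Against an a-priori direction $\theta_0$ (here, from the
geomagnetic prediction — never from the data),
$V = R\cos(\hat\mu - \theta_0)$, $u = V\sqrt{2n}$, with a one-tailed
upper-tail normal p-value. The normal approximation matches common
practice at the large $n$ of pooled-population data; the suite verifies
its size under rotated uniform nulls.

*Pooling.* Population-level tests treat each worm as one observation,
pooling worms across plates (the study pools over a thousand worms per
satiation state); `per_assay_summaries()` provides the per-plate
alternative for sensitivity analyses, since the right unit of inference is
arguable when plates contribute unequal counts.

*Histograms.* Circular plots use 18 bins of 20°, half-open
$[a, a + 20)$ and edge-aligned at 0° (bin phase is a convention; nothing
downstream depends on it), expressed in percent of animals.

## Behavioral indices

The magnetotaxis index $MI = (M - C)/(M + C)$ and burrowing index
$BI = (A - B)/(A + B)$ use only worms that reached a goal, matching the
formulas exactly; worms that reach neither end are excluded. An assay in
which *no* worm arrived is dropped from aggregation with a warning rather
than imputed as 0 — an arrival-free assay says nothing about choice.
Replicates are summarized by mean and SEM, with a two-tailed one-sample
test of mean = 0: Student's t when a Shapiro–Wilk screen at $\alpha = 0.05$
does not reject normality of the per-assay indices, otherwise the Wilcoxon
signed-rank test (`test_used` records the choice; the selection rule is
ours, since source analyses report using both t and rank tests without
stating a rule). If every replicate has the identical index the test is
degenerate: p = 1 when that index is 0, else 0.

## Isolate correlation and hold-out prediction

Per-isolate mean indices are regressed on one field parameter at a time
(inclination, vertical or horizontal intensity) by *unweighted* OLS with a
Pearson correlation — the source analyses are simple linear regressions,
and per-isolate SEMs are carried for display only. The held-out isolate is
predicted from the fitted line with a standard t-based 95% prediction
interval for a new observation. Coverage of that interval and recovery of
the generating slope are verified by simulation (1,000 seeded replicates);
the suite also checks the qualitative signature that motivates the
analysis — on a generator that couples the index to the vertical
component, the vertical-component correlation dominates the horizontal one
in ≥ 99% of replicates, because the synthetic horizontal component is an
even function of the vertical one and so carries no linear signal.

## Calcium-trace quantification

Fluorescence traces (GCaMP soma brightness, 3.5–8 Hz, 50-s runs: 12.5 s
baseline, 6-s stimulus, 31.5 s recovery) bleach under illumination.
Bleaching is modeled as mono-exponential, $I(t) = f_0 e^{-t/\tau}$, fitted
to samples *outside* the stimulus windows so the transient cannot drag the
baseline, and the trace is divided by the fit. The published description
of the correction procedure lives in an external reference without
formulas, so the exponential model is an explicit modeling choice here,
made for testability: the synthetic generator uses the same family, giving
exact round trips. The fit is seeded by log-linear regression (exact for
noiseless data; the nonlinear refinement is skipped when the seed already
fits to $10^{-9}$, where least squares on zero residuals is ill-posed) and
refined by `nls`; non-convergence falls back to a linear detrend with a
warning. A constant trace is normalized to 1 with $\tau = \infty$.

The response statistic is
$$\Delta\% = 100 \cdot
 \frac{\overline{I}_{[t_{off}-4, t_{off}]} - \overline{I}_{[t_{on}-4, t_{on})}}
      {\overline{I}_{[t_{on}-4, t_{on})}},$$
the mean corrected brightness over the final 4 s of the stimulus versus
the 4 s immediately before onset, positive for increases. Windows are
realized as the sample timestamps they contain (14–32 frames at the
supported rates; partial edge frames excluded). The 6-s stimulus duration
is the default protocol; an 8-s variant appears in some experiments, and
the epoch's true duration is always an explicit argument rather than a
constant — the package presumes neither. Adaptation across repeated
stimuli is reported as one statistic per epoch, ordered by onset; a
decrease is reported, never enforced. For partially restrained animals the
4-frame protocol compares the mean of the four during-exposure frames to
the mean of the eight surrounding (before + after) frames. Group-level
inference pairs each worm's baseline and response window means and applies
the same t-versus-rank rule as the indices module.

## Synthetic generators: what they emulate, and what not

* `sample_headings()`: von Mises headings (Best–Fisher rejection
  sampling). The von Mises is the canonical unimodal circular noise model;
  the real heading histograms are unimodal but their concentration is not
  published numerically. The default $\kappa = 1$ ($R \approx 0.45$)
  approximates the visible dispersion and is a configuration knob, not a
  claim. The sampler is validated against the Bessel-function identity
  $E[R] \to I_1(\kappa)/I_0(\kappa)$.
* `simulate_assay_counts()`: arrivals binomial in ~48 plated worms
  (`arrival_fraction` defaults to 1, as non-arrival rates are not
  reported), then a binomial magnet/control choice. A choice probability
  of 2/3 reproduces the published "about two thirds to the magnet"
  benchmark, giving indices near 1/3.
* `simulate_isolate_table()`: index linear in one field parameter plus
  Gaussian noise (default sd 0.05, a plausible between-assay SEM scale),
  clipped to $[-1, 1]$, over a synthetic world table of 11 sites spanning
  both hemispheres.
* `simulate_trace()`: exponential bleach ($\tau$ = 60 s default) times
  (1 + boxcar transient) plus Gaussian noise proportional to the decaying
  baseline. The boxcar is chosen so window means round-trip exactly; an
  alpha-kernel option exists for robustness checks against smooth
  transients (where the 4-s window mean necessarily under-reads the peak).

All generators are bit-identical under a fixed seed and leave the caller's
RNG stream untouched. What passing tests on these generators does *not*
show: real worms are not von Mises-distributed draws (headings correlate
within plates), real arrivals are not independent Bernoulli choices, and
real photobleaching is only approximately exponential. The generators
establish that the *statistics* are implemented correctly and calibrated;
they cannot validate the biological model itself.

## Numerical choices and problem sizes

Angle normalization uses the modulo convention with signed differences in
$(-180, 180]$ (antipodes map to $+180$). Heading recovery checks run at
the study's population sizes ($n = 1268$ fed, $1079$ starved), where the
circular-mean standard error $\sqrt{-2\ln R / n}$ is about $2^\circ$;
recovery is asserted within 3 SE. Monte Carlo calibrations use 10,000
replicates for test size and 1,000 for interval coverage; smaller
replicate counts (200–800) are used where a frequency over seeds is being
bounded rather than estimated. These sizes make the whole suite run in
well under a minute on a laptop while keeping Monte Carlo error far below
the asserted bands.

## Known limitations

* Southern-hemisphere published arcs are not numerically anchored: the
  geometric rule is validated against the England numbers and by the 3-D
  oracle; mirrored-hemisphere behavior is covered by symmetry properties
  only.
* The bleach model is mono-exponential by design; traces with two-phase
  bleaching will correct imperfectly (the fallback is a linear detrend,
  flagged by a warning).
* The index test's normality screen on ≤ ~10 discrete replicate indices
  has limited power; the Monte Carlo size check covers exactly this
  regime.
* No spatial model of the plate or of worm trajectories: indices and
  headings are endpoints, as in the assays themselves.
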