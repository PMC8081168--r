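---
title: "Measuring drinking-context characteristics from short clips: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring drinking-context characteristics from short clips: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(clipcontext)
```

# The measurement problem

Studies of drinking behavior increasingly ask participants to document
their drinking situations in the moment, including a short (10-second)
video clip of the location. Three independent channels can then measure
the same situational characteristics — brightness, loudness, and how
many people are present:

1. **Participants** rate the situation in place on five-point scales
   and report their company.
2. **Annotators** (five per clip) later rate the video clips on the
   same scales.
3. **Algorithms** extract the characteristics directly from the clip's
   pixels and audio samples.

The scientific questions are (a) how well these channels agree, (b) how
the characteristics differ between alcoholic and non-alcoholic
drinking situations across location types, (c) how the characteristics
relate to the odds of drinking alcohol once the nesting of situations
within participants is respected, and (d) how accurately the drink type
can be inferred from the context ratings alone.

Since the underlying raw videos of such studies cannot be shared, the
package includes a synthetic-study generator that emulates the study
conditions end to end: every analysis stage runs on data the package
itself can produce, and all algorithmic measures can be checked against
the generator's ground truth.

# Algorithmic measures (`rateClip`)

## Brightness

Frames are stored as intensities in $[0, 255]$. The raw luminance is the
mean intensity over all pixels of all frames, rescaled to $[0, 100]$.
Perceived lightness follows the cube-root law
$$L = 25.29\,Y^{1/3} - 18.38,$$
clamped to $[0, 100]$; the compressive exponent mirrors human
brightness perception. Lightness is binned into the five rating
categories by 20-point bins, $\lfloor L/20 \rfloor$ capped at 4, so the
bin boundaries are 20/40/60/80.

## Loudness

The audio waveform (mono, samples in $[-1, 1]$) is A-weighted in the
frequency domain with the analog IEC weighting curve, which is exact at
the FFT bin frequencies and 0 dB at 1 kHz. The squared weighted samples
are smoothed by an exponential moving average with a 0.125 s time
constant ("fast" meter dynamics), averaged, log-transformed, and
shifted by a calibration constant $C$ (default 94, i.e. an RMS of 1
corresponds to 94 dB):
$$\mathrm{dB} = 10 \log_{10} \overline{p_A(t)} + C.$$
A full-scale 1 kHz sine therefore reads $C - 3.01$ dB. Silence is
floored at 0 dB. Levels are binned at 40/50/70/85 dB into the five
rating categories.

## Attendance (person counting)

Trained deep person detectors are not reproducible deterministically,
so the package uses a surrogate with the same contract — report the
number of identity clusters (tracks) across frames:

1. background: per-pixel temporal median;
2. foreground: $|$frame $-$ background$| > \max(k \cdot 1.4826 \cdot
   \mathrm{med}|{\cdot}|,\ 10)$, with $k = 3$;
3. detections: connected components of at least `minArea` (15) pixels;
4. tracking: greedy nearest-centroid matching gated at `maxDisp` (12)
   pixels per frame, tolerating `maxGap` (2) unseen frames;
5. count: tracks observed in at least 3 frames.

On the generator's non-overlapping scenes the count is exact for 0–15
people (the acceptance suite tests every value). In crowded scenes with
random trajectories, transient overlaps can split or merge tracks —
deliberate, since real trackers degrade the same way.

# Annotator fusion (`fuseAnnotations`)

Five annotators rate each clip. Per item:

* **Ordinal items** (brightness; music and chatter loudness): if at
  least 3 of 5 raters agree, that value wins; otherwise the mean is
  rounded (half away from zero — with five integers the mean is a
  multiple of 0.2, so exact ties cannot occur).
* **Overall loudness**: each rater's maximum of music and chatter is
  taken first, then fused. Fusing before taking the maximum would let
  two different minority opinions manufacture a majority; the max is a
  per-rater judgment and is treated as such.
* **Attendance**: the categories 0, 1, 2–4, 5–10, >10 are recoded to
  0, 1, 3, 7.5, 15 and averaged.

Inter-rater reliability uses the Shrout–Fleiss two-way random-effects
intraclass correlation for the average of $k$ raters,
$$\mathrm{ICC}(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$
with Cicchetti's bands (poor/fair/good/excellent) for labelling.

# Source comparison

Sources are compared by 5×5 correspondence matrices (attendance binned
into the annotator categories first), Pearson correlations, and paired
t-tests. Because situations are nested within participants, the
correlation and t-test p-values use cluster-robust (sandwich) standard
errors clustered on the participant, with $J - 1$ degrees of freedom
for $J$ participants. Location-by-drink contrasts report Cohen's $d$
with the pooled SD and the normal-approximation confidence interval
with variance $(n_1+n_2)/(n_1 n_2) + d^2 / (2(n_1+n_2))$.

```{r}
# annotators' loudness in private places (summary statistics)
cohensD(189, 0.5, 0.8, 195, 1.6, 1.0)$d
```

# The multilevel model (`fitRandomInterceptLogit`)

The odds of drinking alcohol are modelled per source and coarse
location type by a random-intercept logistic regression,
$$\Pr(y_{ij} = 1) = \mathrm{logit}^{-1}\!\big(\beta_0 + \beta^\top x_{ij}
 + u_j\big), \qquad u_j \sim N(0, \sigma_u^2),$$
with brightness, loudness, attendance and prior drinks as predictors
and a participant-level intercept.

Numerical choices:

* **Adaptive Gauss–Hermite quadrature**, 15 nodes by default (minimum
  12): nodes are centered and scaled at each cluster's posterior mode
  (found by a damped per-cluster Newton iteration, warm-started across
  optimizer steps), which keeps the marginal likelihood accurate even
  for large random effects. The outer optimization is BFGS on
  $(\beta, \log \sigma_u)$ with a relative tolerance of $10^{-12}$.
* **Cluster-robust ("robust ML") standard errors**: the bread is the
  observed information of the marginal likelihood (numerical Hessian),
  the meat the outer product of per-cluster score vectors (central
  differences). This is the sandwich analogue of MLR estimation.
* **Convergence flag**: the gradient norm is compared against
  `gradTol` (default $10^{-4}$, scaled by the log-likelihood
  magnitude). The tolerance is deliberately looser than the optimizer's
  own ($10^{-12}$ relative): the numerical gradient of a quadrature
  approximation carries noise of roughly square-root machine precision,
  so demanding $10^{-8}$ would flag perfectly usable optima.

Fits agree with `lme4::glmer(..., nAGQ = 15)` to about three decimals
on problems of the package's size (hundreds of clusters, thousands of
observations); the unit tests assert this directly.

Model summaries report exponentiated coefficients (odds ratios) with
robust Wald intervals, the McKelvey–Zavoina fixed-effects pseudo
$R^2$
$$R^2_{MZ} = \frac{\operatorname{Var}(X\hat\beta)}
 {\operatorname{Var}(X\hat\beta) + \hat\sigma_u^2 + \pi^2/3},$$
and a Hosmer–Lemeshow test on the fixed-part probabilities with decile
groups (ties merge groups and reduce the degrees of freedom,
$df = g_{\mathrm{eff}} - 2$). The test's size under a correct model is
calibrated to 5% in the acceptance suite.

# Inference (`cvInference`)

The two-class task (alcohol vs no alcohol) is run per source and coarse
location with a random forest (300 trees by default), 10-fold
cross-validation, 10 iterations, and minority oversampling to balance
the classes. Two orderings are implemented:

* `leakage_safe` (default): oversampling happens inside each training
  fold, so duplicated minority rows can never appear on both sides of a
  split.
* `paper_mode`: the full dataset is balanced first and then
  cross-validated, reproducing the workflow in which balancing precedes
  splitting. On uninformative imbalanced data this ordering is
  measurably more optimistic — the acceptance suite asserts
  `paper_mode >= leakage_safe` — which is exactly why it is not the
  default.

# The synthetic-study generator

`generatorConfig()` defaults encode the emulated study conditions:

* **Structure**: 210 participants; situations per participant from a
  truncated negative binomial (mean 11.2, size 1), so the top 20% of
  participants contribute roughly half the situations.
* **Locations**: seven types with the study's relative frequencies
  (about 55% private); per-location luminance, sound level and
  attendance distributions are set so the *measured* bins reproduce the
  published per-location means (e.g. nightclubs loudest, private
  quietest and darkest among indoor venues).
* **Alcohol**: drawn from the same random-intercept logistic model the
  analysis fits, with location-specific coefficients and
  $\sigma_u = 1$, so model recovery can be verified on known truth.
* **Ratings**: participant and annotator ratings are the true bins
  plus bias and Gaussian noise on the bin scale (annotators less noisy
  than in-the-moment participants), clamped to 0–4; attendance gets
  multiplicative noise.
* **Media**: clips are rendered so that the algorithmic measures hit
  the generating targets exactly: the background intensity is
  compensated for blob area so mean luminance is exact; audio is a
  1 kHz carrier plus band-limited pink noise (≥ 200 Hz, 14 dB below
  the carrier) scaled so the A-weighted level is exact. Full-band pink
  noise at the more natural −10 dB has so much unweighted low-frequency
  energy that levels above ~85 dB would clip the waveform; band-limiting
  and −14 dB keep about 2 dB of crest-factor headroom at the loudest
  target. True levels are truncated to [20, 85] dB for the same reason —
  `renderClip()` refuses unreachable targets rather than clipping
  silently.
* **Blobs**: moving people are elliptical blobs at a fixed contrast
  margin. When each blob can be assigned its own cell of a lane grid,
  trajectories never overlap and the tracker's count is exact by
  construction; blob speed is bounded below so no pixel is covered for
  more than half the clip, keeping the temporal-median background
  clean. Beyond the grid capacity, trajectories are random and overlaps
  are allowed.

What the generator does **not** emulate: camera auto-exposure, real
acoustic scenes (it is a calibration signal, not soundscape synthesis),
appearance variation between people, GPS/location reassignment, and
recruitment/sample-flow dynamics.

# A small end-to-end run

```{r, eval = FALSE}
cfg <- generatorConfig(nParticipants = 40,
                       media = list(fps = 2, duration = 10, height = 60,
                                    width = 80, sampleRate = 8000),
                       seed = 11)
res <- runAll(cfg, outDir = "report")
res$inference$table
```

`runAll()` writes `table1_*.csv` (source agreement),
`correspondence_*.csv`, `table2.csv` (location-by-drink contrasts),
`table3.csv` (multilevel models), `inference.csv`, a manifest echoing
the full configuration, and a structured log. Re-running with the same
configuration reproduces the CSVs byte for byte.

# Limitations

* The person counter is a surrogate: it shares the contract of a
  detector-plus-tracker chain, not its appearance model. Accuracy
  claims transfer to the contract (identity clusters), not to
  real-world footage.
* The loudness channel is calibrated, not psychoacoustic: no sones or
  LUFS, and the EMA start-up transient biases very short signals by a
  few hundredths of a dB.
* Cluster-robust descriptive inference assumes enough participants
  (the code requires at least 3 clusters; stable behavior needs far
  more).
* `paper_mode` inference exists for comparability; its accuracies on
  imbalanced data are optimistic by construction.
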