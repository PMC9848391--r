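---
title: "Methods: information flow and functional parcellation of prefrontal ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information flow and functional parcellation of prefrontal ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rats foraging on Restaurant Row visit four reward sites in sequence. At
each site a tone cues a delay offer (1--30 s, uniform); the animal either
skips, or accepts and waits the delay out in the Wait Zone (earning food)
or abandons the countdown (a quit). Economic behavior is summarized per
restaurant by a *threshold*: the delay below which the animal reliably
earns. Spike ensembles are recorded along a linear silicon probe spanning
the dorso-ventral (DV) extent of the medial prefrontal wall, so every
cell carries a DV coordinate. The analyses in this package ask two
questions: (1) where, along that axis, does pairwise functional
communication between cells concentrate — and do its local minima define
subregion boundaries; (2) what task variables (phase, time, reward rank,
offer delay, choice) do cells in each subregion encode.

## The estimators

**Transfer entropy (TE).** Spike trains are binned at 10 ms and
binarized (0 / at least one spike). For an input cell $X$ and recipient
$Y$, with order-1 histories,

$$TE_{X\to Y} = \sum p(Y_t, Y_{t-1}, X_{t-1})\,
\log_2 \frac{p(Y_t \mid Y_{t-1}, X_{t-1})}{p(Y_t \mid Y_{t-1})},$$

a plug-in estimate over the empirical joint of the 8 binary patterns,
with $0 \log 0 = 0$. TE is directional and nonnegative.

**Surrogate normalization.** Every statistic in the package — PETHs, MI,
TE, rate--behavior correlations — is reported as raw minus the mean of
the same statistic over 30 circular time-shifts of the spike train
(uniform shifts of 1--59 min on the 1 h session circle). For TE, only
the predictor $X$ is shifted; $Y$ is never shifted. The null preserves
each train's internal structure (count, ISI distribution up to one wrap)
while destroying its alignment to events and partners, so it cancels the
positive plug-in bias: normalized values scatter around zero for
unrelated data and may be negative.

**Mutual information (MI).** Continuous variables and firing rates are
discretized into 5 uniform-width bins spanning their observed range (top
edge closed; categorical variables keep their natural categories), and
$MI = \sum p(B,S) \log_2 [p(B,S)/(p(B)p(S))]$ is computed from the joint
counts, then shuffle-normalized. For time courses, each PETH bin is
treated independently and rates are discretized with that bin's own
range (the per-bin choice is deliberate: each bin is an independent
comparison, and a global range would let a single transient compress the
resolution everywhere else). No bias-corrected estimators are used;
comparability with the shuffle-subtracted plug-in is the point.

**Anatomical aggregation.** Normalized TE of every directed pair is
binned on a 100 µm × 100 µm grid over (input depth, recipient depth),
anchored at the dorsal-most recorded depth; each bin stores the mean.
The DV profile takes, at each grid depth, the unweighted mean of the
occupied bins whose two coordinates are both within 200 µm of that
depth. Subregion boundaries are the interior local minima of this
profile; multimodality of the profile is checked with Hartigan's dip
test (implemented here from the published algorithm, bootstrap p-value
under the uniform null).

## Time normalization

Offer Zone and Reward Zone passages are self-paced, so their PETHs use
relative time: 20 bins of 5% of the zone occupancy, flanked by 3 bins of
10% of the preceding and following zone's occupancy (26 bins). Wait Zone
analyses use absolute 100 ms bins. Visits shorter than 20 ms are dropped
from normalized PETHs rather than produce empty fractional bins. Where
visit durations differ, per-visit rates are computed first and averaged
unweighted across visits.

## The synthetic world

Every stage is validated against a generator with planted ground truth;
its defaults are fixed once and state the world the tests live in:

* **Task**: 4 restaurants, 3600 s sessions, integer delays uniform on
  [1, 30] s, thresholds (22, 17, 12, 7) s, logistic accept rule with
  slope 1.5 per second of subjective value (threshold − delay),
  quit hazard $0.05\,e^{-v/4}$ per second, log-normal reaction and
  linger times with mild value dependence, 4 s travel. The hazard form
  is a stand-in: the study reports that quits exist and depend on value,
  not their hazard; an early draft used a hazard proportional to
  $\max(0, -v)$, which yields almost no quits because accepted offers
  rarely have negative value, and was replaced at design time.
* **Ensembles**: base rates uniform 2--8 Hz; depths *stratified*
  uniform over 0--3000 µm — marginally uniform but evenly spread, as
  cells recorded on 20 µm-pitch probe contacts are; an i.i.d. uniform
  draw leaves some 100 µm map bins nearly empty, and because the profile
  averages *bin means* unweighted, one- or two-pair bins would dominate
  its noise in a way real probe data does not. Spike widths are a
  principal/interneuron normal mixture (≈500 µs vs ≈220 µs).
* **Planted structure**: multiplicative tuning gains per task phase,
  session-time trend, reward rank and OZ choice; directed coupling
  organized into 4 depth blocks with boundaries at 750/1500/2250 µm.
  Each input spike begets an excess recipient spike one 10 ms bin later
  with probability 0.35; each cell couples to an evenly spread 30% of
  its within-block partners (deterministic depth-rank stride). The
  systematic pattern, rather than independent Bernoulli edges, is
  deliberate: with ~30 cells per block, Bernoulli edge realization
  noise is comparable to the block contrast itself and boundary
  recovery would measure the generator's luck, not the detector.
  Coupling excess spikes are driven by the input cell's own base spikes
  only (no cascades through chains of edges).

What a green recovery test establishes: the chain TE → map → profile →
minima identifies planted communication blocks at desk scale (120
cells, one session). What it does not establish: performance on real
data, where coupling is distance-graded rather than block-constant,
rates are non-stationary, and the map pools ~10^5 pairs across a
hundred sessions.

## Numerical choices

* **Threshold fit.** The earn indicator is fit by least squares to a
  Heaviside step of delay over the candidate grid 0.5, 1.5, ..., 30.5 s;
  a tying run of candidates reports its midpoint (the longest run if
  several, with a warning). All-earn and no-earn sessions map to 30.5
  and 0.5 s, preserving the "willing to wait longest" ordering. Rank
  ties break by earned-reward count, then restaurant id (warned).
* **Boundary detection.** No smoothing by default (an optional width-3
  moving average exists, but on 100 µm grids it displaces sharp minima
  by a bin — more than the tolerance it buys). Guards instead: a valley
  must have topographic prominence of at least 0.25 of the profile
  range, and reported minima must be 200 µm apart (the deeper valley
  wins). Each single-point minimum is refined to the vertex of the
  parabola through it and its neighbors — the standard sub-grid
  localization of an extremum sampled on a grid; the shift is bounded
  by half a grid step, and a valley whose bottom is a near-tie between
  adjacent bins resolves toward the lower flank instead of snapping to
  an arbitrary bin. Cells exactly on a boundary join the dorsal region.
* **Phase-restricted TE.** The circular shift of the predictor is
  applied on the full session timeline *before* masking, so surrogate
  structure is destroyed relative to the mask, not concatenated into
  artificial adjacencies; triplets are counted only when bins $t$ and
  $t-1$ both fall inside the phase.
* **Seeds.** A master seed spawns per-stage sub-seeds by hashing
  (stage label, seed) down to 31 bits (`derive_seed`); all shifts and
  draws are reproducible and below `2^31`.
* **TE shuffle shifts** are drawn per input cell (not per pair) — the
  stated re-draw granularity — which also lets the implementation rotate
  each input's bit-field once per surrogate and reuse it across all its
  pairs.
* **Degenerate inputs.** Burst ratio with no long ISIs, correlations of
  zero-variance vectors, MI bins with under-filled categories, and
  empty choice categories are all reported `NA` ("undefined"), never 0.

## Known limitations

* History order 1 and a binary alphabet are the stated estimator; no
  multivariate or longer-history TE.
* The dip test treats the DV profile either as a value sample or, via
  `profile_depth_sample()`, as a value-weighted depth density; the
  mapping from a smooth profile to a "sample" is a modeling choice.
* The per-cell stepwise regression reproduces greedy residual-variance
  ordering with OLS; it is not a reimplementation of any particular
  stepwise routine's entry/exit statistics.
* Localization assumes a straight entry→tip trajectory; anterior-
  posterior precision is a passthrough, as the source coordinate frame
  is coarse along that axis.
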