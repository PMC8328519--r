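---
title: "Measuring gist-based bias in spatial memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gist-based bias in spatial memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The paradigm and its measures

Participants learn the screen locations of a set of landmarks, then — at one
or more retention intervals — first click where they believe the *centre* of
the set is (explicit gist retrieval) and then recall each landmark's
location (item retrieval). `gistbias` implements the quantitative machinery
this design needs: error metrics with geometry-derived chance baselines, a
bias statistic that asks whether item retrievals drift toward a remembered
centre, null simulations that control for the artifactual bias produced by
error magnitude alone, a grid model for the weight of a spatial outlier in
the reported centre, and a synthetic-cohort generator that makes the whole
pipeline testable end to end.

All positions are continuous pixel coordinates with the standard screen
convention (origin top-left, y downward). Nothing published depends on the
convention: every output is a distance or a dimensionless ratio. Distances
are Minkowski, $d(a,b) = (|a_1-b_1|^g + |a_2-b_2|^g)^{1/g}$ with
$1 < g \le 2$; $g = 2$ is the Euclidean default and $g = 1.5$ the customary
choice when allowing for non-linear warping of perceived space. Keeping
$g > 1$ preserves the triangle inequality, which the bias bound below
relies on.

The three error measures for a participant-session are the mean retrieved-
to-encoded item distance (item error), the reported-centre to true-centroid
distance (gist error), and the retrieved-centroid to true-centroid distance
(estimated-centre error — what gist accuracy would be if the gist were
assembled purely from the recalled items). Chance baselines come from the
layout alone: the mean item-to-screen-centre distance, the mean
item-to-centroid distance, and the centroid-to-screen-centre distance
correspond to the error of strategy-free responders who only remember the
screen centre or only the set centre.

## The bias statistic

For one item,

$$\mathrm{bias} = \frac{d(\mathrm{encoded}, c) - d(\mathrm{retrieved}, c)}
                       {d(\mathrm{encoded}, \mathrm{retrieved})},$$

where $c$ is a reference centre. The triangle inequality confines the value
to $[-1, 1]$; $+1$ is a retrieval displaced straight toward $c$, $-1$
straight away. A participant's bias is the unweighted mean over items.

Two conventions needed fixing. A perfect retrieval makes the ratio $0/0$;
it is defined as bias 0 (the numerator is also zero, and the item carries
no directional information), with `zero_error = "drop"` available to
exclude such items from the mean instead. And four reference centres are
supported — the participant's reported centre (the default, because the
remembered gist, not the objective one, is the hypothesised attractor), the
encoded centroid (the ensemble-perception convention), an accuracy-weighted
centroid with weights $(1 - e_i/\sum e)/(n-1)$ (items recalled more
accurately count more; the weights are non-negative and sum to one, and the
all-equal-error limit — including all-zero — is the plain centroid), and
the local centre excluding a designated outlier. In local mode the outlier
item stays in the participant average (its own bias is also reported
separately so outlier-only contrasts remain possible).

## Why null simulations are indispensable

Random retrieval error produces negative bias on its own: on the circle of
radius $e$ around an encoded location, the arc closer to the centre than
the encoded point is shorter than the arc farther from it whenever $e$ is
comparable to the item-centre distance. Observed bias is therefore only
interpretable against simulations matched to each participant's error
magnitudes.

Both null models draw, per run, one simulated retrieval per item at
*exactly* the observed error radius. The **item-only** model (Sim-I) draws
the direction uniformly; it embodies "item memory but no gist influence".
The **item-plus-gist** model (Sim-G) discretises the circle into
`n_angles = 200` candidate points (centres of equal arcs, angle zero on the
+x axis — the phase is fixed and seed-independent) and assigns candidate
$i$ at distance $d_i$ from the centre the probability

$$P_i = \frac{d_i - \max_j d_j}{\sum_j \left(d_j - \max_j d_j\right)},$$

so the farthest candidate gets probability zero and probability decreases
linearly with distance to the centre. The strength of this pull is fixed by
the formula itself; it is deliberately a qualitative, not fitted, amount of
gist influence, so Sim-G is a directional benchmark rather than a
generative model of the data. Per run, bias is averaged over items against
the same centre, and the run's estimated-centre error (simulated centroid
to true centroid) is kept alongside; 1000 runs per participant by default.

Boundary handling: draws falling off-screen are redrawn. For Sim-I this is
literal rejection sampling (with a $10^4$-round cap that raises a geometry
error rather than looping forever); for Sim-G the candidate set is
restricted to in-bounds points and renormalised — the same distribution,
without the loop. When every candidate is (numerically) equidistant from
the centre — the centre at the encoded point, or distance differences at
floating-point noise, detected at relative tolerance $10^{-9}$ — the
distribution degenerates to uniform.

Reproducibility: every stochastic routine derives a 32-bit substream seed
from (base seed, participant, session, model) via an exact integer hash, so
results are bit-identical regardless of the order in which participants are
processed, and the caller's RNG state is left untouched.

## The outlier-weight grid model

For eight-item designs with one spatial outlier, the reported centre is
modelled as a weighted centroid giving the outlier weight $w$ and each
other item $(1-w)/(n-1)$. Candidate centres for $w \in \{0, 0.0125, \dots,
1\}$ (81 points) trace the straight segment from the local centre ($w=0$)
through the global centroid ($w = 1/n$) to the outlier itself ($w=1$); the
estimate is the $w$ minimising the distance to the reported centre, with
ties broken toward the smaller $w$ (conservative toward discounting the
outlier; ties have measure zero on continuous data). Because the candidates
are collinear, the distance profile is a quadratic in $w$ — unimodal along
the grid — and the grid argmin equals the orthogonal projection of the
reported centre onto the segment snapped to the nearest grid point, which
is how the tests cross-check it. The equal-weight benchmark is computed as
$1/n$ from the layout rather than hard-coded 0.125, so six-item outlier
layouts are handled too. A continuous projection estimate is exposed as a
diagnostic only; the headline estimator is the grid.

One wrinkle: the non-outlier weight $(1-w)/(n-1)$ at $w=0$ equals $1/7$ for
eight items, not the 0.125 sometimes quoted as the top of its range; the
formula is implemented as printed and the prose range treated as a
description of the $w \ge 0.125$ regime.

## Preprocessing rules

**Swap (misbinding) correction.** A pair (A, B) is flagged when each
retrieval is strictly closest to the *other* item's encoded location, both
lie within half the encoded A-B separation of the encoded location they are
closest to, and no other retrieval intrudes into that range. The
half-separation reading of the third condition is the default
(`rule = "nearest"`): requiring each retrieval to be within that range *of
both* endpoints would conflict with the nearest-to-the-partner geometry of
the first two conditions, but that stricter lens-shaped reading is
available as `rule = "both"`. Nearest-encoded ties are broken by label
order. Correcting a detected pair exchanges the two retrieved points; the
detection criterion guarantees the pair's summed error never increases, and
re-detection after one correction finds nothing (a fixed point).

**Exclusions.** Three rules, mirroring the two experimental designs:
participants whose Session-1 reported centre lies farther from the true
centroid than the gist chance baseline (the "reported gist out of the scope
of the learned landmarks" rule — applied in the no-outlier design only,
because in the outlier design a large gist error is itself a meaningful
overweighting result); participants who placed the outlier farther from its
encoded location than the screen-centre-to-outlier distance (outlier
designs only — such outlier swaps would spuriously inflate global bias);
and a 3-SD screen excluding anyone whose item or gist error at any session
is more than three standard deviations worse than the cohort mean for that
session and measure. Participant-local rules run first; the 3-SD screen is
evaluated once on the remainder (no iterative re-exclusion), is skipped
with a warning below two participants, and — being cohort-dependent by
construction — is documented as such rather than forced to be monotone.

## Layout calibration

Published studies of this design report their chance baselines but not the
encoded coordinates. `calibrate_layout()` therefore reconstructs a layout
matching the printed geometry: a seeded multi-start BFGS minimisation of
the squared baseline residuals (pixels²), with smooth squared-hinge
penalties keeping pairwise separations above the training-criterion bound
(plus a 2-px slack so the strict inequality holds), items at least 10 px
inside the screen, and — for outlier designs — the last item at its
published offset from the screen centre. Feasibility of the three target
distances is checked up front via the triangle inequality on means. A
candidate is accepted only if every baseline residual is within 0.5 px and
all constraints hold strictly; otherwise the optimiser restarts from a new
seeded configuration (cluster centroid at the gist-baseline distance from
the screen centre, kept mostly horizontal so the item ring fits a 16:9
screen; items on a jittered ring; bounded restart budget, then a
calibration error reporting the best residuals). The default screen is
1366 × 768 — a generic laptop panel whose half-diagonal comfortably exceeds
the 573-px outlier offset — and is configurable; with three (or four)
constraints on 12-16 coordinates the solution manifold is large, so the
seed selects one representative layout, deterministically.

## The synthetic-cohort generator

The generator is the package's testing ground and defines the conditions
under which the pipeline's claims are verified. Per item it draws an error
magnitude $|\mathcal N(\text{scale}, 0.3 \cdot \text{scale})|$ — a folded
normal with coefficient of variation 0.3, an invented but conventional
choice, swappable, since no retrieval-error distribution is published — and
a direction that is uniform with probability $1-\lambda$ and otherwise
follows the same angle-probability law as Sim-G toward the generative pull
centre (the local centre for outlier layouts, matching the empirical
finding that the local gist is the attractor there; the global centroid
otherwise; both overridable). Reusing the null model's direction law is
deliberate: it gives test suites a known ground truth in which Sim-G is
correctly specified at $\lambda = 1$. The reported centre is the weighted
centre for the preset outlier weight (or the plain centroid) plus isotropic
normal noise; off-screen draws are redrawn; with probability `swap_rate`
one random item pair is exchanged.

The two shipped presets encode the study design shapes: 130 participants in
44/43/43 delay groups, six items, two sessions (`exp1`); 43 participants,
eight items with the outlier, three within-subject sessions (`exp2`).
Session error scales (55 → 70/95/130 px item error for `exp1`, 35 → 55 →
110 px for `exp2`, gist scales growing more slowly), the gist-pull schedule
(zero immediately after learning, strong only at the longest delay), the
2% swap rate, and the `exp2` outlier weight of 0.25 (over the 0.125
equal-weight benchmark) are the package's own choices: they respect the
printed training criteria (initial errors below the 80 px / 50 px learning
thresholds), keep errors well under the chance baselines, and reproduce the
qualitative signatures — item error outgrowing gist error, a positive
observed-minus-Sim-I gap only at long delays, an over-weighted outlier —
without targeting any participant-level published statistic, which would
require the original raw data. What the generator does *not* emulate:
individual differences beyond what the schedules induce, reaction times,
training dynamics, boundary-repulsion effects, or confidence. Passing tests
therefore validate the pipeline's correctness and sensitivity under a
known generative process, not the empirical claims themselves.

## Numerical and testing decisions

* Bias bound checks use $10^6$-plus fuzzed configurations per run and treat
  $[-1-10^{-12},\, 1+10^{-12}]$ as the admissible interval (floating-point
  slack only).
* Null-confirmation checks (no gap expected under $\lambda = 0$) require
  the cohort mean gap to lie within three standard errors of zero rather
  than passing a 5%-level t-test: the gap is provably mean-zero there but
  heavy-tailed — items with tiny observed error contribute near-unit bias
  draws — so a 5% false-alarm rate would make a deterministic suite flaky
  by design. Positive-effect checks use the conventional one-sided 5%
  level.
* Problem sizes are chosen for a laptop-class single core: 1000 simulation
  runs per participant (the published operating point), cohorts of 40-60
  for power-style checks, 200,000-point quadrature grids for oracles, and
  dense fuzzing only where vectorisable. The full suite runs in well under
  a minute.
* Multiple-comparison correction is off by default throughout (matching
  the reporting convention of the target literature); the rank-test
  wrappers return raw p-values.

## Limitations

The bias statistic conflates direction and magnitude by design; its
error-magnitude artifact is handled by simulation rather than analytically.
Sim-G's gist influence is fixed, not fitted, so observed-versus-Sim-G
comparisons are directional only. The calibration reconstructs *a* layout
consistent with published distances, not *the* layout — all downstream
geometry (e.g. edge distances, hence boundary-truncation behaviour) is
representative rather than exact. And the exclusion and swap rules encode
one defensible reading of informally described criteria; the flagged
alternatives are available behind arguments where the text is ambiguous.
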