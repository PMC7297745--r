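---
title: "Polygon-based contact networks from RTLS point data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygon-based contact networks from RTLS point data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycontact)
```

## The problem

Real-time location systems (RTLS) — GPS collars, radio-telemetry ear tags,
RFID — report tagged animals as moving *points*. Contact networks built
from such data usually declare two animals "in contact" when their points
fall within a spatial threshold (SpTh) of each other. Two things are lost
in that reduction. First, an animal is not a point: an ear tag says nothing
about where the hindquarters are, so head-to-rump interactions (a principal
route for faecal-oral pathogen transfer in cattle) are invisible or badly
misplaced. Second, reported positions are wrong by a device-specific
amount, so a strict threshold silently discards true contacts.

`polycontact` addresses both. It transforms each point fix into one or more
rigid, oriented polygons describing the space an animal's body (or visual
field) occupies, and it calibrates the spatial threshold to the positional
error of the device so that a stated fraction of true contacts is still
captured. Downstream it provides per-timestep distances, contact bouts,
time-aggregated weighted networks, and permutation null models.

## From points to oriented polygons

A **planar model** is a template in its own coordinate frame: a reference
point $loc^*$ (where the device sits on the body), a forward direction
$\eta^*$ (degrees counter-clockwise from +x), and one or more named vertex
rings $\{V^*\}$. The bundled `calf.json` model has three square parts —
head ($0.333\,\mathrm{m} \times 0.333\,\mathrm{m}$), anterior body
($1\,\mathrm{m} \times 1\,\mathrm{m}$) and posterior body
($1\,\mathrm{m} \times 1\,\mathrm{m}$) — laid out nose-to-tail with the
reference point at the left ear. The exact abutment of the head square
against the anterior square and the ear-tag position are not fully
determined by any published figure; the bundled layout is a documented
approximation, and every test that depends on part layout constructs its
model explicitly in code.

**Headings.** When no gyroscopic sensor is available, the heading
$\eta_{it}$ is estimated from movement: the angle of the vector from the
*anchor* (the last position at which the pose was updated) to the current
fix. A fix closer than the **immobility threshold** to the anchor leaves
position and heading frozen, so that jitter such as head-shaking (or pure
measurement noise) does not spin the polygon. Two consequences follow
directly: no polygon exists before the first qualifying relocation
($t \ge 2$), and during a frozen span the previous polygon is re-emitted
unchanged. We use anchor displacement rather than consecutive-step
displacement deliberately: with a consecutive-step rule, an animal drifting
slowly but persistently below the threshold would never update its pose.
This is an interpretation — the alternative reading is defensible — and
after a frozen span ends we re-estimate the heading from the anchor rather
than reusing any pre-freeze heading. External headings (e.g. from a
gyroscope) can be supplied by passing a compatible states table straight to
`derive_polygons()`.

**The transformation.** For template vertex $l$ with radial distance
$d_l = \lVert V^*_l - loc^* \rVert$ and template angle $\theta^*_l$ (the
angle of the vector $loc^* \to V^*_l$), the empirical vertex is placed at

$$V_{itl} = loc_{it} + d_l\,
  (\cos \alpha_l, \sin \alpha_l), \qquad
  \alpha_l = (\theta^*_l + \eta_{it} - \eta^*) \bmod 360.$$

Taking $\theta^*_l$ as the *outgoing* angle from the reference point makes
$\eta_{it} = \eta^*$ reduce exactly to a pure translation, which is the
behaviour the construction is meant to have; the tests assert this
identity, the equivariance of the whole series under global rotations of
the input, and rigid-body conservation of edge lengths and areas at
$10^{-9}$ m.

All angles in the package are degrees, counter-clockwise positive, zero
along +x, reduced modulo 360.

**Visual fields** are isosceles triangles with the apex at the collar,
opening along the heading: `build_visual_field_model(height, apex_angle)`
gives a base half-width of $h \tan(\text{apex}/2)$ (173.2 m for the bundled
100 m, 120° model). A directed contact $i \to j$ occurs when $j$'s point
lies inside (or within SpTh of) $i$'s triangle; the relation is
deliberately never symmetrised.

## Calibrating the threshold for positional error

Device accuracy is stated as "a fraction $p$ of reported points fall within
$\delta$ of the true location". With independent Gaussian errors per
coordinate this pins the per-coordinate SD at
$\sigma = \delta / z$, $z = \Phi^{-1}((1+p)/2)$ — 1.64 for $p = 0.90$, 3.89
for $p = 0.9999$ (the mapping we use for "approximately 100%" accuracy
claims). Note the containment statement holds per coordinate
($P(|e_x| \le \delta) = p$ exactly); the corresponding radial containment
is $1 - e^{-z^2/2}$, smaller than $p$, and the synthetic-data tests check
the per-coordinate law because that is the statement the model encodes.

`sample_contact_distances()` draws hypothetical in-contact pairs
$[x_1, y_1, x_2, y_2]$ with means $(0, 0, 0, \text{SpTh})$ and SD $\sigma$
in each coordinate; the pair distance then follows a Rice distribution with
scale $s = \sigma\sqrt{2}$ (Rayleigh when SpTh $= 0$), and the test suite
validates the sampler against those closed forms by quadrature.

"Take the upper 99% of the expected distance distribution" admits two
readings, and `estimate_threshold()` implements both:

* `mean_distribution_quantile` (default): the 0.99 quantile of the
  per-replicate *mean* distances (1,000 replicates of 1,000 pairs by
  default — $10^6$ pairs in total). A distribution of averages is what the
  phrase "distribution describing average distances between point pairs"
  describes; for the ear-tag accuracy model
  ($\delta = 0.5$ m, $p = 0.90$, SpTh$_0 = 0$) this yields 0.56 m.
* `distance_quantile`: the 0.99 quantile of the pooled distances — the
  threshold below which 99% of individual in-contact pairs fall. This is
  the operational reading of "captures ≥ 99% of contacts", and the
  coverage-law test verifies it directly.

The two modes differ substantially (the mean-based estimate concentrates
near the Rice mean; the pooled quantile sits far in the tail), which is why
both are exposed and the choice is an explicit argument. A related
ambiguity we document rather than resolve: for the GPS-collar model
($\sigma = 0.26/3.89$) neither mode reproduces the published 0.109 m
visual-contact threshold (both give ≈ 0.118–0.123 m), and the two published
thresholds (0.56 m, 0.109 m) are not proportional to their $\sigma$'s, so
no single procedure can produce both. The package encodes no guess; the
calibration acceptance for that accuracy model is closed-form agreement of
the simulated distance distribution with its Rayleigh/Rice laws.

## Contacts, bouts, networks

Distances are exact planar minimum distances: 0 on intersection or
containment, otherwise the vertex-to-edge minimum (for simple polygons
whose boundaries do not cross, the minimum is attained at a vertex, so the
sweep is exact; the tests check 500 random convex pairs against an
independent segment-by-segment oracle at $10^{-9}$ m). Contact is
**inclusive**: distance $\le$ SpTh, so SpTh $= 0$ is polygon intersection.
"Precise" networks use SpTh $= 0$; "expected" networks enlarge SpTh by the
calibrated amount rather than buffering polygons — the two framings are
equivalent, and the distance formulation is exact. Contact sets are nested
in SpTh, which the suite asserts.

Edge formation is restricted to different individuals; part pairings
(`head:head`, `head:posterior`, `fullBody`, `point`) choose which
geometries may touch. For asymmetric pairings both ordered combinations are
computed and, in undirected networks, folded into the single $(i, j)$ edge.

A **bout** is a maximal run of consecutive in-contact grid timesteps. A
missing fix yields *no* distance record — never distance 0 — and breaks
bouts under the default `max_gap = 0`; a configurable `max_gap` merges runs
separated by short gaps, with the bout length still counting only
in-contact timesteps. **Edge weight is contact frequency**: the summed
in-contact timesteps of the dyad over the aggregation window, not the bout
count — at a 10-s grid over 24 h that is what makes per-capita sums in the
thousands dimensionally sensible. Density, degree, bout-duration and
per-capita-sum summaries (plus per-UTC-day degree and, for directed visual
networks, the instantaneous out-degree series) come from
`network_metrics()`; UTC calendar days are used as day boundaries because
the motivating data subsets are defined in UTC.

## Null models and testing

`randomize_paths()` cuts each individual's series into consecutive blocks
of `block_length` timesteps and permutes the block order uniformly at
random, preserving exactly the location multiset, record count and
timestamp set per individual. The block-shuffle family has several
published variants; uniform within-individual block permutation with a
configurable block length (one day = 8,640 timesteps at 10 s) is the member
implemented here. The `stage` argument matters precisely when orientations
come from movement: randomising *before* polygon derivation re-randomises
headings, randomising *after* keeps the empirical orientations — a decision
that must be made a priori, so it is an explicit argument rather than a
default.

`mantel_test()` is the two-sided permutation Mantel test on off-diagonal
entries with simultaneous row/column permutation and the $+1$-corrected
p-value $(\#\{|r_\pi| \ge |r_{obs}|\} + 1)/(B + 1)$, guaranteeing $p > 0$.
`contact_chi2_test()` is the $\chi^2$ goodness-of-fit of observed against
null-expected contact counts with pooling of non-positive expectation cells
and $k - 1$ degrees of freedom.

## The synthetic generator

`simulate_tracks()` emulates the data the method is designed for:
fixed-interval fixes (1–10 s), correlated-random-walk movement
(wrapped-normal turning parameterised by the mean resultant length,
truncated-normal step lengths, reflective arena boundaries), per-coordinate
Gaussian reporting error with $\sigma = \delta/z$, and scripted events that
hold a pair at an exact separation so the true bout table is known by
construction. The four `scripted_contact_scenario()` fixtures
(`converge_pair`, `parallel_walk`, `head_to_tail`, `visual_crossing`) give
closed-form ground truth for, respectively, bout extraction, full-span
contact, part-pair selectivity (nose-to-tail spacing of 2.4 m puts the
follower's head 0.067 m from the leader's posterior and 2.067 m from its
head), and visual-field directedness.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: behavioural states, social attraction or
avoidance, temporally autocorrelated or spatially structured positional
error, device dropout patterns, and body-shape change. Default parameters
were chosen once for the motivating systems: 10-s intervals and
$\delta = 0.5$ m at $p = 0.90$ for the feedlot setting, 1-s intervals for
the collar setting, step lengths of a slow-moving grazer
(0.3 ± 0.1 m per 10 s), turning concentration 0.8.

## Numerical choices and scales

* Earth radius 6,371,000 m; the azimuthal equidistant projection is
  spherical, centred by default on the data centroid, and exact in
  centre-distances (checked against a haversine oracle at 0.01% on 1,000
  random points). Points at the centre's antipode are rejected with a
  report.
* Timestamps are UTC, stored as integer epoch seconds, because the target
  grids are 1-s and 10-s.
* Points exactly on a confinement boundary are retained; duplicate
  resolution keeps the first record in file order; the speed filter anchors
  to the last *retained* fix in a single forward pass so one corrupt fix
  cannot cascade into deleting everything after it.
* Gap filling in `aggregate_time()` is last-observation-carried-forward,
  bounded by `max_fill_gap`, and off by default: interval-averaging is the
  stated smoothing procedure, the fill rule is this package's addition for
  grid completeness.
* Rigid-body tolerances are $10^{-9}$ m; equivariance is asserted at
  $10^{-6}$ m on unit-scale inputs; file round-trips preserve coordinates
  to $10^{-9}$ m.
* Test problem sizes: $10^6$ pairs for calibration checks, $10^5$ for
  coverage and containment laws, 500 polygon pairs for the distance oracle,
  2,000 seeds for shuffle uniformity, 1,000 simulations for the $\chi^2$
  type-I check. These sizes give Monte-Carlo standard errors comfortably
  below the asserted tolerances.

## Known limitations

Polygons are rigid: a species whose body outline changes with behaviour
needs multiple planar models and switching criteria, which this package
does not provide. Visual fields assume unobstructed, constant-range vision;
incorporating terrain or vegetation occlusion would require external
surface data. Great-circle distances are supported for point data only;
polygon workflows require projected planar coordinates. The heading
estimator assumes forward, straight-line movement between fixes, so fix
intervals must be short relative to the animal's turning behaviour.
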