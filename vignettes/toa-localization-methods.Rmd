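---
title: "Robust ToA localization: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust ToA localization: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toatrack)
```

# The estimation problem

A regional wildlife-tracking network consists of fixed radio receivers at
known positions $\rho_r$ (a local planar ENU frame, meters) whose clocks
carry unknown, effectively constant offsets $o_r$ (GPS-disciplined rates,
but arbitrary phase plus antenna-to-digitizer delays; milliseconds in
practice). A tag at unknown $\ell$ transmitting at unknown $\tau_i$
produces arrival-time measurements

$$t_{ir} = \tau_i + \tfrac1c\lVert \rho_r - \ell\rVert + o_r +
\epsilon_{ir},$$

where the receiver estimates $\sigma_{ir}^2 = \mathrm{var}(\epsilon_{ir})$
from the packet's SNR (nanoseconds at good SNR). Beacons — transmitters at
surveyed positions — satisfy the same equation and tie the offsets
together. Because only the sums $\tau + o_r$ are observable, one offset is
a gauge freedom: we pin the offset of the lexicographically smallest
participating receiver to zero. The choice provably does not affect
$\ell$; the projection below absorbs any residual redundancy
automatically, and a dedicated test perturbs the pinning choice and
verifies $f(\ell)$ is unchanged to $10^{-9}$ relative.

Receiver elevations vary far less than plan coordinates, so the altitude
is normally not estimable: the default mode fixes $z$ (2D mode) and
estimates $(x, y)$; distances are always evaluated in 3D.

# The objective and nuisance elimination

Collect the raw tag and beacon constraints selected for a solve as
$y \approx m(\ell) + N\theta$, where $m(\ell)$ stacks the geometric
delays, $\theta$ the linear nuisance parameters (the tag's $\tau_i$, one
$\tau_b$ per *beacon transmission* — a beacon transmitting twice inside
the admission window contributes two distinct $\tau_b$ — and the
unpinned offsets), and $N$ is their 0/1 incidence. With
$W = \mathrm{diag}(1/\sigma)$ and $U$ an orthonormal basis of
$\mathrm{range}(WN)$,

$$f(\ell) \;=\; \min_\theta \lVert W(y - m(\ell) - N\theta)\rVert_2^2
\;=\; \lVert (I - UU^{\mathsf T})\, W (y - m(\ell))\rVert_2^2 .$$

$U$ is computed rank-aware from the SVD of $WN$ (singular values below
$10^{-10}$ of the largest treated as zero). A numerical detail that
matters: $y$ contains second-scale transmission times while $1/\sigma$ is
of order $10^8$, so projecting $W y$ directly loses eight digits. We
therefore subtract a rough nuisance solve $N\theta_0$ (dense QR at the
receiver centroid) from $y$ at construction time — exactly neutral after
projection, but it leaves the projector acting on residual-scale numbers.
Tests pin the resulting invariants: orthogonality of the projected
residual to $\mathrm{range}(WN)$ below $10^{-10}$, agreement with a
dense-QR nuisance minimization to $10^{-9}$ relative, and (for
single-beacon problems) coincidence of this minimizer with that of the
differenced objective below.

## Difference constraints

Subtracting a beacon detection from a tag detection at the same receiver
cancels $o_r$:

$$t_{ir}-t_{br}+\tfrac1c\lVert\rho_r-\ell_b\rVert =
(\tau_i-\tau_b) + \tfrac1c\lVert\rho_r-\ell\rVert +
\epsilon_{ir}-\epsilon_{br},$$

with variance $\sigma_{ir}^2+\sigma_{br}^2$. For a single beacon
transmission, weighted least squares on these differences is equivalent
to the projected full objective — the package uses the differenced form
for outlier classification and fast refinement, and the full form
(never the differences) for the ultimate solve.

# The closed-form triplet solver

In meters, each difference constraint reads $t_i - t = \lVert p_i -
u\rVert$ with $t = c(\tau_i-\tau_b)$ unknown. Squaring and differencing
adjacent equations cancels the quadratic terms, leaving a linear system
$Au=b$ with a one-dimensional null space; substituting $u = w + \alpha v$
(minimum-norm particular solution and null vector from the thin SVD) into
one squared equation yields a quadratic in $\alpha$: zero, one or two
solutions. Squaring introduces sign spurious solutions: solutions with all
$t_i - t \ge 0$ are genuine; when all $t_i$ are equal and negative
differences occur, $t \mapsto 2t_i - t$ repairs the solution; mixed signs
mean the unsquared system is inconsistent and the solution is dropped
(logged when verbose).

Numerical choices, all surfaced in tests:

* a common shift of $(t_i, t)$ is removed before squaring — a beacon
  transmitting 0.2 s before the tag puts $6\times10^7$ m into every
  $t_i$, and squared arithmetic at that magnitude loses nine digits;
* after back-substitution, two Newton steps on the *unsquared* range
  equations polish each solution;
* rank tolerance $10^{-8}\sigma_{\max}$ declares degenerate geometry
  (near-coincident stations) rather than returning wild solutions;
  discriminants within $10^{-12}$ (relative) of zero return one root;
* even so, the double representation of the inputs themselves limits
  accuracy: at second-scale transmission offsets each $t_i$ carries
  $\sim10^{-8}$ m of rounding that unfavorable hyperbola geometry
  amplifies. The exactness study therefore uses geometry-scale offsets
  (where sub-micrometer recovery is expected and achieved), and a
  separate test pins the large-offset regime below a millimeter.

# Robust stages

**Outlier rule.** Against a hypothesis $(\bar\ell, \bar d)$, a difference
constraint is an outlier iff its weighted residual exceeds $\delta$
standard deviations **and** its unweighted residual exceeds 100 m (both
strict; defaults $\delta = 3$, 100 m, the AND combination configurable to
the weighted test alone). The AND keeps the metric threshold binding for
high-SNR constraints whose $\sigma$ is optimistically small. When only
$\bar\ell$ is available, $\bar d$ is first set to the median of the
per-receiver implied time differences (breakdown 50%).

**Hypothesis generation.** Beacon detsets are ranked by shared-receiver
count, then by an approximate $|\tau_i-\tau_b| < 2$ s, then by mean
beacon SNR. For each of the best five, receiver triplets are ordered by
their worst (then next-worst) $\sigma$ and solved closed-form at the
assumed altitude. The triplet budget defaults to 20 per beacon
(constraints capped at the 12 smallest-$\sigma$ ones first). We
deliberately do not stop at 10: the NLOS failure mode reports an
*unchanged* $\sigma$ for a delayed arrival, so ordering by $\sigma$ can
concentrate the first few triplets on contaminated constraints; at 20,
a 6-receiver detset is enumerated exhaustively and a clean triplet is
always present, which raises the all-outliers detection rate in the
1–2-outlier study from roughly 75% to over 90%.

**Selection.** The consensus variant scores each hypothesis against its
own beacon's constraints and ranks by consensus size, then (when a track
prior exists and the best weighted residuals differ by at most 1) by
distance to the prior, then by the maximal weighted residual; all ties
break by enumeration order, so selection is permutation-invariant. The
clustering variant runs DBSCAN (hand-implemented; eps 50 m, minPts 3, on
$x,y$ only) and returns the member hypothesis nearest the largest
cluster's per-axis medians — an actual solution, so its $\bar d$
survives.

**Refinement and the ultimate set.** Consensus sets larger than three are
refined by weighted least squares over $(x, y, cd)$ — the time difference
is carried in meters so the three unknowns share a scale and the damped
normal equations stay well-conditioned. The ultimate solve then uses the
*raw* constraints constituting the inlier differences: the best beacon
only (single mode) or all beacons classified against the refined
location with per-beacon median $\bar d$ (multi mode); each raw
constraint enters once.

# Covariance, altitude, tracking

The covariance of the final estimate uses first derivatives only:
$\mathrm{cov}(\hat\ell) \approx (BJ_M)^{+}(I-UU^{\mathsf T})
((BJ_M)^{+})^{\mathsf T}$, $B=(I-UU^{\mathsf T})W$, pseudoinverse via SVD
at tolerance $10^{-10}\sigma_\max$; a rank-deficient design yields a
flagged, ceiling-inflated covariance rather than a silently tiny one. A
2000-replicate Monte Carlo at a fixed wedge-shaped 8-receiver geometry
(chosen so the error ellipse is strongly $x$–$y$ correlated and every
covariance entry is informative, not near zero) matches the formula
entrywise within 15%, and the median of (true error)/`std` sits well
inside $[0.3, 3]$.

Altitude has four modes: fixed; terrain (solve at the fixed altitude,
look up a DEM at the estimate, re-solve with $z$ = elevation + species
offset — a two-pass snap, not an iterated fixed point); supplied (e.g.
an altimeter value); and free 3D (requires four receivers, emitted with
a warning because planar networks barely constrain $z$). DEMs are
in-memory grids with bilinear interpolation; ESRI ASCII grids are read
and written directly. Terrain gains matter close to an elevated
receiver, where a wrong assumed altitude projects into plan error; the
paired ramp-DEM study shows an order-of-magnitude median improvement
there.

Per-tag track priors use a Kalman filter with constant-position (default)
or constant-velocity evolution. The evolution noise is
$q(\Delta t)=\min(10\,\Delta t, 750)$ m — the constant is exposed because
10 m/s is a generic upper bound on animal speed, and deployments should
set it per species (for the CV model the constant doubles as the
white-acceleration standard deviation). Fixes are gated: rejected iff
farther than $20\Delta t$ m from the prediction, or 250 m when based on
three receivers, or 1 km when based on four. The ambiguity flag starts
ambiguous, reverts after 20 minutes of silence, and clears on one fix
with six receivers or five consecutive accepted fixes with four or more —
then the state resets to the fix nearest the five's per-axis medians.
Mirror-ambiguous problems (three receivers, ambiguous prior) are queued
(cap 1000, oldest evicted and emitted flagged); once an unambiguous fix
arrives, the queue is walked newest-to-oldest, choosing per problem the
candidate closer to the backward-propagated state. Batch runs can seed
priors from up to the ten most recent $\ge4$-receiver fixes of the prior
12 h.

# The simulator

`simulate_scenario()` emulates a deployment end to end: a seeded jittered
receiver grid (default 9 receivers over 10×10 km, separations over
500 m), beacons at receiver sites plus interior points, stationary /
constant-velocity / waypoint tag tracks, per-receiver clock offsets
uniform on ±1 ms, SNR decaying with log-distance plus scatter, ToA noise
$\sigma = \sigma_0 10^{-(\mathrm{SNR}-\mathrm{SNR}_0)/20}$ (nanoseconds),
logistic distance-dependent dropout, coarse grouping timestamps jittered
by ±0.5 ms, and NLOS outliers: a log-uniform 1–10 µs positive delay whose
reported $\sigma$ is deliberately *unchanged*, reproducing the
overestimated-SNR failure mode. Every draw descends from one root seed;
identical seeds give byte-identical streams, and simulation never
disturbs the caller's RNG state.

What the simulator does not model — multipath correlation between
receivers, antenna patterns, time-varying clock drift, packet collisions
— bounds what green tests prove: they validate the estimators under the
stated error model, not radio physics. Real deployments should expect
heavier outlier tails and correlated errors that the diagonal-covariance
assumption ignores.

# Study sizes and numerical defaults

The validation studies (`eval_*` in `R/benchmarks.R`, asserted in
`test-acceptance.R`, reported by `scripts/acceptance.R`) use: 1000
closed-form problems; 200 equivalence instances (simulated at a tenth of
the nominal noise, since the study checks an algebraic identity and the
numerically flat valley around a noisy minimum would otherwise dominate
the comparison); 100 nuisance-oracle instances; 500 paired
outlier problems (6 receivers, 3 beacons, 1–2 delays); 2000 covariance
replicates at 5 ns; 200 mirror-ambiguous tracks of 10 queued fixes; 40
paired DEM problems. These sizes put Monte-Carlo standard errors
comfortably inside each tolerance while keeping the full run at a few
minutes on one CPU.

Levenberg–Marquardt uses multiplicative damping (start $10^{-3}$,
$\times10$ on reject, $/10$ on accept), stops at step $<10^{-4}$ m or 50
iterations, and reports failure on damping overflow; the tolerances are
arguments where a study needs tighter convergence. Times are serialized
as fixed-point seconds at 12 decimals (picoseconds): fixed-point for
byte-stable round trips, and fine enough that quantization (~0.3 mm) is
negligible against any real ToA error.

# Known limitations

* Outlier classification acts on differenced pairs, so one bad
  observation discards both members of its pair.
* The clustering variant needs many hypotheses to be robust and is
  slower; consensus is the default for good reason.
* Free-3D altitude is a technical capability, rarely useful on planar
  networks.
* The equivalence of gated estimates across the single/multi beacon
  modes holds only when beacon geometry is adequate; with a single
  marginal beacon the multi mode has nothing to add.
* Batch (hourly-reprocessing-style) execution only: no streaming
  buffers or network transport.
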