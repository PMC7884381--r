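---
title: "Forest-space information geometry: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest-space information geometry: models, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waldspace)
```

## The space

A point of the space is an equivalence class of *forests*: graphs on
`N` labelled leaves and unlabelled internal vertices of degree at least
three, each edge carrying a length `ℓ^e ∈ [0, ∞]` or equivalently a
weight `λ^e = 1 − exp(−ℓ^e) ∈ [0, 1]`. Pendant edges of directly
constructed trees must have positive length, and every pair of leaves in
a component must be separated by at least one positive-weight edge
(otherwise two leaves would be statistically indistinguishable and no
metric below would separate them). Two reduction rules generate the
equivalence:

* an internal edge of weight 0 is contracted (its endpoints merge) — the
  usual boundary identification between tree topologies, where three
  maximal orthants meet at every codimension-1 face and nearest-neighbour
  interchange moves between them;
* an edge of weight 1 (infinite length) is deleted, disconnecting its
  component; an unlabelled vertex left with degree two has its two edges
  merged with weight `λ + λ' − λλ'` (lengths add). This *boundary at
  infinity* is what distinguishes the space from the classical orthant
  complex: substitution saturation makes infinitely long edges finitely
  far away, and crossing such a face realizes bisection–reconnection
  moves.

`canonicalize()` applies both rules to a fixed point and returns a unique
reduced representative; `forests_equivalent()` compares canonical forms
(weights compared with absolute tolerance 1e−12, chosen so that equality
is decidable after floating-point arithmetic without merging genuinely
distinct trees).

## Two models, two metrics

**Two-state symmetric model.** Each edge carries a symmetric two-state
Markov process in stationarity (Bernoulli(1/2) marginals); the chance
that the states at two points distance `ℓ` apart agree is
`(1 + e^{−ℓ})/2`. A forest induces a strictly positive distribution
`p(s)` on the `2^N` binary characters `s`, computed by post-order pruning
on each component (components are independent). The pruning recursion is
differentiated *forward-mode* through every transition and product, so
first and second derivatives of every `p(s)` in every edge length are
exact — no finite differences enter the metric:

`g_ij = Σ_s p(s) ∂_i log p(s) ∂_j log p(s)`.

Infinitesimally `δℓᵀ g δℓ` equals twice the Kullback–Leibler divergence
between the perturbed and unperturbed character distributions (and, after
a `2/f''(1)` normalization, the same holds for any f-divergence); the unit
tests verify this expansion numerically at third-order accuracy.

**Gaussian (OU) model.** A mean-reverting Gaussian process with standard
normal stationary law matches the two-state moments: leaf covariances are
`exp(−ℓ_uv)` (zero across components), giving a positive definite matrix
`S_F` with unit diagonal. The Fisher metric of zero-mean Gaussians is the
affine-invariant form `⟨X, Y⟩_S = tr(S⁻¹XS⁻¹Y)/2`, and pulling it back
through `∂S/∂ℓ^i = −(S ∘ σ^i)` (σ^i the 0/1 split matrix of edge `i`)
yields the closed-form tensor

`g_ij = tr(S⁻¹(S∘σ^i) S⁻¹(S∘σ^j))/2`.

The sign of `∂S/∂ℓ^i` follows from differentiating the product-over-edges
form of `S`; it matters for gradients (not for `g` itself) and is verified
against central finite differences in the tests.

**Derivatives of the Gaussian metric.** Matrices of the form
`S ∘ m` (m a product of split masks) are closed under differentiation:
`∂_k (S∘m) = −S∘m∘σ^k` and `∂_k S⁻¹ = S⁻¹(S∘σ^k)S⁻¹`. First derivatives
of `g` are evaluated from explicit four-to-six-factor trace formulas;
second derivatives (needed only for curvature) are produced by a small
symbolic term engine that differentiates trace terms factor by factor.
Christoffel symbols use the standard formula
`Γ^k_ij = g^{kl}(∂_i g_lj + ∂_j g_li − ∂_l g_ij)/2`; the Riemann tensor is
assembled from `Γ` and `∂Γ` and validated two ways (tensor symmetries, and
finite differences of the analytic Christoffels — a sharper and equally
independent alternative to a holonomy estimate). Sectional curvatures of
coordinate planes at random 5-leaf trees take both signs, so no global
curvature bound of either sign holds for this geometry.

## Geodesic shooting

`shoot_geodesic()` integrates `ẍ^k + Γ^k_ij ẋ^i ẋ^j = 0` with classical
RK4 at a fixed step (default `5e−3` after unit-speed normalization, so
time equals arc length; halving the step changes endpoint coordinates at
the 1e−6 level on the documented examples). Boundary rules follow the
space's structure:

* an internal coordinate reaching 0 stops the integration (the chart
  ends at the orthant wall); the crossing time is located by bisection on
  the step fraction to 1e−10;
* a pendant coordinate reaching 0 is set to 0 **with its velocity
  zeroed**, and integration continues. The velocity treatment at the clamp
  is a genuine choice (projecting the velocity is the alternative); zeroing
  is simple, keeps the state admissible, and the clamp is flagged in the
  output;
* in weight coordinates, a weight reaching 1 means the boundary at
  infinity has been reached in *finite* time. The metric pulled back to
  weight coordinates loses rank like `(1 − λ)⁴` near a disconnection face
  (the pendant directions of a departing component carry vanishing
  information), so the last numerically representable interior points sit
  about `1e−3` from the face; arrival is declared at `λ ≥ 1 − 1e−3` and
  arrival times are accurate to that resolution.

Weight-coordinate integration transforms `g` and `∂g` *before* forming
Christoffels (the length-coordinate tensor is numerically singular near
the boundary, the transformed one is not), through the diagonal map
`ℓ = −log(1 − λ)`. Length- and weight-coordinate solutions agree as loci
to 1e−7 on the tested examples, reflecting parametrization invariance of
the geodesic equation.

The two-state and Gaussian Christoffels differ noticeably at short edge
lengths and converge with saturation; the integrated trajectories from
identical initial conditions trace loci within a few percent of each
other, which is why the cheaper Gaussian model is the default.

## Projection onto the embedded space

For a target `S₀`, `d_cov(S₀, S_ℓ)²` is differentiable in the edge
lengths, with gradient
`tr(log(S₀^{-1/2} S_ℓ S₀^{-1/2}) S₀^{1/2} S_ℓ⁻¹ ∂_i S_ℓ S₀^{-1/2})`.
Descent uses Barzilai–Borwein steps (`α = sᵀs/sᵀy`) with safeguards
`α ∈ [1e−8, 1e2]`, halving backtracks when the objective increases, a
gradient-infinity-norm tolerance of 1e−8, at most 5000 iterations, a
pendant floor of 1e−10, and a length cap of 50 (a cap hit is meaningful:
genuine optima at the boundary at infinity exist). Two additions proved
necessary in practice and are deliberate design choices:

* **stationary-step stop** — near a minimum the objective reaches its
  floating-point floor while the gradient norm stalls just above the
  tolerance; an accepted step smaller than 1e−12 in every coordinate ends
  the run as converged;
* **boundary pinning** — when the crossing variant oscillates across the
  same codimension-1 face with shrinking overshoots, the projection target
  lies *on* the face; the offending coordinate is pinned at 0 (an
  unresolved tree) and released only if its gradient later points into the
  interior. Convergence at a pinned coordinate uses the one-sided
  optimality condition (gradient ≥ 0).

Three variants: `project_within_orthant()` halts at the first negative
internal proposal (status `boundary_halt`); `project_crossing()`
reinterprets the absolute values of the proposal in the two
NNI-neighbouring orthants and continues from the closer (ties broken
toward the lexicographically smaller split set and logged — non-unique
projections are real, a midpoint between two orthants can have two
equally close trees); `project_global()` runs the constrained variant in
all `(2N−5)!!` orthants (guarded at N ≤ 6). Per-orthant initialization
defaults to the ordinary-least-squares branch-length fit to `−log S₀` —
the standard distance-based estimate — because a fixed all-equal start
can drive even the correct orthant's descent into a wall before it turns
toward an interior optimum.

## Approximate boundary-value geodesics

Between arbitrary forests the boundary-value problem is solved
approximately by projecting points of the ambient SPD geodesic
(`Γ(t) = S₁^{1/2} exp(tU) S₁^{1/2}`, `U = log(S₁^{-1/2}S₂S₁^{-1/2})`):
the *recursive* construction steps a fraction `1/(k−i+1)` along the
geodesic from the current point to the far endpoint and projects
(initialized from the previous point), producing `G_0..G_k`; the
*symmetrized* construction runs the same update from both ends at
proportions `1/(k−i+1)` and `1−1/(k−i+1)` and outputs
`G_0..G_{k−1}, H_{k−1}..H_0`. The seam between the two half-sequences is
treated as an ordinary segment; by construction the last two iterates
project the same ambient midpoint, so the seam length is numerically
zero whenever both projections land in the same basin. Discrete length is
the sum of consecutive ambient distances; it always dominates the
endpoint chord. Default subdivision is `k = 64` for path construction.

Empirically, on the documented 5-taxon instances, the symmetrized path is
the shortest of the three constructions when the endpoints are one
rearrangement apart, but on the two-rearrangement instance it measures
0.1–0.7% *longer* than the better recursive orientation across all tested
`k` (16–128) and internal-length settings, even though all three paths
traverse the same orthant sequence and the seam is exact. The three
constructions remain within one percent of each other; none of them comes
with an optimality guarantee, and convergence theory for the symmetrized
variant is open. Users comparing path constructions should treat
differences below a percent as discretization-level and prefer the
symmetrized output for its swap symmetry rather than for minimality.

The star-stratum experiment (`star_stratum_curve()`) measures the
approximate intrinsic distance from a resolved 4-taxon tree with all
edge weights `λ₀` to the star tree with pendant weights `λ`, over a grid
of `λ`. It uses symmetrized paths with `k = 16` by default (`k = 12` in
the automated runs); the distance values on these instances change only
in the fourth digit between `k = 12` and `k = 64`, while cost grows
linearly in `k`. The curve diverges as `λ → 0` (the star covariance loses
rank, `λ = 0` is rejected), its minimizer sits slightly above `λ₀`, and
the minimum decreases as `λ₀ → 1`.

## Synthetic data and what the tests show

There is no external data; every input is generated in code. The
generators emulate the study conditions of the methods themselves:
5-taxon trees (the smallest size with two internal coordinates, so orthant
interiors are two-dimensional and visualizable), pendant lengths 0.1–0.5,
internal lengths 0.15–0.5, exponential(mean 0.5) random edge lengths with
uniformly drawn topologies, and aligned binary characters simulated by
root-to-tip propagation (10^5 sites where empirical moments are compared
with closed forms). What passing tests show is internal consistency of
the geometry — exact derivatives, metric oracles, boundary behaviour,
recovery of planted projection targets — not performance on real
alignments: real sequence data bring model misspecification (rate
heterogeneity, four-letter alphabets, alignment error) that these
generators deliberately do not emulate, and the character-distribution
machinery is exponential in `N` (guarded at 16 leaves; the geometric
algorithms are polynomial through the Gaussian route).

## Problem sizes in the automated runs

Unit plus acceptance suites: trees with N ≤ 6 leaves; 2000 random trees
for topology-uniformity; 10^5 simulated characters; 5·10^5–10^6
Monte-Carlo score samples for the Gaussian-metric oracle; RK4 steps 5e−3
over horizons ≤ 3; paths at k = 8–64 subdivisions; star-stratum grids of
~9 weights at k = 12; 20 random trees for curvature signs. On one CPU the
full suite runs in a few minutes.

## Known limitations

* Character-distribution computations are exponential in the leaf count
  (guard at N = 16; derivatives are practical to N ≈ 8).
* Approximate geodesics are heuristic: no convergence proof, possible
  local minima in the projection subproblems, and the symmetrized/
  recursive length ordering is instance-dependent at the sub-percent
  level (see above).
* Topology enumeration and global projection are factorial in N (guards
  at 9 and 6 respectively).
* The geodesic integrator works within one maximal orthant; it stops at
  BHV boundaries rather than continuing into a neighbouring orthant
  (boundary-crossing paths are the projection algorithms' job).
* Four-letter (DNA) substitution models, site-rate heterogeneity and
  statistical inference on the space (means, hypothesis tests) are out of
  scope.
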