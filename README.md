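# waldspace

Information geometry for phylogenetic forests in R.

Phylogenetic trees inferred from sequence data are probability models: a
tree with leaf set `1..N` and edge lengths `ℓ^e` induces a distribution on
the characters observed at its leaves. Two trees are biologically close
when those distributions are close, which is not what the classical
(BHV / tropical) tree-space metrics measure. This package implements a
space of *forests* — leaf-labelled trees that may disconnect when edges
become infinitely long, with edge weights `λ^e = 1 − exp(−ℓ^e) ∈ [0,1]` —
together with two Riemannian geometries on it:

* the **two-state symmetric substitution model** geometry, where the metric
  tensor is the Fisher information of the character distribution,

  `g_ij(ℓ) = Σ_s p_ℓ(s) ∂_i log p_ℓ(s) ∂_j log p_ℓ(s)`,

  computed from exact (algorithmically differentiated) character
  probabilities, and
* the **Gaussian (Ornstein–Uhlenbeck) trait model** geometry, where a
  forest maps to the covariance matrix `S_F = (exp(−ℓ_uv))_{u,v}` and the
  metric is the affine-invariant (Fisher–Rao) form
  `⟨X,Y⟩_S = tr(S⁻¹XS⁻¹Y)/2`, so the forest space embeds into the cone of
  symmetric positive definite matrices with distance
  `d_cov(S₁,S₂)² = tr log²(S₁^{-1/2} S₂ S₁^{-1/2}) / 2`.

On top of these the package provides:

* Newick I/O for forests (integer leaf labels, `inf` edge lengths, one
  statement per component), splits, split matrices, topology enumeration
  ((2N−5)!! resolved topologies), NNI neighbourhoods and the canonical
  reduction rules of the space (zero-weight internal edges contract;
  weight-one edges disconnect);
* geodesic shooting by RK4 integration of the geodesic ODE
  `ℓ̈^k + Γ^k_ij ℓ̇^i ℓ̇^j = 0` in either model, in length or weight
  coordinates, with boundary handling (stop at orthant walls, clamp
  pendant edges at zero, finite-time arrival at the boundary at infinity);
* Christoffel symbols and sectional curvatures from analytic first and
  second derivatives of the Gaussian metric;
* projection of an arbitrary SPD matrix onto the embedded forest space by
  Barzilai–Borwein gradient descent (orthant-constrained, boundary
  crossing via NNI, or global over all orthants);
* approximate boundary-value geodesics between trees of different
  topologies by recursive / symmetrized projection of ambient SPD
  geodesics, discrete path lengths, and the star-stratum distance profile;
* tree comparison metrics (ambient `d_cov`, Jensen–Shannon, Hellinger,
  path difference) and deterministic fixture/random-tree generators.

## Worked example

Two 5-taxon trees one rearrangement apart (the second swaps leaves 1 and 3
relative to the first):

```r
library(waldspace)
F1 <- fixture_forest("F1")   # ((1:0.1,2:0.1):0.3,3:0.1,(4:0.1,5:0.1):0.2)
F2 <- fixture_forest("F2")   # ((2:0.1,3:0.1):0.3,1:0.1,(4:0.1,5:0.1):0.2)

spd_distance(covariance_matrix(F1), covariance_matrix(F2))
#> [1] 1.02885
js_metric(character_pmf(F1), character_pmf(F2))
#> [1] 0.2296588
```

The first number is the ambient (chordal) covariance distance between the
embedded trees; the second the exact Jensen–Shannon distance between their
character distributions (a sum over all 2^5 characters). An approximate
*intrinsic* geodesic between them, constrained to the forest space, is
longer than the chord:

```r
path <- symmetrized_path(F1, F2, k = 64)
discrete_length(path)
#> [1] 1.178175
```

Projecting the ambient midpoint of the two trees back into the forest
space finds the nearest forest, here a tree near the boundary between the
two topologies:

```r
S <- spd_geodesic_point(covariance_matrix(F1), covariance_matrix(F2), 0.5)
project_crossing(S, F1)
#> wald_projection: objective 0.0575918 after 34 iterations (converged)
#> wald_forest: 5 leaves, 7 edges, 1 component(s)
#> (1:0.0700549152585,((2:0.1183203758,3:0.174941339977):0.066166177513,(4:0.100226090669,5:0.100226090669):0.249010827539):0.0700549152585);
```

The reported objective is the squared ambient distance from `S` to the
projected tree. A thin command-line front end over the same functions is
installed as `exec/waldspace` (subcommands `dist`, `spd-dist`,
`spd-geodesic`, `shoot`, `project`, `geodesic`, `star-curve`,
`fixtures`).

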