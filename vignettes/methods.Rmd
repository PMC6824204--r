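---
title: "Bayesian vowel motor planning: model, surrogate plant, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian vowel motor planning: model, surrogate plant, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`speechplan` implements a Bayesian account of vowel motor planning in
which a phoneme is characterized by Gaussian goal regions in two sensory
spaces at once, and a motor command is selected by sampling the
posterior that those goals induce over a bounded control space. This
vignette describes the model and its assumptions, the synthetic
articulatory plant the package uses in place of a biomechanical
simulator, the tunable parameters and their defaults, the numerical
choices, and the known limitations.

## 1. The generative model

The probabilistic variables are the 6-D motor command $M$ (muscle
control variables $\lambda_1,\dots,\lambda_6$, each confined to a
closed interval), the phoneme label $\Phi$, predicted sensory
consequences $A_M, S_M$, sensory-phonological variables $A_\Phi,
S_\Phi$, and binary coherence variables $C_A, C_S$ that act as
probabilistic switches enforcing a match between prediction and goal.
The assumptions, in order of importance:

* **Deterministic internal models.** $P(X_M \mid M)$ is a Dirac
  distribution at $\rho_x(M)$, a learned forward map from command to
  sensory consequence. There is no sensory or motor noise in the
  planning loop; all posterior spread comes from the width of the goal
  regions and the redundancy of the plant.
* **Gaussian goals.** $P(X_\Phi \mid \Phi = \phi) =
  \mathcal N(\mu_{X\phi}, \Gamma_{X\phi})$. The order-$k$ dispersion
  ellipsoid of such a goal (semi-axes $k\sqrt{\text{eigenvalues}}$) is
  the package's standard region summary; order 2 for plots, order 3
  for coverage checks.
* **Flat priors** over $M$ (on its box) and $\Phi$, so they contribute
  only constants.

Conditioning on the switches collapses analytically to three planning
posteriors: auditory-only, somatosensory-only, and their product
("fusion"). The switches are never sampled; the package evaluates the
collapsed densities directly.

## 2. Adaptation to an auditory perturbation

A formant perturbation adds a constant $\delta$ (default
$(-100, 0, 0)$ Hz) to the produced sound. Adaptation is modelled as a
*complete and perfect* update of the auditory internal model:
$\rho_a^*(m) = \rho_a(m) + \delta$. The package implements this as a
stored additive offset on the map rather than a refit: for a constant
$\delta$ the two are mathematically identical, and the offset makes the
adaptation contract exact (no fitting noise), which the test suite
checks to numerical precision. Offsets compose additively, so adapting
by $\delta$ then $-\delta$ restores the original map exactly. Learning
*dynamics* (trial-by-trial error correction) are out of scope; only the
adapted end state is modelled, and the pre-adaptation condition simply
re-uses unperturbed plans with a shifted percept.

## 3. Sensory preference

Two mechanisms modulate how strongly each modality constrains planning:

* **Target-based**: $\Gamma_X \to \kappa_X \Gamma_X$, $\kappa_X > 0$.
  Larger $\kappa$ lowers the modality's precision at the level of the
  stored goal itself.
* **Comparison-based**: the exact matching constraint is relaxed to
  $P(C_X = 1 \mid x_1, x_2) = \exp(-\|x_1 - x_2\|^2 / 2\eta_X^2)$.
  Summing the sensory-phonological variable out is a convolution of two
  Gaussians, so the planning density is again Gaussian with covariance
  $\Gamma_X + \eta_X^2 I$. The package only ever uses this closed form;
  the kernel itself is exposed as `soft_match_prob()` and its
  $\eta \to 0$ limit as `strict_match()`.

In 1-D the mechanisms are exactly equivalent under
$\kappa = 1 + \eta^2/\Gamma$ (`kappa_equivalent_1d()`). In 3-D they
differ unless $\Gamma$ is isotropic: $\kappa$-scaling preserves
eigenvectors *and* eigenvalue ratios, while $\eta^2 I$-inflation
preserves eigenvectors but drives the condition number monotonically to
1 — the goal region swells and loses its elongation, though its
principal axes never rotate. The literal testable content of
"progressive alignment with the coordinate axes" is this progressive
isotropy, and that is what the property suite asserts; a region with
condition number 1 has no preferred orientation left. `anisotropy()`
exposes the condition number and leading axis for such checks.

Units: $\eta_A$ is in Hz, $\eta_S$ in PC units. Because these scales
are incommensurable, sweep grids express $\eta$ as a multiple of the
corresponding sensory space's corpus standard deviation and convert
internally; $\kappa$ is dimensionless. One further wrinkle is worth
recording: in the 1-D correspondence the additive increment to the
variance is $\eta^2$, which is what the convolution identity and
`kappa_equivalent_1d()` implement; a reading in which the increment is
written as a bare $\eta$ is dimensionally inconsistent with the kernel
definition and is not used.

## 4. The synthetic plant

No biomechanical simulator is available to this package, so a seeded
synthetic plant defines the ground truth. Its design goals, in order:
smooth nonlinearity between control and both sensory spaces; mutually
distorted auditory/somatosensory geometry; a somatosensory space that
is genuinely the 3-PC summary of a higher-dimensional tongue contour;
and — critical for the planning properties — formants that are, to a
very good approximation, a function of tongue *shape*, as in a real
vocal tract.

* **Contour**: 17 nodes (34 coordinates, node-major, x before y) =
  resting arc + orthonormally mixed saturating latents
  $z_j = \tanh(\alpha_j v_j^\top m)$ (3 strong, scales 3/2/1.2; 2 weak,
  scales 0.15/0.1) + a small direct affine term (SD 0.03) that keeps
  the contour Jacobian full rank 6.
* **Somatosensory space**: PCA of 5000 contours; the three components
  carry ≥ 97% of the variance by construction.
* **Acoustics**: a quadratic score of the *same* latents (weak latents
  damped to 2%), standardized over the build corpus, scaled to
  per-formant SDs of 130/330/280 Hz, and soft-clipped by a tanh into
  the ranges F1 ∈ [150, 900], F2 ∈ [800, 2800], F3 ∈ [2000, 3800] Hz.

The weak-latent damping deserves a comment because it was forced by the
model's own claims, not by aesthetics. If the acoustics depend
appreciably on degrees of freedom that the 3-PC somatosensory code
compresses away, then somatosensory-only planning — which constrains
only the PCs — wanders along acoustically relevant fibers, and its
auditory outcomes spill outside the auditory goal region. Real tongues
do not have this pathology (formants are determined by the vocal-tract
area function, i.e. by shape), and the claim that all three planning
modes reach *both* goal regions unperturbed requires its absence. With
2% damping the plant retains full-rank redundancy while the
somatosensory code determines the acoustics to within a few Hz.

Both maps remain clearly nonlinear: the best affine fit from control to
either sensory space leaves ≥ 14% relative residual, well above the 5%
floor below which the RBF internal-model stage would be pointless.

The plant's weights are a deterministic function of a build seed. That
seed (default 20) is a *model constant*, analogous to a fixed
biomechanical model; run-level seeds (corpus sampling, map fitting,
target derivation, MCMC) are spawned from the user's master seed in a
fixed documented order (`spawn_seeds()`): plant corpus, training
corpus, auditory fit, somatosensory fit, inventory.

## 5. Internal models

`fit_sensory_map()` fits Gaussian-RBF ridge regression with an affine
tail (so affine plants are interpolated exactly), centers from seeded
k-means, bandwidth 0.65 × median inter-center distance, ridge $10^{-8}$
escalating ×100 on a singular solve, and a 20% held-out split whose
RMSE is stored on the object. The pipeline default is 800 centers on a
50,000-sample corpus; at the reduced sizes used in tests and in the
acceptance script (600 centers, 20,000 samples) the held-out RMSE is
≈ 1–2% of each output's SD (≈ 2 Hz in F1). That fidelity budget is
asserted by the test suite *before* any planning property is tested,
because internal-model error bounds every downstream accuracy claim —
most visibly the full-compensation check, whose tolerance (±0.05 of the
100 Hz shift) leaves room for a few Hz of map bias.

## 6. Targets

The paper-level description of vowel goal regions (dispersion
ellipsoids adapted to a specific biomechanical model) provides no
reusable numbers, so the package generates a layout on its own plant:

* Six anchor points on the reachable formant cloud: the reference vowel
  /ɔ/ (used in all perturbation experiments) is pinned at a canonical
  quantile position with mid-range F1, and the other five are chosen by
  farthest-point selection pulled 0.7 of the way toward the cloud
  centroid. Labels are assigned to anchors by least-squares matching to
  a canonical (F1, F2) vowel-chart layout. Pinning /ɔ/ at mid F1
  matters: the adapted auditory goal sits 100 Hz *above* the original,
  and if that image falls in the sparse upper tail of the reachable set
  the posterior mean is pulled down and "full" compensation is
  structurally truncated.
* Means are local averages of the 100 nearest corpus points
  (guaranteeing reachability); covariances combine the local corpus
  correlation (shrunk 40% toward identity, guaranteeing SPD) with
  per-formant SDs of (24, 45, 60) Hz — typical within-speaker vowel
  dispersions. Pairwise Mahalanobis separation ≥ 2 is enforced.
* Somatosensory goals are *derived*, not designed: commands are sampled
  from the auditory-only posterior for each vowel (5000 draws by
  default), pushed through $\rho_s$, and moment-matched by a Gaussian.
  This uses only machinery the model already has, and reduces to the
  exact affine push-forward when the plant is affine — the test suite
  checks that correspondence against the closed form.

## 7. Sampling and diagnostics

Random-walk Metropolis–Hastings over the control box; out-of-bounds
proposals are rejected (the bounded uniform prior's support). Proposal
SD starts at 0.05 × box width per dimension and adapts every 50
burn-in iterations by $\exp(\text{rate} - 0.234)$ toward the standard
23% acceptance target, then freezes, keeping the retained chain a
proper MH chain. Each chain starts at the best of 200 uniform probes.
Per-chain seeds derive from the run seed, so runs are bit-reproducible;
an error is raised if every chain accepts < 1% of proposals. Reported
means carry Monte-Carlo standard errors computed from between-chain
variance.

The default protocol is 20 chains × (10³ burn-in + 10³ retained) =
2·10⁴ retained draws. The sampler is validated two ways: against the
closed-form moments of a Gaussian target, and against an exhaustively
grid-normalized posterior on a 2-D reduced problem
(`grid_marginals()` / `ks_to_grid()`), where the marginal KS distance
at 2·10⁴ draws is ≈ 0.02, comfortably under the 0.05 bound asserted in
the tests.

## 8. Experiments and the compensation metric

The perturbation figures of this literature report ellipse positions,
not scalars, so the package defines one: the displacement of the
produced (ground-truth plant, unshifted) auditory mean from an
unperturbed baseline, projected on $-\delta/\|\delta\|$ and divided by
$\|\delta\|$. 1 = full compensation, 0 = none. Pure-mode runs use
their own mode's baseline; sweep curves and their pure-mode reference
lines all share the unperturbed no-preference fusion baseline, so that
endpoint comparisons are lineage-consistent (the pure modes' posterior
means differ from fusion's by a few Hz even unperturbed, and mixing
baselines would fold that offset into the endpoint gap).

Default sweep grids are 6-point geometric series spanning the
*transition* from fusion-like to single-modality behavior: $\kappa \in
[1, 32]$ and $\eta \in [10^{-1.75}, 10^{0.75}]$ corpus SDs. Wider
grids (e.g. three full decades) were rejected because the continuum
saturates within about one decade; beyond it the curve is flat at the
pure-mode value and Monte-Carlo noise in the flat tail degrades rank
statistics without adding information.

## 9. Problem sizes

The package defaults reproduce the reference protocol (50,000 training
simulations, 5000-draw target derivations, 2·10⁴ retained planning
draws). The test suite and the acceptance script run the same code at
reduced sizes chosen as the smallest at which the planning properties
hold with clear margins: 20,000 training samples, 600 centers, 4000
PCA contours, 4000-draw derivations, 10 chains × 500 retained draws
per planning run (6 × 300 for the 18-condition coverage scan), and
5·10³ draws per sweep point. Re-running the acceptance script under
several seeds moves the headline numbers by well under their test
tolerances (e.g. the auditory compensation ratio stays within
1 ± 0.025).

## 10. What the synthetic conditions do and do not show

The generator emulates: smooth redundant control-to-sensory maps, a
PCA-built proprioceptive space, mutually distorted sensory geometries,
bounded control, and goal regions of realistic formant dispersion. It
does not emulate: biomechanics (muscle forces, contacts, dynamics),
acoustic wave propagation, sensory noise, jaw/lip articulators,
coarticulation or sequence planning, perceptual boundary shifts, or
adaptation dynamics. Passing tests therefore demonstrate that the
inference machinery — fusion, adaptation, and both preference
mechanisms with their equivalence — behaves as the theory says *given*
deterministic internal models on a redundant nonlinear plant; they do
not validate the biomechanics or predict quantitative human
compensation magnitudes. Degenerate inputs are rejected rather than
repaired: non-SPD covariances, out-of-bounds commands, rank-deficient
PCA corpora, under-separated target layouts, and queries with both
coherence switches off (the uniform prior) all raise errors.
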