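---
title: "Coarse-grained transition pathways with demon-biased elastic-network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained transition pathways with demon-biased elastic-network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebdims)
```

Many proteins work by moving between two (or more) crystallographically
solved conformations — a binding protein closes around its ligand, a pump
alternates access between membrane sides, a channel gates. X-ray
crystallography freezes the end-states and sometimes a handful of trapped
intermediates, but not the route between them. This package generates
candidate routes with a deliberately minimal physical model and then
*validates* them against whatever experimental ensemble exists, using
principal component analysis (PCA) of the solved structures as the common
coordinate system.

## The model

Each residue is reduced to its C-alpha carbon, with a uniform mass of
100 Da (the average amino-acid mass). Residues interact through harmonic
springs whose rest lengths are the inter-residue distances of the starting
structure:

$$V(\mathbf{r}) = \sum_{(i,j)} K_{ij}\,\bigl(d_{ij} - d_{ij}^0\bigr)^2 .$$

Note the convention: no factor 1/2. A pair stretched by $\delta$ pulls each
partner with force $2K\delta$, and the two-bead Hessian has its non-trivial
eigenvalue at $4K$. All printed constants assume this convention.

The spring constants follow an essential-dynamics calibrated recipe: the
first `n_seq = 3` chain neighbours receive stiff, sequence-separation
scaled constants $K = c_\mathrm{seq}/s^2$ (default
$c_\mathrm{seq} = 60\ \mathrm{kcal\,mol^{-1}\,\text{\AA}^{-2}}$) that
preserve backbone stereochemistry, while every other pair within the
12 Å cutoff decays with distance,
$K = \varepsilon\,(c/d^0)^p$ with defaults $\varepsilon = 6$, $c = 6$ Å,
$p = 6$. A gap in author numbering or a chain change demotes a "sequential"
pair to the long-range rule, so springs across chain breaks never inherit
backbone stiffness. These defaults are configuration values — every one is
an argument of `enm_params()` — and none of the package's validation
checks depends on their exact magnitudes.

## Langevin dynamics and the thermostat

The network moves in a stochastic bath: per bead,

$$m\ddot{\mathbf r}_i = \mathbf F_i - \gamma m \dot{\mathbf r}_i + \boldsymbol\xi_i(t),$$

with Gaussian white noise obeying the fluctuation–dissipation relation.
The discretization is the BBK variant of velocity Verlet with a fresh
Gaussian force of per-component variance $2\gamma m k_B T/\Delta t$ each
step. Defaults: $\Delta t = 1$ fs, $T = 300$ K, $\gamma = 50$ ps$^{-1}$
(solvent-like damping; the friction constant is a package choice, exposed
in `bd_params()`). Units are kcal mol$^{-1}$, Å, fs and Da throughout,
with $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$; the single conversion
constant lives in `ebdims_constants()`.

Friction and noise together act as the thermostat. The BBK discretization
carries an $O(\gamma\Delta t)$ bias in the kinetic temperature — about 2 %
at the default $\gamma$ — which is why the thermostat checks use a 5 %
band. Equipartition holds mode-by-mode: the positional variance along a
normal mode of eigenvalue $\lambda$ (a true second derivative of $V$, so
the harmonic energy along the mode is $\tfrac12\lambda a^2$) converges to
$k_B T/\lambda$, and the test suite verifies this on fast-relaxing modes.

## The demon

Directionality comes from dynamic importance sampling. The progress
variable towards the target is built from inter-residue distances only,

$$\Gamma = \sum_{(i,j)\in P}\bigl(d_{ij} - d_{ij}^{\mathrm{target}}\bigr)^2,$$

so it needs no superposition and is invariant under rigid motion. Every
`k_unbiased = 100` steps $\Gamma$ is re-evaluated: if it strictly
decreased, the stretch is kept as a checkpoint; otherwise coordinates
*and* velocities revert to the last checkpoint while the random-number
stream continues, so each retry explores a new branch. Equality is
rejected, which prevents stagnation on plateaus. The pair set $P$ defaults
to all pairs of the residue correspondence; restricting it
(`pair_subset`) lets a run proceed when the target structure has large
unresolved regions, since the elastic network itself only ever needs the
complete starting structure.

Iteration stops when the instantaneous structure reaches the target basin
— RMSD within the range of thermal oscillation, default 1.5 Å, widened to
3 Å above 1000 residues — or after `max_cycles` demon cycles (default
40000, a give-up bound: on the bundled benchmark forward runs need
2000–3000 cycles and reverse runs 6000–18500 depending on the seed). The
accepted checkpoints are the stored pathway, one frame per cycle, and the
$\Gamma$ record over checkpoints is strictly decreasing by construction.

Two demon-design points were genuinely open and are resolved as follows.
First, the baseline for acceptance is the last *accepted* checkpoint, not
the previous evaluation; a drifting baseline can wander uphill
indefinitely. Second, velocities revert together with coordinates, which
keeps the thermostat stationary across rejections while the continuing
RNG stream still decorrelates retries.

## Ensemble PCA and pathway validation

Solved structures of the same protein are corresponded residue-by-residue
(`residue_correspondence()`: intersection of residues resolved in all
members, matched by chain and author residue id, with a 95 % sequence
identity floor — these are same-protein crystal forms, so no alignment
algorithm is needed; unresolved residues are simply excluded rather than
rebuilt). Each member is superposed once onto the reference — the
inactive/resting state — and the coordinate covariance is taken about the
ensemble mean and decomposed by SVD.

Projections deliberately subtract the *reference structure* rather than
the mean:

$$p_k = (\mathbf x_\mathrm{aligned} - \mathbf x_\mathrm{ref}) \cdot \mathrm{PC}_k,$$

so that a projection reads as a deformation relative to a real structure
rather than a geometric average. The consequence — the reference itself
generally projects away from the origin of the mean-centred cloud — is
intentional and its projection is part of every output table. Covariance
about the reference is available via `fit_pca(..., center =
"reference")`. Component signs are fixed deterministically (the member
with the largest absolute projection projects positively), which makes
plots reproducible and, for a two-state ensemble with the inactive state
as reference, puts the active state on the positive PC1 side.

Validation then uses three instruments:

* **Approach profiles** (`approach_profile()`): per-frame RMSD and PC1-2
  Euclidean distance from a pathway to each candidate intermediate, with
  minima and their frame indices. The PC distance weights differences by
  the dominant ensemble motions and so filters the local noise that
  inflates an RMSD.
* **Transition coverage** (`transition_coverage()`): the fraction of the
  squared end-state difference vector captured by the first $k$
  components.
* **Asymmetry score** (`asymmetry_score()`): forward and reverse pathways
  in the PC1-2 plane, scored in $[0,1]$ with 0 for coincident routes.

The asymmetry score needed a concrete protocol. The score is a
minor-to-major axis ratio of the divergence ellipse: the reverse path is
flipped to run start-to-target, both paths are resampled onto a common
progress parameter, and the perpendicular variance — the mean squared
offset of each path from the pair's mid-line, which removes the shared
start-to-target trend — is divided by the leading eigenvalue of the
pooled PC1-2 covariance; the score is the square root. Two anchor cases
pin the behaviour: identical paths score exactly 0, and a symmetric
elliptical loop of axis ratio $b/a$ scores $b/a$. A classical
eccentricity would run the other way (thin, overlapping loops would score
near 1), contradicting the ordering in which overlapping routes score
low; the axis ratio preserves that ordering.

`projection_histogram()` converts pooled projection sets into a
$-k_BT\ln\rho$ surface for visual comparison with energy landscapes. It
is a display utility for sampling density; it makes no reweighting claim.

## The synthetic benchmark

Because the validation framework needs a system with known ground truth,
the package generates one (`make_hinge_models()`): two compact triangular
bundles of three ten-residue helices on an idealized lattice (1.5 Å rise,
2.3 Å radius, 100°/residue, so consecutive C-alphas sit at 3.8 Å and
nothing clashes), joined by a three-residue linker. Conformers rotate the
second domain about the network's own softest axis through the hinge. The
defaults — 63 residues, 0° to −90°, open/closed RMSD 5.17 Å — emulate a
mid-sized hinge-bending protein in miniature.

Three geometric points mattered and are worth recording. First, domain
*rigidity* is essential: with extended single-helix domains the softest
motions are internal bending, and the demon lowers $\Gamma$ by deforming
domains instead of rotating them — runs stall far from the target.
Second, the rotation axis is chosen as the axis about which the open
network's lowest normal mode is an almost pure rigid counter-rotation of
the domains (overlap 0.78 with the full end-state difference), so the toy
really is a "single soft hinge" system. Third, with no residue pair of
the two domains inside the cutoff, a central-force network acquires a
seventh zero mode — an exact mechanism whose energy grows only quartically
— and the short 3.8 Å stalk is what lifts it; the open network then has a
clean 6-fold rigid-body null space and a 100-fold eigenvalue gap to the
hinge mode.

What the toy does *not* emulate: sequence heterogeneity, side chains,
secondary-structure energetics, solvent structure, and crystallographic
noise (available as `noise_sd`, but off by default). Passing the
benchmark therefore demonstrates the machinery — thermostat, demon,
projections, scores — under conditions where the answer is known, not
transferability of the force-field defaults to real proteins.

A note on the demon-cycle length `k`. At the scale of single demon moves,
larger `k` gives slower but wider sampling — checkpoint-to-checkpoint
displacement grows with `k` while the number of checkpoints falls, and the
suite asserts exactly that. At the scale of the whole 63-residue pathway
the net perpendicular spread runs the *other* way: several thousand tiny
accepted moves random-walk further off the geodesic than a hundred large
ones. On systems this small, path-level width is dominated by the number
of ratchet events, so cycle-level and path-level width need not agree.

The forward and reverse directions are not equally hard: the open-state
network is much softer along the hinge than the closed-state network
(lowest internal eigenvalues $2.7\times10^{-4}$ versus
$1.7\times10^{-2}$ kcal mol$^{-1}$ Å$^{-2}$), so closing converges in a
few thousand demon cycles while opening takes several thousand more. That
directional difference is of the same kind the asymmetry score is built
to expose on real systems.

## Numerical choices and degenerate inputs

* Superposition is Kabsch via SVD with the determinant corrected to +1;
  coincident or collinear point sets are flagged and fitted by
  translation only.
* Rigid-body modes are identified by the eigenvalue gap above the
  near-zero cluster, not a fixed count of six, tolerating collinear toys
  (five) — and detecting, rather than hiding, genuine mechanisms.
* $\Gamma$ uses squared distance differences; $\Gamma = 0$ exactly at the
  target geometry (and at its mirror image — distances cannot see
  chirality, which is one reason convergence is declared on RMSD, not on
  $\Gamma$).
* A numbering gap or chain change in the correspondence demotes
  sequential springs, as described above; coincident beads make pair
  forces undefined and error immediately; numerical blow-up
  (coordinates or velocities beyond sanity bounds) errors with the step
  number.
* Problem sizes in the test suite — a 10-residue helical fragment for
  analytic and thermostat checks, the 63-residue hinge with seeds 1–5
  for end-to-end runs, 200–5000-member synthetic ensembles for PCA
  recovery — were chosen so each check is statistically decisive for its
  stated tolerance.

## Limitations

The force field is a configuration default, not the published
essential-dynamics calibration, whose constants live outside this
package; absolute time scales of the coarse-grained dynamics are not
physical and pathway "speed" should never be read as kinetics. The demon
produces physically plausible, stereochemically gentle interpolations —
not minimum free-energy paths; on real systems forward and reverse runs
are best read together, as boundaries of a transition region. PCA
validation inherits the ensemble's biases: sparsely sampled or
crystal-packing-distorted ensembles give principal components that
describe the data, not necessarily the functional motion.
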