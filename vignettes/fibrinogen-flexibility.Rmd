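---
title: "Quantifying fibrinogen hinge-bending flexibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrinogen hinge-bending flexibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibriflex)
```

## The scientific problem

Fibrinogen is an elongated, tri-nodular blood protein: two globular D regions
connected to a central E region by stiff coiled-coils. Halfway along each
coiled-coil sits a flexible hinge — a non-helical loop of the gamma chain
(residues gamma 70–78) — about which the molecule bends. This flexibility
matters in at least three ways: bending exposes the plasmin cleavage sites on
the coiled-coil (fibrinolysis), it produces the broad distribution of
tri-nodular shapes seen when fibrinogen adsorbs to surfaces (biomaterials,
AFM imaging), and correlated motions inside the D region couple the
polymerization pockets (the a- and b-holes) to the integrin binding sites
(allostery). `fibriflex` implements the quantitative machinery for all three
strands, together with synthetic-data generators so that each estimator can
be validated against a known ground truth.

## Hinge angles from trajectories

A hinge is characterized by two angles measured on *group centroids*, each
group being a set of C-alpha atoms named by chain and residue range:

* the **bending angle** `gamma`: the interior angle at the hinge-group
  centroid between rays to the E-group and D-group centroids. 180° is fully
  extended; the crystal conformation sits near 160°; the solution simulations
  that motivate this package reach below 90°.
* the **torsion angle** `phi`: the signed dihedral (IUPAC convention,
  `(-180°, 180°]`) of four group centroids — two E sub-groups, the hinge
  group, the D group — describing rotation of the D arm about the coiled-coil
  axis.

`fg_atom_groups()` carries the standard group definitions for one fibrinogen
protomer (E = alpha 50–58 + beta 82–90 + gamma 23–31, hinge = alpha 99–110 +
beta 130–155 + gamma 70–100, D = beta 200–458 + gamma 140–394; the two phi
E sub-groups deliberately share gamma 23–31). Centroids are unweighted means
over C-alpha atoms: C-alpha is the common denominator across structure and
trajectory formats, and for groups of tens to hundreds of residues the
difference from a mass-weighted all-atom centroid is negligible against the
~40° amplitude of the motions being measured.

PCA (`ca_pca()`) follows the standard essential-dynamics recipe:
rigid-body motion is removed by an iterated Kabsch fit of every frame onto
the running mean structure (converged when the mean moves less than
1e-5 Å RMS), then the coordinate covariance is diagonalized. Two mode sets
are compared with the subspace overlap
`O = (1/n) * sum_ij (x_i . y_j)^2`, which is 1 exactly when the two spans
coincide and 0 when they are orthogonal, and is invariant under re-basing of
either span. Correlation between collective modes and hinge angles is
quantified by the Pearson correlation of the angle series with a linear
combination `CP(t) = sum_j a_j P_j(t)` of mode projections
(`projection_combination_correlation()`).

Helicity around the plasmin cleavage sites is assigned per residue and frame
from backbone dihedrals: a residue is helical when `phi` lies in
(-100°, -30°) and `psi` in (-80°, -5°). No single assignment convention is
canonical; this boxed Ramachandran basin is deliberately simple, and the
boundaries are exposed as arguments of `is_helical()`. The joint table of
per-frame helical fraction against `gamma` (`helicity_vs_bending()`)
defaults to 10° gamma bins over [60°, 180°].

## The coarse-grained adsorption model

The molecule is reduced to a rigid rod (the two coiled-coils) carrying the
E sphere at its center and a hinge at each end; a rigid arm connects each
hinge to a D sphere. The four hinge angles `(gamma1, phi1, gamma2, phi2)`
are the only degrees of freedom; a reference point `x0` on the E-sphere
surface fixes the torsion zero. Defaults (`fg_default_geometry()`) follow
the ~45 nm fibrinogen architecture: rod half-length 8 nm, hinge-to-D-center
9 nm, sphere radii 1.3 nm (E) and 2.7 nm (D), and an adsorption height
threshold `h_max = 1.1 * r_D`. When a crystal structure is available,
`build_cg_geometry()` extracts all lengths from group centroids and radii of
gyration instead.

A conformation is **adsorbed** when the E and both D sphere centers sit below
`h_max` over the surface plane while both hinges stay above the plane.
During Monte Carlo placement, "contact" is the stricter condition
height = sphere radius; `h_max` then implements the adsorption definition
for arbitrary conformations.

`mc_generate()` creates adsorbed conformations the way an AFM experimentalist
would see them form: draw `(gamma1, phi1)`, place the molecule so the E and
first D spheres touch the surface, draw `gamma2`, and solve the second
torsion `phi2` so the second D sphere also touches. With the rod held
parallel to the surface, both contact conditions reduce to the same closed
form, `cos(angle) = (r_D - r_E) / (arm * sin gamma)`: the roll of the
molecule about the rod axis solves the first, `phi2` the second. Each
equation has two roots; one is chosen uniformly at random, and a draw whose
`gamma` makes the right-hand side exceed 1 is rejected (no contact
geometry exists). An earlier design sketch used a bracketed 1-D root search
for `phi2`; the closed form finds exactly the same roots without iteration
and is used instead.

The `(gamma, phi)` plane of one hinge is discretized into 12 rectangular
bins — gamma edges 60/100/140/180° (the 40°-wide ranges used to discuss bent
and extended hinge populations) by four 90° phi bins; the phi edges are a
package choice, configurable in `bin_grid()`. Sampling is stratified over
ordered bin pairs so the accepted per-hinge bin occupancy is uniform across
bins that admit adsorption; within a stratum the angles are uniform. Pairs
that cannot fill their quota within the attempt budget (default 1000 draws
per requested sample) are reported as starved and masked non-adsorbing.

For each accepted conformation the **alpha angle** — the AFM observable — is
measured by projecting the three sphere centers onto the surface and taking
the angle at the projected E center. `bin_pij()` then histograms alpha
(default 5° bins) conditional on the unordered bin pair `(i, j)` of the two
hinges, giving the symmetric table `P_ij(alpha)`.

Production-scale tables in the original analysis tradition use tens of
millions of samples; the package computes its tables at 10^6 samples
(seconds to a minute on one CPU), which converges every `P_ij` histogram
well beyond the needs of the fits below, and the sample count is an explicit
argument throughout.

## Maximum-entropy fitting of hinge-weight models

An observed alpha histogram `N(alpha)` (total `N_tot`) is modelled as a
superposition of the conditional distributions:

* **general model**: `P(alpha) = sum_ij a_ij P_ij(alpha)` with one weight
  per adsorbing bin pair — hinge conformations may be correlated;
* **independent model**: pair weights factorize, `a_ij = a_i * a_j`,
  restricted to adsorbing pairs and renormalized — the two hinges draw their
  conformations independently.

Weights are estimated by maximizing the entropy relative to a
simulation-derived prior, subject to normalization and to the reduced
chi-squared of the fit reaching 1:
`J = -sum a log(a/m) - lambda (chi2 - 1) - mu (F - 1)`,
with `m_ij = w_i w_j` built from the single-hinge bin occupancy `w`
(`prior_weights()`). Numerical choices:

* **Degrees of freedom.** The printed form of the reduced chi-squared,
  `sum (N - N_tot P)^2 / (N_tot P)`, needs a dof divisor, but the general
  model has more free weights than alpha bins, so the textbook
  `bins - parameters - 1` is non-positive. The default divides by the number
  of alpha bins carrying model mass; the `dof` entry of `config` overrides
  it, and the 5%-confidence rejection threshold (`chi2_threshold()`) is
  computed from whatever dof is in force.
* **Equality as inequality.** The chi2 = 1 constraint is enforced as
  chi2 <= 1: when the prior already fits (chi2 <= 1 at `lambda = 0`) the
  prior is returned unchanged, since `J` has no interior maximum in
  `lambda` there.
* **Optimizer.** For fixed `lambda` the dual objective
  `-sum a log(a/m) - lambda chi2(a)` is maximized over the simplex by
  exponentiated-gradient (mirror) ascent with backtracking line search; the
  full step is exactly the entropy stationarity fixed point
  `a = normalize(m exp(-lambda dchi2/da))`, so weights stay positive by
  construction. The outer problem brackets and bisects `lambda` until
  `|chi2 - 1| < 1e-3` (weight-change tolerance 1e-8). The general-model
  inner problem is concave; the factorized model is not, so
  `fit_independent()` additionally starts the first inner solve from the
  prior and from smoothed simplex corners and keeps the best dual value.
  Everything is deterministic given the inputs.
* **Unreachable constraints.** Two distinct situations produce
  `converged = FALSE` with chi2 above 1: (i) the factorized family is simply
  too rigid for correlated-hinge data — this is the scientifically meaningful
  failure that the 5%-confidence comparison detects; (ii) at small `N_tot`
  the multinomial draw may fall outside the convex hull of the `P_ij` rows,
  so even the general model has a chi2 floor slightly above 1. In both cases
  the returned fit is the constrained optimum and the achieved chi2 is
  reported as is.
* **Identifiability.** The model is symmetric under reflecting both torsions
  (`phi -> -phi` leaves alpha unchanged), so mirror-phi bins have identical
  `P_ij` and weight vectors are not identifiable even with perfect data.
  Recovery is therefore assessed on the fitted alpha distribution, which is
  the identifiable quantity, not on the weights.

`independent_peak_check()` implements the impossibility argument against
independent hinges: for any single-hinge weight function — including
multi-peaked ones — the factorized model's alpha distribution has its
absolute maximum in the bin containing 180°, because conformations in which
both hinges sample the same weight maximum align the two arms, and the 180°
peak, sitting at the end of the alpha range, accumulates the symmetric
contributions on a single tail. The routine evaluates the factorized model
over a battery of Dirichlet-random weight vectors plus explicit two-peak
constructions (`two_peak_weight()`) and reports each modal bin. A deep
trough at 180° in an observed histogram therefore cannot be produced by
independent hinges, whatever their weight function — adsorption must couple
them.

## Linear-mutual-information networks

For residues `i, j` with mean-subtracted per-residue covariances `C_i`
(3x3) and joint covariance `C_ij` (6x6), the linear mutual information is

`LMI(i, j) = (ln det C_i + ln det C_j - ln det C_ij) / 2`  (nats),

zero for independent motions and divergent as the motions become
deterministically related (`lmi_matrix()` flags singular pairs as infinite
and excludes them from networks). Some formulations print the per-residue
second moment without mean subtraction; that choice would break translation
invariance, so both blocks here are central covariances. Frames are
superposed with the same iterated Kabsch scheme as the PCA module before
covariances are taken (disable with `superpose = FALSE` for synthetic
fluctuations drawn in a fixed frame).

A correlation network connects residues whose LMI exceeds a threshold
`r_crit` (the threshold is applied to the LMI value itself).
`find_pathways()` enumerates *all* shortest paths between a source and a
target residue set, keeps only paths no longer than the largest `N` with
`r_crit^N > 0.025` (links are only trusted while the compounded correlation
stays above that floor — at `r_crit = 0.85`, `N = 22`), and summarizes
per-residue traversal two ways: the fraction of retained paths containing
the residue (pooled convention; residues at 100% form the **bottleneck**)
and the fraction of connected source–target pairs with at least one
traversing path. Both are reported because summary statements like "75% of
all pathways" are ambiguous between the two. `threshold_scan()` lowers
`r_crit` stepwise until the two sites first connect, and `control_pairs()`
lists all residue pairs at least 6 nm apart (60 Å on Angstrom coordinates)
for control enumerations.

## What the synthetic generators emulate — and what they do not

* `gen_hinged_trajectory()` builds rigid point-cloud domains whose centroid
  geometry follows a prescribed `(gamma(t), phi(t))` script exactly, with
  optional isotropic per-atom jitter added per frame. It emulates the
  geometry of hinge bending, so angle recovery, PCA mode structure and
  angle/mode correlations can be checked against a known script. It does
  *not* emulate force-field dynamics: there is no temporal autocorrelation,
  no internal domain deformation, and jitter is white. Passing tests
  validate the estimators' geometry and statistics, not any claim about
  real molecular kinetics.
* `gen_gaussian_trajectory()` draws frames i.i.d. from a specified
  multivariate normal, the exact regime in which the LMI formula is the
  mutual information; closed forms such as
  `LMI = -(3/2) ln(1 - rho^2)` for an isotropically correlated pair
  (`lmi_isotropic_pair()`) provide oracles. Real trajectories are
  autocorrelated and non-Gaussian; the generator shows the estimator is
  right where it can be right.
* `gen_alpha_histogram()` draws multinomial counts from a weight model
  evaluated on a `P_ij` table — an AFM histogram with known generating
  weights. Real AFM histograms add digitization, tip-convolution and
  selection effects that are out of scope here.
* `gen_backbone_trajectory()` builds ideal-geometry N–CA–C backbones from
  phi/psi scripts (NeRF chain construction, omega = 180°) to exercise the
  helicity assignment.
* `gen_synthetic_protomer()` is a labelled *stand-in* for a crystal
  structure: it carries the true fibrinogen chain/residue numbering with the
  measurement groups laid out as compact clouds at a prescribed bending
  angle (default the near-extended 160° crystal-like value). It validates
  selection and measurement on realistic numbering; it contains no real
  crystal coordinates.

## Problem sizes and determinism

The shipped tests and the acceptance script run at sizes chosen for a single
CPU: Monte Carlo tables at 10^4–10^6 samples, Gaussian trajectories at
10^3–10^4 frames, histograms at N_tot = 10^3, pathway oracles on 50-node
graphs. Every stochastic routine takes an explicit integer seed and is
bit-reproducible given it; fits are deterministic functions of their inputs.

## Known limitations

* The coarse-grained model has no excluded volume beyond the height tests
  and omits the alpha-C regions and beta-N stretches entirely, as does the
  adsorption picture it implements.
* The phi-bin edges of the 12-bin grid and the dof convention of the
  reduced chi-squared are package choices (configurable), since neither is
  fixed by the adsorption-model definition itself.
* Weight vectors of the hinge-weight models are identifiable only up to the
  model's mirror symmetry; interpret fitted weights through the fitted
  alpha distribution.
* `lmi_matrix()` is O(R^2) pairwise 6x6 determinants; for trajectories of
  many hundreds of residues expect minutes, and restrict to the region of
  interest (e.g. the D region) where possible.
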