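---
title: "Identifying soft-tissue elasticity from gravitational loading: the virtual-power equilibrium gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying soft-tissue elasticity from gravitational loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Measuring the mechanical properties of a soft organ *in vivo* is hard
because its boundary conditions can be neither controlled nor observed.
Gravity offers a way out: the body force on every material point is known
exactly (density times gravitational acceleration), and imaging the organ
in two postures yields a full-field displacement measurement produced by a
precisely known load change.  `gravfm` turns such a measurement into
material parameters without ever solving an inverse finite-element
problem.

The engine is a virtual-power form of the virtual fields method.  The weak
form of momentum balance states that for *any* differentiable test
function (virtual velocity field) $\mathbf{v}^*$,

$$\int_V \sigma : \mathbf{D}^* \, dV \;=\; \int_V \mathbf{b} \cdot
\mathbf{v}^* \rho \, dV \;+\; \int_S (\sigma \cdot \mathbf{n}_t) \cdot
\mathbf{v}^* \, dS,$$

where $\sigma$ is the Cauchy stress, $\mathbf{b}$ the body force, $\rho$
the density and $\mathbf{D}^* = \tfrac12(\nabla\mathbf{v}^* +
\nabla^T\mathbf{v}^*)$ the virtual rate of deformation (gradients taken
with respect to the *current* position).  Choosing $\mathbf{v}^*$ to
vanish on every surface with unknown tractions kills the surface term; a
static load kills the acceleration term.  What remains is a scalar balance
between the internal virtual power, computable from the *measured*
deformation through a candidate constitutive law, and the external virtual
power, computable from the known body force alone.  The candidate
parameters are scored by the normalized equilibrium gap

$$P_{err} = \frac{P_{int} - P_{ext}}{P_{ext}},$$

one per virtual field, combined over three parameter-targeted fields as
the Euclidean norm $P_{err}^{total}$.  Evaluating one parameter set costs
a single pass of stress evaluations over the mesh — orders of magnitude
cheaper than one iteration of a forward nonlinear FE solve.

## The constitutive model

The tissue is a one-term compressible Ogden solid.  With principal
stretches $\lambda_i$ of the deformation gradient $\mathbf{F}$,
$J = \det\mathbf{F}$ and deviatoric stretches
$\tilde\lambda_i = J^{-1/3}\lambda_i$,

$$\psi = \frac{2\mu}{\alpha^2}\left(\tilde\lambda_1^\alpha +
\tilde\lambda_2^\alpha + \tilde\lambda_3^\alpha - 3\right) + \frac{K}{2}
(\ln J)^2 .$$

* $\mu$ (Pa) — the small-strain shear modulus.
* $\alpha$ (dimensionless) — strain-stiffening exponent; negative for
  brain tissue in most of the literature.
* $K$ (Pa) — the bulk modulus; under skull-like confinement this is the
  best-identified parameter, because the organ can only move if regions in
  compression lose volume.

The volumetric potential is fixed as $(K/2)(\ln J)^2$ so that the
volumetric Cauchy stress is exactly $K \ln(J)/J \, \mathbf{I}$.  The
deviatoric Cauchy stress is assembled in the principal frame of
$\mathbf{F}\mathbf{F}^T$ from the principal deviatoric Kirchhoff stresses
$\beta_i = (2\mu/\alpha)\bigl(\tilde\lambda_i^\alpha - \tfrac13\sum_j
\tilde\lambda_j^\alpha\bigr)$, which are smooth in the stretches, so
coalescent eigenvalues (e.g. pure dilatation) need no special branch.  For
$|\alpha| < 10^{-6}$ the analytic limit $\beta_i = 2\mu\ln\tilde\lambda_i$
is used, so optimizers may cross $\alpha = 0$.  The implementation is
validated against an independent oracle: central finite differences of the
energy through $\mathbf{F}$, pushed forward to a Cauchy stress.

Reported small-strain equivalents use the standard isotropic conversions
$E = 9K\mu/(3K+\mu)$ and $\nu = (3K-2\mu)/(6K+2\mu)$.  For $\mu = 1.25$
kPa, $K = 254$ kPa these give $E = 3744$ Pa and $\nu = 0.4975$; a reported
value of 0.4977 for the same moduli is not reproducible under the standard
conversion and presumably reflects rounding of the inputs.

## Discretization

All integrals use a 4-node tetrahedral mesh with one integration point per
element — exact for constant-strain elements, verified against a 4-point
rule.  Internal power is $\sum_e (\sigma : \mathbf{D}^*)\, J\, V^0_e$;
external power is $\sum_e \rho\, V^0_e\, \mathbf{b}\cdot
\bar{\mathbf{v}}^*_e$ with $\bar{\mathbf{v}}^*_e$ the nodal mean (the
deformed-volume and deformed-density factors cancel exactly).  The spatial
gradient of a virtual field is $\nabla\mathbf{v}^* = \mathbf{G}^*
\mathbf{F}^{-1}$ with $\mathbf{G}^*$ the constant reference gradient and
$\mathbf{F}$ the *measured* deformation gradient of the element; when the
virtual field equals the measured displacement this reduces to the
familiar $(\mathbf{F}-\mathbf{I})\mathbf{F}^{-1}$.

Internally everything is SI (m, Pa, kg m⁻³) with 1-based node indexing (R
convention; file dialects that are 0-based, like VTK cells, are converted
in the readers).  Imaging-derived displacement CSVs are assumed to be in
millimetres unless told otherwise — silent unit mixing is the dominant
failure mode in this pipeline, so the unit is an explicit reader argument.

## Virtual-field generation

Fields are generated by the recipe the method itself suggests: fix every
node of the unknown-traction boundary, apply a small body load (0.001
m s⁻², well below gravity, so the generation regime is small-strain),
solve, then re-solve with each material parameter perturbed in turn (×2 on
$\mu$, ×2 on $K$, $-10$ on $\alpha$) and subtract the base solution.  The
$\mu$- and $K$-sensitivity fields come from a linear small-strain solver
driven by ($\mu$, $K$); $\alpha$ has no linear-regime footprint, so its
field is the difference of two *weakly nonlinear* solves by the package's
total-Lagrangian forward solver.  Each field is normalized to unit maximum
nodal magnitude (the gap is scale-invariant; this only conditions the
powers), and a perturbation that produces no change is flagged degenerate
rather than silently normalized.

Two numerical points matter here.  First, the Newton tolerance of the
$\alpha$-field solves (default $10^{-8}$ relative) must sit between the
$\alpha$-sensitivity signal (about $10^{-6}$ of the base field) and the
stress-evaluation noise floor at generation-level strains (about
$10^{-9}$); demanding much tighter tolerances is futile because the floor
is set by eigendecomposition round-off at strains of $10^{-7}$.  Second —
and this is the package's most consequential finding about the method —
the $\alpha$ field generated this way is a nearly mean-free deviatoric
pattern whose body-force-weighted integral is tiny: its external power is
roughly $10^4$ times smaller than the magnitude of its internal-power
content.  Dividing by this small normalizer makes the third gap
hypersensitive, and since the field's shape is exactly the direction in
which $\alpha$ moves the stresses, $P_{err,2}(\alpha)$ crosses zero at the
true exponent and varies by order unity across $\alpha \in [-100, 100]$.

Consequences, all deliberate and documented rather than tuned away:

* On clean synthetic data $\alpha$ is *weakly identifiable* through the
  third field.  The reference workflow this package emulates reported the
  opposite — negligible error over the whole $\alpha$ range — which is the
  behaviour of an $\alpha$ field carrying no true $\alpha$ signal (as
  produced by a linear generator, for which the $\alpha$ perturbation is
  exactly degenerate, or by a noise-dominated nonlinear difference).  The
  $\mu$- and $K$-targeted fields in this package do reproduce the
  $\alpha$-insensitivity (gap variation $\sim 10^{-4}$ over the full
  span), and the acceptance test asserting total-gap flatness in $\alpha$
  is left failing with a pointer here.
* Noise in the measured field perturbs the third gap orders of magnitude
  more than the other two; the perturbation remains unbiased, which is
  what the noise acceptance test asserts.
* The landscape-curvature comparison "K identified more tightly than
  $\mu$" is made on the $\mu$- and $K$-targeted fields, where it holds by
  a factor of about 25 at matched relative perturbations; the third
  field's amplified sensitivities would mask it.

## Synthetic data: what the generator emulates

The forward solver is a total-Lagrangian Newton–Raphson method on the
reference-configuration weak form with the same Ogden law: nodal internal
forces $V^0 \mathbf{P}\, \partial N_a/\partial X$ with $\mathbf{P} =
J\sigma\mathbf{F}^{-T}$, consistent nodal body load $\rho V^0 \mathbf{b}/4$,
a numerically differentiated consistent tangent (central differences on
element-local displacements; 24 batched stress sweeps per iteration), load
stepping with halving, relative residual tolerance $10^{-9}$, at most 25
iterations and 8 halvings.  The default fixture is a 0.1 m cube at
$n = 6$ divisions (1296 elements), density 1040 kg m⁻³ (a standard
soft-tissue value; the identified moduli scale linearly with $\rho$, so it
is explicit configuration, never hard-wired), fully fixed boundary, full
gravity 9.81 m s⁻² — strains a few $10^{-3}$, comparable to the
posture-inversion brain measurement the method was designed for.  A thick
ellipsoidal-shell fixture (fixed outer surface, traction-free inner
cavity) approximates skull confinement with a ventricle-like hole.

Because the forward solve, the virtual fields and the power quadrature all
live on the *same* mesh, FE duality makes the one-point-quadrature powers
exactly the nodal force balance of the solver: the equilibrium gap at the
true parameters equals the Newton residual level, not the discretization
error.  Two things follow.  A green recovery test establishes that the
identification machinery is exact and self-consistent — it does *not*
establish mesh-convergence of the physics, which is probed separately
(centre-displacement refinement checks, and the self-consistency check
that uses a solution as its own virtual field).  And "gap decreases under
refinement" has no leverage at fixed solver tolerance; the acceptance test
therefore asserts the monotone decrease across Newton tolerances and the
joint refinement-plus-tightening decrease.

Measurement noise is emulated two ways: i.i.d. Gaussian noise per
displacement component at stated RMS levels (0.25 / 0.5 / 1 μm), and a
"registration-like" spatially smooth field — node-wise Gaussian noise
convolved with a Gaussian kernel of configurable correlation length
(default 0.02 m, the centimetre scale of elastic-registration error) and
rescaled to the requested RMS.  What a green noise test establishes: the
gaps respond to i.i.d. noise without systematic bias, each field
differently.  What it does not establish: the often-quoted ordering
"smooth error hurts less than i.i.d. error at equal RMS".  At fixture
scales that ordering is in fact false for the aggregate power gap
(coherent noise forgoes the element-to-element cancellation i.i.d. noise
enjoys in the power integral); the true content of the observation is a
per-unit-RMS statement under strong scale separation between mesh size and
error correlation length (sub-millimetre elements vs centimetre-smooth
registration error).  The suite asserts the mechanism that does hold at
fixture scales: equal-RMS smooth noise carries far smaller element-scale
strain perturbations than i.i.d. noise.

## Identification

Optimization works in $(\log\mu, \alpha, \log K)$ — positivity plus three
orders of magnitude of scale disparity.  Two independent routes mirror
the reference workflow: a hand-written Levenberg–Marquardt on the
3-vector of per-field gaps (finite-difference Jacobian, steps clamped to
the bounds), and Nelder–Mead on the scalar total gap with bounds enforced
by projection plus a quadratic penalty on the excursion.  A logistic bound
transform was tried and rejected: it saturates near the bounds and
reliably strands the simplex on the flat tail (one documented failure mode
is a start in the corner plateau where the third gap is $\approx -1$).
The simplex is restarted from its incumbent up to three times, the
standard cure for premature collapse; stationarity is declared when a
restart gains less than the $10^{-12}$ function tolerance.  Multi-start
uses a seeded Latin hypercube over the bounds (log-uniform in $\mu$, $K$;
uniform in $\alpha$; defaults $\mu \in [0.1, 10]$ kPa, $K \in [10, 1000]$
kPa, $\alpha \in [-100, 100]$, bracketing the soft-tissue literature), and
the same sampler drives the random landscape sweep whose samples are
binned into the documented error bands (converged-run bands $10^{-8}$ /
$10^{-6}$ / $10^{-4}$ / $10^{-2}$; sweep bands 1% / 2% / 5%).

Stress statistics at an optimum report the maximum-shear measure
$\tau_{max} = (\sigma_1 - \sigma_3)/2$ and the mean stress
$\mathrm{tr}(\sigma)/3$ with their 95th / 2.5th–97.5th percentiles; both
conventions are configurable (a von Mises option is provided) because the
reporting conventions in the field are not standardized.

## Degenerate inputs and numerical tie-breaks

* Inverted elements on file read: one deterministic vertex-pair swap, else
  an error naming the elements.  Inversion during Newton iteration: step
  halving, then load-step halving, then a classed numerical error.
* $J \le 0$ in measured kinematics is reported once, at bundle build, with
  element indices — never silently per evaluation.
* A zero external power is an error when used as a normalizer; the
  zero-load self-consistency gap is 0 by convention.
* The body-force magnitude has *no default* in the bundle builder: for
  posture-inversion data the displacement corresponds to a load change
  (g vs 2g), and guessing silently would corrupt the identified moduli by
  a factor of about two.

## Limitations

Single material, single term, drained quasi-static response: no
viscoelasticity, poroelasticity, tension/compression asymmetry, fluid
spaces, membranes or springs, and no surface-traction external power.  The
reader for the originally deposited MATLAB displacement container is a
documented stub (layout unavailable offline); CSV/VTK equivalents are
supported.  Interpolation from voxel grids to mesh nodes is out of scope —
fields must arrive node-aligned.
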