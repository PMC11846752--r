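---
title: "Methods: bone remodelling around a repositioned implant and its POD-RBF surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bone remodelling around a repositioned implant and its POD-RBF surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`osteorom` predicts the converged bone-mass-density (BMD) field around a
rigid implant embedded in bone, as a function of the implant's pose, and
wraps the expensive finite-element prediction in a non-intrusive
reduced-order surrogate. The pipeline has three layers:

1. **mesh morphing** — a fixed-connectivity reference mesh is deformed to a
   new implant pose by a harmonic extension of the boundary motion;
2. **high-fidelity remodelling** — a quasi-static, strain-energy-driven,
   gradient-enhanced bone-adaptation solver produces the converged nodal
   BMD field on each morphed mesh;
3. **POD-RBF surrogate** — converged fields at sampled poses form a
   snapshot matrix; proper orthogonal decomposition (POD) extracts
   dominant spatial modes, and radial basis function (RBF) interpolation
   of the reduced coordinates maps any new pose to a full field in
   milliseconds.

Patient-specific femur geometry is outside the package's scope. The
reference domain is a synthetic desk-scale analogue: a rectangular (2D) or
box-shaped (3D) bone domain with an embedded, stiffer, axis-aligned
implant inclusion that can be rigidly translated and rotated within
configured bounds. All methods are dimension-agnostic; the 2D triangle
path is the primary configuration and the tetrahedral path shares every
code path on a coarse box fixture.

# Mesh morphing by Laplace's equation

The implant pose is $\mu = (\delta_x, \delta_y, \gamma)$ in 2D
(translations in mm, rotation in degrees), or the six-parameter analogue
in 3D. Three node sets partition the mesh: the fixed outer boundary
$\Omega_1$, the implant plus a one-element-deep interface ring $\Omega_2$
(the ring plays the role of the resection-interface nodes, carried along
rigidly so the transition stays smooth), and the interior $\Omega$.

$\Omega_2$ nodes move rigidly, $x|_{\Omega_2} = T(\mu)\,(p, q, 1)^T$, with
the homogeneous transform composed as $T = R_x R_y R_z D$ (translation
applied first, then the axis rotations). The rotation centre is **not**
part of the transform definition and had to be fixed by convention: we
conjugate $T$ with the translation to the $\Omega_2$ centroid, so small
rotations produce small displacements. With the centre at the origin the
plain composition is recovered.

Every other coordinate solves the Laplace equation componentwise with
$\Omega_1 \cup \Omega_2$ as Dirichlet data. Discretised with P1 elements
and partitioned by node set, static condensation gives

$$x_3(\mu) = -K_{33}^{-1} K_{31}\, p_{\Omega_1} \; - \; K_{33}^{-1} K_{32}\, H^T T^T(\mu),$$

where $H$ stacks the homogeneous reference coordinates of $\Omega_2$. The
package factorises $K_{33}$ once (sparse Cholesky) and precomputes both
products, so a new pose costs two small dense matrix-vector products per
coordinate direction. Harmonicity implies a discrete maximum principle on
the structured (non-obtuse) triangulation, and the interior residual of
the full system is checked to be at solver precision for every morph.

After morphing, element quality is checked against the reference volumes
(`tol` = 0.01 of the reference volume by default; no established value
exists, and 1% keeps the elasticity assembly well conditioned). Inverted
elements are repaired by swapping their last two node indices — a
transposition flips orientation without moving nodes. Two failure modes
remain fatal by design: elements still below tolerance after repair, and
global fold-over, detected by comparing the unsigned volume sum with the
domain volume (signed sums telescope and cannot detect overlap).

# The remodelling model

Isotropic linear elasticity with a density-dependent stiffness
$E = E_0 (\varrho / \varrho_0)^2$ gives the stress
$\sigma = (\varrho/\varrho_0)^2\, \mathbb{C}^{LE} : \varepsilon$ and the
strain-energy density

$$\Psi(\varrho, \varepsilon) = \left(\frac{\varrho}{\varrho_0}\right)^2
  \left[\frac{\lambda}{2}\,\mathrm{tr}(\varepsilon)^2
  + \mu\,\mathrm{tr}(\varepsilon^2)\right].$$

Bone adapts by the first-order source $\dot\varrho = c\,(\Psi -
\Psi_{\mathrm{ref}})$, clamped to physiological limits
$[\varrho_{\min}, \varrho_{\max}]$. Defaults ( `material_params()` ):
$E_0 = 6500$ N/mm², $\nu = 0.3$, $\varrho_0 = 1$ g/cm³,
$\Psi_{\mathrm{ref}} = 0.002$ N/mm², $c = 0.01$,
$\varrho \in [0.001, 2]$ g/cm³; the implant is titanium
($E = 105000$ N/mm², $\nu = 0.3$), linear elastic, and never remodels.
Units are the mixed mm-N-(g/cm³) convention; unit bookkeeping is by
convention, not conversion, with one deliberate exception discussed below.

To suppress mesh-scale checkerboarding, the density is coupled to a
smooth nodal field $\phi$ through the enhancement energy
$\frac{\alpha_{GE}}{2}(\phi-\varrho)^2 +
\frac{\beta_{GE}}{2}|\nabla\phi|^2$. Stationarity in $\phi$ yields the
screened L2 projection
$(M + \frac{\beta_{GE}}{\alpha_{GE}} K)\,\phi = M \varrho$-projection,
assembled over the bone subdomain with consistent P1 mass and Laplace
matrices. With $\beta_{GE} = 0$ the plain L2 projection is recovered
exactly.

**Unit choice for the enhancement ratio.** $\alpha_{GE}$ and $\beta_{GE}$
are tabulated in SI units, so their ratio $10^{-6}$ is a squared length in
m². Read naively in the mesh's mm units this would give a screening
length of $10^{-3}$ mm — three orders of magnitude below the element size,
making the enhancement numerically inert (we verified that fields then
checkerboard into bang-bang patterns). The physically consistent reading
converts the ratio to mm² (factor $10^6$), i.e. a screening length of
1 mm, which is the scale at which the enhancement meaningfully filters the
element-level density. The package hard-codes this conversion in the
projection operator and keeps the tabulated parameter values themselves
untouched.

## Time stepping, stability and the convergence criterion

The coupled problem is staggered per step: (i) mechanical equilibrium at
frozen density — the problem is linear there, so the Newton iteration is
asserted to converge in one step against an 1e-8 residual tolerance;
(ii) screened projection $\varrho \to \phi$; (iii) implicit Euler density
update $\varrho^{(i+1)} = \varrho^{(i)} + \Delta t\,c\,(\Psi(\varepsilon^{(i+1)},
\phi^{(i+1)}) - \Psi_{\mathrm{ref}})$, with $\Psi$ evaluated from the new
strain and the enhanced density interpolated to the element integration
point, then clamped to the physiological limits.

Linearising the update around the interior equilibrium of a
load-controlled state gives a contraction factor
$1 - \Delta t\,c\,|\partial\Psi/\partial\varrho| \approx 1 - 6\cdot10^{-5}
\Delta t$ per step, and a stability bound
$\Delta t\,c\,|\partial\Psi/\partial\varrho| < 2$, i.e.
$\Delta t \lesssim 3\cdot10^4$. The default $\Delta t = 500$ sits two
orders inside the bound and reaches engineering convergence within a few
hundred steps; a much smaller step would need tens of thousands of steps
for the same accuracy without being more stable.

**Why the default tolerance is an engineering one.** The per-volume
strain-energy stimulus with $E \propto \varrho^2$ is locally stable under
load control ($\Psi \propto \varrho^{-2}$ at fixed stress) but unstable
against transverse redistribution: of two parallel load paths sharing a
displacement, the denser one attracts more energy and densifies further.
This is the classical behaviour of this model family — fields segregate
towards patchwork structures of $\varrho_{\min}$ and $\varrho_{\max}$ with
slowly creeping interfaces, which is also the caricature of real
cortical/trabecular organisation. The gradient enhancement removes the
mesh-scale modes but long-wavelength segregation persists, so the density
field cannot converge to arbitrarily tight tolerances on generic domains.
The default stopping rule is therefore a relative L2 change of the nodal
field below `1e-3` per step (`remodelling_config()`), which the campaign
runs meet within ~150-300 steps; analytic fixtures such as the
homogeneous bar are free of the instability and converge to `1e-6` and
beyond when asked. Runs that exhaust `max_steps` return their final state
with an explicit warning.

A fixture worth noting: for a *confined homogeneous bar*, the closed-form
interior equilibrium
$\varrho^\ast = \varrho_0\sqrt{\Psi_{\mathrm{ref}} / \Psi^{LE}(\varepsilon^\ast)}
= 0.676123$ g/cm³ at $\varepsilon^\ast = 10^{-3}$ is an **attractor under
load control** (end traction $\sigma = 4$ N/mm², for which
$\varepsilon = 10^{-3}$ holds exactly at equilibrium) but a **repeller
under displacement control** (at fixed strain $\Psi \propto \varrho^2$, so
any deviation grows until a bound). The package's equilibrium test drives
the bar by traction; the displacement-controlled bar is exercised as a
fixed-point test started at $\varrho^\ast$.

# Study conditions of the synthetic campaign

The generator's defaults define the study conditions; they were chosen
once, for physical reasons, and are not tuned per experiment:

* **Domain** — 10 × 10 mm plate, 2 × 4 mm implant at the centre, element
  size 1/3 mm (≈ 1800 triangles, ≈ 2000 dof), pose bounds ±1 mm and ±1°.
  The implant clearance must exceed the largest admissible translation;
  this is validated at construction.
* **Load case** (`plate_load_case()`) — bottom boundary clamped, lateral
  boundaries on vertical rollers (the continuation of the cortical shaft:
  load cannot escape sideways), 4 N/mm² compression on the top boundary
  standing in for the joint load. All constrained facets lie on the fixed
  outer boundary, so the identical load case transfers unchanged to every
  morphed mesh.
* **Initial BMD** (`initial_density_field()`) — the closed-form interior
  equilibrium of the confined column under that traction
  (0.676 g/cm³), modulated by ±5% sinusoidally across the domain. This
  mirrors initialising patient-specific simulations from a
  biomechanically equilibrated measured BMD: the adaptation signal is then
  dominated by the implant, and the campaign fields respond smoothly to
  pose changes. Because the field is closed-form in position, evaluating
  it at morphed element centroids plays the role of projecting the
  initial BMD onto each morphed mesh.

What the generator deliberately does **not** emulate: real femur geometry
and cortical shells, CT-derived density maps, muscle-force systems,
press-fit contact mechanics, and anisotropy. Passing tests therefore
demonstrate the correctness and internal consistency of the morphing,
remodelling and reduction machinery under controlled conditions — not
clinical validity on real anatomy.

# The reduced-order model

Snapshots are the final enhanced nodal fields $\phi$ restricted to the
bone-supported nodes, collected as columns of $S$ alongside the pose
matrix $P$ (columns never reordered independently). A thin SVD
$S = U \Sigma Z^T$ yields the POD basis; the retained count $n$ is the
smallest for which the captured energy $\sum_{i\le n}\varsigma_i^2 /
\sum_i \varsigma_i^2$ *strictly* exceeds $\kappa$ (default 0.9999). The
truncation error is the relative tail energy
$\epsilon(n) = (\sum_{i>n}\varsigma_i^2 / \sum_i \varsigma_i^2)^{1/2}$,
which equals the relative Frobenius reconstruction error; captured energy
and $\epsilon(n)^2$ sum to one. No snapshot centring is applied, and mode
signs are fixed so each mode's largest-magnitude entry is positive,
making repeated decompositions bit-identical.

Reduced coordinates $S_r = V^T S$ are interpolated over the pose space
with RBFs. Poses are min-max normalised to $[0,1]^{n_p}$ from the
training bounds (the normalisation scheme is a package decision; z-score
would equally remove the mm-vs-degree scale disparity, min-max was chosen
for its exact invertibility on the bounds), and distances are Euclidean
in the normalised space. Six kernel families are provided (Gaussian,
multiquadric, inverse multiquadric, Matérn C0/C2/C4). The plain system
$A = S_r B^{-1}$ is solved by direct factorisation without
regularisation; ill-conditioning is surfaced as a warning via a
reciprocal-condition estimate rather than masked by jitter. The augmented
system appends a degree-1 polynomial tail with the $n_p{+}1$ side
conditions that the kernel coefficients be orthogonal to the polynomials,
which makes the conditionally positive definite multiquadric well posed
and buys exact affine reproduction for every family. The pipeline default
is the augmented Matérn C0 with shape parameter $a = 10^{-4}$; a
`shape_parameter_sweep()` over families, shape grid and augmentation is
available and selects the holdout-MAE argmin with ties broken towards the
smaller (flatter) shape parameter.

Training poses come from an equidistant tensor grid (3 points per active
dimension, endpoints included; a dimension with a single point is frozen
at its midpoint and excluded from interpolation). Holdout poses are
seeded uniform draws. Parameters that are frozen in the plan are recorded
in the model; predictions that deviate in a frozen parameter warn.

The online stage is non-intrusive by interface: `online_predict()` uses
only the basis, the interpolant and the pose — no assembled operator, no
solver. Accuracy is quantified by the mean absolute error
$e = \frac{1}{n}\sum_i |\phi_i - \tilde\phi_i|$ per pose, its mean over a
holdout set, and region-wise over a Gruen-zone-style partition
(`define_regions()`: medial/lateral split around the implant centre, cut
into equal-count bands along the implant's long axis — a testable
stand-in for the anatomical zones).

# Problem sizes and numerical choices

The shipped configuration uses: ≈1800-element meshes for campaign runs
(9 training runs for the 3×3 grid, 25 for the 5×5 refinement check,
10-pose holdouts); a 160-element bar for the equilibrium oracle; coarse
(≤200-node) meshes wherever a dense oracle (full Laplace solve, dense L2
projection) backs the sparse path; and a 1296-tet box for the 3D path.
Sparse operators are assembled from precomputed triplets, with the
elasticity pattern rescaled per step by the element density factor, and
the screened-projection operator factorised once per mesh.

Degenerate inputs are rejected rather than repaired silently: empty
interior or implant node sets, duplicate training poses after
normalisation, degenerate (constant) parameter dimensions, densities
outside the physiological bounds, Dirichlet data insufficient to remove
rigid-body modes. Ties in Spearman ranks use average ranks; constant
inputs return a flagged `NA`, never a silent zero.

# Known limitations

* The transverse remodelling instability bounds the achievable field
  convergence on generic domains; the engineering tolerance and the
  near-equilibrium initial state manage, but do not remove, it.
* The enhancement-ratio unit conversion (m² to mm²) is a modelling
  judgement; with the naive reading the enhancement is inert.
* Laplacian morphing degrades for pose excursions comparable to the
  implant clearance; fold-over is detected and reported, not prevented.
* The synthetic domain is a structured mesh; unstructured-mesh import is
  supported through the VTK reader but not exercised by the shipped
  campaigns.
* Loads are applied on the fixed outer boundary; implant-borne loading
  (a joint force following the stem) would require transferring tractions
  to morphed interior facets, which the load-case layer does not do.
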