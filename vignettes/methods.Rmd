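---
title: "Modeling TTFields dose and gel heating in voxel head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TTFields dose and gel heating in voxel head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tumor treating fields (TTFields) deliver 200 kHz alternating electric
fields to a glioblastoma through two transducer arrays glued to the scalp
with hydrogel pads. Two quantities govern therapy: the field magnitude in
the tumor (in vitro, proliferation is inhibited above roughly 1.0 V/cm,
with maximal effect near 2.5 V/cm) and the Joule heating of the gel pads,
because the device lowers its drive voltage whenever a transducer
approaches the 41 degC skin-safety limit. A craniectomy changes both: the
skull is by far the most resistive layer, so removing a bone flap opens a
low-impedance window that raises the tumor dose - and the gel heating.
This package simulates that trade-off in synthetic voxel head phantoms:
the intact skull, a skull with a circular defect refilled with scalp
tissue, and the defect plus a thin insulating film between transducer and
gel, compared through a power-normalized field statistic.

## Model

### Electro-quasistatics

At 200 kHz, wave propagation and induction are negligible on the scale of
a head, so the complex potential satisfies the volume-conductor equation

$$\nabla \cdot \big( (\sigma + i\,\omega \varepsilon_0 \varepsilon_r)\,
\nabla \varphi \big) = 0,$$

with per-tissue conductivity $\sigma$ (S/m) and relative permittivity
$\varepsilon_r$. The complex coefficient
$\kappa = \sigma + i \omega \varepsilon_0 \varepsilon_r$ is the
*admittivity*; `admittivity()` evaluates it from the packaged property
table, with $\varepsilon_0$ fixed at $8.8541878128 \times 10^{-12}$ F/m so
closed-form checks reproduce bit-identical values. Boundary conditions
follow clinical operation: 80 V on the outer faces of the active array's
electrodes, 0 V on the opposite array, zero normal current elsewhere. The
electrode ceramic itself is a lossless dielectric ($\sigma = 0$,
$\varepsilon_r = 16000$), so current enters tissue capacitively, and all
nine transducers of an array share one potential (current is controlled
per array, not per transducer).

Derived fields: $\mathbf{E} = -\nabla\varphi$ (phasor amplitude
$|\mathbf{E}| = \sqrt{\sum_c |E_c|^2}$, reported in V/cm),
$\mathbf{J} = \kappa \mathbf{E}$, and the Joule heating
$Q = \tfrac12 \mathrm{Re}(\mathbf{J}\cdot\mathbf{E}^*)$ in W/m^3^.

### Dose and thermogenesis metrics

* `tissue_field_stats()`: volume-weighted mean and max $|\mathbf{E}|$ per
  tissue; "brain" is the union of gray matter, white matter and CSF.
* `atv()`: the above-threshold volume, the percentage of tumor-shell
  voxels with $|\mathbf{E}|$ at or above a threshold (inclusive
  comparison; the boundary set has zero measure in the continuum, so the
  convention only needs to be fixed and documented). Defaults: 1.0 and
  2.5 V/cm.
* `gel_power_stats()`: per-pad max/mean volumetric heating and integrated
  power; the case statistic `W_max` is the maximum over pads of the
  pad-wise maximum $Q$ (ties resolve to the lowest pad id).
* `normalized_field_strength()`: because the device would throttle the
  hottest pad to the same temperature in every case,
  $E_{\mathrm{norm}} = E_2 \sqrt{W_1 / W_2}$ rescales a case's mean
  tumor-shell field ($E_2$) by the intact-case-to-case ratio of maximum
  pad heating ($W_1$ intact, $W_2$ evaluated case). With $E_2$ expressed
  relative to the intact baseline the statistic is a percentage of that
  baseline, 100% for the intact case by construction.

## The synthetic phantom: what it emulates and what it does not

Real studies segment patient MRIs into scalp, skull, CSF, gray and white
matter plus a two-compartment tumor. The generator replaces that with
concentric spheres (outer radii 92 / 85 / 78 / 75 / 60 mm for
scalp / skull / CSF / GM / WM; human-scale 7 mm scalp and skull, 3 mm
CSF), a spherical tumor with a low-conductivity enhancing shell around a
high-conductivity necrotic core, an optional cylindrical craniectomy
window (default 50 mm diameter, surgeon-sized in practice) refilled with
scalp tissue, and two opposed 3x3 arrays whose gel discs (12.5 mm radius,
1 mm thick) and electrode cylinders (10 mm radius, 1 mm high) conform to
the curved scalp. The 30 mm center-to-center pitch is the smallest
spacing that keeps neighboring gel discs from merging, comparable to the
clinical array. Two tumor fixtures ship: *superficial* (center 55 mm from
the head center, under the array) and *deep* (15 mm), emulating the
frontal/temporal versus insular/brainstem contrast.

A green test on these phantoms establishes that the solver and metrics
are correct and that the qualitative physics (skull shunting, window
re-routing, gel edge heating) behaves as in the published head models. It
does *not* establish quantitative agreement with any patient anatomy:
there is no cortical folding, no ventricles or air sinuses, the layers
are perfect shells, and one idealization has visible consequences - the
50 mm window in a perfect spherical insulator carries a much larger share
of the total current than in a realistic head, so the whole-brain mean
field rises ~15% with the defect (the published models report little
change), the defect-side corner pads *lose* peak heating as current
re-routes into the window, and the superficial fixture's intact-case
ATV(1.0) starts at 97%, leaving no room for the large ATV gains the
low-baseline published models show. The corresponding acceptance
assertions are left red deliberately; loosening them would hide a real
property of the idealization.

## Numerics

* **Discretization.** Cell-centered finite volumes on the uniform voxel
  grid; the face conductance between two cells is the harmonic mean of
  their admittivities times face area over center distance - exact for
  layered 1-D profiles. Interior rows conserve current exactly and the
  matrix is complex symmetric.
* **Boundary conditions.** Dirichlet is imposed on the outermost
  electrode faces through half-cell conductances; every other outer face
  is zero-flux. A per-transducer contact-impedance film (thickness $d$,
  admittivity $\kappa_f$) replaces the transducer-gel face conductance by
  the series combination with surface admittance $Y = \kappa_f / d$ -
  meshing a 1 um film explicitly would force sub-micrometer voxels.
* **Linear solve.** Sparse LU on the real-split system below 30k unknowns
  (a 3-D direct factorization beyond that exceeds desk-scale memory);
  conjugate-orthogonal CG (COCG, the complex-symmetric analogue of CG)
  with an SSOR preconditioner above, to a relative residual of 1e-8.
  Pure-Neumann validation systems (cap current injection) are compatible
  by construction and solved up to a constant, which is removed.
* **Field reconstruction.** $\mathbf{J}$ is rebuilt from face currents
  (per-cell mean of the two face current densities per axis) and
  $\mathbf{E} = \mathbf{J}/\kappa$. Naive central differencing of
  $\varphi$ across a conductivity jump mixes the two layer fields and
  overshoots $Q$ by up to the squared conductivity ratio at interface
  cells; the flux-consistent reconstruction is exact for layered slabs. A
  `central` method is retained for comparison.
* **Two Joule-heating estimators.** The pointwise map
  $\tfrac12\mathrm{Re}(\mathbf{J}\cdot\mathbf{E}^*)$ satisfies the
  algebraic identity $\tfrac12\sigma|\mathbf{E}|^2$ voxel by voxel but
  loses ~10% of the global power on one-voxel-thin layers. The default
  *conservative* map attributes each face's exact discrete dissipation
  $\tfrac12|I|^2\mathrm{Re}(z)$ to its two half-links
  ($z = (h/2)/(\kappa A)$ per side), which reduces to
  $\tfrac12\sigma|\mathbf{E}|^2$ in uniform regions, keeps $Q \ge 0$ and
  $Q = 0$ where $\sigma = 0$, and balances the electrode input power to
  solver precision on every fixture - the property the power-balance gate
  checks.
* **Validation oracles.** A layered-slab closed form (series impedance)
  and an N-layer concentric-sphere Legendre series driven by opposed
  polar-cap current injection (the caps avoid the point-source
  singularity; only odd degrees survive by symmetry; truncation at
  L = 60 leaves < 1e-10 in the interior). The sphere gate runs at DC with
  the scalp/skull/gray-matter conductivities on the head phantom's own
  layer radii. For this analytically known geometry the assembler splits
  face links at the exact interface radii (series conductance of the two
  segments), removing the oscillating shell-quantization bias of
  nearest-center labeling so that refinement converges monotonically:
  8.2% / 5.1% / 3.8% / 2.5% relative L2 over the inner sphere at
  3 / 2 / 1.5 / 1 mm. The residual first-order bias at 2 mm (5.1% vs the
  5% gate) is the staircase representation of the 7 mm skull shell plus
  the staircase outer boundary; the series itself was cross-checked
  against an independent axisymmetric finite-difference solution
  (< 1% disagreement).
* **Degenerate inputs.** DC with a zero-conductivity electrode has no
  conductive or capacitive path and is rejected at assembly; a
  non-positive defect diameter is a warned no-op; tumors reaching outside
  the brain compartment and non-nested layer radii are configuration
  errors; iterative non-convergence raises an error carrying the achieved
  residual.

## Design choices where the design was genuinely open

* The working frequency may be 0: the physical device runs at 200 kHz,
  but the analytic accuracy gates run in the DC (Laplace) limit, so
  `frequency_spec(0)` is allowed and documented as that limit.
* `W_max` is implemented as the maximum over gel pads of the pad-wise
  maximum volumetric heating, with pad-wise means and integrated powers
  also reported, keeping both readings of "maximum heating power"
  available.
* The insulated case applies the film to all nine defect-side
  transducers by default; per-transducer flags allow partial patterns.
* One array pair is simulated per run (chosen by montage): the skull
  defect only affects the pair it touches.
* Phantom voxelization is deterministic; optional transducer-center
  jitter activates only when a seed is supplied.

## Known limitations

* Isotropic conductivities only; no anisotropy or field-correlation
  effects.
* No temperature prediction: heating power is the thermogenesis proxy;
  the 41 degC regulation loop is represented only through the
  power-normalized field statistic.
* Voxel (staircase) geometry: first-order boundary errors; the sphere
  gate quantifies them against the series oracle.
* The concentric-sphere head is an idealization; see the fixture section
  for the three directional claims of the published study it does not
  reproduce and why.
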