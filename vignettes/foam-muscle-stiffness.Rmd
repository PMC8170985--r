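---
title: "Modeling muscle-tissue stiffness with a compressible foam material: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling muscle-tissue stiffness with a compressible foam material}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foamfem)
```

## The problem

Crash-safety human body models represent muscle and adipose tissue as
volumetric solid elements with a hyperelastic foam material whose input is
an engineering stress–strain load curve. Because isometric contraction
stiffens muscle severalfold, a common device is to scale the ordinate of
that curve by a factor (SFO) and treat SFO in {0.5, 1, 2, 10} as a family
of contraction states, plus a strain-rate-dependent variant defined by a
table of curves keyed by strain rate. `foamfem` provides the full desk-
scale pipeline for this kind of study: the constitutive model, a minimal
explicit solver to exercise it, and the strain- and force-based injury
post-processing used to compare stiffness states.

## The material model

The strain energy per reference volume is an Ogden-type compressible foam
("Hill functional" in the solver literature — unrelated to 1D Hill-type
contractile elements):

$$\Psi(\lambda_1,\lambda_2,\lambda_3)
  = \sum_{j=1}^m \frac{C_j}{b_j}\Big[\lambda_1^{b_j}+\lambda_2^{b_j}
  +\lambda_3^{b_j}-3+\tfrac1n\big(J^{-n b_j}-1\big)\Big], \qquad
  J=\lambda_1\lambda_2\lambda_3 .$$

Principal Cauchy stresses follow as
$\sigma_a = J^{-1}\lambda_a\,\partial\Psi/\partial\lambda_a
 = J^{-1}\sum_j C_j(\lambda_a^{b_j}-J^{-n b_j})$
and the tensor is assembled spectrally, $\boldsymbol\sigma=\sum_a \sigma_a\,
\mathbf n_a\otimes\mathbf n_a$.

**Assumptions.** Isotropy; hyperelasticity (no viscous branch — rate
effects enter only through the curve table); compressibility controlled by
a single Poisson ratio; passive response only (no active contraction
model — SFO scaling is the proxy).

**Penalty-exponent convention.** Solver documentation disagrees on the
sign of the relation between the penalty exponent and the Poisson ratio.
We default to `standard`, $n=\nu/(1-2\nu)$, because it reproduces the
physically expected lateral contraction $\lambda_\text{lat}
=\lambda^{-\nu}$ under uniaxial stress — a closed form that is exact for
*every* exponent set, because the zero-lateral-stress condition
annihilates each Ogden term separately. The printed variant
$n=\nu/(2\nu-1)$ is available as `convention = "paper"`; for
$0<\nu<0.5$ it yields lateral *expansion* under tension. At $\nu=0$ both
give $n=0$ and the penalty bracket is replaced by its analytic limit
$-b_j\ln J$.

**Curve-to-constants conversion.** How the reference solver turns the
input curve into stresses is not documented; we fit the coefficients
$C_j$ for a fixed exponent set by ordinary least squares against the
uniaxial closed form (linear in $C_j$), report the RMS residual, and
refuse fits worse than 5 % of peak stress unless overridden. Curves
without an origin sample are anchored at (0, 0). Exactly duplicated
exponents are rejected; a basis that is merely *numerically* collinear
(every term is linear at small strain) falls back to the pivoted
solution with dropped columns at zero, which preserves the fitted
tangent. The default basis is {1, 2, 4, −1, −2}; the shipped fixtures use
the even basis {2, 4, −2}, which is exact for their generating curve and
lets the solver evaluate the spectral sum as a polynomial in the left
Cauchy–Green tensor, avoiding a per-Gauss-point eigendecomposition.

**Rate tables.** Coefficients are prefitted at every tabulated rate; at
run time they are interpolated linearly in log(rate) and clamped outside
the table — equivalent to interpolating the curve ordinates themselves,
because the fit is linear in the ordinates. The lookup rate is the
element's effective-strain rate smoothed by an exponential moving average
(default time constant 0.1 ms) because raw per-cycle rates in explicit
dynamics are noise.

**Card fields.** Following the documented role of the keyword card, `KM`
feeds only the wave speed (time step) and contact stiffness; `MU` and
`SIGF` are parsed and stored with no constitutive effect.

## The explicit solver

Hex8 elements with trilinear shape functions and full 2x2x2 quadrature
(no hourglass control needed), row-sum lumped mass ($\rho V/8$ per node),
and central-difference integration with velocities on staggered half
steps. The critical step is $\Delta t = L/c$ with the conservative
characteristic length $L = V/A_\text{max face}$ and
$c=\sqrt{(K+4G/3)/\rho}$ from the card. Two step policies exist:

* `auto` — $\Delta t = s\,\min_e L_e/c_e$, re-scanned every 8 cycles on
  the current geometry (the safety factor $s$, default 0.9, covers the
  drift between scans);
* `dt2ms` — fixed step with selective mass scaling: any element whose
  critical step falls below target/$s$ has its density raised to
  $(\Delta t_\text{target}/(sL))^2(K+4G/3)$, never lowered, continuously
  during the run; added mass is reported absolutely and as a percentage
  of the unscaled total.

**Spatial frame for the stress.** The principal directions used to
assemble the Cauchy stress are those of the left stretch ($FF^\top$),
i.e. the material eigenvectors pushed forward by $F$ — the only choice
that keeps the assembled spatial tensor objective. Documentation that
cites eigenvectors of $C=F^\top F$ (a material-frame object) for the same
spatial formula is reinterpreted accordingly; no strict mode is provided.

**Contact.** Rigid planes with node-wise penalty forces proportional to
penetration depth. The penalty should be sized so that the contact
oscillator $\omega_c=\sqrt{k/m}$ satisfies $\Delta t\,\omega_c \lesssim
0.5$; the drop fixture uses $k = 0.03\,K\,A_\text{face}/L$ per node
(about 14 steps per contact period), which keeps the energy drift of an
impact under 1 %. Stiffer penalties remain stable up to
$\Delta t\,\omega_c < 2$ but degrade the audit.

**Energy audit.** Kinetic energy is reported with time-centered
velocities (the staggered half-step velocity would be first-order
inaccurate); internal and external work accumulate as trapezoidal
increments $\tfrac12(f_n+f_{n+1})\cdot\Delta u$ — the standard explicit-
solver bookkeeping. The balance error is
$E_\text{kin}+W_\text{int}+W_\text{damp}-W_\text{ext}-E_\text{kin,0}$;
the Ψ-based strain energy is reported alongside as a physical
cross-check. Runs abort with a classed error on non-finite forces or when
kinetic energy exceeds 10x the running reference energy, and terminate
early — keeping partial histories — on negative element volume, naming
the offending element.

## Post-processing and injury criteria

Effective stress is standard von Mises,
$\sqrt{((\sigma_1-\sigma_2)^2+(\sigma_1-\sigma_3)^2
+(\sigma_2-\sigma_3)^2)/2}$; a printed variant that omits the final
square is treated as a typographical slip, since the quantity is named
von Mises. Effective strain is $\sqrt{(2/3)\,\varepsilon:\varepsilon}$;
the strain tensor fed to it is the spatial logarithmic (Hencky) strain —
bounded, standard in crash post-processing, and with trace $\ln J$. The
reference material is hyperelastic, so solver-produced histories carry
zero plastic increments; accumulated effective plastic strain
$\int\sqrt{(2/3)\,d\varepsilon^p:d\varepsilon^p}$ is implemented for
externally supplied histories (bone post-processing) and returns zeros
with a notice otherwise.

Injury measures: failed-element volume accumulates each element's
reference volume from the first sample whose chosen strain field
*strictly* exceeds the threshold (default 1.5 % for bone fields);
exceedance is permanent by default ("accumulated over the entire
computation time"), with an instantaneous mode behind a flag. CSDM does
the same on effective strain at threshold 0.59 — the lower limit of the
reported muscle failure elongation 95 ± 36 % — grouped by tissue label
and body side from part metadata, reporting absolute volume and group
fraction. The Young's modulus of a stiffness state is the OLS slope of
effective stress vs effective strain over the contiguous window where
stress is at least 25 % of its peak ("timespan of highest loading");
the fraction is a parameter. Risk curves are user-supplied
(force, probability) points — published hip/knee parameters are not
shipped — interpolated linearly and clamped.

## Fixtures: what the synthetic world does and does not show

All fixtures use a synthetic stand-in material because the real tissue
curves belong to a licensed model: a single-term foam, $C=8$ kPa, $b=4$,
$\nu=0.3$ (tangent modulus ≈ 41.6 kPa, in the range of relaxed muscle),
density 1050 kg/m³, sampled to a 25-point convex curve on strains
0–0.6. The card bulk modulus is deliberately 25x the tangent modulus —
real tissue cards carry a near-incompressible bulk that governs the time
step — which also keeps SFO = 10 inside the explicit stability region.

* **cuboid8** — the 2x2x2 block of 1 mm elements, no loading, 50 ms,
  CFL-auto stepping. Card moduli are *fixed* across SFO (as in the source
  model), so the cycle count is constant across all material variants;
  displacements stay at machine zero.
* **uniaxial coupon** — one 1 mm element, both end faces ramped axially
  (smooth sine-squared onset, speed 5·10⁻⁴ of the mass-scaled wave
  speed), free lateral faces, near-critical mass damping. It runs under
  fixed-step mass scaling with a tiny nominal density, so the scaled
  density is *proportional to the card stiffness*, which the coupon ties
  to SFO: nodal trajectories are then identical across SFO and the
  stress response is an exact scalar family — the discrete analogue of
  the quasi-static statement that SFO multiplies the response.
* **drop block** — a 10 mm, 8-element block hitting a rigid plane at
  3 m/s; card moduli and contact penalty scale with SFO so both the CFL
  estimate and the contact-to-element frequency ratio track the true
  stiffness. Across SFO {0.5, 1, 2, 10} it reproduces the qualitative
  trends of the full-scale study — rising peak force and fitted modulus,
  falling peak strain and CSDM — as monotonicity, *not* as values.
* **synthetic histories** — seeded element histories with prescribed peak
  effective strains (uniaxial-incompressible tensors, so the metrics
  recover the peaks exactly) and optional plastic increments, for
  closed-form testing of the injury module.

A green test on these fixtures establishes internal consistency of the
machinery (constitutive law, integrator, bookkeeping, criteria) and the
direction of stiffness effects. It does **not** establish anatomical
fidelity, validated injury probabilities, or the full-scale study's
numeric strains and forces, which depend on a licensed geometry and a
commercial solver.

## Numerical choices and degenerate inputs

* Tolerances: constitutive gradient checks at 1e−6 relative; spectral
  round trips at 1e−10; curve refits at 1e−6.
* Repeated principal stretches: the spatial triad comes from
  $F N_a/\lambda_a$, orthonormal for any symmetric eigen-basis, so
  assembled stresses are basis-independent; hydrostatic states assemble
  to $p\,I$ for any triad.
* Lateral equilibrium by Newton from the analytic solution: the residual
  can have several roots for mixed-sign exponent sets and the physical
  branch is the one continuous with $\lambda^{-n/(1+2n)}$.
* Ties in peak-force extraction resolve to the earliest time; the
  stress-window fit requires ≥ 3 samples and nonzero strain variance.
* Decks: comma and fixed-width card dialects (fixed-width recognized by
  leading blanks); `$` comments skipped; unknown keywords preserved
  verbatim and logged, never dropped; dangling cross-references are named
  errors; negative `dt2ms` means "mass-scale to |value|", blank means
  CFL-auto. Default deck units mm–ms–kg (stresses GPa) converted to SI
  internally; `--units si` bypasses.
* Determinism: the solver uses no randomness; identical inputs give
  byte-identical history files. Seeds parameterize only the synthetic-
  history generator and are recorded in every manifest.

## Known limitations

Single-material-family solver (no shells, seatbelts, airbags, or
deformable–deformable contact); penalty contact only; mass-proportional
damping only; the rubber (incompressible) branch of the material and
tension–compression curve splitting are out of scope; shell "failed
volume" requires a thickness in the history metadata and excludes the
element (with a notice) otherwise; the energy audit treats prescribed-
motion work with a first-order approximation, so the 1 % audit claim is
made for unconstrained impacts.
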