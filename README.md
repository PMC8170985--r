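# foamfem

Desk-scale computational machinery for studying how the stiffness of
volumetric muscle and soft tissue changes impact response and predicted
injury in crash-type simulations. Occupant-safety studies model these
tissues with a hyperelastic, compressible, *simplified foam* material whose
input is an engineering stress–strain load curve; scaling the curve's
ordinate (the **SFO** factor) is used as a proxy for isometric contraction
states, from relaxed (SFO 0.5–1) through partly (SFO 2) to fully
contracted (SFO 10). `foamfem` re-implements that toolchain at a size that
runs on a laptop in seconds:

* **Material model.** An Ogden-type foam strain-energy functional in
  principal stretches,

  `Psi = sum_j (C_j / b_j) [ lambda_1^b_j + lambda_2^b_j + lambda_3^b_j - 3
         + (1/n)(J^(-n b_j) - 1) ]`,

  with principal Cauchy stresses `sigma_a = J^-1 lambda_a dPsi/dlambda_a`
  and spectral assembly `sigma = sum_a sigma_a n_a (x) n_a`. The penalty
  exponent is tied to the Poisson ratio (`n = nu/(1 - 2 nu)` by default,
  giving the uniaxial lateral law `lambda_lat = lambda^-nu`; the sign
  variant `nu/(2 nu - 1)` found in some documentation is available as
  `convention = "paper"`). Coefficients `C_j` are least-squares fitted to
  SFO-scaled engineering stress–strain curves, optionally keyed by strain
  rate through a table (log-rate interpolation, clamped).
* **Explicit FE mini-solver.** 8-node solid elements with full 2x2x2
  quadrature, lumped mass, central-difference time integration, the CFL
  critical step `dt = L/c` with `c = sqrt((K + 4G/3)/rho)` from the
  material card, selective mass scaling to a fixed target step (the
  `dt2ms` mechanism, with added mass reported absolutely and in percent),
  rigid-plane penalty contact, and a trapezoidal energy audit.
* **Post-processing.** Effective (von Mises) stress, effective strain
  `sqrt((2/3) e:e)`, accumulated effective plastic strain, linear-fit
  Young's moduli over the window of highest loading.
* **Injury criteria.** Failed-element volume above a strain threshold
  (once failed, always counted), the cumulative strain damage measure
  (CSDM, default threshold 59% = the lower limit of the 95 +/- 36 %
  muscle failure elongation), peak contact force, and pluggable
  force -> probability risk curves.
* **Fixtures and I/O.** Deterministic generators for the 8-element cuboid
  verification model, a quasi-static uniaxial coupon, a drop-impact block,
  and synthetic element histories; a reader/writer for a small
  keyword-deck subset (`*NODE`, `*ELEMENT_SOLID`, `*PART`,
  `*MAT_SIMPLIFIED_RUBBER/FOAM`, `*DEFINE_CURVE`, `*DEFINE_TABLE`,
  `*CONTROL_TIMESTEP` with negative `dt2ms`, `*CONTROL_TERMINATION`), and
  a CLI.

Everything ships with synthetic stand-in materials: the licensed human
body models and their tissue curves are deliberately out of scope.

## Worked example

Fit a material to the stand-in soft-tissue curve, drop a 10 mm block of it
onto a rigid plane at 3 m/s, and post-process:

```r
library(foamfem)

curve <- default_soft_tissue_curve()                 # convex, peak ~24 kPa
mat <- curve_material(curve, density = 1050, K = 1.04e6, G = 1.6e4,
                      nu = 0.3, exponents = c(2, 4, -2))
tangent_young_modulus(mat)
#> [1] 41600                      # Pa; ~42 kPa, a relaxed-muscle stiffness
uniaxial_nominal_stress(1.5, mat)
#> [1] 23721.39                   # Pa at 50 % engineering strain

run <- run_simulation(make_drop_block(sfo = 2))      # "partly contracted"
run$manifest$termination_status
#> [1] "normal"
max(run$contact$magnitude)
#> [1] 2.893187                   # N, peak plane reaction at 1.3 ms

hs <- as_element_histories(run)
max(sapply(hs, function(h) max(history_effective_strain(h))))
#> [1] 0.3799253                  # peak effective strain, below the 0.59
#>                                # CSDM threshold: no damage at SFO 2
loaded <- which.max(sapply(hs, function(h) max(history_effective_stress(h))))
fit_young_modulus(history_effective_stress(hs[[loaded]]),
                  history_effective_strain(hs[[loaded]]))
#> <stiffness_fit> E = 78580.2 Pa (R^2 = 0.9884, 20 samples, window 7..26)

risk <- risk_curve(c(1, 3, 6), c(0.05, 0.3, 0.8), label = "hip AIS2+")
risk_lookup(risk, max(run$contact$magnitude))
#> [1] 0.2866484                  # interpolated injury probability
```

Sweeping `sfo` over `c(0.5, 1, 2, 10)` reproduces the qualitative
stiffness trends: peak contact force and fitted modulus rise with SFO
while peak effective strain and terminal CSDM fall (run
`tests/testthat/test-acceptance.R` criterion 9). The energy audit of the
run above closes to 0.7 % of the impact energy.

The same workflow is scriptable:

```sh
Rscript -e 'quit(status = foamfem::cli())' fixture cuboid8 --sfo 10 --out cube.k
Rscript -e 'quit(status = foamfem::cli())' simulate --deck cube.k --out hist
Rscript -e 'quit(status = foamfem::cli())' metrics  --histories hist
Rscript -e 'quit(status = foamfem::cli())' injury   --histories hist --csdm-threshold 0.59
```

## Documentation

The methods vignette (`vignettes/foam-muscle-stiffness.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic fixtures do and do not emulate, and the
numerical choices (time-step policy, mass scaling, contact penalty sizing,
energy bookkeeping, degenerate inputs).
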