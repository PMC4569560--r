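# adhesim

Stochastic adhesive-dynamics simulation of a circulating melanoma tumor
cell (TC) interacting with a substrate-adherent polymorphonuclear
neutrophil (PMN) in near-wall shear flow.

PMN-mediated adhesion of melanoma cells to the vessel wall is a known
participating mechanism in melanoma metastasis: ICAM-1 on the tumor cell
binds the β2 integrins LFA-1 and Mac-1 on the neutrophil, tethering the
tumor cell against the shear flow. `adhesim` is a desk-scale simulator of
that interaction for modelers who want the full localized biochemistry —
individual bonds forming and breaking between discretized membrane faces —
without running a CFD solver.

## The model

Both cells carry triangulated surface meshes. Adhesion molecules are
distributed uniformly, `n_L · A_L` (possibly fractional) molecules per
face, and every pair of faces whose centroid separation `d` falls inside
the adhesive gate can host bonds with Bell/Dembo slip-bond kinetics:

```
k_on  = k_on0 · n_L A_L · exp( − s_ts (d − λ)² / 2 k_B T )
k_off = k_off0 · exp( (s − s_ts)(d − λ)² / 2 k_B T )
P     = 1 − exp(−k Δt)
```

with spring constant `s = 2×10⁻³` N/m, transition-state constant
`s_ts = 10⁻³` N/m and equilibrium bond length `λ = 0.05` μm. Each formed
bond is a Hookean spring `f = s (d − λ)` acting along the line joining
the bonded face centroids; a per-face, per-species molecule ledger
(fractional counts, strict conservation) prevents a molecule engaged by
one bond type from being double-booked by another. Because molecules are
taken to sit at the tips of ~μm-scale microvilli, the bond coordinate is
the face separation minus a standoff `ε_mv` (default 1.2 μm).

Close face pairs additionally exchange a gated nonlinear-spring repulsion
`F_rep = a d + b d³` (`a = −110×10⁻⁶` N/m, `b = 600×10⁶` N/m³, applied
below the critical distance `ε = 1.2` μm), which lumps microvillus
pushing, electrostatic repulsion and steric stabilization and holds the
surfaces ~0.3 μm apart. The tumor cell moves with full 6DOF rigid-body
dynamics under the aggregate of bond, repulsion and hydrodynamic loads;
the hydrodynamics is an analytic near-wall surrogate (wall-corrected
Stokes drag plus shear-induced rotation about the vorticity axis), not a
Navier–Stokes solution, and every output file says so in its header.

See the methods vignette (`vignettes/adhesive-dynamics.Rmd`) for the full
model description, parameter table, numerical choices and known
limitations — including a measured, strong mesh-resolution dependence of
absolute bond counts that the localized formulation does not remove.

## Worked example

A tumor cell released upstream at the reference conditions (Table-level
parameters, shear rate 100 s⁻¹) sweeps over the adherent PMN, is caught
briefly, and is carried off:

```r
library(adhesim)
cfg <- default_config(tc = list(subdivisions = 2),
                      pmn = list(resolution = 6),
                      environment = list(n_steps = 40),
                      seed = 42L)
sim <- simulate(cfg, quiet = FALSE)
#> adhesim: exited_domain after 38 steps, 0 live bonds
tr <- sim$trajectory
max(tr$n_bonds)                       # 8   (peak live bonds while passing)
round(min(tr$min_separation_m)*1e6, 3)  # 1.218 um closest face approach
nrow(sim$bond_log)                    # 16  formation/breakage events
head(sim$bond_log[, c("step","event","tc_face","pmn_face","bond_type")], 3)
#>   step event tc_face pmn_face  bond_type
#> 1    9  form     161       11 ICAM1:LFA1
#> 2    9  form     161       11 ICAM1:LFA1
#> 3    9  form     161       11 ICAM1:LFA1
```

Up to 8 ICAM-1–LFA-1 bonds form while the cell crosses the adhesive gate
above the PMN apex and all release as the shear carries it downstream —
a transient capture. `write_trajectory_csv()` / `write_bond_log_csv()`
dump the full per-step record; `approach_experiment()` and
`mesh_independence_experiment()` script the two standard numerical
experiments. The same runs are available from a shell:

```sh
Rscript -e 'adhesim::run_cli()' run --seed 42 --steps 40 --out out/
Rscript -e 'adhesim::run_cli()' fixture       # planar P=1 verification
Rscript -e 'adhesim::run_cli()' approach      # repulsion on/off contrast
Rscript -e 'adhesim::run_cli()' compare-meshes --seeds 50
```

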