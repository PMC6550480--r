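# aqpore

Continuum diffusion modelling of aquaporin-occluded nanofiltration
membranes.

## The problem

Biomimetic nanofiltration membranes are built by anchoring aquaporin water
channels onto a nanoporous polymer support (e.g. a polybenzimidazole film
carrying ~1 nm pores under an amphiphilic PVA-alkyl sealing layer).  The
proteins pass water but block ions, so each aquaporin parked on a pore
opening acts as an impermeable cap for solute transport.  The surface
density of the anchored proteins is below the detection limit of electron
microscopy, but it leaves a clear fingerprint in the transport data: the
more pore openings are capped, the lower the steady-state solute flux.
`aqpore` turns that fingerprint into an estimate.  It is aimed at membrane
scientists who have bench flux and rejection tables and want a
physics-based, fully reproducible inversion from flux ratios to
packing/capping fractions.

## The model

Steady-state Fickian diffusion through a reservoir–film–reservoir domain:

    j = -D ∇c,        ∇·(D ∇c) = 0

with Dirichlet concentrations `c(L) = 1`, `c(R) = 0` on the outer reservoir
faces and the bulk diffusivity nondimensionalized to `D_bulk = 1`.  The film
is a slab with straight cylindrical pores (diameter 1 nm) on a square
lattice whose spacing is set so that pores cover 28% of the face; aquaporins
are impermeable cylindrical obstructions on the feed-side face.  The domain
is voxelized and solved with a conservative finite-volume scheme (harmonic
face diffusivities, direct sparse Cholesky).  From the converged field the
area-averaged plane flux

    <j> = (1/A) ∫ D ∇c · dS

yields the effective diffusivity through

    <j> ≈ De (c(L) - c(R)) / (x(L) - x(R))

For a film of straight, aligned, uncapped channels `De/D_bulk` equals the
areal pore fraction (`SA_pore / SA_total`); capping a fraction *f* of the
pores removes the same fraction of the flux, so the monotone `De(f)` curve
from a packing sweep can be inverted — by piecewise-linear interpolation,
with a reported bracket — at any measured flux or diffusivity ratio.
Alongside the solver the package implements the standard membrane
characterization math: apparent solute rejection `R = (1 - Cp/Cf)·100%`, the
90%-rejection molecular-weight-cut-off rule on the PEG/sucrose probe series,
and Stokes–Einstein radius lookup, plus a synthetic-data generator that
emulates bench flux/rejection tables for end-to-end parameter-recovery
studies.

## Worked example

```r
library(aqpore)

## the study membrane: 1 nm pores at 28% areal coverage, 50 nm selective layer
geom <- film_geometry(pore_diameter = 1, coverage = 0.28,
                      film_thickness = 50, n_pores_x = 5)

## solve the uncapped film and extract the effective diffusivity
field <- solve_steady_state(voxelize(geom))
effective_diffusivity(field)
#> <effective_diffusivity> De/D_bulk = 0.265306 (film separation 50.01 nm, <j> = 0.00500208)

## sweep the capped-pore fraction and invert a bench flux ratio:
## the occluded membrane passed 36% of the reference flux
curve <- sweep_capping(geom, fractions = c(seq(0, 1, by = 0.2), 0.64))
estimate <- estimate_packing(curve, 0.36, measured = "flux_ratio")
tidy(estimate)
#> # A tibble: 1 × 8
#>   model     estimate definition     measured measured_ratio de_ratio    lo    hi
#>   <chr>        <dbl> <chr>          <chr>             <dbl>    <dbl> <dbl> <dbl>
#> 1 aggregate    0.638 fraction_of_p… flux_ra…           0.36   0.0955   0.6  0.64

## molecular-weight cut-off of the unmodified support from its rejections
profile <- tibble::tibble(
  solute = c("PEG 200", "Sucrose", "PEG 400", "PEG 600", "PEG 1000"),
  molecular_weight = c(200, 342.3, 400, 600, 1000),
  rejection_pct = c(35, 48, 62, 81, 94.2))
determine_mwco(profile)
#> <mwco_result> MWCO 1000 g/mol, defined by PEG 1000 at 94.2% rejection
```

Reading the numbers: the uncapped film transports like a homogeneous slab
with 26.5% of the bulk diffusivity — exactly the film's rasterized pore
fraction at this resolution (the continuum target is 28%).  A membrane
passing 36% of the reference flux inverts to ~64% of its pore openings
capped, bracketed by the 0.60 and 0.64 sweep points.  The rejection profile
crosses 90% at PEG 1000, so the support's cut-off is 1000 g/mol.

`autoplot(curve)` draws the `De(f)` curve (overlaying a
`monomer_curve()` shows the aggregate/monomer comparison),
`autoplot(field)` shows a concentration slice, and
`plot_rejection_profile(profile)` the rejection-versus-radius curve.
`run_pipeline()` (or the thin CLI wrapper in `inst/cli/aqpore.R`) chains
`synth → simulate → sweep → infer → characterize` from a YAML config into
CSV/VTK/JSON outputs with a run manifest.

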