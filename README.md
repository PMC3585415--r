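# ectotilt

Where does the ligand-binding domain of a bent integrin sit relative to the
plasma membrane?  `ectotilt` is an R package for the quantitative pipeline
that answers this for receptors probed with a fluorescently labelled Fab
fragment: it converts fluorescence-lifetime imaging (FLIM) measurements
into FRET efficiencies and Förster distances, runs a systematic
membrane-orientation (tilt) search of an atomic ectodomain model under
steric and distance constraints, and validates hybrid atomic models against
negative-stain EM class averages by sequential two-body projection
matching, with Fourier shell correlation for resolution estimation.

It is written for structural biologists and quantitative microscopists who
have (a) per-cell donor lifetime tables for donor-only and donor+acceptor
conditions, (b) an atomic model of the ectodomain (PDB), and optionally
(c) 2D class averages (MRC).  Fully synthetic substitutes for all three
inputs are generated by the package itself, so the entire pipeline runs —
and is tested — without any external data.

## The core quantities

With donor-only lifetime τ<sub>D</sub> and quenched lifetime τ<sub>DA</sub>:

- FRET efficiency: E = 1 − τ<sub>DA</sub>/τ<sub>D</sub>
- donor–acceptor distance: r = R₀ (τ<sub>D</sub>/τ<sub>DA</sub> − 1)<sup>−1/6</sup>,
  with R₀ = 62 Å by default (Alexa488 pair, κ² = 2/3)
- efficiency at distance: E(r) = R₀⁶ / (R₀⁶ + r⁶)

The orientation search places the model in a canonical frame (α-chain
terminal residue at the origin, Calf-1/Calf-2 leg axis along +z), models
the membrane as the plane z = −linker_offset, and evaluates every tilt
direction Φ ∈ [0°, 360°) × tilt rotation ρ ∈ [0°, 180°] on a 5° grid
(2,664 orientations).  Orientations with any atom below the plane are
rejected; the Fab lysine-Cα centroid distance to the plane is compared
with the FLIM-derived r to select the consistent subset, whose tilt
(arithmetic) and Φ (circular) statistics are reported.

## Worked example

```r
library(ectotilt)

# synthetic per-cell lifetimes with the study's statistics
sim <- simulate_lifetimes(lifetime_sim_spec(seed = 1),
                          lifetime_sim_spec(mu = 1529, sigma = 115, seed = 2))
fit_d  <- fit_lifetime_gaussian(sim$donor_only)
fit_da <- fit_lifetime_gaussian(sim$donor_acceptor)
fit_d
#> <gaussian_fit> mu = 2230.4 +/- 8.1 ps (95% CI), sigma = 76.0 ps, r = 0.989 (n = 176, 50 ps bins)
fit_da
#> <gaussian_fit> mu = 1532.1 +/- 23.9 ps (95% CI), sigma = 145.1 ps, r = 0.941 (n = 176, 50 ps bins)

eff <- fret_efficiency(fit_d$mu, fit_da$mu)      # 0.313 -> 31.3%
r   <- forster_distance(fit_d$mu, fit_da$mu)     # 70.7 Angstrom
distance_range(fit_d, fit_da)                    # 66.4  76.5

# orientation scan of a toy receptor whose Fab centroid is engineered
# 71 A above the membrane plane (66 A head offset + 5 A linker)
toy    <- make_toy_integrin(toy_integrin_spec(head_offset = c(25, 0, 66)))
framed <- canonicalize(toy, attr(toy, "calf_spec"))
scan   <- orientation_scan(framed, membrane_plane(-5), step = 5)
scan   <- apply_flim_constraint(scan, target = r, tolerance = 2.5)
scan
#> <orientation_scan_result> step 5 deg, 2664 samples; allowed 1155; FLIM-consistent 273 (target 70.67655 +/- 2.5 A)
#>   tilt 77.2 (SD 13.7) deg; phi 182.3 (SD 94.2) deg
```

Reading the output: the donor fit recovers the generating mean (2,234 ps)
within its CI; the fitted pair gives ~31% FRET efficiency, a ~71 Å
fluorophore–membrane distance and a 66–77 Å ±1σ range.  Of the 2,664
scanned orientations, 1,155 keep every atom above the membrane plane and
273 of those also place the Fab centroid within 2.5 Å of the FLIM
distance; their mean tilt of ~77° reflects this toy's geometry (a real
receptor model with asymmetric bulk is far more constrained).

For EM model validation, `sequential_fit()` matches an ectodomain body
into a class average, subtracts the aligned projection, matches the αA/Fab
body into the difference image, and reports per-body and composite
cross-correlations; `fsc()` and `resolution_at()` give map resolution at
the FSC = 0.5 criterion.  `run_full_analysis()` chains the FLIM and
orientation stages from a YAML config and writes a JSON report, the scan
table and a log; `inst/scripts/ectotilt.R` exposes `flim`, `orient`,
`simulate` and `run` subcommands for shell use.

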