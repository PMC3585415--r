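Package: ectotilt
Title: Membrane Orientation of Integrin Ectodomains from FLIM-FRET Distances
    and EM Projection Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to localize the ligand-binding domain of a cell-surface
    receptor relative to the plasma membrane by combining three analyses:
    conversion of fluorescence-lifetime (FLIM) measurements into FRET
    efficiencies and Forster distances with +/-1 sigma range propagation; a
    systematic rigid-body orientation (tilt) search of a membrane-framed
    atomic model under steric clash and fluorophore-centroid distance
    constraints; and sequential two-body 2D projection matching of simulated
    electron-microscopy density into class averages, with Fourier shell
    correlation for resolution estimation.  Includes generators for fully
    synthetic test data (toy atomic models, per-cell lifetime tables, noisy
    class averages) so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
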