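Package: serpdyn
Title: Trajectory Interaction Analysis and Stability Quantitation for Serpin Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of molecular-dynamics trajectories of serpin
    variants and quantitation of their spectroscopic stability readouts.
    Implements hydrogen-bond and salt-bridge detection with occupancy
    statistics and between-variant differencing, Kabsch superposition with
    RMSD/RMSF/radius-of-gyration profiles, Shrake-Rupley solvent-accessible
    surface area, covariance-based linear mutual information with
    generalized-correlation ranking of long-range residue pairs, and
    sigmoid fitting of thermal and chemical denaturation curves together
    with emission-spectrum first moments and gel-lane densitometry
    normalisation. A synthetic-data module generates every input with known
    ground truth (Gaussian ensembles with prescribed covariance, planted
    interaction geometries, rigid-body tumbles, noisy denaturation curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
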