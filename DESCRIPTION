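Package: petctiq
Title: Digital PET/CT Image-Quality Phantoms and NEMA-Style Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital twins of the NIM PET/CT phantom and the NEMA IEC body
    phantom, with voxel rasterization of activity and Hounsfield-unit maps,
    a desk-scale slice-wise PET simulator (parallel-beam forward projection,
    Poisson counting noise, OSEM reconstruction with optional point-spread
    function modelling and a time-of-flight count-gain approximation), a
    Gaussian-noise CT simulator, NEMA NU2-style region-of-interest placement,
    the standard image-quality metrics (hot and cold contrast recovery,
    percent background variability, lung-insert residual error, low-contrast
    delta-CT and contrast-to-noise ratio, boundary noise, uniformity), and
    comparison arithmetic across phantoms, scanners and reconstruction
    algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
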