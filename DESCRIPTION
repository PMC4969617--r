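Package: nanoheat
Title: Benchmarking Plasmonic Nano-Heaters from Optics to PET Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computational platform for benchmarking plasmonic
    photothermal nano-heaters. Computes analytic Mie absorption,
    scattering and extinction cross-section spectra for solid gold
    nanoparticles and silica-core gold-shell nanoshells; extracts melted
    bilayer footprint radii from single-particle fluorescence images via
    centroid location, rotational averaging and half-maximum
    thresholding; converts footprints into single-particle surface
    temperatures and experimental absorption cross-sections through the
    point-source heating relation; quantifies early photothermal
    treatment response in FDG-PET tumor volumes with a low-uptake-volume
    statistic; and generates ground-truthed synthetic microscopy frames,
    heating series and PET phantoms so every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    RNifti,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
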