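Package: clemtarget
Title: Automated Targeting Toolkit for Correlative Light and FIB-SEM Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of an automated correlative light / focused ion
    beam scanning electron microscopy (FIB-SEM) targeting workflow on gridded
    culture substrates. Detects the imprinted grid coordinate system in
    reflected-light and SEM images by angular line projection, extracts grid-bar
    crossing landmarks with alphanumeric square identification, registers light
    and electron microscope stage frames with global and locally refined affine
    transforms, provides acquisition-geometry heuristics (beam coincidence
    point, trench detection, autofocus site selection), per-slice run monitoring
    (drift tracking, focus and stigmatism quality), Golgi-morphology phenotype
    scoring, and stereological quantification (Cavalieri point counting,
    cycloid intersections). Ships deterministic synthetic-image generators with
    exact ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
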