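Package: diffractr
Title: Diffraction Geometry Calibration and Reduction of 2D X-Ray Scattering Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calibrates the six-parameter diffraction geometry of a flat 2D
    area detector (sample-detector distance, beam centre, two detector tilts
    and wavelength/energy) from powder ring images of a calibration standard,
    by automatic single-image, multi-distance and manual routes, and reduces
    raw 2D diffraction/SAXS frames to corrected diffractograms, azimuth-radial
    cake grids, peak-position/FWHM time series and azimuthal orientation maps
    through provenance-preserving, rank-preserving processing chains written
    as NeXus/HDF5 files. Includes seeded synthetic generators for calibrant
    ring images, multi-distance series, peak-shift series and oriented grid
    scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
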