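Package: pawkit
Title: Photoacoustic Wave Analysis for Vesicle Permeabilization Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying photoacoustic-wave-mediated permeabilization
    of giant unilamellar vesicles (GUVs). Implements closed-form photoacoustic
    transduction formulas (thin/thick absorber peak pressures, Grueneisen
    parameter, acoustic impedance transmission, Mechanical Index), conversion
    of Mach-Zehnder interferogram pairs into quantitative 2D pressure maps via
    Fourier fringe demodulation and the Tait equation of state, calibration and
    metrics for hydrophone pressure waveforms, detection and tracking of GUVs
    in fluorescence time-lapse stacks with Ritger-Peppas release-kinetics
    fitting, and seeded synthetic-data generators for every input so the whole
    chain can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
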