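Package: flowphantom
Title: Virtual Aortic-Stenosis Flow Phantom and Pressure-Drop Metric Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-channel pressure recordings from a virtual
    mock circulatory loop with a stenotic aortic valve (pulsatile or
    constant pump output, vena-contracta pressure drop with downstream
    pressure recovery, distal wave reflections, distance-dependent
    turbulence noise and pump artifacts), and implements the companion
    signal pipeline that extracts the instantaneous peak, net and
    peak-to-peak transvalvular pressure drops (zero-phase Butterworth
    filtering, cardiac-cycle ensemble averaging, modified-Akima spatial
    interpolation). Includes a test-retest reproducibility harness
    (4 handling conditions x 2 sessions x 8 flow regimens) with ordinary
    least-squares and Bland-Altman agreement statistics, for studying
    which pressure-drop metrics are robust to factors extrinsic to the
    valve, such as wave reflection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
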