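Package: clicktrackr
Title: Passive-Acoustic Localization and Tracking of Echolocating Whales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional tracks of echolocating odontocetes
    (e.g. Cuvier's beaked whale) from arrays of passive acoustic recorders that
    combine small-aperture volumetric (tetrahedral) four-channel arrays with
    widely spaced single-channel instruments. Provides click detection with a
    zero-phase elliptic high-pass filter, small-aperture time-difference-of-
    arrival (TDOA) measurement by sub-sample cross-correlation, least-squares
    direction-of-arrival (DOA) estimation, click-train correlation to associate
    detections across instruments, Monte-Carlo/bootstrap localization with
    propagated TDOA uncertainties, a fast two-DOA intersection localizer with
    jackknife confidence intervals, deployment calibration (hydrophone geometry
    from ship noise, instrument trilateration, clock-drift polynomials from
    periodic pings), and a synthetic-scene simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    MASS,
    jsonlite,
    yaml,
    pracma,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
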