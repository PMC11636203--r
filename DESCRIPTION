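Package: beegate
Title: Entrance-Camera Fiducial-Tag Analysis of Honey Bee Foraging Trips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing fiducial-tag detection logs recorded by a
    camera watching a hive-entrance tunnel. Detections of individually tagged
    honey bees are parsed and validated, grouped into events by temporal
    proximity (a 60-second window by default), classified as enter, exit or
    unknown from net displacement along the tunnel axis, and paired into
    foraging trips whose duration distribution is summarised and plotted.
    Includes a synthetic entrance-traffic simulator with ground truth for
    end-to-end validation, and a circular 44-bit tag layout model with
    rendering, decoding, white-pixel dilation preprocessing and printable
    sheet generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    EBImage,
    withr,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
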