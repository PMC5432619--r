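Package: betacage
Title: Closed-Loop Beta-Band Conditioning and Depth-Camera Movement
    Monitoring for Home-Cage Neurophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software re-implementation of a wireless closed-loop operant
    conditioning and free-behavior monitoring system for home-cage primate
    neurophysiology.  Computes sliding-window rectified beta-band (10-30 Hz)
    local field potential power, calibrates reward thresholds against
    unrewarded baseline recordings, detects threshold crossings under a
    refractory lockout, schedules Reinforced/Non-Reinforced epochs with audio
    feedback, encodes reward events as redundant biphasic radio-frequency
    pulse trains with a lossy-channel simulator and decoder, quantifies gross
    body movement from depth-camera frame sequences via extremal-voxel
    differencing, maintains event-triggered rolling clip buffers, and provides
    session-level analyses (epoch reward rates, normalized performance,
    event-triggered averages, permutation comparisons).  A synthetic session
    generator produces coupled LFP and depth-video data with known ground
    truth so every component is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
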