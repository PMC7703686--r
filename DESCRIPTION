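Package: caindex
Title: Non-Invasive Cerebral Autoregulation Indices from Transcranial
    Doppler and Arterial Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes non-invasive cerebral autoregulation metrics from
    paired transcranial Doppler blood-flow-velocity and arterial
    blood-pressure waveforms: the nMxa index (moving 5-minute-window
    Pearson correlation between slow-wave, 0.005-0.05 Hz, fluctuations of
    pressure and flow velocity, summarised on 10-second block averages)
    and the transient hyperaemic response ratio (THRR) from carotid
    compression tests. Includes artefact detection and masking, systolic
    beat detection, a parameterisable synthetic hemodynamic waveform
    generator with known ground-truth autoregulation status for
    validation, participant-level scoring (Post-Concussion Symptom
    Scale), cohort summaries, and power/sample-size projection.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
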