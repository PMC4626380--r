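Package: hemowave
Title: Arterial Wave Separation, Impedance, and Windkessel Flow Synthesis
    from Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-arm analysis of central arterial hemodynamics from
    one averaged cardiac cycle. The measured arm derives the input impedance
    spectrum, characteristic impedance, systemic vascular resistance and
    forward/backward wave separation from paired pressure and flow waveforms.
    The model arm synthesizes an aortic flow waveform from a calibrated
    pressure waveform alone via a modified 3-element Windkessel inversion,
    yielding the same parameters plus a characteristic-impedance-derived
    pulse wave velocity. A synthetic cohort generator with known ground truth,
    Bland-Altman / correlation / stepwise-regression method-comparison tools
    and subgroup summaries complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
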