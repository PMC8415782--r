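Package: seegdecode
Title: Decoding Sustained Movement and Tactile Stimuli from Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for decoding cued, sustained motor and
    tactile events from stereo-EEG (SEEG) and electrocorticography (ECoG)
    recordings. Converts multichannel voltage data to integrated amplitude
    features (IAFs) on a 200 ms window grid via bipolar re-referencing,
    Blackman-tapered short FFTs, frequency-band integration, boxcar smoothing
    and z-standardization; selects features by trial-to-trial repeatability
    using the mean correlation coefficient (MCC) of single-trial temporal
    responses against their trial-averaged composite; and trains and
    evaluates window-wise decoders (gaussian-kernel multi-class SVM and an
    LSTM sequence classifier) with and without feature selection. Includes a
    synthetic-recording generator that plants ground-truthed, band-limited
    phasic and phasic-tonic amplitude modulations in 1/f background noise so
    the full pipeline can be exercised and validated without patient data,
    plus EDF and tab-separated event file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
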