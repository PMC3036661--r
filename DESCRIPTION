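Package: pcgenergy
Title: Quantification of Non-Deterministic Energy in Heart Sound Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify non-repeating (non-deterministic) events such as
    mechanical-heart-valve cavitation or murmurs in phonocardiogram (PCG)
    recordings, against the louder repeating heart-beat background. The
    pipeline segments a recording into heart beats, truncates and superimposes
    them into an equal-length ensemble, optionally aligns beats on their S1 or
    S2 peaks and removes badly shifted beats, and decomposes signal energy into
    a deterministic part (energy of the ensemble-averaged beat) and a
    non-deterministic remainder (mean per-beat energy minus deterministic
    energy). A Short-Time Fourier Transform extension resolves the same
    decomposition over time within the beat. Includes a synthetic-signal
    generator (analytic sine ensembles and realistic PCG-like fixtures with
    ground truth) and brute-force numerical oracles used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
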