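Package: osadetect
Title: Noise-Robust Acoustic Detection of Obstructive Sleep Apnea Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects obstructive sleep apnea (OSA) events from overnight
    breathing-sound recordings. The night is split into 30-second epochs,
    each epoch is converted to a log-mel spectrogram, and a compact neural
    detector maps 14-epoch context windows to per-epoch probabilities over
    no-event, apnea and hypopnea. Robustness to domestic background noise is
    obtained by home-noise consistency training: clean windows are corrupted
    with concatenated noise clips at random signal-to-noise ratios and a
    mean-squared-error consistency term ties the two predictions together.
    Per-epoch detections are converted to an apnea-hypopnea index (AHI) by a
    robust (RANSAC) linear calibration, with screening and agreement metrics
    (accuracy, Cohen's kappa, macro F1, sensitivity/specificity, AUC,
    Bland-Altman). A seeded synthetic-night generator produces breathing
    audio with apneas (silence then a recovery gasp), hypopneas (attenuated
    irregular breathing) and nine categories of synthetic home noise, so the
    whole pipeline is testable end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
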