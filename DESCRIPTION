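Package: circact
Title: Circadian Analysis of Rodent Locomotor Activity Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of binned locomotor-activity time series (actograms) from
    rodents under light-dark (LD), constant-darkness (DD) and jet-lag lighting
    protocols. Implements the Sokolove-Bushell chi-square periodogram for
    free-running and entrained period estimation, Morlet-wavelet instantaneous
    period tracking with AR(1) chi-square significance and a Shannon-entropy
    period-variability index, nonparametric circadian rhythm analysis
    (interdaily stability and intradaily variability), mean-waveform phase
    metrics (activity onset, alpha/rho partition, phase angle, diurnal
    activity), sigmoid (variable-slope) resynchronization fitting with PS50 and
    extra sum-of-squares F-tests, and Rayleigh circular statistics for
    LD-to-DD phase differences. A synthetic actogram generator with known
    ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
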