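Package: qcsentinel
Title: System Suitability Monitoring and Quality-Control Triage for
    Quantitative LC-MS Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-tier quality-control toolkit for quantitative
    bottom-up proteomics. Longitudinal system-suitability series are
    monitored with statistical-process-control charts (Levey-Jennings,
    CUSUM, moving range, trailing mean and trailing CV); protein- and
    peptide-level internal QC standards are combined with isotope-envelope
    similarity (idotp) to localize failures to sample preparation, the LC,
    or the mass spectrometer; and external-QC samples drive assessment of
    the raw / log2-median-normalized / batch-adjusted data ladder through
    coefficient-of-variation summaries. A built-in simulator generates
    measurement reports with log-normally noisy peak areas, retention-time
    jitter, ppm-scale mass error, theoretical isotope envelopes, and six
    canonical failure modes, so every detector is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
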