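# Small in-code fixtures shared across tests.

toy_report_lines <- function() {
  c(paste(c("run_id", "acquired_at", "peptide", "precursor_charge",
            "analyte_class", "precursor_area", "transition_area", "rt_min",
            "mass_error_ppm", "iso_m0", "iso_m1", "iso_m2"), collapse = "\t"),
    "R2\t2024-01-01T01:00:00Z\tLVNELTEFAK\t2\tSUITABILITY_PEPTIDE\t3500\t10000\t15.2\t1.1\t2000\t1100\t380",
    "R1\t2024-01-01T00:00:00Z\tLVNELTEFAK\t2\tSUITABILITY_PEPTIDE\t3400\t9800\t15.1\t-0.4\t1950\t1080\t370",
    "R3\t2024-01-01T02:00:00Z\tLVNELTEFAK\t2\tSUITABILITY_PEPTIDE\t3600\t10100\t15.3\t0.2\t2050\t1120\t390")
}

toy_runlog_lines <- function() {
  c("run_id\tacquired_at\trun_type\tbatch_id",
    "R1\t2024-01-01T00:00:00Z\tsystem_suitability\tB1",
    "R2\t2024-01-01T01:00:00Z\tSample\tB1",
    "R3\t2024-01-01T02:00:00Z\tSYSTEM_SUITABILITY\tB1")
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# A metric series built directly from values, hourly spacing.
make_series <- function(values, metric = "TRANSITION_AREA",
                        analyte_id = "PEP/2") {
  n <- length(values)
  pts <- tibble::tibble(
    run_id = sprintf("R%04d", seq_len(n)),
    acquired_at = as.POSIXct("2024-01-01", tz = "UTC") + 3600 * seq_len(n),
    value = values)
  structure(pts, metric = metric, analyte_id = analyte_id, n_omitted = 0L,
            class = c("metric_series", class(tibble::tibble())))
}

make_baseline <- function(mean, sd, n = 10L,
                          guide_run_ids = sprintf("R%04d", seq_len(n))) {
  structure(list(mean = mean, sd = sd, n = n, guide_run_ids = guide_run_ids),
            class = "qc_baseline")
}

# One-row internal-QC summary with sane defaults, for classify_run tests.
make_summary <- function(run_id = "R0001", eno_z = 0, prtc_z = 0,
                         eno_ratio = 1, prtc_ratio = 1, rt_shift_min = 0,
                         min_idotp = 0.99, ss_status = "OK") {
  tibble::tibble(run_id = run_id,
                 acquired_at = as.POSIXct("2024-01-01", tz = "UTC"),
                 eno_z = eno_z, prtc_z = prtc_z, eno_ratio = eno_ratio,
                 prtc_ratio = prtc_ratio, rt_shift_min = rt_shift_min,
                 min_idotp = min_idotp, ss_status = ss_status)
}
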