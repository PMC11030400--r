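## triage: combine protein internal QC (ENO), peptide internal QC (PRTC),
## isotope envelopes and system-suitability context into per-run failure
## classifications.

#' Triage thresholds
#'
#' All triage thresholds are configuration, not science: the source
#' observations ("reduced", "consistent", "shifted by several minutes") are
#' qualitative, so the defaults are engineering choices documented here.
#'
#' @param low_ratio A run's median IQC area ratio to baseline below which the
#'   class is considered "reduced" (default 0.5).
#' @param rt_tol Absolute retention-time shift, in minutes, beyond which an
#'   injection/LC event is suspected (default 2.0).
#' @param idotp_min Minimum acceptable isotope dot product (default 0.90).
#' @param z_tol Peptide-IQC z-score window regarded as "consistent"
#'   (default 2).
#' @param decline_runs Number of consecutive strictly decreasing
#'   peptide-IQC ratios that counts as a decline (default 3).
#' @param decline_ratio A decline must end below this ratio (default 0.7).
#' @param ss_window Number of most recent suitability runs consulted for the
#'   system status (default 3).
#' @param ss_fail_fraction Fraction of suitability analytes that must FAIL
#'   Levey-Jennings on transition area before a suitability run is counted
#'   as degraded (default 0.5).
#' @param first_k Guide-set size used when baselines are built automatically
#'   (default 10).
#' @param min_guide Minimum guide-set size (default 5).
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(low_ratio = 0.5, rt_tol = 2.0, idotp_min = 0.90,
                          z_tol = 2, decline_runs = 3L, decline_ratio = 0.7,
                          ss_window = 3L, ss_fail_fraction = 0.5,
                          first_k = 10L, min_guide = 5L) {
  structure(list(low_ratio = low_ratio, rt_tol = rt_tol,
                 idotp_min = idotp_min, z_tol = z_tol,
                 decline_runs = as.integer(decline_runs),
                 decline_ratio = decline_ratio,
                 ss_window = as.integer(ss_window),
                 ss_fail_fraction = ss_fail_fraction,
                 first_k = as.integer(first_k),
                 min_guide = as.integer(min_guide)),
            class = "triage_config")
}

#' Build per-analyte area and retention-time baselines
#'
#' Suitability peptides are baselined on the first `first_k` suitability
#' runs; internal-QC peptides (protein and peptide classes) on the first
#' `first_k` sample runs, in acquisition order.
#'
#' @param table A `measurement_table`.
#' @param runlog A `run_log`.
#' @param first_k,min_guide Guide-set sizes, see [establish_baseline()].
#' @return A list of class `qc_baseline_set`: per analyte_id, a list with
#'   `area` and `rt` baselines plus the analyte class.
#' @export
build_qc_baselines <- function(table, runlog, first_k = 10L, min_guide = 5L) {
  classes <- c(SUITABILITY_PEPTIDE = "SYSTEM_SUITABILITY",
               PROTEIN_IQC = "SAMPLE", PEPTIDE_IQC = "SAMPLE")
  out <- list()
  for (cls in names(classes)) {
    ids <- unique(table$analyte_id[table$analyte_class == cls])
    for (id in ids) {
      area_series <- extract_metric(table, runlog, "TRANSITION_AREA", id,
                                    run_types = classes[[cls]])
      k <- min(first_k, nrow(area_series))
      rt_series <- extract_metric(table, runlog, "RT_MIN", id,
                                  run_types = classes[[cls]])
      out[[id]] <- list(
        area = establish_baseline(area_series, first_k = k, min_guide = min_guide),
        rt = establish_baseline(rt_series, first_k = k, min_guide = min_guide),
        analyte_class = cls)
    }
  }
  if (length(out) == 0) qcs_config_error("no baselines could be built")
  structure(out, class = "qc_baseline_set")
}

## Levey-Jennings FAIL fraction per suitability run, over suitability
## analytes' transition areas. Returns tibble(run_id, acquired_at,
## fail_fraction) in acquisition order.
ss_fail_timeline <- function(table, runlog, baselines) {
  ss_ids <- names(baselines)[vapply(baselines, function(b)
    b$analyte_class == "SUITABILITY_PEPTIDE", logical(1))]
  ss_runs <- runlog[runlog$run_type == "SYSTEM_SUITABILITY", , drop = FALSE]
  if (length(ss_ids) == 0 || nrow(ss_runs) == 0)
    return(tibble(run_id = character(), acquired_at = as.POSIXct(character(), tz = "UTC"),
                  fail_fraction = numeric()))
  fail_mat <- matrix(NA, nrow = nrow(ss_runs), ncol = length(ss_ids),
                     dimnames = list(ss_runs$run_id, ss_ids))
  for (id in ss_ids) {
    series <- extract_metric(table, runlog, "TRANSITION_AREA", id,
                             run_types = "SYSTEM_SUITABILITY")
    lj <- levey_jennings(series, baselines[[id]]$area)
    fail_mat[lj$run_id, id] <- lj$flag == "FAIL"
  }
  tibble(run_id = ss_runs$run_id, acquired_at = ss_runs$acquired_at,
         fail_fraction = rowMeans(fail_mat, na.rm = TRUE))
}

#' Summarize internal QCs for every sample run
#'
#' For each sample (and external-QC) run, aggregates the protein-IQC and
#' peptide-IQC analytes by their medians: z-scores and ratios of transition
#' area to the per-analyte baseline means, the median retention-time
#' deviation, and the minimum isotope dot product across IQC analytes. The
#' system-suitability status is read off the most recent `ss_window`
#' suitability runs: `DEGRADED` if any of them FAILed Levey-Jennings on
#' transition area for at least `ss_fail_fraction` of the suitability
#' analytes, `OK` if none did, `UNKNOWN` if there is no suitability run yet.
#'
#' @param table A `measurement_table`.
#' @param runlog A `run_log`.
#' @param baselines A `qc_baseline_set` from [build_qc_baselines()].
#' @param config A `triage_config`.
#' @return A tibble of class `run_iqc_summary` with one row per
#'   sample/external-QC run, carrying the suitability timeline as attribute
#'   `ss_timeline`.
#' @export
summarize_internal_qc <- function(table, runlog, baselines,
                                  config = triage_config()) {
  cls <- vapply(baselines, function(b) b$analyte_class, character(1))
  eno_ids <- names(baselines)[cls == "PROTEIN_IQC"]
  prtc_ids <- names(baselines)[cls == "PEPTIDE_IQC"]
  if (length(eno_ids) == 0 || length(prtc_ids) == 0)
    qcs_config_error("baselines must cover at least one PROTEIN_IQC and one PEPTIDE_IQC analyte")
  timeline <- ss_fail_timeline(table, runlog, baselines)
  sample_runs <- runlog[runlog$run_type != "SYSTEM_SUITABILITY", , drop = FALSE]
  iqc_ids <- c(eno_ids, prtc_ids)
  run_ids <- sample_runs$run_id

  if (nrow(sample_runs) == 0) {
    out <- tibble(run_id = character(),
                  acquired_at = as.POSIXct(character(), tz = "UTC"),
                  eno_z = numeric(), prtc_z = numeric(),
                  eno_ratio = numeric(), prtc_ratio = numeric(),
                  rt_shift_min = numeric(), min_idotp = numeric(),
                  ss_status = character())
    return(structure(out, ss_timeline = timeline,
                     class = c("run_iqc_summary", class(tibble()))))
  }

  ## theoretical envelopes, cached per analyte
  envs <- lapply(setNames(iqc_ids, iqc_ids), function(id) {
    pep <- sub("/[0-9]+$", "", id)
    label <- if (baselines[[id]]$analyte_class == "PEPTIDE_IQC")
      "LABEL_13C6_15N2_K_and_13C6_15N4_R" else "NONE"
    isotope_distribution(peptide_composition(pep, heavy_label = label), 3L)
  })

  sub <- table[table$analyte_id %in% iqc_ids &
                 table$run_id %in% run_ids, , drop = FALSE]
  ri <- match(sub$analyte_id, iqc_ids)
  ci <- match(sub$run_id, run_ids)
  fill <- function(v) {
    m <- matrix(NA_real_, length(iqc_ids), length(run_ids))
    m[cbind(ri, ci)] <- v
    m
  }
  A <- fill(sub$transition_area)
  RT <- fill(sub$rt_min)
  I0 <- fill(sub$iso_m0); I1 <- fill(sub$iso_m1); I2 <- fill(sub$iso_m2)

  b_mean <- vapply(iqc_ids, function(id) baselines[[id]]$area$mean, numeric(1))
  b_sd <- vapply(iqc_ids, function(id) baselines[[id]]$area$sd, numeric(1))
  rt_mean <- vapply(iqc_ids, function(id) baselines[[id]]$rt$mean, numeric(1))

  Z <- (A - b_mean) / ifelse(b_sd > 0, b_sd, NA_real_)
  Ratio <- A / ifelse(b_mean != 0, b_mean, NA_real_)
  RTd <- RT - rt_mean

  ## idotp per (analyte, run), vectorized across runs
  ID <- matrix(NA_real_, length(iqc_ids), length(run_ids))
  for (i in seq_along(iqc_ids)) {
    e <- as.numeric(envs[[iqc_ids[i]]])
    dot <- e[1] * I0[i, ] + e[2] * I1[i, ] + e[3] * I2[i, ]
    onorm <- sqrt(I0[i, ]^2 + I1[i, ]^2 + I2[i, ]^2)
    val <- dot / (sqrt(sum(e^2)) * onorm)
    val[!is.finite(val)] <- NA_real_
    ID[i, ] <- pmin(1, val)
  }

  col_median <- function(m) {
    apply(m, 2, function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE))
  }
  eno_rows <- iqc_ids %in% eno_ids
  prtc_rows <- iqc_ids %in% prtc_ids

  n_ss <- findInterval(as.numeric(sample_runs$acquired_at),
                       as.numeric(timeline$acquired_at))
  ss_status <- vapply(seq_along(run_ids), function(i) {
    k <- n_ss[i]
    if (k == 0) return("UNKNOWN")
    recent <- timeline$fail_fraction[max(1, k - config$ss_window + 1):k]
    if (any(recent >= config$ss_fail_fraction)) "DEGRADED" else "OK"
  }, character(1))

  out <- tibble(
    run_id = run_ids,
    acquired_at = sample_runs$acquired_at,
    eno_z = col_median(Z[eno_rows, , drop = FALSE]),
    prtc_z = col_median(Z[prtc_rows, , drop = FALSE]),
    eno_ratio = col_median(Ratio[eno_rows, , drop = FALSE]),
    prtc_ratio = col_median(Ratio[prtc_rows, , drop = FALSE]),
    rt_shift_min = col_median(RTd),
    min_idotp = apply(ID, 2, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)),
    ss_status = ss_status)
  structure(out, ss_timeline = timeline,
            class = c("run_iqc_summary", class(tibble())))
}

ratio_passlike <- function(s, low_ratio) {
  ## boundary runs (no neighbor) are treated as PASS-like
  if (is.null(s)) return(TRUE)
  er <- s$eno_ratio; pr <- s$prtc_ratio
  (is.na(er) || er >= low_ratio) && (is.na(pr) || pr >= low_ratio)
}

#' Classify one run from its internal-QC summary
#'
#' Ordered diagnostic rules; the first match wins. Fields that are `NA`
#' (unmeasured) skip the rules that need them.
#'
#' * **R1 ISOTOPE_ENVELOPE_LOSS** - the minimum isotope dot product falls
#'   below `idotp_min` while both IQC classes remain at normal abundance.
#'   Evaluated first because envelope loss leaves total areas intact.
#' * **R2 SAMPLE_PREP_FAILURE** - protein IQC reduced (`eno_ratio <
#'   low_ratio`) while the post-digestion peptide IQC is consistent
#'   (`|prtc_z| <= z_tol`).
#' * **R3 INJECTION_LC_EVENT** - both IQC classes reduced with a large
#'   retention-time shift, and the neighboring runs look normal (an
#'   isolated event).
#' * **R4 MS_SENSITIVITY_LOSS** - peptide IQC reduced, or in a sustained
#'   decline (`decline_runs` consecutive strictly decreasing ratios ending
#'   below `decline_ratio`), with the suitability context DEGRADED.
#' * **R5 SYSTEM_CHECK_NEEDED** - the same intensity evidence as R4 but the
#'   suitability context is OK or UNKNOWN: queue suitability runs to
#'   confirm before blaming the instrument.
#'
#' @param summary One row of a `run_iqc_summary`.
#' @param prev List of the immediately preceding summaries (most recent
#'   last), or `NULL`; used for the decline test and the R3 neighbor check.
#' @param nxt The following summary, or `NULL`.
#' @param config A `triage_config`.
#' @return A list of class `triage_call`: `run_id`, `call`, `rule_id`,
#'   `evidence`.
#' @export
classify_run <- function(summary, prev = NULL, nxt = NULL,
                         config = triage_config()) {
  s <- as.list(summary)
  cfg <- config
  has <- function(x) !is.null(x) && !is.na(x)
  call <- "PASS"; rule <- NA_character_; evidence <- list()

  ratios_ok <- (has(s$eno_ratio) && s$eno_ratio >= cfg$low_ratio) &&
    (has(s$prtc_ratio) && s$prtc_ratio >= cfg$low_ratio)

  prtc_declining <- FALSE
  if (has(s$prtc_ratio) && length(prev) >= cfg$decline_runs - 1) {
    recent <- vapply(tail(prev, cfg$decline_runs - 1),
                     function(p) p$prtc_ratio, numeric(1))
    seq_r <- c(recent, s$prtc_ratio)
    if (!anyNA(seq_r))
      prtc_declining <- all(diff(seq_r) < 0) &&
        s$prtc_ratio < cfg$decline_ratio
  }
  prtc_low <- has(s$prtc_ratio) && s$prtc_ratio < cfg$low_ratio
  intensity_evidence <- prtc_low || prtc_declining

  if (has(s$min_idotp) && s$min_idotp < cfg$idotp_min && ratios_ok) {
    call <- "ISOTOPE_ENVELOPE_LOSS"; rule <- "R1"
    evidence <- list(min_idotp = s$min_idotp, idotp_min = cfg$idotp_min,
                     eno_ratio = s$eno_ratio, prtc_ratio = s$prtc_ratio)
  } else if (has(s$eno_ratio) && s$eno_ratio < cfg$low_ratio &&
             has(s$prtc_z) && abs(s$prtc_z) <= cfg$z_tol) {
    call <- "SAMPLE_PREP_FAILURE"; rule <- "R2"
    evidence <- list(eno_ratio = s$eno_ratio, prtc_z = s$prtc_z)
  } else if (has(s$eno_ratio) && s$eno_ratio < cfg$low_ratio &&
             prtc_low && has(s$rt_shift_min) &&
             abs(s$rt_shift_min) > cfg$rt_tol &&
             ratio_passlike(if (length(prev) > 0) prev[[length(prev)]] else NULL,
                            cfg$low_ratio) &&
             ratio_passlike(nxt, cfg$low_ratio)) {
    call <- "INJECTION_LC_EVENT"; rule <- "R3"
    evidence <- list(eno_ratio = s$eno_ratio, prtc_ratio = s$prtc_ratio,
                     rt_shift_min = s$rt_shift_min)
  } else if (intensity_evidence && identical(s$ss_status, "DEGRADED")) {
    call <- "MS_SENSITIVITY_LOSS"; rule <- "R4"
    evidence <- list(prtc_ratio = s$prtc_ratio, declining = prtc_declining,
                     ss_status = s$ss_status)
  } else if (intensity_evidence && s$ss_status %in% c("OK", "UNKNOWN")) {
    call <- "SYSTEM_CHECK_NEEDED"; rule <- "R5"
    evidence <- list(prtc_ratio = s$prtc_ratio, declining = prtc_declining,
                     ss_status = s$ss_status)
  }
  structure(list(run_id = s$run_id, call = call, rule_id = rule,
                 evidence = evidence),
            class = "triage_call")
}

#' Triage every sample run of an experiment
#'
#' Builds baselines (unless supplied), summarizes internal QCs per run, and
#' applies the ordered rules of [classify_run()] to each run in acquisition
#' order. Deterministic given its inputs.
#'
#' @param table A `measurement_table`.
#' @param runlog A `run_log`.
#' @param baselines Optional `qc_baseline_set`; built from the data when
#'   `NULL`.
#' @param config A `triage_config`.
#' @return A list of class `triage_report`: `calls` (tibble: run_id,
#'   acquired_at, call, rule_id, evidence list-column), `summaries`,
#'   `ss_timeline`, and `batch_counts` of non-PASS calls per batch.
#' @export
triage_experiment <- function(table, runlog, baselines = NULL,
                              config = triage_config()) {
  if (is.null(baselines))
    baselines <- build_qc_baselines(table, runlog, first_k = config$first_k,
                                    min_guide = config$min_guide)
  summaries <- summarize_internal_qc(table, runlog, baselines, config)
  if (nrow(summaries) == 0) {
    warn("no sample or external-QC runs to triage; empty report")
    calls <- tibble(run_id = character(), acquired_at = as.POSIXct(character(), tz = "UTC"),
                    call = character(), rule_id = character(), evidence = list())
    return(structure(list(calls = calls, summaries = summaries,
                          ss_timeline = attr(summaries, "ss_timeline"),
                          batch_counts = tibble()),
                     class = "triage_report"))
  }
  n <- nrow(summaries)
  rows <- vector("list", n)
  summary_list <- lapply(seq_len(n), function(i) as.list(summaries[i, ]))
  for (i in seq_len(n)) {
    prev <- if (i > 1) summary_list[seq_len(i - 1)] else NULL
    nxt <- if (i < n) summary_list[[i + 1]] else NULL
    tc <- classify_run(summaries[i, ], prev = prev, nxt = nxt, config = config)
    rows[[i]] <- tibble(run_id = tc$run_id,
                        acquired_at = summaries$acquired_at[i],
                        call = tc$call,
                        rule_id = tc$rule_id,
                        evidence = list(tc$evidence))
  }
  calls <- do.call(rbind, rows)
  batch_map <- setNames(runlog$batch_id, runlog$run_id)
  calls$batch_id <- unname(batch_map[calls$run_id])
  nonpass <- calls[calls$call != "PASS", , drop = FALSE]
  batch_counts <- if (nrow(nonpass) > 0)
    as_tibble(as.data.frame(base::table(batch_id = nonpass$batch_id,
                                        call = nonpass$call),
                            stringsAsFactors = FALSE))
  else tibble(batch_id = character(), call = character(), Freq = integer())
  structure(list(calls = calls, summaries = summaries,
                 ss_timeline = attr(summaries, "ss_timeline"),
                 batch_counts = batch_counts),
            class = "triage_report")
}
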