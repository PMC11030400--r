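## spc: statistical-process-control chart suite over any metric series
## extracted from system-suitability (or internal-QC) runs.

new_metric_series <- function(points, metric, analyte_id, n_omitted = 0L) {
  structure(points, metric = metric, analyte_id = analyte_id,
            n_omitted = n_omitted,
            class = c("metric_series", class(tibble())))
}

new_chart_result <- function(df, chart, metric, analyte_id) {
  structure(df, chart = chart, metric = metric, analyte_id = analyte_id,
            class = c("chart_result", class(tibble())))
}

#' Extract a metric series for one analyte
#'
#' Pulls one tracked metric (areas, their ratio, retention time, mass error,
#' or idotp against the analyte's theoretical envelope) for a single analyte
#' across the selected run types, ordered by acquisition time.
#'
#' @param table A `measurement_table`.
#' @param runlog A `run_log`.
#' @param metric One of `"PRECURSOR_AREA"`, `"TRANSITION_AREA"`,
#'   `"AREA_RATIO"`, `"RT_MIN"`, `"MASS_ERROR_PPM"`, `"IDOTP"`.
#'   `AREA_RATIO` is precursor/transition; points with a zero or missing
#'   denominator are omitted and counted in the `n_omitted` attribute.
#'   `IDOTP` compares the observed M0..M+2 areas with the envelope derived
#'   from the peptide sequence (heavy-labeled for `PEPTIDE_IQC` analytes).
#' @param analyte_id Analyte identifier (`"PEPTIDE/charge"`).
#' @param run_types Character vector of run types to include.
#' @return A `metric_series` tibble with columns `run_id`, `acquired_at`,
#'   `value`.
#' @export
extract_metric <- function(table, runlog, metric, analyte_id,
                           run_types = "SYSTEM_SUITABILITY") {
  metric <- match.arg(metric, METRICS)
  run_types <- match.arg(run_types, RUN_TYPES, several.ok = TRUE)
  runs <- runlog$run_id[runlog$run_type %in% run_types]
  sub <- table[table$analyte_id == analyte_id & table$run_id %in% runs, , drop = FALSE]
  if (nrow(sub) == 0)
    stop_qcs(paste0("analyte ", analyte_id, " absent from all selected runs"),
             "qcs_empty_series_error")
  value <- switch(metric,
    PRECURSOR_AREA  = sub$precursor_area,
    TRANSITION_AREA = sub$transition_area,
    RT_MIN          = sub$rt_min,
    MASS_ERROR_PPM  = sub$mass_error_ppm,
    AREA_RATIO      = ifelse(!is.na(sub$transition_area) & sub$transition_area > 0,
                             sub$precursor_area / sub$transition_area, NA_real_),
    IDOTP           = idotp_series(sub)
  )
  keep <- !is.na(value)
  n_omitted <- sum(!keep)
  pts <- tibble(run_id = sub$run_id[keep],
                acquired_at = sub$acquired_at[keep],
                value = value[keep])
  pts <- pts[order(pts$acquired_at, pts$run_id, method = "radix"), , drop = FALSE]
  new_metric_series(pts, metric, analyte_id, n_omitted)
}

idotp_series <- function(sub) {
  seq_ <- sub$peptide[1]
  label <- if (sub$analyte_class[1] == "PEPTIDE_IQC")
    "LABEL_13C6_15N2_K_and_13C6_15N4_R" else "NONE"
  env <- isotope_distribution(peptide_composition(seq_, heavy_label = label), 3L)
  vapply(seq_len(nrow(sub)), function(i) {
    obs <- c(sub$iso_m0[i], sub$iso_m1[i], sub$iso_m2[i])
    if (anyNA(obs) || all(obs == 0)) return(NA_real_)
    idotp(env, obs)
  }, numeric(1))
}

#' Establish a guide-set baseline
#'
#' The initial runs of a series serve as the baseline against which later
#' runs are charted: the arithmetic mean and sample standard deviation
#' (n - 1 denominator) of the guide values.
#'
#' @param series A `metric_series`.
#' @param guide_runs Explicit run ids to use as the guide set; overrides
#'   `first_k`.
#' @param first_k Number of initial runs to use when `guide_runs` is `NULL`
#'   (default 10; fewer-than-`first_k` series are rejected).
#' @param min_guide Minimum acceptable guide-set size (default 5).
#' @return A `qc_baseline`: list with `mean`, `sd`, `n`, `guide_run_ids`.
#' @export
establish_baseline <- function(series, guide_runs = NULL, first_k = 10L,
                               min_guide = 5L) {
  if (is.null(guide_runs)) {
    if (nrow(series) < first_k)
      qcs_insufficient_error(paste0("series has ", nrow(series),
                                    " points; first_k = ", first_k,
                                    " guide runs requested"))
    guide_runs <- series$run_id[seq_len(first_k)]
  }
  vals <- series$value[series$run_id %in% guide_runs]
  if (length(vals) < min_guide)
    qcs_insufficient_error(paste0("only ", length(vals),
                                  " guide points; minimum is ", min_guide))
  structure(list(mean = mean(vals), sd = sd(vals), n = length(vals),
                 guide_run_ids = guide_runs),
            class = "qc_baseline")
}

#' Levey-Jennings chart
#'
#' Per-run z-scores against the baseline with a Westgard-style rule subset:
#' `1_3s` (FAIL when |z| > 3) and `2_2s` (WARN when this point and the
#' previous one sit on the same side of the mean with |z| > 2). With a
#' zero-SD baseline the chart degenerates to an exact-deviation rule: any
#' value different from the mean FAILs.
#'
#' @param series A `metric_series`.
#' @param baseline A `qc_baseline`.
#' @param rules Named list of rule settings: `fail_sigma` (default 3),
#'   `warn_sigma` (default 2).
#' @return A `chart_result` tibble with columns `run_id`, `value`, `z`,
#'   `flag`, `rule_fired`.
#' @export
levey_jennings <- function(series, baseline, rules = list()) {
  rules <- modifyList(list(fail_sigma = 3, warn_sigma = 2), rules)
  v <- series$value
  if (baseline$sd > 0) {
    z <- (v - baseline$mean) / baseline$sd
    flag <- rep("PASS", length(v))
    rule <- rep(NA_character_, length(v))
    fail <- abs(z) > rules$fail_sigma
    flag[fail] <- "FAIL"
    rule[fail] <- "1_3s"
    if (length(v) >= 2) {
      same_side <- sign(z[-1]) == sign(z[-length(z)])
      both_out <- abs(z[-1]) > rules$warn_sigma & abs(z[-length(z)]) > rules$warn_sigma
      warn <- c(FALSE, same_side & both_out) & !fail
      flag[warn] <- "WARN"
      rule[warn] <- "2_2s"
    }
  } else {
    z <- ifelse(v == baseline$mean, 0, Inf * sign(v - baseline$mean))
    flag <- ifelse(v == baseline$mean, "PASS", "FAIL")
    rule <- ifelse(v == baseline$mean, NA_character_, "exact_deviation")
  }
  new_chart_result(tibble(run_id = series$run_id, value = v, z = z,
                          flag = flag, rule_fired = rule),
                   "LEVEY_JENNINGS", attr(series, "metric"),
                   attr(series, "analyte_id"))
}

#' Tabular CUSUM chart
#'
#' Two-sided standardized cumulative sums with slack `k` and decision
#' interval `h`: `S+_i = max(0, S+_{i-1} + z_i - k)`,
#' `S-_i = max(0, S-_{i-1} - z_i - k)`, both starting at 0; a run FAILs when
#' either statistic exceeds `h`. The defaults (k = 0.5, h = 5) are the
#' common SPC choice tuned to detect sustained ~1 SD shifts.
#'
#' @param series A `metric_series`.
#' @param baseline A `qc_baseline` with `sd > 0`.
#' @param k Slack parameter (>= 0), in SD units.
#' @param h Decision interval (> 0), in SD units.
#' @return A `chart_result` with columns `run_id`, `value`, `z`,
#'   `cusum_pos`, `cusum_neg`, `flag`, `rule_fired`.
#' @export
cusum <- function(series, baseline, k = 0.5, h = 5) {
  if (k < 0 || h <= 0) qcs_argument_error("require k >= 0 and h > 0")
  if (baseline$sd <= 0) qcs_argument_error("CUSUM requires baseline sd > 0")
  z <- (series$value - baseline$mean) / baseline$sd
  n <- length(z)
  sp <- numeric(n); sn <- numeric(n)
  prev_p <- 0; prev_n <- 0
  for (i in seq_len(n)) {
    prev_p <- max(0, prev_p + z[i] - k)
    prev_n <- max(0, prev_n - z[i] - k)
    sp[i] <- prev_p; sn[i] <- prev_n
  }
  fail <- sp > h | sn > h
  new_chart_result(tibble(run_id = series$run_id, value = series$value, z = z,
                          cusum_pos = sp, cusum_neg = sn,
                          flag = ifelse(fail, "FAIL", "PASS"),
                          rule_fired = ifelse(fail, "cusum_h", NA_character_)),
                   "CUSUM", attr(series, "metric"), attr(series, "analyte_id"))
}

#' Moving-range chart
#'
#' `MR_i = |x_i - x_{i-1}|` for `i >= 2` (undefined, and flagged PASS, for
#' the first point). A point FAILs when its moving range exceeds
#' `3.267 * mean(MR)`, the standard individuals-chart upper limit (D4 for
#' n = 2 subgroups). When a baseline is supplied, `mean(MR)` is computed
#' over the guide-set region only; otherwise over the whole series.
#'
#' @param series A `metric_series` with at least 2 points.
#' @param baseline Optional `qc_baseline` identifying the guide region.
#' @return A `chart_result` with columns `run_id`, `value`, `moving_range`,
#'   `flag`, `rule_fired`, plus attributes `mr_mean` and `mr_limit`.
#' @export
moving_range <- function(series, baseline = NULL) {
  v <- series$value
  if (length(v) < 2)
    qcs_insufficient_error("moving range needs at least 2 points")
  mr <- c(NA_real_, abs(diff(v)))
  if (!is.null(baseline)) {
    in_guide <- series$run_id %in% baseline$guide_run_ids
    ## MR_i belongs to the guide region when both endpoints do
    use <- in_guide & c(FALSE, in_guide[-length(in_guide)])
    if (sum(use) < 1)
      qcs_insufficient_error("guide region yields no moving ranges")
    mr_mean <- mean(mr[use])
  } else {
    mr_mean <- mean(mr[-1])
  }
  limit <- 3.267 * mr_mean
  fail <- !is.na(mr) & mr > limit
  out <- new_chart_result(tibble(run_id = series$run_id, value = v,
                                 moving_range = mr,
                                 flag = ifelse(fail, "FAIL", "PASS"),
                                 rule_fired = ifelse(fail, "mr_3.267", NA_character_)),
                          "MOVING_RANGE", attr(series, "metric"),
                          attr(series, "analyte_id"))
  attr(out, "mr_mean") <- mr_mean
  attr(out, "mr_limit") <- limit
  out
}

#' Trailing mean and trailing CV
#'
#' For each run `i >= window`, the mean and CV% of the values in the window
#' ending at run `i` (the current run and the `window - 1` before it,
#' mirroring a "trailing CV of the previous 5 replicates" dashboard).
#' `CV% = 100 * sd / mean` with the sample (n - 1) SD, the same convention
#' as [establish_baseline()]. Runs before the first full window carry no
#' statistic. The trailing-CV chart FAILs when CV% exceeds
#' `cv_fail_threshold`.
#'
#' @param series A `metric_series` with at least 2 points.
#' @param window Window length (default 5, >= 2).
#' @param cv_fail_threshold FAIL threshold on trailing CV%, default 20.
#' @return A list with elements `trailing_mean` and `trailing_cv`, each a
#'   `chart_result` with one record per input point.
#' @export
trailing_stats <- function(series, window = 5L, cv_fail_threshold = 20) {
  if (!is.numeric(window) || window < 2) qcs_argument_error("window must be >= 2")
  window <- as.integer(window)
  v <- series$value
  n <- length(v)
  tmean <- rep(NA_real_, n); tcv <- rep(NA_real_, n)
  if (n < window) {
    warn(paste0("series has ", n, " points; no window of ", window, " is defined"))
  } else {
    for (i in window:n) {
      w <- v[(i - window + 1):i]
      m <- mean(w)
      s <- sd(w)
      tmean[i] <- m
      tcv[i] <- if (m != 0) 100 * s / abs(m) else NA_real_
    }
  }
  mean_res <- new_chart_result(
    tibble(run_id = series$run_id, value = v, statistic = tmean,
           flag = rep("PASS", n), rule_fired = rep(NA_character_, n)),
    "TRAILING_MEAN", attr(series, "metric"), attr(series, "analyte_id"))
  fail <- !is.na(tcv) & tcv > cv_fail_threshold
  cv_res <- new_chart_result(
    tibble(run_id = series$run_id, value = v, statistic = tcv,
           flag = ifelse(fail, "FAIL", "PASS"),
           rule_fired = ifelse(fail, "trailing_cv", NA_character_)),
    "TRAILING_CV", attr(series, "metric"), attr(series, "analyte_id"))
  list(trailing_mean = mean_res, trailing_cv = cv_res)
}
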