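## quantnorm: the level-1 (raw) -> level-2 (log2, median-normalized) ->
## level-3 (batch-adjusted) data ladder, and external-QC CV assessment.

new_quant_matrix <- function(values, level, batch_of, analyte_kind,
                             provenance = character()) {
  structure(values, level = level, batch_of = batch_of,
            analyte_kind = analyte_kind, provenance = provenance,
            class = c("quant_matrix", "matrix", "array"))
}

#' Construct a quant matrix from user data
#'
#' Wraps an analytes x runs numeric matrix with the metadata the ladder
#' functions need. Level-1 matrices hold linear-scale areas; levels 2-3 are
#' log2.
#'
#' @param values Numeric matrix with analyte rownames and run colnames.
#' @param level `"L1_RAW"`, `"L2_NORMALIZED"` or `"L3_BATCH_ADJUSTED"`.
#' @param batch_of Named character vector, run id -> batch id, covering all
#'   columns.
#' @param analyte_kind `"PEPTIDE"` or `"PROTEIN"`.
#' @return A `quant_matrix`.
#' @export
quant_matrix <- function(values, level = "L1_RAW", batch_of = NULL,
                         analyte_kind = "PEPTIDE") {
  level <- match.arg(level, c("L1_RAW", "L2_NORMALIZED", "L3_BATCH_ADJUSTED"))
  analyte_kind <- match.arg(analyte_kind, c("PEPTIDE", "PROTEIN"))
  if (is.null(colnames(values)) || is.null(rownames(values)))
    qcs_argument_error("values must have analyte rownames and run colnames")
  if (is.null(batch_of)) batch_of <- setNames(rep("B1", ncol(values)), colnames(values))
  if (!all(colnames(values) %in% names(batch_of)))
    qcs_validation_error("batch_of must map every run (column) to a batch")
  if (level == "L1_RAW" && any(values < 0, na.rm = TRUE))
    qcs_validation_error("level-1 values must be non-negative or missing")
  new_quant_matrix(values, level, batch_of[colnames(values)], analyte_kind,
                   provenance = paste0("user-supplied ", level, " matrix"))
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d analytes x %d runs, level %s, kind %s\n",
              nrow(x), ncol(x), attr(x, "level"), attr(x, "analyte_kind")))
  for (p in attr(x, "provenance")) cat("# ", p, "\n", sep = "")
  invisible(x)
}

#' Build a level-1 abundance matrix
#'
#' Collects one quantity per (analyte, run) into an analytes x runs matrix
#' of linear-scale areas. Unmeasured cells are missing; zero areas are also
#' recorded as missing, since a zero from the integration software means
#' "nothing integrated", not a measured abundance of zero.
#'
#' @param table A `measurement_table`.
#' @param runlog A `run_log`.
#' @param run_filter Run types to include (default the inter-batch external
#'   QC runs).
#' @param quantity `"TRANSITION_AREA"` (default) or `"PRECURSOR_AREA"`.
#' @param analyte_classes Analyte classes to include (default
#'   `"ENDOGENOUS"`).
#' @return A `quant_matrix` at level `L1_RAW` with a run -> batch map.
#' @export
build_matrix <- function(table, runlog, run_filter = "EXTERNAL_QC_INTERBATCH",
                         quantity = c("TRANSITION_AREA", "PRECURSOR_AREA"),
                         analyte_classes = "ENDOGENOUS") {
  quantity <- match.arg(quantity)
  runs <- runlog[runlog$run_type %in% run_filter, , drop = FALSE]
  sub <- table[table$run_id %in% runs$run_id &
                 table$analyte_class %in% analyte_classes, , drop = FALSE]
  if (nrow(runs) < 2 || nrow(sub) == 0)
    qcs_validation_error("matrix requires >= 2 selected runs and >= 1 analyte")
  analytes <- sort(unique(sub$analyte_id))
  run_ids <- runs$run_id
  m <- matrix(NA_real_, nrow = length(analytes), ncol = length(run_ids),
              dimnames = list(analytes, run_ids))
  v <- if (quantity == "TRANSITION_AREA") sub$transition_area else sub$precursor_area
  v[!is.na(v) & v == 0] <- NA_real_
  m[cbind(match(sub$analyte_id, analytes), match(sub$run_id, run_ids))] <- v
  new_quant_matrix(m, "L1_RAW", setNames(runs$batch_id, runs$run_id), "PEPTIDE",
                   provenance = paste0("level 1: raw ", tolower(quantity)))
}

#' Log2 transform and median-normalize (level 2)
#'
#' `v' = log2(v)`, then each run (column) is shifted by
#' `-(run median - grand median of run medians)`, so every run's median of
#' observed values equals the grand median. Re-centering on the grand median
#' rather than zero keeps values in the original intensity register.
#'
#' @param m A `quant_matrix` at level `L1_RAW`.
#' @param min_obs Minimum non-missing values a run must have (default 10).
#' @return A `quant_matrix` at level `L2_NORMALIZED` (log2 scale).
#' @export
log2_median_normalize <- function(m, min_obs = 10L) {
  if (attr(m, "level") != "L1_RAW")
    qcs_argument_error("log2_median_normalize expects a level-1 matrix")
  n_obs <- colSums(!is.na(m))
  low <- colnames(m)[n_obs < min_obs]
  if (length(low) > 0)
    qcs_validation_error(paste0("run(s) below min_obs = ", min_obs, ": ",
                                paste(low, collapse = ", ")))
  lv <- log2(unclass(m))
  med <- apply(lv, 2, median, na.rm = TRUE)
  grand <- median(med)
  lv <- sweep(lv, 2, med - grand, "-")
  new_quant_matrix(lv, "L2_NORMALIZED", attr(m, "batch_of"),
                   attr(m, "analyte_kind"),
                   provenance = c(attr(m, "provenance"),
                                  "level 2: log2, per-run median-normalized"))
}

#' Batch adjustment by per-analyte location (level 3)
#'
#' For each analyte, subtracts the batch mean and adds back the analyte's
#' grand mean: a transparent location-only batch correction. Within-batch,
#' per-analyte variances are untouched; per-analyte batch means become
#' equal and the analyte grand means are preserved. With
#' `scale_adjust = TRUE`, within-batch deviations are additionally rescaled
#' to equalize batch SDs.
#'
#' @param m A `quant_matrix` at level `L2_NORMALIZED`.
#' @param min_per_cell Minimum observations per (analyte, batch) cell for
#'   that analyte to be adjusted (default 2); analytes failing the threshold
#'   pass through unadjusted and are listed in the `unadjusted` attribute.
#' @param scale_adjust Also equalize batch SDs (default `FALSE`).
#' @return A `quant_matrix` at level `L3_BATCH_ADJUSTED`.
#' @export
batch_adjust <- function(m, min_per_cell = 2L, scale_adjust = FALSE) {
  if (attr(m, "level") != "L2_NORMALIZED")
    qcs_argument_error("batch_adjust expects a level-2 matrix")
  batch_of <- attr(m, "batch_of")
  batches <- unique(batch_of[colnames(m)])
  out <- unclass(m)
  if (length(batches) < 2) {
    warn("single batch: batch adjustment is a no-op")
    return(new_quant_matrix(out, "L3_BATCH_ADJUSTED", batch_of,
                            attr(m, "analyte_kind"),
                            provenance = c(attr(m, "provenance"),
                                           "level 3: single batch, no adjustment")))
  }
  bcols <- lapply(setNames(batches, batches),
                  function(b) which(batch_of[colnames(m)] == b))
  unadjusted <- character()
  for (a in seq_len(nrow(out))) {
    row <- out[a, ]
    cell_n <- vapply(bcols, function(ix) sum(!is.na(row[ix])), integer(1))
    if (any(cell_n > 0 & cell_n < min_per_cell) || sum(cell_n >= min_per_cell) < 2) {
      unadjusted <- c(unadjusted, rownames(out)[a])
      next
    }
    grand <- mean(row, na.rm = TRUE)
    for (b in batches) {
      ix <- bcols[[b]]
      bm <- mean(row[ix], na.rm = TRUE)
      if (is.nan(bm)) next
      if (scale_adjust) {
        bs <- sd(row[ix], na.rm = TRUE)
        pooled <- sd(row - ave_by_batch(row, bcols), na.rm = TRUE)
        if (!is.na(bs) && bs > 0 && !is.na(pooled) && pooled > 0)
          row[ix] <- (row[ix] - bm) * (pooled / bs) + grand
        else row[ix] <- row[ix] - bm + grand
      } else {
        row[ix] <- row[ix] - bm + grand
      }
    }
    out[a, ] <- row
  }
  res <- new_quant_matrix(out, "L3_BATCH_ADJUSTED", batch_of,
                          attr(m, "analyte_kind"),
                          provenance = c(attr(m, "provenance"),
                                         "level 3: per-analyte batch mean-centering"))
  attr(res, "unadjusted") <- unadjusted
  res
}

ave_by_batch <- function(row, bcols) {
  out <- row
  for (ix in bcols) out[ix] <- mean(row[ix], na.rm = TRUE)
  out
}

#' Roll peptides up to proteins
#'
#' Protein abundance per run is the mean of the protein's observed peptide
#' log2 values (levels 2-3), or the sum of linear peptide areas (level 1).
#' The rollup method is recorded in the matrix provenance; protein-level
#' results are comparable only within one rollup scheme.
#'
#' @param m A `quant_matrix`.
#' @param mapping Named character vector: peptide analyte_id -> protein id.
#' @param min_peptides Proteins with fewer mapped peptides are dropped
#'   (default 1).
#' @return A `quant_matrix` with `analyte_kind = "PROTEIN"`.
#' @export
rollup_proteins <- function(m, mapping, min_peptides = 1L) {
  if (length(mapping) == 0) qcs_argument_error("empty peptide->protein mapping")
  peptides <- intersect(rownames(m), names(mapping))
  if (length(peptides) == 0) qcs_argument_error("mapping covers no peptide in the matrix")
  prots <- split(peptides, mapping[peptides])
  prots <- prots[vapply(prots, length, integer(1)) >= min_peptides]
  if (length(prots) == 0) qcs_validation_error("no protein retains min_peptides peptides")
  level <- attr(m, "level")
  vals <- unclass(m)
  out <- t(vapply(prots, function(peps) {
    block <- vals[peps, , drop = FALSE]
    if (level == "L1_RAW") {
      s <- colSums(block, na.rm = TRUE)
      s[colSums(!is.na(block)) == 0] <- NA_real_
      s
    } else {
      colMeans(block, na.rm = TRUE)
    }
  }, numeric(ncol(vals))))
  out[is.nan(out)] <- NA_real_
  method <- if (level == "L1_RAW") "protein rollup: sum of linear peptide areas"
            else "protein rollup: mean of peptide log2 values"
  new_quant_matrix(out, level, attr(m, "batch_of"), "PROTEIN",
                   provenance = c(attr(m, "provenance"), method))
}

#' Per-analyte coefficients of variation
#'
#' CVs are computed on the linear scale: log2-level matrices are
#' back-transformed (`2^v`) first, then `CV% = 100 * sd / mean` with the
#' sample SD. `cv_method = "geometric"` instead uses the log-normal closed
#' form `100 * sqrt(exp((s * ln 2)^2) - 1)` on the log2-scale SD. The
#' summary statistic eta is the median CV% over analytes with at least
#' `min_obs` observations.
#'
#' @param m A `quant_matrix`.
#' @param runs Run ids to use (default: all columns).
#' @param scope `"INTER_BATCH"`, `"INTRA_BATCH"` (one CV per analyte per
#'   batch) or `"INTER_EXPERIMENT"`.
#' @param min_obs Minimum observations per CV cell (default 3).
#' @param cv_method `"linear"` (default) or `"geometric"`.
#' @return A tibble of class `cv_table` with columns `analyte_id`, `scope`,
#'   `batch_id`, `cv_percent`, `log2_median_abundance`, `n_obs`, and
#'   attribute `median_cv_eta`.
#' @export
compute_cv <- function(m, runs = NULL,
                       scope = c("INTER_BATCH", "INTRA_BATCH", "INTER_EXPERIMENT"),
                       min_obs = 3L, cv_method = c("linear", "geometric")) {
  scope <- match.arg(scope)
  cv_method <- match.arg(cv_method)
  runs <- runs %||% colnames(m)
  runs <- intersect(colnames(m), runs)
  if (length(runs) < 2) qcs_insufficient_error("CV needs >= 2 runs in the subset")
  vals <- unclass(m)[, runs, drop = FALSE]
  on_log2 <- attr(m, "level") != "L1_RAW"
  lin <- if (on_log2) 2^vals else vals
  lg <- if (on_log2) vals else log2(vals)
  groups <- if (scope == "INTRA_BATCH") {
    b <- attr(m, "batch_of")[runs]
    split(runs, b)
  } else list(all = runs)
  rows <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (length(cols) < 2) qcs_insufficient_error(
      paste0("scope cell '", g, "' has < 2 runs"))
    sub_lin <- lin[, cols, drop = FALSE]
    sub_lg <- lg[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub_lin))
    cv <- vapply(seq_len(nrow(sub_lin)), function(a) {
      x <- sub_lin[a, ]
      x <- x[!is.na(x)]
      if (length(x) < 2) return(NA_real_)
      if (cv_method == "linear") 100 * sd(x) / mean(x)
      else {
        s <- sd(log2(x))
        100 * sqrt(exp((s * log(2))^2) - 1)
      }
    }, numeric(1))
    med_ab <- apply(sub_lg, 1, median, na.rm = TRUE)
    gbatch <- if (scope == "INTRA_BATCH") g else NA_character_
    rows[[g]] <- tibble(analyte_id = rownames(vals), scope = scope,
                        batch_id = gbatch,
                        cv_percent = cv, log2_median_abundance = med_ab,
                        n_obs = as.integer(n_obs))
  }
  out <- do.call(rbind, rows)
  eligible <- out$n_obs >= min_obs & !is.na(out$cv_percent)
  eta <- if (any(eligible)) median(out$cv_percent[eligible]) else NA_real_
  structure(out, median_cv_eta = eta, analyte_kind = attr(m, "analyte_kind"),
            level = attr(m, "level"),
            class = c("cv_table", class(tibble())))
}

#' Smoothed CV-versus-abundance curve
#'
#' Locally weighted linear regression (tricube weights, one robustness
#' iteration) of CV% on log2 median abundance, evaluated on a 100-point grid
#' spanning the observed abundance range. Deterministic.
#'
#' @param cvt A `cv_table` with at least 10 analytes.
#' @param span Fraction of points in each local fit (default 0.5).
#' @return A tibble with columns `abundance`, `cv_smooth`.
#' @export
cv_abundance_curve <- function(cvt, span = 0.5) {
  ok <- !is.na(cvt$cv_percent) & !is.na(cvt$log2_median_abundance)
  x <- cvt$log2_median_abundance[ok]
  y <- cvt$cv_percent[ok]
  if (length(x) < 10)
    qcs_insufficient_error("fewer than 10 analytes; plot the raw scatter instead")
  fit <- lowess(x, y, f = span, iter = 1)
  grid <- seq(min(x), max(x), length.out = 100)
  sm <- approx(fit$x, fit$y, xout = grid, rule = 2, ties = mean)$y
  tibble(abundance = grid, cv_smooth = sm)
}

#' Compare the data ladder across levels
#'
#' Computes a CV table per level on the shared QC runs and tabulates the
#' median CV (eta) per level with pairwise deltas, flagging any transition
#' that increased eta.
#'
#' @param l1,l2,l3 `quant_matrix` objects at levels 1, 2, 3 sharing analytes
#'   and runs.
#' @param runs Run ids to use (default: all shared columns).
#' @param scope Passed to [compute_cv()].
#' @param min_obs Passed to [compute_cv()].
#' @return A list of class `level_comparison`: `eta` (tibble level x eta),
#'   `deltas`, `cv_tables`, `flags`.
#' @export
assess_levels <- function(l1, l2, l3, runs = NULL, scope = "INTER_BATCH",
                          min_obs = 3L) {
  mats <- list(L1_RAW = l1, L2_NORMALIZED = l2, L3_BATCH_ADJUSTED = l3)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1)
    qcs_validation_error("level matrices have mismatched shapes")
  cvts <- lapply(mats, compute_cv, runs = runs, scope = scope, min_obs = min_obs)
  eta <- vapply(cvts, attr, numeric(1), which = "median_cv_eta")
  eta_tbl <- tibble(level = names(eta), median_cv_eta = unname(eta))
  deltas <- tibble(
    transition = c("L1->L2", "L2->L3", "L1->L3"),
    delta_eta = c(eta[["L2_NORMALIZED"]] - eta[["L1_RAW"]],
                  eta[["L3_BATCH_ADJUSTED"]] - eta[["L2_NORMALIZED"]],
                  eta[["L3_BATCH_ADJUSTED"]] - eta[["L1_RAW"]]))
  flags <- deltas$transition[!is.na(deltas$delta_eta) & deltas$delta_eta > 0]
  structure(list(eta = eta_tbl, deltas = deltas, cv_tables = cvts,
                 flags = flags, scope = scope),
            class = "level_comparison")
}

#' Write a quant matrix as TSV with provenance headers
#'
#' @param table A `quant_matrix`.
#' @param path Output path.
#' @param format Only `"TSV"` is supported for matrices.
#' @export
write_table.quant_matrix <- function(table, path, format = "TSV") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# level: ", attr(table, "level")), con)
  writeLines(paste0("# analyte_kind: ", attr(table, "analyte_kind")), con)
  for (p in attr(table, "provenance")) writeLines(paste0("# ", p), con)
  writeLines(paste0("# batches: ",
                    paste(paste0(names(attr(table, "batch_of")), "=",
                                 attr(table, "batch_of")), collapse = ",")), con)
  writeLines(paste(c("analyte_id", colnames(table)), collapse = "\t"), con)
  vals <- unclass(table)
  for (i in seq_len(nrow(vals))) {
    row <- format_number(vals[i, ])
    row[is.na(row)] <- ""
    writeLines(paste(c(rownames(vals)[i], row), collapse = "\t"), con)
  }
  invisible(path)
}
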