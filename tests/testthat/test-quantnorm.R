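test_that("build_matrix records unmeasured and zero cells as missing", {
  f <- write_tmp_lines(c(
    paste(c("run_id", "acquired_at", "peptide", "precursor_charge",
            "analyte_class", "precursor_area", "transition_area", "rt_min",
            "mass_error_ppm", "iso_m0", "iso_m1", "iso_m2"), collapse = "\t"),
    "Q1\t2024-01-01T00:00:00Z\tPEPA\t2\tENDOGENOUS\t10\t100\t5\t0\t\t\t",
    "Q1\t2024-01-01T00:00:00Z\tPEPB\t2\tENDOGENOUS\t10\t200\t6\t0\t\t\t",
    "Q2\t2024-01-01T01:00:00Z\tPEPA\t2\tENDOGENOUS\t10\t0\t5\t0\t\t\t"))
  tab <- parse_measurement_report(f)
  log <- validate_run_log(tibble::tibble(
    run_id = c("Q1", "Q2"),
    acquired_at = as.POSIXct(c("2024-01-01 00:00", "2024-01-01 01:00"), tz = "UTC"),
    run_type = "EXTERNAL_QC_INTERBATCH", batch_id = "B1"))
  m <- build_matrix(tab, log)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["PEPA/2", "Q1"], 100)
  expect_true(is.na(m["PEPA/2", "Q2"]))   # zero area -> missing, not 0
  expect_true(is.na(m["PEPB/2", "Q2"]))   # unmeasured -> missing
  expect_error(build_matrix(tab, log, run_filter = "SAMPLE"),
               class = "qcs_validation_error")
})

test_that("median normalization equalizes run medians and removes scale", {
  withr::with_seed(8, {
    vals <- matrix(2^rnorm(50 * 12, 20, 1), 50, 12,
                   dimnames = list(paste0("A", 1:50), paste0("R", 1:12)))
    m <- quant_matrix(vals)
    l2 <- log2_median_normalize(m)
    med <- apply(unclass(l2), 2, median)
    expect_lt(max(abs(med - median(med))), 1e-9)
    expect_equal(attr(l2, "level"), "L2_NORMALIZED")

    # a run scaled by 2x becomes identical to the original after normalization
    two <- vals[, 1, drop = FALSE] * 2
    m2 <- quant_matrix(cbind(vals[, 1, drop = FALSE], R2 = two[, 1]))
    l2b <- log2_median_normalize(m2)
    expect_equal(unname(unclass(l2b)[, 1]), unname(unclass(l2b)[, 2]),
                 tolerance = 1e-12)

    # centering is idempotent
    back <- quant_matrix(2^unclass(l2), batch_of = attr(l2, "batch_of"))
    l2c <- log2_median_normalize(back)
    expect_equal(unclass(l2c), unclass(l2), tolerance = 1e-12)
  })
  small <- quant_matrix(matrix(1:6, 3, 2, dimnames = list(letters[1:3], c("r1", "r2"))))
  err <- tryCatch(log2_median_normalize(small), error = identity)
  expect_s3_class(err, "qcs_validation_error")
  expect_match(conditionMessage(err), "r1")
})

test_that("batch adjustment removes location offsets and nothing else", {
  withr::with_seed(13, {
    vals <- matrix(rnorm(40 * 8, 20, 1), 40, 8,
                   dimnames = list(paste0("A", 1:40), paste0("R", 1:8)))
    batch <- setNames(rep(c("B1", "B2"), each = 4), colnames(vals))

    # identical batches: unchanged
    dup <- vals
    dup[, 5:8] <- dup[, 1:4]
    m <- quant_matrix(dup, level = "L2_NORMALIZED", batch_of = batch)
    expect_equal(unclass(batch_adjust(m)), unclass(m), tolerance = 1e-12,
                 ignore_attr = TRUE)

    # a pure +1 log2 offset on batch 2 is removed exactly
    shifted <- vals; shifted[, 5:8] <- shifted[, 1:4] + 1
    m <- quant_matrix(shifted, level = "L2_NORMALIZED", batch_of = batch)
    l3 <- batch_adjust(m)
    b1 <- rowMeans(unclass(l3)[, 1:4]); b2 <- rowMeans(unclass(l3)[, 5:8])
    expect_lt(max(abs(b1 - b2)), 1e-9)
    expect_equal(rowMeans(unclass(l3)), rowMeans(shifted), tolerance = 1e-9)
    # within-batch variances are untouched (location shift only)
    expect_equal(apply(unclass(l3)[, 1:4], 1, var),
                 apply(shifted[, 1:4], 1, var), tolerance = 1e-12)

    # single batch: warning no-op
    m1 <- quant_matrix(vals, level = "L2_NORMALIZED",
                       batch_of = setNames(rep("B1", 8), colnames(vals)))
    expect_warning(l3b <- batch_adjust(m1), "single batch")
    expect_equal(unclass(l3b), unclass(m1), ignore_attr = TRUE)
  })
})

test_that("injected batch offsets are recovered within the analytic SE", {
  # 8 batches x 12 QC runs, per-analyte offsets ~ N(0, 0.5^2), within-batch
  # SD 0.2: the batch-mean estimator has SE 0.2/sqrt(12) = 0.058, so the
  # RMSE of the recovered (centered) offsets should sit near
  # 0.058 * sqrt(7/8) = 0.054, comfortably below 0.07.
  withr::with_seed(99, {
    n_an <- 50; n_b <- 8; n_r <- 12
    runs <- paste0("R", seq_len(n_b * n_r))
    batch <- setNames(rep(paste0("B", 1:n_b), each = n_r), runs)
    offsets <- matrix(rnorm(n_an * n_b, 0, 0.5), n_an, n_b)
    base <- rnorm(n_an, 20, 1)
    vals <- base + offsets[, rep(1:n_b, each = n_r)] +
      matrix(rnorm(n_an * n_b * n_r, 0, 0.2), n_an)
    dimnames(vals) <- list(paste0("A", 1:n_an), runs)
    m <- quant_matrix(vals, level = "L2_NORMALIZED", batch_of = batch)
    l3 <- batch_adjust(m)
    est <- unclass(m) - unclass(l3)                    # removed batch effect
    est_b <- t(apply(est, 1, function(r) tapply(r, batch, mean)))
    truth <- offsets - rowMeans(offsets)               # identifiable part
    rmse <- sqrt(mean((est_b[, paste0("B", 1:n_b)] - truth)^2))
    expect_lt(rmse, 0.07)
  })
})

test_that("protein rollup averages log2 peptides and sums linear areas", {
  vals <- matrix(c(10, 12, 11, 13, 20, 21), 3, 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("r1", "r2")))
  m2 <- quant_matrix(vals, level = "L2_NORMALIZED")
  mapping <- c(p1 = "PROT1", p2 = "PROT1", p3 = "PROT2")
  pr <- rollup_proteins(m2, mapping)
  expect_equal(attr(pr, "analyte_kind"), "PROTEIN")
  expect_equal(unname(unclass(pr)["PROT1", ]), c(10.5, 12.5))  # mean of 10,11 / 12,13
  expect_equal(unname(unclass(pr)["PROT2", ]), c(20, 21))      # single peptide

  lin <- quant_matrix(2^vals)
  pr1 <- rollup_proteins(lin, mapping)
  expect_equal(unname(unclass(pr1)["PROT1", 1]), 2^10 + 2^11)  # linear sum
  expect_error(rollup_proteins(m2, character(0)), class = "qcs_argument_error")
})

test_that("protein-level CV does not exceed the worst peptide CV (averaging)", {
  withr::with_seed(17, {
    wins <- 0
    for (i in 1:500) {
      vals <- matrix(rnorm(3 * 10, 20, 0.3), 3, 10,
                     dimnames = list(c("p1", "p2", "p3"), paste0("r", 1:10)))
      m <- quant_matrix(vals, level = "L2_NORMALIZED")
      pr <- rollup_proteins(m, c(p1 = "P", p2 = "P", p3 = "P"))
      cvs <- compute_cv(m, min_obs = 2L)$cv_percent
      cvp <- compute_cv(pr, min_obs = 2L)$cv_percent
      if (cvp <= max(cvs)) wins <- wins + 1
    }
    expect_gte(wins / 500, 0.95)
  })
})

test_that("CVs follow the linear-scale definition and its invariances", {
  vals <- matrix(c(90, 100, 110, 50, 50, 50), 2, 3, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("r1", "r2", "r3")))
  cvt <- compute_cv(quant_matrix(vals), min_obs = 3L)
  expect_equal(cvt$cv_percent[cvt$analyte_id == "a"], 10)  # sd 10, mean 100
  expect_equal(cvt$cv_percent[cvt$analyte_id == "b"], 0)
  expect_equal(attr(cvt, "median_cv_eta"), 5)

  # invariant to global positive rescaling of linear values
  cvt2 <- compute_cv(quant_matrix(vals * 37), min_obs = 3L)
  expect_equal(cvt2$cv_percent, cvt$cv_percent, tolerance = 1e-12)

  # intra-batch scope computes one CV per analyte per batch
  batch <- setNames(c("B1", "B1", "B2"), colnames(vals))
  err <- tryCatch(compute_cv(quant_matrix(vals, batch_of = batch),
                             scope = "INTRA_BATCH"), error = identity)
  expect_s3_class(err, "qcs_insufficient_data_error")  # B2 has one run
  vals4 <- cbind(vals, r4 = c(105, 50))
  batch4 <- setNames(c("B1", "B1", "B2", "B2"), colnames(vals4))
  cvt3 <- compute_cv(quant_matrix(vals4, batch_of = batch4), scope = "INTRA_BATCH",
                     min_obs = 2L)
  expect_equal(nrow(cvt3), 4)
  expect_setequal(unique(cvt3$batch_id), c("B1", "B2"))

  # geometric CV agrees with the log-normal closed form on log-constant data
  l2 <- quant_matrix(matrix(c(10, 11, 12, 10, 11, 12), 2, 3, byrow = TRUE,
                            dimnames = list(c("a", "b"), c("r1", "r2", "r3"))),
                     level = "L2_NORMALIZED")
  g <- compute_cv(l2, min_obs = 3L, cv_method = "geometric")
  expect_equal(g$cv_percent[1], 100 * sqrt(exp((1 * log(2))^2) - 1),
               tolerance = 1e-9)
})

test_that("the smoothed CV-abundance curve reproduces flat and linear truths", {
  withr::with_seed(3, {
    ab <- sort(runif(60, 10, 25))
    flat <- tibble::tibble(analyte_id = paste0("a", 1:60), scope = "INTER_BATCH",
                           batch_id = NA_character_, cv_percent = rep(12, 60),
                           log2_median_abundance = ab, n_obs = 10L)
    curve <- cv_abundance_curve(flat)
    expect_lt(max(abs(curve$cv_smooth - 12)), 1e-6)

    lin <- flat
    lin$cv_percent <- 40 - ab
    curve <- cv_abundance_curve(lin)
    interior <- curve$abundance > quantile(ab, 0.05) &
      curve$abundance < quantile(ab, 0.95)
    expect_lt(max(abs(curve$cv_smooth[interior] -
                        (40 - curve$abundance[interior]))), 1e-6)

    expect_error(cv_abundance_curve(flat[1:5, ]),
                 class = "qcs_insufficient_data_error")
  })
})

test_that("smoothed CV falls with abundance under additive + multiplicative noise", {
  withr::with_seed(41, {
    n_an <- 300; n_run <- 24
    ab <- runif(n_an, 14, 24)
    A <- 2^ab
    vals <- A * (1 + matrix(rnorm(n_an * n_run, 0, 0.08), n_an)) +
      matrix(rnorm(n_an * n_run, 0, 2^15), n_an)
    vals[vals <= 0] <- NA
    dimnames(vals) <- list(paste0("a", 1:n_an), paste0("r", 1:n_run))
    cvt <- compute_cv(quant_matrix(vals), min_obs = 3L)
    curve <- cv_abundance_curve(cvt, span = 0.6)
    rng <- range(cvt$log2_median_abundance, na.rm = TRUE)
    interior <- curve$abundance > rng[1] + 0.05 * diff(rng) &
      curve$abundance < rng[2] - 0.05 * diff(rng)
    d <- diff(curve$cv_smooth[interior])
    expect_true(all(d <= 1e-8))
  })
})

test_that("assess_levels tabulates eta per level with deltas and flags", {
  withr::with_seed(5, {
    vals <- matrix(2^rnorm(30 * 12, 20, 0.5), 30, 12,
                   dimnames = list(paste0("A", 1:30), paste0("R", 1:12)))
    batch <- setNames(rep(c("B1", "B2"), each = 6), colnames(vals))
    l1 <- quant_matrix(vals, batch_of = batch)
    l2 <- log2_median_normalize(l1)
    l3 <- suppressWarnings(batch_adjust(l2))
    cmp <- assess_levels(l1, l2, l3)
    expect_equal(nrow(cmp$eta), 3)
    expect_equal(cmp$deltas$delta_eta[3],
                 cmp$eta$median_cv_eta[3] - cmp$eta$median_cv_eta[1],
                 tolerance = 1e-12)

    # identical matrices at all levels give zero deltas
    lx <- quant_matrix(unclass(l2), level = "L2_NORMALIZED", batch_of = batch)
    cmp0 <- assess_levels(
      quant_matrix(2^unclass(l2), batch_of = batch), lx,
      quant_matrix(unclass(l2), level = "L3_BATCH_ADJUSTED", batch_of = batch))
    expect_true(all(abs(cmp0$deltas$delta_eta) < 1e-9))

    # single batch: the L2 -> L3 transition is a no-op
    single <- setNames(rep("B1", 12), colnames(vals))
    s1 <- quant_matrix(vals, batch_of = single)
    s2 <- log2_median_normalize(s1)
    s3 <- suppressWarnings(batch_adjust(s2))
    cmp1 <- assess_levels(s1, s2, s3)
    expect_equal(cmp1$deltas$delta_eta[2], 0, tolerance = 1e-12)
  })
})

test_that("quant matrices round-trip through their TSV representation", {
  withr::with_seed(2, {
    vals <- matrix(2^rnorm(6 * 4, 20, 1), 6, 4,
                   dimnames = list(paste0("A", 1:6), paste0("R", 1:4)))
    m <- quant_matrix(vals)
    f <- tempfile(fileext = ".tsv")
    write_table(m, f)
    lines <- readLines(f)
    expect_true(any(grepl("^# level: L1_RAW", lines)))
    body <- read.delim(f, comment.char = "#", check.names = FALSE)
    expect_equal(as.matrix(body[, -1]), unclass(vals),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
})
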