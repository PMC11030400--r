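test_that("ordered rules reproduce the canonical failure signatures", {
  cfg <- triage_config()

  # protein IQC nearly absent, peptide IQC consistent: a digestion failure
  call <- classify_run(make_summary(eno_ratio = 0.01, prtc_z = 0.3,
                                    min_idotp = 0.99), config = cfg)
  expect_equal(call$call, "SAMPLE_PREP_FAILURE")
  expect_equal(call$rule_id, "R2")

  # both IQCs reduced with a +4 min RT shift, clean neighbors: bad injection
  call <- classify_run(make_summary(eno_ratio = 0.3, prtc_ratio = 0.3,
                                    prtc_z = -8, rt_shift_min = 4),
                       prev = list(as.list(make_summary())),
                       nxt = as.list(make_summary()), config = cfg)
  expect_equal(call$call, "INJECTION_LC_EVENT")
  expect_equal(call$rule_id, "R3")

  # envelope loss with normal abundances
  call <- classify_run(make_summary(min_idotp = 0.85), config = cfg)
  expect_equal(call$call, "ISOTOPE_ENVELOPE_LOSS")
  expect_equal(call$rule_id, "R1")

  # reduced peptide IQC: instrument loss if suitability is degraded,
  # otherwise queue suitability runs to confirm
  call <- classify_run(make_summary(eno_ratio = 0.3, prtc_ratio = 0.3,
                                    prtc_z = -8, ss_status = "DEGRADED"),
                       config = cfg)
  expect_equal(call$call, "MS_SENSITIVITY_LOSS")
  expect_equal(call$rule_id, "R4")
  call <- classify_run(make_summary(eno_ratio = 0.3, prtc_ratio = 0.3,
                                    prtc_z = -8, ss_status = "OK"),
                       config = cfg)
  expect_equal(call$call, "SYSTEM_CHECK_NEEDED")
  expect_equal(call$rule_id, "R5")

  # three consecutive strictly decreasing ratios ending below 0.7 count as
  # intensity evidence even above the low_ratio threshold
  prev <- list(as.list(make_summary(prtc_ratio = 0.95)),
               as.list(make_summary(prtc_ratio = 0.80)))
  call <- classify_run(make_summary(prtc_ratio = 0.65, ss_status = "DEGRADED"),
                       prev = prev, config = cfg)
  expect_equal(call$call, "MS_SENSITIVITY_LOSS")

  call <- classify_run(make_summary(), config = cfg)
  expect_equal(call$call, "PASS")
  expect_true(is.na(call$rule_id))
  expect_equal(length(call$evidence), 0)
})

test_that("non-PASS calls always carry a rule and evidence", {
  grid <- list(
    make_summary(min_idotp = 0.5),
    make_summary(eno_ratio = 0.1),
    make_summary(eno_ratio = 0.2, prtc_ratio = 0.2, prtc_z = -9,
                 rt_shift_min = 5),
    make_summary(prtc_ratio = 0.2, prtc_z = -9, ss_status = "DEGRADED"),
    make_summary(prtc_ratio = 0.2, prtc_z = -9, ss_status = "UNKNOWN"))
  for (s in grid) {
    call <- classify_run(s)
    expect_false(call$call == "PASS")
    expect_false(is.na(call$rule_id))
    expect_gt(length(call$evidence), 0)
  }
})

test_that("internal-QC summaries aggregate by medians against baselines", {
  an <- default_analytes()
  cfg <- simulation_config(samples_per_batch = 15L, ss_every = 3L,
                           analytes = list(suitability = an$suitability[1:4],
                                           protein_iqc = an$protein_iqc[1:3],
                                           peptide_iqc = an$peptide_iqc[1:3]),
                           noise_cv = 0.001, iso_noise_cv = 0.001,
                           rt_jitter_sd = 0, ppm_sd = 0, seed = 9L)
  sim <- simulate_experiment(cfg)
  tab <- sim$table
  # degrade the protein IQC of the 12th sample run to 1% of baseline
  sample_ids <- sim$runlog$run_id[sim$runlog$run_type == "SAMPLE"]
  target <- sample_ids[12]
  hit <- tab$run_id == target & tab$analyte_class == "PROTEIN_IQC"
  tab$transition_area[hit] <- tab$transition_area[hit] * 0.01

  baselines <- build_qc_baselines(tab, sim$runlog)
  summaries <- summarize_internal_qc(tab, sim$runlog, baselines)
  row <- summaries[summaries$run_id == target, ]
  expect_equal(row$eno_ratio, 0.01, tolerance = 1e-2)
  expect_equal(row$prtc_ratio, 1, tolerance = 1e-2)
  expect_lt(abs(row$prtc_z), 2)
  expect_equal(row$ss_status, "OK")
  clean <- summaries[summaries$run_id != target, ]
  expect_true(all(abs(clean$eno_ratio - 1) < 0.01))
  expect_true(all(clean$min_idotp > 0.999))
})

test_that("a noise-free decay run shows the injected ratio sequence exactly", {
  an <- default_analytes()
  cfg <- simulation_config(samples_per_batch = 20L, ss_every = 4L,
                           analytes = list(suitability = an$suitability[1:4],
                                           protein_iqc = an$protein_iqc[1:3],
                                           peptide_iqc = an$peptide_iqc[1:3]),
                           noise_cv = 0, iso_noise_cv = 0, rt_jitter_sd = 0,
                           ppm_sd = 0, seed = 2L)
  sched <- build_run_schedule(cfg)
  start <- sched$run_idx[sched$run_type == "SYSTEM_SUITABILITY"][4]
  cfg$events <- list(event_sensitivity_decay(start_run = start, rate = 0.8))
  sim <- simulate_experiment(cfg)
  baselines <- build_qc_baselines(sim$table, sim$runlog)
  summaries <- summarize_internal_qc(sim$table, sim$runlog, baselines)
  decayed <- summaries$run_id %in% sched$run_id[sched$run_idx >= start]
  expected <- 0.8^(match(summaries$run_id[decayed], sched$run_id) - start + 1)
  expect_equal(summaries$prtc_ratio[decayed], expected, tolerance = 1e-9)
  expect_true(all(diff(summaries$prtc_ratio[decayed]) < 0))
})

test_that("raising low_ratio monotonically increases non-PASS calls", {
  sim <- simulate_failure_mixture(3)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(lr) {
    rep_ <- triage_experiment(sim$table, sim$runlog,
                              config = triage_config(low_ratio = lr))
    sum(rep_$calls$call != "PASS")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("an in-control experiment triages to all PASS", {
  cfg <- simulation_config(samples_per_batch = 20L, ss_every = 4L, seed = 31L)
  sim <- simulate_experiment(cfg)
  rep_ <- triage_experiment(sim$table, sim$runlog)
  expect_true(all(rep_$calls$call == "PASS"))
  expect_equal(nrow(rep_$calls), 20)
  expect_equal(nrow(rep_$batch_counts), 0)
})

test_that("an experiment without sample runs yields an empty report", {
  sim <- simulate_experiment(vignette_presets("vignette1", seed = 1))
  # a suitability-only series has no internal QCs to summarize
  expect_error(triage_experiment(sim$table, sim$runlog),
               class = "qcs_config_error")

  # with sample runs present but none selected, the report is empty
  sim2 <- simulate_experiment(simulation_config(samples_per_batch = 20L,
                                                ss_every = 4L, seed = 5L))
  baselines <- build_qc_baselines(sim2$table, sim2$runlog)
  log_no_samples <- sim2$runlog[sim2$runlog$run_type == "SYSTEM_SUITABILITY", ]
  expect_warning(rep_ <- triage_experiment(
    sim2$table, validate_run_log(log_no_samples), baselines = baselines))
  expect_equal(nrow(rep_$calls), 0)
})
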