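## presets: documented simulation configurations reproducing the run layout
## of six canonical QC failure scenarios, plus a mixed-failure benchmark
## used to validate the triage rules.

#' Preset simulation scenarios
#'
#' Returns a documented [simulation_config()] reproducing one of six
#' canonical failure scenarios. Magnitudes are synthetic, chosen to be
#' comfortably detectable at the default 10% area CV:
#'
#' * `vignette1` - longitudinal suitability series with an abrupt 50%
#'   transition-area drop (runs 21-30) and recovery, as after an LC pump
#'   or solvent problem.
#' * `vignette2` - suitability series with sporadic loss of the M+1/M+2
#'   13C isotope peaks (x0.05) that leaves total areas intact.
#' * `vignette3` - 4 preparation arms x 8 randomized replicates; the
#'   in-solution-digestion arm ("ISD") loses protein-IQC peptides (x0.01)
#'   while the post-digestion peptide IQC stays normal.
#' * `vignette4` - a sample series with a single bad injection (areas
#'   x0.3, retention times +4 min), neighbors unaffected.
#' * `vignette5` - interleaved suitability and sample runs with two
#'   progressive sensitivity-decay episodes separated by maintenance.
#' * `vignette6` - 8 batches with inter-batch external-QC runs, per-batch
#'   log2 offsets and per-run loading variation, for the normalization /
#'   batch-adjustment ladder.
#'
#' @param name Preset name, `"vignette1"` ... `"vignette6"`.
#' @param seed Seed stored in the config (default 1).
#' @return A `simulation_config`.
#' @export
vignette_presets <- function(name, seed = 1L) {
  presets <- c("vignette1", "vignette2", "vignette3", "vignette4",
               "vignette5", "vignette6")
  if (!is.character(name) || length(name) != 1 || !name %in% presets)
    qcs_argument_error(paste0("unknown preset; available: ",
                              paste(presets, collapse = ", ")))
  switch(name,
    vignette1 = simulation_config(
      samples_per_batch = 0L, ss_only_runs = 40L,
      events = list(event_step_change(start_run = 21L, magnitude = 0.5,
                                      end_run = 30L)),
      seed = seed),
    vignette2 = simulation_config(
      samples_per_batch = 0L, ss_only_runs = 30L,
      events = list(event_isotope_loss(prob = 0.3, attenuation = 0.05,
                                       from_run = 11L)),
      seed = seed),
    vignette3 = simulation_config(
      samples_per_batch = 32L, ss_every = 6L,
      arms = c("1BD", "2BD", "STR", "ISD"),
      events = list(event_arm_digestion_failure("ISD", magnitude = 0.01)),
      seed = seed),
    vignette4 = {
      cfg <- simulation_config(samples_per_batch = 12L, ss_every = 8L, seed = seed)
      sched <- build_run_schedule(cfg)
      bad <- sched$run_idx[sched$run_type == "SAMPLE"][7]
      cfg$events <- list(event_bad_injection(run = bad, magnitude = 0.3,
                                             rt_shift_min = 4))
      cfg
    },
    vignette5 = {
      cfg <- simulation_config(samples_per_batch = 36L, ss_every = 3L, seed = seed)
      sched <- build_run_schedule(cfg)
      ss_idx <- sched$run_idx[sched$run_type == "SYSTEM_SUITABILITY"]
      ## two decay episodes, each starting at a suitability-cycle boundary,
      ## ended by maintenance
      cfg$events <- list(
        event_sensitivity_decay(start_run = ss_idx[6], rate = 0.6,
                                end_run = ss_idx[8] - 1L),
        event_sensitivity_decay(start_run = ss_idx[11], rate = 0.6,
                                end_run = NULL))
      cfg
    },
    vignette6 = simulation_config(
      n_batches = 8L, samples_per_batch = 10L, qc_per_batch = 12L,
      ss_every = 23L, n_endogenous = 60L, run_scale_sd_log2 = 0.5,
      events = list(event_batch_effect(sd_log2 = 0.5)),
      seed = seed)
  )
}

#' Mixed-failure benchmark experiment
#'
#' One simulated experiment containing all four triage-relevant failure
#' modes at their preset magnitudes, on a clean guide period: 22
#' suitability cycles of [SS, sample, sample]; sporadic isotope loss (3
#' runs, M+1/M+2 x0.05), an arm-wise digestion failure (5 "ISD" runs,
#' protein IQC x0.01), one bad injection (x0.3, +4 min), and a
#' sensitivity-decay episode (x0.6 per injection) opening at a
#' suitability-cycle boundary and running to the end. Event positions are
#' randomized per seed within the post-guide region, with bad-injection
#' neighbors kept clean so the event is genuinely isolated.
#'
#' @param seed Integer seed.
#' @return As [simulate_experiment()]: list with `table` and `runlog`.
#' @export
simulate_failure_mixture <- function(seed) {
  panels <- default_analytes()
  analytes <- list(suitability = panels$suitability[1:8],
                   protein_iqc = panels$protein_iqc,
                   peptide_iqc = panels$peptide_iqc[1:8])
  cfg <- simulation_config(samples_per_batch = 44L, ss_every = 2L,
                           analytes = analytes, seed = seed)
  sched <- build_run_schedule(cfg)
  sample_idx <- sched$run_idx[sched$run_type == "SAMPLE"]
  ss_idx <- sched$run_idx[sched$run_type == "SYSTEM_SUITABILITY"]

  ## candidate sample ordinals 11..32 (after the guide window, before decay)
  picks <- with_local_seed(seed + 104729L, {
    repeat {
      cand <- sample(11:32)
      iso <- sort(cand[1:3])
      isd <- sort(cand[4:8])
      bad <- cand[9]
      ## the bad injection must be isolated: adjacent sample runs must not
      ## carry an abundance-reducing event
      if (!any(abs(isd - bad) <= 1)) break
    }
    list(iso = iso, isd = isd, bad = bad)
  })

  arm <- rep("STR", length(sample_idx))
  arm[picks$isd] <- "ISD"
  cfg$arm_assignment <- arm
  cfg$events <- list(
    event_isotope_loss(runs = sample_idx[picks$iso], attenuation = 0.05),
    event_arm_digestion_failure("ISD", magnitude = 0.01),
    event_bad_injection(run = sample_idx[picks$bad], magnitude = 0.3,
                        rt_shift_min = 4),
    event_sensitivity_decay(start_run = ss_idx[18], rate = 0.6,
                            label_below = 0.5))
  simulate_experiment(cfg)
}

#' Map ground-truth event labels to expected triage calls
#'
#' @return Named character vector, truth_event -> triage call.
#' @export
truth_call_map <- function() {
  c(ISOTOPE_LOSS = "ISOTOPE_ENVELOPE_LOSS",
    ARM_DIGESTION_FAILURE = "SAMPLE_PREP_FAILURE",
    BAD_INJECTION = "INJECTION_LC_EVENT",
    SENSITIVITY_DECAY = "MS_SENSITIVITY_LOSS")
}

#' Triage precision and recall on the mixed-failure benchmark
#'
#' Runs [simulate_failure_mixture()] and [triage_experiment()] over a set of
#' seeds and pools the per-run confusion between ground-truth labels and
#' triage calls.
#'
#' @param n_seeds Number of simulated experiments.
#' @param base_seed Seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param config A `triage_config`.
#' @return A tibble with one row per failure class: `class`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`.
#' @export
triage_precision_recall <- function(n_seeds = 200L, base_seed = 1L,
                                    config = triage_config()) {
  map <- truth_call_map()
  classes <- unname(map)
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_failure_mixture(base_seed + s - 1L)
    rep_ <- triage_experiment(sim$table, sim$runlog, config = config)
    calls <- rep_$calls
    truth <- sim$runlog$truth_event[match(calls$run_id, sim$runlog$run_id)]
    expected <- unname(map[truth])
    expected[is.na(truth)] <- "PASS"
    for (cl in classes) {
      tp[cl] <- tp[cl] + sum(calls$call == cl & expected == cl, na.rm = TRUE)
      fp[cl] <- fp[cl] + sum(calls$call == cl & expected != cl, na.rm = TRUE)
      fn[cl] <- fn[cl] + sum(calls$call != cl & expected == cl, na.rm = TRUE)
    }
  }
  tibble(class = classes, tp = unname(tp), fp = unname(fp), fn = unname(fn),
         precision = unname(tp / (tp + fp)), recall = unname(tp / (tp + fn)))
}
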