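## simulate: synthetic measurement tables + run logs with ground-truth event
## labels, reproducing the statistical structure of targeted LC-MS QC data
## and six canonical failure modes.

#' Default analyte panels
#'
#' The default simulated panels mirror a common targeted QC setup: a
#' suitability standard of a BSA digest plus a synthetic heavy-labeled
#' retention-time peptide mixture (17 peptides tracked), yeast enolase 1
#' peptides as the protein internal QC, and the heavy peptide mixture as the
#' peptide internal QC.
#'
#' @return Named list with `suitability`, `protein_iqc`, `peptide_iqc`
#'   character vectors of peptide sequences.
#' @export
default_analytes <- function() {
  prtc <- c("SSAAPPPPPR", "GISNEGQNASIK", "HVLTSIGEK", "DIPVPKPK",
            "IGDYAGIK", "TASEFDSAIAQDK", "SAAGAFGPELSR", "ELGQSGVDTYLQTK",
            "GLILVGGYGTR", "GILFVGSGVSGGEEGAR", "SFANQPLEVVYSK",
            "LTILEELR", "NGFILDGFPR", "ELASGLSFPVGFK", "LSSEAPALFQFDLK")
  list(
    suitability = c("LVNELTEFAK", "YLYEIAR", "HLVDEPQNLIK",
                    "KVPQVSTPTLVEVSR", "AEFVEVTK", "QTALVELLK",
                    "LGEYGFQNALIVR", "DAFLGSFLYEYSR", "TVMENFVAFVDK",
                    "RHPEYAVSVLLR", "FKDLGEEHFK", "LVTDLTK", "SEIAHR",
                    "DLGEEHFK", "VPQVSTPTLVEVSR", "HPEYAVSVLLR", "AWSVAR"),
    protein_iqc = c("VNQIGTLSESIK", "AADALLLK", "AVDDFLISLDGTANK",
                    "GNPTVEVELTTEK", "TAGIQIVADDLTVTNPK", "NVNDVIAPAFVK"),
    peptide_iqc = prtc
  )
}

#' Simulation configuration
#'
#' Defines the run layout, analyte panels, noise model and failure events of
#' a simulated experiment. Areas are log-normal: each (run, analyte) draws
#' `log2 area = base + batch offset + run scale + noise`, with the log2
#' noise SD derived from `noise_cv` through the log-normal CV relation
#' `sigma_ln = sqrt(log(1 + cv^2))`. Suitability runs measure the
#' suitability panel; sample and external-QC runs measure the internal QCs
#' plus `n_endogenous` synthetic endogenous peptides. Suitability runs are
#' interleaved, one before every `ss_every` sample runs.
#'
#' @param n_batches Number of batches.
#' @param samples_per_batch Sample runs per batch.
#' @param qc_per_batch Inter-batch external-QC runs per batch, spread evenly
#'   among the samples.
#' @param ss_every Suitability-run cadence in sample runs (default 8).
#' @param ss_only_runs If `samples_per_batch` is 0, a plain longitudinal
#'   suitability series of this length is generated.
#' @param analytes Named list as [default_analytes()].
#' @param n_endogenous Number of synthetic endogenous peptides (default 0).
#' @param base_log2_range Range from which per-analyte base log2 areas are
#'   drawn (once, from the seed).
#' @param noise_cv Within-condition coefficient of variation of areas
#'   (default 0.10).
#' @param iso_noise_cv Elementwise CV of isotope-peak areas (default 0.05).
#' @param rt_jitter_sd Retention-time jitter SD, minutes (default 0.05).
#' @param ppm_sd Mass-error SD in ppm (default 2.0).
#' @param batch_offset_sd_log2 SD of per-(batch, analyte) offsets drawn by a
#'   `BATCH_EFFECT_ONLY` event (default 0.5).
#' @param run_scale_sd_log2 SD of per-run global scale factors, log2 units
#'   (default 0: no loading variation).
#' @param precursor_ratio Mean precursor/transition area ratio
#'   (default 0.35).
#' @param arms Optional character vector of sample-preparation arms; sample
#'   runs are assigned arms in randomized balanced order.
#' @param arm_assignment Optional explicit arm label per sample run (in run
#'   order); overrides `arms` randomization.
#' @param events List of event specs from the `event_*()` constructors.
#' @param seed Integer seed; the simulation is deterministic given the
#'   config.
#' @param start_time First acquisition timestamp (runs are spaced 1 h).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_batches = 1L, samples_per_batch = 48L,
                              qc_per_batch = 0L, ss_every = 8L,
                              ss_only_runs = 0L,
                              analytes = default_analytes(),
                              n_endogenous = 0L,
                              base_log2_range = c(18, 24),
                              noise_cv = 0.10, iso_noise_cv = 0.05,
                              rt_jitter_sd = 0.05, ppm_sd = 2.0,
                              batch_offset_sd_log2 = 0.5,
                              run_scale_sd_log2 = 0,
                              precursor_ratio = 0.35,
                              arms = NULL, arm_assignment = NULL,
                              events = list(), seed = 1L,
                              start_time = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  if (ss_every < 1) qcs_argument_error("ss_every must be >= 1")
  if (noise_cv < 0 || iso_noise_cv < 0 || rt_jitter_sd < 0 || ppm_sd < 0 ||
      batch_offset_sd_log2 < 0 || run_scale_sd_log2 < 0)
    qcs_argument_error("all noise SDs/CVs must be >= 0")
  structure(list(n_batches = as.integer(n_batches),
                 samples_per_batch = as.integer(samples_per_batch),
                 qc_per_batch = as.integer(qc_per_batch),
                 ss_every = as.integer(ss_every),
                 ss_only_runs = as.integer(ss_only_runs),
                 analytes = analytes, n_endogenous = as.integer(n_endogenous),
                 base_log2_range = base_log2_range,
                 noise_cv = noise_cv, iso_noise_cv = iso_noise_cv,
                 rt_jitter_sd = rt_jitter_sd, ppm_sd = ppm_sd,
                 batch_offset_sd_log2 = batch_offset_sd_log2,
                 run_scale_sd_log2 = run_scale_sd_log2,
                 precursor_ratio = precursor_ratio,
                 arms = arms, arm_assignment = arm_assignment,
                 events = events, seed = as.integer(seed),
                 start_time = start_time),
            class = "simulation_config")
}

## Event constructors -------------------------------------------------------

#' Failure-event specifications
#'
#' Constructors for the event specs accepted by
#' [simulation_config()]`$events`. Run positions are global indices into the
#' ordered run schedule (see [build_run_schedule()]).
#'
#' * `event_step_change()` multiplies all areas by `magnitude` from
#'   `start_run` until `end_run` (inclusive; `NULL` = to the end) - an
#'   abrupt, persistent sensitivity change.
#' * `event_isotope_loss()` multiplies the M+1 and M+2 isotope-peak areas by
#'   `attenuation` in the given runs, or in each run from `from_run` on with
#'   probability `prob` - sporadic loss of the 13C peaks that leaves total
#'   areas intact.
#' * `event_arm_digestion_failure()` multiplies protein-IQC and endogenous
#'   areas by `magnitude` in sample runs of the named preparation `arm`,
#'   leaving the post-digestion peptide IQC untouched.
#' * `event_bad_injection()` multiplies all areas of one run by `magnitude`
#'   and shifts all its retention times by `rt_shift_min`.
#' * `event_sensitivity_decay()` multiplies areas by `rate^(i - start_run + 1)`
#'   for every run `i` in the window - progressive loss with each
#'   injection. Runs whose cumulative attenuation is at or below
#'   `label_below` carry the ground-truth label (the decay has materially
#'   manifested there).
#' * `event_batch_effect()` draws per-(batch, analyte) log2 offsets
#'   ~ Normal(0, `sd_log2`); it labels no runs.
#'
#' @param start_run,end_run,run,runs,from_run Global run indices.
#' @param magnitude,attenuation,rate Multiplicative factors in (0, 1] (or
#'   above 1 for gains).
#' @param prob Per-run probability for sporadic isotope loss.
#' @param arm Preparation-arm label.
#' @param rt_shift_min Retention-time shift in minutes.
#' @param label_below Ground-truth labeling threshold for decay.
#' @param sd_log2 Batch-offset SD in log2 units.
#' @return An event spec (list with class `qcs_event`).
#' @name simulation_events
NULL

new_event <- function(kind, ...) {
  ev <- list(kind = kind, ...)
  structure(ev, class = "qcs_event")
}

#' @rdname simulation_events
#' @export
event_step_change <- function(start_run, magnitude, end_run = NULL) {
  if (magnitude <= 0) qcs_argument_error("magnitude must be > 0")
  new_event("STEP_CHANGE", start_run = start_run, magnitude = magnitude,
            end_run = end_run)
}

#' @rdname simulation_events
#' @export
event_isotope_loss <- function(runs = NULL, prob = NULL, attenuation = 0.05,
                               from_run = 1L) {
  if (attenuation <= 0) qcs_argument_error("attenuation must be > 0")
  if (is.null(runs) && is.null(prob))
    qcs_argument_error("give either explicit runs or a probability")
  new_event("ISOTOPE_LOSS", runs = runs, prob = prob,
            attenuation = attenuation, from_run = from_run)
}

#' @rdname simulation_events
#' @export
event_arm_digestion_failure <- function(arm, magnitude = 0.01) {
  if (magnitude <= 0) qcs_argument_error("magnitude must be > 0")
  new_event("ARM_DIGESTION_FAILURE", arm = arm, magnitude = magnitude)
}

#' @rdname simulation_events
#' @export
event_bad_injection <- function(run, magnitude = 0.3, rt_shift_min = 4) {
  if (magnitude <= 0) qcs_argument_error("magnitude must be > 0")
  new_event("BAD_INJECTION", run = run, magnitude = magnitude,
            rt_shift_min = rt_shift_min)
}

#' @rdname simulation_events
#' @export
event_sensitivity_decay <- function(start_run, rate = 0.75, end_run = NULL,
                                    label_below = 0.5) {
  if (rate <= 0 || rate > 1) qcs_argument_error("decay rate must be in (0, 1]")
  new_event("SENSITIVITY_DECAY", start_run = start_run, rate = rate,
            end_run = end_run, label_below = label_below)
}

#' @rdname simulation_events
#' @export
event_batch_effect <- function(sd_log2 = 0.5) {
  new_event("BATCH_EFFECT_ONLY", sd_log2 = sd_log2)
}

## Schedule -----------------------------------------------------------------

#' Build the ordered run schedule of a simulated experiment
#'
#' Deterministic given the config (arm randomization uses the config seed).
#'
#' @param cfg A `simulation_config`.
#' @return A tibble with columns `run_idx`, `run_id`, `run_type`,
#'   `batch_id`, `prep_arm`, `acquired_at`.
#' @export
build_run_schedule <- function(cfg) {
  rows <- list()
  if (cfg$samples_per_batch == 0 && cfg$ss_only_runs > 0) {
    rows[[1]] <- data.frame(run_type = rep("SYSTEM_SUITABILITY", cfg$ss_only_runs),
                            batch_id = "B1", prep_arm = NA_character_,
                            stringsAsFactors = FALSE)
  } else {
    arm_labels <- NULL
    n_samples_total <- cfg$n_batches * cfg$samples_per_batch
    if (!is.null(cfg$arm_assignment)) {
      arm_labels <- cfg$arm_assignment
      if (length(arm_labels) != n_samples_total)
        qcs_config_error("arm_assignment length must equal total sample runs")
    } else if (!is.null(cfg$arms)) {
      if (n_samples_total %% length(cfg$arms) != 0)
        qcs_config_error("sample runs must divide evenly among arms")
      balanced <- rep(cfg$arms, each = n_samples_total / length(cfg$arms))
      arm_labels <- with_local_seed(cfg$seed, sample(balanced))
    }
    s_done <- 0
    for (b in seq_len(cfg$n_batches)) {
      batch <- paste0("B", b)
      n_s <- cfg$samples_per_batch
      n_q <- cfg$qc_per_batch
      ## spread QC runs evenly among the batch's injections
      inj_types <- rep("SAMPLE", n_s)
      if (n_q > 0) {
        qpos <- unique(round(seq(1, n_s + n_q, length.out = n_q)))
        full <- character(n_s + n_q)
        full[qpos] <- "EXTERNAL_QC_INTERBATCH"
        full[full == ""] <- "SAMPLE"
        inj_types <- full
      }
      out_types <- character(0)
      since_ss <- cfg$ss_every  # force a suitability run at batch start
      for (tp in inj_types) {
        if (since_ss >= cfg$ss_every) {
          out_types <- c(out_types, "SYSTEM_SUITABILITY")
          since_ss <- 0
        }
        out_types <- c(out_types, tp)
        since_ss <- since_ss + 1
      }
      arm <- rep(NA_character_, length(out_types))
      if (!is.null(arm_labels)) {
        is_s <- out_types == "SAMPLE"
        arm[is_s] <- arm_labels[s_done + seq_len(sum(is_s))]
        s_done <- s_done + sum(is_s)
      }
      rows[[b]] <- data.frame(run_type = out_types, batch_id = batch,
                              prep_arm = arm, stringsAsFactors = FALSE)
    }
  }
  sched <- do.call(rbind, rows)
  n <- nrow(sched)
  tibble(run_idx = seq_len(n),
         run_id = sprintf("R%04d", seq_len(n)),
         run_type = sched$run_type,
         batch_id = sched$batch_id,
         prep_arm = sched$prep_arm,
         acquired_at = cfg$start_time + (seq_len(n) - 1) * 3600)
}

## Simulation ---------------------------------------------------------------

cv_to_log2_sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)

## multiplicative log-normal noise with unit median
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  2^rnorm(n, 0, cv_to_log2_sd(cv))
}

#' Simulate a measurement table and run log
#'
#' Draws a full experiment under the generative model of
#' [simulation_config()], applies the configured failure events, and writes
#' ground-truth event labels into the run log's `truth_event` column.
#' Deterministic given the config seed.
#'
#' @param cfg A `simulation_config`.
#' @return List with elements `table` (a `measurement_table`) and `runlog`
#'   (a `run_log`).
#' @export
simulate_experiment <- function(cfg) {
  sched <- build_run_schedule(cfg)
  n_runs <- nrow(sched)

  panels <- list(SUITABILITY_PEPTIDE = cfg$analytes$suitability,
                 PROTEIN_IQC = cfg$analytes$protein_iqc,
                 PEPTIDE_IQC = cfg$analytes$peptide_iqc)
  if (cfg$n_endogenous > 0)
    panels$ENDOGENOUS <- with_local_seed(cfg$seed + 7919L,
                                         random_peptides(cfg$n_endogenous))
  panels <- panels[vapply(panels, length, integer(1)) > 0]
  analyte_df <- do.call(rbind, lapply(names(panels), function(cls) {
    data.frame(peptide = panels[[cls]], analyte_class = cls,
               stringsAsFactors = FALSE)
  }))
  analyte_df$precursor_charge <- 2L
  analyte_df$analyte_id <- paste0(analyte_df$peptide, "/2")
  if (anyDuplicated(analyte_df$analyte_id))
    qcs_config_error("duplicate analyte across panels")
  n_an <- nrow(analyte_df)

  ## theoretical envelopes (heavy label on the synthetic peptide-IQC panel)
  env_mat <- t(vapply(seq_len(n_an), function(i) {
    label <- if (analyte_df$analyte_class[i] == "PEPTIDE_IQC")
      "LABEL_13C6_15N2_K_and_13C6_15N4_R" else "NONE"
    as.numeric(isotope_distribution(
      peptide_composition(analyte_df$peptide[i], heavy_label = label), 3L))
  }, numeric(3)))

  ## which analytes are measured in which runs
  is_ss_run <- sched$run_type == "SYSTEM_SUITABILITY"
  measured <- outer(analyte_df$analyte_class == "SUITABILITY_PEPTIDE", is_ss_run, "&") |
    outer(analyte_df$analyte_class != "SUITABILITY_PEPTIDE", !is_ss_run, "&")

  res <- with_local_seed(cfg$seed, {
    base_log2 <- runif(n_an, cfg$base_log2_range[1], cfg$base_log2_range[2])
    rt_mean <- seq(8, 28, length.out = n_an)[order(order(runif(n_an)))]
    run_scale <- if (cfg$run_scale_sd_log2 > 0)
      rnorm(n_runs, 0, cfg$run_scale_sd_log2) else numeric(n_runs)

    batch_offsets <- matrix(0, n_an, n_runs)
    for (ev in cfg$events) {
      if (ev$kind == "BATCH_EFFECT_ONLY") {
        batches <- unique(sched$batch_id)
        off <- matrix(rnorm(n_an * length(batches), 0, ev$sd_log2),
                      n_an, length(batches), dimnames = list(NULL, batches))
        batch_offsets <- off[, sched$batch_id, drop = FALSE]
      }
    }

    eps <- matrix(rnorm(n_an * n_runs, 0, cv_to_log2_sd(cfg$noise_cv)), n_an, n_runs)
    log2_area <- base_log2 + batch_offsets +
      matrix(run_scale, n_an, n_runs, byrow = TRUE) + eps

    area_mult <- matrix(1, n_an, n_runs)      # event multipliers on areas
    iso_att <- matrix(1, n_an, n_runs)        # attenuation of M+1/M+2
    rt_shift <- numeric(n_runs)
    truth <- rep(NA_character_, n_runs)
    area_event <- rep(NA_character_, n_runs)  # conflict bookkeeping

    mark_area_event <- function(idx, kind) {
      clash <- idx[!is.na(area_event[idx]) & area_event[idx] != kind]
      if (length(clash) > 0)
        qcs_config_error(paste0("contradictory events overlap on run(s) ",
                                paste(sched$run_id[clash], collapse = ", ")))
      area_event[idx] <<- kind
    }
    label <- function(idx, kind) {
      truth[idx] <<- ifelse(is.na(truth[idx]), kind,
                            paste(truth[idx], kind, sep = ";"))
    }

    for (ev in cfg$events) {
      if (ev$kind == "STEP_CHANGE") {
        end <- ev$end_run %||% n_runs
        idx <- ev$start_run:end
        mark_area_event(idx, "STEP_CHANGE")
        area_mult[, idx] <- area_mult[, idx] * ev$magnitude
        label(idx, "STEP_CHANGE")
      } else if (ev$kind == "ISOTOPE_LOSS") {
        idx <- ev$runs
        if (is.null(idx)) {
          eligible <- ev$from_run:n_runs
          idx <- eligible[runif(length(eligible)) < ev$prob]
        }
        if (length(idx) > 0) {
          iso_att[, idx] <- ev$attenuation
          label(idx, "ISOTOPE_LOSS")
        }
      } else if (ev$kind == "ARM_DIGESTION_FAILURE") {
        idx <- which(!is.na(sched$prep_arm) & sched$prep_arm == ev$arm)
        if (length(idx) == 0)
          qcs_config_error(paste0("no sample run in arm ", ev$arm))
        mark_area_event(idx, "ARM_DIGESTION_FAILURE")
        hit <- analyte_df$analyte_class %in% c("PROTEIN_IQC", "ENDOGENOUS")
        area_mult[hit, idx] <- area_mult[hit, idx] * ev$magnitude
        label(idx, "ARM_DIGESTION_FAILURE")
      } else if (ev$kind == "BAD_INJECTION") {
        mark_area_event(ev$run, "BAD_INJECTION")
        area_mult[, ev$run] <- area_mult[, ev$run] * ev$magnitude
        rt_shift[ev$run] <- rt_shift[ev$run] + ev$rt_shift_min
        label(ev$run, "BAD_INJECTION")
      } else if (ev$kind == "SENSITIVITY_DECAY") {
        end <- ev$end_run %||% n_runs
        idx <- ev$start_run:end
        mark_area_event(idx, "SENSITIVITY_DECAY")
        fac <- ev$rate^(seq_along(idx))
        area_mult[, idx] <- sweep(area_mult[, idx, drop = FALSE], 2, fac, "*")
        label(idx[fac <= ev$label_below], "SENSITIVITY_DECAY")
      }
    }

    transition <- 2^log2_area * area_mult
    precursor <- transition * cfg$precursor_ratio *
      matrix(lognoise(n_an * n_runs, cfg$noise_cv / 2), n_an, n_runs)
    rt <- rt_mean + matrix(rnorm(n_an * n_runs, 0, cfg$rt_jitter_sd), n_an, n_runs) +
      matrix(rt_shift, n_an, n_runs, byrow = TRUE)
    ppm <- matrix(rnorm(n_an * n_runs, 0, cfg$ppm_sd), n_an, n_runs)
    iso_noise <- array(lognoise(n_an * n_runs * 3, cfg$iso_noise_cv),
                       dim = c(n_an, n_runs, 3))
    iso0 <- precursor * env_mat[, 1] * iso_noise[, , 1]
    iso1 <- precursor * env_mat[, 2] * iso_noise[, , 2] * iso_att
    iso2 <- precursor * env_mat[, 3] * iso_noise[, , 3] * iso_att
    list(transition = transition, precursor = precursor, rt = rt, ppm = ppm,
         iso0 = iso0, iso1 = iso1, iso2 = iso2, truth = truth)
  })

  keep <- which(measured, arr.ind = TRUE)
  a <- keep[, 1]; r <- keep[, 2]
  df <- tibble(
    run_id = sched$run_id[r],
    acquired_at = sched$acquired_at[r],
    peptide = analyte_df$peptide[a],
    precursor_charge = analyte_df$precursor_charge[a],
    analyte_class = analyte_df$analyte_class[a],
    precursor_area = res$precursor[keep],
    transition_area = res$transition[keep],
    rt_min = res$rt[keep],
    mass_error_ppm = res$ppm[keep],
    iso_m0 = res$iso0[keep],
    iso_m1 = res$iso1[keep],
    iso_m2 = res$iso2[keep])
  table <- validate_measurement_table(df)
  runlog <- validate_run_log(tibble(
    run_id = sched$run_id, acquired_at = sched$acquired_at,
    run_type = sched$run_type, batch_id = sched$batch_id,
    prep_arm = sched$prep_arm, annotation = NA_character_,
    truth_event = res$truth))
  list(table = table, runlog = runlog)
}

## deterministic synthetic tryptic-like peptides (end in K or R)
random_peptides <- function(n) {
  aa <- c("A", "D", "E", "F", "G", "I", "L", "N", "P", "Q", "S", "T", "V", "Y")
  out <- character(0)
  while (length(out) < n) {
    len <- sample(7:14, 1)
    pep <- paste0(paste(sample(aa, len, replace = TRUE), collapse = ""),
                  sample(c("K", "R"), 1))
    if (!pep %in% out) out <- c(out, pep)
  }
  out
}
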