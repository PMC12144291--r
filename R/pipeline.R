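#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end chain. The task chain order is
#' fixed: high-pass, downsample, bad-channel detection/interpolation, robust
#' average reference, epoching, muscle BSS-CCA, epoch-statistic rejection,
#' ocular proxy regression, baseline correction.
#'
#' @param hp_cutoff_hz task-chain high-pass cutoff (0.2)
#' @param rest_hp_cutoff_hz resting-chain high-pass cutoff (0.5)
#' @param target_fs analysis sampling rate after decimation (250)
#' @param reference_exclude channels never entering the common average
#' @param artifact_stages run the artifact-handling stages; `FALSE` gives
#'   the pure measurement path used with noise-free synthetic data
#' @param epoch_windows per-paradigm epoch windows in seconds
#' @param baseline_window baseline window for ERP epochs
#' @param response_window behavioral attribution window
#' @param components component definitions
#' @param bands resting band definitions
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(hp_cutoff_hz = 0.2, rest_hp_cutoff_hz = 0.5,
                            target_fs = 250,
                            reference_exclude = c("TP9", "TP10",
                                                  "Fp1", "Fp2"),
                            artifact_stages = TRUE,
                            epoch_windows = list(
                              mmn = c(-0.5, 0.5),
                              oddball = c(-1, 2),
                              assr = c(-1.248, 1.752)),
                            baseline_window = c(-0.1, 0),
                            response_window = c(0.1, 1.0),
                            components = default_component_definitions(),
                            bands = default_band_definitions()) {
  structure(list(hp_cutoff_hz = hp_cutoff_hz,
                 rest_hp_cutoff_hz = rest_hp_cutoff_hz,
                 target_fs = target_fs,
                 reference_exclude = reference_exclude,
                 artifact_stages = artifact_stages,
                 epoch_windows = epoch_windows,
                 baseline_window = baseline_window,
                 response_window = response_window,
                 components = components, bands = bands),
            class = "pipeline_config")
}

#' Continuous preprocessing of a task run
#'
#' High-pass, downsample, bad-channel detection and spherical-spline
#' interpolation (mastoids and frontopolar channels excluded from both, to
#' preserve them for referencing choices and the blink proxy), then the
#' robust common average reference.
#'
#' @param raw a `raw_session` at the acquisition rate
#' @param config a [pipeline_config()]
#' @return list with `raw` (referenced, at `target_fs`) and `report`
#' @export
preprocess_continuous <- function(raw, config = pipeline_config()) {
  # high-pass and anti-alias low-pass fused into one zero-phase cascade
  # (identical to highpass_filter() then downsample(); one pass over the data)
  fs <- raw$sampling_rate
  if (fs %% config$target_fs != 0)
    stop("target rate must divide sampling rate")
  sos <- c(.butter_sos(4, config$hp_cutoff_hz, fs, "high"),
           if (fs > config$target_fs)
             .butter_sos(8, 0.4 * config$target_fs, fs, "low"))
  pad <- round(min(3 / config$hp_cutoff_hz, 30) * fs)
  raw$data <- .sos_filtfilt_mat(sos, raw$data, pad)[,
    seq(1, ncol(raw$data), by = fs %/% config$target_fs), drop = FALSE]
  raw$sampling_rate <- config$target_fs
  # bad channels are detected inside the robust-reference iteration (in the
  # average-reference frame, where near-reference channels carry signal
  # again), then interpolated, and the reference is re-zeroed
  raw <- robust_average_reference(raw, exclude = config$reference_exclude,
                                  detect = config$artifact_stages)
  bads <- raw$reference_info$bad_channels
  if (length(bads)) {
    raw <- interpolate_channels(raw, bads,
                                exclude = config$reference_exclude)
    incl <- raw$reference_info$included
    raw$data <- sweep(raw$data, 2, colMeans(raw$data[incl, , drop = FALSE]))
  }
  list(raw = raw,
       report = list(bad_channels = bads,
                     reference_bads = bads))
}

#' Epoch-level cleaning of one stimulus stream
#'
#' Epochs the selected events and applies the epoch-level stages in fixed
#' order: muscle BSS-CCA, epoch-statistic outlier rejection, ocular proxy
#' regression, baseline correction.
#'
#' @param raw preprocessed `raw_session` (from [preprocess_continuous()])
#' @param events event selection to epoch
#' @param window epoch window
#' @param config a [pipeline_config()]
#' @return list with `epochs` and `report`
#' @export
clean_epochs <- function(raw, events, window, config = pipeline_config()) {
  eps <- epoch(raw, events, window)
  report <- list(n_epochs = dim(eps$data)[3], n_cca_removed = 0,
                 n_rejected = 0, n_blink_samples = 0)
  if (config$artifact_stages) {
    cca <- bsscca_muscle_removal(eps)
    eps <- cca$epochs
    report$n_cca_removed <- cca$report$n_components_removed
    eps <- reject_epochs_faster(eps)
    report$n_rejected <- sum(eps$rejected)
    oc <- remove_ocular(eps)
    eps <- oc$epochs
    report$n_blink_samples <- oc$report$n_blink_samples
  }
  eps <- baseline_correct(eps, config$baseline_window)
  list(epochs = eps, report = report)
}

#' Concatenate epoch sets from multiple runs
#'
#' @param sets list of `epoch_set`s with identical channels and time axes
#' @return combined `epoch_set`
#' @export
combine_epochs <- function(sets) {
  stopifnot(length(sets) >= 1)
  e1 <- sets[[1]]
  for (e in sets[-1]) {
    stopifnot(identical(e$channels, e1$channels),
              isTRUE(all.equal(e$times, e1$times)))
  }
  e1$data <- array(unlist(lapply(sets, function(e) e$data)),
                   dim = c(dim(e1$data)[1:2],
                           sum(vapply(sets, function(e) dim(e$data)[3],
                                      numeric(1)))),
                   dimnames = list(e1$channels, NULL, NULL))
  for (f in c("condition", "run_index", "onset", "rejected",
              "reject_reason"))
    e1[[f]] <- unlist(lapply(sets, `[[`, f), use.names = FALSE)
  e1
}

#' Process one synthesized (or loaded) session into measures
#'
#' Runs the full measurement chain on every run recording of a session and
#' returns session-level (and optionally run-level) measure rows plus a QC
#' summary.
#'
#' @param session a `session_set` (list of per-run `raw_session`s)
#' @param config a [pipeline_config()]
#' @param meta list with `subject_id`, `group`, `occasion` (occasion label,
#'   e.g. `"baseline"`)
#' @param per_run also emit per-run ERP component rows
#' @param paradigms subset of paradigms to process (default: those present)
#' @return list with `measures` (a [measure_table()]) and `qc` (per-run
#'   reports)
#' @export
process_session <- function(session, config = pipeline_config(), meta,
                            per_run = TRUE, paradigms = NULL) {
  runs <- session$runs
  run_paradigm <- vapply(runs, function(r) r$meta$paradigm, character(1))
  if (is.null(paradigms)) paradigms <- unique(run_paradigm)
  qc <- list()
  rows <- list()
  add <- function(measure, value, run = "all") {
    rows[[length(rows) + 1]] <<- data.frame(
      subject_id = meta$subject_id, group = meta$group,
      occasion = meta$occasion, run_index = as.character(run),
      measure_name = measure, value = value, stringsAsFactors = FALSE)
  }

  # --- ERP paradigms -------------------------------------------------
  for (p in intersect(c("mmn_vod", "aod"), paradigms)) {
    streams <- if (p == "mmn_vod") {
      list(list(modality = "auditory", window = config$epoch_windows$mmn,
                comps = "mmn"),
           list(modality = "visual", window = config$epoch_windows$oddball,
                comps = c("vod_p3b", "vod_p3a")))
    } else {
      list(list(modality = "auditory", window = config$epoch_windows$oddball,
                comps = c("aod_p3b", "aod_p3a")))
    }
    # accumulate per-run, per-condition epoch sums: the session-level ERP
    # is the trial-count-weighted combination of the run sums, identical to
    # averaging the pooled surviving epochs
    acc <- lapply(streams, function(st) list(sum = list(), n = list(),
                                             times = NULL))
    all_events <- list()
    for (rn in names(runs)[run_paradigm == p]) {
      pc <- preprocess_continuous(runs[[rn]], config)
      qc[[rn]] <- pc$report
      rr <- runs[[rn]]$meta$run
      for (si in seq_along(streams)) {
        st <- streams[[si]]
        ev <- pc$raw$events
        ev <- ev[ev$modality == st$modality, ]
        ce <- clean_epochs(pc$raw, ev, st$window, config)
        qc[[rn]][[paste0("epochs_", st$modality)]] <- ce$report
        conds <- unique(unlist(lapply(config$components[st$comps], function(d)
          c(d$numerator, d$denominator))))
        for (cond in conds) {
          sel <- !ce$epochs$rejected & ce$epochs$condition == cond
          key <- as.character(rr)
          acc[[si]]$n[[cond]][key] <- sum(sel)
          acc[[si]]$sum[[cond]][[key]] <-
            if (sum(sel)) rowSums(ce$epochs$data[, , sel, drop = FALSE],
                                  dims = 2) else NULL
        }
        acc[[si]]$times <- ce$epochs$times
        acc[[si]]$channels <- ce$epochs$channels
      }
      # rebase run-local event clocks onto the session clock for behavior
      evr <- as.data.frame(runs[[rn]]$events)
      evr$onset_time <- evr$onset_time +
        .run_offset(NULL, p, runs[[rn]]$meta$run)
      all_events[[rn]] <- evr
    }
    for (si in seq_along(streams)) {
      st <- streams[[si]]
      a <- acc[[si]]
      wave <- function(cond, run_keys = NULL) {
        keys <- if (is.null(run_keys)) names(a$sum[[cond]]) else run_keys
        keys <- intersect(keys, names(a$sum[[cond]]))
        n_tot <- sum(a$n[[cond]][keys])
        if (!length(keys) || n_tot == 0) return(NULL)
        structure(list(data = Reduce(`+`, a$sum[[cond]][keys]) / n_tot,
                       times = a$times, sampling_rate = config$target_fs,
                       channels = a$channels, condition = cond,
                       n_epochs = n_tot), class = "erp_wave")
      }
      run_keys <- sort(unique(unlist(lapply(a$n, names))))
      for (cn in st$comps) {
        def <- config$components[[cn]]
        num <- wave(def$numerator); den <- wave(def$denominator)
        add(def$name, if (is.null(num) || is.null(den)) NA_real_
            else score_component(difference_wave(num, den), def))
        if (per_run) {
          for (key in run_keys) {
            nr <- wave(def$numerator, key); dr <- wave(def$denominator, key)
            if (!is.null(nr) && !is.null(dr))
              add(def$name, score_component(difference_wave(nr, dr), def),
                  key)
          }
        }
      }
    }
    # behavioral performance from the attended stream
    evd <- do.call(rbind, all_events)
    bp <- if (p == "mmn_vod") "vod" else "aod"
    class(evd) <- c("event_table", "data.frame")
    pm <- tryCatch(performance_measures(evd, bp, meta),
                   error = function(e) NULL)
    if (!is.null(pm)) rows[[length(rows) + 1]] <- as.data.frame(pm)
  }

  # --- steady-state paradigm -----------------------------------------
  if ("assr" %in% paradigms) {
    for (rn in names(runs)[run_paradigm == "assr"]) {
      pc <- preprocess_continuous(runs[[rn]], config)
      qc[[rn]] <- pc$report
      raw <- rereference(pc$raw, c("P7", "P8"))
      ev <- raw$events[raw$events$condition == "train", ]
      ce <- clean_epochs(raw, ev, config$epoch_windows$assr, config)
      eps <- ce$epochs
      cluster_ch <- unique(c("FCz", "FC1", "FC2", "Cz", "C1", "C2",
                             "Fz", "F1", "F2"))
      tfc <- morlet_transform(eps, freqs = seq(4, 100, by = 2),
                              channels = cluster_ch)
      add("assr_itc", extract_assr_measure(itc(tfc)))
      add("assr_total_power", extract_assr_measure(total_power(tfc)))
      tfc_avg <- morlet_transform(average_epochs(eps),
                                  freqs = seq(4, 100, by = 2),
                                  channels = cluster_ch)
      add("assr_evoked_power", extract_assr_measure(evoked_power(tfc_avg)))
    }
  }

  # --- resting paradigms ---------------------------------------------
  for (p in intersect(c("rest_open", "rest_closed"), paradigms)) {
    for (rn in names(runs)[run_paradigm == p]) {
      rp <- resting_preprocess(runs[[rn]],
                               artifact_stages = config$artifact_stages)
      qc[[rn]] <- rp$report
      psd <- compute_psd(rp$epochs)
      for (b in config$bands)
        add(paste0(p, "_", b$name), band_power(psd, b))
    }
  }

  df <- do.call(rbind, rows)
  list(measures = measure_table(df$subject_id, df$group, df$occasion,
                                df$run_index, df$measure_name, df$value),
       qc = qc)
}

#' Run a complete simulated study
#'
#' End-to-end orchestration: draws person effects, synthesizes every
#' person/occasion session, processes each into measures, and computes the
#' per-measure reliability report. Deterministic given the seed. A failing
#' session is isolated: its error is recorded in the QC summary and the
#' remaining sessions complete.
#'
#' @param n_persons persons per group
#' @param truth a [study_truth()]
#' @param config a [pipeline_config()]
#' @param seed master seed
#' @param group group label
#' @param paradigms paradigms to simulate and process
#' @param per_run emit run-level ERP rows
#' @param include_noise,include_artifacts forwarded to the synthesizer
#' @return list with `measures`, `report` (reliability), `qc`,
#'   `ground_truth` (per person/occasion expected scores)
#' @export
run_pipeline <- function(n_persons = 8, truth = study_truth(),
                         config = pipeline_config(), seed = 1,
                         group = "CHR",
                         paradigms = c("mmn_vod", "aod", "assr",
                                       "rest_open", "rest_closed"),
                         per_run = TRUE, include_noise = TRUE,
                         include_artifacts = TRUE) {
  pe <- person_effects(truth, n_persons, .derive_seed(seed, 99))
  occ_names <- c("baseline", "month2")
  all_measures <- list()
  qc <- list()
  gt <- list()
  for (i in seq_len(n_persons)) {
    for (occ in 1:2) {
      sid <- sprintf("sub%03d", i)
      meta <- list(subject_id = sid, group = group,
                   occasion = occ_names[occ])
      res <- tryCatch({
        sess <- synthesize_session(truth, pe[i, ], occasion = occ,
                                   seed = .derive_seed(seed, i * 2 + occ),
                                   paradigms = paradigms,
                                   include_noise = include_noise,
                                   include_artifacts = include_artifacts,
                                   meta = meta)
        gt[[paste(sid, occ_names[occ], sep = "_")]] <- sess$ground_truth
        process_session(sess, config, meta, per_run = per_run)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        qc[[paste(sid, occ_names[occ], sep = "_")]] <-
          list(failed = TRUE, message = conditionMessage(res))
        warning("session ", sid, "/", occ_names[occ], " failed: ",
                conditionMessage(res))
        next
      }
      all_measures[[length(all_measures) + 1]] <- res$measures
      qc[[paste(sid, occ_names[occ], sep = "_")]] <- res$qc
    }
  }
  measures <- do.call(bind_measures, all_measures)
  report <- tryCatch(reliability_report(measures, group = group),
                     error = function(e) NULL)
  list(measures = measures, report = report, qc = qc, ground_truth = gt)
}
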