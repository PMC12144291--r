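# Synthetic session generation: paradigm event sequences are rendered into
# 63-channel, 1000 Hz recordings with analytically known ground truth.
#
# Amplitude convention: a component kernel's amplitude is calibrated in
# "measure units" - the topography and temporal shape are scaled so that an
# ideal pipeline (average reference over the included channels, difference
# wave, cluster-window mean) scores exactly the requested amplitude. This
# makes end-to-end recovery tests exact by construction.

#' Default component kernels
#'
#' One kernel per scored ERP component: a temporal Gaussian at the
#' component's canonical peak latency and a spatial Gaussian field centered
#' on its peak electrode. Amplitudes are taken at score time from the study
#' truth (or supplied explicitly); negative for the mismatch response,
#' positive for the P300 family.
#'
#' @param fwhm_ms temporal full width at half maximum per kernel
#' @param topo_rho spatial Gaussian width (radians of arc on the unit
#'   sphere)
#' @return named list of kernels aligned with
#'   [default_component_definitions()]
#' @export
default_component_kernels <- function(fwhm_ms = NULL, topo_rho = 0.8) {
  defs <- default_component_definitions()
  fw <- c(mmn = 70, aod_p3b = 160, aod_p3a = 150, vod_p3b = 180,
          vod_p3a = 160)
  if (!is.null(fwhm_ms)) fw[names(fwhm_ms)] <- fwhm_ms
  out <- lapply(names(defs), function(k) {
    d <- defs[[k]]
    list(name = d$name, paradigm = d$paradigm, condition = d$numerator,
         peak_latency_ms = d$peak_latency_ms,
         sigma_ms = fw[[k]] / (2 * sqrt(2 * log(2))),
         peak_electrode = d$peak_electrode, topo_rho = topo_rho,
         cluster = d$cluster, score_window_ms = d$score_window_ms)
  })
  names(out) <- names(defs)
  out
}

# true-scalp spatial field centered on an electrode (or unit vector), over
# all montage positions including the reference
.topo_field <- function(montage, center, rho) {
  pos <- montage$positions
  if (is.character(center) && !center %in% rownames(pos))
    stop("electrode not in montage: ", center)
  cv <- if (is.character(center)) pos[center, ] else center / sqrt(sum(center^2))
  ca <- pos %*% cv
  ca[ca > 1] <- 1; ca[ca < -1] <- -1
  w <- exp(-acos(ca)^2 / (2 * rho^2))
  stats::setNames(as.vector(w), rownames(pos))
}

# recorded-frame topography: the acquisition is referenced to FCz, so the
# recorded value at each electrode is (true - true at FCz)
.recorded_topo <- function(montage, w_true) {
  rec <- setdiff(rownames(montage$positions), montage$reference_label)
  w_true[rec] - w_true[[montage$reference_label]]
}

# scoring gain of a kernel: expected cluster-window mean of a unit-amplitude
# kernel after reference reconstruction and average referencing, on the
# 250 Hz scoring grid
.kernel_score_gain <- function(kernel, montage,
                               exclude = c("TP9", "TP10", "Fp1", "Fp2"),
                               score_fs = 250) {
  w_true <- .topo_field(montage, kernel$peak_electrode, kernel$topo_rho)
  # pipeline frame: recorded channels + reconstructed all-zero reference row
  v <- w_true - w_true[[montage$reference_label]]
  incl <- setdiff(names(v), exclude)
  v_ref <- v - mean(v[incl])
  m_c <- mean(v_ref[kernel$cluster])
  grid <- seq(-2000, 2000, by = 1000 / score_fs)
  wsel <- grid >= kernel$score_window_ms[1] - 1e-9 &
    grid <= kernel$score_window_ms[2] + 1e-9
  wm <- mean(exp(-(grid[wsel] - kernel$peak_latency_ms)^2 /
                   (2 * kernel$sigma_ms^2)))
  m_c * wm
}

#' Draw person-level effects for EEG-level synthesis
#'
#' @param truth a [study_truth()]
#' @param n_persons number of persons
#' @param seed non-negative integer
#' @return matrix persons x measures of person effects `p_i`
#' @export
person_effects <- function(truth, n_persons, seed = 1) {
  m <- truth$measures
  with_seed(seed, function() {
    p <- vapply(m$sigma_p, function(s) stats::rnorm(n_persons, 0, s),
                numeric(n_persons))
    p <- matrix(p, n_persons, nrow(m))
    colnames(p) <- m$measure_name
    p
  })
}

# session-level component amplitudes for one person and occasion:
# mu + p_i + occasion_shift * (occasion - 1) + e_ij
component_session_amplitudes <- function(truth, person_row, occasion, seed,
                                         residual = TRUE) {
  m <- truth$measures
  with_seed(seed, function() {
    e <- if (residual) stats::rnorm(nrow(m), 0, m$sigma_res) else 0
    amps <- m$mu + person_row[m$measure_name] +
      m$occasion_shift * (occasion - 1) + e
    stats::setNames(amps, m$measure_name)
  })
}

# sample from a von Mises distribution (Best-Fisher); kappa = 0 is uniform,
# kappa = Inf is a point mass at mu
.rvonmises <- function(n, kappa, mu = 0) {
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (out + mu + pi) %% (2 * pi) - pi
}

# 1/f^exponent noise (power spectrum), unit RMS, via spectral shaping
.one_over_f <- function(n, fs, exponent = 1) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  f <- c(1, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f + fs / n)  # mirror for the upper half
  gain <- f^(-exponent / 2)
  gain[1] <- 0  # no DC
  x <- Re(stats::fft(sp * gain, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited Gaussian noise with a Gaussian spectral bump, unit RMS
.narrowband <- function(n, fs, f0, bw = 1) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  gain <- exp(-(f - f0)^2 / (2 * bw^2))
  x <- Re(stats::fft(sp * gain, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize one paradigm run
#'
#' Renders the events of a single (paradigm, run) into a 63-channel 1000 Hz
#' recording: ERP kernels scaled by person/occasion/habituation factors,
#' steady-state click-train responses with von Mises trial phase, spatially
#' correlated 1/f background with a parieto-occipital alpha rhythm (boosted
#' for eyes-closed rest), and optional blink/muscle/line/bad-channel
#' artifacts. Button responses to targets are emitted with the configured
#' miss probability and log-normal reaction times.
#'
#' @param events `event_table` rows of one paradigm run (session-relative
#'   onsets; rebased internally)
#' @param paradigm paradigm name
#' @param run run number
#' @param truth a [study_truth()]
#' @param amplitudes named vector of session-level component amplitudes in
#'   measure units (see [component_session_amplitudes()]); the per-run
#'   habituation multiplier is applied on top
#' @param occasion occasion number (1 = baseline, 2 = follow-up); selects
#'   the habituation decay rate when `truth$habituation$run_decay` has
#'   length 2
#' @param seed non-negative integer
#' @param kernels component kernels, see [default_component_kernels()]
#' @param montage montage
#' @param include_noise render background noise (FALSE gives the noise-free
#'   signal path used by analytic recovery tests)
#' @param include_artifacts render blinks, muscle bursts, line noise, bad
#'   channels
#' @param meta session metadata stored on the result
#' @return a `raw_session` (recorded FCz-referenced frame) with
#'   `$ground_truth`: per-component expected run-level and session-level
#'   scores and the steady-state phase-locking target
#' @export
synthesize_run <- function(events, paradigm, run, truth, amplitudes,
                           occasion = 1, seed = 1,
                           kernels = default_component_kernels(),
                           montage = standard_montage(),
                           include_noise = TRUE, include_artifacts = TRUE,
                           meta = list()) {
  fs <- 1000
  dur <- run_recording_duration(paradigm)
  n <- dur * fs
  rec <- setdiff(rownames(montage$positions), montage$reference_label)
  n_ch <- length(rec)
  offset <- .run_offset(events, paradigm, run)
  ev <- as.data.frame(events)
  ev <- ev[ev$paradigm == paradigm & ev$run_index == run, , drop = FALSE]
  ev$onset_time <- ev$onset_time - offset

  r_dec <- truth$habituation$run_decay
  if (length(r_dec) == 1) r_dec <- rep(r_dec, 2)
  run_mult <- (1 - r_dec[occasion])^(run - 1)

  gt <- list(run_multiplier = run_mult, components = list())
  with_seed(seed, function() {
    W <- NULL; S <- NULL
    add_source <- function(w_rec, s) {
      W <<- cbind(W, w_rec[rec])
      S <<- rbind(S, s)
    }

    # ERP component kernels
    for (k in kernels) {
      if (k$paradigm != paradigm) next
      idx <- which(ev$condition == k$condition &
                   ev$modality != "response")
      if (!length(idx)) next
      gain <- .kernel_score_gain(k, montage)
      amp <- unname(amplitudes[[k$name]]) * run_mult
      a_eff <- amp / gain
      w_true <- .topo_field(montage, k$peak_electrode, k$topo_rho)
      w_rec <- w_true - w_true[[montage$reference_label]]
      s <- numeric(n)
      half <- ceiling(4 * k$sigma_ms / 1000 * fs)
      # kernel support relative to stimulus onset (peak after stimulus)
      sup0 <- round(k$peak_latency_ms / 1000 * fs)
      tt <- (sup0 - half):(sup0 + half)
      shape <- exp(-((tt / fs * 1000) - k$peak_latency_ms)^2 /
                     (2 * k$sigma_ms^2))
      for (t0 in round(ev$onset_time[idx] * fs)) {
        ii <- t0 + tt + 1
        ok <- ii >= 1 & ii <= n
        s[ii[ok]] <- s[ii[ok]] + shape[ok]
      }
      add_source(a_eff * w_rec, s)
      gt$components[[k$name]] <<- list(expected_run_score = amp,
                                       n_events = length(idx))
    }

    # steady-state click-train response
    if (paradigm == "assr") {
      a <- truth$assr_amplitude %||% 1.5
      kappa <- truth$assr_phase_jitter
      w_true <- .topo_field(montage, "Cz", 0.7)
      w_rec <- w_true - w_true[[montage$reference_label]]
      s <- numeric(n)
      t_train <- seq(0, 0.5, by = 1 / fs)
      env <- rep(1, length(t_train))
      ramp <- round(0.05 * fs)
      env[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
      env[(length(env) - ramp + 1):length(env)] <- seq(1, 0,
                                                       length.out = ramp)
      phases <- .rvonmises(nrow(ev), kappa)
      for (j in seq_len(nrow(ev))) {
        t0 <- round(ev$onset_time[j] * fs)
        ii <- t0 + seq_along(t_train)
        ok <- ii >= 1 & ii <= n
        s[ii[ok]] <- s[ii[ok]] +
          (sin(2 * pi * 40 * t_train + phases[j]) * env)[ok]
      }
      add_source(a * w_rec, s)
      gt$assr <<- list(amplitude = a, kappa = kappa,
                       expected_itc = .vm_itc(kappa))
    }

    x <- if (is.null(W)) matrix(0, n_ch, n,
                                dimnames = list(rec, NULL))
         else {
           m <- W %*% S
           rownames(m) <- rec
           m
         }

    if (include_noise) x <- x + .background_noise(truth, montage, rec, n, fs,
                                                  paradigm)
    if (include_artifacts) x <- .add_artifacts(x, truth, montage, rec, n, fs)

    # behavioral responses to targets
    ev_out <- ev
    resp <- .simulate_responses(ev, truth$response, dur)
    if (nrow(resp)) {
      ev_out <- rbind(ev_out, resp)
      ev_out <- ev_out[order(ev_out$onset_time), ]
    }
    evt <- event_table(ev_out$onset_time, ev_out$code, ev_out$modality,
                       ev_out$condition, ev_out$run_index, ev_out$paradigm)
    sess <- raw_session(x, fs, montage, evt,
                        meta = c(meta, list(paradigm = paradigm, run = run,
                                            occasion = occasion,
                                            seed = seed)))
    sess$ground_truth <- gt
    sess
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expected inter-trial coherence of a von Mises phase distribution
.vm_itc <- function(kappa) {
  if (is.infinite(kappa)) return(1)
  if (kappa == 0) return(0)
  besselI(kappa, 1) / besselI(kappa, 0)
}

.run_offset <- function(events, paradigm, run) {
  (run - 1) * run_recording_duration(paradigm)
}

# spatially correlated background: latent 1/f sources with smooth random
# topographies + alpha sources + independent sensor noise
.background_noise <- function(truth, montage, rec, n, fs, paradigm) {
  nz <- truth$noise
  n_src <- 12
  W <- matrix(0, length(rec), 0)
  S <- matrix(0, 0, n)
  for (k in seq_len(n_src)) {
    c_vec <- stats::rnorm(3); c_vec[3] <- abs(c_vec[3]) + 0.3
    w_true <- .topo_field(montage, c_vec, 1.0)
    W <- cbind(W, (w_true - w_true[[montage$reference_label]])[rec])
    S <- rbind(S, .one_over_f(n, fs, nz$one_over_f_exponent))
  }
  # scale so the median channel RMS of the 1/f background is nz$scale
  ch_sd <- sqrt(rowSums(W^2))
  W <- W * (nz$scale / stats::median(ch_sd))
  x <- W %*% S

  # alpha rhythm, parieto-occipital, boosted with eyes closed
  gain <- if (paradigm == "rest_closed") nz$alpha_gain_closed else 1
  for (ctr in c("POz", "Oz")) {
    w_true <- .topo_field(montage, ctr, 0.6)
    w <- (w_true - w_true[[montage$reference_label]])[rec]
    x <- x + (nz$alpha_scale * gain) * outer(w, .narrowband(n, fs, nz$alpha_hz))
  }
  x + nz$sensor_noise * matrix(stats::rnorm(length(rec) * n), length(rec), n)
}

.add_artifacts <- function(x, truth, montage, rec, n, fs) {
  nz <- truth$noise
  dur <- n / fs
  # blinks: smooth frontal bumps
  n_blink <- stats::rpois(1, nz$blink_rate * dur / 60)
  if (n_blink > 0) {
    fp_center <- colMeans(montage$positions[c("Fp1", "Fp2"), ])
    w_true <- .topo_field(montage, fp_center, 0.5)
    w <- (w_true - w_true[[montage$reference_label]])[rec]
    blen <- round(0.3 * fs)
    shape <- sin(pi * seq_len(blen) / blen)^2
    s <- numeric(n)
    t0s <- sort(stats::runif(n_blink, 0.5, dur - 0.5))
    for (t0 in round(t0s * fs)) {
      ii <- t0 + seq_len(blen)
      amp <- stats::rnorm(1, 120, 20)
      s[ii] <- s[ii] + amp * shape
    }
    x <- x + outer(w, s)
  }
  # muscle bursts: high-frequency, spatially localized at temporal sites
  n_musc <- stats::rpois(1, nz$muscle_rate * dur / 60)
  if (n_musc > 0) {
    sos <- .butter_sos(4, 25, fs, "high")
    for (j in seq_len(n_musc)) {
      site <- sample(c("T7", "T8", "FT7", "FT8", "TP7", "TP8"), 1)
      w_true <- .topo_field(montage, site, 0.3)
      w <- (w_true - w_true[[montage$reference_label]])[rec]
      blen <- round(stats::runif(1, 0.2, 0.5) * fs)
      t0 <- round(stats::runif(1, 1, dur - 1) * fs)
      burst <- .sos_filtfilt_vec(sos, stats::rnorm(blen), pad = 50)
      burst <- burst / stats::sd(burst) * 15 * sin(pi * seq_len(blen) / blen)
      ii <- t0 + seq_len(blen)
      x[, ii] <- x[, ii] + outer(w, burst)
    }
  }
  # line noise: common sinusoid with per-channel gain
  if (nz$line_amp > 0) {
    tvec <- (seq_len(n) - 1) / fs
    s <- sin(2 * pi * nz$line_hz * tvec + stats::runif(1, 0, 2 * pi))
    g <- stats::runif(length(rec), 0.5, 1.5) * nz$line_amp
    x <- x + outer(g, s)
  }
  # dead/noisy channels
  for (bc in intersect(nz$bad_channels, rec)) {
    x[bc, ] <- stats::rnorm(n, 0, 50 * max(nz$scale, 1))
  }
  x
}

.simulate_responses <- function(ev, resp_par, dur) {
  stim <- ev[ev$modality %in% c("auditory", "visual") &
             ev$paradigm %in% c("aod", "mmn_vod"), , drop = FALSE]
  # only the attended stream yields button presses
  if (nrow(stim) && stim$paradigm[1] == "mmn_vod")
    stim <- stim[stim$modality == "visual", , drop = FALSE]
  if (!nrow(stim)) return(ev[0, , drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(stim))) {
    cond <- stim$condition[i]
    press <- if (cond == "target") stats::runif(1) > resp_par$miss_prob
             else stats::runif(1) < resp_par$fa_prob
    if (!press) next
    rt <- stats::rlnorm(1, log(resp_par$rt_median_s), resp_par$rt_sdlog)
    rt <- min(max(rt, 0.15), 0.99)
    t_r <- round((stim$onset_time[i] + rt) * 1000) / 1000
    if (t_r >= dur) next
    out[[length(out) + 1]] <- data.frame(
      onset_time = t_r, code = "R  1", modality = "response",
      condition = "button", run_index = stim$run_index[i],
      paradigm = stim$paradigm[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(ev[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Synthesize a full session for one person and occasion
#'
#' Generates the paradigm event sequences and renders each run into its own
#' recording (runs are independent recordings, as acquired), returning the
#' per-run sessions together with the analytic ground truth.
#'
#' @param truth a [study_truth()]
#' @param person_row named person-effect vector (one row of
#'   [person_effects()]); zeros if `NULL`
#' @param occasion occasion number (1 or 2)
#' @param seed non-negative integer controlling sequences, noise, residuals,
#'   and responses
#' @param paradigms which paradigms to render
#' @param kernels component kernels
#' @param include_noise,include_artifacts see [synthesize_run()]
#' @param meta session metadata (`subject_id`, `group`, ...)
#' @return object of class `session_set`: list with `runs` (list of
#'   `raw_session`), `events` (full session event table), `amplitudes`,
#'   and `ground_truth` (per-component expected session-level scores)
#' @export
synthesize_session <- function(truth, person_row = NULL, occasion = 1,
                               seed = 1,
                               paradigms = c("mmn_vod", "aod", "assr",
                                             "rest_open", "rest_closed"),
                               kernels = default_component_kernels(),
                               include_noise = TRUE,
                               include_artifacts = TRUE,
                               meta = list()) {
  if (is.null(person_row)) {
    person_row <- stats::setNames(rep(0, nrow(truth$measures)),
                                  truth$measures$measure_name)
  }
  amps <- component_session_amplitudes(truth, person_row, occasion,
                                       seed = .derive_seed(seed, 1),
                                       residual = include_noise)
  spec <- paradigm_spec()
  runs <- list()
  all_events <- list()
  r_dec <- truth$habituation$run_decay
  if (length(r_dec) == 1) r_dec <- rep(r_dec, 2)

  for (p in paradigms) {
    ev <- switch(p,
      mmn_vod = generate_mmn_vod_sequence(spec, .derive_seed(seed, 2)),
      aod = generate_aod_sequence(spec, .derive_seed(seed, 3)),
      assr = generate_assr_sequence(spec, .derive_seed(seed, 4)),
      rest_open = empty_event_table(),
      rest_closed = empty_event_table())
    n_runs <- if (nrow(ev)) max(ev$run_index) else 1L
    for (r in seq_len(n_runs)) {
      sess <- synthesize_run(ev, p, r, truth, amps, occasion = occasion,
                             seed = .derive_seed(seed, 10 + r, p),
                             kernels = kernels,
                             include_noise = include_noise,
                             include_artifacts = include_artifacts,
                             meta = meta)
      runs[[paste0(p, "_run", r)]] <- sess
    }
    if (nrow(ev)) all_events[[p]] <- ev
  }

  # expected session-level scores: equal trials per run, so the session
  # score is the mean over runs of the run-decay multiplier times the
  # session amplitude
  gt <- list()
  for (k in kernels) {
    n_runs <- spec[[switch(k$paradigm, mmn_vod = "mmn", aod = "aod")]]$n_runs
    mult <- mean((1 - r_dec[occasion])^(seq_len(n_runs) - 1))
    gt[[k$name]] <- unname(amps[[k$name]]) * mult
  }
  structure(list(runs = runs,
                 events = do.call(rbind, all_events),
                 amplitudes = amps, ground_truth = gt,
                 occasion = occasion, meta = meta, seed = seed),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("<session_set> %d run recordings, occasion %d\n",
              length(x$runs), x$occasion))
  invisible(x)
}

# deterministic sub-seed derivation (kept below 2^31)
.derive_seed <- function(seed, k, tag = "") {
  h <- sum(utf8ToInt(tag)) %% 1000
  as.integer((as.numeric(seed) * 7919 + k * 104729 + h) %% 2147483647)
}
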