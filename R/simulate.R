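#' Ground-truth parameters for study-level simulation
#'
#' Bundles the parameters of the persons x occasions measurement model
#' `y_ij = mu + p_i + o_j + e_ij`, with `p_i ~ N(0, sigma_p^2)` (stable
#' person-level trait), `o_j` fixed occasion shifts (habituation over
#' sessions), and `e_ij ~ N(0, sigma_res^2)` (person-by-occasion interaction
#' plus measurement error), together with the signal-level parameters used by
#' the session synthesizer.
#'
#' The population G-coefficient implied by a row is
#' `sigma_p^2 / (sigma_p^2 + sigma_res^2)` for `n_o = 1`.
#'
#' @param measures data.frame with columns `measure_name`, `mu`, `sigma_p`,
#'   `occasion_shift`, `sigma_res` (one row per measure); defaults cover the
#'   package's scored measures with reliabilities in the good-to-excellent
#'   range typical of these paradigms
#' @param habituation list with per-run multiplicative decay rates:
#'   `run_decay` (amplitude multiplier `(1 - r)^(run-1)` within session) and
#'   `session_scale` (multiplier `s^(occasion-1)` across sessions), per
#'   component name
#' @param noise list of background-noise parameters for session synthesis:
#'   `scale` (background RMS in microvolts), `one_over_f_exponent`,
#'   `alpha_hz`, `alpha_gain_closed`, `alpha_scale`, `line_hz`, `line_amp`,
#'   `blink_rate` (per minute), `muscle_rate` (per minute), `bad_channels`
#'   (labels), `sensor_noise` (channel-independent RMS)
#' @param assr_phase_jitter von Mises concentration kappa of the trial phase
#'   distribution of the steady-state response (`Inf` = perfect locking)
#' @param response list: `miss_prob`, `fa_prob`, `rt_median_s`,
#'   `rt_sdlog`
#' @return object of class `study_truth`
#' @export
study_truth <- function(measures = default_truth_measures(),
                        habituation = list(run_decay = 0.05,
                                           session_scale = 0.93),
                        noise = list(scale = 10, one_over_f_exponent = 1,
                                     alpha_hz = 10, alpha_gain_closed = 2,
                                     alpha_scale = 4, line_hz = 60,
                                     line_amp = 0, blink_rate = 8,
                                     muscle_rate = 2,
                                     bad_channels = character(0),
                                     sensor_noise = 1),
                        assr_phase_jitter = 4,
                        response = list(miss_prob = 0.04, fa_prob = 0.01,
                                        rt_median_s = 0.45,
                                        rt_sdlog = 0.22)) {
  stopifnot(all(c("measure_name", "mu", "sigma_p", "occasion_shift",
                  "sigma_res") %in% names(measures)))
  stopifnot(all(measures$sigma_p >= 0), all(measures$sigma_res >= 0),
            assr_phase_jitter >= 0)
  structure(list(measures = measures, habituation = habituation,
                 noise = noise, assr_phase_jitter = assr_phase_jitter,
                 response = response),
            class = "study_truth")
}

#' Default measure-level truth table
#'
#' Typical magnitudes for the scored measures (microvolts for ERP amplitudes,
#' unitless ITC, dB for total power, ms for median RT, microvolts^2/Hz for
#' band power) with person/residual standard deviations chosen so that the
#' implied test-retest G-coefficients fall in the published good-to-excellent
#' range for these paradigms, and small negative occasion shifts emulating
#' session-level habituation of the evoked measures.
#'
#' @return data.frame usable as the `measures` field of [study_truth()]
#' @export
default_truth_measures <- function() {
  df <- rbind(
    data.frame(measure_name = "mmn_amplitude",        mu = -2.5, sigma_p = 0.95, occasion_shift = 0.15,  sigma_res = 0.50),
    data.frame(measure_name = "aod_p3b_amplitude",    mu = 5.0,  sigma_p = 1.90, occasion_shift = -0.40, sigma_res = 1.20),
    data.frame(measure_name = "aod_p3a_amplitude",    mu = 4.0,  sigma_p = 1.50, occasion_shift = 0.00,  sigma_res = 1.00),
    data.frame(measure_name = "vod_p3b_amplitude",    mu = 6.0,  sigma_p = 2.20, occasion_shift = -0.35, sigma_res = 1.25),
    data.frame(measure_name = "vod_p3a_amplitude",    mu = 4.5,  sigma_p = 1.70, occasion_shift = -0.50, sigma_res = 1.05),
    data.frame(measure_name = "assr_itc",             mu = 0.35, sigma_p = 0.09, occasion_shift = 0.00,  sigma_res = 0.06),
    data.frame(measure_name = "assr_evoked_power",    mu = 1.2,  sigma_p = 0.50, occasion_shift = -0.05, sigma_res = 0.29),
    data.frame(measure_name = "assr_total_power",     mu = 1.5,  sigma_p = 0.55, occasion_shift = 0.00,  sigma_res = 0.40),
    data.frame(measure_name = "rest_open_alpha",      mu = 12,   sigma_p = 5.0,  occasion_shift = 0.00,  sigma_res = 2.1),
    data.frame(measure_name = "rest_closed_alpha",    mu = 25,   sigma_p = 9.0,  occasion_shift = 0.00,  sigma_res = 4.4),
    data.frame(measure_name = "aod_median_rt",        mu = 450,  sigma_p = 75,   occasion_shift = -5,    sigma_res = 40),
    data.frame(measure_name = "vod_median_rt",        mu = 480,  sigma_p = 80,   occasion_shift = 10,    sigma_res = 42)
  )
  df$measure_name <- as.character(df$measure_name)
  df
}

#' Simulate measure-level study data
#'
#' Draws a balanced complete persons x occasions measure table directly from
#' the measurement model `y_ij = mu + p_i + o_j + e_ij` (no signal
#' synthesis), for fast reliability-recovery and calibration studies.
#'
#' @param truth a [study_truth()]; every row of `truth$measures` is simulated
#' @param n_persons number of persons (>= 2)
#' @param n_occasions number of occasions (>= 2); occasion shift `o_j` is
#'   `occasion_shift * (j - 1)`
#' @param seed non-negative integer
#' @param group group label for all persons
#' @return a [measure_table()] with run `"all"` rows
#' @export
simulate_measures <- function(truth, n_persons, n_occasions = 2, seed = 1,
                              group = "CHR") {
  stopifnot(inherits(truth, "study_truth"), n_persons >= 2, n_occasions >= 2)
  occ_names <- if (n_occasions == 2) c("baseline", "month2")
               else paste0("occasion", seq_len(n_occasions))
  with_seed(seed, function() {
    parts <- vector("list", nrow(truth$measures))
    ids <- sprintf("sub%05d", seq_len(n_persons))
    for (i in seq_len(nrow(truth$measures))) {
      m <- truth$measures[i, ]
      if (!is.finite(m$sigma_p) || !is.finite(m$sigma_res))
        stop("non-finite variance for measure ", m$measure_name)
      p <- stats::rnorm(n_persons, 0, m$sigma_p)
      y <- outer(p, m$occasion_shift * (seq_len(n_occasions) - 1), `+`) +
        m$mu + stats::rnorm(n_persons * n_occasions, 0, m$sigma_res)
      parts[[i]] <- data.frame(
        subject_id = rep(ids, n_occasions),
        group = group,
        occasion = rep(occ_names, each = n_persons),
        run_index = "all",
        measure_name = m$measure_name,
        value = as.vector(y),
        stringsAsFactors = FALSE
      )
    }
    df <- do.call(rbind, parts)
    measure_table(df$subject_id, df$group, df$occasion, df$run_index,
                  df$measure_name, df$value)
  })
}

#' Simulate run-level scores with habituation
#'
#' Fast measure-level emulation of per-run component scores: the person- and
#' occasion-level model of [simulate_measures()] with a multiplicative
#' within-session run decay `(1 - r)^(run - 1)` whose rate may differ between
#' sessions (steeper decay at follow-up reproduces the published
#' Session x Run interaction pattern).
#'
#' @param truth a [study_truth()]
#' @param measure one measure name from `truth$measures`
#' @param n_persons persons
#' @param n_runs runs per session
#' @param run_decay length-2 numeric: per-run decay rate at (baseline,
#'   follow-up); defaults to `truth$habituation$run_decay` and 1.6x that at
#'   follow-up
#' @param seed non-negative integer
#' @param group group label
#' @return a [measure_table()] with run-level rows at both occasions
#' @export
simulate_run_measures <- function(truth, measure = "mmn_amplitude",
                                  n_persons = 100, n_runs = 5,
                                  run_decay = NULL, seed = 1, group = "CHR") {
  m <- truth$measures[truth$measures$measure_name == measure, ]
  if (!nrow(m)) stop("unknown measure: ", measure)
  if (is.null(run_decay)) {
    r0 <- truth$habituation$run_decay
    run_decay <- c(r0, 1.6 * r0)
  }
  ses_scale <- truth$habituation$session_scale
  occ <- c("baseline", "month2")
  with_seed(seed, function() {
    ids <- sprintf("sub%05d", seq_len(n_persons))
    p <- stats::rnorm(n_persons, 0, m$sigma_p)
    parts <- list()
    for (s in 1:2) {
      for (r in seq_len(n_runs)) {
        mult <- (1 - run_decay[s])^(r - 1) * ses_scale^(s - 1)
        # run-level scores average ~1/n_runs of the trials, so run-level
        # noise is inflated relative to the session-level residual
        y <- (m$mu + p) * mult +
          stats::rnorm(n_persons, 0, m$sigma_res * sqrt(n_runs))
        parts[[length(parts) + 1]] <- data.frame(
          subject_id = ids, group = group, occasion = occ[s],
          run_index = as.character(r), measure_name = measure, value = y,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, parts)
    measure_table(df$subject_id, df$group, df$occasion, df$run_index,
                  df$measure_name, df$value)
  })
}
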