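#' Paradigm constants
#'
#' Fixed stimulus-sequence parameters for the five session paradigms:
#' * MMN stream: 633 Hz/50 ms standards (90%) and 1000 Hz/100 ms
#'   pitch+duration double deviants (10%), 500 ms SOA, 5 runs of 640 tones,
#'   each run opening with 20 standards (3200 tones total).
#' * Visual oddball (VOD), interleaved with the MMN stream: 80/10/10%
#'   standard/target/novel, 500 ms stimulus duration, SOA uniform on a
#'   1.6-2.4 s grid in 1/60 s steps (display-frame quantized), 5 runs of 160
#'   (800 total: 640/80/80).
#' * Auditory oddball (AOD): 80/10/10%, SOA uniform on a 1.1-1.4 s grid in
#'   25 ms steps, 4 runs of 200 (800 total).
#' * 40-Hz ASSR: 150 click trains, 500 ms each, clicks every 25 ms (40 Hz),
#'   SOA 1.5 s.
#' * Resting: 185 s eyes open, 185 s eyes closed.
#'
#' @return nested list of paradigm constants
#' @export
paradigm_spec <- function() {
  list(
    mmn = list(n_runs = 5L, tones_per_run = 640L, soa = 0.5,
               p_deviant = 0.1, leading_standards = 20L,
               standard_hz = 633, standard_ms = 50,
               deviant_hz = 1000, deviant_ms = 100),
    vod = list(n_runs = 5L, stim_per_run = 160L, p_target = 0.1,
               p_novel = 0.1, stim_dur = 0.5,
               soa_min = 1.6, soa_max = 2.4, soa_step = 1 / 60,
               min_cross_modal_gap = 0.05),
    aod = list(n_runs = 4L, stim_per_run = 200L, p_target = 0.1,
               p_novel = 0.1,
               soa_min = 1.1, soa_max = 1.4, soa_step = 0.025),
    assr = list(n_trials = 150L, train_dur = 0.5, click_interval = 0.025,
                soa = 1.5),
    rest = list(duration = 185, n_epochs = 180L)
  )
}

#' Session run timeline
#'
#' The published fixed run order of a recording session, with per-block
#' durations in seconds (instruction and practice blocks included). The total
#' is 3443 s (57:23). Note the printed ASSR block duration is shorter than
#' 150 trials at a 1.5 s SOA; the timeline reproduces the published schedule
#' while the sequence generator follows the stated trial count and SOA.
#'
#' @return data.frame with columns `order`, `block`, `paradigm`, `run`,
#'   `duration_s`
#' @export
session_timeline <- function() {
  data.frame(
    order = 1:16,
    block = c("MMN/VOD instructions", "VOD practice", "MMN/VOD run",
              "AOD instructions", "AOD practice", "AOD run",
              "MMN/VOD run", "AOD run", "MMN/VOD run", "AOD run",
              "MMN/VOD run", "AOD run", "MMN/VOD run",
              "40-Hz ASSR", "Resting eyes open", "Resting eyes closed"),
    paradigm = c(NA, NA, "mmn_vod", NA, NA, "aod", "mmn_vod", "aod",
                 "mmn_vod", "aod", "mmn_vod", "aod", "mmn_vod", "assr",
                 "rest_open", "rest_closed"),
    run = c(NA, NA, 1, NA, NA, 1, 2, 2, 3, 3, 4, 4, 5, 1, 1, 1),
    duration_s = c(50, 105, 320, 38, 105, 255, 320, 255, 320, 255, 320,
                   255, 320, 155, 185, 185),
    stringsAsFactors = FALSE
  )
}

# run a function with a local, seeded RNG without disturbing the caller's
# RNG state
with_seed <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0)
    stop("seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# constrained pseudorandom oddball order: rare stimuli never occur on two
# consecutive positions (rares pooled: no rare directly follows any rare)
.constrained_order <- function(n, n_rare_each, rare_labels,
                               standard_label = "standard",
                               max_tries = 1000) {
  n_rare <- sum(n_rare_each)
  for (try in seq_len(max_tries)) {
    # choose rare slots by gap sampling: need gaps >= 1 standard between rares
    slots <- sort(sample.int(n - n_rare + 1, n_rare)) + seq_len(n_rare) - 1
    # the +offset trick guarantees non-adjacent slots
    labels <- rep(standard_label, n)
    rare_seq <- sample(rep(rare_labels, n_rare_each))
    labels[slots] <- rare_seq
    return(labels)
  }
  stop("could not build constrained order")
}

#' Generate the interleaved MMN/VOD stimulus sequence
#'
#' Five runs; per run 640 tones at 500 ms SOA beginning with 20 standards
#' followed by a constrained pseudorandom 90/10 standard/deviant order (no two
#' consecutive deviants), and 160 visual stimuli (128 standard / 16 target /
#' 16 novel, no two consecutive rares) with frame-quantized jittered SOA.
#' Visual onsets are re-jittered until every one is at least 50 ms away from
#' every tone onset, so the two stimulus streams are never simultaneous.
#' Onsets are session-relative with runs laid out back to back and rounded to
#' the 1000 Hz sample grid.
#'
#' @param spec [paradigm_spec()]
#' @param seed non-negative integer; the sequence is deterministic given the
#'   seed
#' @return an [event_table()] with paradigm `"mmn_vod"`
#' @export
generate_mmn_vod_sequence <- function(spec = paradigm_spec(), seed = 1) {
  m <- spec$mmn; v <- spec$vod
  with_seed(seed, function() {
    run_len <- run_recording_duration("mmn_vod")
    out <- vector("list", m$n_runs)
    for (r in seq_len(m$n_runs)) {
      offset <- (r - 1) * run_len
      n_tail <- m$tones_per_run - m$leading_standards
      n_dev <- as.integer(round(m$tones_per_run * m$p_deviant))
      tail_cond <- .constrained_order(n_tail, n_dev, "deviant")
      tone_cond <- c(rep("standard", m$leading_standards), tail_cond)
      tone_onset <- offset + 2 + (seq_len(m$tones_per_run) - 1) * m$soa

      n_t <- as.integer(round(v$stim_per_run * v$p_target))
      n_n <- as.integer(round(v$stim_per_run * v$p_novel))
      vis_cond <- .constrained_order(v$stim_per_run, c(n_t, n_n),
                                     c("target", "novel"))
      vis_onset <- .jitter_visual_onsets(v, m, offset, run_len)

      df <- rbind(
        data.frame(onset_time = tone_onset,
                   code = ifelse(tone_cond == "deviant", "S  2", "S  1"),
                   modality = "auditory", condition = tone_cond,
                   stringsAsFactors = FALSE),
        data.frame(onset_time = vis_onset,
                   code = c(standard = "S  3", target = "S  4",
                            novel = "S  5")[vis_cond],
                   modality = "visual", condition = vis_cond,
                   stringsAsFactors = FALSE)
      )
      df$run_index <- r
      out[[r]] <- df[order(df$onset_time), ]
    }
    df <- do.call(rbind, out)
    event_table(df$onset_time, df$code, df$modality, df$condition,
                df$run_index, "mmn_vod")
  })
}

# Nominal per-run recording durations (seconds) for synthesized runs: the
# stimulus payload plus lead-in/lead-out so that the widest epoch window fits
# around every event.
run_recording_duration <- function(paradigm) {
  switch(paradigm,
         mmn_vod = 330, aod = 255, assr = 228,
         rest_open = 185, rest_closed = 185,
         stop("unknown paradigm: ", paradigm))
}

# Draw visual onsets sequentially on the 1/60 s SOA grid, redrawing any SOA
# whose resulting onset would fall within the cross-modal gap of a tone onset
# (tones sit on the 0.5 s grid). Onsets are snapped to the 1000 Hz sample
# grid only at the end.
.jitter_visual_onsets <- function(v, m, offset, run_len, max_tries = 200) {
  n <- v$stim_per_run
  grid <- seq(v$soa_min, v$soa_max, by = v$soa_step)
  phase_ok <- function(t) {
    ph <- (t - offset) %% m$soa
    min(ph, m$soa - ph) >= v$min_cross_modal_gap - 1e-9
  }
  for (try in seq_len(max_tries)) {
    on <- numeric(n)
    t <- offset + 2
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_len(60)) {
        cand <- t + sample(grid, 1)
        if (phase_ok(cand)) { on[i] <- cand; t <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok && on[n] <= offset + run_len - 3) {
      on <- round(on * 1000) / 1000
      if (!anyDuplicated(on)) return(on)
    }
  }
  stop("could not place visual onsets with the required cross-modal gap")
}

#' Generate the auditory oddball (AOD) stimulus sequence
#'
#' Four runs of 200 stimuli (160 standard / 20 target / 20 novel, no two
#' consecutive rares) with SOA drawn uniformly from the 1.1-1.4 s grid in
#' 25 ms steps. Onsets are session-relative (runs back to back, nominal run
#' length from the session timeline) and deterministic given the seed.
#'
#' @inheritParams generate_mmn_vod_sequence
#' @return an [event_table()] with paradigm `"aod"`
#' @export
generate_aod_sequence <- function(spec = paradigm_spec(), seed = 1) {
  a <- spec$aod
  with_seed(seed, function() {
    grid <- seq(a$soa_min, a$soa_max, by = a$soa_step)
    run_len <- run_recording_duration("aod")  # payload ~250 s plus padding
    out <- vector("list", a$n_runs)
    for (r in seq_len(a$n_runs)) {
      offset <- (r - 1) * run_len
      n_t <- as.integer(round(a$stim_per_run * a$p_target))
      n_n <- as.integer(round(a$stim_per_run * a$p_novel))
      cond <- .constrained_order(a$stim_per_run, c(n_t, n_n),
                                 c("target", "novel"))
      soas <- sample(grid, a$stim_per_run, replace = TRUE)
      onset <- offset + 2 + cumsum(c(0, soas[-a$stim_per_run]))
      out[[r]] <- data.frame(
        onset_time = onset,
        code = c(standard = "S  1", target = "S  4",
                 novel = "S  5")[cond],
        modality = "auditory", condition = cond, run_index = r,
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    event_table(df$onset_time, df$code, df$modality, df$condition,
                df$run_index, "aod")
  })
}

#' Generate the 40-Hz ASSR click-train sequence
#'
#' 150 train-onset events at a fixed 1.5 s SOA; each 500 ms train implies 20
#' clicks at 25 ms spacing (40 Hz stimulation).
#'
#' @inheritParams generate_mmn_vod_sequence
#' @return an [event_table()] with paradigm `"assr"`
#' @export
generate_assr_sequence <- function(spec = paradigm_spec(), seed = 1) {
  s <- spec$assr
  onset <- 2 + (seq_len(s$n_trials) - 1) * s$soa
  event_table(onset, "S 10", "click_train", "train", 1L, "assr")
}
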