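#' Oddball task performance from an event stream
#'
#' Attributes each button response to the most recent stimulus whose
#' response window contains it (each response to at most one stimulus; later
#' responses to the same stimulus are ignored). Targets without an
#' attributed response are misses; responses attributed to novels or
#' standards are false alarms. Reaction time is response onset minus target
#' onset; the reported RT is the median over correct targets.
#'
#' @param events an `event_table` containing stimulus and response records
#'   (one paradigm)
#' @param response_window seconds after stimulus onset within which a
#'   response may be attributed (default `c(0.1, 1.0)`, below the minimum
#'   SOA so a response can match at most one stimulus)
#' @return object of class `performance_result`: `miss_rate_targets`,
#'   `fa_rate_novels`, `fa_rate_standards` (percent), `median_rt_ms`,
#'   counts per category
#' @export
score_performance <- function(events, response_window = c(0.1, 1.0)) {
  ev <- as.data.frame(events)
  stim <- ev[ev$modality != "response", ]
  resp <- ev[ev$modality == "response", ]
  if (!nrow(stim) || !any(stim$condition == "target"))
    stop("no target stimuli in event stream")

  hit_stim <- rep(NA_integer_, nrow(resp))
  answered <- rep(FALSE, nrow(stim))
  rt <- rep(NA_real_, nrow(stim))
  if (nrow(resp)) {
    for (i in seq_len(nrow(resp))) {
      t_r <- resp$onset_time[i]
      cand <- which(stim$onset_time <= t_r - response_window[1] &
                    stim$onset_time >= t_r - response_window[2])
      if (!length(cand)) next
      j <- cand[length(cand)]  # most recent qualifying stimulus
      if (answered[j]) next    # already attributed
      answered[j] <- TRUE
      hit_stim[i] <- j
      rt[j] <- t_r - stim$onset_time[j]
    }
  }
  is_t <- stim$condition == "target"
  is_n <- stim$condition == "novel"
  is_s <- stim$condition == "standard"
  n_t <- sum(is_t); n_n <- sum(is_n); n_s <- sum(is_s)
  miss <- 100 * sum(is_t & !answered) / n_t
  fa_n <- if (n_n) 100 * sum(is_n & answered) / n_n else NA_real_
  fa_s <- if (n_s) 100 * sum(is_s & answered) / n_s else NA_real_
  rts <- rt[is_t & answered]
  structure(
    list(miss_rate_targets = miss, fa_rate_novels = fa_n,
         fa_rate_standards = fa_s,
         median_rt_ms = if (length(rts)) 1000 * stats::median(rts)
                        else NA_real_,
         n = c(targets = n_t, novels = n_n, standards = n_s,
               responses = nrow(resp), correct_targets = length(rts))),
    class = "performance_result"
  )
}

#' @export
print.performance_result <- function(x, ...) {
  cat(sprintf(
    "<performance_result> miss %.1f%%, FA novel %.2f%%, FA standard %.2f%%, median RT %.0f ms\n",
    x$miss_rate_targets, x$fa_rate_novels, x$fa_rate_standards,
    x$median_rt_ms))
  invisible(x)
}

#' Performance rows for a measure table
#'
#' @param events paradigm event stream including responses
#' @param paradigm `"aod"` or `"vod"` (prefix of the measure names)
#' @param meta list with `subject_id`, `group`, `occasion`
#' @return a [measure_table()] with miss/FA/RT rows, run `"all"`
#' @export
performance_measures <- function(events, paradigm, meta) {
  ev <- as.data.frame(events)
  # the interleaved task's performance concerns the visual stream only
  task_mod <- if (paradigm == "vod") "visual" else "auditory"
  ev <- ev[ev$modality %in% c(task_mod, "response"), ]
  class(ev) <- c("event_table", "data.frame")
  pr <- score_performance(ev)
  measure_table(
    subject_id = meta$subject_id, group = meta$group,
    occasion = meta$occasion, run_index = "all",
    measure_name = paste0(paradigm, c("_miss_rate", "_fa_novel",
                                      "_fa_standard", "_median_rt")),
    value = c(pr$miss_rate_targets, pr$fa_rate_novels,
              pr$fa_rate_standards, pr$median_rt_ms)
  )
}
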