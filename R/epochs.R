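#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per selected event using a half-open window
#' `[start, end)` in seconds relative to event onset. Events whose epoch
#' would extend beyond the recording are dropped with a warning.
#'
#' @param raw a `raw_session`
#' @param events an `event_table` subset selecting the events to epoch
#'   (defaults to all stimulus events in the session)
#' @param window length-2 numeric `(start, end)` in seconds, bracketing 0
#' @return object of class `epoch_set`: `data` is a channels x time x epochs
#'   array; `times` holds the sample times relative to onset; `condition`,
#'   `run_index`, `onset` per epoch; `rejected`/`reject_reason` flags
#' @export
epoch <- function(raw, events = NULL, window) {
  stopifnot(length(window) == 2, window[1] < 0, window[2] > 0)
  if (is.null(events)) events <- raw$events[raw$events$modality != "response", ]
  if (!nrow(events)) stop("empty event selection")
  fs <- raw$sampling_rate
  n_samp <- ncol(raw$data)
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)  # half-open
  onset_samp <- round(events$onset_time * fs)
  ok <- onset_samp + rel[1] >= 0 & onset_samp + rel[length(rel)] <= n_samp - 1
  if (!all(ok)) {
    warning(sum(!ok), " events too close to recording edges dropped")
    events <- events[ok, , drop = FALSE]
    onset_samp <- onset_samp[ok]
  }
  if (!nrow(events)) stop("empty event selection after edge dropping")
  n_ep <- nrow(events); n_ch <- nrow(raw$data); n_t <- length(rel)
  idx <- outer(rel, onset_samp, `+`) + 1L  # 0-based samples -> R indices
  data <- array(raw$data[, as.vector(idx)], dim = c(n_ch, n_t, n_ep),
                dimnames = list(rownames(raw$data), NULL, NULL))
  structure(
    list(data = data, times = rel / fs, sampling_rate = fs,
         channels = rownames(raw$data), condition = events$condition,
         run_index = events$run_index, onset = events$onset_time,
         rejected = rep(FALSE, n_ep),
         reject_reason = rep(NA_character_, n_ep),
         reference = raw$reference, montage = raw$montage),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d ch x %d samples @ %g Hz [%0.3f, %0.3f) s, %d rejected\n",
    dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$sampling_rate,
    x$times[1], x$times[length(x$times)] + 1 / x$sampling_rate,
    sum(x$rejected)))
  invisible(x)
}

#' Number of surviving (non-rejected) epochs
#' @param epochs an `epoch_set`
#' @param condition optional condition filter
#' @return integer count
#' @export
n_surviving <- function(epochs, condition = NULL) {
  keep <- !epochs$rejected
  if (!is.null(condition)) keep <- keep & epochs$condition %in% condition
  sum(keep)
}

#' Epoch-statistic outlier rejection (z >= 3 rule)
#'
#' Computes three per-epoch statistics, each averaged over channels: mean
#' amplitude, variance, and peak-to-peak voltage. Each statistic is z-scored
#' across epochs once (no re-iteration) and epochs with `|z| >= z_max` on any
#' statistic are flagged as rejected with the offending criterion recorded.
#' A degenerate zero-spread statistic defines no rejections.
#'
#' @param epochs an `epoch_set`
#' @param z_max rejection threshold in standard deviations (default 3)
#' @return `epoch_set` with updated `rejected`/`reject_reason`
#' @export
reject_epochs_faster <- function(epochs, z_max = 3) {
  x <- epochs$data
  n_ep <- dim(x)[3]
  if (n_ep < 3) stop("need at least 3 epochs")
  stat_mean <- apply(x, 3, mean)
  stat_var <- colMeans(apply(x, c(1, 3), stats::var))
  stat_p2p <- colMeans(apply(x, c(1, 3), function(v) max(v) - min(v)))
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  z <- cbind(mean_amplitude = zs(stat_mean), variance = zs(stat_var),
             peak_to_peak = zs(stat_p2p))
  hit <- abs(z) >= z_max
  flag <- rowSums(hit) > 0
  reason <- apply(hit, 1, function(h)
    if (any(h)) paste(colnames(z)[h], collapse = "+") else NA_character_)
  epochs$rejected <- epochs$rejected | flag
  epochs$reject_reason <- ifelse(flag & is.na(epochs$reject_reason),
                                 reason, epochs$reject_reason)
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts the per-epoch, per-channel mean over the baseline window
#' (samples whose centers lie in the closed interval) from every sample.
#'
#' @param epochs an `epoch_set`
#' @param window length-2 numeric baseline window in seconds (default
#'   `c(-0.1, 0)`)
#' @return baseline-corrected `epoch_set`
#' @export
baseline_correct <- function(epochs, window = c(-0.1, 0)) {
  sel <- epochs$times >= window[1] - 1e-9 & epochs$times <= window[2] + 1e-9
  if (!any(sel)) stop("baseline window outside epoch")
  d <- dim(epochs$data)
  bl <- apply(epochs$data[, sel, , drop = FALSE], c(1, 3), mean)
  epochs$data <- epochs$data - aperm(array(bl, c(d[1], d[3], d[2])),
                                     c(1, 3, 2))
  epochs
}

# concatenate surviving epochs into channels x (time*epochs), plus index info
.concat_epochs <- function(epochs, surviving_only = TRUE) {
  keep <- if (surviving_only) !epochs$rejected else rep(TRUE, dim(epochs$data)[3])
  x <- epochs$data[, , keep, drop = FALSE]
  d <- dim(x)
  mat <- matrix(x, d[1], d[2] * d[3])
  rownames(mat) <- epochs$channels
  list(mat = mat, n_time = d[2], n_ep = d[3], keep = keep)
}

# write a channels x (time*epochs) matrix back into the kept epochs
.unconcat_epochs <- function(epochs, mat, keep) {
  d <- dim(epochs$data)
  epochs$data[, , keep] <- array(mat, c(d[1], d[2], sum(keep)))
  epochs
}
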