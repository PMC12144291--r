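# Butterworth filtering as a cascade of bilinear-transformed second-order
# sections. The cascade form stays numerically stable for the very low
# relative cutoffs used here (0.2 Hz at 1000 Hz), where a single expanded
# polynomial would be ill-conditioned.

# analog Butterworth pole pairs for even order n (normalized cutoff 1 rad/s)
.butter_pole_pairs <- function(n) {
  stopifnot(n %% 2 == 0)
  k <- seq_len(n / 2)
  theta <- pi * (2 * k - 1) / (2 * n) + pi / 2
  exp(1i * theta)  # upper-half-plane pole of each conjugate pair
}

# second-order sections for a digital Butterworth filter
.butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must lie in (0, Nyquist)")
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)  # prewarped analog cutoff
  K <- 2 * fs
  lapply(.butter_pole_pairs(order), function(p0) {
    p <- wc * (if (type == "low") p0 else 1 / p0)
    a1 <- -2 * Re(p); a0 <- Mod(p)^2
    if (type == "low") { b2 <- 0; b1 <- 0; b0 <- a0 } else {
      b2 <- 1; b1 <- 0; b0 <- 0
    }
    B0 <- b2 * K^2 + b1 * K + b0
    B1 <- 2 * b0 - 2 * b2 * K^2
    B2 <- b2 * K^2 - b1 * K + b0
    A0 <- K^2 + a1 * K + a0
    A1 <- 2 * a0 - 2 * K^2
    A2 <- K^2 - a1 * K + a0
    list(b = c(B0, B1, B2) / A0, a = c(1, A1 / A0, A2 / A0))
  })
}

.sos_coef <- function(sos) {
  list(b = do.call(rbind, lapply(sos, `[[`, "b")),
       a = do.call(rbind, lapply(sos, `[[`, "a")))
}

# zero-phase (forward-backward) application of an SOS cascade to the rows of
# a matrix, with odd-reflection padding against edge transients
.sos_filtfilt_mat <- function(sos, data, pad) {
  n <- ncol(data)
  pad <- min(pad, n - 1)
  xp <- cbind(2 * data[, 1] - data[, (pad + 1):2, drop = FALSE],
              data,
              2 * data[, n] - data[, (n - 1):(n - pad), drop = FALSE])
  co <- .sos_coef(sos)
  xp <- sos_filtfilt_rows(xp, co$b, co$a)
  out <- xp[, (pad + 1):(pad + n), drop = FALSE]
  dimnames(out) <- dimnames(data)
  out
}

.sos_filtfilt_vec <- function(sos, x, pad) {
  as.vector(.sos_filtfilt_mat(sos, matrix(x, 1), pad))
}

#' High-pass filter a session
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high-pass, removing DC
#' and slow drift while leaving the passband essentially untouched
#' (ripple-free Butterworth response; gain error < 1% by 10x the cutoff).
#'
#' @param raw a `raw_session`
#' @param cutoff_hz high-pass cutoff in Hz (must be below Nyquist)
#' @param order filter order (even; applied forward-backward so the effective
#'   attenuation is doubled)
#' @return filtered `raw_session`
#' @export
highpass_filter <- function(raw, cutoff_hz, order = 4) {
  fs <- raw$sampling_rate
  if (cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist")
  sos <- .butter_sos(order, cutoff_hz, fs, "high")
  pad <- round(min(3 / cutoff_hz, 30) * fs)
  raw$data <- .sos_filtfilt_mat(sos, raw$data, pad)
  raw
}

#' Low-pass filter a session
#'
#' Zero-phase Butterworth low-pass (used as the anti-alias stage of
#' [downsample()] and available on its own).
#'
#' @inheritParams highpass_filter
#' @param cutoff_hz low-pass cutoff in Hz
#' @return filtered `raw_session`
#' @export
lowpass_filter <- function(raw, cutoff_hz, order = 8) {
  fs <- raw$sampling_rate
  if (cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist")
  sos <- .butter_sos(order, cutoff_hz, fs, "low")
  raw$data <- .sos_filtfilt_mat(sos, raw$data, pad = round(fs))
  raw
}

#' Downsample a session
#'
#' Anti-alias filters (zero-phase 8th-order Butterworth at 0.4x the target
#' rate) and decimates. Event onsets are stored in seconds and therefore
#' remain on the same clock.
#'
#' @param raw a `raw_session`
#' @param target_hz new sampling rate; must divide the current rate
#' @return downsampled `raw_session`
#' @export
downsample <- function(raw, target_hz = 250) {
  fs <- raw$sampling_rate
  if (fs %% target_hz != 0) stop("target rate must divide sampling rate")
  factor <- fs %/% target_hz
  if (factor == 1) return(raw)
  sos <- .butter_sos(8, 0.4 * target_hz, fs, "low")
  raw$data <- .sos_filtfilt_mat(sos, raw$data, pad = round(fs))[,
    seq(1, ncol(raw$data), by = factor), drop = FALSE]
  raw$sampling_rate <- target_hz
  raw
}
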