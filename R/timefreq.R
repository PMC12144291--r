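#' Morlet wavelet specification
#'
#' Frequency-dependent Gaussian wavelet parameters: `sigma_f = f / C`,
#' `sigma_t = 1 / (2 pi sigma_f)`, kernel duration `6 sigma_t`. The constant
#' trades frequency against temporal resolution: `C = 7` at and below 20 Hz,
#' `C = 14` at and above 40 Hz, linearly interpolated in between, which makes
#' the spectral bandwidth `6 sigma_f` equal (17.1429 Hz) across the
#' 20-40 Hz transition band.
#'
#' @param f center frequency in Hz (> 0)
#' @return list with `f`, `C`, `sigma_f`, `sigma_t`, `duration`
#' @export
wavelet_spec <- function(f) {
  if (f <= 0) stop("center frequency must be positive")
  C <- if (f <= 20) 7 else if (f >= 40) 14 else 7 + (14 - 7) * (f - 20) / 20
  sigma_f <- f / C
  sigma_t <- 1 / (2 * pi * sigma_f)
  list(f = f, C = C, sigma_f = sigma_f, sigma_t = sigma_t,
       duration = 6 * sigma_t)
}

# complex Morlet kernel sampled at fs, truncated at +/- 3 sigma_t,
# L2-normalized so coefficient magnitudes are amplitude-comparable across
# frequencies
.morlet_kernel <- function(f, fs) {
  ws <- wavelet_spec(f)
  half <- ceiling(3 * ws$sigma_t * fs)
  t <- (-half:half) / fs
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * ws$sigma_t^2))
  k / sqrt(sum(Mod(k)^2))
}

#' Morlet wavelet decomposition of epochs
#'
#' Convolves every trial and channel with complex Morlet kernels (no
#' padding); the output is restricted to the time range where the kernel
#' fits entirely inside the epoch, so the epoch must extend at least half a
#' kernel duration beyond the requested output range at every frequency.
#'
#' @param epochs an `epoch_set` (surviving epochs only are decomposed)
#' @param freqs center frequencies in Hz (default 2-Hz bins 4-100)
#' @param channels channel subset to decompose (default all)
#' @param out_range output time range in seconds relative to onset (default
#'   `c(-0.248, 0.752)`)
#' @return object of class `tf_coefficients`: complex array
#'   `channels x freq x time x trials`, plus `times`, `freqs`, `channels`
#' @export
morlet_transform <- function(epochs, freqs = seq(4, 100, by = 2),
                             channels = NULL,
                             out_range = c(-0.248, 0.752)) {
  fs <- epochs$sampling_rate
  if (is.null(channels)) channels <- epochs$channels
  keep <- !epochs$rejected
  x <- epochs$data[channels, , keep, drop = FALSE]
  d <- dim(x)
  t_axis <- epochs$times
  out_sel <- which(t_axis >= out_range[1] - 1e-9 &
                   t_axis <= out_range[2] + 1e-9)
  n_sig <- d[1] * d[3]
  sig <- matrix(aperm(x, c(2, 1, 3)), d[2], n_sig)  # time x (ch*trial)

  n <- d[2]
  # kernel half-lengths; validity check
  halves <- vapply(freqs, function(f) ceiling(3 * wavelet_spec(f)$sigma_t * fs),
                   numeric(1))
  if (min(out_sel) - max(halves) < 1 || max(out_sel) + max(halves) > n)
    stop("epoch too short for requested frequency's wavelet at the output range")

  nfft <- stats::nextn(n + 2 * max(halves), 2)
  F_sig <- stats::mvfft(rbind(sig, matrix(0, nfft - n, n_sig)))
  out <- array(0i, c(d[1], length(freqs), length(out_sel), d[3]),
               dimnames = list(channels, NULL, NULL, NULL))
  for (j in seq_along(freqs)) {
    k <- .morlet_kernel(freqs[j], fs)
    half <- halves[j]
    kf <- stats::fft(c(k, rep(0, nfft - length(k))))
    conv <- stats::mvfft(F_sig * kf, inverse = TRUE) / nfft
    # 'same' alignment: sample t of the signal sits at row t + half
    vals <- conv[out_sel + half, , drop = FALSE]
    out[, j, , ] <- aperm(array(t(vals), c(d[1], d[3], length(out_sel))),
                          c(1, 3, 2))
  }
  structure(list(coef = out, times = t_axis[out_sel], freqs = freqs,
                 channels = channels, sampling_rate = fs,
                 n_trials = d[3]),
            class = "tf_coefficients")
}

#' Inter-trial coherence
#'
#' Mean resultant length of the trial phases at each (channel, frequency,
#' time) point: `|mean(c / |c|)|`, identically 1 minus the circular phase
#' variance. Zero-magnitude coefficients (undefined phase) are excluded
#' pointwise and counted.
#'
#' @param tfc a `tf_coefficients` object (or a complex array with trials in
#'   the last dimension)
#' @return object of class `tf_result` with `kind = "itc"`, `values`
#'   (channels x freq x time in `[0, 1]`), axes, and `n_excluded`
#' @export
itc <- function(tfc) {
  co <- if (inherits(tfc, "tf_coefficients")) tfc$coef else tfc
  d <- dim(co)
  n_tr <- d[length(d)]
  if (n_tr < 2) stop("need at least 2 trials")
  mag <- Mod(co)
  zero <- mag == 0
  ph <- co / ifelse(zero, 1, mag)
  ph[zero] <- 0i
  n_valid <- n_tr - rowSums(zero, dims = length(d) - 1)
  vals <- Mod(rowSums(ph, dims = length(d) - 1)) / pmax(n_valid, 1)
  vals[n_valid == 0] <- NA_real_
  .tf_result("itc", vals, tfc, n_excluded = sum(zero))
}

.tf_result <- function(kind, values, tfc, ...) {
  structure(c(list(kind = kind, values = values),
              if (inherits(tfc, "tf_coefficients"))
                list(times = tfc$times, freqs = tfc$freqs,
                     channels = tfc$channels, n_trials = tfc$n_trials),
              list(...)),
            class = "tf_result")
}

#' @export
print.tf_result <- function(x, ...) {
  cat(sprintf("<tf_result> %s: %s\n", x$kind,
              paste(dim(x$values), collapse = " x ")))
  invisible(x)
}

#' Baseline-corrected total power
#'
#' Trial-averaged squared coefficient magnitudes, 10log10-transformed, then
#' baseline corrected by subtracting the mean over the pre-stimulus baseline
#' window per channel and frequency: dB change from baseline. Power below
#' the numeric floor is clipped before the log.
#'
#' @param tfc a `tf_coefficients` object
#' @param baseline baseline window in seconds (default `c(-0.2, -0.1)`)
#' @param floor numeric floor for power before the log
#' @return `tf_result` with `kind = "total_power_db"`
#' @export
total_power <- function(tfc, baseline = c(-0.2, -0.1), floor = 1e-12) {
  stopifnot(inherits(tfc, "tf_coefficients"))
  p <- rowMeans(Mod(tfc$coef)^2, dims = 3)  # channels x freq x time
  p <- 10 * log10(pmax(p, floor))
  bsel <- tfc$times >= baseline[1] - 1e-9 & tfc$times <= baseline[2] + 1e-9
  if (!any(bsel)) stop("baseline window outside time axis")
  bl <- apply(p[, , bsel, drop = FALSE], c(1, 2), mean)
  vals <- sweep(p, c(1, 2), bl)
  .tf_result("total_power_db", vals, tfc)
}

#' Baseline-corrected evoked power
#'
#' Squared coefficient magnitudes of the trial-average (ERP) waveform,
#' baseline-mean subtracted in linear units (no dB transform). Pass the
#' coefficients of the averaged waveform (a single "trial").
#'
#' @param tfc_avg `tf_coefficients` of the ERP average (1 trial)
#' @param baseline baseline window in seconds
#' @return `tf_result` with `kind = "evoked_power"`
#' @export
evoked_power <- function(tfc_avg, baseline = c(-0.2, -0.1)) {
  stopifnot(inherits(tfc_avg, "tf_coefficients"))
  p <- rowMeans(Mod(tfc_avg$coef)^2, dims = 3)
  bsel <- tfc_avg$times >= baseline[1] - 1e-9 &
    tfc_avg$times <= baseline[2] + 1e-9
  if (!any(bsel)) stop("baseline window outside time axis")
  bl <- apply(p[, , bsel, drop = FALSE], c(1, 2), mean)
  vals <- sweep(p, c(1, 2), bl)
  .tf_result("evoked_power", vals, tfc_avg)
}

#' Average the trials of an epoch set into a one-trial epoch set
#'
#' ERP averaging prior to wavelet decomposition, for evoked power.
#'
#' @param epochs an `epoch_set`
#' @return `epoch_set` with a single (average) epoch
#' @export
average_epochs <- function(epochs) {
  keep <- !epochs$rejected
  avg <- rowMeans(epochs$data[, , keep, drop = FALSE], dims = 2)
  epochs$data <- array(avg, c(dim(avg), 1),
                       dimnames = list(epochs$channels, NULL, NULL))
  epochs$condition <- epochs$condition[1]
  epochs$run_index <- epochs$run_index[1]
  epochs$onset <- epochs$onset[1]
  epochs$rejected <- FALSE
  epochs$reject_reason <- NA_character_
  epochs
}

#' Extract steady-state-response measures
#'
#' Averages a `tf_result` over the 100-500 ms window, the 38/40/42 Hz bins,
#' and the measure's electrode cluster. The input session is expected to
#' have been re-referenced to the mean of P7 and P8 before decomposition.
#'
#' @param tf a `tf_result`
#' @param cluster electrode labels (defaults per measure kind: fronto-central
#'   for evoked power, central for ITC and total power)
#' @param time_window seconds (default `c(0.1, 0.5)`)
#' @param freq_bins Hz (default `c(38, 40, 42)`)
#' @return scalar measure value
#' @export
extract_assr_measure <- function(tf, cluster = NULL,
                                 time_window = c(0.1, 0.5),
                                 freq_bins = c(38, 40, 42)) {
  if (is.null(cluster)) {
    cluster <- if (tf$kind == "evoked_power")
      c("Fz", "F1", "F2", "FCz", "FC1", "FC2")
    else c("FCz", "FC1", "FC2", "Cz", "C1", "C2")
  }
  missing <- setdiff(cluster, tf$channels)
  if (length(missing)) stop("cluster channels missing: ",
                            paste(missing, collapse = ", "))
  fsel <- tf$freqs %in% freq_bins
  if (sum(fsel) != length(freq_bins)) stop("frequency bins not all present")
  tsel <- tf$times >= time_window[1] - 1e-9 & tf$times <= time_window[2] + 1e-9
  mean(tf$values[cluster, fsel, tsel])
}
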