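#' Preprocess a resting-state run
#'
#' Fixed chain for eyes-open/eyes-closed runs: 0.5 Hz high-pass, downsample
#' to 250 Hz, common average reference, bad-channel detection (epochs
#' statistics from clean channels only), division into the first 180 whole
#' 1-second epochs, outlier-epoch rejection, conservative artifact-component
#' removal (muscle BSS-CCA and ocular proxy regression at stricter
#' thresholds than the task chain), interpolation of the bad channels, and a
#' final robust common average reference.
#'
#' @param raw a `raw_session` holding one rest run of at least 180 s
#' @param n_epochs number of 1-s epochs (default 180)
#' @param artifact_stages run the artifact stages (bad channels, rejection,
#'   component removal); disable for noise-free validation data
#' @return list with `epochs` (clean `epoch_set`) and `report`
#' @export
resting_preprocess <- function(raw, n_epochs = 180, artifact_stages = TRUE) {
  if (session_duration(raw) < n_epochs) stop("rest run shorter than ",
                                             n_epochs, " s")
  raw <- highpass_filter(raw, 0.5)
  raw <- downsample(raw, 250)
  raw <- reconstruct_reference_channel(raw)
  # initial plain common average
  raw$data <- sweep(raw$data, 2, colMeans(raw$data))
  raw$reference <- "average"
  bad <- if (artifact_stages) detect_bad_channels(raw) else character(0)

  # epoch into the first n_epochs whole seconds
  eps <- epoch_1s_grid(raw, n_epochs)

  report <- list(bad_channels = bad, n_epochs_rejected = 0,
                 n_cca_components_removed = 0, n_blink_samples = 0)
  if (artifact_stages) {
    # rejection statistics from clean channels only
    clean <- setdiff(eps$channels, bad)
    stats_set <- eps
    stats_set$data <- eps$data[clean, , , drop = FALSE]
    stats_set$channels <- clean
    flagged <- reject_epochs_faster(stats_set)
    eps$rejected <- flagged$rejected
    eps$reject_reason <- flagged$reject_reason
    report$n_epochs_rejected <- sum(eps$rejected)

    cca <- bsscca_muscle_removal(eps, max_autocorr = 0.5,
                                 min_hf_fraction = 0.6)
    eps <- cca$epochs
    report$n_cca_components_removed <- cca$report$n_components_removed
    oc <- remove_ocular(eps, blink_z = 5)
    eps <- oc$epochs
    report$n_blink_samples <- oc$report$n_blink_samples
  }
  if (length(bad)) {
    cc <- .concat_epochs(eps, surviving_only = FALSE)
    fake <- raw; fake$data <- cc$mat
    fake <- interpolate_channels(fake, bad)
    eps <- .unconcat_epochs(eps, fake$data, cc$keep)
  }
  # final robust common average over the epoch data; channels that needed
  # interpolation stay out of the reference set
  cc <- .concat_epochs(eps, surviving_only = FALSE)
  fake <- raw; fake$data <- cc$mat
  fake <- robust_average_reference(fake, exclude = bad,
                                   detect = artifact_stages)
  eps <- .unconcat_epochs(eps, fake$data, cc$keep)
  report$final_reference_set <- fake$reference_info$included
  eps$reference <- "average"
  list(epochs = eps, report = report)
}

# cut the first n whole-second epochs off a continuous recording
epoch_1s_grid <- function(raw, n_epochs) {
  fs <- raw$sampling_rate
  n_ch <- nrow(raw$data)
  idx <- seq_len(n_epochs * fs)
  x <- array(raw$data[, idx], c(n_ch, fs, n_epochs),
             dimnames = list(rownames(raw$data), NULL, NULL))
  structure(
    list(data = x, times = (seq_len(fs) - 1) / fs, sampling_rate = fs,
         channels = rownames(raw$data),
         condition = rep("rest", n_epochs),
         run_index = rep(1L, n_epochs),
         onset = seq_len(n_epochs) - 1,
         rejected = rep(FALSE, n_epochs),
         reject_reason = rep(NA_character_, n_epochs),
         reference = raw$reference, montage = raw$montage),
    class = "epoch_set"
  )
}

#' Power spectral density of clean resting epochs
#'
#' Per-epoch Hamming-tapered periodograms averaged over surviving epochs
#' (Welch's method across non-overlapping 1-s segments). Density
#' normalization: the integral of the one-sided PSD over frequency equals the
#' (tapered) signal variance, so a unit-amplitude sinusoid integrates to
#' ~0.5 and white noise of variance s^2 to ~s^2.
#'
#' @param epochs an `epoch_set` of 1-s epochs
#' @param min_epochs minimum surviving epochs required
#' @return object of class `psd_result`: `values` (channels x frequency,
#'   microvolts^2/Hz), `freqs` (0..Nyquist at 1 Hz), `n_epochs_used`
#' @export
compute_psd <- function(epochs, min_epochs = 10) {
  keep <- !epochs$rejected
  if (sum(keep) < min_epochs) stop("fewer than ", min_epochs,
                                   " surviving epochs")
  x <- epochs$data[, , keep, drop = FALSE]
  d <- dim(x)
  fs <- epochs$sampling_rate
  n <- d[2]
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hamming
  scale <- 1 / (fs * sum(w^2))
  n_half <- n %/% 2 + 1
  acc <- matrix(0, d[1], n_half)
  for (e in seq_len(d[3])) {
    seg <- x[, , e] * rep(w, each = d[1])
    sp <- Mod(t(stats::mvfft(t(seg))))^2 * scale
    half <- sp[, seq_len(n_half), drop = FALSE]
    half[, 2:(n_half - 1)] <- 2 * half[, 2:(n_half - 1)]  # one-sided
    acc <- acc + half
  }
  vals <- acc / d[3]
  colnames(vals) <- NULL
  structure(list(values = vals, freqs = (seq_len(n_half) - 1) * fs / n,
                 channels = epochs$channels, n_epochs_used = d[3]),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d ch x %d bins (0-%g Hz), %d epochs\n",
              nrow(x$values), ncol(x$values), max(x$freqs), x$n_epochs_used))
  invisible(x)
}

#' Frequency band definitions with scoring clusters
#'
#' Conventional band limits (inclusive integer bins) and the electrode
#' clusters over which each band's absolute power is averaged.
#'
#' @return named list of lists with `name`, `f_low`, `f_high`, `cluster`
#' @export
default_band_definitions <- function() {
  list(
    delta = list(name = "delta", f_low = 1, f_high = 3,
                 cluster = c("Fz", "FCz")),
    theta = list(name = "theta", f_low = 4, f_high = 7,
                 cluster = c("Fz", "FCz")),
    alpha = list(name = "alpha", f_low = 8, f_high = 12,
                 cluster = c("Pz", "P1", "P2", "POz", "PO3", "PO4")),
    beta = list(name = "beta", f_low = 13, f_high = 30,
                cluster = c("AF3", "AF4", "F3", "F4", "F5", "F6",
                            "POz", "PO3", "PO4")),
    gamma = list(name = "gamma", f_low = 31, f_high = 48,
                 cluster = c("AFz", "AF3", "AF4", "Fz", "F3", "F4",
                             "F5", "F6"))
  )
}

#' Band power from a PSD
#'
#' Mean PSD across the band's integer-frequency bins, then mean across the
#' band's cluster electrodes ("absolute power", density units). Set
#' `integrate = TRUE` for the band integral in microvolts^2 instead.
#'
#' @param psd a `psd_result`
#' @param band one element of [default_band_definitions()]
#' @param integrate return integrated band power instead of mean density
#' @return scalar band power
#' @export
band_power <- function(psd, band, integrate = FALSE) {
  missing <- setdiff(band$cluster, psd$channels)
  if (length(missing)) stop("cluster electrodes missing: ",
                            paste(missing, collapse = ", "))
  fsel <- psd$freqs >= band$f_low - 1e-9 & psd$freqs <= band$f_high + 1e-9
  if (!any(fsel)) stop("band outside frequency axis")
  v <- mean(psd$values[band$cluster, fsel])
  if (integrate) v * sum(fsel) else v
}
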