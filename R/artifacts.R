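#' Muscle-artifact removal by blind source separation with CCA
#'
#' Canonical correlation analysis between the epoch data and a one-sample
#' delayed copy yields components ordered by lag-1 autocorrelation (the
#' canonical correlation). Broadband muscle activity is nearly white, so
#' components with low autocorrelation and predominantly high-frequency
#' power are removed and the data reconstructed from the retained
#' components. Implemented in a PCA-whitened space (rank-deficient input is
#' reduced with a warning): components are the eigenvectors of the
#' symmetrized lag-1 covariance of the whitened data.
#'
#' @param epochs an `epoch_set`
#' @param max_autocorr components with lag-1 autocorrelation below this AND
#' @param min_hf_fraction relative power above `hf_cutoff_hz` above this are
#'   removed
#' @param hf_cutoff_hz high-frequency boundary (default 30 Hz)
#' @param rank_tol relative eigenvalue tolerance for the PCA rank reduction
#' @return list with `epochs` (cleaned) and `report` (a list with
#'   `n_components_removed`, `autocorr`, `hf_fraction`, `removed`)
#' @export
bsscca_muscle_removal <- function(epochs, max_autocorr = 0.6,
                                  min_hf_fraction = 0.5, hf_cutoff_hz = 30,
                                  rank_tol = 1e-10) {
  cc <- .concat_epochs(epochs)
  x <- cc$mat
  mu <- rowMeans(x)
  xc <- x - mu
  n_ch <- nrow(xc)

  # PCA whitening (handles rank deficiency)
  C <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > rank_tol * eg$values[1]
  r <- sum(keep)
  # average-referenced data are structurally deficient by exactly one
  # dimension; only a deeper deficiency is worth flagging
  if (r < n_ch - 1) warning("rank-deficient data: reduced to ", r,
                            " dimensions")
  U <- eg$vectors[, keep, drop = FALSE]
  dhalf <- sqrt(eg$values[keep])
  z <- crossprod(U, xc) / dhalf  # whitened r x T

  # lag-1 covariance within epochs (no cross-epoch pairs)
  t_idx <- rep(seq_len(cc$n_time - 1), cc$n_ep) +
    rep((seq_len(cc$n_ep) - 1) * cc$n_time, each = cc$n_time - 1)
  z1 <- z[, t_idx, drop = FALSE]; z2 <- z[, t_idx + 1, drop = FALSE]
  M <- tcrossprod(z1, z2) / ncol(z1)
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  V <- ev$vectors            # components sorted by autocorrelation (desc)
  autocorr <- ev$values
  s <- crossprod(V, z)       # component time courses

  hf_fraction <- apply(s, 1, .hf_power_fraction, fs = epochs$sampling_rate,
                       cutoff = hf_cutoff_hz)
  removed <- autocorr < max_autocorr & hf_fraction > min_hf_fraction

  if (any(removed)) {
    s[removed, ] <- 0
    z_clean <- V %*% s
    x_clean <- U %*% (dhalf * z_clean) + mu
  } else {
    x_clean <- U %*% (dhalf * z) + mu  # reconstruction through the basis
  }
  epochs <- .unconcat_epochs(epochs, x_clean, cc$keep)
  list(epochs = epochs,
       report = list(n_components_removed = sum(removed),
                     autocorr = autocorr, hf_fraction = hf_fraction,
                     removed = removed, rank = r))
}

# fraction of spectral power above `cutoff` Hz
.hf_power_fraction <- function(v, fs, cutoff) {
  n <- length(v)
  sp <- Mod(stats::fft(v - mean(v))[seq_len(n %/% 2)])^2
  if (sum(sp) == 0) return(0)
  f <- (seq_len(n %/% 2) - 1) * fs / n
  sum(sp[f > cutoff]) / sum(sp)
}

#' Ocular-artifact removal by blink-proxy regression
#'
#' Deterministic stand-in for component-classifier ocular cleaning: the blink
#' proxy is the mean of Fp1 and Fp2 band-limited to the blink band
#' (low-passed at `proxy_lp_hz` after per-epoch demeaning), blink segments
#' are detected where the proxy exceeds `blink_z` robust SDs, per-channel
#' regression coefficients onto the proxy are estimated on those segments
#' only, and the fitted proxy contribution is subtracted everywhere. With no
#' detected blink segments the data are returned unchanged.
#'
#' @param epochs an `epoch_set` containing Fp1 and Fp2
#' @param proxy_lp_hz proxy low-pass cutoff (blink energy is below ~8 Hz)
#' @param blink_z robust-z threshold defining blink segments
#' @param min_blink_samples minimum number of blink samples required to fit
#'   the regression
#' @return list with `epochs` and `report` (`n_blink_samples`,
#'   `coefficients`)
#' @export
remove_ocular <- function(epochs, proxy_lp_hz = 8, blink_z = 4,
                          min_blink_samples = 25) {
  chans <- epochs$channels
  if (!all(c("Fp1", "Fp2") %in% chans))
    stop("Fp1/Fp2 required for the blink proxy")
  cc <- .concat_epochs(epochs)
  x <- cc$mat
  # per-epoch demeaning of the proxy channels
  proxy_raw <- colMeans(x[c("Fp1", "Fp2"), , drop = FALSE])
  pm <- matrix(proxy_raw, cc$n_time, cc$n_ep)
  pm <- sweep(pm, 2, colMeans(pm))
  sos <- .butter_sos(4, proxy_lp_hz, epochs$sampling_rate, "low")
  for (j in seq_len(cc$n_ep)) pm[, j] <- .sos_filtfilt_vec(sos, pm[, j],
                                                           pad = 50)
  proxy <- as.vector(pm)
  s <- stats::mad(proxy)
  blink <- if (s > 0) abs(proxy) > blink_z * s else rep(FALSE, length(proxy))
  if (sum(blink) < min_blink_samples) {
    return(list(epochs = epochs,
                report = list(n_blink_samples = sum(blink),
                              coefficients = stats::setNames(
                                rep(0, length(chans)), chans))))
  }
  pb <- proxy[blink]
  beta <- as.vector(x[, blink, drop = FALSE] %*% pb) / sum(pb^2)
  names(beta) <- chans
  x_clean <- x - outer(beta, proxy)
  epochs <- .unconcat_epochs(epochs, x_clean, cc$keep)
  list(epochs = epochs,
       report = list(n_blink_samples = sum(blink), coefficients = beta))
}
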