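# Shared fixtures for the test suite. Everything is generated in code.

the_montage <- standard_montage()

# Build an epoch_set directly from a channels x time x epochs array.
make_epochs <- function(arr, fs = 250, t0 = -0.5, montage = the_montage,
                        condition = NULL, run_index = NULL) {
  n_ep <- dim(arr)[3]
  if (is.null(dimnames(arr)[[1]]))
    dimnames(arr) <- list(montage$channel_labels[seq_len(dim(arr)[1])],
                          NULL, NULL)
  structure(
    list(data = arr, times = t0 + (seq_len(dim(arr)[2]) - 1) / fs,
         sampling_rate = fs, channels = dimnames(arr)[[1]],
         condition = condition %||% rep("standard", n_ep),
         run_index = run_index %||% rep(1L, n_ep),
         onset = seq_len(n_ep),
         rejected = rep(FALSE, n_ep),
         reject_reason = rep(NA_character_, n_ep),
         reference = "average", montage = montage),
    class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spatially correlated synthetic background: latent white/band sources mixed
# through smooth scalp fields, plus a little independent sensor noise.
# Cheap stand-in for a full generator run in channel-level tests.
make_background <- function(n_samples, fs = 250, montage = the_montage,
                            n_src = 14, sensor_sd = 0.1, seed = 1) {
  labels <- montage$channel_labels
  set.seed(seed)
  W <- sapply(seq_len(n_src), function(k) {
    ctr <- stats::rnorm(3); ctr[3] <- abs(ctr[3]) + 0.3
    w <- eegret:::.topo_field(montage, ctr, 1.0)
    (w - w[[montage$reference_label]])[labels]
  })
  S <- sapply(seq_len(n_src), function(k)
    eegret:::.one_over_f(n_samples, fs, 1.5))
  x <- W %*% t(S)
  x <- x + sensor_sd * matrix(stats::rnorm(length(labels) * n_samples),
                              length(labels))
  x <- sweep(x, 2, colMeans(x))  # average-reference frame
  rownames(x) <- labels
  raw_session(x, fs, montage, empty_event_table(), reference = "average")
}

# a small balanced persons x 2 table with roughly the requested G
make_g_table <- function(n, g_true, seed = 1, mu = 0, shift = 0) {
  set.seed(seed)
  p <- stats::rnorm(n, 0, sqrt(g_true))
  e <- matrix(stats::rnorm(2 * n, 0, sqrt(1 - g_true)), n, 2)
  mu + cbind(p + e[, 1], p + e[, 2] + shift)
}
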