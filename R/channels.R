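.robust_z <- function(v) {
  med <- stats::median(v)
  s <- stats::mad(v)
  if (s == 0) return(rep(0, length(v)))
  (v - med) / s
}

#' Detect outlier channels
#'
#' Flags channels on three criteria inspired by reference-free bad-channel
#' detection practice: amplitude deviation (robust z of the channel's robust
#' amplitude > `z_amplitude`), low correlation with the average of its
#' spatial neighbors (< `min_neighbor_cor`), and high-frequency noisiness
#' (robust z of the high-frequency to total amplitude ratio >
#' `z_noisiness`). Flat channels fail the correlation criterion.
#'
#' @param raw a `raw_session` (or channels x samples matrix via `data` +
#'   `montage`)
#' @param z_amplitude robust-z threshold for amplitude deviation
#' @param min_neighbor_cor minimum correlation with the neighbor average
#' @param z_noisiness robust-z threshold for high-frequency noisiness
#' @param exclude labels never flagged (and never used as neighbors)
#' @return character vector of flagged channel labels
#' @export
detect_bad_channels <- function(raw, z_amplitude = 5, min_neighbor_cor = 0.4,
                                z_noisiness = 5, exclude = character(0)) {
  x <- raw$data
  labels <- rownames(x)
  if (nrow(x) < 8) stop("need at least 8 channels")
  consider <- setdiff(labels, exclude)
  xc <- x - rowMeans(x)

  # amplitude deviation: robust per-channel amplitude
  amp <- apply(xc, 1, function(v) stats::mad(v))
  z_amp <- .robust_z(amp[consider])
  bad_amp <- consider[z_amp > z_amplitude]

  # high-frequency noisiness: first-difference amplitude relative to total
  hf <- apply(xc, 1, function(v) stats::mad(diff(v)))
  ratio <- hf / pmax(amp, 1e-12)
  z_hf <- .robust_z(ratio[consider])
  bad_hf <- consider[z_hf > z_noisiness]

  # neighbor correlation: a good channel correlates with at least one of
  # its spatial neighbors; using the best single neighbor keeps one corrupt
  # channel from dragging down its whole neighborhood
  nb <- montage_neighbors(raw$montage)
  sds <- apply(xc, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(xc[consider, , drop = FALSE])))
  bad_cor <- character(0)
  for (l in consider) {
    if (sds[l] == 0) { bad_cor <- c(bad_cor, l); next }
    nbl <- intersect(nb[[l]], consider)
    nbl <- nbl[sds[nbl] > 0]
    if (!length(nbl)) next
    if (max(cm[l, nbl], na.rm = TRUE) < min_neighbor_cor)
      bad_cor <- c(bad_cor, l)
  }
  sort(unique(c(bad_amp, bad_hf, bad_cor)))
}

# spherical-spline interpolation matrix: estimates values at `to` positions
# from values at `from` positions (Perrin-style spline on the unit sphere,
# stiffness m, Legendre series truncated at n_terms)
.spline_g <- function(cosang, m = 4, n_terms = 50) {
  # Legendre polynomials by recursion, accumulated into the g kernel
  g <- matrix(0, nrow(cosang), ncol(cosang))
  p_prev <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
  p_cur <- cosang                                   # P_1
  for (n in seq_len(n_terms)) {
    g <- g + (2 * n + 1) / (n^m * (n + 1)^m) * p_cur
    p_next <- ((2 * n + 1) * cosang * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur; p_cur <- p_next
  }
  g / (4 * pi)
}

.spline_interp_matrix <- function(pos_from, pos_to, m = 4, lambda = 1e-5) {
  cos_ff <- tcrossprod(pos_from); cos_ff[cos_ff > 1] <- 1; cos_ff[cos_ff < -1] <- -1
  cos_tf <- pos_to %*% t(pos_from); cos_tf[cos_tf > 1] <- 1; cos_tf[cos_tf < -1] <- -1
  g_ff <- .spline_g(cos_ff, m)
  g_tf <- .spline_g(cos_tf, m)
  n <- nrow(pos_from)
  A <- rbind(cbind(g_ff + diag(lambda, n), rep(1, n)), c(rep(1, n), 0))
  # solve for [weights; constant] applied to data: interp = [g_tf 1] A^-1 [y;0]
  Ainv <- solve(A)
  cbind(g_tf, rep(1, nrow(pos_to))) %*% Ainv[, seq_len(n), drop = FALSE]
}

#' Interpolate channels by spherical splines
#'
#' Replaces the listed channels with spherical-spline estimates from the
#' remaining good channels.
#'
#' @param raw a `raw_session`
#' @param labels channels to interpolate (empty is a no-op)
#' @param exclude additional labels not used as sources (e.g. other
#'   suspect channels)
#' @return `raw_session` with interpolated data
#' @export
interpolate_channels <- function(raw, labels, exclude = character(0)) {
  if (!length(labels)) return(raw)
  all_labels <- rownames(raw$data)
  if (!all(labels %in% all_labels))
    stop("labels not in recording: ",
         paste(setdiff(labels, all_labels), collapse = ", "))
  good <- setdiff(all_labels, c(labels, exclude))
  if (length(good) < 4) stop("fewer than 4 good channels remain")
  pos <- raw$montage$positions
  W <- .spline_interp_matrix(pos[good, , drop = FALSE],
                             pos[labels, , drop = FALSE])
  raw$data[labels, ] <- W %*% raw$data[good, , drop = FALSE]
  raw
}

#' Reconstruct the online reference as an explicit channel
#'
#' In the FCz-referenced acquisition frame the reference carries no data row;
#' re-referencing operations need it as an explicit (initially all-zero)
#' channel so that reference-site clusters remain scorable.
#'
#' @param raw a `raw_session`
#' @return `raw_session` including the reference channel row
#' @export
reconstruct_reference_channel <- function(raw) {
  ref <- raw$montage$reference_label
  if (ref %in% rownames(raw$data)) return(raw)
  raw$data <- rbind(raw$data, matrix(0, 1, ncol(raw$data),
                                     dimnames = list(ref)))
  raw
}

#' Robust common average reference
#'
#' Iteratively estimates the common average reference from all channels that
#' are neither excluded a priori nor currently detected as bad, re-detects
#' bad channels in the re-referenced frame, and repeats until the bad set is
#' stable (at most `max_iter` iterations). The final reference is the mean
#' of the included good channels of the original data and is subtracted from
#' every channel, including excluded ones; excluded channels never
#' contribute to the reference. The online reference channel is
#' reconstructed first if absent.
#'
#' @param raw a `raw_session`
#' @param exclude channels never entering the reference (noisy sites by
#'   design: mastoids and the two frontopolar channels)
#' @param max_iter maximum detect/re-reference iterations
#' @param detect run bad-channel re-detection (set `FALSE` to reference
#'   with the a priori exclusions only)
#' @param ... passed to [detect_bad_channels()]
#' @return `raw_session`, re-referenced, with attributes `bad_channels` and
#'   `converged` recorded in `raw$reference_info`
#' @export
robust_average_reference <- function(raw,
                                     exclude = c("TP9", "TP10", "Fp1", "Fp2"),
                                     max_iter = 10, detect = TRUE, ...) {
  raw <- reconstruct_reference_channel(raw)
  labels <- rownames(raw$data)
  bad <- character(0)
  converged <- !detect
  if (detect) {
    for (it in seq_len(max_iter)) {
      incl <- setdiff(labels, union(exclude, bad))
      ref <- colMeans(raw$data[incl, , drop = FALSE])
      tmp <- raw
      tmp$data <- sweep(raw$data, 2, ref)
      new_bad <- detect_bad_channels(tmp, exclude = exclude, ...)
      if (setequal(new_bad, bad)) { converged <- TRUE; break }
      bad <- new_bad
    }
    if (!converged) warning("robust reference did not converge; using last iterate")
  }
  incl <- setdiff(labels, union(exclude, bad))
  ref <- colMeans(raw$data[incl, , drop = FALSE])
  raw$data <- sweep(raw$data, 2, ref)
  raw$reference <- "average"
  raw$reference_info <- list(bad_channels = bad, included = incl,
                             excluded = exclude, converged = converged)
  raw
}

#' Re-reference to the mean of selected channels
#'
#' Used for the steady-state-response chain, which is referenced to the mean
#' of P7 and P8 (near-mastoid sites) before time-frequency decomposition.
#'
#' @param raw a `raw_session`
#' @param channels labels averaged into the new reference
#' @return re-referenced `raw_session`
#' @export
rereference <- function(raw, channels = c("P7", "P8")) {
  raw <- reconstruct_reference_channel(raw)
  missing <- setdiff(channels, rownames(raw$data))
  if (length(missing)) stop("reference channels missing: ",
                            paste(missing, collapse = ", "))
  ref <- colMeans(raw$data[channels, , drop = FALSE])
  raw$data <- sweep(raw$data, 2, ref)
  raw$reference <- paste(channels, collapse = "/")
  raw
}
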