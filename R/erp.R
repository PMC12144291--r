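#' Average surviving epochs into an ERP
#'
#' Arithmetic mean over all surviving (non-rejected) epochs of the requested
#' condition, irrespective of behavioral performance.
#'
#' @param epochs an `epoch_set`
#' @param condition condition label(s) to average (default: all)
#' @return object of class `erp_wave`: `data` (channels x time), `times`,
#'   `condition`, `n_epochs`
#' @export
average_erp <- function(epochs, condition = NULL) {
  keep <- !epochs$rejected
  if (!is.null(condition)) keep <- keep & epochs$condition %in% condition
  if (!sum(keep)) stop("zero surviving epochs for condition ",
                       paste(condition, collapse = "/"))
  x <- epochs$data[, , keep, drop = FALSE]
  structure(
    list(data = rowMeans(x, dims = 2), times = epochs$times,
         sampling_rate = epochs$sampling_rate,
         channels = epochs$channels,
         condition = paste(condition, collapse = "/"),
         n_epochs = sum(keep)),
    class = "erp_wave"
  )
}

#' @export
print.erp_wave <- function(x, ...) {
  cat(sprintf("<erp_wave> %s: %d ch x %d samples, %d epochs averaged\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_epochs))
  invisible(x)
}

#' Difference wave between two ERPs
#'
#' @param a,b `erp_wave` objects on identical time axes
#' @return `erp_wave` equal to `a - b` pointwise; `n_epochs` records both
#' @export
difference_wave <- function(a, b) {
  if (!isTRUE(all.equal(a$times, b$times)) ||
      !identical(a$channels, b$channels))
    stop("ERP time axes or channels do not match")
  out <- a
  out$data <- a$data - b$data
  out$condition <- paste0(a$condition, "-", b$condition)
  out$n_epochs <- c(a = a$n_epochs, b = b$n_epochs)
  out
}

#' Locate a component peak on a grand-average wave
#'
#' Finds the extremum of the stated polarity within the search window at one
#' electrode; ties are broken toward the earliest latency. If the wave is
#' monotone (extremum at a window edge), the edge latency is returned with a
#' warning.
#'
#' @param wave an `erp_wave` (typically a pooled grand average)
#' @param polarity `"+"` or `"-"`
#' @param search_window_ms length-2 window in ms post-stimulus
#' @param electrode electrode label
#' @return peak latency in ms
#' @export
find_component_peak <- function(wave, polarity = c("-", "+"),
                                search_window_ms, electrode) {
  polarity <- match.arg(polarity)
  t_ms <- wave$times * 1000
  sel <- which(t_ms >= search_window_ms[1] - 1e-9 &
               t_ms <= search_window_ms[2] + 1e-9)
  if (!length(sel)) stop("search window outside wave")
  v <- wave$data[electrode, sel]
  if (polarity == "-") v <- -v
  i <- which.max(v)  # which.max takes the earliest of tied extrema
  if (i == 1 || i == length(sel)) {
    dv <- diff(v)
    if (all(dv >= 0) || all(dv <= 0))
      warning("no interior extremum of stated polarity; returning window edge")
  }
  t_ms[sel[i]]
}

#' Scored ERP component definitions
#'
#' The fixed component windows and electrode clusters used for session-level
#' scoring: each component is measured as the mean amplitude over a +/-40 ms
#' window centered on its canonical grand-average peak latency, averaged
#' over a 6-electrode cluster.
#'
#' @return data-frame-free list of `component_definition` lists with fields
#'   `name`, `paradigm`, `numerator`/`denominator` conditions of the
#'   difference wave, `polarity`, `search_window_ms`, `peak_latency_ms`,
#'   `score_window_ms`, `peak_electrode`, `cluster`
#' @export
default_component_definitions <- function() {
  def <- function(name, paradigm, num, den, pol, search, peak, electrode,
                  cluster) {
    list(name = name, paradigm = paradigm, numerator = num,
         denominator = den, polarity = pol, search_window_ms = search,
         peak_latency_ms = peak, score_window_ms = c(peak - 40, peak + 40),
         peak_electrode = electrode, cluster = cluster)
  }
  list(
    mmn = def("mmn_amplitude", "mmn_vod", "deviant", "standard", "-",
              c(100, 200), 126, "FCz",
              c("Fz", "F1", "F2", "FCz", "FC1", "FC2")),
    aod_p3b = def("aod_p3b_amplitude", "aod", "target", "standard", "+",
                  c(250, 450), 339, "Pz",
                  c("CPz", "CP1", "CP2", "Pz", "P1", "P2")),
    aod_p3a = def("aod_p3a_amplitude", "aod", "novel", "standard", "+",
                  c(250, 450), 316, "Cz",
                  c("FCz", "FC1", "FC2", "Cz", "C1", "C2")),
    vod_p3b = def("vod_p3b_amplitude", "mmn_vod", "target", "standard", "+",
                  c(300, 550), 433, "Pz",
                  c("CPz", "CP1", "CP2", "Pz", "P1", "P2")),
    vod_p3a = def("vod_p3a_amplitude", "mmn_vod", "novel", "standard", "+",
                  c(300, 500), 372, "CPz",
                  c("Cz", "C1", "C2", "CPz", "CP1", "CP2"))
  )
}

#' Score a component on a difference wave
#'
#' Mean amplitude over the score-window samples (sample centers within the
#' closed window) at each cluster electrode, then mean over the cluster.
#'
#' @param wave an `erp_wave` (difference wave)
#' @param definition one element of [default_component_definitions()]
#' @return amplitude in microvolts
#' @export
score_component <- function(wave, definition) {
  missing <- setdiff(definition$cluster, wave$channels)
  if (length(missing)) stop("cluster electrodes missing: ",
                            paste(missing, collapse = ", "))
  t_ms <- wave$times * 1000
  sel <- t_ms >= definition$score_window_ms[1] - 1e-9 &
    t_ms <= definition$score_window_ms[2] + 1e-9
  if (!any(sel)) stop("score window outside wave")
  mean(colMeans(wave$data[definition$cluster, sel, drop = FALSE]))
}

#' Score a component from epochs
#'
#' Convenience wrapper: averages the numerator and denominator conditions,
#' forms the difference wave, and scores it.
#'
#' @param epochs an `epoch_set`
#' @param definition component definition
#' @return amplitude in microvolts
#' @export
score_component_epochs <- function(epochs, definition) {
  dw <- difference_wave(average_erp(epochs, definition$numerator),
                        average_erp(epochs, definition$denominator))
  score_component(dw, definition)
}

#' Per-run component scores
#'
#' Scores the component separately within each run using the fixed
#' session-level window and cluster. Runs lacking surviving epochs of either
#' condition yield an `NA` row flagged missing.
#'
#' @param epochs an `epoch_set` with `run_index` per epoch
#' @param definition component definition
#' @return data.frame with `run_index`, `value`, `n_numerator`,
#'   `n_denominator`, `missing`
#' @export
score_by_run <- function(epochs, definition) {
  runs <- sort(unique(epochs$run_index))
  out <- lapply(runs, function(r) {
    sub <- subset_epochs(epochs, epochs$run_index == r)
    n_num <- n_surviving(sub, definition$numerator)
    n_den <- n_surviving(sub, definition$denominator)
    if (n_num == 0 || n_den == 0)
      return(data.frame(run_index = r, value = NA_real_,
                        n_numerator = n_num, n_denominator = n_den,
                        missing = TRUE))
    data.frame(run_index = r, value = score_component_epochs(sub, definition),
               n_numerator = n_num, n_denominator = n_den, missing = FALSE)
  })
  do.call(rbind, out)
}

#' Subset an epoch set
#' @param epochs an `epoch_set`
#' @param keep logical vector over epochs
#' @return `epoch_set` restricted to `keep`
#' @export
subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$condition <- epochs$condition[keep]
  epochs$run_index <- epochs$run_index[keep]
  epochs$onset <- epochs$onset[keep]
  epochs$rejected <- epochs$rejected[keep]
  epochs$reject_reason <- epochs$reject_reason[keep]
  epochs
}
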