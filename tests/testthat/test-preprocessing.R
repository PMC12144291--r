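test_that("high-pass filter removes DC and preserves the passband", {
  m <- the_montage
  fs <- 1000; n <- 20000; t <- (0:(n - 1)) / fs
  x <- matrix(rep(sin(2 * pi * 10 * t) + 5, 3), 3, n, byrow = TRUE,
              dimnames = list(m$channel_labels[1:3]))
  raw <- raw_session(x, fs, m, empty_event_table())
  hp <- highpass_filter(raw, 0.2)
  mid <- 5000:15000  # edge-trimmed
  expect_lt(abs(mean(hp$data[1, mid])), 1e-3 * 5)
  amp <- sd(hp$data[1, mid]) * sqrt(2)
  expect_equal(amp, 1, tolerance = 0.01)
  expect_error(highpass_filter(raw, 500), "Nyquist")
})

test_that("downsampling decimates cleanly with anti-alias protection", {
  m <- the_montage
  fs <- 1000; n <- 20000; t <- (0:(n - 1)) / fs
  mk <- function(f) {
    x <- matrix(rep(sin(2 * pi * f * t), 2), 2, n, byrow = TRUE,
                dimnames = list(m$channel_labels[1:2]))
    raw_session(x, fs, m, event_table(1.0, "S  1", "auditory", "standard",
                                      1L, "aod"))
  }
  ds <- downsample(mk(30), 250)
  expect_equal(ncol(ds$data), n / 4)
  expect_equal(ds$sampling_rate, 250)
  mid <- 1250:3750
  expect_equal(sd(ds$data[1, mid]) * sqrt(2), 1, tolerance = 0.02)
  # events live on the seconds clock: unchanged
  expect_equal(ds$events$onset_time, 1.0)

  ds2 <- downsample(mk(200), 250)
  att <- 20 * log10(sd(ds2$data[1, mid]) / (1 / sqrt(2)))
  expect_lt(att, -40)
  expect_error(downsample(mk(30), 300), "divide")
})

test_that("bad-channel detection flags planted outliers but not clean data", {
  raw <- make_background(5000, seed = 21)
  expect_length(detect_bad_channels(raw), 0)

  noisy <- raw
  noisy$data["C3", ] <- rnorm(5000, 0, 100 * sd(raw$data["C3", ]))
  expect_identical(detect_bad_channels(noisy), "C3")

  flat <- raw
  flat$data["P3", ] <- 0
  expect_true("P3" %in% detect_bad_channels(flat))

  # specificity across seeds: at most 1 false flag over 50 backgrounds
  fp <- sum(vapply(1:50, function(s)
    length(detect_bad_channels(make_background(1500, seed = 300 + s))),
    numeric(1)))
  expect_lte(fp, 1)
})

test_that("spherical-spline interpolation recovers a smooth corrupted channel", {
  m <- the_montage
  set.seed(22)
  w <- eegret:::.topo_field(m, "Cz", 0.9)[m$channel_labels]
  sig <- outer(w, sin(2 * pi * 5 * (0:999) / 250)) +
    0.01 * matrix(rnorm(63 * 1000), 63)
  rownames(sig) <- m$channel_labels
  raw <- raw_session(sig, 250, m, empty_event_table())
  orig <- raw$data["C1", ]
  raw$data["C1", ] <- rnorm(1000, 0, 50)
  ri <- interpolate_channels(raw, "C1")
  expect_gt(cor(ri$data["C1", ], orig), 0.9)
  # identity and error paths
  expect_identical(interpolate_channels(raw, character(0)), raw)
  expect_error(interpolate_channels(raw, "XX"), "not in recording")
  expect_error(interpolate_channels(raw, m$channel_labels[1:60]),
               "fewer than 4")
})

test_that("robust average reference zeroes the included mean and resists outliers", {
  raw <- make_background(4000, seed = 23)
  rr <- robust_average_reference(raw)
  incl <- rr$reference_info$included
  expect_lt(max(abs(colMeans(rr$data[incl, ]))), 1e-9)
  expect_true("FCz" %in% rownames(rr$data))

  # one huge-noise channel: robust reference stays close to the clean mean
  noisy <- raw
  noisy$data["C3", ] <- rnorm(4000, 0, 200)
  excl <- c("TP9", "TP10", "Fp1", "Fp2")
  raw_f <- reconstruct_reference_channel(raw)
  clean_ref <- colMeans(raw_f$data[setdiff(rownames(raw_f$data), excl), ])
  rr2 <- robust_average_reference(noisy)
  noisy_f <- reconstruct_reference_channel(noisy)
  used_ref <- colMeans(noisy_f$data[rr2$reference_info$included, ])
  naive_ref <- colMeans(noisy_f$data[setdiff(rownames(noisy_f$data), excl), ])
  rms <- function(v) sqrt(mean(v^2))
  # scale: typical channel amplitude (the fixture is already average
  # referenced, so the clean reference itself is near zero)
  scale <- stats::median(apply(raw$data, 1, stats::sd))
  expect_lt(rms(used_ref - clean_ref), 0.05 * scale)
  expect_gt(rms(naive_ref - clean_ref), 0.05 * scale)
  expect_true("C3" %in% rr2$reference_info$bad_channels)

  # excluded channels are offset by the reference but keep their shape
  fp1_diff <- raw$data["Fp1", ] - rr$data["Fp1", ]
  ref <- colMeans(raw$data[incl, ])
  expect_equal(fp1_diff, ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("epoching honors the half-open window and the edge rule", {
  raw <- make_background(2500, seed = 24)  # 10 s at 250 Hz
  ev <- event_table(c(0.1, 2, 4, 6), "S  2", "auditory", "deviant", 1L,
                    "mmn_vod")
  raw$events <- ev
  expect_warning(ep <- epoch(raw, ev, c(-0.5, 0.5)), "edges")
  expect_equal(dim(ep$data)[3], 3)  # the 0.1 s event is dropped
  expect_equal(dim(ep$data)[2], 250)
  expect_equal(ep$times[1], -0.5)
  expect_error(epoch(raw, ev[0, ], c(-0.5, 0.5)), "empty")
})

test_that("epoch-statistic rejection flags exactly the planted outlier", {
  set.seed(25)
  arr <- array(rnorm(10 * 100 * 51), c(10, 100, 51))
  arr[, , 17] <- arr[, , 17] * 10
  eps <- reject_epochs_faster(make_epochs(arr))
  expect_identical(which(eps$rejected), 17L)
  expect_match(eps$reject_reason[17], "variance|peak_to_peak|mean")

  # degenerate zero-spread statistics reject nothing
  same <- array(rep(rnorm(10 * 100), 5), c(10, 100, 5))
  expect_equal(sum(reject_epochs_faster(make_epochs(same))$rejected), 0)
})

test_that("rejection decisions match a brute-force z-score oracle", {
  for (s in 1:20) {
    set.seed(400 + s)
    n_ep <- 30
    arr <- array(rnorm(5 * 50 * n_ep, sd = sample(1:3, 1)), c(5, 50, n_ep))
    got <- reject_epochs_faster(make_epochs(arr))$rejected
    # oracle: channel-mean statistics z-scored across epochs
    st <- sapply(seq_len(n_ep), function(e) {
      m <- arr[, , e]
      c(mean(m), mean(apply(m, 1, var)),
        mean(apply(m, 1, function(v) max(v) - min(v))))
    })
    z <- apply(st, 1, function(v) (v - mean(v)) / sd(v))
    expect_identical(got, unname(apply(abs(z) >= 3, 1, any)))
  }
})

test_that("baseline correction zeroes the baseline window and is shift invariant", {
  set.seed(26)
  arr <- array(rnorm(6 * 250 * 8), c(6, 250, 8))
  eps <- make_epochs(arr)
  bc <- baseline_correct(eps)
  sel <- bc$times >= -0.1 & bc$times <= 0
  bl <- apply(bc$data[, sel, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(bl)), 1e-9)

  const <- make_epochs(array(7, c(3, 100, 4)), t0 = -0.2)
  expect_equal(max(abs(baseline_correct(const)$data)), 0)

  shifted <- eps
  shifted$data <- shifted$data + 42
  expect_equal(baseline_correct(shifted)$data, bc$data, tolerance = 1e-12)
})
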