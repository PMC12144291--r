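# build an ASSR-like epoch set directly: per-trial 40 Hz segments with
# chosen phases, on the full -1.248..1.752 s epoch grid
make_assr_epochs <- function(phases, amp = 1, noise_sd = 0, channels = "Cz",
                             f = 40, amp_baseline = 0) {
  fs <- 250
  times <- seq(round(-1.248 * fs), round(1.752 * fs) - 1) / fs
  nch <- length(channels)
  arr <- array(0, c(nch, length(times), length(phases)),
               dimnames = list(channels, NULL, NULL))
  for (j in seq_along(phases)) {
    sig <- amp_baseline * sin(2 * pi * f * times + phases[j])
    on <- times >= 0 & times <= 0.5
    sig[on] <- amp * sin(2 * pi * f * times[on] + phases[j])
    arr[, , j] <- matrix(rep(sig, each = nch), nch) +
      if (noise_sd > 0) rnorm(nch * length(times), 0, noise_sd) else 0
  }
  eps <- make_epochs(arr, fs = fs, t0 = times[1])
  eps$condition <- rep("train", length(phases))
  eps
}

test_that("wavelet constants follow the piecewise rule with equal bandwidth 20-40 Hz", {
  w40 <- wavelet_spec(40)
  expect_equal(w40$C, 14)
  expect_equal(6 * w40$sigma_f, 17.1429, tolerance = 1e-4)
  w20 <- wavelet_spec(20)
  expect_equal(w20$C, 7)
  expect_equal(6 * w20$sigma_f, 17.1429, tolerance = 1e-4)
  w30 <- wavelet_spec(30)
  expect_equal(w30$C, 10.5)
  expect_equal(w30$sigma_f, 30 / 10.5, tolerance = 1e-6)
  for (f in seq(20, 40, by = 0.5))
    expect_equal(6 * wavelet_spec(f)$sigma_f, 120 / 7, tolerance = 1e-9)
  expect_equal(wavelet_spec(60)$C, 14)
  expect_equal(wavelet_spec(10)$C, 7)
  expect_error(wavelet_spec(0), "positive")
})

test_that("Morlet coefficients localize, scale linearly, and separate frequencies", {
  eps <- make_assr_epochs(phases = rep(0, 3), amp = 1, amp_baseline = 1)
  tfc <- morlet_transform(eps, freqs = seq(4, 100, by = 2))
  mag <- Mod(tfc$coef[1, , , 1])
  # maximal at the 40 Hz bin
  expect_equal(tfc$freqs[which.max(rowMeans(mag))], 40)
  # constant over time mid-epoch for a stationary sinusoid
  mid <- tfc$times > 0.15 & tfc$times < 0.45
  m40 <- mag[tfc$freqs == 40, mid]
  expect_lt((max(m40) - min(m40)) / mean(m40), 0.02)

  # linearity
  eps2 <- eps; eps2$data <- eps2$data * 2
  tfc2 <- morlet_transform(eps2, freqs = c(38, 40, 42))
  expect_equal(Mod(tfc2$coef), 2 * Mod(tfc$coef[, tfc$freqs %in% c(38, 40, 42), , , drop = FALSE]),
               tolerance = 1e-9)

  # 30 and 80 Hz content stays in its own bins
  fs <- 250
  times <- eps$times
  arr <- array(sin(2 * pi * 30 * times) + sin(2 * pi * 80 * times),
               c(1, length(times), 2), dimnames = list("Cz", NULL, NULL))
  e3 <- make_epochs(arr, fs = fs, t0 = times[1])
  t3 <- morlet_transform(e3, freqs = seq(20, 90, by = 2))
  mg <- rowMeans(Mod(t3$coef[1, , t3$times > 0 & t3$times < 0.5, 1]))
  names(mg) <- t3$freqs
  mid_bin <- mg[["54"]] + mg[["56"]]
  expect_lt(mid_bin / (mg[["30"]] + mg[["80"]]), 0.1)

  # epochs too short for the kernel error out
  short <- make_epochs(array(0, c(1, 100, 2)), fs = 250, t0 = -0.2)
  expect_error(morlet_transform(short, freqs = 4), "too short")
})

test_that("inter-trial coherence is the mean resultant length of trial phases", {
  # identical phases -> 1
  co <- array(exp(1i * rep(0.7, 8)), c(1, 1, 1, 8))
  expect_equal(itc(co)$values[1], 1)
  # symmetric phases cancel -> 0
  co4 <- array(exp(1i * c(0, pi / 2, pi, 3 * pi / 2)), c(1, 1, 1, 4))
  expect_lt(itc(co4)$values[1], 1e-12)
  # invariant to per-trial amplitude scaling
  set.seed(50)
  ph <- runif(30, -pi, pi)
  a <- array(exp(1i * ph), c(1, 1, 1, 30))
  b <- array(runif(30, 0.5, 5) * exp(1i * ph), c(1, 1, 1, 30))
  expect_equal(itc(a)$values, itc(b)$values, tolerance = 1e-12)
  # bounded in [0, 1]
  expect_true(all(itc(b)$values >= 0 & itc(b)$values <= 1))
  # zero-magnitude coefficients are excluded and counted
  c0 <- array(c(0 + 0i, exp(1i * c(0.2, 0.2, 0.2))), c(1, 1, 1, 4))
  r <- itc(c0)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$values[1], 1)
})

test_that("uniform random phases give the closed-form expected resultant length", {
  # E[R] for N uniform phases is sqrt(pi)/(2 sqrt(N)) = 0.0886 at N = 100
  set.seed(51)
  reps <- replicate(200, {
    co <- array(exp(1i * runif(100, -pi, pi)), c(1, 1, 1, 100))
    itc(co)$values[1]
  })
  expect_equal(mean(reps), sqrt(pi) / (2 * sqrt(100)), tolerance = 0.01)
})

test_that("total power reports baseline-relative dB and ignores phase", {
  set.seed(52)
  # stationary signal: ~0 dB everywhere
  eps <- make_assr_epochs(runif(40, -pi, pi), amp = 1, amp_baseline = 1,
                          noise_sd = 0.05)
  tp <- total_power(morlet_transform(eps, freqs = c(38, 40, 42)))
  expect_lt(max(abs(tp$values)), 0.5)

  # amplitude doubling post-stimulus: +6.02 dB at the signal frequency
  eps2 <- make_assr_epochs(runif(40, -pi, pi), amp = 2, amp_baseline = 1)
  tp2 <- total_power(morlet_transform(eps2, freqs = 40))
  mid <- tp2$times > 0.15 & tp2$times < 0.45
  expect_equal(mean(tp2$values[1, 1, mid]), 20 * log10(2), tolerance = 0.2)

  # phase randomization leaves total power unchanged
  eps3 <- make_assr_epochs(rep(0, 40), amp = 2, amp_baseline = 1)
  tp3 <- total_power(morlet_transform(eps3, freqs = 40))
  expect_equal(mean(tp3$values[1, 1, mid]), mean(tp2$values[1, 1, mid]),
               tolerance = 0.05)
})

test_that("evoked power equals total power for locked trials and vanishes for random phase", {
  # perfectly phase-locked: evoked == total in the linear domain
  eps <- make_assr_epochs(rep(0.3, 30), amp = 1.5, amp_baseline = 0.5)
  tfc <- morlet_transform(eps, freqs = 40)
  ev <- evoked_power(morlet_transform(average_epochs(eps), freqs = 40))
  mid <- which(tfc$times > 0.15 & tfc$times < 0.45)
  p_lin <- rowMeans(Mod(tfc$coef[1, 1, , , drop = FALSE])^2, dims = 3)
  base <- tfc$times >= -0.2 & tfc$times <= -0.1
  total_lin_rise <- mean(p_lin[mid]) - mean(p_lin[base])
  expect_equal(mean(ev$values[1, 1, mid]), total_lin_rise, tolerance = 0.01)

  # uniform phases: evoked power collapses to a few percent of the
  # single-trial (total) power in the same linear units
  set.seed(53)
  eps2 <- make_assr_epochs(runif(400, -pi, pi), amp = 1.5)
  tfc2 <- morlet_transform(eps2, freqs = 40)
  ev2 <- evoked_power(morlet_transform(average_epochs(eps2), freqs = 40))
  total_lin <- mean(rowMeans(Mod(tfc2$coef)^2, dims = 3)[1, 1, mid])
  expect_lt(mean(abs(ev2$values[1, 1, mid])), 0.05 * total_lin)
  expect_gt(mean(total_power(morlet_transform(eps2, freqs = 40))$values[
    1, 1, mid]), 3)

  # zero signal -> exactly zero after baseline subtraction
  z <- make_assr_epochs(rep(0, 5), amp = 0, amp_baseline = 0)
  evz <- evoked_power(morlet_transform(average_epochs(z), freqs = 40))
  expect_equal(max(abs(evz$values)), 0)
})

test_that("measure extraction averages exactly the 38/40/42 Hz bins over 100-500 ms", {
  cluster <- c("FCz", "FC1", "FC2", "Cz", "C1", "C2")
  eps <- make_assr_epochs(rep(0, 10), amp = 1, channels = cluster)
  tfc <- morlet_transform(eps, freqs = seq(34, 46, by = 2))
  r <- itc(tfc)
  v1 <- extract_assr_measure(r)
  expect_equal(v1, 1, tolerance = 1e-6)
  # perturbing the 44 Hz bin leaves the measure unchanged
  r2 <- r
  r2$values[, r$freqs == 44, ] <- 0
  expect_identical(extract_assr_measure(r2), v1)
  r3 <- r
  r3$values[, r$freqs == 40, ] <- 0
  expect_false(identical(extract_assr_measure(r3), v1))
  expect_error(extract_assr_measure(r, cluster = "XX"), "missing")
})

test_that("wavelet path agrees with an FFT-bandpass + Hilbert-phase oracle", {
  set.seed(54)
  phases <- runif(25, -pi, pi)
  eps <- make_assr_epochs(phases, amp = 1.2, amp_baseline = 0.4,
                          noise_sd = 0.05)
  tfc <- morlet_transform(eps, freqs = 40)
  mid <- tfc$times > 0.15 & tfc$times < 0.45
  itc_wav <- mean(itc(tfc)$values[1, 1, mid])

  # oracle: FFT band mask around 40 Hz -> analytic signal -> phase
  fs <- 250; n <- dim(eps$data)[2]
  f <- (0:(n - 1)) * fs / n
  mask <- as.numeric(f >= 36 & f <= 44)  # positive-frequency band only
  hilb <- function(x) fft(fft(x) * mask * 2, inverse = TRUE) / n
  analytic <- sapply(seq_along(phases), function(j) hilb(eps$data[1, , j]))
  mid_f <- which(eps$times > 0.15 & eps$times < 0.45)
  ph <- analytic[mid_f, ] / Mod(analytic[mid_f, ])
  itc_orc <- mean(Mod(rowMeans(ph)))
  expect_equal(itc_wav, itc_orc, tolerance = 0.02)

  # power: compare the two paths on stationary signals (amplitude doubled
  # between datasets) where neither path suffers transition edges; the
  # amplitude-squared ratio is normalization-free
  mk_flat <- function(a) make_assr_epochs(runif(10, -pi, pi), amp = a,
                                          amp_baseline = a,
                                          noise_sd = 0.02)
  lo <- mk_flat(0.6); hi <- mk_flat(1.2)
  pw <- function(e) {
    tf <- morlet_transform(e, freqs = 40)
    mean(rowMeans(Mod(tf$coef)^2, dims = 3)[1, 1,
      tf$times > 0.15 & tf$times < 0.45])
  }
  pw_orc <- function(e) {
    a <- sapply(seq_len(dim(e$data)[3]), function(j) hilb(e$data[1, , j]))
    mean(Mod(a[mid_f, ])^2)
  }
  ratio_wav <- pw(hi) / pw(lo)
  ratio_orc <- pw_orc(hi) / pw_orc(lo)
  expect_equal(ratio_wav, 4, tolerance = 0.02)
  expect_equal(ratio_wav, ratio_orc, tolerance = 0.02)
})

test_that("phase locking through the wavelet path rises monotonically with concentration", {
  set.seed(55)
  vals <- sapply(c(0, 1, 4, 16, Inf), function(kappa) {
    ph <- eegret:::.rvonmises(100, kappa)
    eps <- make_assr_epochs(ph, amp = 1)
    mean(itc(morlet_transform(eps, freqs = 40))$values[1, 1,
      morlet_transform(eps, freqs = 40)$times > 0.15 &
      morlet_transform(eps, freqs = 40)$times < 0.45])
  })
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[5], 1, tolerance = 1e-6)
  # and tracks the analytic von Mises resultant
  expect_equal(vals[3], besselI(4, 1) / besselI(4, 0), tolerance = 0.1)
})
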