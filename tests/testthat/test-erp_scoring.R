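test_that("epoch averaging is the arithmetic mean over surviving epochs", {
  set.seed(40)
  w <- sin(2 * pi * 3 * (0:249) / 250)
  arr <- array(rep(w, each = 4), c(4, 250, 20))
  eps <- make_epochs(arr)
  av <- average_erp(eps)
  expect_equal(av$data[1, ], w, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(av$n_epochs, 20)

  # averaging law: residual noise shrinks as noise/sqrt(n)
  n <- 400
  arr2 <- array(rep(w, each = 4), c(4, 250, n)) +
    array(rnorm(4 * 250 * n), c(4, 250, n))
  av2 <- average_erp(make_epochs(arr2))
  expect_lt(sqrt(mean((av2$data[1, ] - w)^2)), 3 / sqrt(n))

  # rejected epochs are excluded from the mean
  eps$data[, , 1] <- 100
  eps$rejected[1] <- TRUE
  av3 <- average_erp(eps)
  expect_equal(av3$n_epochs, 19)
  eps$rejected[1] <- FALSE
  expect_false(isTRUE(all.equal(average_erp(eps)$data, av3$data)))
  expect_error(average_erp(eps, "deviant"), "zero surviving")
})

test_that("difference waves subtract pointwise and are antisymmetric", {
  set.seed(41)
  arr <- array(rnorm(3 * 100 * 10), c(3, 100, 10))
  a <- average_erp(make_epochs(arr))
  b <- average_erp(make_epochs(arr * 0.5))
  d <- difference_wave(a, b)
  expect_equal(d$data, a$data - b$data)
  expect_equal(difference_wave(b, a)$data, -d$data)
  expect_equal(max(abs(difference_wave(a, a)$data)), 0)
  short <- a; short$times <- short$times + 1
  expect_error(difference_wave(a, short), "match")
})

test_that("a planted mismatch response is recovered on the difference wave", {
  m <- the_montage
  labels <- rownames(m$positions)  # average-reference frame includes FCz
  times <- seq(-0.5, 0.5 - 1 / 250, by = 1 / 250)
  w <- eegret:::.topo_field(m, "FCz", 0.8)[labels]
  shape <- -3 * exp(-((times * 1000 - 126)^2) / (2 * 30^2))
  dev <- array(outer(w, shape), c(length(labels), 250, 8),
               dimnames = list(labels, NULL, NULL))
  std <- array(0, c(length(labels), 250, 8),
               dimnames = list(labels, NULL, NULL))
  dw <- difference_wave(average_erp(make_epochs(dev)),
                        average_erp(make_epochs(std)))
  expect_equal(min(dw$data["FCz", ]), -3 * w[["FCz"]], tolerance = 0.02)
  # peak finder puts the planted extremum at 126 ms (4 ms grid -> 124)
  pk <- find_component_peak(dw, "-", c(100, 200), "FCz")
  expect_lt(abs(pk - 126), 4)
})

test_that("peak finding honors polarity, ties, and the monotone edge case", {
  times <- seq(-0.1, 0.5 - 1 / 250, by = 1 / 250)
  mk <- function(v) structure(list(data = matrix(v, 1,
                                                 dimnames = list("FCz")),
                                   times = times, sampling_rate = 250,
                                   channels = "FCz", condition = "d",
                                   n_epochs = 1), class = "erp_wave")
  # two equal minima: earliest wins
  v <- rep(0, length(times))
  v[times * 1000 >= 118 & times * 1000 <= 122] <- -1
  v[times * 1000 >= 158 & times * 1000 <= 162] <- -1
  expect_equal(find_component_peak(mk(v), "-", c(100, 200), "FCz"), 120)
  # monotone wave: edge + warning
  expect_warning(
    pk <- find_component_peak(mk(-seq_along(times)), "-", c(100, 200),
                              "FCz"),
    "edge")
  expect_equal(pk, 200)
})

test_that("component definitions carry the canonical windows and clusters", {
  d <- default_component_definitions()
  expect_equal(d$mmn$score_window_ms, c(86, 166))
  expect_equal(d$mmn$cluster, c("Fz", "F1", "F2", "FCz", "FC1", "FC2"))
  expect_equal(d$vod_p3b$score_window_ms, c(393, 473))
  expect_equal(d$vod_p3b$peak_latency_ms, 433)
  expect_equal(d$aod_p3b$score_window_ms, c(299, 379))
  expect_equal(d$aod_p3a$cluster, c("FCz", "FC1", "FC2", "Cz", "C1", "C2"))
  expect_equal(d$vod_p3a$score_window_ms, c(332, 412))
  expect_equal(d$vod_p3a$cluster, c("Cz", "C1", "C2", "CPz", "CP1", "CP2"))
  for (x in d) expect_equal(diff(x$score_window_ms), 80)
})

test_that("window scoring is the cluster-window mean and is linear", {
  def <- default_component_definitions()$mmn
  m <- the_montage
  labels <- rownames(m$positions)
  times <- seq(-0.5, 0.5 - 1 / 250, by = 1 / 250)
  mkwave <- function(vals_by_ch) {
    data <- matrix(0, length(labels), length(times),
                   dimnames = list(labels, NULL))
    for (ch in names(vals_by_ch)) data[ch, ] <- vals_by_ch[[ch]]
    structure(list(data = data, times = times, sampling_rate = 250,
                   channels = labels, condition = "d", n_epochs = 1),
              class = "erp_wave")
  }
  w1 <- mkwave(setNames(as.list(rep(-2, 6)), def$cluster))
  expect_equal(score_component(w1, def), -2)
  w2 <- mkwave(setNames(as.list(1:6), def$cluster))
  expect_equal(score_component(w2, def), 3.5)
  # linearity
  w3 <- w1; w3$data <- 2 * w1$data + w2$data
  expect_equal(score_component(w3, def),
               2 * score_component(w1, def) + score_component(w2, def))
  bad <- def; bad$cluster <- c(def$cluster, "XX")
  expect_error(score_component(w1, bad), "missing")
})

test_that("per-run scoring uses fixed windows and reports one row per run", {
  set.seed(42)
  def <- default_component_definitions()$mmn
  labels <- rownames(the_montage$positions)
  n_runs <- 5; per_run <- 12
  amps <- -2 * (1 - 0.1)^(0:(n_runs - 1))
  shape <- exp(-((seq(-0.5, 0.5 - 1 / 250, by = 1 / 250) * 1000 - 126)^2) /
                 (2 * 30^2))
  arrs <- list(); conds <- c(); runs <- c()
  for (r in seq_len(n_runs)) {
    for (j in seq_len(per_run)) {
      is_dev <- j <= per_run / 2
      base <- matrix(0, length(labels), 250, dimnames = list(labels, NULL))
      if (is_dev) base[def$cluster, ] <-
          matrix(rep(amps[r] * shape, each = 6), 6)
      arrs[[length(arrs) + 1]] <- base
      conds <- c(conds, if (is_dev) "deviant" else "standard")
      runs <- c(runs, r)
    }
  }
  arr <- array(unlist(arrs), c(length(labels), 250, length(arrs)),
               dimnames = list(labels, NULL, NULL))
  eps <- make_epochs(arr, condition = conds, run_index = runs)
  br <- score_by_run(eps, def)
  expect_equal(nrow(br), 5)
  expect_false(any(br$missing))
  # monotone habituation pattern recovered; run scores scale with amps
  expect_equal(br$value / br$value[1], amps / amps[1], tolerance = 1e-6)
  # a run lacking deviants is flagged missing
  eps2 <- subset_epochs(eps, !(runs == 3 & conds == "deviant"))
  br2 <- score_by_run(eps2, def)
  expect_true(br2$missing[br2$run_index == 3])
})
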