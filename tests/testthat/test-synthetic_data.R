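test_that("stimulus counts match the paradigm design for every seed", {
  for (seed in c(1, 17, 202)) {
    s <- generate_mmn_vod_sequence(seed = seed)
    aud <- s[s$modality == "auditory", ]
    vis <- s[s$modality == "visual", ]
    expect_equal(nrow(aud), 3200)
    expect_equal(sum(aud$condition == "deviant"), 320)
    expect_equal(nrow(vis), 800)
    expect_equal(sum(vis$condition == "target"), 80)
    expect_equal(sum(vis$condition == "novel"), 80)
    expect_equal(sum(vis$condition == "standard"), 640)
    # each run opens with 20 standards, and rare stimuli are never adjacent
    for (r in 1:5) {
      ar <- aud[aud$run_index == r, ]
      expect_equal(nrow(ar), 640)
      expect_true(all(ar$condition[1:20] == "standard"))
      rare <- which(ar$condition == "deviant")
      expect_true(all(diff(rare) >= 2))
      vr <- vis[vis$run_index == r, ]
      rare_v <- which(vr$condition != "standard")
      expect_true(all(diff(rare_v) >= 2))
    }
  }
})

test_that("visual onsets keep the cross-modal gap and the frame-grid jitter", {
  s <- generate_mmn_vod_sequence(seed = 5)
  for (r in 1:5) {
    aud <- s$onset_time[s$modality == "auditory" & s$run_index == r]
    vis <- s$onset_time[s$modality == "visual" & s$run_index == r]
    # tones on the 0.5 s grid; every visual onset >= 50 ms from every tone
    ph <- (vis - min(aud)) %% 0.5
    expect_true(all(pmin(ph, 0.5 - ph) >= 0.05 - 2e-3))  # ms rounding slack
    soas <- diff(vis)
    expect_true(all(soas >= 1.6 - 2e-3 & soas <= 2.4 + 2e-3))
    # tone stream spans 640 x 0.5 s
    expect_equal(max(aud) - min(aud), 639 * 0.5)
  }
})

test_that("auditory oddball sequence uses the 25 ms SOA grid with mean 1.25 s", {
  s <- generate_aod_sequence(seed = 9)
  expect_equal(nrow(s), 800)
  expect_equal(sum(s$condition == "target"), 80)
  expect_equal(sum(s$condition == "novel"), 80)
  soas <- unlist(lapply(1:4, function(r) diff(s$onset_time[s$run_index == r])))
  expect_true(all(abs(soas / 0.025 - round(soas / 0.025)) < 1e-9))
  expect_true(all(soas >= 1.1 - 1e-9 & soas <= 1.4 + 1e-9))
  # law of large numbers: 796 draws from a uniform grid with mean 1.25
  expect_equal(mean(soas), 1.25, tolerance = 0.01)
  # run payload duration at mean SOA
  for (r in 1:4) {
    on <- s$onset_time[s$run_index == r]
    expect_true(max(on) - min(on) > 220 && max(on) - min(on) < 280)
  }
})

test_that("click-train sequence implies 40 Hz stimulation at a fixed SOA", {
  s <- generate_assr_sequence()
  expect_equal(nrow(s), 150)
  expect_equal(unique(diff(s$onset_time)), 1.5)
  expect_equal(max(s$onset_time) - min(s$onset_time), 149 * 1.5)
  # 20 clicks per 500 ms train at 25 ms spacing = 40 Hz
  expect_equal(1 / paradigm_spec()$assr$click_interval, 40)
  expect_equal(paradigm_spec()$assr$train_dur /
                 paradigm_spec()$assr$click_interval, 20)
})

test_that("sequences are deterministic in the seed", {
  a <- generate_mmn_vod_sequence(seed = 42)
  b <- generate_mmn_vod_sequence(seed = 42)
  c <- generate_mmn_vod_sequence(seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$condition, c$condition))
  # same counts regardless of seed
  expect_equal(table(a$condition), table(c$condition))
})

test_that("session timeline reproduces the published schedule", {
  tl <- session_timeline()
  expect_equal(sum(tl$duration_s), 3443)  # 57:23
  expect_equal(sum(tl$paradigm == "mmn_vod", na.rm = TRUE), 5)
  expect_equal(sum(tl$paradigm == "aod", na.rm = TRUE), 4)
})

test_that("measure-level simulator matches its variance-component model", {
  tr <- study_truth(measures = data.frame(
    measure_name = "m", mu = 10, sigma_p = sqrt(0.75),
    occasion_shift = 0, sigma_res = sqrt(0.25)))
  mt <- simulate_measures(tr, n_persons = 10000, seed = 3)
  w <- matrix(mt$value, ncol = 2)
  vc <- variance_components(w)
  # empirical components converge to truth
  expect_equal(vc$sigma2_p, 0.75, tolerance = 0.05 * 0.75 / 1)
  expect_equal(vc$sigma2_po_e, 0.25, tolerance = 0.05)
  g <- g_coefficient(vc)
  expect_equal(g$g, 0.75, tolerance = 0.02)

  # zero relative error: G = 1 exactly
  tr0 <- study_truth(measures = data.frame(
    measure_name = "m", mu = 1, sigma_p = 1, occasion_shift = 0,
    sigma_res = 0))
  mt0 <- simulate_measures(tr0, n_persons = 50, seed = 4)
  g0 <- g_coefficient(variance_components(matrix(mt0$value, ncol = 2)))
  expect_identical(g0$g, 1)
})

test_that("an occasion shift moves the paired test but not the G-coefficient", {
  base <- data.frame(measure_name = "m", mu = 0, sigma_p = 1,
                     occasion_shift = 0, sigma_res = 0.2)
  shifted <- transform(base, occasion_shift = 1)
  m0 <- simulate_measures(study_truth(measures = base), 300, seed = 8)
  m1 <- simulate_measures(study_truth(measures = shifted), 300, seed = 8)
  w0 <- matrix(m0$value, ncol = 2); w1 <- matrix(m1$value, ncol = 2)
  expect_lt(paired_t(w1)$p, 0.05)
  # same seed: identical noise, so G is unchanged by the pure shift
  expect_equal(g_coefficient(variance_components(w1))$g,
               g_coefficient(variance_components(w0))$g, tolerance = 1e-10)
})

test_that("simulator is deterministic and balanced", {
  tr <- study_truth()
  a <- simulate_measures(tr, 20, seed = 5)
  b <- simulate_measures(tr, 20, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  tab <- table(a$measure_name, a$occasion)
  expect_true(all(tab == 20))
})
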