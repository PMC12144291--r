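test_that("standard montage has 63 recorded channels, FCz reference, and all cluster sites", {
  m <- standard_montage()
  expect_length(m$channel_labels, 63)
  expect_identical(m$reference_label, "FCz")
  expect_false(anyDuplicated(m$channel_labels) > 0)
  expect_true(all(c("Fp1", "Fp2", "TP9", "TP10") %in% m$channel_labels))
  cluster_sites <- unique(c(
    unlist(lapply(default_component_definitions(), `[[`, "cluster")),
    unlist(lapply(default_band_definitions(), `[[`, "cluster")),
    "P7", "P8", "POz", "AF3", "CP1"))
  expect_true(all(cluster_sites %in% rownames(m$positions)))
  expect_equal(unname(sqrt(rowSums(m$positions^2))),
               rep(1, nrow(m$positions)), tolerance = 1e-12)
})

test_that("brainvision reader parses a hand-built fixture triplet", {
  d <- withr::local_tempdir()
  fs <- 100
  x <- matrix(seq(0, 2.99, by = 0.01), nrow = 3, byrow = TRUE)
  writeLines(c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=fix.eeg", "MarkerFile=fix.vmrk",
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    "NumberOfChannels=3", "SamplingInterval=10000",
    "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    "Ch1=Fz,,1,µV", "Ch2=Cz,,1,µV", "Ch3=Pz,,1,µV"),
    file.path(d, "fix.vhdr"))
  writeLines(c(
    "BrainVision Data Exchange Marker File Version 1.0",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    "Mk2=Stimulus,S  1,11,1,0",
    "Mk3=Stimulus,S  2,51,1,0"),
    file.path(d, "fix.vmrk"))
  con <- file(file.path(d, "fix.eeg"), "wb")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  close(con)

  s <- read_brainvision(file.path(d, "fix.vhdr"))
  expect_equal(nrow(s$events), 2)
  expect_equal(s$events$onset_time, c(0.10, 0.50))
  expect_equal(s$events$condition, c("standard", "deviant"))
  expect_equal(dim(s$data), c(3, 100))
  expect_equal(s$data, x, tolerance = 1e-6, ignore_attr = TRUE)

  # missing companion file errors
  file.remove(file.path(d, "fix.eeg"))
  expect_error(read_brainvision(file.path(d, "fix.vhdr")), "missing data")
})

test_that("session writers round-trip through both formats", {
  set.seed(10)
  m <- the_montage
  x <- matrix(rnorm(63 * 500), 63, dimnames = list(m$channel_labels))
  ev <- event_table(c(0.05, 0.21, 0.4), c("S  1", "S  2", "S  1"),
                    "auditory", c("standard", "deviant", "standard"),
                    1L, "mmn_vod")
  s <- raw_session(x, 1000, m, ev, meta = list(subject_id = "rt1"))
  d <- withr::local_tempdir()

  # archive: exact round trip, one events row per record
  write_session(s, file.path(d, "arch"), "archive")
  s2 <- read_session_archive(file.path(d, "arch"))
  expect_identical(s2$data, s$data)
  expect_equal(as.data.frame(s2$events), as.data.frame(s$events))
  ev_file <- read.table(file.path(d, "arch", "events.tsv"), sep = "\t",
                        header = TRUE)
  expect_equal(nrow(ev_file), nrow(ev))

  # brainvision: float32 precision, events exact, readable by the reader
  write_session(s, file.path(d, "bv"), "brainvision")
  s3 <- read_brainvision(file.path(d, "bv.vhdr"))
  expect_lt(max(abs(s3$data - s$data)), 1e-5)
  expect_equal(s3$events$onset_time, s$events$onset_time)
  expect_equal(s3$events$condition, s$events$condition)
  # onset monotonicity preserved by the round trip
  expect_false(is.unsorted(s3$events$onset_time, strictly = TRUE))
})

test_that("unmapped marker codes are retained as unknown with a warning", {
  d <- withr::local_tempdir()
  m <- the_montage
  x <- matrix(0, 63, 200, dimnames = list(m$channel_labels))
  ev <- event_table(0.05, "S 99", "auditory", "unknown", 1L, "aod")
  s <- raw_session(x, 1000, m, ev)
  write_session(s, file.path(d, "u"), "brainvision")
  expect_warning(s2 <- read_brainvision(file.path(d, "u.vhdr")), "unmapped")
  expect_equal(s2$events$condition, "unknown")
  expect_equal(s2$events$code, "S 99")
})

test_that("measure tables round-trip losslessly and reject duplicate keys", {
  set.seed(11)
  n <- 571
  ids <- sprintf("s%04d", seq_len(n))
  mt <- measure_table(rep(ids, 2), "CHR",
                      rep(c("baseline", "month2"), each = n), "all",
                      "mmn_amplitude", rnorm(2 * n))
  f <- withr::local_tempfile()
  write_measures(mt, f)
  mt2 <- read_measures(f)
  expect_equal(as.data.frame(mt2), as.data.frame(mt))
  expect_false(anyNA(mt2$value))

  # duplicate (subject, occasion, run, measure) keys error on construction
  # and on read
  expect_error(measure_table(c("a", "a"), "CHR", "baseline", "all",
                             "m", c(1, 2)), "duplicate")
  lines <- readLines(f)
  writeLines(c(lines, lines[2]), f)
  expect_error(read_measures(f), "duplicate")
})

test_that("event onsets must increase within a paradigm", {
  expect_error(event_table(c(0.5, 0.1), "S  1", "auditory", "standard",
                           1L, "aod"), "increasing")
})
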