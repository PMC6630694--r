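test_that("Shannon envelope basics: zeros, localization, scale invariance", {
  zero <- pcg_record(numeric(6000), 2000)
  expect_true(all(shannon_energy_envelope(zero)$envelope == 0))

  t <- (0:5999) / 2000
  burst <- exp(-(t - 1)^2 / (2 * 0.01^2)) * sin(2 * pi * 60 * (t - 1))
  rec <- pcg_record(burst + 1e-6 * sin(2 * pi * 40 * t), 2000)
  env <- shannon_energy_envelope(rec)
  tmax <- env$centers[which.max(env$envelope)] / 2000
  expect_lt(abs(tmax - 1), 0.02 + 0.005)

  scaled <- rec
  scaled$samples <- 0.01 * rec$samples
  expect_equal(shannon_energy_envelope(scaled)$envelope, env$envelope,
               tolerance = 1e-12)

  expect_error(shannon_energy_envelope(rec, frame_s = 0.005), "10 ms")
  expect_error(shannon_energy_envelope(pcg_record(1:5 / 5, 2000)), "shorter")
})

test_that("detected S1 peaks match generator ground truth", {
  cfg <- synth_config(seed = 7, heart_rate_bpm = 60, duration_s = 10)
  rec <- generate_pcg(cfg)
  pk <- detect_s1_peaks(preprocess_record(rec)) / 2000
  s1 <- rec$annotations$time_s[rec$annotations$event == "S1"]
  expect_length(pk, length(s1))
  expect_true(all(vapply(s1, function(x) min(abs(pk - x)), numeric(1)) <= 0.02))
})

test_that("flat input yields no peaks; single-burst input warns", {
  zero <- pcg_record(numeric(6000), 2000)
  expect_identical(detect_s1_peaks(zero), integer(0))
})

test_that("peak spacing respects heart-rate bounds at extreme rates", {
  for (hr in c(45, 150)) {
    cfg <- synth_config(seed = 5, heart_rate_bpm = hr, duration_s = 8)
    pk <- detect_s1_peaks(preprocess_record(generate_pcg(cfg)),
                          hr_bounds_bpm = c(40, 180))
    gaps <- diff(pk) / 2000
    expect_true(all(gaps >= 60 / 180 - 1e-9))
    expect_true(all(gaps <= 60 / 40 + 1e-9))
  }
})

test_that("segmentation recovers at least 95% of S1s across seeds and rates", {
  ok <- 0L; tot <- 0L; dup <- FALSE
  for (seed in 1:20) {
    for (hr in c(50, 60, 90, 120)) {
      cfg <- synth_config(heart_rate_bpm = hr, noise_snr_db = 10,
                          seed = seed, duration_s = 8)
      rec <- generate_pcg(cfg)
      pk <- detect_s1_peaks(preprocess_record(rec)) / 2000
      s1 <- rec$annotations$time_s[rec$annotations$event == "S1"]
      tot <- tot + length(s1)
      matched <- integer(0)
      for (x in s1) {
        if (length(pk) == 0) next
        j <- which.min(abs(pk - x))
        if (abs(pk[j] - x) <= 0.02) {
          if (j %in% matched) dup <- TRUE
          matched <- c(matched, j)
          ok <- ok + 1L
        }
      }
    }
  }
  expect_gte(ok / tot, 0.95)
  expect_false(dup)
})

test_that("cycles follow the fencepost rule and duration filter", {
  rec <- pcg_record(stats::rnorm(20000), 2000)
  pk <- as.integer(seq(1000, 17000, by = 4000))   # 5 peaks, 2 s apart
  cy <- segment_cycles(rec, pk)
  expect_length(cy, 4)
  expect_equal(cy[[1]]$start_index, 1000L - 100L)
  expect_equal(cy[[1]]$end_index, 5000L - 100L)

  close_pk <- as.integer(seq(1000, 1800, by = 200))
  expect_warning(none <- segment_cycles(rec, close_pk), "dropped")
  expect_length(none, 0)

  expect_error(segment_cycles(rec, 5L), "at least 2")
})

test_that("each synthetic cycle contains exactly one S2 after its S1", {
  cfg <- synth_config(seed = 9, duration_s = 8)
  rec <- generate_pcg(cfg)
  pre <- preprocess_record(rec)
  cy <- segment_record(pre)
  s2 <- rec$annotations$time_s[rec$annotations$event == "S2"]
  for (c1 in cy) {
    inside <- s2[s2 * 2000 >= c1$start_index & s2 * 2000 < c1$end_index]
    expect_length(inside, 1)
    expect_gt(inside * 2000, c1$s1_index)
  }
})

test_that("cycles partition the inter-peak span when none are dropped", {
  rec <- pcg_record(stats::rnorm(20000), 2000)
  pk <- as.integer(seq(1000, 17000, by = 1600))
  cy <- segment_cycles(rec, pk)
  for (i in seq_len(length(cy) - 1)) {
    expect_equal(cy[[i]]$end_index, cy[[i + 1]]$start_index)
  }
})

test_that("cycle averaging is idempotent, cancels opposites, reduces noise", {
  cyc <- make_noise_cycle(3, n = 600)
  avg <- average_cycles(list(cyc, cyc, cyc))
  expect_equal(avg, cyc$samples, tolerance = 1e-12)

  neg <- cyc
  neg$samples <- -cyc$samples
  expect_equal(max(abs(average_cycles(list(cyc, neg)))), 0, tolerance = 1e-12)

  base <- sin(2 * pi * 5 * (0:599) / 600)
  cys <- lapply(1:20, function(s) {
    set.seed(s)
    structure(list(samples = base + stats::rnorm(600, sd = 0.5),
                   start_index = 0L, end_index = 600L, s1_index = 0L,
                   sample_rate_hz = 2000L), class = "heart_cycle")
  })
  resid_avg <- stats::var(average_cycles(cys) - base)
  resid_one <- stats::var(cys[[1]]$samples - base)
  expect_lt(resid_avg, resid_one)

  expect_error(average_cycles(list()), "no cycles")
})
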