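test_that("generation is seed-deterministic and seeds differentiate", {
  cfg <- synth_config(seed = 7)
  r1 <- generate_pcg(cfg, "normal")
  r2 <- generate_pcg(cfg, "normal")
  expect_identical(r1$samples, r2$samples)
  cfg2 <- synth_config(seed = 8)
  expect_false(identical(generate_pcg(cfg2, "normal")$samples, r1$samples))
})

test_that("the isolated S2 component peaks in the 80-90 Hz band", {
  # smoothed-periodogram argmax: the raw burst-train periodogram is a comb
  # sampling the Gaussian burst spectrum, so a 5 Hz moving average recovers
  # the spectral envelope peak
  smooth_peak <- function(x, fs, half_hz = 5) {
    pg <- cycle_periodogram(x, fs)
    k <- max(1, round(half_hz / (pg$freq_hz[2] - pg$freq_hz[1])))
    sm <- stats::filter(pg$power, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
    sm[is.na(sm)] <- 0
    pg$freq_hz[which.max(sm)]
  }
  for (f2 in c(82, 85, 88)) {
    cfg <- synth_config(seed = 3, s2_freq_hz = f2)
    rec <- generate_pcg(cfg, "normal", keep_components = TRUE)
    peak <- smooth_peak(attr(rec, "components")$s2, 2000)
    expect_gte(peak, 80)
    expect_lte(peak, 90)
    expect_lt(abs(peak - f2), 2)
  }
})

test_that("abnormal records carry more 300-600 Hz band power than paired normals", {
  for (seed in c(1, 5, 11)) {
    cfg <- synth_config(seed = seed, duration_s = 6)
    nb <- band_power(generate_pcg(cfg, "normal")$samples, 2000, 300, 600)
    ab <- band_power(generate_pcg(cfg, "abnormal")$samples, 2000, 300, 600)
    expect_gt(ab, nb)
  }
})

test_that("normal records keep under 5% of band power above 300 Hz", {
  for (seed in 1:3) {
    x <- generate_pcg(synth_config(seed = seed, duration_s = 6))$samples
    high <- band_power(x, 2000, 300, 1000)
    total <- band_power(x, 2000, 0.1, 1000)
    expect_lt(high / total, 0.05)
  }
})

test_that("annotated S1 intervals match the heart rate within the jitter bound", {
  for (hr in c(50, 90)) {
    cfg <- synth_config(heart_rate_bpm = hr, seed = 4, timing_jitter_s = 0.01)
    ann <- generate_pcg(cfg)$annotations
    gaps <- diff(ann$time_s[ann$event == "S1"])
    expect_true(all(abs(gaps - 60 / hr) <= 0.011))
  }
})

test_that("optional S3/S4 sounds appear at their configured timings", {
  cfg <- synth_config(seed = 6, include_s3 = TRUE, include_s4 = TRUE,
                      s3_delay_after_s2_s = 0.12, s4_lead_before_s1_s = 0.08)
  ann <- generate_pcg(cfg)$annotations
  s2 <- ann$time_s[ann$event == "S2"]
  s3 <- ann$time_s[ann$event == "S3"]
  expect_equal(s3, s2[seq_along(s3)] + 0.12, tolerance = 1e-9)
  expect_true(all(c("S3", "S4") %in% ann$event))
})

test_that("too-short duration and invalid bands are rejected", {
  expect_error(synth_config(heart_rate_bpm = 60, duration_s = 1.5),
               "two cardiac cycles")
  expect_error(synth_config(s1_freq_hz = 70))
})

test_that("sensor chain: zero in, zero out; tone amplitude follows the gain", {
  chain <- sensor_chain_config()
  zero <- pcg_record(c(numeric(1999), 1e-12), 2000)
  out <- apply_sensor_chain(zero, chain)
  expect_lt(max(abs(out$samples)), 2 / 2^10 + 1e-12)

  t <- (0:3999) / 2000
  tone <- pcg_record(0.01 * sin(2 * pi * 100 * t), 2000)
  out <- apply_sensor_chain(tone, chain)
  mid <- out$samples[1000:3000]
  gain_band <- filter_response(signal::butter(2, c(20, 600) / 1000, "pass"),
                               100, 2000)
  expect_equal(max(abs(mid)), 0.01 * chain$preamp_gain * gain_band,
               tolerance = 0.05)
})

test_that("sensor chain saturates and warns beyond ADC full scale", {
  t <- (0:1999) / 2000
  loud <- pcg_record(0.5 * sin(2 * pi * 100 * t), 2000)
  expect_warning(out <- apply_sensor_chain(loud), "full scale")
  expect_lte(max(abs(out$samples)), 1)
})

test_that("the 10-bit 3.0 V ADC model has a 2.93 mV step", {
  expect_equal(adc_step_volts(sensor_chain_config()), 3 / 1024)
  expect_equal(round(adc_step_volts() * 1000, 2), 2.93)
})

test_that("battery life follows capacity / current x 0.70", {
  expect_equal(round(battery_life_hours(300, 1.48)), 142)
  expect_equal(battery_life_hours(300, 7.18), 300 / 7.18 * 0.7, tolerance = 1e-12)
  expect_equal(battery_life_hours(300, 7.18), 29.2479, tolerance = 1e-4)
  for (C in c(1, 120, 3000)) expect_equal(battery_life_hours(C, C), 0.70)
  expect_error(battery_life_hours(-1, 2), "positive")
  expect_error(battery_life_hours(300, 0), "positive")
})

test_that("generated datasets are reproducible with correct class counts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synth_config(duration_s = 4)
  m1 <- generate_dataset(8, 2, d1, base_config = cfg, seed = 1)
  expect_equal(m1$class_counts, c(normal = 8L, abnormal = 2L))
  m2 <- generate_dataset(8, 2, d2, base_config = cfg, seed = 1)
  for (i in seq_len(nrow(m1$entries))) {
    expect_identical(readBin(m1$entries$path[i], "raw", 1e6),
                     readBin(m2$entries$path[i], "raw", 1e6))
  }
  d3 <- withr::local_tempdir()
  m3 <- generate_dataset(1, 1, d3, base_config = cfg, seed = 2)
  expect_equal(nrow(m3$entries), 2)
  expect_false(anyDuplicated(m3$entries$record_id) > 0)
})
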