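test_that("detection sequence is zero on zero input and band-selective", {
  cfg <- arspl_config()
  det0 <- build_detection_sequence(numeric(4096), 1000, cfg)
  expect_equal(det0$r, numeric(4096))
  # QRS-band selectivity: a 1 Hz sinusoid leaves almost no energy in the
  # detection sequence compared with a transient burst of equal amplitude
  fs <- 1000
  t <- (0:9999) / fs
  sine <- 500 * sin(2 * pi * 1 * t)
  burst <- numeric(10000)
  w <- t >= 5 & t < 5.2
  burst[w] <- 500 * sin(2 * pi * 10 * (t[w] - 5))
  e_sine <- sum(build_detection_sequence(sine, fs, cfg)$r)
  e_burst <- sum(build_detection_sequence(burst, fs, cfg)$r)
  expect_lt(e_sine, 0.05 * e_burst)
})

test_that("true R peaks produce local detection-sequence maxima nearby", {
  g <- quick_gen()
  y <- g$clean$leads$II
  det <- build_detection_sequence(y, 1000)
  for (px in g$peaks$peak_x) {
    win <- (px - 19):(px + 21)              # +/- 20 ms, 1-based slice
    expect_gt(max(det$r[win]), max(det$r) * 0.1)
    local_max <- win[which.max(det$r[win])]
    expect_lte(abs(local_max - 1 - px), 20)
  }
})

test_that("initial threshold is the configured fraction of the early maximum", {
  cfg <- arspl_config()
  r <- c(rep(0, 500), 200, rep(0, 2499))    # max 200 within the first 2 s
  expect_equal(initial_threshold(r, 1000, cfg), 60)
  expect_equal(initial_threshold(numeric(3000), 1000, cfg), 0)
  expect_equal(initial_threshold(10 * r, 1000, cfg), 600)  # homogeneity
  expect_error(initial_threshold(r[1:100], 1000, cfg), "window")
})

test_that("heart-rate gate rejects the weaker of two close candidates", {
  fs <- 1000
  t <- (0:5999) / fs
  bump <- function(c_s, h) h * exp(-(t - c_s)^2 / (2 * 0.03^2))
  # fourth bump 150 ms after the third: 150 ms < 60/220 min = 272.7 ms
  r <- bump(1, 1) + bump(2, 1) + bump(3, 1) + bump(3.15, 0.6)
  det <- structure(list(r = r, d = diff(r), fs = fs, levels = 3:5),
                   class = "detection_sequence")
  pk <- detect_peaks(det, r, fs)
  expect_equal(pk$peak_x, c(1000, 2000, 3000))
  # the stronger late candidate displaces the earlier weak one instead
  r2 <- bump(1, 1) + bump(2, 1) + bump(3, 0.6) + bump(3.15, 1)
  det2 <- structure(list(r = r2, d = diff(r2), fs = fs, levels = 3:5),
                    class = "detection_sequence")
  pk2 <- detect_peaks(det2, r2, fs)
  expect_equal(pk2$peak_x, c(1000, 2000, 3150))
})

test_that("all-zero input yields the fewer-than-three-peaks error", {
  det <- build_detection_sequence(numeric(4096), 1000)
  expect_error(detect_peaks(det, numeric(4096), 1000), "fewer than 3")
})

test_that("clean synthetic beats are found within 2 samples after correction", {
  g <- quick_gen()
  pk <- detect_rpeaks(g$record)
  expect_identical(pk$M, g$peaks$M)
  expect_true(all(abs(pk$peak_x - g$peaks$peak_x) <= 2))
  # every consecutive pair respects the heart-rate gate
  expect_true(all(60 / pk$rr <= arspl_config()$max_hr_bpm))
})

test_that("detection is invariant to positive rescaling of the record", {
  g <- quick_gen()
  pk1 <- detect_rpeaks(g$record)
  scaled <- ecg_record(lapply(g$record$leads, function(y) 10 * y), g$record$fs)
  pk2 <- detect_rpeaks(scaled)
  expect_identical(pk1$peak_x, pk2$peak_x)
})

test_that("corrected peaks sit on the signal maximum of their window", {
  cfg <- arspl_config()
  g <- quick_gen(seed = 21, noise = list(white_sd_uV = 30))
  y <- denoise(g$record$leads$II, 1000, cfg)
  det <- build_detection_sequence(y, 1000, cfg)
  pk <- detect_peaks(det, y, 1000, cfg)
  half <- round(cfg$correction_window_s / 2 * 1000)
  for (px in pk$peak_x) {
    win <- max(0, px - half):min(length(y) - 1, px + half)
    expect_gte(y[px + 1], max(y[win + 1]) - 1e-12)
  }
})
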