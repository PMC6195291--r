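test_that("correlation coefficient basics", {
  a <- c(1, 2, 3, 4)
  expect_equal(correlation_coefficient(a, a), 1.0)
  expect_equal(correlation_coefficient(a, -a), -1.0)
  expect_equal(correlation_coefficient(a, c(2, 4, 6, 8)), 1.0)
  # affine invariance with positive slope, sign flip with negative
  set.seed(51)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(correlation_coefficient(2 * x + 3, y),
               correlation_coefficient(x, y))
  expect_equal(correlation_coefficient(-x, y), -correlation_coefficient(x, y))
  expect_error(correlation_coefficient(rep(1, 5), 1:5), "constant")
})

test_that("rmse hand values and symmetry", {
  expect_equal(rmse(c(0, 1, 2, 3), c(0, 1, 2, 7)), 2.0)
  expect_equal(rmse(1:5, 1:5), 0)
  set.seed(52)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_equal(rmse(a + 10, b + 10), rmse(a, b))
  expect_gt(rmse(a, b), 0)
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("st_level measures 60 ms after the J-point against the PR reference", {
  y <- numeric(1000)
  y[561] <- 150                       # 0-based index 560 = j_point 500 + 60 ms
  expect_equal(st_level(y, 1000, j_point = 500, pr_ref = 100), 0.15)
  expect_equal(st_level(numeric(1000), 1000, 500, 100), 0)
  expect_error(st_level(y, 1000, j_point = 990, pr_ref = 100), "outside")
})

test_that("st_report counts elevation and depression cycles", {
  fs <- 1000
  n <- 12000
  pk_at <- seq(500, 11500, by = 1000)   # 12 peaks -> 10 evaluable cycles
  b <- quick_boundaries(pk_at, n)
  ori <- ecg_record(list(V1 = numeric(n)), fs)
  ys <- numeric(n)
  st_idx <- b$B_SE[5] + 60              # cycle 5 ST measurement point, 0-based
  ys[st_idx + 1] <- 150                 # +0.15 mV in one cycle of ten
  syn <- ecg_record(list(V1 = ys), fs)
  rep1 <- st_report(syn, ori, b, fs, lead = "V1")
  expect_identical(rep1$n_cycles, 10L)
  expect_equal(rep1$ER, 10)
  expect_equal(rep1$DR, 0)
  expect_equal(rep1$CDR, 10)
  # identical records give all zeros
  rep0 <- st_report(ori, ori, b, fs, lead = "V1")
  expect_equal(rep0$CDR + rep0$ER + rep0$DR, 0)
  expect_true(all(rep0$stse_mv == 0))
  # CDR = ER + DR by construction, also with mixed signs
  ys2 <- numeric(n)
  ys2[b$B_SE[3] + 61] <- 200
  ys2[b$B_SE[7] + 61] <- -300
  rep2 <- st_report(ecg_record(list(V1 = ys2), fs), ori, b, fs)
  expect_equal(rep2$CDR, rep2$ER + rep2$DR)
  expect_equal(rep2$ER, 10)
  expect_equal(rep2$DR, 10)
})

test_that("detection metrics match hand-computed matching", {
  m <- evaluate_detection(c(102, 1100, 3000), c(100, 1100, 2100),
                          fs = 1000, tol_s = 0.05)
  expect_identical(m$TP, 2L)
  expect_identical(m$FN, 1L)
  expect_identical(m$FP, 1L)
  expect_equal(round(m$Se, 2), 66.67)
  expect_equal(round(m$P_plus, 2), 66.67)
  expect_equal(round(m$Acc, 2), 50.00)
  m2 <- evaluate_detection(c(10, 500, 900), c(10, 500, 900), 1000)
  expect_equal(c(m2$Se, m2$P_plus, m2$Acc), c(100, 100, 100))
  # permutation invariance of the detected list
  m3 <- evaluate_detection(c(900, 10, 500), c(10, 500, 900), 1000)
  expect_equal(c(m3$TP, m3$FN, m3$FP), c(m2$TP, m2$FN, m2$FP))
})

test_that("matching is one-to-one: a single detection cannot claim two beats", {
  m <- evaluate_detection(c(100), c(90, 110), fs = 1000, tol_s = 0.05)
  expect_identical(m$TP, 1L)
  expect_identical(m$FN, 1L)
  expect_identical(m$FP, 0L)
})

test_that("amplitude gaps pick up constructed junction steps", {
  n <- 4000
  b <- quick_boundaries(c(1000, 2000, 3000), n)
  # 40 uV step exactly at the QRS -> ST-T junction of cycle 2 (B_SE(2))
  y <- numeric(n)
  y[(b$B_SE[2] + 1):n] <- 40
  gaps <- amplitude_gaps(ecg_record(list(V1 = y), 1000), b)
  expect_equal(unname(gaps["G2", "V1"]), 40)
  expect_equal(unname(gaps["G1", "V1"]), 0)
  expect_equal(unname(gaps["G3", "V1"]), 0)
  # continuous record: all gaps at numerical-noise level
  g <- quick_gen()
  pk <- detect_rpeaks(g$record)
  bb <- derive_boundaries(pk, 1000, g$record$n_samples)
  g0 <- amplitude_gaps(g$record, bb)
  expect_lt(max(unclass(g0)["G2", ], na.rm = TRUE), 50)  # smooth signal steps
})

test_that("G1 averages the per-cycle R-P to QRS steps", {
  n <- 5000
  b <- quick_boundaries(c(1000, 2000, 3000, 4000), n)
  y <- numeric(n)
  # steps of 10 and 30 uV at the two R-P -> QRS junctions (B_QS(2), B_QS(3))
  y[(b$B_QS[2] + 1):(b$B_SE[2])] <- 10
  y[(b$B_SE[2] + 1):b$B_QS[3]] <- 10       # carry through to avoid G2/G3 noise
  y[(b$B_QS[3] + 1):n] <- 10 + 30
  gaps <- amplitude_gaps(ecg_record(list(V3 = y), 1000), b)
  expect_equal(unname(gaps["G1", "V3"]), 20)
})
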