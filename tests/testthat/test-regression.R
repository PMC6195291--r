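test_that("fit_lr reproduces exact linear relations and known coefficients", {
  set.seed(31)
  s <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("I", "II", "V2")))
  b_true <- matrix(c(10, 0.5, -0.2, 1.1), 4, 1)
  y <- cbind(1, s) %*% b_true
  expect_equal(unname(fit_lr(s, y)), b_true, tolerance = 1e-8)
  expect_error(fit_lr(s[1:3, ], y[1:3, , drop = FALSE]), "underdetermined")
  s_bad <- s; s_bad[, 3] <- 2 * s_bad[, 1] - s_bad[, 2]
  expect_error(fit_lr(s_bad, y), "singular")
})

test_that("fit_lr agrees with normal-equations and pseudo-inverse oracles", {
  set.seed(32)
  for (rep in 1:100) {
    s <- matrix(rnorm(150), 50, 3)
    b_true <- matrix(rnorm(8), 4, 2)
    y <- cbind(1, s) %*% b_true + matrix(rnorm(100, sd = 5), 50, 2)
    b <- unname(fit_lr(s, y))
    b_ne <- oracle_normal_equations(s, y)
    b_pi <- oracle_pinv_fit(s, y)
    expect_lt(max(abs(b - b_ne)) / max(abs(b)), 1e-10)
    expect_lt(max(abs(b - b_pi)) / max(abs(b)), 1e-10)
  }
})

test_that("fitted coefficients are least-squares optimal", {
  set.seed(33)
  s <- matrix(rnorm(240), 80, 3)
  y <- cbind(1, s) %*% matrix(rnorm(8), 4, 2) + matrix(rnorm(160), 80, 2)
  b <- fit_lr(s, y)
  X <- cbind(1, s)
  rss <- function(bb) sum((y - X %*% bb)^2)
  base <- rss(b)
  for (rep in 1:100) {
    expect_lte(base, rss(b + matrix(rnorm(8, sd = 0.01), 4, 2)))
  }
})

test_that("apply_lr performs the affine map and checks shapes", {
  s <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_lr(s, matrix(0, 4, 2)), matrix(0, 10, 2))
  b_id <- matrix(c(0, 1, 0, 0), 4, 1)
  expect_equal(as.numeric(apply_lr(s, b_id)), s[, 1])
  expect_error(apply_lr(s[, 1:2], b_id), "shape mismatch")
  # round trip through fit_lr on consistent targets
  y <- cbind(1, s) %*% matrix(c(3, 0.2, -1, 0.8), 4, 1)
  expect_equal(apply_lr(s, fit_lr(s, y)), y, tolerance = 1e-8)
})

test_that("limb-lead arithmetic and Einthoven closure", {
  d <- derive_limb_leads(rep(0.5, 4), rep(1.0, 4))
  expect_equal(d$III, rep(0.5, 4))
  expect_equal(d$aVR, rep(-0.75, 4))
  expect_equal(d$aVL, rep(0.0, 4))
  expect_equal(d$aVF, rep(0.75, 4))
  d2 <- derive_limb_leads(rep(1, 3), rep(1, 3))
  expect_equal(d2$aVR, rep(-1, 3))
  expect_equal(d2$aVL, rep(0.5, 3))
  expect_equal(d2$III, rep(0, 3))
  set.seed(34)
  I <- rnorm(100); II <- rnorm(100)
  d3 <- derive_limb_leads(I, II)
  expect_lt(max(abs(I - II + d3$III)), 1e-12)
  expect_lt(max(abs(d3$aVR + d3$aVL + d3$aVF)), 1e-12)
  expect_error(derive_limb_leads(1:3, 1:4), "length mismatch")
})

test_that("train_arspl recovers distinct regional matrices exactly", {
  g <- quick_gen(duration_s = 20, seed = 5)
  models <- arspl_fit(g$clean, peaks = g$peaks, boundaries = g$boundaries,
                      preprocess = FALSE)
  expect_lt(max(abs(models$b_STT - g$region_matrices$STT)), 1e-6)
  expect_lt(max(abs(models$b_RP - g$region_matrices$RP)), 1e-6)
  expect_lt(max(abs(models$b_QRS - g$region_matrices$QRS)), 1e-6)
  expect_lt(max(abs(models$b_HT - g$region_matrices$HT)), 1e-6)
})

test_that("a single global linear law makes all regional matrices equal", {
  rm_eq <- default_region_matrices()
  rm_eq$RP <- rm_eq$QRS <- rm_eq$HT <- rm_eq$STT
  g <- quick_gen(duration_s = 12, seed = 6, region_matrices = rm_eq)
  models <- arspl_fit(g$clean, peaks = g$peaks, boundaries = g$boundaries,
                      preprocess = FALSE)
  expect_equal(models$b_STT, models$b_RP, tolerance = 1e-8)
  expect_equal(models$b_STT, models$b_QRS, tolerance = 1e-8)
  expect_equal(models$b_STT, models$b_HT, tolerance = 1e-8)
})

test_that("the head-tail matrix equals the complete-sequence fit by definition", {
  g <- quick_gen(duration_s = 12, seed = 7)
  work <- g$clean
  models <- arspl_fit(work, peaks = g$peaks, boundaries = g$boundaries,
                      preprocess = FALSE)
  b_full <- fit_lr(do.call(cbind, work$leads[c("I", "II", "V2")]),
                   do.call(cbind, work$leads[c("V1", "V3", "V4", "V5", "V6")]))
  expect_equal(models$b_HT, b_full, tolerance = 1e-10)
})

test_that("synthesis reproduces piecewise-linear targets exactly and beats the baseline", {
  g <- quick_gen(duration_s = 20, seed = 5)
  rec3 <- ecg_record(g$clean$leads[c("I", "II", "V2")], 1000)
  models <- arspl_fit(g$clean, peaks = g$peaks, boundaries = g$boundaries,
                      preprocess = FALSE)
  syn <- synthesize_arspl(rec3, models, peaks = g$peaks,
                          boundaries = g$boundaries, preprocess = FALSE)
  ev <- evaluate_leads(syn, g$clean, c("V1", "V3", "V4", "V5", "V6"))
  expect_true(all(ev$rmse_uv <= 1e-6))
  # zero matrices give zero output
  z <- models
  z$b_STT[] <- z$b_RP[] <- z$b_QRS[] <- z$b_HT[] <- 0
  syn0 <- synthesize_arspl(rec3, z, peaks = g$peaks,
                           boundaries = g$boundaries, preprocess = FALSE)
  expect_equal(max(abs(unlist(syn0$leads[c("V1", "V3", "V4", "V5", "V6")]))), 0)
  # baseline comparison: with region-dependent mixing the piecewise model
  # attains lower error on every target lead
  lrm <- train_lr(g$clean, preprocess = FALSE)
  synlr <- synthesize_lr(rec3, lrm, preprocess = FALSE)
  evlr <- evaluate_leads(synlr, g$clean, c("V1", "V3", "V4", "V5", "V6"))
  expect_true(all(ev$rmse_uv <= evlr$rmse_uv))
  expect_gt(min(evlr$rmse_uv), 1e-3)  # the baseline genuinely misfits
})

test_that("parameter recovery holds across seeded subjects", {
  for (seed in c(101, 102, 103)) {
    g <- quick_gen(duration_s = 12, hr_bpm = 70, seed = seed)
    models <- arspl_fit(g$clean, peaks = g$peaks, boundaries = g$boundaries,
                        preprocess = FALSE)
    err <- max(abs(models$b_STT - g$region_matrices$STT),
               abs(models$b_RP - g$region_matrices$RP),
               abs(models$b_QRS - g$region_matrices$QRS))
    expect_lt(err, 1e-5)
  }
})
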