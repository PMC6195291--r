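test_that("R-T windows scale with the RR interval", {
  cfg <- arspl_config()
  pk <- peak_list(c(0, 1000, 2000), c(1, 1, 1), 1000)
  expect_equal(adjust_time_windows(pk, cfg), c(0.37, 0.37))
  pk2 <- peak_list(c(0, 800, 1600), c(1, 1, 1), 1000)
  expect_equal(adjust_time_windows(pk2, cfg), c(0.296, 0.296))
  expect_error(adjust_time_windows(peak_list(c(0, 500), c(1, 1), 1000)),
               "M >= 3")
})

test_that("boundaries follow the experienced time windows", {
  pk <- peak_list(c(5000, 6000, 7000), c(1, 1, 1), 1000)
  b <- derive_boundaries(pk, 1000, 9000)
  expect_equal(b$B_SE[1], 5040L)   # peak + T_RS * fs
  expect_equal(b$B_QS[2], 5970L)   # peak - T_QR * fs
  expect_equal(b$B_TE[1], 5370L)   # peak + a_RT * rr * fs
  b2 <- quick_boundaries(c(1000, 2000, 3000), 4000)
  expect_equal(b2$B_TE[1], 1370L)
  # per-cycle ordering invariant B_QS(n) < peak(n) < B_SE(n) < B_TE(n)
  expect_true(all(b$B_QS[2] < 6000, 6000 < b$B_SE[2], b$B_SE < b$B_TE))
})

test_that("short cycles are resolved by clamping, never by overlap", {
  # 100 ms cycles force B_SE past B_TE (T window a_RT * rr = 37 ms < T_RS
  # window 40 ms), so ST-T fragments collapse to empty instead of overlapping
  pk <- peak_list(seq(1000, 1500, by = 100), rep(1, 6), 1000)
  b <- derive_boundaries(pk, 1000, 3000)
  expect_true(all(b$B_TE[1:(b$M - 1)] <= b$B_QS[2:b$M] - 1L, na.rm = TRUE))
  expect_true(all(b$B_SE <= b$B_TE))
  lens <- record_segment_lengths(b)
  expect_true(all(lens$SegL_RP[-1] >= 1))
  expect_true(all(lens$SegL_STT == 0))
})

test_that("segmentation yields the fixed pattern and conserves samples", {
  for (seed in c(3, 12)) {
    g <- quick_gen(duration_s = 8, hr_bpm = 72, seed = seed)
    pk <- detect_rpeaks(g$record)
    M <- pk$M
    b <- derive_boundaries(pk, 1000, g$record$n_samples)
    seg <- segment_record(g$record, b, pk)
    l <- seg$lengths
    # M-1 ST-T, M-1 R-P, M-2 QRS fragments, one H-T region
    expect_length(l$SegL_STT, M - 1L)
    expect_identical(sum(!is.na(l$SegL_RP)), M - 1L)
    expect_identical(sum(!is.na(l$SegL_QRS)), M - 2L)
    total <- sum(l$SegL_STT) + sum(l$SegL_RP, na.rm = TRUE) +
      sum(l$SegL_QRS, na.rm = TRUE) + l$head_len + l$tail_len
    expect_identical(as.integer(total), g$record$n_samples)
    # per-lead subsequence lengths match the bookkeeping
    r1 <- seg$regions[[1]]
    expect_length(r1$stt_seq, sum(l$SegL_STT))
    expect_length(r1$rp_seq, sum(l$SegL_RP, na.rm = TRUE))
    expect_length(r1$qrs_seq, sum(l$SegL_QRS, na.rm = TRUE))
    expect_length(r1$ht_seq, l$head_len + l$tail_len)
  }
})

test_that("worked QRS length example: peaks at 1000/2000/3000", {
  b <- quick_boundaries(c(1000, 2000, 3000), 4000)
  lens <- record_segment_lengths(b)
  expect_identical(lens$SegL_QRS[2], 70L)        # 2040 - 1970
  expect_identical(lens$SegL_STT[1], 330L)       # 1370 - 1040
  expect_identical(lens$SegL_RP[2], 600L)        # 1970 - 1370
})

test_that("segmentation is deterministic and order-preserving", {
  g <- quick_gen()
  pk <- detect_rpeaks(g$record)
  b <- derive_boundaries(pk, 1000, g$record$n_samples)
  s1 <- segment_record(g$record, b, pk)
  s2 <- segment_record(g$record, b, pk)
  expect_identical(s1, s2)
  # fragments appear in cycle order: first ST-T fragment equals the slice
  # taken directly at the first cycle's boundaries
  y <- g$record$leads$II
  expect_identical(s1$regions$II$stt_seq[seq_len(b$B_TE[1] - b$B_SE[1])],
                   y[(b$B_SE[1] + 1):b$B_TE[1]])
})

test_that("inconsistent boundaries are rejected", {
  g <- quick_gen()
  pk <- detect_rpeaks(g$record)
  b <- derive_boundaries(pk, 1000, g$record$n_samples)
  b_bad <- b
  b_bad$B_TE[1] <- b_bad$B_QS[2] + 50L   # ST-T overruns the next R-P
  expect_error(segment_record(g$record, b_bad, pk), "inconsistent")
})
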