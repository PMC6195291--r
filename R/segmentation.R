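# Region boundary determination and region segmentation: experienced time
# windows anchored on R peaks split each cycle into ST-T / R-P / QRS regions,
# with the incomplete first/last cycles spliced into a head-tail region.

#' Adapt the R-T experienced time window to the RR intervals
#'
#' `T_RT(n) = a_RT * rr(n)` for `n = 1..M-1`: unlike the fixed Q-R and R-S
#' windows, the distance from the R peak to the end of the T wave scales with
#' cycle length.
#'
#' @param peaks A [peak_list()] with `M >= 3`.
#' @param cfg An [arspl_config()].
#' @return Numeric vector of per-cycle windows in seconds, length `M - 1`.
#' @export
adjust_time_windows <- function(peaks, cfg = arspl_config()) {
  stopifnot(inherits(peaks, "peak_list"))
  if (peaks$M < 3L) stop("adjust_time_windows: requires M >= 3 peaks")
  cfg$a_RT * peaks$rr
}

#' Derive region boundaries from R peaks
#'
#' Computes, in samples (0-based):
#' `B_SE(n) = peak_x(n) + round(T_RS * fs)` and
#' `B_TE(n) = peak_x(n) + round(T_RT(n) * fs)` for cycles `1..M-1`, and
#' `B_QS(n) = peak_x(n) - round(T_QR * fs)` for cycles `2..M`.
#'
#' Overlapping windows in short (tachycardic) cycles are resolved by
#' clamping: if `B_TE(n) >= B_QS(n+1)` then `B_TE(n) = B_QS(n+1) - 1` so the
#' following R-P fragment keeps length >= 1, and `B_SE(n)` is pulled down to
#' `B_TE(n)` if needed (the ST-T fragment may then be empty). Boundaries are
#' clamped into `[0, n_samples)` with a warning.
#'
#' @param peaks A [peak_list()] with `M >= 3`.
#' @param fs Sampling rate in Hz.
#' @param n_samples Length of the record the boundaries index into.
#' @param cfg An [arspl_config()].
#' @return A [region_boundaries()].
#' @export
#' @examples
#' pk <- peak_list(c(1000, 2000, 3000), c(1, 1, 1), fs = 1000)
#' b <- derive_boundaries(pk, fs = 1000, n_samples = 4000)
#' b$B_SE[1]  # 1000 + 0.04 * 1000 = 1040
#' b$B_TE[1]  # 1000 + 0.37 * 1 * 1000 = 1370
derive_boundaries <- function(peaks, fs, n_samples, cfg = arspl_config()) {
  stopifnot(inherits(peaks, "peak_list"))
  if (peaks$M < 3L) stop("derive_boundaries: requires M >= 3 peaks")
  M <- peaks$M
  px <- peaks$peak_x
  T_RT <- adjust_time_windows(peaks, cfg)

  B_SE <- px[seq_len(M - 1L)] + round(cfg$T_RS * fs)
  B_TE <- px[seq_len(M - 1L)] + round(T_RT * fs)
  B_QS <- c(NA_real_, px[2:M] - round(cfg$T_QR * fs))

  if (any(B_SE >= n_samples) || any(B_TE > n_samples) ||
      any(B_QS < 0, na.rm = TRUE))
    stop("derive_boundaries: boundary outside the record; record too short ",
         "around its first/last peak")

  # resolve window overlap in short cycles
  for (n in seq_len(M - 1L)) {
    if (B_TE[n] >= B_QS[n + 1L]) B_TE[n] <- B_QS[n + 1L] - 1L
    if (B_SE[n] > B_TE[n]) B_SE[n] <- B_TE[n]
  }

  clamp <- function(b) pmin(pmax(b, 0), n_samples)
  if (any(B_SE < 0) || any(B_TE < 0)) {
    warning("derive_boundaries: boundaries clamped to the record limits")
    B_SE <- clamp(B_SE); B_TE <- clamp(B_TE)
  }

  region_boundaries(B_SE, B_TE, B_QS, M = M, n_samples = n_samples)
}

#' Segment lengths per region and cycle
#'
#' Bookkeeping needed to invert segmentation: `SegL_STT(n) = B_TE(n) -
#' B_SE(n)`, `SegL_RP(n) = B_QS(n) - B_TE(n-1)`, `SegL_QRS(n) = B_SE(n) -
#' B_QS(n)`, plus `head_len = B_SE(1)` and `tail_len = N - B_QS(M)`. The sum
#' of all lengths equals the record length.
#'
#' @param boundaries A [region_boundaries()].
#' @return Object of class `segment_lengths`: list with `SegL_STT` (cycles
#'   1..M-1), `SegL_RP` and `SegL_QRS` (length-M vectors, `NA` where the
#'   cycle has no such region), `head_len`, `tail_len`, `M`, `n_samples`.
#' @export
record_segment_lengths <- function(boundaries) {
  stopifnot(inherits(boundaries, "region_boundaries"))
  b <- boundaries
  M <- b$M
  SegL_STT <- b$B_TE - b$B_SE
  SegL_RP <- rep(NA_integer_, M)
  SegL_RP[2:M] <- b$B_QS[2:M] - b$B_TE[1:(M - 1L)]
  SegL_QRS <- rep(NA_integer_, M)
  if (M >= 3L) SegL_QRS[2:(M - 1L)] <- b$B_SE[2:(M - 1L)] - b$B_QS[2:(M - 1L)]
  head_len <- b$B_SE[1L]
  tail_len <- b$n_samples - b$B_QS[M]
  lens <- c(SegL_STT, SegL_RP[!is.na(SegL_RP)], SegL_QRS[!is.na(SegL_QRS)],
            head_len, tail_len)
  if (any(lens < 0))
    stop("record_segment_lengths: negative segment length; boundaries were ",
         "not clamped consistently")
  structure(list(SegL_STT = as.integer(SegL_STT),
                 SegL_RP = as.integer(SegL_RP),
                 SegL_QRS = as.integer(SegL_QRS),
                 head_len = as.integer(head_len),
                 tail_len = as.integer(tail_len),
                 M = M, n_samples = b$n_samples),
            class = "segment_lengths")
}

#' Segment a record into the four region subsequences
#'
#' Partitions every lead into the fixed pattern (0-based, half-open): head
#' `[0, B_SE(1))`, ST-T(n) `[B_SE(n), B_TE(n))` for `n = 1..M-1`, R-P(n)
#' `[B_TE(n-1), B_QS(n))` for `n = 2..M`, QRS(n) `[B_QS(n), B_SE(n))` for
#' `n = 2..M-1`, and tail `[B_QS(M), N)`; head and tail are juxtaposed into
#' the H-T region. Same-type fragments are concatenated in cycle order.
#' Every sample belongs to exactly one region.
#'
#' @param record An [ecg_record()].
#' @param boundaries A [region_boundaries()] consistent with the record.
#' @param peaks The [peak_list()] the boundaries came from (consistency
#'   checks only).
#' @return Object of class `segmentation_result`: `regions` (per lead a list
#'   with `stt_seq`, `rp_seq`, `qrs_seq`, `ht_seq`), `lengths`
#'   ([record_segment_lengths()]), `boundaries`, `fs`.
#' @export
segment_record <- function(record, boundaries, peaks = NULL) {
  validate_record(record, required_leads = character(0))
  stopifnot(inherits(boundaries, "region_boundaries"))
  b <- boundaries
  M <- b$M
  N <- record$n_samples
  if (b$n_samples != N)
    stop("segment_record: boundaries refer to a record of length ", b$n_samples,
         ", got ", N)
  if (!is.null(peaks)) {
    stopifnot(inherits(peaks, "peak_list"))
    if (peaks$M != M) stop("segment_record: peak count and boundary cycle count differ")
    bad <- peaks$peak_x[seq_len(M - 1L)] >= b$B_TE |
      peaks$peak_x[seq_len(M - 1L)] > b$B_SE
    if (any(bad))
      stop("segment_record: inconsistent boundaries (R peak outside its cycle)")
  }
  ok <- all(b$B_SE <= b$B_TE) &&
    all(b$B_TE[1:(M - 1L)] <= b$B_QS[2:M]) &&
    all(diff(b$B_QS[2:M]) > 0) && b$B_SE[1L] >= 0 && b$B_QS[M] <= N
  if (!ok) stop("segment_record: inconsistent boundaries")

  # half-open [lo, hi) with 0-based lo/hi -> R indices lo+1 .. hi
  slice <- function(y, lo, hi) if (hi > lo) y[(lo + 1L):hi] else numeric(0)

  regions <- lapply(record$leads, function(y) {
    stt <- unlist(lapply(seq_len(M - 1L), function(n)
      slice(y, b$B_SE[n], b$B_TE[n])), use.names = FALSE)
    rp <- unlist(lapply(2:M, function(n)
      slice(y, b$B_TE[n - 1L], b$B_QS[n])), use.names = FALSE)
    qrs <- unlist(lapply(2:(M - 1L), function(n)
      slice(y, b$B_QS[n], b$B_SE[n])), use.names = FALSE)
    ht <- c(slice(y, 0L, b$B_SE[1L]), slice(y, b$B_QS[M], N))
    list(stt_seq = stt, rp_seq = rp, qrs_seq = qrs, ht_seq = ht)
  })
  lengths <- record_segment_lengths(b)

  total <- sum(vapply(regions[[1L]], length, integer(1)))
  if (total != N)
    stop("segment_record: partition does not conserve samples (internal error)")

  structure(list(regions = regions, lengths = lengths, boundaries = b,
                 fs = record$fs),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  l <- x$lengths
  cat(sprintf(paste0("Segmentation: %d cycles, %d leads; |ST-T| = %d, |R-P| = %d, ",
                     "|QRS| = %d, |H-T| = %d of %d samples\n"),
              l$M, length(x$regions), sum(l$SegL_STT),
              sum(l$SegL_RP, na.rm = TRUE), sum(l$SegL_QRS, na.rm = TRUE),
              l$head_len + l$tail_len, l$n_samples))
  invisible(x)
}
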