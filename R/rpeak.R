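# R-peak determination: detection sequence from band-passed wavelet details,
# adaptive amplitude thresholding with an RR-interval heart-rate gate, and
# final position correction against the original signal.

# Centered moving average that keeps length and shrinks the window at the
# edges (partial means), so the smoothed energy envelope stays non-negative.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Build the R-peak detection sequence
#'
#' Reconstructs the band-passed component of `y` from the configured wavelet
#' detail levels (covering the QRS energy band, roughly 15-125 Hz at 1000 Hz
#' with levels 3-5), squares it, and smooths it with a centered moving
#' average of width `cfg$smooth_window_s`. The result `r` is a non-negative
#' energy envelope whose local maxima align with QRS complexes; `d` is its
#' first difference.
#'
#' @param y Numeric single-lead signal in microvolts (typically denoised).
#' @param fs Sampling rate in Hz.
#' @param cfg An [arspl_config()].
#' @return Object of class `detection_sequence`: list with `r`, `d`
#'   (`length(r) - 1`), `fs` and the levels used.
#' @export
build_detection_sequence <- function(y, fs, cfg = arspl_config()) {
  if (length(y) == 0L) stop("build_detection_sequence: empty input")
  levels <- detection_levels_for_fs(cfg, fs)
  depth <- max(levels)
  if (length(y) < 2L^depth)
    stop("build_detection_sequence: input too short for detail level ", depth)
  band <- modwt_details(y, depth, levels)
  r <- band^2
  r <- moving_average(r, round(cfg$smooth_window_s * fs))
  structure(list(r = r, d = diff(r), fs = fs, levels = levels),
            class = "detection_sequence")
}

#' Initial detection threshold
#'
#' `cfg$init_threshold_frac` (default 30%) of the maximum of the detection
#' sequence over its first `cfg$init_threshold_window_s` (default 2 s).
#'
#' @param det A `detection_sequence` (or numeric vector `r`).
#' @param fs Sampling rate in Hz.
#' @param cfg An [arspl_config()].
#' @return Scalar threshold on the `r` scale.
#' @export
initial_threshold <- function(det, fs, cfg = arspl_config()) {
  r <- if (inherits(det, "detection_sequence")) det$r else as.numeric(det)
  nwin <- round(cfg$init_threshold_window_s * fs)
  if (length(r) < nwin)
    stop("initial_threshold: input shorter than the ",
         cfg$init_threshold_window_s, " s threshold window")
  cfg$init_threshold_frac * max(r[seq_len(nwin)])
}

#' Detect R peaks from a detection sequence
#'
#' Scans the detection sequence for inflection points (`sign(d(i)) >
#' sign(d(i+1))`) exceeding the amplitude threshold; registers the local
#' maximum of `r` within `cfg$candidate_window_s` of each firing; validates
#' each registration against the heart-rate gate (instantaneous rate from the
#' two most recent peaks must not exceed `cfg$max_hr_bpm` -- on conflict the
#' candidate with the larger `r` value survives); adapts the threshold to
#' `cfg$adapt_threshold_frac` times the mean of the most recent
#' `cfg$adapt_peak_count` registered amplitudes once that many peaks exist;
#' and finally shifts every peak to the maximum of the original signal `y`
#' within `cfg$correction_window_s`, re-reading its amplitude from `y`.
#'
#' @param det A `detection_sequence` built from `y` at the same `fs`.
#' @param y The single-lead signal the detection sequence was built from.
#' @param fs Sampling rate in Hz.
#' @param cfg An [arspl_config()].
#' @return A [peak_list()] (0-based indices). Errors if fewer than three
#'   peaks are found, since segmentation assumes M >= 3.
#' @export
detect_peaks <- function(det, y, fs, cfg = arspl_config()) {
  stopifnot(inherits(det, "detection_sequence"))
  r <- det$r
  d <- det$d
  n <- length(r)
  if (length(y) != n) stop("detect_peaks: `y` and detection sequence length mismatch")
  thr <- initial_threshold(det, fs, cfg)

  s <- sign(d)
  cand <- which(s[-length(s)] > s[-1])  # i with sign(d(i)) > sign(d(i+1))
  half_cand <- max(1L, round(cfg$candidate_window_s / 2 * fs))
  min_gap <- 60 / cfg$max_hr_bpm  # seconds; RR below this violates the gate

  peak_x <- integer(0)
  peak_y <- numeric(0)

  register <- function(px, py) {
    m <- length(peak_x)
    if (m > 0L) {
      if (px == peak_x[m]) return(NULL)          # same maximum re-found
      gap <- (px - peak_x[m]) / fs
      if (gap < min_gap) {
        # heart-rate gate violated: keep the stronger of the conflicting pair
        if (py > peak_y[m]) {
          peak_x[m] <<- px
          peak_y[m] <<- py
        }
        return(NULL)
      }
    }
    peak_x[m + 1L] <<- px
    peak_y[m + 1L] <<- py
    NULL
  }

  for (i in cand) {
    if (r[i] <= thr) next
    lo <- max(1L, i - half_cand)
    hi <- min(n, i + half_cand)
    px <- lo - 1L + which.max(r[lo:hi])
    py <- r[px]
    register(px, py)
    m <- length(peak_x)
    if (m >= cfg$adapt_peak_count) {
      recent <- peak_y[(m - cfg$adapt_peak_count + 1L):m]
      thr <- cfg$adapt_threshold_frac * mean(recent)
    }
  }

  if (length(peak_x) < 3L)
    stop("detect_peaks: fewer than 3 R peaks found (M = ", length(peak_x),
         "); segmentation requires M >= 3")

  # Step 6: correct positions against the original signal
  half_corr <- max(1L, round(cfg$correction_window_s / 2 * fs))
  for (k in seq_along(peak_x)) {
    lo <- max(1L, peak_x[k] - half_corr)
    hi <- min(n, peak_x[k] + half_corr)
    px <- lo - 1L + which.max(y[lo:hi])
    peak_x[k] <- px
    peak_y[k] <- y[px]
  }
  # corrections may merge neighbours onto one maximum; keep the stronger
  keep <- !duplicated(peak_x)
  peak_x <- peak_x[keep]; peak_y <- peak_y[keep]
  if (is.unsorted(peak_x)) {
    o <- order(peak_x)
    peak_x <- peak_x[o]; peak_y <- peak_y[o]
  }
  if (length(peak_x) < 3L)
    stop("detect_peaks: fewer than 3 R peaks after position correction")

  peak_list(peak_x - 1L, peak_y, fs)  # 0-based indices
}

#' Detect R peaks in an ECG record
#'
#' Convenience wrapper: optionally denoises the configured detection lead
#' (default `II`), builds the detection sequence and runs [detect_peaks()].
#'
#' @param record An [ecg_record()] containing `cfg$detection_lead`.
#' @param cfg An [arspl_config()].
#' @param preprocess Denoise the detection lead first (default `TRUE`).
#' @return A [peak_list()].
#' @export
detect_rpeaks <- function(record, cfg = arspl_config(), preprocess = TRUE) {
  validate_record(record, required_leads = cfg$detection_lead)
  y <- record$leads[[cfg$detection_lead]]
  if (preprocess) y <- denoise(y, record$fs, cfg)
  det <- build_detection_sequence(y, record$fs, cfg)
  detect_peaks(det, y, record$fs, cfg)
}
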