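#' ARSPL configuration
#'
#' Bundles every tunable of the segmentation and synthesis pipeline. Defaults
#' follow the published operating point for 1000 Hz recordings: sym5 wavelet,
#' 8 decomposition levels, detection sequence rebuilt from detail levels 3-5,
#' an initial detection threshold of 30% of the maximum of the first two
#' seconds, an adaptive threshold of 50% of the mean of the three most recent
#' registered peaks, a 220 bpm heart-rate gate, and experienced time windows
#' `T_QR` = 0.03 s, `T_RS` = 0.04 s and `a_RT` = 0.37 (the R-T window is
#' `a_RT * rr(n)`, adapted per cycle).
#'
#' @param wavelet_name Wavelet basis; only `"sym5"` is built in.
#' @param decomp_levels Decomposition depth for denoising (levels; the
#'   approximation band below `fs / 2^(decomp_levels+1)` Hz is removed).
#' @param detection_detail_levels Detail levels used to rebuild the R-peak
#'   detection sequence at 1000 Hz; shifted by `round(log2(fs/1000))` at other
#'   sampling rates so the selected frequency band is preserved.
#' @param init_threshold_frac Fraction of the early-signal maximum used as the
#'   initial detection threshold.
#' @param init_threshold_window_s Length of the initial-threshold window (s).
#' @param adapt_threshold_frac Fraction of the recent-peak mean used once the
#'   threshold turns adaptive.
#' @param adapt_peak_count Number of registered peaks after which the
#'   threshold becomes adaptive, and the number averaged.
#' @param max_hr_bpm Maximum physiological heart rate; candidate peaks closer
#'   than `60/max_hr_bpm` seconds to the previous peak are arbitrated.
#' @param T_QR,T_RS Experienced time windows (s) from the R peak to the start
#'   of the Q wave and the end of the S wave.
#' @param a_RT Fraction of the RR interval from the R peak to the end of the
#'   T wave.
#' @param smooth_window_s Moving-average width (s) for the detection-sequence
#'   envelope; about one QRS duration.
#' @param candidate_window_s Window (s) searched around a threshold crossing
#'   for the detection-sequence maximum.
#' @param correction_window_s Window (s) searched in the original signal when
#'   correcting a peak position.
#' @param detection_lead Lead used for R-peak detection; boundaries derived
#'   from it are applied to every lead.
#' @param rng_seed Optional integer seed recorded for reproducibility.
#'
#' @return An object of class `arspl_config` (a named list).
#' @export
#' @examples
#' cfg <- arspl_config()
#' cfg$T_RS
arspl_config <- function(wavelet_name = "sym5",
                         decomp_levels = 8L,
                         detection_detail_levels = c(3L, 4L, 5L),
                         init_threshold_frac = 0.30,
                         init_threshold_window_s = 2.0,
                         adapt_threshold_frac = 0.50,
                         adapt_peak_count = 3L,
                         max_hr_bpm = 220,
                         T_QR = 0.03,
                         T_RS = 0.04,
                         a_RT = 0.37,
                         smooth_window_s = 0.15,
                         candidate_window_s = 0.10,
                         correction_window_s = 0.05,
                         detection_lead = "II",
                         rng_seed = NULL) {
  stopifnot(identical(wavelet_name, "sym5"))
  cfg <- list(
    wavelet_name = wavelet_name,
    decomp_levels = as.integer(decomp_levels),
    detection_detail_levels = as.integer(detection_detail_levels),
    init_threshold_frac = init_threshold_frac,
    init_threshold_window_s = init_threshold_window_s,
    adapt_threshold_frac = adapt_threshold_frac,
    adapt_peak_count = as.integer(adapt_peak_count),
    max_hr_bpm = max_hr_bpm,
    T_QR = T_QR,
    T_RS = T_RS,
    a_RT = a_RT,
    smooth_window_s = smooth_window_s,
    candidate_window_s = candidate_window_s,
    correction_window_s = correction_window_s,
    detection_lead = detection_lead,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  durations <- c("init_threshold_window_s", "T_QR", "T_RS", "smooth_window_s",
                 "candidate_window_s", "correction_window_s")
  for (d in durations) {
    if (!is.numeric(cfg[[d]]) || cfg[[d]] <= 0)
      stop("arspl_config: `", d, "` must be a positive duration in seconds")
  }
  fracs <- c("init_threshold_frac", "adapt_threshold_frac", "a_RT")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("arspl_config: `", f, "` must lie in (0, 1)")
  }
  if (cfg$decomp_levels < 1L) stop("arspl_config: `decomp_levels` must be >= 1")
  if (cfg$max_hr_bpm <= 0) stop("arspl_config: `max_hr_bpm` must be positive")
  if (any(cfg$detection_detail_levels < 1L))
    stop("arspl_config: `detection_detail_levels` must be positive integers")
  class(cfg) <- "arspl_config"
  cfg
}

#' @export
print.arspl_config <- function(x, ...) {
  cat("ARSPL configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# Detail levels actually used for detection at sampling rate fs: the defaults
# target 1000 Hz; a power-of-two rate change shifts every dyadic band by
# log2(fs/1000) levels, so shifting the level set preserves the band in Hz.
detection_levels_for_fs <- function(cfg, fs) {
  shift <- round(log2(fs / 1000))
  lev <- cfg$detection_detail_levels + shift
  lev <- lev[lev >= 1L]
  if (length(lev) == 0L) lev <- 1L
  as.integer(lev)
}
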