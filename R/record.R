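#' Multi-lead ECG record
#'
#' A sampled multi-lead ECG. Amplitudes are stored in microvolts; all leads
#' share one sampling rate and one length.
#'
#' @param leads Named list (or data frame) of equal-length numeric amplitude
#'   vectors in microvolts, one per lead. Standard names are `I`, `II`, `III`,
#'   `aVR`, `aVL`, `aVF`, `V1`-`V6`, but any names are accepted.
#' @param fs Sampling rate in Hz (> 0).
#'
#' @return An object of class `ecg_record` with elements `leads` (named list),
#'   `fs` and `n_samples`.
#' @export
#' @examples
#' rec <- ecg_record(list(I = sin(1:100 / 10), II = cos(1:100 / 10)), fs = 100)
#' rec$n_samples
ecg_record <- function(leads, fs) {
  if (is.data.frame(leads)) leads <- as.list(leads)
  if (!is.list(leads) || length(leads) == 0L || is.null(names(leads)) ||
      any(!nzchar(names(leads))))
    stop("ecg_record: `leads` must be a non-empty named list of numeric vectors")
  leads <- lapply(leads, as.numeric)
  lens <- vapply(leads, length, integer(1))
  if (any(lens != lens[[1]]))
    stop("ecg_record: lead length mismatch (", paste(unique(lens), collapse = ", "),
         " samples)")
  if (lens[[1]] < 1L) stop("ecg_record: leads must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("ecg_record: `fs` must be a positive sampling rate in Hz")
  structure(list(leads = leads, fs = as.numeric(fs), n_samples = lens[[1]]),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d leads (%s), %d samples @ %g Hz (%.2f s)\n",
              length(x$leads), paste(names(x$leads), collapse = ", "),
              x$n_samples, x$fs, x$n_samples / x$fs))
  invisible(x)
}

#' @export
as.matrix.ecg_record <- function(x, ...) {
  do.call(cbind, x$leads)
}

#' Validate an ECG record
#'
#' Checks that an [ecg_record()] contains the required leads, that all leads
#' have the same length and that the sampling rate is positive. Returns the
#' record unchanged on success.
#'
#' @param record An [ecg_record()].
#' @param required_leads Character vector of lead names that must be present.
#' @return `record`, invisibly unchanged.
#' @export
validate_record <- function(record, required_leads = c("I", "II", "V2")) {
  if (!inherits(record, "ecg_record"))
    stop("validate_record: `record` must be an ecg_record")
  missing <- setdiff(required_leads, names(record$leads))
  if (length(missing) > 0L)
    stop("validate_record: missing lead(s): ", paste(missing, collapse = ", "))
  lens <- vapply(record$leads, length, integer(1))
  if (any(lens != record$n_samples))
    stop("validate_record: lead length mismatch")
  if (record$fs <= 0) stop("validate_record: non-positive sampling rate")
  record
}

#' Detected R peaks
#'
#' Container for R-peak detections: 0-based sample indices, amplitudes read
#' from the signal, and the derived RR intervals in seconds.
#'
#' @param peak_x Integer vector of strictly increasing 0-based sample indices.
#' @param peak_y Numeric vector of peak amplitudes (microvolts), same length.
#' @param fs Sampling rate in Hz used to convert index gaps to RR seconds.
#'
#' @return An object of class `peak_list` with elements `peak_x`, `peak_y`,
#'   `M` (peak count) and `rr` (RR intervals in s, length `M - 1`).
#' @export
peak_list <- function(peak_x, peak_y, fs) {
  peak_x <- as.integer(round(peak_x))
  peak_y <- as.numeric(peak_y)
  if (length(peak_x) != length(peak_y))
    stop("peak_list: `peak_x` and `peak_y` must have the same length")
  if (length(peak_x) >= 2L && any(diff(peak_x) <= 0L))
    stop("peak_list: `peak_x` must be strictly increasing")
  if (fs <= 0) stop("peak_list: `fs` must be positive")
  rr <- if (length(peak_x) >= 2L) diff(peak_x) / fs else numeric(0)
  structure(list(peak_x = peak_x, peak_y = peak_y, M = length(peak_x),
                 rr = rr, fs = as.numeric(fs)),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("R peaks: M = %d", x$M))
  if (x$M >= 2L)
    cat(sprintf(", mean HR = %.1f bpm", 60 / mean(x$rr)))
  cat("\n")
  invisible(x)
}

#' Region boundaries of a segmented ECG
#'
#' The three boundary families anchoring the region segmentation, all 0-based
#' sample indices interpreted with half-open ranges: `B_SE(n)` (end of S wave,
#' cycles 1..M-1), `B_TE(n)` (end of T wave, cycles 1..M-1) and `B_QS(n)`
#' (start of Q wave, cycles 2..M). Vectors are stored aligned to cycle number:
#' `B_QS[1]` is `NA` (cycle 1 has no Q-wave start).
#'
#' @param B_SE,B_TE Numeric vectors of length `M - 1`.
#' @param B_QS Numeric vector of length `M` with `NA` in position 1, or of
#'   length `M - 1` holding cycles 2..M.
#' @param M Number of R peaks the boundaries refer to.
#' @param n_samples Record length the boundaries index into.
#' @return An object of class `region_boundaries`.
#' @export
region_boundaries <- function(B_SE, B_TE, B_QS, M, n_samples) {
  M <- as.integer(M)
  if (M < 3L) stop("region_boundaries: requires M >= 3 peaks")
  if (length(B_SE) != M - 1L || length(B_TE) != M - 1L)
    stop("region_boundaries: B_SE and B_TE must have length M - 1")
  if (length(B_QS) == M - 1L) B_QS <- c(NA_real_, B_QS)
  if (length(B_QS) != M)
    stop("region_boundaries: B_QS must cover cycles 2..M")
  B_SE <- as.integer(round(B_SE)); B_TE <- as.integer(round(B_TE))
  B_QS <- as.integer(round(B_QS))
  structure(list(B_SE = B_SE, B_TE = B_TE, B_QS = B_QS, M = M,
                 n_samples = as.integer(n_samples)),
            class = "region_boundaries")
}

#' @export
print.region_boundaries <- function(x, ...) {
  cat(sprintf("Region boundaries: M = %d cycles over %d samples\n",
              x$M, x$n_samples))
  invisible(x)
}
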