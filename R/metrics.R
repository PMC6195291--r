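# Evaluation metrics: waveform agreement (CC, RMSE), ST-level denivelation
# (STSE, CDR/ER/DR), R-peak detection quality (Se, +P, Acc) and inter-region
# amplitude gaps.

#' Product-moment correlation coefficient
#'
#' @param a,b Equal-length numeric vectors (length >= 2, non-constant).
#' @return Scalar in `[-1, 1]`.
#' @export
correlation_coefficient <- function(a, b) {
  if (length(a) != length(b)) stop("correlation_coefficient: length mismatch")
  if (length(a) < 2L) stop("correlation_coefficient: need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation_coefficient: constant input")
  stats::cor(a, b)
}

#' Root-mean-square error
#'
#' @param a,b Equal-length numeric vectors in microvolts.
#' @return RMSE in microvolts.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("rmse: length mismatch")
  if (length(a) < 1L) stop("rmse: empty input")
  sqrt(mean((a - b)^2))
}

#' ST-level of one cardiac cycle
#'
#' ST amplitude measured 60 ms after the J-point, referenced to the PR
#' segment: `(y[j_point + round(0.060 * fs)] - y[pr_ref])`, returned in
#' millivolts (input in microvolts). Indices are 0-based.
#'
#' @param y Single-lead cycle (or record) in microvolts.
#' @param fs Sampling rate in Hz.
#' @param j_point 0-based index of the J-point (QRS end).
#' @param pr_ref 0-based index of the PR-segment reference sample.
#' @return ST level in millivolts.
#' @export
st_level <- function(y, fs, j_point, pr_ref) {
  st_idx <- j_point + round(0.060 * fs)
  if (st_idx < 0L || st_idx >= length(y) || pr_ref < 0L || pr_ref >= length(y))
    stop("st_level: measurement index outside the cycle")
  (y[st_idx + 1L] - y[pr_ref + 1L]) / 1000
}

#' ST-level synthesis error report
#'
#' Per-cycle STSE = ST(synthesized) - ST(original), measured on one lead with
#' the shared boundaries: the J-point is proxied by `B_SE(n)` and the PR
#' reference by `B_QS(n) - round(0.02 * fs)`. Cycles `2..M-1` (those with
#' both boundaries) are evaluated. CDR is the percentage of cycles with
#' `|STSE| > 0.1 mV`, split into elevation (ER, `STSE > 0.1`) and depression
#' (DR, `STSE < -0.1`); `CDR = ER + DR` identically. Both records should be
#' free of baseline wander (the synthesis pipeline detrends; detrend the
#' original the same way before calling).
#'
#' @param syn,ori [ecg_record()]s sharing `lead`, length and boundaries.
#' @param boundaries A [region_boundaries()] shared by both records.
#' @param fs Sampling rate in Hz.
#' @param lead Lead to measure (default `"V1"`).
#' @return Object of class `st_report`: list with `stse_mv` (per-cycle, mV),
#'   `CDR`, `ER`, `DR` (percent), `n_cycles`.
#' @export
st_report <- function(syn, ori, boundaries, fs, lead = "V1") {
  stopifnot(inherits(boundaries, "region_boundaries"))
  validate_record(syn, lead); validate_record(ori, lead)
  if (syn$n_samples != ori$n_samples)
    stop("st_report: record length mismatch")
  if (syn$n_samples != boundaries$n_samples)
    stop("st_report: cycle-count/boundary mismatch with the records")
  b <- boundaries
  M <- b$M
  cycles <- 2:(M - 1L)
  ys <- syn$leads[[lead]]
  yo <- ori$leads[[lead]]
  stse <- vapply(cycles, function(n) {
    j <- b$B_SE[n]
    pr <- max(b$B_QS[n] - round(0.02 * fs), 0L)
    st_level(ys, fs, j, pr) - st_level(yo, fs, j, pr)
  }, numeric(1))
  nc <- length(stse)
  ER <- 100 * sum(stse > 0.1) / nc
  DR <- 100 * sum(stse < -0.1) / nc
  structure(list(stse_mv = stse, CDR = ER + DR, ER = ER, DR = DR,
                 n_cycles = nc, lead = lead),
            class = "st_report")
}

#' @export
print.st_report <- function(x, ...) {
  cat(sprintf("ST report (%s, %d cycles): CDR = %.2f%%, ER = %.2f%%, DR = %.2f%%\n",
              x$lead, x$n_cycles, x$CDR, x$ER, x$DR))
  invisible(x)
}

#' Beat-detection quality
#'
#' Greedy one-to-one matching of detected peaks to reference peaks within
#' `tol_s` (closest pairs first). Unmatched reference beats are false
#' negatives, unmatched detections false positives. Reports
#' `Se = TP/(TP+FN)`, `+P = TP/(TP+FP)` and `Acc = TP/(TP+FP+FN)`, each in
#' percent.
#'
#' @param detected A [peak_list()] or vector of 0-based detected indices.
#' @param truth Vector of 0-based reference peak indices.
#' @param fs Sampling rate in Hz.
#' @param tol_s Matching tolerance in seconds (default 0.05).
#' @return Object of class `detection_metrics`: list with `TP`, `FN`, `FP`,
#'   `Se`, `P_plus`, `Acc`.
#' @export
#' @examples
#' m <- evaluate_detection(c(102, 1100, 3000), c(100, 1100, 2100), fs = 1000)
#' m$Se  # 66.67
evaluate_detection <- function(detected, truth, fs, tol_s = 0.05) {
  if (tol_s <= 0) stop("evaluate_detection: `tol_s` must be positive")
  det <- if (inherits(detected, "peak_list")) detected$peak_x else
    as.numeric(detected)
  truth <- as.numeric(truth)
  tol <- tol_s * fs
  # all candidate pairs within tolerance, matched greedily by distance
  pairs <- NULL
  if (length(det) > 0L && length(truth) > 0L) {
    dmat <- abs(outer(det, truth, "-"))
    idx <- which(dmat <= tol, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      idx <- idx[order(dmat[idx]), , drop = FALSE]
      used_d <- logical(length(det)); used_t <- logical(length(truth))
      keep <- logical(nrow(idx))
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE; used_t[j] <- TRUE; keep[k] <- TRUE
        }
      }
      pairs <- idx[keep, , drop = FALSE]
    }
  }
  TP <- if (is.null(pairs)) 0L else nrow(pairs)
  FN <- length(truth) - TP
  FP <- length(det) - TP
  detection_metrics(TP, FN, FP)
}

#' Detection metrics from raw counts
#'
#' @param TP,FN,FP Beat counts (true positives, false negatives, false
#'   positives).
#' @return Object of class `detection_metrics` with percentages `Se`,
#'   `P_plus` and `Acc`.
#' @export
#' @examples
#' detection_metrics(TP = 11916, FN = 119, FP = 37)
detection_metrics <- function(TP, FN, FP) {
  structure(list(TP = TP, FN = FN, FP = FP,
                 Se = 100 * TP / (TP + FN),
                 P_plus = 100 * TP / (TP + FP),
                 Acc = 100 * TP / (TP + FP + FN)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("Detection: TP = %d, FN = %d, FP = %d | Se = %.2f%%, +P = %.2f%%, Acc = %.2f%%\n",
              x$TP, x$FN, x$FP, x$Se, x$P_plus, x$Acc))
  invisible(x)
}

#' Inter-region amplitude gaps
#'
#' Piecewise synthesis can leave amplitude steps at region junctions. For
#' each junction type -- R-P to QRS (G1, at `B_QS(n)`), QRS to ST-T (G2, at
#' `B_SE(n)`, inner cycles) and ST-T to R-P (G3, at `B_TE(n)`) -- reports the
#' mean over cycles of the absolute step, i.e. |first sample after boundary -
#' last sample before boundary|, per lead.
#'
#' @param record An [ecg_record()] (typically a synthesized one).
#' @param boundaries A [region_boundaries()] consistent with the record.
#' @return Object of class `gap_report`: matrix with rows G1, G2, G3 and one
#'   column per lead (microvolts), plus an `Average` column.
#' @export
amplitude_gaps <- function(record, boundaries) {
  validate_record(record, character(0))
  stopifnot(inherits(boundaries, "region_boundaries"))
  b <- boundaries
  M <- b$M
  step_at <- function(y, idx) {
    idx <- idx[idx >= 1L & idx <= length(y) - 1L]
    if (length(idx) == 0L) return(NA_real_)
    mean(abs(y[idx + 1L] - y[idx]))  # 0-based boundary: sample idx vs idx-1
  }
  per_lead <- vapply(record$leads, function(y) {
    c(G1 = step_at(y, b$B_QS[2:(M - 1L)]),
      G2 = step_at(y, b$B_SE[2:(M - 1L)]),
      G3 = step_at(y, b$B_TE[1:(M - 1L)]))
  }, numeric(3))
  out <- cbind(per_lead, Average = rowMeans(per_lead, na.rm = TRUE))
  structure(out, class = c("gap_report", class(out)))
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Mean absolute inter-region amplitude gaps (microvolts):\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Per-lead agreement between two records
#'
#' Convenience table of CC and RMSE per shared lead.
#'
#' @param syn,ori [ecg_record()]s of equal length.
#' @param leads Leads to compare (default: those present in both).
#' @return Data frame with columns `lead`, `cc`, `rmse_uv`.
#' @export
evaluate_leads <- function(syn, ori, leads = NULL) {
  if (is.null(leads)) leads <- intersect(names(syn$leads), names(ori$leads))
  if (syn$n_samples != ori$n_samples)
    stop("evaluate_leads: record length mismatch")
  data.frame(
    lead = leads,
    cc = vapply(leads, function(l)
      correlation_coefficient(syn$leads[[l]], ori$leads[[l]]), numeric(1)),
    rmse_uv = vapply(leads, function(l)
      rmse(syn$leads[[l]], ori$leads[[l]]), numeric(1)),
    row.names = NULL
  )
}
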