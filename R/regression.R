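# Least-squares lead transformation: a single global model (the common
# linear-regression baseline) or one model per segmented region (piecewise).
# Design matrix X = [1 | I | II | V2]; coefficients solve min ||X b - R||_F.

SOURCE_LEADS <- c("I", "II", "V2")
TARGET_PRECORDIAL <- c("V1", "V3", "V4", "V5", "V6")
STANDARD_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
                 "V1", "V2", "V3", "V4", "V5", "V6")

#' Least-squares fit of the lead transformation matrix
#'
#' Solves the multi-response least-squares problem `targets ~ [1 | source]`
#' via a QR factorization (numerically equivalent to the normal-equations
#' estimator `b = (X'X)^-1 X' R`).
#'
#' @param source Numeric matrix, N x 3, columns ordered as the source leads
#'   (I, II, V2).
#' @param targets Numeric matrix (or vector), N x K, one column per target
#'   lead.
#' @return Coefficient matrix, `(1 + ncol(source)) x K`; row 1 is the
#'   intercept. Errors when `N <= ncol(source)` (underdetermined) or the
#'   augmented design is rank deficient (collinear leads).
#' @export
#' @examples
#' s <- matrix(rnorm(300), 100, 3)
#' b_true <- matrix(c(10, 0.5, -0.2, 1.1), 4, 1)
#' y <- cbind(1, s) %*% b_true
#' fit_lr(s, y)
fit_lr <- function(source, targets) {
  source <- as.matrix(source)
  targets <- as.matrix(targets)
  n <- nrow(source)
  if (nrow(targets) != n)
    stop("fit_lr: source and targets row counts differ (", n, " vs ",
         nrow(targets), ")")
  p <- ncol(source) + 1L
  if (n < p)
    stop("fit_lr: underdetermined system: N = ", n,
         " samples for ", p, " coefficients (need N > ", p - 1L, ")")
  X <- cbind(1, source)
  qrx <- qr(X)
  if (qrx$rank < p)
    stop("fit_lr: singular design: source leads are collinear")
  b <- qr.coef(qrx, targets)
  b <- matrix(b, nrow = p, ncol = ncol(targets))
  rownames(b) <- c("(Intercept)", colnames(source) %||% paste0("s", seq_len(p - 1L)))
  colnames(b) <- colnames(targets)
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a lead transformation matrix
#'
#' Returns `[1 | source] %*% b`: the synthesized target-lead samples.
#'
#' @param source Numeric matrix, N x 3.
#' @param b Coefficient matrix from [fit_lr()], `(1 + ncol(source)) x K`.
#' @return Numeric matrix, N x K.
#' @export
apply_lr <- function(source, b) {
  source <- as.matrix(source)
  b <- as.matrix(b)
  if (ncol(source) + 1L != nrow(b))
    stop("apply_lr: shape mismatch: source has ", ncol(source),
         " leads but coefficients expect ", nrow(b) - 1L)
  cbind(1, source) %*% b
}

#' Derive lead III and the augmented limb leads
#'
#' Einthoven/Goldberger arithmetic: `III = II - I`, `aVR = -(I + II)/2`,
#' `aVL = I - II/2`, `aVF = II - I/2`. The derived set satisfies
#' `I - II + III = 0` and `aVR + aVL + aVF = 0` identically.
#'
#' @param leadI,leadII Equal-length numeric vectors (microvolts).
#' @return Named list with `III`, `aVR`, `aVL`, `aVF`.
#' @export
derive_limb_leads <- function(leadI, leadII) {
  if (length(leadI) != length(leadII))
    stop("derive_limb_leads: lead length mismatch")
  list(III = leadII - leadI,
       aVR = -(leadI + leadII) / 2,
       aVL = leadI - leadII / 2,
       aVF = leadII - leadI / 2)
}

region_matrix <- function(seg, region, leads) {
  do.call(cbind, lapply(stats::setNames(leads, leads),
                        function(l) seg$regions[[l]][[region]]))
}

#' Train the four regional transformation matrices
#'
#' Fits `b_STT`, `b_RP` and `b_QRS` on the respective reorganized region
#' subsequences and `b_HT` on the complete (unsegmented) sequences -- the
#' head and tail are generally unrelated and may contain any sub-wave, so
#' the head-tail region borrows the global model.
#'
#' @param seg3 A `segmentation_result` of the source leads (I, II, V2).
#' @param seg_targets A `segmentation_result` of the target leads, segmented
#'   with the same boundaries.
#' @param full3 Complete N x 3 source matrix (same record, unsegmented).
#' @param full_targets Complete N x K target matrix.
#' @return Object of class `region_models`: list with the four coefficient
#'   matrices, `target_leads`, `source_leads` and `config` (may be `NULL`).
#' @export
train_arspl <- function(seg3, seg_targets, full3, full_targets) {
  stopifnot(inherits(seg3, "segmentation_result"),
            inherits(seg_targets, "segmentation_result"))
  if (!identical(seg3$boundaries, seg_targets$boundaries))
    stop("train_arspl: source and target segmentations use different boundaries")
  src_leads <- names(seg3$regions)
  tgt_leads <- names(seg_targets$regions)
  full3 <- as.matrix(full3)
  full_targets <- as.matrix(full_targets)
  colnames(full3) <- colnames(full3) %||% src_leads
  colnames(full_targets) <- colnames(full_targets) %||% tgt_leads

  fit_region <- function(region) {
    fit_lr(region_matrix(seg3, region, src_leads),
           region_matrix(seg_targets, region, tgt_leads))
  }
  models <- list(
    b_STT = fit_region("stt_seq"),
    b_RP = fit_region("rp_seq"),
    b_QRS = fit_region("qrs_seq"),
    b_HT = fit_lr(full3, full_targets),
    target_leads = tgt_leads,
    source_leads = src_leads,
    config = NULL
  )
  class(models) <- "region_models"
  models
}

#' @export
print.region_models <- function(x, ...) {
  cat(sprintf("Piecewise lead models: %s -> %s (4 regional 4x%d matrices)\n",
              paste(x$source_leads, collapse = ","),
              paste(x$target_leads, collapse = ","),
              length(x$target_leads)))
  invisible(x)
}

#' Train a piecewise model from a 12-lead record
#'
#' High-level trainer: optionally crops the record to `train_seconds`,
#' denoises every lead, detects R peaks on the configured detection lead,
#' derives boundaries, segments source and target leads with the same
#' pattern and calls [train_arspl()].
#'
#' @param record An [ecg_record()] containing the source leads and
#'   `target_leads`.
#' @param cfg An [arspl_config()].
#' @param train_seconds Optional training length in seconds (record cropped
#'   from its start). Training below 10 s triggers a warning.
#' @param target_leads Leads to model (default V1, V3-V6).
#' @param peaks,boundaries Optional ground-truth [peak_list()] /
#'   [region_boundaries()] to bypass detection.
#' @param preprocess Denoise before segmentation (default `TRUE`).
#' @return A `region_models` with the config snapshot attached.
#' @export
arspl_fit <- function(record, cfg = arspl_config(), train_seconds = NULL,
                      target_leads = TARGET_PRECORDIAL,
                      peaks = NULL, boundaries = NULL, preprocess = TRUE) {
  validate_record(record, required_leads = c(SOURCE_LEADS, target_leads))
  if (!is.null(train_seconds)) {
    if (train_seconds < 10)
      warning("arspl_fit: training on less than 10 s of data; coefficient ",
              "estimates may be unstable")
    n_keep <- min(record$n_samples, round(train_seconds * record$fs))
    record <- ecg_record(lapply(record$leads, function(y) y[seq_len(n_keep)]),
                         record$fs)
  }
  work <- if (preprocess) denoise_record(record, cfg) else record
  if (is.null(peaks))
    peaks <- detect_rpeaks(work, cfg, preprocess = FALSE)
  if (is.null(boundaries))
    boundaries <- derive_boundaries(peaks, work$fs, work$n_samples, cfg)
  seg3 <- segment_record(
    ecg_record(work$leads[SOURCE_LEADS], work$fs), boundaries, peaks)
  segt <- segment_record(
    ecg_record(work$leads[target_leads], work$fs), boundaries, peaks)
  models <- train_arspl(seg3, segt,
                        do.call(cbind, work$leads[SOURCE_LEADS]),
                        do.call(cbind, work$leads[target_leads]))
  models$config <- cfg
  models
}

#' Synthesize a 12-lead ECG from leads I, II and V2
#'
#' Full piecewise synthesis pipeline: denoise, detect R peaks, derive
#' boundaries, segment, apply the regional matrices to each region
#' subsequence, restore the full-length target leads, and derive lead III
#' and the augmented limb leads. The source leads are passed through (after
#' preprocessing, when enabled).
#'
#' @param record3 An [ecg_record()] containing at least I, II and V2.
#' @param models A `region_models` from [train_arspl()] / [arspl_fit()].
#' @param cfg An [arspl_config()]; defaults to the snapshot in `models`.
#' @param peaks,boundaries Optional ground truth to bypass detection.
#' @param preprocess Denoise before segmentation (default `TRUE`).
#' @return A 12-lead [ecg_record()] (leads in standard order).
#' @export
synthesize_arspl <- function(record3, models, cfg = NULL,
                             peaks = NULL, boundaries = NULL,
                             preprocess = TRUE) {
  stopifnot(inherits(models, "region_models"))
  if (is.null(cfg)) cfg <- models$config %||% arspl_config()
  validate_record(record3, required_leads = SOURCE_LEADS)
  work <- if (preprocess) {
    denoise_record(ecg_record(record3$leads[SOURCE_LEADS], record3$fs), cfg)
  } else {
    ecg_record(record3$leads[SOURCE_LEADS], record3$fs)
  }
  if (is.null(peaks))
    peaks <- detect_rpeaks(work, cfg, preprocess = FALSE)
  if (is.null(boundaries))
    boundaries <- derive_boundaries(peaks, work$fs, work$n_samples, cfg)
  seg3 <- segment_record(work, boundaries, peaks)

  coef_of <- c(stt_seq = "b_STT", rp_seq = "b_RP", qrs_seq = "b_QRS",
               ht_seq = "b_HT")
  syn_regions <- lapply(models$target_leads, function(l) l)  # placeholder
  names(syn_regions) <- models$target_leads
  per_region <- lapply(names(coef_of), function(region) {
    S <- region_matrix(seg3, region, SOURCE_LEADS)
    if (nrow(S) == 0L)
      return(matrix(numeric(0), 0L, length(models$target_leads),
                    dimnames = list(NULL, models$target_leads)))
    apply_lr(S, models[[coef_of[[region]]]])
  })
  names(per_region) <- names(coef_of)
  for (l in models$target_leads) {
    syn_regions[[l]] <- lapply(per_region, function(m) m[, l])
    names(syn_regions[[l]]) <- names(coef_of)
  }
  seg_syn <- structure(list(regions = syn_regions, lengths = seg3$lengths,
                            boundaries = boundaries, fs = work$fs),
                       class = "segmentation_result")
  syn <- restore_record(seg_syn)

  limb <- derive_limb_leads(work$leads[["I"]], work$leads[["II"]])
  leads <- c(list(I = work$leads[["I"]], II = work$leads[["II"]]),
             limb, list(V2 = work$leads[["V2"]]), syn$leads)
  present <- intersect(STANDARD_12, names(leads))
  ecg_record(leads[c(present, setdiff(names(leads), present))], work$fs)
}

#' Train the plain linear-regression baseline
#'
#' One global transformation matrix fitted on the complete sequences; the
#' standard single-model baseline that piecewise synthesis improves on.
#'
#' @inheritParams arspl_fit
#' @return Object of class `lr_model`: list with `b`, `target_leads`.
#' @export
train_lr <- function(record, cfg = arspl_config(), train_seconds = NULL,
                     target_leads = TARGET_PRECORDIAL, preprocess = TRUE) {
  validate_record(record, required_leads = c(SOURCE_LEADS, target_leads))
  if (!is.null(train_seconds)) {
    n_keep <- min(record$n_samples, round(train_seconds * record$fs))
    record <- ecg_record(lapply(record$leads, function(y) y[seq_len(n_keep)]),
                         record$fs)
  }
  work <- if (preprocess) denoise_record(record, cfg) else record
  b <- fit_lr(do.call(cbind, work$leads[SOURCE_LEADS]),
              do.call(cbind, work$leads[target_leads]))
  structure(list(b = b, target_leads = target_leads,
                 source_leads = SOURCE_LEADS, config = cfg),
            class = "lr_model")
}

#' Synthesize with the plain linear-regression baseline
#'
#' @param record3 An [ecg_record()] with I, II, V2.
#' @param model An `lr_model` from [train_lr()].
#' @param preprocess Denoise the source leads first (default `TRUE`).
#' @return A 12-lead [ecg_record()].
#' @export
synthesize_lr <- function(record3, model, preprocess = TRUE) {
  stopifnot(inherits(model, "lr_model"))
  validate_record(record3, required_leads = SOURCE_LEADS)
  work <- if (preprocess) {
    denoise_record(ecg_record(record3$leads[SOURCE_LEADS], record3$fs),
                   model$config %||% arspl_config())
  } else {
    ecg_record(record3$leads[SOURCE_LEADS], record3$fs)
  }
  Yhat <- apply_lr(do.call(cbind, work$leads[SOURCE_LEADS]), model$b)
  syn <- stats::setNames(lapply(seq_along(model$target_leads),
                                function(k) Yhat[, k]),
                         model$target_leads)
  limb <- derive_limb_leads(work$leads[["I"]], work$leads[["II"]])
  leads <- c(list(I = work$leads[["I"]], II = work$leads[["II"]]),
             limb, list(V2 = work$leads[["V2"]]), syn)
  present <- intersect(STANDARD_12, names(leads))
  ecg_record(leads[c(present, setdiff(names(leads), present))], work$fs)
}
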