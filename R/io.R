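# Waveform and model I/O: CSV (one column per lead, microvolts), WFDB
# format 16 (text header .hea + interleaved little-endian int16 .dat, the
# layout used by the PTB diagnostic records), and JSON model persistence.

#' Read an ECG record from CSV or WFDB
#'
#' Format is inferred from the extension (`.csv`, or `.hea`/bare record name
#' for WFDB) unless given. CSV files carry lead names in the header row,
#' amplitudes in microvolts, and optionally a `# fs: <Hz>` comment line;
#' WFDB amplitudes are converted to microvolts using the per-channel gain.
#'
#' @param path File path (for WFDB: the `.hea` path or the record name).
#' @param format `"csv"`, `"wfdb"` or `NULL` (infer).
#' @param fs Sampling rate override for CSV files without an `fs` comment
#'   (default 1000 Hz).
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = NULL, fs = 1000) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format,
         csv = read_record_csv(path, fs = fs),
         wfdb = read_record_wfdb(path),
         stop("read_record: unknown format `", format, "`"))
}

#' Write an ECG record to CSV or WFDB
#'
#' @param record An [ecg_record()].
#' @param path Output path (`.csv`, or record name / `.hea` path for WFDB,
#'   which also writes the sibling `.dat`).
#' @param format `"csv"`, `"wfdb"` or `NULL` (infer from extension).
#' @param gain WFDB gain in ADC units per millivolt (default 2000, the PTB
#'   convention; quantization step 0.5 microvolts).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = NULL, gain = 2000) {
  validate_record(record, character(0))
  if (record$n_samples < 1L) stop("write_record: empty record")
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format,
         csv = write_record_csv(record, path),
         wfdb = write_record_wfdb(record, path, gain = gain),
         stop("write_record: unknown format `", format, "`"))
  invisible(path)
}

read_record_csv <- function(path, fs = 1000) {
  if (!file.exists(path))
    stop("read_record_csv: file not found: ", path)
  lines <- readLines(path, n = 5L)
  m <- regmatches(lines, regexec("^#\\s*fs\\s*[:=]\\s*([0-9.]+)", lines))
  hit <- which(vapply(m, length, integer(1)) == 2L)
  if (length(hit) > 0L) fs <- as.numeric(m[[hit[1L]]][2L])
  nf <- utils::count.fields(path, sep = ",", comment.char = "#")
  if (length(unique(nf)) > 1L)
    stop("read_record_csv: ragged CSV `", path, "`: row ",
         which(nf != nf[1L])[1L], " has ", nf[which(nf != nf[1L])[1L]],
         " fields, expected ", nf[1L])
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (nrow(df) == 0L) stop("read_record_csv: `", path, "` contains no samples")
  ecg_record(as.list(df), fs = fs)
}

write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", record$fs), con)
  df <- as.data.frame(record$leads, check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

wfdb_paths <- function(path) {
  base <- sub("\\.hea$", "", path)
  list(hea = paste0(base, ".hea"), dat = paste0(base, ".dat"),
       name = basename(base))
}

read_record_wfdb <- function(path) {
  p <- wfdb_paths(path)
  if (!file.exists(p$hea)) stop("read_record_wfdb: header not found: ", p$hea)
  lines <- readLines(p$hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(hdr[2L])
  fs <- as.numeric(hdr[3L])
  nsamp <- as.integer(hdr[4L])
  sig <- lines[2:(1L + nsig)]
  leads <- list()
  gains <- numeric(nsig); baselines <- numeric(nsig); names_ <- character(nsig)
  for (k in seq_len(nsig)) {
    f <- strsplit(trimws(sig[k]), "\\s+")[[1L]]
    if (f[2L] != "16")
      stop("read_record_wfdb: unsupported signal format `", f[2L],
           "` (only format 16)")
    gspec <- f[3L]                       # e.g. "2000", "2000(0)", "2000/mV"
    gspec <- sub("/.*$", "", gspec)
    base_m <- regmatches(gspec, regexec("\\(([-0-9]+)\\)", gspec))[[1L]]
    baselines[k] <- if (length(base_m) == 2L) as.numeric(base_m[2L]) else
      if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0
    if (is.na(baselines[k])) baselines[k] <- 0
    gains[k] <- as.numeric(sub("\\(.*$", "", gspec))
    names_[k] <- f[length(f)]
  }
  datfile <- file.path(dirname(p$hea), strsplit(trimws(sig[1L]), "\\s+")[[1L]][1L])
  raw <- readBin(datfile, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = nsig * nsamp)
  if (length(raw) < nsig * nsamp)
    stop("read_record_wfdb: signal file shorter than header declares")
  mat <- matrix(raw, nrow = nsig)        # interleaved sample-major
  for (k in seq_len(nsig)) {
    leads[[names_[k]]] <- (mat[k, ] - baselines[k]) / gains[k] * 1000  # uV
  }
  ecg_record(leads, fs)
}

write_record_wfdb <- function(record, path, gain = 2000) {
  p <- wfdb_paths(path)
  nsig <- length(record$leads)
  digi <- vapply(record$leads, function(y) {
    v <- round(y / 1000 * gain)          # uV -> mV -> ADC units
    if (any(abs(v) > 32767))
      stop("write_record_wfdb: amplitude exceeds the 16-bit range at gain ",
           gain)
    as.integer(v)
  }, integer(record$n_samples))
  if (is.null(dim(digi))) digi <- matrix(digi, nrow = 1L)
  inter <- as.integer(t(digi))           # sample-major interleave
  writeBin(inter, file.path(dirname(p$hea), paste0(p$name, ".dat")),
           size = 2L, endian = "little")
  chks <- vapply(seq_len(nsig), function(k) {
    s <- sum(as.numeric(digi[, k])) %% 65536
    if (s >= 32768) s <- s - 65536
    as.integer(s)
  }, integer(1))
  hdr <- c(sprintf("%s %d %g %d", p$name, nsig, record$fs, record$n_samples),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s",
                   p$name, gain, digi[1L, ], chks, names(record$leads)))
  writeLines(hdr, p$hea)
  invisible(p$hea)
}

#' Persist regional transformation matrices as JSON
#'
#' Serializes the four coefficient matrices (or the single baseline matrix),
#' the lead ordering and the configuration snapshot to one JSON document.
#'
#' @param models A `region_models` or `lr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "region_models")) {
    doc <- list(type = "arspl",
                b_STT = models$b_STT, b_RP = models$b_RP,
                b_QRS = models$b_QRS, b_HT = models$b_HT)
  } else if (inherits(models, "lr_model")) {
    doc <- list(type = "lr", b = models$b)
  } else stop("write_models: unsupported model object")
  doc$target_leads <- models$target_leads
  doc$source_leads <- models$source_leads
  cfg <- models$config
  if (!is.null(cfg)) doc$config <- unclass(cfg)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load models written by [write_models()]
#'
#' @param path JSON path.
#' @return A `region_models` or `lr_model`.
#' @export
read_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  remat <- function(m) {
    m <- as.matrix(m)
    rownames(m) <- c("(Intercept)", doc$source_leads)
    colnames(m) <- doc$target_leads
    m
  }
  cfg <- NULL
  if (!is.null(doc$config)) {
    keep <- intersect(names(doc$config), names(formals(arspl_config)))
    cfg <- do.call(arspl_config, doc$config[keep])
  }
  if (identical(doc$type, "arspl")) {
    structure(list(b_STT = remat(doc$b_STT), b_RP = remat(doc$b_RP),
                   b_QRS = remat(doc$b_QRS), b_HT = remat(doc$b_HT),
                   target_leads = doc$target_leads,
                   source_leads = doc$source_leads, config = cfg),
              class = "region_models")
  } else if (identical(doc$type, "lr")) {
    structure(list(b = remat(doc$b), target_leads = doc$target_leads,
                   source_leads = doc$source_leads, config = cfg),
              class = "lr_model")
  } else stop("read_models: unrecognized model file")
}
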