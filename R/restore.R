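# Sequence restoration: exact inverse of region segmentation. The region
# subsequences are re-split by the recorded per-cycle lengths and pasted back
# in temporal order: head, ST-T(1), then R-P(n)/QRS(n)/ST-T(n) for each inner
# cycle, R-P(M), tail.

#' Restore a full-length sequence from region subsequences
#'
#' Inverts segmentation for one lead: fragments are cut from the four region
#' subsequences strictly in cycle order according to `lengths` and pasted at
#' their original positions. `restore_sequence(seg$regions[[lead]],
#' seg$lengths)` reproduces the original lead exactly.
#'
#' @param region_seqs List with `stt_seq`, `rp_seq`, `qrs_seq`, `ht_seq`
#'   (one lead's reorganized subsequences).
#' @param lengths A [record_segment_lengths()] object.
#' @return Numeric vector of length `lengths$n_samples`.
#' @export
restore_sequence <- function(region_seqs, lengths) {
  stopifnot(inherits(lengths, "segment_lengths"))
  need <- c("stt_seq", "rp_seq", "qrs_seq", "ht_seq")
  if (!all(need %in% names(region_seqs)))
    stop("restore_sequence: region_seqs must contain ",
         paste(need, collapse = ", "))
  l <- lengths
  M <- l$M

  expected <- c(stt_seq = sum(l$SegL_STT),
                rp_seq = sum(l$SegL_RP, na.rm = TRUE),
                qrs_seq = sum(l$SegL_QRS, na.rm = TRUE),
                ht_seq = l$head_len + l$tail_len)
  for (nm in need) {
    if (length(region_seqs[[nm]]) != expected[[nm]])
      stop("restore_sequence: `", nm, "` has ", length(region_seqs[[nm]]),
           " samples but the segment lengths require ", expected[[nm]])
  }

  # per-region consumption cursors
  pos <- c(stt_seq = 0L, rp_seq = 0L, qrs_seq = 0L, ht_seq = 0L)
  take <- function(region, len, cycle) {
    if (len == 0L) return(numeric(0))
    src <- region_seqs[[region]]
    if (pos[[region]] + len > length(src))
      stop("restore_sequence: `", region, "` exhausted at cycle ", cycle,
           " (needs ", len, " more samples)")
    out <- src[(pos[[region]] + 1L):(pos[[region]] + len)]
    pos[region] <<- pos[[region]] + len
    out
  }

  out <- vector("list", 3L * M)
  k <- 0L
  add <- function(x) { k <<- k + 1L; out[[k]] <<- x }

  add(take("ht_seq", l$head_len, 1L))        # head: first B_SE(1) points of H-T
  add(take("stt_seq", l$SegL_STT[1L], 1L))
  if (M >= 3L) {
    for (n in 2:(M - 1L)) {
      add(take("rp_seq", l$SegL_RP[n], n))
      add(take("qrs_seq", l$SegL_QRS[n], n))
      add(take("stt_seq", l$SegL_STT[n], n))
    }
  }
  add(take("rp_seq", l$SegL_RP[M], M))
  add(take("ht_seq", l$tail_len, M))         # tail: the rest of H-T

  y <- unlist(out[seq_len(k)], use.names = FALSE)
  if (length(y) != l$n_samples)
    stop("restore_sequence: restored ", length(y), " of ", l$n_samples,
         " samples (internal error)")
  y
}

#' Restore every lead of a segmentation result
#'
#' @param seg A `segmentation_result` (possibly with synthesized region
#'   subsequences substituted in).
#' @return An [ecg_record()] with the restored leads.
#' @export
restore_record <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  leads <- lapply(seg$regions, restore_sequence, lengths = seg$lengths)
  ecg_record(leads, seg$fs)
}
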