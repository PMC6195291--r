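# Maximal-overlap discrete wavelet transform (MODWT) with the symlet-5 basis.
#
# The MODWT pyramid (undecimated, circular convolution with dyadically
# upsampled filters) is used instead of the decimated DWT: every detail level
# keeps the signal length, the transform is shift-invariant, and the inverse
# is exact. Level j details cover the dyadic band [fs/2^(j+1), fs/2^j] Hz,
# identical to the decimated transform, so level selections phrased for the
# DWT carry over unchanged.
#
# Boundary handling: the signal is extended by whole reflection to length 2N
# before the circular transform and trimmed afterwards, i.e. symmetric signal
# extension, which keeps edge artifacts away from the record's head and tail.

# Symlet-5 analysis filters (least-asymmetric Daubechies, 10 taps).
SYM5_DEC_LO <- c(0.027333068345077982, 0.029519490925774643,
                 -0.039134249302383094, 0.1993975339773936,
                 0.7234076904024206, 0.6339789634582119,
                 0.01660210576452232, -0.17532808990845047,
                 -0.021101834024758855, 0.019538882735286728)
SYM5_DEC_HI <- c(-0.019538882735286728, -0.021101834024758855,
                 0.17532808990845047, 0.01660210576452232,
                 -0.6339789634582119, 0.7234076904024206,
                 -0.1993975339773936, -0.039134249302383094,
                 -0.029519490925774643, 0.027333068345077982)

# y(t) = sum_l f[l] * x[(t - step*(l-1)) mod n], vectorized over t
modwt_circ_filter <- function(x, f, step) {
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    out <- out + f[l] * x[((idx - step * (l - 1L)) %% n) + 1L]
  }
  out
}

# adjoint: y(t) = sum_l f[l] * x[(t + step*(l-1)) mod n]
modwt_circ_filter_adj <- function(x, f, step) {
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    out <- out + f[l] * x[((idx + step * (l - 1L)) %% n) + 1L]
  }
  out
}

#' Maximal-overlap discrete wavelet transform (sym5)
#'
#' Multilevel undecimated wavelet decomposition with the symlet-5 basis and
#' symmetric (reflection) boundary handling. Each detail level and the final
#' approximation have the same length as the input; [imodwt()] inverts the
#' transform exactly.
#'
#' If `length(y)` is too short for the requested depth the depth is reduced
#' to `floor(log2(length(y)))` with a warning.
#'
#' @param y Numeric signal.
#' @param levels Decomposition depth J.
#' @return An object of class `arspl_modwt`: list with `W` (list of J detail
#'   coefficient vectors, level 1 = finest), `V` (level-J approximation
#'   coefficients), `n` (original length) and `levels`.
#' @export
modwt <- function(y, levels) {
  n <- length(y)
  if (n == 0L) stop("modwt: empty input")
  levels <- as.integer(levels)
  max_lev <- max(1L, as.integer(floor(log2(max(n, 2L)))))
  if (levels > max_lev) {
    warning(sprintf("modwt: input of length %d supports at most %d levels; reducing from %d",
                    n, max_lev, levels))
    levels <- max_lev
  }
  # whole reflection to length 2n makes the circular transform see a
  # symmetrically extended signal
  x <- c(y, rev(y))
  g <- SYM5_DEC_LO / sqrt(2)
  h <- SYM5_DEC_HI / sqrt(2)
  W <- vector("list", levels)
  V <- x
  for (j in seq_len(levels)) {
    step <- 2L^(j - 1L)
    W[[j]] <- modwt_circ_filter(V, h, step)
    V <- modwt_circ_filter(V, g, step)
  }
  structure(list(W = W, V = V, n = n, levels = levels), class = "arspl_modwt")
}

#' Inverse MODWT
#'
#' Exact inverse of [modwt()]. Coefficient vectors may be modified (e.g.
#' zeroed or thresholded) before inversion.
#'
#' @param dec An `arspl_modwt` object.
#' @return Numeric vector of length `dec$n`.
#' @export
imodwt <- function(dec) {
  stopifnot(inherits(dec, "arspl_modwt"))
  g <- SYM5_DEC_LO / sqrt(2)
  h <- SYM5_DEC_HI / sqrt(2)
  V <- dec$V
  for (j in rev(seq_len(dec$levels))) {
    step <- 2L^(j - 1L)
    V <- modwt_circ_filter_adj(dec$W[[j]], h, step) +
      modwt_circ_filter_adj(V, g, step)
  }
  V[seq_len(dec$n)]
}

#' Reconstruct a signal from selected detail levels
#'
#' Inverts the MODWT with the approximation band and all unselected detail
#' levels zeroed, yielding the band-passed component of `y` carried by the
#' chosen levels (level j spans roughly `fs/2^(j+1)` to `fs/2^j` Hz).
#'
#' @param y Numeric signal.
#' @param levels Total decomposition depth.
#' @param keep Integer vector of detail levels to retain.
#' @return Numeric vector, same length as `y`.
#' @export
modwt_details <- function(y, levels, keep) {
  dec <- modwt(y, levels)
  keep <- intersect(as.integer(keep), seq_len(dec$levels))
  if (length(keep) == 0L)
    stop("modwt_details: no valid detail level selected")
  npad <- length(dec$V)
  dec$V <- numeric(npad)
  for (j in seq_len(dec$levels)) {
    if (!(j %in% keep)) dec$W[[j]] <- numeric(npad)
  }
  imodwt(dec)
}

# Detail coefficients trimmed to the original (unreflected) length, for
# noise-level estimation.
modwt_detail_coeffs <- function(dec) {
  lapply(dec$W, function(w) w[seq_len(dec$n)])
}
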