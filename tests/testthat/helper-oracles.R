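# Shared fixtures and independent oracles used across test files.

# --- independent MODWT oracle -------------------------------------------
# Direct per-sample convolution implementation of the undecimated pyramid
# with sym5 filters and reflection padding; deliberately written as plain
# loops, sharing no code with the package's vectorized transform.

oracle_sym5 <- function() {
  list(
    lo = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.7234076904024206, 0.6339789634582119,
           0.01660210576452232, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728) / sqrt(2),
    hi = c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047,
           0.01660210576452232, -0.6339789634582119, 0.7234076904024206,
           -0.1993975339773936, -0.039134249302383094, -0.029519490925774643,
           0.027333068345077982) / sqrt(2)
  )
}

oracle_conv <- function(x, f, step, forward = TRUE) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (l in seq_along(f)) {
      shift <- step * (l - 1L)
      idx <- if (forward) (t - 1L - shift) %% n else (t - 1L + shift) %% n
      acc <- acc + f[l] * x[idx + 1L]
    }
    out[t] <- acc
  }
  out
}

oracle_modwt <- function(y, J) {
  flt <- oracle_sym5()
  x <- c(y, rev(y))
  W <- vector("list", J)
  V <- x
  for (j in seq_len(J)) {
    step <- 2L^(j - 1L)
    W[[j]] <- oracle_conv(V, flt$hi, step, forward = TRUE)
    V <- oracle_conv(V, flt$lo, step, forward = TRUE)
  }
  list(W = W, V = V, n = length(y), J = J)
}

oracle_imodwt <- function(dec) {
  flt <- oracle_sym5()
  V <- dec$V
  for (j in rev(seq_len(dec$J))) {
    step <- 2L^(j - 1L)
    V <- oracle_conv(dec$W[[j]], flt$hi, step, forward = FALSE) +
      oracle_conv(V, flt$lo, step, forward = FALSE)
  }
  V[seq_len(dec$n)]
}

# approximation-band removal (detrend only, no shrinkage), oracle route
oracle_detrend <- function(y, J) {
  dec <- oracle_modwt(y, J)
  dec$V <- numeric(length(dec$V))
  oracle_imodwt(dec)
}

# --- normal-equations / pseudo-inverse least-squares oracles -------------

oracle_normal_equations <- function(source, targets) {
  X <- cbind(1, as.matrix(source))
  solve(t(X) %*% X) %*% t(X) %*% as.matrix(targets)
}

oracle_pinv_fit <- function(source, targets) {
  X <- cbind(1, as.matrix(source))
  s <- svd(X)
  dinv <- ifelse(s$d > max(s$d) * 1e-12, 1 / s$d, 0)
  (s$v %*% (dinv * t(s$u))) %*% as.matrix(targets)
}

# --- fixtures -------------------------------------------------------------

# short clean synthetic subject; cached per (duration, hr, seed)
quick_gen <- local({
  cache <- list()
  function(duration_s = 10, hr_bpm = 60, seed = 1, ...) {
    key <- paste(duration_s, hr_bpm, seed, length(list(...)), sep = "_")
    if (is.null(cache[[key]]) || length(list(...)) > 0) {
      g <- generate_ecg(synth_spec(duration_s = duration_s, hr_bpm = hr_bpm,
                                   seed = seed, ...))
      if (length(list(...)) == 0) cache[[key]] <<- g else return(g)
    }
    cache[[key]]
  }
})

# boundaries for hand-built peak sets at fs = 1000 over n samples
quick_boundaries <- function(peaks_at, n, fs = 1000) {
  pk <- peak_list(peaks_at, rep(1, length(peaks_at)), fs)
  derive_boundaries(pk, fs, n)
}
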