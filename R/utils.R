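# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  All stochastic generators route through this so that
# cohorts are reproducible from (config, seed) without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a scalar in [%g, %g]", name, lower, upper))
  invisible(x)
}

# Zero-phase frequency-domain filter applied along the rows of a matrix
# (or to a vector).  `response(f)` maps non-negative frequencies in Hz to a
# real gain in [0, 1]; the gain is applied symmetrically so the output is
# real and the filter has exactly zero phase.  Used for the EMG band-pass,
# the MEG low-pass/notch, and the muscle-band isolation, where short
# fixed-length epochs make FFT filtering the natural zero-phase
# implementation.  Pairs of real rows share one complex FFT (the gain is
# real and symmetric, so the real and imaginary parts filter
# independently).
fft_filter <- function(x, fs, response) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else x
  n <- ncol(X)
  R <- nrow(X)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)              # fold to [0, fs/2]
  gain <- response(f)
  out <- matrix(0, R, n)
  npair <- R %/% 2L
  if (npair) {
    odd <- 2L * seq_len(npair) - 1L
    Z <- matrix(complex(real = t(X[odd, , drop = FALSE]),
                        imaginary = t(X[odd + 1L, , drop = FALSE])),
                n, npair)
    Y <- stats::mvfft(stats::mvfft(Z) * gain, inverse = TRUE) / n
    out[odd, ] <- t(Re(Y))
    out[odd + 1L, ] <- t(Im(Y))
  }
  if (R %% 2L) {
    out[R, ] <- Re(stats::fft(stats::fft(X[R, ]) * gain,
                              inverse = TRUE) / n)
  }
  if (vec) drop(out) else out
}

# DFT coefficients at selected bins for every column of a real time x
# signals matrix, with pairs of real columns packed into one complex FFT
# and recovered through conjugate symmetry.  `sel` is 1-based bin index.
packed_mvfft_sel <- function(M, sel) {
  n <- nrow(M)
  R <- ncol(M)
  out <- matrix(0i, length(sel), R)
  npair <- R %/% 2L
  conj_idx <- ifelse(sel == 1L, 1L, n - sel + 2L)
  if (npair) {
    odd <- 2L * seq_len(npair) - 1L
    Z <- matrix(complex(real = M[, odd], imaginary = M[, odd + 1L]),
                n, npair)
    F <- stats::mvfft(Z)
    Fp <- F[sel, , drop = FALSE]
    Fc <- Conj(F[conj_idx, , drop = FALSE])
    out[, odd] <- (Fp + Fc) / 2
    out[, odd + 1L] <- (Fp - Fc) / 2i
  }
  if (R %% 2L) out[, R] <- stats::fft(M[, R])[sel]
  out
}

# Smallest 5-smooth length >= n (R's mixed-radix FFT degrades badly on
# lengths with large prime factors).
next_fast_len <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# Smooth raised-cosine transition from 1 to 0 between f0 and f1.
cos_taper <- function(f, f0, f1) {
  g <- rep(1, length(f))
  g[f >= f1] <- 0
  mid <- f > f0 & f < f1
  g[mid] <- 0.5 * (1 + cos(pi * (f[mid] - f0) / (f1 - f0)))
  g
}

lowpass_gain <- function(cutoff, transition = 4) {
  function(f) cos_taper(f, cutoff - transition / 2, cutoff + transition / 2)
}

notch_gain <- function(center, half_width = 2, transition = 1) {
  function(f) {
    d <- abs(f - center)
    1 - cos_taper(d, half_width - transition, half_width + transition)
  }
}

# Mean magnitude of the band-limited analytic signal per row (the
# band envelope), via one packed forward FFT and a short inverse over
# the band bins only.  Scale is arbitrary but consistent across rows.
band_envelope_means <- function(X, fs, band, transition = 6, L = 128L) {
  n <- ncol(X)
  f_pos <- (seq_len(n) - 1L) / n * fs
  sel <- which(f_pos >= band[1] - transition & f_pos <= band[2] + transition &
                 f_pos <= fs / 2)
  gb <- bandpass_gain(band[1], band[2], transition)(f_pos[sel])
  F <- packed_mvfft_sel(t(X), sel) * gb
  L <- max(L, 2L * length(sel))
  Zb <- matrix(0i, L, ncol(F))
  Zb[seq_along(sel), ] <- F
  env <- Mod(stats::mvfft(Zb, inverse = TRUE))
  colMeans(env) * 2 / n
}

bandpass_gain <- function(lo, hi, transition = 4) {
  function(f) {
    cos_taper(f, hi - transition / 2, hi + transition / 2) *
      (1 - cos_taper(f, lo - transition / 2, lo + transition / 2))
  }
}
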