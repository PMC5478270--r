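#' Magnetic leadfield of a current dipole in a conducting sphere
#'
#' Closed-form field of a current dipole inside a homogeneous conducting
#' sphere (Sarvas solution), evaluated at the sensor positions and
#' projected onto each sensor's orientation (radial for the synthetic
#' magnetometer array).  The volume currents contribute no radial field,
#' so a radially oriented dipole is magnetically silent -- a property
#' the test suite exploits as an oracle.  Linear in the dipole moment.
#'
#' @param dipole_pos dipole position (metres, length-3), strictly inside
#'   the sphere and off-centre.
#' @param moment dipole moment vector (length-3); only its tangential
#'   part produces signal.
#' @param sensor_pos sensors x 3 position matrix, outside the sphere.
#' @param sensor_ori sensors x 3 unit orientation matrix (projection
#'   directions).
#' @param center sphere centre, default the origin.
#' @param radius conductor radius used only to validate geometry
#'   (default 0.09 m).
#' @return numeric leadfield vector, one value per sensor (Tesla per
#'   unit moment scale).
#' @export
sarvas_leadfield <- function(dipole_pos, moment, sensor_pos, sensor_ori,
                             center = c(0, 0, 0), radius = 0.09) {
  r0 <- as.numeric(dipole_pos) - center
  q <- as.numeric(moment)
  if (sqrt(sum(r0^2)) < 1e-9)
    stop("dipole at sphere centre: leadfield undefined")
  if (sqrt(sum(r0^2)) >= radius)
    stop("dipole outside the conducting sphere")
  mu0_4pi <- 1e-7
  sp <- sweep(as.matrix(sensor_pos), 2L, center)
  if (any(sqrt(rowSums(sp^2)) <= radius))
    stop("sensors must lie outside the conductor")
  B <- matrix(0, nrow(sp), 3L)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  for (i in seq_len(nrow(sp))) {
    r <- sp[i, ]
    a_vec <- r - r0
    a <- sqrt(sum(a_vec^2))
    rn <- sqrt(sum(r^2))
    ar <- sum(a_vec * r)
    F <- a * (rn * a + rn^2 - sum(r0 * r))
    gradF <- (a^2 / rn + ar / a + 2 * a + 2 * rn) * r -
      (a + 2 * rn + ar / a) * r0
    B[i, ] <- mu0_4pi / F^2 * (F * qxr0 - sum(qxr0 * r) * gradF)
  }
  rowSums(B * as.matrix(sensor_ori))
}

#' Build a regular source grid and fixed-orientation leadfields
#'
#' Dipoles on a regular grid inside the conductor (upper half by
#' default, mirroring a hemispherical sensor array), each with a fixed
#' tangential unit orientation, and their leadfield vectors.
#'
#' @param spacing grid spacing in metres, default 0.02.
#' @param radius source sphere radius, default 0.085 m.
#' @param sensor_pos,sensor_ori sensor geometry.
#' @param center conductor centre.
#' @param conductor_radius conductor radius, default 0.09 m.
#' @param upper_only keep only z >= 0 grid points (default TRUE).
#' @return list of class `source_model`: `pos`, `ori`, `leadfield`
#'   (sensors x sources), `spacing`, `center`, `conductor_radius`.
#' @export
build_source_model <- function(spacing = 0.02, radius = 0.085,
                               sensor_pos, sensor_ori,
                               center = c(0, 0, 0),
                               conductor_radius = 0.09,
                               upper_only = TRUE) {
  g <- seq(-radius, radius, by = spacing)
  pos <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- sqrt(rowSums(pos^2)) <= radius & rowSums(abs(pos)) > 1e-9
  if (upper_only) keep <- keep & pos[, 3] >= 0
  pos <- pos[keep, , drop = FALSE]
  pos <- sweep(pos, 2L, -as.numeric(center))
  ns <- nrow(pos)
  ori <- matrix(0, ns, 3L)
  L <- matrix(0, nrow(sensor_pos), ns)
  for (s in seq_len(ns)) {
    rhat <- (pos[s, ] - center) / sqrt(sum((pos[s, ] - center)^2))
    ref <- if (abs(rhat[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    tang <- c(ref[2] * rhat[3] - ref[3] * rhat[2],
              ref[3] * rhat[1] - ref[1] * rhat[3],
              ref[1] * rhat[2] - ref[2] * rhat[1])
    ori[s, ] <- tang / sqrt(sum(tang^2))
    L[, s] <- sarvas_leadfield(pos[s, ], ori[s, ], sensor_pos, sensor_ori,
                               center, conductor_radius)
  }
  structure(list(pos = pos, ori = ori, leadfield = L, spacing = spacing,
                 center = center, conductor_radius = conductor_radius),
            class = "source_model")
}

#' Cross-spectral density matrix from tapered Fourier coefficients
#'
#' Mean over trials, tapers and band frequencies of the outer product of
#' the Slepian-tapered Fourier coefficients; Hermitian and positive
#' semidefinite by construction.
#'
#' @param epochs `sensor_epochs` or trial x sensor x time array.
#' @param band frequency band `c(lo, hi)` in Hz.
#' @param fs_hz sampling rate.
#' @param nw,n_tapers taper parameters, defaults 2 and 2.
#' @param trials optional trial subset (indices).
#' @return list of class `csd_matrix`: complex `csd` (sensors x
#'   sensors), `band`, `n_trials`, `n_tapers`.
#' @export
compute_csd <- function(epochs, band, fs_hz = NULL, nw = 2, n_tapers = 2L,
                        trials = NULL) {
  if (inherits(epochs, "sensor_epochs")) {
    fs_hz <- fs_hz %||% epochs$fs_hz
    epochs <- epochs$epochs
  }
  d <- dim(epochs)
  trials <- trials %||% seq_len(d[1])
  if (!length(trials)) stop("empty trial subset")
  n <- d[3]
  tap <- dpss_tapers(n, nw, n_tapers)
  freq_all <- (0:(n - 1L)) / n * fs_hz
  sel <- which(freq_all >= band[1] - 1e-9 & freq_all <= band[2] + 1e-9)
  if (!length(sel)) stop("band contains no FFT frequencies")
  ep <- epochs[trials, , , drop = FALSE]
  ntr <- length(trials)
  m <- t(matrix(ep, ntr * d[2], n))      # time x (trial, sensor)
  C <- matrix(0 + 0i, d[2], d[2])
  cnt <- 0L
  for (k in seq_len(n_tapers)) {
    F <- packed_mvfft_sel(m * tap[, k], sel)
    for (j in seq_along(sel)) {
      Fj <- matrix(F[j, ], ntr, d[2])    # trials x sensors
      C <- C + crossprod(Fj, Conj(Fj))   # sum over trials of f f^H
      cnt <- cnt + ntr
    }
  }
  C <- C / cnt
  C <- (C + Conj(t(C))) / 2              # enforce exact Hermitian symmetry
  structure(list(csd = C, band = band, n_trials = length(trials),
                 n_tapers = n_tapers, freqs = freq_all[sel]),
            class = "csd_matrix")
}

#' DICS spatial filters (common filter)
#'
#' Unit-gain minimum-variance filters from the real part of the CSD:
#' `C_reg = Re(C) + lambda * (tr(Re(C)) / N) * I`, and per source
#' `w = (l' C_reg^-1 l)^-1 l' C_reg^-1` so that `w l = 1` exactly.
#'
#' @param csd `csd_matrix` (typically from all trials pooled -- the
#'   common filter the condition contrast shares).
#' @param source_model `source_model` with `leadfield`.
#' @param lambda regularization as a fraction of mean sensor power,
#'   default 0.05.
#' @return list of class `dics_filters`: `weights` (sources x sensors),
#'   `lambda`.
#' @export
dics_filters <- function(csd, source_model, lambda = 0.05) {
  C <- Re(csd$csd)
  N <- nrow(C)
  Creg <- C + lambda * (sum(diag(C)) / N) * diag(N)
  Ci <- tryCatch(solve(Creg), error = function(e)
    stop("regularized CSD is singular; increase lambda"))
  L <- source_model$leadfield
  W <- matrix(0, ncol(L), N)
  for (s in seq_len(ncol(L))) {
    l <- L[, s]
    cl <- Ci %*% l
    W[s, ] <- as.numeric(cl / sum(l * cl))
  }
  structure(list(weights = W, lambda = lambda), class = "dics_filters")
}

#' Project condition CSD through DICS filters to source power
#'
#' `power(s) = Re(w_s C w_s^H)`, non-negative up to numerical
#' tolerance.  Apply the common filter to each condition's CSD to get
#' condition-wise source power maps sharing one projection.
#'
#' @param filters `dics_filters`.
#' @param csd `csd_matrix` for one condition.
#' @return numeric vector of source power values.
#' @export
project_source_power <- function(filters, csd) {
  W <- filters$weights
  if (ncol(W) != nrow(csd$csd)) stop("filter/CSD dimension mismatch")
  as.numeric(Re(rowSums((W %*% csd$csd) * Conj(W))))
}
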