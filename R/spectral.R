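#' Dephasing trace of a waveform
#'
#' The dephasing vector `F(t) = gamma * integral_0^t g(t') dt'` (rad/m),
#' computed as the cumulative sum of the piecewise-constant gradient. Row `j`
#' holds `F(j dt)`; `F(0) = 0` is implicit and `F(tau)` is within the
#' refocusing tolerance of zero for any valid waveform.
#'
#' @param w an [waveform()].
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return object of class `mde_dephasing`: list with `values` (n x 3 matrix,
#'   rad/m) and `dt` (s).
#' @export
dephasing_time <- function(w, gamma = mde_gamma()) {
  stopifnot(inherits(w, "mde_waveform"))
  Ft <- apply(w$g, 2, cumsum) * gamma * w$dt
  structure(list(values = Ft, dt = w$dt), class = "mde_dephasing")
}

#' b-tensor of a waveform
#'
#' The time-domain outer-product integral of the dephasing vector,
#' `b = integral F(t) (x) F(t) dt`, a symmetric positive-semidefinite 3 x 3
#' matrix in s/m^2. Its trace is the b-value; its eigenvalue shape
#' distinguishes directional (rank-1, "stick") from isotropic ("sphere")
#' encoding.
#'
#' @param w an [waveform()].
#' @param gamma gyromagnetic ratio.
#' @return object of class `mde_btensor`: list with `matrix` (3 x 3, s/m^2).
#' @seealso [b_value()], [b_shape()]
#' @export
b_tensor <- function(w, gamma = mde_gamma()) {
  Ft <- dephasing_time(w, gamma = gamma)$values
  M <- crossprod(Ft) * w$dt
  M <- (M + t(M)) / 2
  structure(list(matrix = M), class = "mde_btensor")
}

#' @rdname b_tensor
#' @param B an `mde_btensor`.
#' @export
b_value <- function(B) {
  if (inherits(B, "mde_btensor")) B <- B$matrix
  sum(diag(B))
}

#' @rdname b_tensor
#' @export
b_shape <- function(B) {
  if (inherits(B, "mde_btensor")) B <- B$matrix
  ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  m <- mean(ev)
  list(eigenvalues = ev,
       spread = if (m > 0) (ev[1] - ev[3]) / m else 0)
}

#' @export
print.mde_btensor <- function(x, ...) {
  s <- b_shape(x)
  cat(sprintf("<mde_btensor> b = %.1f s/mm2, eigenvalue spread = %.2g\n",
              b_from_si(b_value(x)), s$spread))
  invisible(x)
}

#' Dephasing spectrum of a waveform
#'
#' The spectrum of the dephasing vector,
#' `F(omega) = integral_0^tau F(t) exp(-i omega t) dt`, computed with the FFT
#' after resampling the dephasing trace to a 1 us grid (linear interpolation,
#' which is exact for a piecewise-constant gradient) and zero padding to
#' `zero_pad_to` points (2^21 by default, about 0.48 Hz frequency spacing).
#' The DFT is scaled by the time step so it approximates the continuous
#' transform; with that normalisation the discrete Parseval identity makes
#' the frequency-domain b-tensor equal to the time-domain one exactly on the
#' full grid.
#'
#' Only the one-sided band `0 <= f <= f_max` is stored (Hermitian symmetry
#' `F(-omega) = conj(F(omega))` holds for a real gradient); each stored bin
#' carries an integration weight (2, or 1 at DC) so band sums reproduce
#' two-sided integrals. Both the full time-domain b-tensor (`b_time`) and the
#' in-band one (`b_band`) are kept; the out-of-band remainder is used by
#' [attenuation()] as a high-frequency tail correction.
#'
#' @param x an [waveform()] or an `mde_dephasing` trace.
#' @param zero_pad_to FFT length after zero padding (>= trace length).
#' @param f_max highest stored frequency in Hz (default 25 kHz, well beyond
#'   the band where smooth encoding waveforms retain power; the stored grid
#'   always covers at least the +-10 kHz band).
#' @param resample_dt spectral-analysis time step in s (default 1 us).
#' @param gamma gyromagnetic ratio.
#' @return object of class `mde_spectrum`: list with `values` (m x 3 complex
#'   matrix), `omega` (rad/s), `domega`, `weights`, `b_time`, `b_band`,
#'   `f_max`, `n_fft`, `resample_dt`.
#' @export
dephasing_spectrum <- function(x, zero_pad_to = 2^21, f_max = 25e3,
                               resample_dt = 1e-6, gamma = mde_gamma()) {
  if (inherits(x, "mde_waveform")) x <- dephasing_time(x, gamma = gamma)
  stopifnot(inherits(x, "mde_dephasing"))
  Ft <- x$values
  n <- nrow(Ft)
  tau <- n * x$dt
  if (resample_dt < x$dt) {
    tk <- seq(resample_dt, tau, by = resample_dt)
    t0 <- c(0, seq_len(n) * x$dt)
    Ff <- vapply(1:3, function(i) {
      approx(t0, c(0, Ft[, i]), xout = tk, rule = 2)$y
    }, numeric(length(tk)))
    dtf <- resample_dt
  } else {
    Ff <- Ft
    dtf <- x$dt
  }
  m <- nrow(Ff)
  if (zero_pad_to < m) stop("zero_pad_to must be >= trace length (", m, ")")
  N <- zero_pad_to
  nyquist <- 1 / (2 * dtf)
  if (f_max >= nyquist) f_max <- nyquist * (1 - 1e-12)
  if (f_max <= 0) stop("f_max must be positive")
  b_time <- crossprod(Ff) * dtf
  S <- matrix(0i, nrow = floor(f_max * N * dtf) + 1L, ncol = 3)
  keep <- seq_len(nrow(S))
  for (i in 1:3) {
    z <- complex(real = c(Ff[, i], rep(0, N - m)))
    S[, i] <- fft(z)[keep] * dtf
  }
  freq <- (keep - 1L) / (N * dtf)
  domega <- 2 * pi / (N * dtf)
  wts <- rep(2, length(keep)); wts[1] <- 1
  P <- wts * Re(S * Conj(S))
  b_band <- (domega / (2 * pi)) *
    Re(t(Conj(S)) %*% (wts * S))
  b_band <- (b_band + t(b_band)) / 2
  structure(list(values = S, omega = 2 * pi * freq, domega = domega,
                 weights = wts, power = P, b_time = b_time, b_band = b_band,
                 f_max = f_max, n_fft = N, resample_dt = dtf),
            class = "mde_spectrum")
}

#' @export
print.mde_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<mde_spectrum> %d bins, df = %.3g Hz, band 0-%.3g kHz, ",
                     "b = %.1f s/mm2\n"),
              nrow(x$values), x$domega / (2 * pi), x$f_max / 1e3,
              b_from_si(sum(diag(x$b_time)))))
  invisible(x)
}

#' Signal attenuation from the frequency-domain filter integral
#'
#' In the Gaussian (second-cumulant) approximation the attenuation factor of
#' a compartment with diffusion spectrum `D(omega)` is
#' `beta = (1/2pi) integral F^T(omega) D(omega) F(-omega) domega`,
#' and the signal is `E = exp(-beta)`. With `D(omega) = R lambda(omega) R^-1`
#' the quadrature reduces to per-axis power sums in the model's principal
#' frame. The integral is evaluated on the stored one-sided grid, truncated
#' where the cumulative encoding power reaches `1 - power_tol` of the total;
#' the neglected in-band and out-of-band power is assigned the
#' high-frequency limit of each principal spectrum (exact for Gaussian
#' compartments, error bounded by neglected power times D0 otherwise).
#'
#' @param spec an [dephasing_spectrum()] object.
#' @param model an [make_model()] diffusion model.
#' @param rotation optional extra 3 x 3 rotation applied to the model (on top
#'   of the model's own orientation), e.g. one frame of an
#'   [orientation_set()].
#' @param power_tol fraction of total encoding power allowed outside the
#'   explicit quadrature (default 1e-6).
#' @return `attenuation()`: the scalar `beta` (dimensionless, >= 0).
#' @examples
#' w <- qmas_fixture()
#' sp <- dephasing_spectrum(w, zero_pad_to = 2^18)
#' m <- make_model("sphere", R = 2.5e-6, D0 = 1e-9)
#' beta <- attenuation(sp, m)
#' adc(sp, m) # beta / b
#' @export
attenuation <- function(spec, model, rotation = NULL, power_tol = 1e-6) {
  stopifnot(inherits(spec, "mde_spectrum"), inherits(model, "mde_model"))
  R <- model$rotation
  if (!is.null(rotation)) R <- rotation %*% R
  Fr <- spec$values %*% R
  P <- spec$weights * Re(Fr * Conj(Fr))       # m x 3 per principal axis
  tot <- sum(P)
  if (tot <= 0) return(0)
  cp <- cumsum(rowSums(P))
  M <- which(cp >= (1 - power_tol) * tot)[1]
  lam <- model_lambda(model, spec$omega[seq_len(M)])
  k <- spec$domega / (2 * pi)
  beta <- k * sum(P[seq_len(M), , drop = FALSE] * lam)
  # tail within the stored band
  if (M < nrow(P)) {
    tailP <- colSums(P[(M + 1L):nrow(P), , drop = FALSE])
    beta <- beta + k * sum(tailP * model$lambda_inf)
  }
  # out-of-band remainder (above f_max), rotated into the principal frame
  rem <- spec$b_time - spec$b_band
  rem_p <- diag(t(R) %*% rem %*% R)
  beta + sum(pmax(rem_p, 0) * model$lambda_inf)
}

#' @rdname attenuation
#' @return `adc()`: the apparent diffusion coefficient `beta / b` in m^2/s,
#'   where `b` is the time-domain b-value of the encoding.
#' @export
adc <- function(spec, model, rotation = NULL, power_tol = 1e-6) {
  b <- sum(diag(spec$b_time))
  if (b <= 0) stop("b = 0: ADC undefined for a zero waveform")
  attenuation(spec, model, rotation = rotation, power_tol = power_tol) / b
}

#' Encoding power in a frequency band
#'
#' Integrates the one-sided encoding power spectrum below `f_cut`
#' (two-sided convention, so the band powers over a partition of the stored
#' band sum to the in-band b-value).
#'
#' @param spec an [dephasing_spectrum()].
#' @param f_cut band edge in Hz, `0 < f_cut <= f_max` of the spectrum.
#' @param axis `"trace"` (default), `"x"`, `"y"` or `"z"`.
#' @return band power in s/m^2.
#' @export
band_power <- function(spec, f_cut, axis = c("trace", "x", "y", "z")) {
  axis <- match.arg(axis)
  stopifnot(inherits(spec, "mde_spectrum"), f_cut > 0)
  if (f_cut > spec$f_max * (1 + 1e-12)) {
    stop("f_cut above the stored band (f_max = ", spec$f_max, " Hz)")
  }
  sel <- spec$omega <= 2 * pi * f_cut * (1 + 1e-12)
  k <- spec$domega / (2 * pi)
  P <- spec$power[sel, , drop = FALSE]
  switch(axis,
         trace = k * sum(P),
         x = k * sum(P[, 1]),
         y = k * sum(P[, 2]),
         z = k * sum(P[, 3]))
}
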