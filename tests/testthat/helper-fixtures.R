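# Shared fixtures, memoised per test run. Spectra use a reduced FFT length
# (2^18, ~3.8 Hz spacing) in unit tests; the acceptance suite uses the full
# 2^21 default.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_iso <- function() memo("iso", qmas_fixture())
fx_tuned <- function() memo("tuned", derive_tuned(fx_iso()))
fx_detuned <- function() memo("detuned", derive_detuned(fx_iso()))

fx_spec <- function(which = c("iso", "tuned", "detuned"), pad = 2^18) {
  which <- match.arg(which)
  memo(paste0("spec_", which, "_", pad), {
    w <- switch(which, iso = fx_iso(), tuned = fx_tuned(),
                detuned = fx_detuned())
    dephasing_spectrum(w, zero_pad_to = pad)
  })
}

# ideal PGSE on one axis: rectangular lobes +g / -g of width delta separated
# by Delta (start to start), on a dt grid
make_pgse <- function(g = 0.1, delta = 5e-3, Delta = 15e-3, dt = 1e-5) {
  n_d <- round(delta / dt)
  n_gap <- round((Delta - delta) / dt)
  gx <- c(rep(g, n_d), rep(0, n_gap), rep(-g, n_d))
  waveform(cbind(gx, 0, 0), dt = dt)
}

# discrete-convention b of an ideal PGSE (rectangle-rule oracle on the
# same grid the package uses), for exact comparisons
pgse_b_discrete <- function(g = 0.1, delta = 5e-3, Delta = 15e-3,
                            dt = 1e-5, gamma = mde_gamma()) {
  w <- make_pgse(g, delta, Delta, dt)
  Ft <- apply(w$g, 2, cumsum) * gamma * dt
  sum(Ft^2) * dt
}
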