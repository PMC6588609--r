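#' Diffusion substrate for Monte Carlo simulation
#'
#' @param geometry `"free"`, `"sphere"` or `"cylinder"` (infinite cylinder
#'   along its symmetry axis z).
#' @param R restriction radius in m (required for restricted geometries).
#' @param D0 intrinsic diffusivity in m^2/s.
#' @return object of class `mde_substrate`.
#' @export
substrate <- function(geometry = c("free", "sphere", "cylinder"),
                      R = NULL, D0 = 1e-9) {
  geometry <- match.arg(geometry)
  if (geometry != "free") {
    if (is.null(R) || R <= 0) stop("restricted substrate needs R > 0")
  } else {
    R <- 0
  }
  stopifnot(D0 > 0)
  structure(list(geometry = geometry, R = R, D0 = D0),
            class = "mde_substrate")
}

#' Random-walk configuration
#'
#' @param n_steps number of time steps (>= 100; 5000 by default).
#' @param n_particles number of diffusing particles (1e4 by default; use 1e5
#'   for production-grade statistics).
#' @param seed integer seed; each particle derives its own RNG stream from
#'   `(seed, particle index)`, so runs are bitwise reproducible and earlier
#'   particles are unchanged when the particle count grows.
#' @param tau walk duration in s.
#' @return object of class `mde_walk_config`.
#' @export
walk_config <- function(n_steps = 5000, n_particles = 1e4, seed = 1,
                        tau = 23e-3) {
  stopifnot(n_steps >= 100, n_particles >= 1, tau > 0)
  structure(list(n_steps = as.integer(n_steps),
                 n_particles = as.integer(n_particles),
                 seed = as.integer(seed), tau = tau,
                 dt = tau / n_steps),
            class = "mde_walk_config")
}

check_step_size <- function(sub, cfg) {
  if (sub$geometry == "free") return(invisible())
  rms <- sqrt(6 * sub$D0 * cfg$dt)
  if (rms > sub$R / 2) {
    stop(sprintf(paste0("RMS step %.3g m exceeds R/2 = %.3g m: rejection ",
                        "bias would dominate; increase n_steps"),
                 rms, sub$R / 2))
  }
  invisible()
}

# Coarse-grain a waveform onto the walk grid: the dephasing is interpolated
# (exact for a piecewise-constant gradient) and differenced, so each walk
# step sees the average gradient over its interval.
resample_gradient <- function(w, n_steps, tau, gamma = mde_gamma()) {
  if (abs(wf_duration(w) - tau) > tau * 1e-6) {
    stop(sprintf("waveform duration %.6g s does not match walk duration %.6g s",
                 wf_duration(w), tau))
  }
  dt_mc <- tau / n_steps
  Ft <- dephasing_time(w, gamma = gamma)$values
  t0 <- c(0, seq_len(nrow(Ft)) * w$dt)
  tk <- seq_len(n_steps) * dt_mc
  Fk <- vapply(1:3, function(i) approx(t0, c(0, Ft[, i]), xout = tk,
                                       rule = 2)$y, numeric(n_steps))
  G <- apply(rbind(0, Fk), 2, diff) / (gamma * dt_mc)
  b_ref <- sum(Fk^2) * dt_mc
  list(G = G, b_ref = b_ref, dt = dt_mc)
}

#' Run a restricted random walk
#'
#' Particles start uniformly inside the restriction (at the origin for free
#' diffusion) and take per-axis Gaussian steps with variance `2 D0 dt`;
#' steps whose endpoint would cross the barrier are rejected (the particle
#' stays in place for that step), so positions never leave the barrier.
#'
#' @param sub an [substrate()].
#' @param cfg a [walk_config()]. The RMS step must satisfy
#'   `sqrt(6 D0 dt) <= R/2`, otherwise rejection bias would dominate and an
#'   error is raised.
#' @return object of class `mde_walk`: list with `msd` (mean squared
#'   displacement from the start position after each step, m^2), `r_final`
#'   (n_particles x 3), `max_outside` (largest barrier penetration observed;
#'   0 by construction) and `dt`.
#' @export
run_walk <- function(sub, cfg) {
  stopifnot(inherits(sub, "mde_substrate"), inherits(cfg, "mde_walk_config"))
  check_step_size(sub, cfg)
  geom <- match(sub$geometry, c("free", "sphere", "cylinder")) - 1L
  res <- mc_walk_cpp(geom, sub$R, sub$D0, cfg$n_steps, cfg$n_particles,
                     cfg$dt, matrix(0, cfg$n_steps, 0), mde_gamma(),
                     as.double(cfg$seed))
  structure(list(msd = res$msd, r_final = res$r_final,
                 max_outside = res$max_outside, dt = cfg$dt,
                 substrate = sub, config = cfg),
            class = "mde_walk")
}

#' Monte Carlo diffusion-weighted signal
#'
#' Runs the random walk once and accumulates, per particle and waveform, the
#' phase moment matrix `M_ab = gamma dt sum_t g_a(t) r_b(t)`; the phase for
#' substrate orientation `Rot` (the substrate frame rotated relative to the
#' gradient frame) is `phi = sum_ab Rot[a,b] M_ab`, and gradient amplitudes
#' are rescaled per b-value as `sqrt(b / b_ref)`, exactly as amplitudes are
#' adjusted on a scanner. The signal is `E = <cos phi>`; the residual
#' imaginary part `<sin phi>` (zero in expectation) is reported as a sanity
#' metric together with the standard error of `E`.
#'
#' @param sub an [substrate()].
#' @param cfg a [walk_config()]; the walk duration must equal the waveform
#'   duration.
#' @param waveforms one [waveform()] or a (preferably named) list of them.
#' @param b_values b-values in s/m^2 at which to evaluate the signal.
#' @param orientations an [orientation_set()], a list of 3 x 3 rotation
#'   matrices, or `NULL` for the identity orientation.
#' @return object of class `mde_mc_result`: a data frame with columns
#'   `waveform`, `orientation`, `b`, `E`, `E_imag`, `se`.
#' @examples
#' \donttest{
#' sub <- substrate("sphere", R = 2.5e-6)
#' cfg <- walk_config(n_steps = 1000, n_particles = 2000, seed = 7)
#' res <- mc_signal(sub, cfg, qmas_fixture(),
#'                  b_values = b_to_si(c(0, 100, 1000)))
#' mc_adc(res)
#' }
#' @export
mc_signal <- function(sub, cfg, waveforms, b_values,
                      orientations = NULL) {
  stopifnot(inherits(sub, "mde_substrate"), inherits(cfg, "mde_walk_config"))
  check_step_size(sub, cfg)
  if (inherits(waveforms, "mde_waveform")) {
    waveforms <- setNames(list(waveforms), waveforms$label)
  }
  if (is.null(names(waveforms))) {
    names(waveforms) <- vapply(waveforms, function(w) w$label, "")
  }
  rots <- orientation_matrices(orientations)
  stopifnot(all(b_values >= 0))

  rs <- lapply(waveforms, resample_gradient, n_steps = cfg$n_steps,
               tau = cfg$tau)
  G <- do.call(cbind, lapply(rs, `[[`, "G"))
  b_ref <- vapply(rs, `[[`, numeric(1), "b_ref")
  geom <- match(sub$geometry, c("free", "sphere", "cylinder")) - 1L
  res <- mc_walk_cpp(geom, sub$R, sub$D0, cfg$n_steps, cfg$n_particles,
                     cfg$dt, G, mde_gamma(), as.double(cfg$seed))
  M <- res$M
  nP <- cfg$n_particles
  out <- vector("list", length(waveforms) * length(rots) * length(b_values))
  i <- 0L
  for (wi in seq_along(waveforms)) {
    Mw <- M[, (9 * (wi - 1) + 1):(9 * wi), drop = FALSE]
    for (oi in seq_along(rots)) {
      phi <- drop(Mw %*% as.vector(rots[[oi]]))
      for (bi in seq_along(b_values)) {
        b <- b_values[bi]
        if (b > 0 && b_ref[wi] <= 0) {
          stop("cannot scale a zero waveform to b > 0")
        }
        s <- if (b == 0) 0 else sqrt(b / b_ref[wi])
        cphi <- cos(s * phi)
        i <- i + 1L
        out[[i]] <- data.frame(
          waveform = names(waveforms)[wi], orientation = oi, b = b,
          E = mean(cphi), E_imag = mean(sin(s * phi)),
          se = stats::sd(cphi) / sqrt(nP))
      }
    }
  }
  df <- do.call(rbind, out)
  structure(df, class = c("mde_mc_result", "data.frame"),
            substrate = sub, config = cfg, b_ref = b_ref)
}

#' Monte Carlo apparent diffusion coefficient
#'
#' Computes per waveform and orientation the ADC from the exponential decay
#' between the two lowest b-values (0 and 100 s/mm^2 by default):
#' `ADC = -ln(E(b2)/E(b1)) / (b2 - b1)`.
#'
#' @param result an [mc_signal()] result.
#' @param b_pair the two b-values (s/m^2) to use; both must be present in
#'   the result.
#' @return data frame with columns `waveform`, `orientation`, `adc` (m^2/s).
#' @export
mc_adc <- function(result, b_pair = c(0, 1e8)) {
  stopifnot(inherits(result, "mde_mc_result"), length(b_pair) == 2)
  b_pair <- sort(b_pair)
  pick <- function(b) {
    sel <- abs(result$b - b) <= 1e-9 * max(1, b)
    if (!any(sel)) stop("b = ", b, " s/m^2 not present in the MC result")
    result[sel, ]
  }
  lo <- pick(b_pair[1]); hi <- pick(b_pair[2])
  key <- function(d) paste(d$waveform, d$orientation)
  hi <- hi[match(key(lo), key(hi)), ]
  if (any(hi$E <= 0)) {
    stop("E <= 0 at the upper b-value: Monte Carlo noise too large, ",
         "increase n_particles")
  }
  data.frame(waveform = lo$waveform, orientation = lo$orientation,
             adc = log(lo$E / hi$E) / (b_pair[2] - b_pair[1]))
}
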