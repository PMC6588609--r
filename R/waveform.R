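#' Effective gradient waveform
#'
#' The encoding primitive: a time-sampled three-axis effective gradient trace
#' with uniform time step. The sample `g[j, ]` is the gradient amplitude held
#' constant over the interval `((j-1) dt, j dt]`, i.e. the waveform is
#' piecewise constant exactly as a discrete waveform is played out on a
#' scanner. With this convention cumulative summation (the dephasing) and
#' finite differencing invert each other exactly, so derived waveforms are
#' refocused to machine precision.
#'
#' A valid waveform must satisfy the echo (refocusing) condition: the net
#' time integral of every axis over `[0, tau]` must vanish to within
#' `1e-9 * max|g| * tau`, so that the dephasing returns to zero at the echo.
#'
#' @param g numeric matrix of gradient samples in T/m, one row per time step;
#'   three axis columns, or one column which is promoted to a single-axis
#'   (x) waveform with zeros elsewhere.
#' @param dt time-step duration in seconds.
#' @param label encoding-type tag: `"isotropic"`, `"tuned"`, `"detuned"` or
#'   `"custom"`.
#' @param repair if `TRUE`, remove the per-axis mean gradient so the
#'   refocusing condition holds exactly instead of raising an error.
#' @return An object of class `mde_waveform`: list with elements `g`
#'   (n x 3 matrix, T/m), `dt` (s) and `label`. The encoding duration is
#'   `tau = nrow(g) * dt`.
#' @seealso [read_waveform()], [generate_qmas()], [b_tensor()]
#' @examples
#' # two-lobe bipolar pulse on x
#' g <- cbind(c(rep(0.1, 50), rep(-0.1, 50)), 0, 0)
#' w <- waveform(g, dt = 1e-4)
#' b_value(b_tensor(w))
#' @export
waveform <- function(g, dt, label = c("custom", "isotropic", "tuned", "detuned"),
                     repair = FALSE) {
  label <- match.arg(label)
  if (is.vector(g)) g <- matrix(g, ncol = 1)
  g <- as.matrix(g)
  if (ncol(g) == 1) g <- cbind(g, 0, 0)
  if (ncol(g) != 3) {
    stop("waveform samples must have 1 or 3 axis columns, got ", ncol(g))
  }
  storage.mode(g) <- "double"
  if (!all(is.finite(g))) stop("waveform contains non-finite amplitudes")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("dt must be a single positive number (seconds)")
  }
  if (nrow(g) < 2) stop("waveform needs at least 2 time steps")
  if (repair) {
    g <- sweep(g, 2, colMeans(g))
  }
  w <- structure(list(g = g, dt = dt, label = label), class = "mde_waveform")
  res <- refocusing_residual(w)
  if (res$residual > res$tolerance) {
    stop(sprintf(paste0(
      "refocusing condition violated: |integral g dt| = %.3g T s/m on axis %d ",
      "exceeds tolerance %.3g; pass repair = TRUE to remove the mean gradient"),
      res$residual, res$axis, res$tolerance))
  }
  w
}

#' @rdname waveform
#' @param w an `mde_waveform`.
#' @export
wf_duration <- function(w) nrow(w$g) * w$dt

#' @rdname waveform
#' @export
wf_max_gradient <- function(w) max(abs(w$g))

# Net area per axis versus the echo-condition tolerance.
refocusing_residual <- function(w) {
  area <- abs(colSums(w$g)) * w$dt
  gmax <- max(abs(w$g))
  tol <- 1e-9 * gmax * wf_duration(w)
  list(residual = max(area), axis = which.max(area), tolerance = tol)
}

#' Report the peak gradient amplitude against a hardware cap
#'
#' @param w an `mde_waveform`.
#' @param cap hardware maximum gradient in T/m (default 0.5, i.e. 500 mT/m).
#' @return list with `max_gradient` (T/m), `cap`, `within_cap` and the sample
#'   index at which the peak occurs.
#' @export
gradient_report <- function(w, cap = 0.5) {
  m <- max(abs(w$g))
  idx <- which(abs(w$g) == m, arr.ind = TRUE)[1, 1]
  list(max_gradient = m, cap = cap, within_cap = m <= cap, index = idx)
}

#' @export
print.mde_waveform <- function(x, ...) {
  B <- b_tensor(x)
  cat(sprintf("<mde_waveform> label=%s, %d samples, dt=%.3g s, tau=%.4g ms\n",
              x$label, nrow(x$g), x$dt, 1e3 * wf_duration(x)))
  cat(sprintf("  max |g| = %.1f mT/m, b = %.1f s/mm2\n",
              1e3 * wf_max_gradient(x), b_from_si(b_value(B))))
  invisible(x)
}

#' Read a gradient waveform from a delimited text file
#'
#' The file dialect is whitespace- or comma-delimited numeric columns
#' (three axes, or a single axis promoted to x), with optional `#` comment
#' header lines. Header lines of the form `# dt=1e-5` and `# unit=mT/m`
#' (or `T/m`) are honoured; an explicit `dt` argument overrides the header.
#'
#' @param source path to the waveform file, or a connection.
#' @param dt time step in seconds; required unless the file header carries it.
#' @param unit amplitude unit of the file if the header does not say:
#'   `"T/m"` (default) or `"mT/m"`.
#' @param label encoding-type tag to attach.
#' @param repair remove the per-axis mean gradient if the file violates the
#'   refocusing condition (e.g. after coarse rounding).
#' @return an [waveform()] object.
#' @export
read_waveform <- function(source, dt = NULL, unit = c("T/m", "mT/m"),
                          label = c("custom", "isotropic", "tuned", "detuned"),
                          repair = FALSE) {
  unit <- match.arg(unit)
  label <- match.arg(label)
  lines <- readLines(source)
  header <- grep("^\\s*#", lines, value = TRUE)
  for (h in header) {
    m <- regmatches(h, regexec("dt\\s*=\\s*([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 2 && is.null(dt)) dt <- as.numeric(m[2])
    m <- regmatches(h, regexec("unit\\s*=\\s*(m?T/m)", h))[[1]]
    if (length(m) == 2) unit <- m[2]
  }
  if (is.null(dt)) stop("dt not given and not found in file header")
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) stop("no data rows in waveform file")
  rows <- strsplit(trimws(lines[keep]), "[,\\s]+", perl = TRUE)
  ncols <- lengths(rows)
  if (any(ncols != ncols[1])) {
    bad <- keep[which(ncols != ncols[1])[1]]
    stop("malformed waveform row at line ", bad, ": expected ", ncols[1],
         " columns, got ", ncols[which(ncols != ncols[1])[1]])
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / ncols[1])
    stop("malformed waveform row at line ", keep[bad_row],
         ": non-numeric field")
  }
  g <- matrix(vals, ncol = ncols[1], byrow = TRUE)
  if (unit == "mT/m") g <- gradient_to_si(g)
  waveform(g, dt = dt, label = label, repair = repair)
}

#' Write a waveform to a delimited text file
#'
#' Emits a `#` header carrying `dt` and the amplitude unit, then one row of
#' three axis amplitudes per time step.
#'
#' @param w an [waveform()] object.
#' @param path output file path.
#' @param unit amplitude unit to write: `"T/m"` or `"mT/m"`.
#' @param digits significant digits (9 by default; enough that the
#'   refocusing condition survives the round trip).
#' @export
write_waveform <- function(w, path, unit = c("T/m", "mT/m"), digits = 9) {
  unit <- match.arg(unit)
  g <- w$g
  if (unit == "mT/m") g <- gradient_from_si(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mdesim gradient waveform, label=%s", w$label),
               sprintf("# dt=%.12g", w$dt),
               sprintf("# unit=%s", unit)), con)
  fmt <- sprintf("%%.%de", digits)
  writeLines(apply(g, 1, function(r) paste(sprintf(fmt, r), collapse = " ")),
             con)
  invisible(path)
}

# Rotation taking the unit vector `from` onto `to` (Rodrigues formula).
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Generate an isotropic q-MAS encoding waveform
#'
#' Builds a gradient waveform whose dephasing q-vector spins on a cone at the
#' magic angle `zeta = acos(1/sqrt(3))` — magic-angle spinning of the
#' q-vector — so that the resulting b-tensor is isotropic:
#' `q(t) = q0 a(t) [sin z cos psi(t), sin z sin psi(t), cos z]` with the
#' envelope `a(t) = sin^2(pi t / tau)` and azimuthal rule
#' `dpsi/dt` proportional to `a(t)^2`, normalised to `n_turns` full turns.
#' That rate rule makes the time average of `cos^2 psi` weighted by `a^2`
#' exactly 1/2 over whole turns, which renders the b-tensor isotropic up to
#' discretisation.
#'
#' By default the cone axis is rotated from z onto the body diagonal
#' `(1,1,1)/sqrt(3)`. On the cone axis the channel is pure envelope (low
#' frequency) while the transverse channels carry the azimuthal modulation
#' (high frequency); placing the axis on the body diagonal makes the three
#' laboratory channels equivalent under a 120-degree rotation, so each
#' channel's power spectrum approximates one third of the total encoding
#' power spectrum. This is what lets [derive_tuned()] extract a spectrally
#' matched single-axis waveform from the x channel.
#'
#' The amplitude is set, in order of precedence, by `b` (target b-value,
#' s/m^2), by `q0` (peak dephasing magnitude, rad/m), or — when both are
#' `NULL` — so that the peak gradient equals `max_gradient`.
#'
#' @param tau encoding duration in s (default 23 ms).
#' @param dt sample duration in s (default 10 us; spectra are computed on a
#'   1 us grid downstream, see [dephasing_spectrum()]).
#' @param n_turns number of full azimuthal turns of the q-vector.
#' @param cone_axis direction of the spinning-cone axis (need not be unit).
#' @param max_gradient hardware cap in T/m; exceeding it raises an error
#'   naming the offending time index.
#' @param q0 peak dephasing magnitude in rad/m, or `NULL`.
#' @param b target b-value in s/m^2, or `NULL`.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return an [waveform()] with label `"isotropic"`.
#' @examples
#' iso <- generate_qmas(tau = 23e-3, dt = 2e-5)
#' eigen(b_tensor(iso)$matrix)$values # nearly equal: isotropic encoding
#' @export
generate_qmas <- function(tau = 23e-3, dt = 1e-5, n_turns = 4,
                          cone_axis = c(1, 1, 1), max_gradient = 0.5,
                          q0 = NULL, b = NULL, gamma = mde_gamma()) {
  stopifnot(tau > 0, dt > 0)
  n <- round(tau / dt)
  if (n < 64) stop("q-MAS grid too coarse: need at least 64 samples")
  tq <- seq(0, n) * dt                      # q defined on interval boundaries
  a <- sin(pi * tq / tau)^2
  # psi from d psi/dt ~ a(t)^2, cumulative rectangle sum, n_turns full turns
  wgt <- a^2
  cum <- cumsum(c(0, (wgt[-1] + wgt[-length(wgt)]) / 2))
  psi <- 2 * pi * n_turns * cum / cum[length(cum)]
  zeta <- acos(1 / sqrt(3))
  qv <- cbind(sin(zeta) * a * cos(psi),
              sin(zeta) * a * sin(psi),
              cos(zeta) * a)
  qv <- qv %*% t(rotation_between(c(0, 0, 1), cone_axis))
  # unit-q0 gradient and b
  gu <- diff(qv) / (gamma * dt)
  b1 <- sum(qv[-1, ]^2) * dt                # rectangle sum of |F|^2
  if (!is.null(b)) {
    stopifnot(b >= 0)
    q0 <- sqrt(b / b1)
  } else if (is.null(q0)) {
    q0 <- max_gradient / max(abs(gu))
  }
  g <- q0 * gu
  if (max(abs(g)) > max_gradient * (1 + 1e-12)) {
    idx <- which(abs(g) == max(abs(g)), arr.ind = TRUE)[1, 1]
    stop(sprintf(paste0("requested amplitude gives |g| = %.3f T/m at time ",
                        "index %d, above the %.3f T/m cap"),
         max(abs(g)), idx, max_gradient))
  }
  waveform(g, dt = dt, label = "isotropic")
}

#' Derive the spectrally tuned directional waveform
#'
#' The tuned single-axis encoding is the x channel of the isotropic waveform
#' scaled by `sqrt(3)` to match the same b-value. When the per-axis encoding
#' powers of the isotropic waveform are equal (as for the default q-MAS
#' generator) the b-value is preserved exactly up to discretisation; the
#' power spectrum approximates the trace power spectrum of the isotropic
#' encoding, hence "tuned".
#'
#' Applying `derive_tuned()` to an already-tuned waveform is a caller error:
#' the function scales by `sqrt(3)` again (b times 3) and is therefore
#' restricted to inputs labelled `"isotropic"`.
#'
#' @param iso an [waveform()] with label `"isotropic"`.
#' @return a single-axis `mde_waveform` with label `"tuned"`.
#' @export
derive_tuned <- function(iso) {
  stopifnot(inherits(iso, "mde_waveform"))
  if (iso$label != "isotropic") {
    stop("derive_tuned() expects an isotropic waveform, got label '",
         iso$label, "'")
  }
  g <- cbind(sqrt(3) * iso$g[, 1], 0, 0)
  waveform(g, dt = iso$dt, label = "tuned")
}

#' Derive the spectrally detuned directional waveform
#'
#' The detuned single-axis encoding has scalar dephasing equal to the
#' dephasing *magnitude* of the isotropic waveform: `F_d(t) = |F(t)|`. Its
#' gradient is obtained by differencing `F_d` on the sample grid (the exact
#' inverse of the package's piecewise-constant integration convention, taken
#' without smoothing: `|F|` is non-smooth at zero crossings and the derived
#' waveform is what a scanner would actually play). Because
#' `sum |F(t)|^2 = sum F_d(t)^2` exactly, the b-value is preserved exactly.
#' The envelope `|F(t)|` varies on the encoding-time scale, so the detuned
#' spectrum concentrates its power at low frequencies — this is the
#' deliberate spectral mismatch that sensitises the tuned-minus-detuned
#' signal difference to time-dependent (restricted) diffusion.
#'
#' @param iso an [waveform()] with label `"isotropic"`.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return a single-axis `mde_waveform` with label `"detuned"`.
#' @export
derive_detuned <- function(iso, gamma = mde_gamma()) {
  stopifnot(inherits(iso, "mde_waveform"))
  if (iso$label != "isotropic") {
    stop("derive_detuned() expects an isotropic waveform, got label '",
         iso$label, "'")
  }
  Ft <- dephasing_time(iso, gamma = gamma)$values
  Fd <- sqrt(rowSums(Ft^2))
  g <- diff(c(0, Fd)) / (gamma * iso$dt)
  waveform(cbind(g, 0, 0), dt = iso$dt, label = "detuned")
}

#' Scale a waveform to a target b-value
#'
#' Multiplies the amplitudes by `sqrt(b_target / b_current)`; since b scales
#' with the square of the amplitude the resulting b-value equals the target
#' to machine precision.
#'
#' @param w an [waveform()].
#' @param b_target target b-value in s/m^2 (use [b_to_si()] for s/mm^2).
#' @return the rescaled waveform (same label).
#' @export
scale_to_b <- function(w, b_target) {
  stopifnot(inherits(w, "mde_waveform"), b_target >= 0)
  b_c <- b_value(b_tensor(w))
  if (b_target == 0) {
    w$g[] <- 0
    return(w)
  }
  if (b_c <= 0) stop("cannot scale a zero waveform to a positive b-value")
  w$g <- w$g * sqrt(b_target / b_c)
  w
}

#' Rotate a waveform
#'
#' Applies an orthonormal rotation to every gradient sample. The b-tensor of
#' the output is `R b R^T`; its trace (the b-value) is invariant.
#'
#' @param w an [waveform()].
#' @param rotation 3 x 3 orthonormal matrix (checked to 1e-8).
#' @return the rotated waveform.
#' @export
rotate_waveform <- function(w, rotation) {
  stopifnot(inherits(w, "mde_waveform"))
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(dim(rotation), c(3L, 3L))) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be a 3x3 orthonormal matrix (R^T R = I to 1e-8)")
  }
  w$g <- w$g %*% t(rotation)
  w
}

#' The q-MAS waveform fixture shipped with the package
#'
#' A fixed, pre-generated isotropic q-MAS waveform (tau = 23 ms, dt = 20 us,
#' peak gradient 500 mT/m) stored as plain text under `extdata`. All internal
#' defaults, examples and tests use this fixture so that results do not
#' depend on the generator defaults; any published numeric waveform can be
#' substituted through [read_waveform()].
#'
#' @return an [waveform()] with label `"isotropic"`.
#' @export
qmas_fixture <- function() {
  path <- system.file("extdata", "qmas_isotropic.txt", package = "mdesim",
                      mustWork = TRUE)
  read_waveform(path, label = "isotropic")
}
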