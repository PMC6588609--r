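#' Multi-compartment system
#'
#' A weighted mixture of diffusion models emulating a phantom or tissue
#' region of interest. Signal fractions must be in [0, 1] and sum to 1.
#'
#' @param components list of `list(model = <mde_model>, fraction = <num>)`.
#' @param name display name.
#' @return object of class `mde_system`.
#' @export
compartment_system <- function(components, name = "system") {
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-10) {
    stop("signal fractions must lie in [0, 1] and sum to 1 (got ",
         paste(signif(fr, 4), collapse = ", "), ")")
  }
  for (cmp in components) stopifnot(inherits(cmp$model, "mde_model"))
  structure(list(components = components, name = name),
            class = "mde_system")
}

#' @export
print.mde_system <- function(x, ...) {
  cat(sprintf("<mde_system> %s, %d components\n", x$name,
              length(x$components)))
  for (cmp in x$components) {
    cat(sprintf("  %4.0f %% ", 100 * cmp$fraction)); print(cmp$model)
  }
  invisible(x)
}

#' Built-in phantom and tissue archetypes
#'
#' Synthetic compartment systems emulating four classic phantom materials
#' and four tissue-like regions, stratified by restriction size and
#' microscopic anisotropy:
#' \describe{
#'   \item{yeast}{large isotropic restrictions: 50 % spheres (R = 2.5 um) +
#'     50 % free diffusion, both D0 = 1e-9 m^2/s — the same two-compartment
#'     system used by the simulation benchmark.}
#'   \item{microfibers}{large anisotropic restrictions: water-filled hollow
#'     fibers, inner diameter about 10 um, modelled as impermeable cylinders
#'     R = 5 um, uniformly dispersed.}
#'   \item{liquid_crystal}{small anisotropic restrictions: ~4 nm aqueous
#'     channels modelled as impermeable cylinders R = 2 nm; at encoding
#'     frequencies the transverse diffusivity is effectively zero, giving
#'     apparently one-dimensional, time-independent diffusion.}
#'   \item{polymer}{free multi-Gaussian diffusion: an aqueous polymer
#'     solution emulated as a mixture of three isotropic diffusivities.}
#'   \item{pbs}{a single free-water compartment (control region).}
#'   \item{wm, gm, cerebellum}{illustrative brain archetypes mixing thin
#'     cylinders (axons/dendrites), spheres (cell bodies), anisotropic
#'     Gaussian (extracellular) and free-water compartments. Fractions are
#'     documented defaults, not fits to any measured tissue curve, and can
#'     be overridden through `params`.}
#' }
#'
#' @param kind one of `"yeast"`, `"microfibers"`, `"liquid_crystal"`,
#'   `"polymer"`, `"wm"`, `"gm"`, `"cerebellum"`, `"pbs"`.
#' @param params named list overriding the documented defaults
#'   (e.g. `list(R = 3e-6)` for yeast sphere radius; see the function body
#'   for the per-kind parameter names).
#' @param K eigenmode truncation order for restricted compartments.
#' @return an [compartment_system()].
#' @export
make_phantom <- function(kind, params = list(), K = 250) {
  kinds <- c("yeast", "microfibers", "liquid_crystal", "polymer",
             "wm", "gm", "cerebellum", "pbs")
  if (!kind %in% kinds) {
    stop("unknown phantom kind '", kind, "'; valid kinds: ",
         paste(kinds, collapse = ", "))
  }
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  comps <- switch(kind,
    yeast = list(
      list(model = make_model("sphere", R = p("R", 2.5e-6),
                              D0 = p("D0", 1e-9), K = K),
           fraction = p("f_sphere", 0.5)),
      list(model = make_model("tensor", eigs = rep(p("D0", 1e-9), 3)),
           fraction = 1 - p("f_sphere", 0.5))),
    microfibers = list(
      list(model = make_model("cylinder", R = p("R", 5e-6),
                              D0 = p("D0", 1e-9), K = K),
           fraction = 1)),
    liquid_crystal = list(
      list(model = make_model("cylinder", R = p("R", 2e-9),
                              D0 = p("D0", 1e-9), K = K),
           fraction = 1)),
    polymer = list(
      list(model = make_model("tensor", eigs = rep(p("D_fast", 1.5e-9), 3)),
           fraction = p("f_fast", 0.4)),
      list(model = make_model("tensor", eigs = rep(p("D_mid", 0.5e-9), 3)),
           fraction = p("f_mid", 0.4)),
      list(model = make_model("tensor", eigs = rep(p("D_slow", 0.1e-9), 3)),
           fraction = 1 - p("f_fast", 0.4) - p("f_mid", 0.4))),
    pbs = list(
      list(model = make_model("tensor", eigs = rep(p("D0", 2e-9), 3)),
           fraction = 1)),
    wm = list(
      list(model = make_model("cylinder", R = p("R_axon", 0.5e-6),
                              D0 = p("D0", 1e-9), K = K),
           fraction = p("f_axon", 0.55)),
      list(model = make_model("tensor",
                              eigs = p("eigs_ec", c(1.2e-9, 0.3e-9, 0.3e-9))),
           fraction = p("f_ec", 0.35)),
      list(model = make_model("tensor", eigs = rep(p("D_free", 2e-9), 3)),
           fraction = 1 - p("f_axon", 0.55) - p("f_ec", 0.35))),
    gm = list(
      list(model = make_model("cylinder", R = p("R_dendrite", 0.5e-6),
                              D0 = p("D0", 1e-9), K = K),
           fraction = p("f_dendrite", 0.4)),
      list(model = make_model("tensor", eigs = rep(p("D_ec", 0.8e-9), 3)),
           fraction = p("f_ec", 0.4)),
      list(model = make_model("tensor", eigs = rep(p("D_free", 2e-9), 3)),
           fraction = 1 - p("f_dendrite", 0.4) - p("f_ec", 0.4))),
    cerebellum = list(
      list(model = make_model("sphere", R = p("R_soma", 2.5e-6),
                              D0 = p("D0", 1e-9), K = K),
           fraction = p("f_soma", 0.35)),
      list(model = make_model("cylinder", R = p("R_axon", 0.5e-6),
                              D0 = p("D0", 1e-9), K = K),
           fraction = p("f_axon", 0.35)),
      list(model = make_model("tensor", eigs = rep(p("D_ec", 0.8e-9), 3)),
           fraction = 1 - p("f_soma", 0.35) - p("f_axon", 0.35))))
  compartment_system(comps, name = kind)
}

#' Encoding protocol
#'
#' The three-encoding acquisition: isotropic q-MAS plus the tuned and
#' detuned single-axis waveforms derived from it, repeated at a ladder of
#' b-values (12 logarithmically spaced between 240 and 4800 s/mm^2 by
#' default) over uniformly distributed orientations. All three waveforms
#' share the encoding time; amplitudes are rescaled per b-value, so every
#' encoding hits each b exactly.
#'
#' @param waveforms named list with elements `isotropic`, `tuned`,
#'   `detuned`; by default derived from [qmas_fixture()].
#' @param b_values b-values in s/m^2.
#' @param n_orientations number of powder orientations (default 15).
#' @return object of class `mde_protocol`.
#' @export
protocol <- function(waveforms = NULL,
                     b_values = b_to_si(exp(seq(log(240), log(4800),
                                                length.out = 12))),
                     n_orientations = 15) {
  if (is.null(waveforms)) {
    iso <- qmas_fixture()
    waveforms <- list(isotropic = iso, tuned = derive_tuned(iso),
                      detuned = derive_detuned(iso))
  }
  stopifnot(all(c("isotropic", "tuned", "detuned") %in% names(waveforms)))
  taus <- vapply(waveforms, wf_duration, numeric(1))
  if (max(taus) - min(taus) > 1e-9) {
    stop("all protocol waveforms must share the encoding time tau")
  }
  bs <- vapply(waveforms, function(w) b_value(b_tensor(w)), numeric(1))
  if (max(bs) / min(bs) - 1 > 0.01) {
    stop("protocol waveforms must share trace(b) to 1 % before rescaling")
  }
  stopifnot(all(b_values >= 0))
  structure(list(waveforms = waveforms, b_values = sort(b_values),
                 n_orientations = as.integer(n_orientations),
                 tau = taus[[1]]),
            class = "mde_protocol")
}

#' @export
print.mde_protocol <- function(x, ...) {
  cat(sprintf(paste0("<mde_protocol> tau = %.3g ms, %d b-values ",
                     "(%.0f-%.0f s/mm2), %d orientations\n"),
              1e3 * x$tau, length(x$b_values), b_from_si(min(x$b_values)),
              b_from_si(max(x$b_values)), x$n_orientations))
  invisible(x)
}

# per-component, per-orientation ADC under one encoding spectrum
system_adcs <- function(system, spec, orientations) {
  lapply(system$components, function(cmp) {
    m <- cmp$model
    isotropic_model <- (m$kind == "restricted" && m$geometry == "sphere") ||
      (m$kind == "gaussian_tensor" && diff(range(m$eigs)) == 0)
    if (isotropic_model) {
      rep(adc(spec, m), length(orientation_matrices(orientations)))
    } else {
      adc_by_orientation(spec, m, orientations)
    }
  })
}

#' Predict powder-averaged signal curves for a system
#'
#' For every encoding in the protocol, computes the per-compartment
#' attenuation from the frequency-domain filter integral at each
#' (orientation, b), sums the compartments weighted by signal fraction, and
#' powder-averages over orientations. Within the Gaussian approximation the
#' per-compartment attenuation is mono-exponential in b at fixed waveform
#' shape, so each compartment contributes `exp(-ADC(orientation) * b)`.
#'
#' @param system an [compartment_system()] (or [make_phantom()] output).
#' @param prot an [protocol()].
#' @param keep_orientations attach the pre-average per-orientation
#'   attenuation matrices as attribute `per_orientation`?
#' @param zero_pad_to FFT length for the encoding spectra (see
#'   [dephasing_spectrum()]); the default 2^21 gives ~0.5 Hz resolution.
#' @return named list of `mde_curve` (one per encoding), each with a b = 0
#'   point prepended so that E(0) = 1.
#' @examples
#' \donttest{
#' prot <- protocol(n_orientations = 15)
#' curves <- predict_signals(make_phantom("yeast"), prot)
#' curves$isotropic
#' }
#' @export
predict_signals <- function(system, prot, keep_orientations = FALSE,
                            zero_pad_to = 2^21) {
  stopifnot(inherits(system, "mde_system"), inherits(prot, "mde_protocol"))
  ors <- orientation_set(prot$n_orientations)
  b <- c(0, prot$b_values)
  fractions <- vapply(system$components, `[[`, numeric(1), "fraction")
  out <- list()
  per_or <- list()
  for (enc in names(prot$waveforms)) {
    spec <- dephasing_spectrum(prot$waveforms[[enc]],
                               zero_pad_to = zero_pad_to)
    adcs <- system_adcs(system, spec, ors)   # list over components
    Emat <- 0
    for (ci in seq_along(adcs)) {
      Emat <- Emat + fractions[ci] * exp(-outer(adcs[[ci]], b))
    }
    per_or[[enc]] <- Emat
    cur <- powder_average(Emat, b = b, label = enc)
    attr(cur, "provenance") <- "analytic"
    out[[enc]] <- cur
  }
  if (keep_orientations) attr(out, "per_orientation") <- per_or
  out
}

#' Add Rician noise to signals
#'
#' Magnitude of `(E + N(0, sigma)) + i N(0, sigma)` with
#' `sigma = 1/snr`, the rectified-noise model of magnitude MR images.
#' Reproducible for a fixed seed.
#'
#' @param x an `mde_curve`, numeric vector or array of noiseless signals
#'   (normalised so the unweighted signal is 1).
#' @param snr signal-to-noise ratio at E = 1 (> 0).
#' @param seed integer seed.
#' @return a noisy copy of `x`.
#' @export
add_rician_noise <- function(x, snr, seed = 1) {
  stopifnot(snr > 0)
  noisify <- function(v) {
    sigma <- 1 / snr
    sqrt((v + rnorm(length(v), 0, sigma))^2 + rnorm(length(v), 0, sigma)^2)
  }
  withr_seed(seed, {
    if (inherits(x, "mde_curve")) {
      x$E <- noisify(x$E)
      attr(x, "provenance") <- "synthetic-noisy"
      x
    } else if (is.array(x) || is.numeric(x)) {
      out <- x
      out[] <- noisify(as.numeric(x))
      out
    } else stop("cannot add noise to an object of class ", class(x)[1])
  })
}

#' Render a synthetic labelled signal volume
#'
#' Builds a 4D signal volume from a voxel label map: every voxel of region
#' `l` carries that region's per-orientation attenuations for each
#' (encoding, b, orientation) frame, with optional Rician noise. A sidecar
#' table describes the 4th-dimension frames; label 0 is background (zero
#' signal).
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param systems named list mapping label values (as character, e.g.
#'   `"1"`) to [compartment_system()] objects.
#' @param prot an [protocol()].
#' @param snr optional signal-to-noise ratio for Rician noise (`NULL` for
#'   noiseless).
#' @param seed noise seed.
#' @param voxel_size physical voxel size in mm, length 3.
#' @param zero_pad_to FFT length for the encoding spectra.
#' @return list with `volume` (4D array), `sidecar` (data frame with
#'   columns `frame`, `encoding`, `b`, `orientation`), `labels`,
#'   `voxel_size`.
#' @export
render_volume <- function(labels, systems, prot, snr = NULL, seed = 1,
                          voxel_size = c(2, 2, 2), zero_pad_to = 2^21) {
  stopifnot(length(dim(labels)) == 3, inherits(prot, "mde_protocol"))
  labs <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (!all(as.character(labs) %in% names(systems))) {
    stop("systems must name every non-zero label: missing ",
         paste(setdiff(as.character(labs), names(systems)), collapse = ", "))
  }
  n_or <- prot$n_orientations
  b <- c(0, prot$b_values)
  encs <- names(prot$waveforms)
  sidecar <- expand.grid(orientation = seq_len(n_or), b = b,
                         encoding = encs, stringsAsFactors = FALSE)
  sidecar <- sidecar[, c("encoding", "b", "orientation")]
  sidecar$frame <- seq_len(nrow(sidecar))
  vol <- array(0, dim = c(dim(labels), nrow(sidecar)))
  for (l in labs) {
    sig <- predict_signals(systems[[as.character(l)]], prot,
                           keep_orientations = TRUE,
                           zero_pad_to = zero_pad_to)
    per_or <- attr(sig, "per_orientation")
    vox <- which(labels == l)
    for (fi in seq_len(nrow(sidecar))) {
      E <- per_or[[sidecar$encoding[fi]]][sidecar$orientation[fi],
                                          match(sidecar$b[fi], b)]
      slab <- vol[, , , fi, drop = FALSE]
      slab[vox] <- E
      vol[, , , fi] <- slab
    }
  }
  if (!is.null(snr)) vol <- add_rician_noise(vol, snr = snr, seed = seed)
  list(volume = vol, sidecar = sidecar, labels = labels,
       voxel_size = voxel_size)
}

#' Write a rendered volume and label map as NIfTI-1
#'
#' @param rendered output of [render_volume()].
#' @param prefix output path prefix; writes `<prefix>_signal.nii.gz`,
#'   `<prefix>_labels.nii.gz` and `<prefix>_frames.tsv`.
#' @return invisibly, the paths written.
#' @export
write_volume_nifti <- function(rendered, prefix) {
  sig_path <- paste0(prefix, "_signal.nii.gz")
  lab_path <- paste0(prefix, "_labels.nii.gz")
  tsv_path <- paste0(prefix, "_frames.tsv")
  RNifti::writeNifti(RNifti::asNifti(rendered$volume,
                                     pixdim = rendered$voxel_size),
                     sig_path)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(rendered$labels),
                                           dim = dim(rendered$labels)),
                                     pixdim = rendered$voxel_size),
                     lab_path)
  sc <- rendered$sidecar
  sc$b_smm2 <- b_from_si(sc$b)
  write.table(sc, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(sig_path, lab_path, tsv_path))
}
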