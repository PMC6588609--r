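#' Four-phantom, three-encoding survey
#'
#' The end-to-end noiseless experiment on the four phantom archetypes
#' (yeast, microfibers, liquid crystal, polymer): predicts the
#' powder-averaged signal for the isotropic, tuned and detuned encodings at
#' the standard protocol (tau = 23 ms, 12 b-values 240-4800 s/mm^2), and
#' evaluates the two subtraction contrasts and the pairwise divergences
#' that stratify the phantoms by restriction size and microscopic
#' anisotropy. Fully deterministic.
#'
#' @param prot an [protocol()]; default built from the shipped fixture.
#' @param phantoms phantom kinds to include.
#' @param b_star b-value (s/m^2) for the scalar contrasts (default: top of
#'   the b ladder).
#' @param overlap_max,diverge_min thresholds on the maximum signal
#'   difference used for the qualitative overlap / divergence calls.
#' @param zero_pad_to FFT length for the encoding spectra.
#' @param out_dir optional directory to write per-phantom TSV curves into.
#' @return list with `curves` (long data frame: phantom, encoding, b, E),
#'   `contrasts` (data frame: phantom, size, anisotropy, divergence and
#'   overlap metrics plus qualitative calls), `b_star`, `thresholds`.
#' @export
phantom_panel <- function(prot = protocol(),
                          phantoms = c("yeast", "microfibers",
                                       "liquid_crystal", "polymer"),
                          b_star = max(prot$b_values),
                          overlap_max = 0.01, diverge_min = 0.03,
                          zero_pad_to = 2^21, out_dir = NULL) {
  curves_long <- list()
  rows <- list()
  for (ph in phantoms) {
    sys <- make_phantom(ph)
    cv <- predict_signals(sys, prot, zero_pad_to = zero_pad_to)
    for (enc in names(cv)) {
      curves_long[[paste(ph, enc)]] <-
        data.frame(phantom = ph, encoding = enc, b = cv[[enc]]$b,
                   E = cv[[enc]]$E)
    }
    dv_size <- encoding_divergence(cv$tuned, cv$detuned)
    dv_anis <- encoding_divergence(cv$tuned, cv$isotropic)
    rows[[ph]] <- data.frame(
      phantom = ph,
      size = size_contrast(cv$tuned, cv$detuned, b_star)$value,
      anisotropy = anisotropy_contrast(cv$tuned, cv$isotropic,
                                       b_star)$value,
      max_dev_tuned_detuned = dv_size,
      max_dev_tuned_isotropic = dv_anis,
      size_effect = ifelse(dv_size >= diverge_min, "diverge",
                           ifelse(dv_size <= overlap_max, "overlap",
                                  "intermediate")),
      anisotropy_effect = ifelse(dv_anis >= diverge_min, "diverge",
                                 ifelse(dv_anis <= overlap_max, "overlap",
                                        "intermediate")))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      df <- do.call(rbind, lapply(names(cv), function(enc) {
        data.frame(b_smm2 = b_from_si(cv[[enc]]$b), E = cv[[enc]]$E,
                   label = enc)
      }))
      write.table(df, file.path(out_dir, paste0(ph, "_curves.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list(curves = do.call(rbind, curves_long),
       contrasts = do.call(rbind, rows), b_star = b_star,
       thresholds = c(overlap_max = overlap_max, diverge_min = diverge_min))
}

#' Frequency-domain versus Monte Carlo benchmark
#'
#' Cross-validates the two signal engines on the reference restricted
#' systems (sphere and infinite cylinder, R = 2.5 um, D0 = 1e-9 m^2/s,
#' tau = 23 ms): for each encoding it computes the analytic per-orientation
#' ADC from the filter integral and the Monte Carlo ADC from the decay
#' between the two lowest b-values, plus full signal curves, and reports
#' the orientation-averaged agreement as a fraction of D0.
#'
#' @param prot an [protocol()].
#' @param geometries substrate geometries to benchmark.
#' @param R restriction radius (m).
#' @param D0 intrinsic diffusivity (m^2/s).
#' @param n_particles,n_steps Monte Carlo size (defaults sized for desk
#'   use; the reference configuration is 1e5 particles, 5000 steps).
#' @param n_orientations orientation count for both engines.
#' @param seed Monte Carlo seed.
#' @param adc_b upper b-value (s/m^2) of the low-b pair used for the MC ADC.
#' @param zero_pad_to FFT length for the encoding spectra.
#' @return list with `adc` (data frame: geometry, encoding, analytic and MC
#'   mean ADC, `dev_frac_d0`), `curves` (long data frame of powder-averaged
#'   E(b) from both engines), and the settings used.
#' @export
cross_engine_benchmark <- function(prot = protocol(),
                                   geometries = c("sphere", "cylinder"),
                                   R = 2.5e-6, D0 = 1e-9,
                                   n_particles = 1e4, n_steps = 5000,
                                   n_orientations = 15, seed = 1,
                                   adc_b = 1e8, zero_pad_to = 2^21) {
  if (n_particles < 1) stop("n_particles must be at least 1")
  ors <- orientation_set(n_orientations)
  cfg <- walk_config(n_steps = n_steps, n_particles = n_particles,
                     seed = seed, tau = prot$tau)
  b_mc <- sort(unique(c(0, adc_b, prot$b_values)))
  specs <- lapply(prot$waveforms, dephasing_spectrum,
                  zero_pad_to = zero_pad_to)
  adc_rows <- list(); curve_rows <- list()
  for (geom in geometries) {
    model <- make_model(geom, R = R, D0 = D0)
    sub <- substrate(geom, R = R, D0 = D0)
    mc <- mc_signal(sub, cfg, prot$waveforms, b_values = b_mc,
                    orientations = ors)
    mc_adcs <- mc_adc(mc, b_pair = c(0, adc_b))
    for (enc in names(prot$waveforms)) {
      a_or <- adc_by_orientation(specs[[enc]], model, ors)
      m_or <- mc_adcs$adc[mc_adcs$waveform == enc]
      adc_rows[[paste(geom, enc)]] <- data.frame(
        geometry = geom, encoding = enc,
        adc_analytic = mean(a_or), adc_mc = mean(m_or),
        dev_frac_d0 = abs(mean(a_or) - mean(m_or)) / D0)
      # powder-averaged curves from both engines
      Eb_an <- colMeans(exp(-outer(a_or, b_mc)))
      sel <- mc$waveform == enc
      Eb_mc <- vapply(b_mc, function(bb) {
        mean(mc$E[sel & abs(mc$b - bb) <= 1e-9 * max(1, bb)])
      }, numeric(1))
      curve_rows[[paste(geom, enc)]] <- data.frame(
        geometry = geom, encoding = enc, b = b_mc,
        E_analytic = Eb_an, E_mc = Eb_mc)
    }
  }
  list(adc = do.call(rbind, adc_rows),
       curves = do.call(rbind, curve_rows),
       settings = list(R = R, D0 = D0, n_particles = n_particles,
                       n_steps = n_steps, n_orientations = n_orientations,
                       seed = seed, tau = prot$tau))
}
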