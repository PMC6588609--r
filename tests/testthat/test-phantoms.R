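test_that("compartment systems validate fractions", {
  m <- make_model("tensor", eigs = rep(1e-9, 3))
  expect_error(compartment_system(list(list(model = m, fraction = 0.7))),
               "sum to 1")
  expect_error(make_phantom("granite"), "valid kinds")
  sys <- make_phantom("yeast")
  expect_s3_class(sys, "mde_system")
  expect_equal(sum(vapply(sys$components, `[[`, numeric(1), "fraction")), 1)
})

test_that("protocol checks shared tau and b consistency", {
  prot <- protocol(n_orientations = 6)
  expect_equal(prot$tau, 23e-3, tolerance = 1e-6)
  expect_equal(length(prot$b_values), 12)
  expect_equal(b_from_si(range(prot$b_values)), c(240, 4800),
               tolerance = 1e-6)
  short <- waveform(matrix(1e-3 * c(rep(1, 50), rep(-1, 50))), dt = 1e-4)
  expect_error(protocol(waveforms = list(isotropic = fx_iso(),
                                         tuned = fx_tuned(),
                                         detuned = short)),
               "tau")
})

test_that("single free compartment decays as exp(-b D0) for all encodings", {
  prot <- protocol(n_orientations = 4)
  sys <- compartment_system(list(list(
    model = make_model("tensor", eigs = rep(1.2e-9, 3)), fraction = 1)))
  cv <- predict_signals(sys, prot, zero_pad_to = 2^18)
  for (enc in names(cv)) {
    expect_equal(cv[[enc]]$E, exp(-1.2e-9 * cv[[enc]]$b), tolerance = 1e-9)
  }
})

test_that("signal composition is linear in the fractions", {
  prot <- protocol(n_orientations = 5)
  mA <- make_model("sphere", R = 2.5e-6, D0 = 1e-9)
  mB <- make_model("tensor", eigs = c(2e-9, 0.5e-9, 0.5e-9))
  mk <- function(f) compartment_system(list(
    list(model = mA, fraction = f), list(model = mB, fraction = 1 - f)))
  pa <- function(sys) attr(predict_signals(sys, prot,
                                           keep_orientations = TRUE,
                                           zero_pad_to = 2^18),
                           "per_orientation")
  a <- 0.3
  EA <- pa(mk(1)); EB <- pa(mk(0)); EM <- pa(mk(a))
  for (enc in names(EA)) {
    expect_equal(EM[[enc]], a * EA[[enc]] + (1 - a) * EB[[enc]],
                 tolerance = 1e-10)
  }
})

test_that("the four phantoms reproduce the overlap/divergence stratification", {
  prot <- protocol(n_orientations = 12)
  pp <- phantom_panel(prot, zero_pad_to = 2^19)
  ct <- pp$contrasts
  row <- function(ph) ct[ct$phantom == ph, ]
  # polymer: all three encodings give identical curves
  expect_lt(row("polymer")$max_dev_tuned_detuned, 1e-6)
  expect_lt(row("polymer")$max_dev_tuned_isotropic, 1e-6)
  # yeast: tuned and isotropic overlap, detuned diverges upward
  expect_lte(row("yeast")$max_dev_tuned_isotropic, 0.01)
  expect_gte(row("yeast")$max_dev_tuned_detuned, 0.03)
  expect_gt(row("yeast")$size, 0.03)
  # liquid crystal: tuned and detuned overlap, isotropic diverges,
  # and the isotropic decay is nearly mono-exponential
  expect_lte(row("liquid_crystal")$max_dev_tuned_detuned, 0.01)
  expect_gte(row("liquid_crystal")$max_dev_tuned_isotropic, 0.03)
  lc <- pp$curves[pp$curves$phantom == "liquid_crystal" &
                    pp$curves$encoding == "isotropic", ]
  fit <- fit_cumulant3(lc$b[lc$b > 0], lc$E[lc$b > 0])
  expect_lt(abs(fit$c2) * max(lc$b)^2 / 2, 0.02)
  # microfibers: both contrasts strictly positive, size clearly diverging
  expect_gt(row("microfibers")$size, 0)
  expect_gt(row("microfibers")$anisotropy, 0)
  expect_gte(row("microfibers")$max_dev_tuned_detuned, 0.03)
})

test_that("detuned divergence in yeast goes the right way (higher signal)", {
  prot <- protocol(n_orientations = 6)
  cv <- predict_signals(make_phantom("yeast"), prot, zero_pad_to = 2^18)
  top <- length(cv$tuned$E)
  expect_gt(cv$detuned$E[top], cv$tuned$E[top])
})

test_that("rician noise has the documented floor and is reproducible", {
  # snr -> infinity approaches the identity
  x <- c(0.9, 0.5, 0.1)
  expect_equal(add_rician_noise(x, snr = 1e9, seed = 1), x,
               tolerance = 1e-6)
  # zero signal rises to the Rayleigh floor sigma sqrt(pi/2)
  z <- add_rician_noise(rep(0, 2e4), snr = 20, seed = 2)
  expect_equal(mean(z), (1 / 20) * sqrt(pi / 2), tolerance = 0.02)
  # seeded reproducibility
  expect_identical(add_rician_noise(x, snr = 50, seed = 7),
                   add_rician_noise(x, snr = 50, seed = 7))
  expect_error(add_rician_noise(x, snr = -1))
})

test_that("rendered volumes carry region curves and a consistent sidecar", {
  prot <- protocol(b_values = b_to_si(c(240, 800, 2400, 4800)),
                   n_orientations = 3)
  labels <- array(0L, c(4, 3, 1)); labels[1:2, , ] <- 1L; labels[3:4, , ] <- 2L
  systems <- list("1" = make_phantom("yeast"), "2" = make_phantom("polymer"))
  rv <- render_volume(labels, systems, prot, zero_pad_to = 2^18)
  expect_equal(dim(rv$volume), c(4, 3, 1, nrow(rv$sidecar)))
  # single-region voxels carry exactly the predicted per-orientation signal
  sig <- predict_signals(systems[["1"]], prot, keep_orientations = TRUE,
                         zero_pad_to = 2^18)
  po <- attr(sig, "per_orientation")
  fr <- rv$sidecar[rv$sidecar$encoding == "tuned" &
                     rv$sidecar$orientation == 2, ]
  for (i in seq_len(nrow(fr))) {
    bcol <- match(fr$b[i], c(0, prot$b_values))
    expect_equal(rv$volume[1, 1, 1, fr$frame[i]], po$tuned[2, bcol])
  }
  # seeded noisy volume reproducible
  rn1 <- render_volume(labels, systems, prot, snr = 50, seed = 3,
                       zero_pad_to = 2^18)
  rn2 <- render_volume(labels, systems, prot, snr = 50, seed = 3,
                       zero_pad_to = 2^18)
  expect_identical(rn1$volume, rn2$volume)
  # overlapping labels are impossible by construction (single label map),
  # but systems must cover all labels
  expect_error(render_volume(labels, systems["1"], prot,
                             zero_pad_to = 2^18), "label")
})
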