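# Reduced sizes for unit tests; the acceptance suite runs the full
# reference configuration (5000 steps, 1e5 particles).

test_that("free walks obey the Einstein relation", {
  sub <- substrate("free", D0 = 1e-9)
  cfg <- walk_config(n_steps = 400, n_particles = 4000, seed = 3,
                     tau = 20e-3)
  wk <- run_walk(sub, cfg)
  t <- seq_len(400) * cfg$dt
  expect_equal(wk$msd[400], 6e-9 * t[400], tolerance = 3 / sqrt(4000))
  # msd grows linearly: correlation with t essentially 1
  expect_gt(cor(wk$msd, t), 0.999)
})

test_that("restricted walks stay inside and reach the stationary spread", {
  sub <- substrate("sphere", R = 2.5e-6)
  cfg <- walk_config(n_steps = 2000, n_particles = 4000, seed = 9,
                     tau = 120e-3)
  wk <- run_walk(sub, cfg)
  expect_equal(wk$max_outside, 0)
  # long-time MSD from a uniform start -> 2 * 3R^2/5
  target <- 6 * 2.5e-6^2 / 5
  expect_equal(mean(wk$msd[1800:2000]), target, tolerance = 0.05)
  # final positions uniform in the ball: E|r|^2 = 3R^2/5
  r2 <- rowSums(wk$r_final^2)
  expect_equal(mean(r2), 3 * 2.5e-6^2 / 5, tolerance = 0.05)
  # cylinder: bounded transverse, free axial
  cyl <- run_walk(substrate("cylinder", R = 2.5e-6), cfg)
  expect_equal(cyl$max_outside, 0)
  expect_gt(mean(cyl$r_final[, 3]^2), 10 * 2.5e-6^2 / 5)
})

test_that("walks are bitwise reproducible and particle-count stable", {
  sub <- substrate("sphere", R = 2.5e-6)
  cfg <- walk_config(n_steps = 200, n_particles = 500, seed = 21)
  w1 <- run_walk(sub, cfg)
  w2 <- run_walk(sub, cfg)
  expect_identical(w1$r_final, w2$r_final)
  # growing the particle count leaves earlier particles untouched
  cfg2 <- walk_config(n_steps = 200, n_particles = 800, seed = 21)
  w3 <- run_walk(sub, cfg2)
  expect_identical(w3$r_final[1:500, ], w1$r_final)
})

test_that("too-coarse steps near a barrier are refused", {
  sub <- substrate("sphere", R = 1e-7)
  expect_error(run_walk(sub, walk_config(n_steps = 100, n_particles = 10)),
               "RMS step")
})

test_that("mc signal: zero gradient gives E = 1; free diffusion is exponential", {
  cfg <- walk_config(n_steps = 500, n_particles = 5000, seed = 5)
  z <- waveform(matrix(0, 100, 3), dt = 23e-3 / 100)
  res0 <- mc_signal(substrate("free"), cfg, z, b_values = 0)
  expect_identical(res0$E, 1)
  bvals <- b_to_si(c(0, 100, 500, 1500, 4800))
  res <- mc_signal(substrate("free", D0 = 1e-9), cfg, fx_iso(),
                   b_values = bvals)
  pred <- exp(-1e-9 * res$b)
  expect_true(all(abs(res$E - pred) <= 3 * pmax(res$se, 1e-4)))
  # imaginary part vanishes in expectation
  expect_true(all(abs(res$E_imag) < 5 / sqrt(5000)))
  # duration mismatch is an error
  short <- waveform(matrix(1e-3 * c(rep(1, 50), rep(-1, 50))), dt = 1e-4,
                    repair = TRUE)
  expect_error(mc_signal(substrate("free"), cfg, short, b_values = 0),
               "duration")
})

test_that("E(b) is non-increasing in b within Monte Carlo noise", {
  cfg <- walk_config(n_steps = 1000, n_particles = 5000, seed = 13)
  bvals <- b_to_si(c(0, 240, 700, 1600, 3000, 4800))
  res <- mc_signal(substrate("sphere", R = 2.5e-6), cfg, fx_iso(),
                   b_values = bvals,
                   orientations = orientation_set(4))
  for (o in unique(res$orientation)) {
    sel <- res[res$orientation == o, ]
    sel <- sel[order(sel$b), ]
    expect_true(all(diff(sel$E) <= 2 * (sel$se[-1] + sel$se[-nrow(sel)])
                    + 1e-12))
  }
})

test_that("mc adc recovers free and axial diffusivities", {
  cfg <- walk_config(n_steps = 500, n_particles = 8000, seed = 17)
  bvals <- b_to_si(c(0, 100))
  res <- mc_signal(substrate("free", D0 = 1e-9), cfg, fx_tuned(),
                   b_values = bvals)
  a <- mc_adc(res)
  se_adc <- res$se[res$b > 0] / (res$E[res$b > 0] * b_to_si(100))
  expect_equal(a$adc, 1e-9, tolerance = 3 * se_adc / 1e-9)
  # cylinder with its axis along the gradient: unrestricted flow
  cylx <- substrate("cylinder", R = 2.5e-6, D0 = 1e-9)
  rot_axis_x <- euler_zyz(0, pi / 2, 0)  # cylinder z axis -> lab x
  resc <- mc_signal(cylx, walk_config(n_steps = 1000, n_particles = 8000,
                                      seed = 19),
                    fx_tuned(), b_values = bvals,
                    orientations = rot_axis_x)
  ac <- mc_adc(resc)
  expect_equal(ac$adc, 1e-9, tolerance = 0.05)
  # missing b pair is an error
  expect_error(mc_adc(res, b_pair = c(0, 2e8)), "not present")
})

test_that("transverse cylinder ADC agrees with the frequency-domain engine", {
  cfg <- walk_config(n_steps = 2500, n_particles = 2e4, seed = 23)
  bvals <- b_to_si(c(0, 100))
  sub <- substrate("cylinder", R = 2.5e-6, D0 = 1e-9)
  # identity orientation: cylinder axis z, tuned gradient on x -> transverse
  res <- mc_signal(sub, cfg, fx_tuned(), b_values = bvals)
  a_mc <- mc_adc(res)$adc
  a_eq <- adc(fx_spec("tuned"), make_model("cylinder", R = 2.5e-6,
                                           D0 = 1e-9))
  expect_equal(a_mc, a_eq, tolerance = 0.05 * 1e-9 / a_eq)
})
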