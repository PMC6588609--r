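test_that("orientation sets are deterministic and uniform", {
  o1 <- orientation_set(1)
  expect_equal(o1$rotations[[1]], diag(3))
  o <- orientation_set(1000)
  # spherical moment of (n.z)^2 is 1/3
  expect_equal(mean(o$directions[, 3]^2), 1 / 3, tolerance = 1e-3)
  # and of any linear function via a random direction
  set.seed(2)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  expect_equal(mean((o$directions %*% u)^2), 1 / 3, tolerance = 2e-3)
  # frames orthonormal, third axis = direction
  R5 <- o$rotations[[5]]
  expect_equal(crossprod(R5), diag(3), tolerance = 1e-12)
  expect_equal(R5[, 3], o$directions[5, ], tolerance = 1e-12)
  # determinism across calls; seeded random scheme reproducible
  expect_identical(orientation_set(64)$directions, orientation_set(64)$directions)
  r1 <- orientation_set(16, scheme = "random", seed = 4)
  r2 <- orientation_set(16, scheme = "random", seed = 4)
  expect_identical(r1$directions, r2$directions)
})

test_that("powder averaging is the arithmetic mean and respects isotropy", {
  b <- b_to_si(c(0, 1000, 4800))
  E <- rbind(exp(-1e-9 * b), exp(-1e-9 * b))
  pa <- powder_average(E, b = b)
  expect_equal(pa$E, exp(-1e-9 * b))
  # sphere model: any single orientation equals the powder average
  sp <- fx_spec("tuned")
  m <- make_model("sphere", R = 2.5e-6, D0 = 1e-9)
  adcs <- adc_by_orientation(sp, m, orientation_set(8))
  expect_lt(diff(range(adcs)) / mean(adcs), 1e-10)
  # grid mismatch errors
  c1 <- data.frame(b = b, E = exp(-1e-9 * b))
  c2 <- data.frame(b = b * 2, E = exp(-1e-9 * b))
  expect_error(powder_average(list(c1, c2)), "common b grid")
})

test_that("stick moments match the brute-force sphere integral", {
  # oracle: 1e6 uniform directions, ADC(theta) = D0 cos^2(theta)
  set.seed(31)
  z <- runif(1e6, -1, 1)
  adc_o <- 1e-9 * z^2
  m_oracle <- mean(adc_o); v_oracle <- mean((adc_o - m_oracle)^2)
  expect_equal(m_oracle, 1e-9 / 3, tolerance = 2e-3)
  expect_equal(v_oracle, 4 * (1e-9)^2 / 45, tolerance = 5e-3)
  # engine: stick tensor under the tuned (single-axis) encoding
  sp <- fx_spec("tuned")
  stick <- make_model("tensor", eigs = c(1e-9, 0, 0))
  adcs <- adc_by_orientation(sp, stick, orientation_set(2000))
  mom <- adc_moments(adcs)
  expect_equal(mom$mean, 1e-9 / 3, tolerance = 3e-3)
  expect_equal(mom$variance, 4 * (1e-9)^2 / 45, tolerance = 6e-3)
  # degenerate cases
  expect_equal(adc_moments(rep(1e-9, 5))$variance, 0)
})

test_that("cumulant signal matches the exact stick powder at low b", {
  stick <- make_model("tensor", eigs = c(1e-9, 0, 0))
  sp <- fx_spec("tuned")
  adcs <- adc_by_orientation(sp, stick, orientation_set(2000))
  mom <- adc_moments(adcs)
  b_low <- seq(0, 0.5 / mom$mean, length.out = 6)
  exact <- colMeans(exp(-outer(adcs, b_low)))
  approx2 <- cumulant_signal(mom, b_low)
  expect_equal(approx2$E, exact, tolerance = 1e-2)
  expect_equal(approx2$E[1], 1)
  # V_D = 0 collapses to mono-exponential
  mono <- cumulant_signal(adc_moments(rep(1e-9, 3)), b_low)
  expect_equal(mono$E, exp(-1e-9 * b_low))
  # Jensen: exact powder >= mono-exponential at the mean ADC
  b_all <- seq(0, b_to_si(4800), length.out = 12)
  exact_all <- colMeans(exp(-outer(adcs, b_all)))
  expect_true(all(exact_all >= exp(-mom$mean * b_all) - 1e-12))
})

test_that("powder initial slope equals minus the mean ADC", {
  sp <- fx_spec("iso")
  m <- make_model("cylinder", R = 2.5e-6, D0 = 1e-9)
  adcs <- adc_by_orientation(sp, m, orientation_set(64))
  mom <- adc_moments(adcs)
  db <- 1e5                       # small b step, s/m^2
  E <- colMeans(exp(-outer(adcs, c(0, db))))
  slope <- (log(E[2]) - log(E[1])) / db
  expect_equal(-slope, mom$mean, tolerance = 1e-4)
})

test_that("cumulant fit recovers generating coefficients", {
  b <- b_to_si(exp(seq(log(240), log(4800), length.out = 12)))
  # pure mono-exponential: c2, c3 vanish
  S1 <- exp(-0.7e-9 * b)
  f1 <- fit_cumulant3(b, S1)
  expect_equal(f1$c1, 0.7e-9, tolerance = 1e-6)
  expect_lt(abs(f1$c2) * max(b)^2, 1e-5)
  expect_lt(abs(f1$c3) * max(b)^3, 1e-4)
  # full third-order generative identity
  c1 <- 0.9e-9; c2 <- 0.12e-18; c3 <- 0.03e-27; S0 <- 1.7
  S <- S0 * exp(-c1 * b + c2 * b^2 / 2 - c3 * b^3 / 6)
  f <- fit_cumulant3(b, S)
  expect_equal(f$S0, S0, tolerance = 1e-6)
  expect_equal(f$c1, c1, tolerance = 1e-6)
  expect_equal(f$c2, c2, tolerance = 1e-5)
  expect_equal(f$c3, c3, tolerance = 1e-4)
  # scale equivariance: doubling S doubles S0, leaves c_i unchanged
  f2 <- fit_cumulant3(b, 2 * S)
  expect_equal(f2$S0, 2 * S0, tolerance = 1e-6)
  expect_equal(f2$c1, f$c1, tolerance = 1e-8)
  # noisy recovery at SNR 50: bounded by 3x the estimator's spread
  # (the standard error of c1 at this SNR and design is 5-8 % of c1)
  Sn <- add_rician_noise(S / S0, snr = 50, seed = 1) * S0
  fn <- fit_cumulant3(b, Sn)
  expect_lt(abs(fn$c1 - c1) / c1, 0.25)
  expect_error(fit_cumulant3(b[1:3], S1[1:3]))
  expect_error(fit_cumulant3(b, -S1), "positive")
})
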