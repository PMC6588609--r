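test_that("construction validates shape, finiteness and refocusing", {
  # zero waveform is valid and carries b = 0
  w0 <- waveform(matrix(0, 100, 3), dt = 1e-5)
  expect_s3_class(w0, "mde_waveform")
  expect_equal(b_value(b_tensor(w0)), 0)

  # constant offset on one axis violates the echo condition ...
  g <- matrix(0, 100, 3)
  g[, 2] <- 1e-3
  expect_error(waveform(g, dt = 1e-5), "refocusing")
  # ... unless repaired by removing the mean gradient
  wr <- waveform(g, dt = 1e-5, repair = TRUE)
  expect_s3_class(wr, "mde_waveform")

  expect_error(waveform(matrix(0, 100, 2), dt = 1e-5), "axis columns")
  expect_error(waveform(matrix(c(NA, rep(0, 299)), 100, 3), dt = 1e-5),
               "finite")
  expect_error(waveform(matrix(0, 100, 3), dt = -1), "dt")
})

test_that("ideal PGSE b-value matches the textbook closed form", {
  g <- 0.08; delta <- 4e-3; Delta <- 16e-3; dt <- 1e-6
  w <- make_pgse(g, delta, Delta, dt)
  b_closed <- mde_gamma()^2 * g^2 * delta^2 * (Delta - delta / 3)
  expect_equal(b_value(b_tensor(w)), b_closed, tolerance = 1e-2)
  # and the dephasing plateau sits at gamma * g * delta
  Ft <- dephasing_time(w)$values
  plateau <- max(abs(Ft[, 1]))
  expect_equal(plateau, mde_gamma() * g * delta, tolerance = 1e-3)
})

test_that("waveform file io round-trips and flags malformed input", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  w <- fx_iso()
  write_waveform(w, tmp)
  w2 <- read_waveform(tmp, label = "isotropic")
  expect_equal(w2$dt, w$dt)
  expect_equal(b_value(b_tensor(w2)), b_value(b_tensor(w)),
               tolerance = 1e-9)

  # single column promotes to x axis
  tmp1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# dt=1e-4", sprintf("%e", c(0.1, -0.1))), tmp1)
  w1 <- read_waveform(tmp1)
  expect_equal(ncol(w1$g), 3L)
  expect_equal(w1$g[, 2], c(0, 0))

  # malformed row names the line
  tmp2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# dt=1e-4", "0.1 0 0", "oops 0 0", "-0.1 0 0"), tmp2)
  expect_error(read_waveform(tmp2), "line 3")

  # missing dt
  tmp3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.1 0 0", "-0.1 0 0"), tmp3)
  expect_error(read_waveform(tmp3), "dt")
})

test_that("q-MAS generator yields an isotropic, refocused waveform", {
  w <- generate_qmas(tau = 23e-3, dt = 2e-5)
  expect_identical(w$label, "isotropic")
  sh <- b_shape(b_tensor(w))
  expect_lt(sh$spread, 0.05)
  # zero-amplitude request gives a zero waveform
  w0 <- generate_qmas(tau = 23e-3, dt = 2e-5, q0 = 0)
  expect_equal(b_value(b_tensor(w0)), 0)
  # b scales with q0^2
  wa <- generate_qmas(tau = 23e-3, dt = 2e-5, q0 = 1e4)
  wb <- generate_qmas(tau = 23e-3, dt = 2e-5, q0 = 2e4)
  expect_equal(b_value(b_tensor(wb)) / b_value(b_tensor(wa)), 4,
               tolerance = 1e-10)
  # amplitudes above the cap are refused with the offending index
  expect_error(generate_qmas(tau = 23e-3, dt = 2e-5, q0 = 1e7),
               "cap")
})

test_that("tuned derivation is the sqrt(3)-scaled x channel at equal b", {
  iso <- fx_iso(); tun <- fx_tuned()
  expect_identical(tun$label, "tuned")
  expect_equal(tun$g[, 1], sqrt(3) * iso$g[, 1])
  expect_equal(max(abs(tun$g[, 2:3])), 0)
  b_iso <- b_value(b_tensor(iso)); b_tun <- b_value(b_tensor(tun))
  expect_lt(abs(b_tun / b_iso - 1), 0.05)
  # zero input -> zero output
  z <- waveform(matrix(0, 100, 3), dt = 1e-5, label = "isotropic")
  expect_equal(max(abs(derive_tuned(z)$g)), 0)
  # restricted to isotropic inputs (double application is a caller error)
  expect_error(derive_tuned(tun), "isotropic")
})

test_that("detuned derivation preserves b and carries |F| as dephasing", {
  iso <- fx_iso(); det <- fx_detuned()
  expect_identical(det$label, "detuned")
  expect_equal(b_value(b_tensor(det)), b_value(b_tensor(iso)),
               tolerance = 1e-10)
  # its dephasing equals the magnitude of the isotropic dephasing
  Fi <- dephasing_time(iso)$values
  Fd <- dephasing_time(det)$values
  expect_equal(Fd[, 1], sqrt(rowSums(Fi^2)), tolerance = 1e-10)
  # a unipolar single-axis input is reproduced up to sign
  g1 <- c(rep(0.05, 30), rep(-0.05, 30))
  w1 <- waveform(cbind(g1, 0, 0), dt = 1e-4, label = "isotropic")
  d1 <- derive_detuned(w1)
  expect_equal(abs(d1$g[, 1]), abs(w1$g[, 1]), tolerance = 1e-12)
})

test_that("scale_to_b hits the target exactly and flags impossible targets", {
  w <- fx_iso()
  tgt <- b_to_si(4800)
  ws <- scale_to_b(w, tgt)
  expect_equal(b_value(b_tensor(ws)), tgt, tolerance = 1e-10)
  # amplitude scaling s scales b by s^2
  w2 <- w; w2$g <- 2 * w2$g
  expect_equal(b_value(b_tensor(w2)), 4 * b_value(b_tensor(w)),
               tolerance = 1e-12)
  # identity when target equals current
  wi <- scale_to_b(w, b_value(b_tensor(w)))
  expect_equal(wi$g, w$g, tolerance = 1e-12)
  # reaching the top of the protocol b ladder needs > 500 mT/m here
  rep4800 <- gradient_report(ws)
  expect_false(rep4800$within_cap)
  z <- waveform(matrix(0, 100, 3), dt = 1e-5)
  expect_error(scale_to_b(z, 1e8), "zero waveform")
})

test_that("rotation preserves trace(b) and maps axes as expected", {
  w <- fx_iso()
  expect_equal(rotate_waveform(w, diag(3))$g, w$g)
  b0 <- b_value(b_tensor(w))
  set.seed(42)
  for (i in 1:100) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    wr <- rotate_waveform(w, R)
    expect_equal(b_value(b_tensor(wr)), b0, tolerance = 1e-10)
  }
  # b-tensor transforms by similarity
  R <- euler_zyz(0.4, 0.9, -0.2)
  expect_equal(b_tensor(rotate_waveform(w, R))$matrix,
               R %*% b_tensor(w)$matrix %*% t(R), tolerance = 1e-10)
  # 90 degrees about z sends a pure-x waveform to pure y
  wx <- make_pgse()
  Rz <- euler_zyz(pi / 2, 0, 0)
  wy <- rotate_waveform(wx, Rz)
  expect_equal(max(abs(wy$g[, 1])), 0, tolerance = 1e-16)
  expect_equal(wy$g[, 2], wx$g[, 1], tolerance = 1e-12)
  expect_error(rotate_waveform(w, diag(3) * 1.5), "orthonormal")
})

test_that("generated and derived waveforms satisfy the echo condition", {
  for (w in list(fx_iso(), fx_tuned(), fx_detuned(),
                 generate_qmas(tau = 10e-3, dt = 2e-5, n_turns = 3))) {
    area <- abs(colSums(w$g)) * w$dt
    expect_lt(max(area), 1e-9 * max(abs(w$g)) * wf_duration(w))
  }
})
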