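test_that("closed-form I=1/2 frequencies agree with exact diagonalization", {
  # isotropic coupling: nu = |nu_I -/+ a/2|
  nuI <- larmor_frequency("1H", 283.1)
  cf <- closed_form_I12(3.2, 0, 40, nuI)
  expect_equal(unname(cf), c(abs(nuI - 1.6), nuI + 1.6), tolerance = 1e-12)
  # magic angle with a = 0: degenerate pair
  cfm <- closed_form_I12(0, 4.7, 54.7356, nuI)
  expect_equal(cfm[["nu_alpha"]], cfm[["nu_beta"]], tolerance = 1e-4)
  # printed worked example
  cfh <- closed_form_I12(-0.09, 5.60, 22, 12.054)
  expect_equal(unname(cfh), c(8.21, 16.69), tolerance = 1e-2)
  # property: random axial tensors, exact == closed form to 1e-9
  # (free-electron isotropic g so the quantization axis is the field)
  set.seed(11)
  giso <- rep(2.00231930, 3)
  for (k in 1:25) {
    a <- stats::runif(1, -4, 4)
    T_ax <- stats::runif(1, 0.3, 8)
    th <- stats::runif(1, 0, 90)
    B <- stats::runif(1, 150, 1200)
    nuI <- larmor_frequency("1H", B)
    nuc <- nucleus("1H", axial_hyperfine(a, T_ax, 0, 0))
    d <- c(sin(th * pi / 180), 0, cos(th * pi / 180))
    mf <- manifold_frequencies(nuc, B, d, giso)
    ex <- sort(c(mf[[1]]$transitions$freq_MHz, mf[[2]]$transitions$freq_MHz))
    expect_equal(ex, sort(unname(closed_form_I12(a, T_ax, th, nuI))),
                 tolerance = 1e-9)
  }
})

test_that("exact 14N diagonalization reproduces the published dq
           correlation coordinates", {
  B <- resonance_field(2.443, 9.68)
  mf <- manifold_frequencies(n1_nucleus(), B, c(0, 0, 1), rest_g)
  dq <- sort(c(mf[[1]]$transitions$freq_MHz[3],
               mf[[2]]$transitions$freq_MHz[3]), decreasing = TRUE)
  expect_equal(dq[1], 7.00, tolerance = 0.02)
  expect_equal(dq[2], 3.66, tolerance = 0.02)
  # imidazole nitrogen at the g_x position of the least anisotropic species
  g2 <- c(1.902, 2.258, 2.466)
  Bx <- resonance_field(1.902, 9.68)
  mfx <- manifold_frequencies(n3_nucleus(65), Bx, c(1, 0, 0), g2)
  dqx <- sort(c(mfx[[1]]$transitions$freq_MHz[3],
                mfx[[2]]$transitions$freq_MHz[3]))
  expect_equal(dqx[1], 2.23, tolerance = 0.2)
})

test_that("dq estimate matches its closed form and the exact values in the
           strong-coupling regime", {
  expect_equal(unname(dq_estimate(5.10, 0.45, 1 / 3, 0.871)),
               c(7.02, 3.71), tolerance = 1e-2)
  expect_equal(unname(dq_estimate(3.27, 0.55, 0.455, 1.119)),
               c(5.85, 2.22), tolerance = 1e-2)
  # K = 0 reduces to the pure Zeeman+hyperfine expression
  expect_equal(unname(dq_estimate(4, 0, 0, 1.1)),
               c(2 * (1.1 + 2), 2 * abs(1.1 - 2)))
  # quadrupole_K from principal values
  kk <- quadrupole_K(c(0.90, -0.60, -0.30))
  expect_equal(unname(kk), c(0.45, 1 / 3), tolerance = 1e-12)
  # agreement with exact diagonalization within 5% when |A| > 4 nu_I and
  # the quadrupole is much smaller than the hyperfine coupling
  set.seed(23)
  for (k in 1:10) {
    A <- stats::runif(1, 4, 8)
    Kq <- stats::runif(1, 0.05, 0.25)
    eta <- stats::runif(1, 0, 0.8)
    B <- stats::runif(1, 250, 350)
    nuI <- larmor_frequency("14N", B)
    if (A < 4 * nuI) next
    qz <- 2 * Kq
    qx <- -qz * (1 + eta) / 2
    qy <- -qz * (1 - eta) / 2
    nuc <- nucleus("14N",
                   interaction_tensor(c(-A, -A, -A)),
                   interaction_tensor(c(qx, qy, qz), kind = "quadrupole"))
    mf <- manifold_frequencies(nuc, B, c(0, 0, 1), rep(2.0023, 3))
    ex <- sort(c(mf[[1]]$transitions$freq_MHz[3],
                 mf[[2]]$transitions$freq_MHz[3]))
    est <- sort(unname(dq_estimate(A, Kq, eta, nuI)))
    expect_equal(ex, est, tolerance = 0.05)
  }
})

test_that("manifold structure obeys the spin-1 identities and symmetries", {
  B <- resonance_field(2.443, 9.68)
  mf <- manifold_frequencies(n1_nucleus(), B, c(0, 0, 1), rest_g)
  for (m in mf) {
    tr <- m$transitions
    expect_true(all(tr$freq_MHz >= 0))
    expect_equal(tr$freq_MHz[tr$type == "dq"],
                 sum(tr$freq_MHz[tr$type != "dq"]), tolerance = 1e-6)
  }
  # exchanging the sign of the hyperfine tensor swaps the two manifolds
  nflip <- nucleus("14N",
                   interaction_tensor(c(4.90, 4.80, 5.10), c(90, 0, 0)),
                   interaction_tensor(c(0.90, -0.60, -0.30), c(90, 0, 0),
                                      "quadrupole"))
  mf2 <- manifold_frequencies(nflip, B, c(0, 0, 1), rest_g)
  expect_equal(mf[[1]]$transitions$freq_MHz, mf2[[2]]$transitions$freq_MHz,
               tolerance = 1e-9)
  expect_equal(mf[[2]]$transitions$freq_MHz, mf2[[1]]$transitions$freq_MHz,
               tolerance = 1e-9)
})

test_that("frequencies are covariant under rigid rotation about the field
           frame", {
  # isotropic g: rotating tensor frames and the field direction together
  # must leave all transition frequencies unchanged
  giso <- rep(2.0023, 3)
  B <- 330
  d <- c(0.48, -0.36, sqrt(1 - 0.48^2 - 0.36^2))
  base <- nucleus("14N",
                  interaction_tensor(c(-3.57, -3.20, -2.54), c(20, 35, 0)),
                  interaction_tensor(c(0.30, 0.80, -1.10), c(20, 35, 0),
                                     "quadrupole"))
  ref <- manifold_frequencies(base, B, d, giso)
  for (phi in c(25, 111, -70)) {
    rot <- nucleus("14N",
                   interaction_tensor(c(-3.57, -3.20, -2.54),
                                      c(20 + phi, 35, 0)),
                   interaction_tensor(c(0.30, 0.80, -1.10),
                                      c(20 + phi, 35, 0), "quadrupole"))
    dr <- as.vector(t(euler_matrix(phi, 0, 0)) %*% d)
    got <- manifold_frequencies(rot, B, dr, giso)
    expect_equal(got[[1]]$transitions$freq_MHz,
                 ref[[1]]$transitions$freq_MHz, tolerance = 1e-9)
    expect_equal(got[[2]]$transitions$freq_MHz,
                 ref[[2]]$transitions$freq_MHz, tolerance = 1e-9)
  }
})

test_that("coupling regimes are classified as observed at X- and Q-band", {
  obsX <- observer(9.68, g_obs = rest_g[3])
  obsQ <- observer(34, g_obs = rest_g[3])
  expect_equal(classify_regime(n1_nucleus(), obsX, rest_g)$label, "strong")
  expect_equal(classify_regime(n1_nucleus(), obsQ, rest_g)$label,
               "near-cancellation")
  expect_equal(classify_regime(h1_nucleus(), obsX, rest_g)$label, "weak")
})
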