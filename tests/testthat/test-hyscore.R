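test_that("a system without nuclei gives a constant unit echo", {
  ss <- spin_system(rest_g)
  tr <- time_domain(ss, observer(9.68, g_obs = rest_g[3]),
                    t_ns = seq(0, 496, 16))
  expect_true(all(tr$trace == 1))
})

test_that("analytic I=1/2 propagation equals the density-matrix route", {
  ss <- spin_system(rest_g, list(h1_nucleus()))
  obs <- observer(9.68, g_obs = rest_g[3], tau_ns = 136)
  t_ns <- seq(0, 496, 16)
  a <- time_domain(ss, obs, t_ns = t_ns, knots = 9)
  b <- time_domain(ss, obs, t_ns = t_ns, knots = 9, propagator = "eigen")
  expect_lt(max(abs(a$trace - b$trace)), 1e-8)
})

test_that("the processed trace shows the proton cross peak at the exact
           nuclear frequencies", {
  ss <- spin_system(rest_g, list(h1_nucleus()))
  obs <- observer(9.68, g_obs = rest_g[3], tau_ns = 136)
  tr <- time_domain(ss, obs, tau_ns = 136, t_ns = seq(0, 2032, 16),
                    knots = 13)
  sp <- process_2d(tr)
  pk <- pick_peaks(sp, threshold_rel = 0.25, min_sep_MHz = 1.5)
  off <- pk[pk$nu1_MHz > 1 & pk$nu2_MHz > 1, ]
  expect_gte(nrow(off), 2)
  # strongest off-axis peaks at (nu_alpha, nu_beta) of the single-crystal
  # position, ~(16.7, 8.2) MHz, within a frequency bin
  bin <- diff(sp$f1_MHz[1:2])
  top <- off[1:2, ]
  hit <- function(nu1, nu2) {
    any(abs(top$nu1_MHz - nu1) < bin & abs(top$nu2_MHz - nu2) < bin)
  }
  cf <- closed_form_I12(-0.09, 5.60, 22, larmor_frequency("1H", obs$field_mT))
  expect_true(hit(cf[["nu_beta"]], cf[["nu_alpha"]]))
  expect_true(hit(cf[["nu_alpha"]], cf[["nu_beta"]]))
})

test_that("tau blind spots suppress cross peaks and multi-tau summation
           restores coverage", {
  ss <- spin_system(rest_g, list(h1_nucleus()))
  obs <- observer(9.68, g_obs = rest_g[3])
  cf <- closed_form_I12(-0.09, 5.60, 22, larmor_frequency("1H", obs$field_mT))
  nua <- cf[["nu_alpha"]]
  tau_blind <- 2 / nua * 1e3              # sin(pi nu_alpha tau) = 0
  tau_good <- 0.5 / nua * 1e3             # |sin| = 1
  expect_lt(abs(blind_spot_factor(nua, tau_blind)), 1e-6)
  peak_amp <- function(tau) {
    tr <- time_domain(ss, obs, tau_ns = tau, t_ns = seq(0, 1008, 16),
                      knots = 9)
    sp <- process_2d(tr)
    i <- which.min(abs(sp$f1_MHz - cf[["nu_beta"]]))
    j <- which.min(abs(sp$f2_MHz - nua))
    max(sp$magnitude[i + (-1:1), j + (-1:1)])
  }
  expect_lt(peak_amp(tau_blind), 0.15 * peak_amp(tau_good))
  # worst-case suppression over a frequency band decreases as tau values
  # are added (monotone coverage)
  nus <- seq(2, 20, by = 0.1)
  taus <- c(96, 136, 208, 250)
  worst <- vapply(seq_along(taus), function(k) {
    cover <- apply(vapply(taus[1:k],
                          function(tt) abs(blind_spot_factor(nus, tt)),
                          numeric(length(nus))), 1, max)
    min(cover)
  }, numeric(1))
  expect_true(all(diff(worst) >= 0))
  expect_gt(worst[4], worst[1])
})

test_that("cross-peak lists have mirror symmetry and regime-consistent
           quadrants", {
  fx <- heme_fixture("resting_state_h2o")
  pk <- cross_peaks(fx$system, fx$observers$gz, knots = 13)
  # every peak has its mirror partner
  key <- paste(round(pk$nu1_MHz, 9), round(pk$nu2_MHz, 9), pk$nucleus,
               pk$quadrant)
  mirror_key <- paste(round(pk$nu2_MHz, 9), round(pk$nu1_MHz, 9),
                      pk$nucleus, pk$quadrant)
  expect_true(all(mirror_key %in% key))
  # weakly coupled protons in (+,+); strongly coupled nitrogens in (-,+)
  expect_true(all(pk$quadrant[pk$nucleus %in% c("H1", "H2", "H3")] == "++"))
  expect_true(all(pk$quadrant[pk$nucleus %in% c("N1", "N2")] == "-+"))
})

test_that("weak-coupling proton ridges sit at or above the antidiagonal", {
  fx <- heme_fixture("resting_state_h2o")
  for (onm in c("gz", "gx")) {
    obs <- fx$observers[[onm]]
    nuH <- larmor_frequency("1H", obs$field_mT)
    pk <- cross_peaks(fx$system, obs, knots = 13)
    pr <- pk[pk$nucleus %in% c("H1", "H2", "H3"), ]
    expect_true(all(pr$nu1_MHz + pr$nu2_MHz >= 2 * nuH - 1e-6))
  }
  # zero anisotropy touches the antidiagonal exactly
  nuc0 <- nucleus("1H", axial_hyperfine(1.4, 0))
  ss0 <- spin_system(rest_g, list(nuc0))
  pk0 <- cross_peaks(ss0, fx$observers$gz, knots = 9)
  nuH <- larmor_frequency("1H", fx$observers$gz$field_mT)
  expect_equal(min(pk0$nu1_MHz + pk0$nu2_MHz), 2 * nuH, tolerance = 1e-6)
})

test_that("uncoupled nuclei collapse onto the Larmor diagonal with zero
           amplitude", {
  nuc <- nucleus("1H", axial_hyperfine(0, 0))
  ss <- spin_system(rest_g, list(nuc))
  obs <- observer(9.68, g_obs = rest_g[3])
  pk <- cross_peaks(ss, obs, knots = 9)
  nuH <- larmor_frequency("1H", obs$field_mT)
  expect_equal(pk$nu1_MHz, rep(nuH, nrow(pk)), tolerance = 1e-9)
  expect_equal(pk$nu2_MHz, rep(nuH, nrow(pk)), tolerance = 1e-9)
  expect_equal(max(pk$amplitude), 0, tolerance = 1e-12)
})

test_that("strong-coupling dq-dq correlations lie on the 4 nu_I lines", {
  fx <- heme_fixture("resting_state_h2o")
  for (onm in c("gz", "gy", "gx")) {
    obs <- fx$observers[[onm]]
    nuN <- larmor_frequency("14N", obs$field_mT)
    pk <- cross_peaks(fx$system, obs, knots = 13)
    dq <- pk[pk$type == "dq-dq" & pk$nucleus %in% c("N1", "N2"), ]
    expect_gt(nrow(dq), 0)
    expect_true(all(abs(abs(dq$nu1_MHz - dq$nu2_MHz) - 4 * nuN) < 0.55))
  }
})

test_that("combination peaks follow the multi-nuclear sum rules", {
  fx <- heme_fixture("resting_state_h2o")
  obs <- fx$observers$gz
  fr <- dq_table(fx$system, obs$field_mT, c(0, 0, 1))
  expect_named(fr, c("N1", "N2"))
  cp <- combination_peaks(fr, rules = c("2dq_same", "dq_sum_pair"))
  # two equivalent N1 produce a cluster near (14, 3.7): 2 dq in one
  # manifold against dq in the other
  two <- cp[cp$type == "2dq-dq" & cp$nucleus == "N1", ]
  expect_gt(nrow(two), 0)
  expect_true(any(abs(two$nu1_MHz - 14.0) < 0.25 &
                  abs(two$nu2_MHz - 3.68) < 0.25))
  # mixed-pair sums exist for N1+N2
  expect_gt(nrow(cp[cp$type == "dqsum-dq", ]), 0)
  # a single non-equivalent nucleus cannot give 2dq peaks
  fr1 <- fr["N2"]
  expect_equal(nrow(combination_peaks(fr1, rules = "2dq_same")), 0)
  # larmor rule requires the Larmor frequency
  expect_error(combination_peaks(fr, rules = "larmor_plus_dq"),
               "larmor_MHz")
  cl <- combination_peaks(fr, rules = "larmor_plus_dq",
                          larmor_MHz = larmor_frequency("1H", obs$field_mT))
  expect_gt(nrow(cl), 0)
})

test_that("the exact multi-nucleus product trace contains combination
           frequencies of the equivalent nitrogen pair", {
  # two equivalent N1 nuclei: the 2dq sum appears in the processed
  # spectrum near 14 MHz
  obs <- observer(9.68, g_obs = rest_g[3], tau_ns = 208)
  cluster <- function(n_equiv) {
    ss <- spin_system(rest_g, list(n1_nucleus(n_equiv = n_equiv)))
    sp <- process_2d(time_domain(ss, obs, tau_ns = 208,
                                 t_ns = seq(0, 2032, 16), knots = 9))
    max(sp$magnitude[sp$f1_MHz > 13 & sp$f1_MHz < 15,
                     sp$f2_MHz > 3 & sp$f2_MHz < 4.4])
  }
  pair <- cluster(2)
  single <- cluster(1)
  # the 2dq sum cluster is a genuine multi-spin feature: strong for the
  # equivalent pair, absent (up to leakage) for a single nucleus
  expect_gt(pair, 5 * single)
})

test_that("Nyquist violations are rejected", {
  ss <- spin_system(rest_g, list(h1_nucleus()))
  obs <- observer(9.68, g_obs = rest_g[3])
  expect_error(time_domain(ss, obs, t_ns = seq(0, 2000, 40), knots = 9),
               "Nyquist")
})
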