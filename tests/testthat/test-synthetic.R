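test_that("fixtures carry the published tensor sets", {
  fx <- heme_fixture("resting_state_h2o")
  expect_equal(fx$system$g, c(1.923, 2.253, 2.443))
  labels <- vapply(fx$system$nuclei, function(n) n$label, "")
  expect_setequal(labels, c("H1", "H2", "H3", "N1", "N2"))
  h1 <- fx$system$nuclei[[match("H1", labels)]]
  expect_equal(mean(h1$A$principal), -0.09, tolerance = 1e-9)
  expect_equal((h1$A$principal[3] - mean(h1$A$principal)) / 2, 5.60,
               tolerance = 1e-9)
  expect_equal(h1$A$euler[1:2], c(0, 22))
  n1 <- fx$system$nuclei[[match("N1", labels)]]
  expect_equal(n1$n_equivalent, 2L)
  expect_equal(n1$A$principal, c(-4.90, -4.80, -5.10))
  expect_equal(n1$Q$euler[1], 90)
  im2 <- heme_fixture("imidazole_2")
  l2 <- vapply(im2$system$nuclei, function(n) n$label, "")
  n3 <- im2$system$nuclei[[match("N3", l2)]]
  expect_equal(n3$Q$principal, c(0.30, 0.80, -1.10))
  expect_equal(n3$Q$euler[1], 65)
  expect_equal(im2$system$g, c(1.902, 2.258, 2.466))
  im15 <- heme_fixture("imidazole_15N")
  l15 <- vapply(im15$system$nuclei, function(n) n$label, "")
  n4 <- im15$system$nuclei[[match("N4", l15)]]
  expect_equal(n4$isotope$spin, 0.5)
  expect_null(n4$Q)
  expect_equal(n4$A$principal, c(5.00, 4.48, 3.56))
  # deuterated fixture: scaled protons plus the small water quadrupole
  d2o <- heme_fixture("resting_state_d2o")
  ld <- vapply(d2o$system$nuclei, function(n) n$label, "")
  d1 <- d2o$system$nuclei[[match("D1", ld)]]
  expect_equal((d1$A$principal[3] - mean(d1$A$principal)) / 2, 0.860,
               tolerance = 0.002)
  expect_equal(d1$Q$principal, c(0.1, -0.06, -0.04))
  expect_error(heme_fixture("nonesuch"), "unknown fixture")
})

test_that("the CW generator produces the powder turning points and
           respects weights", {
  s <- cw_powder_spectrum(list(rest_g), linewidth_mT = 1.5,
                          n_points = 1024, knots = 151)
  bz <- resonance_field(rest_g[3], 9.68)
  expect_lt(abs(s$field_mT[which.max(s$spectrum)] - bz), 1)
  # features present near all three canonical fields
  for (gv in rest_g) {
    b <- resonance_field(gv, 9.68)
    win <- abs(s$field_mT - b) < 4
    expect_gt(max(abs(s$spectrum[win])), 0.05 * max(abs(s$spectrum)))
  }
  z <- cw_powder_spectrum(list(rest_g), weights = 0, noise = 0,
                          n_points = 128, knots = 41)
  expect_true(all(z$spectrum == 0))
})

test_that("dataset generation is seed-deterministic and noise-additive", {
  a <- simulate_dataset("resting_state_h2o", "gz", noise_sigma = 0.05,
                        seed = 4, t_ns = seq(0, 496, 16), knots = 7,
                        nuclei = "H1")
  b <- simulate_dataset("resting_state_h2o", "gz", noise_sigma = 0.05,
                        seed = 4, t_ns = seq(0, 496, 16), knots = 7,
                        nuclei = "H1")
  expect_identical(a$traces$gz$trace, b$traces$gz$trace)
  c0 <- simulate_dataset("resting_state_h2o", "gz", noise_sigma = 0,
                         seed = 4, t_ns = seq(0, 496, 16), knots = 7,
                         nuclei = "H1")
  fx <- heme_fixture("resting_state_h2o")
  sysH <- spin_system(fx$system$g, fx$system$nuclei[1])
  direct <- time_domain(sysH, fx$observers$gz,
                        tau_ns = fx$observers$gz$tau_ns[1],
                        t_ns = seq(0, 496, 16), knots = 7)
  expect_equal(c0$traces$gz$trace, direct$trace, tolerance = 1e-12)
  expect_false(identical(a$traces$gz$trace, c0$traces$gz$trace))
})

test_that("the full pipeline recovers the generating distance from a
           noisy powder dataset", {
  # near-isotropic g so the whole powder ridge is excited; coupling with
  # a_iso > T so the alpha/beta assignment never crosses the diagonal and
  # the squared-frequency ridge is a single straight line
  a_true <- 3.0; T_true <- 2.0
  ss <- spin_system(iso_g, list(nucleus("1H",
                                        axial_hyperfine(a_true, T_true),
                                        label = "Hx")))
  obs <- observer(9.68, g_obs = iso_g[2], tau_ns = c(120, 184))
  t_ns <- seq(0, 1264, 16)
  trs <- lapply(c(120, 184), function(tau) {
    time_domain(ss, obs, tau_ns = tau, t_ns = t_ns, knots = 7)
  })
  # noise at SNR 20 relative to the modulation amplitude
  sig <- max(abs(trs[[1]]$trace - mean(trs[[1]]$trace)))
  set.seed(5)
  for (i in seq_along(trs)) {
    trs[[i]]$trace <- trs[[i]]$trace +
      matrix(stats::rnorm(length(trs[[i]]$trace), 0, sig / 20),
             nrow(trs[[i]]$trace))
  }
  sp <- sum_spectra(lapply(trs, process_2d, zerofill = 4))
  nuH <- larmor_frequency("1H", obs$field_mT)
  pk <- pick_peaks(sp, threshold_rel = 0.15, min_sep_MHz = 0.6)
  hi <- pmax(pk$nu1_MHz, pk$nu2_MHz)
  lo <- pmin(pk$nu1_MHz, pk$nu2_MHz)
  sel <- abs(hi + lo - 2 * nuH) < 3 & hi - lo > 1.2 & lo > 5
  arm <- data.frame(nu1 = hi[sel], nu2 = lo[sel],
                    amp = pk$amplitude[sel])
  arm <- unique(arm[arm$amp > 0.4 * max(arm$amp), 1:2])
  expect_gte(nrow(arm), 2)
  fit <- fit_ridge(nu2_transform(arm), nuH)
  r_rec <- suppressWarnings(r_from_T(abs(fit$T_ax[1])))
  expect_equal(r_rec, r_from_T(T_true), tolerance = 0.05 / r_from_T(T_true))
  expect_lt(abs(r_rec - r_from_T(T_true)), 0.05)
})

test_that("run_pipeline validates configuration and reproduces itself", {
  expect_error(run_pipeline(list(observers = "gz")), "fixture")
  expect_error(run_pipeline(list(fixture = "resting_state_h2o",
                                 observers = character(0))), "empty")
  cfg <- list(fixture = "resting_state_h2o", observers = "gz",
              nuclei = "H1", seed = 3, t_ns = seq(0, 496, 16), knots = 7)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$peaks$gz, r2$peaks$gz)
  expect_s3_class(r1$geometry, "data.frame")
  expect_true("H1" %in% r1$geometry$label)
  # output files are written when requested
  out <- file.path(tempdir(), "pipe-out")
  cfg$outdir <- out
  run_pipeline(cfg)
  expect_true(file.exists(file.path(out, "peaks_gz.csv")))
  expect_true(file.exists(file.path(out, "config.json")))
})
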