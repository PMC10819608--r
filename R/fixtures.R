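# tensor sets of the CYP116B5hd heme center; all couplings in MHz,
# angles in degrees relative to the g-frame
.fixture_names <- c("resting_state_h2o", "resting_state_d2o",
                    "imidazole_1", "imidazole_2", "imidazole_15N")

.heme_nitrogens <- function() {
  list(
    nucleus("14N",
            interaction_tensor(c(-4.90, -4.80, -5.10), c(90, 0, 0),
                               "hyperfine"),
            interaction_tensor(c(0.90, -0.60, -0.30), c(90, 0, 0),
                               "quadrupole"),
            label = "N1", n_equivalent = 2),
    nucleus("14N",
            interaction_tensor(c(-4.80, -4.70, -5.80), c(0, 0, 0),
                               "hyperfine"),
            interaction_tensor(c(1.00, -0.60, -0.40), c(0, 0, 0),
                               "quadrupole"),
            label = "N2")
  )
}

.imidazole_nitrogen <- function(alpha, labelled_15N = FALSE) {
  if (labelled_15N) {
    nucleus("15N",
            interaction_tensor(c(5.00, 4.48, 3.56), c(alpha, 0, 0),
                               "hyperfine"),
            NULL, label = "N4")
  } else {
    nucleus("14N",
            interaction_tensor(c(-3.57, -3.20, -2.54), c(alpha, 0, 0),
                               "hyperfine"),
            interaction_tensor(c(0.30, 0.80, -1.10), c(alpha, 0, 0),
                               "quadrupole"),
            label = "N3")
  }
}

#' Reference spin-system fixtures of the CYP116B5hd heme center
#'
#' Fully parameterized spin systems of the low-spin ferric heme of
#' CYP116B5hd as determined by multifrequency HYSCORE: the substrate-free
#' resting state in aqueous or deuterated buffer (axial water protons
#' H1/H2 or deuterons D1/D2, cysteine beta proton H3, two sets of heme
#' nitrogens N1 x2 equivalents and N2), and the two imidazole-bound
#' species with the axial imidazole nitrogen (14N as N3, or 15N as N4 for
#' the labelled inhibitor) and the imidazole ring proton H4. Deuteron
#' hyperfine tensors are the proton ones rescaled by the nuclear
#' g-factors, with a small quadrupole coupling (0.1, -0.06, -0.04) MHz.
#'
#' Each fixture carries observers at the three principal g positions of
#' an X-band (9.68 GHz) spectrum, with the tau values used for the
#' corresponding published panels, and a `truth` record with the
#' generating parameters for end-to-end recovery tests.
#'
#' @param name one of `"resting_state_h2o"`, `"resting_state_d2o"`,
#'   `"imidazole_1"`, `"imidazole_2"`, `"imidazole_15N"`
#' @return A list of class `heme_fixture` with `name`, `system`
#'   ([spin_system()]), `observers` (named list of [observer()], one per
#'   principal g position), `truth` (data frame of proton/deuteron
#'   parameters) and `temperature_K` (metadata only; relaxation is not
#'   modeled).
#' @examples
#' fx <- heme_fixture("resting_state_h2o")
#' fx$system
#' @export
heme_fixture <- function(name) {
  if (!name %in% .fixture_names) {
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixture_names, collapse = ", "))
  }
  g_rest <- c(1.923, 2.253, 2.443)
  g_im1 <- c(1.857, 2.258, 2.589)
  g_im2 <- c(1.902, 2.258, 2.466)
  protons_h <- list(
    nucleus("1H", axial_hyperfine(-0.09, 5.60, 0, 22), label = "H1"),
    nucleus("1H", axial_hyperfine(-1.095, 5.20, 0, 16), label = "H2"),
    nucleus("1H", axial_hyperfine(0.79, 2.60, 0, 47), label = "H3"))
  d_quad <- interaction_tensor(c(0.1, -0.06, -0.04), c(0, 0, 0),
                               "quadrupole")
  deuterons <- list(
    nucleus("2H", isotope_rescale(axial_hyperfine(-0.09, 5.60, 0, 22),
                                  "1H", "2H"), d_quad, label = "D1"),
    nucleus("2H", isotope_rescale(axial_hyperfine(-1.095, 5.20, 0, 16),
                                  "1H", "2H"), d_quad, label = "D2"),
    nucleus("1H", axial_hyperfine(0.79, 2.60, 0, 47), label = "H3"))
  h4 <- function(alpha) {
    nucleus("1H", axial_hyperfine(1.76, 2.66, alpha, 40), label = "H4")
  }
  def <- switch(
    name,
    resting_state_h2o = list(g = g_rest,
                             nuclei = c(protons_h, .heme_nitrogens())),
    resting_state_d2o = list(g = g_rest,
                             nuclei = c(deuterons, .heme_nitrogens())),
    imidazole_1 = list(g = g_im1,
                       nuclei = c(list(h4(-60)), .heme_nitrogens(),
                                  list(.imidazole_nitrogen(30)))),
    imidazole_2 = list(g = g_im2,
                       nuclei = c(list(h4(-25)), .heme_nitrogens(),
                                  list(.imidazole_nitrogen(65)))),
    imidazole_15N = list(g = g_im2,
                         nuclei = c(list(h4(-25)), .heme_nitrogens(),
                                    list(.imidazole_nitrogen(
                                      65, labelled_15N = TRUE))))
  )
  sys <- spin_system(def$g, def$nuclei)
  taus <- list(gz = c(208, 250), gy = 250, gx = 250)
  obs <- list(
    gz = observer(9.68, g_obs = sys$g[3], tau_ns = taus$gz, label = "gz"),
    gy = observer(9.68, g_obs = sys$g[2], tau_ns = taus$gy, label = "gy"),
    gx = observer(9.68, g_obs = sys$g[1], tau_ns = taus$gx, label = "gx"))
  truth <- do.call(rbind, lapply(def$nuclei, function(n) {
    pv <- n$A$principal
    data.frame(label = n$label, isotope = n$isotope$name,
               a_iso = mean(pv),
               T_ax = (pv[3] - mean(pv)) / 2,
               alpha = n$A$euler[1], beta = n$A$euler[2],
               n_equivalent = n$n_equivalent)
  }))
  structure(list(name = name, system = sys, observers = obs,
                 truth = truth, temperature_K = 10),
            class = "heme_fixture")
}

#' Simulate a rhombic powder CW-EPR spectrum
#'
#' First-derivative powder pattern of one or more S = 1/2 species with
#' rhombic g, each broadened by a Gaussian field-domain kernel, weighted
#' and summed, with optional additive white Gaussian noise. The stick
#' pattern is accumulated over a dense deterministic orientation grid.
#'
#' @param g_sets list of numeric length-3 g-sets
#' @param weights non-negative species weights
#' @param linewidth_mT Gaussian FWHM in mT (scalar or per species)
#' @param mw_freq_GHz microwave frequency in GHz
#' @param field_mT field axis; defaults to a grid spanning all species
#' @param n_points grid length when `field_mT` is not supplied
#' @param noise standard deviation of additive Gaussian noise relative to
#'   the peak-to-peak signal amplitude
#' @param seed RNG seed used for the noise (ignored when `noise = 0`)
#' @param knots orientation grid density
#' @return A list of class `cw_spectrum` with `field_mT`, `spectrum`
#'   (first derivative, arbitrary units) and the generation parameters.
#' @export
cw_powder_spectrum <- function(g_sets, weights = 1, linewidth_mT = 2,
                               mw_freq_GHz = 9.68, field_mT = NULL,
                               n_points = 1024, noise = 0, seed = 1,
                               knots = 201) {
  if (is.numeric(g_sets) && length(g_sets) == 3) g_sets <- list(g_sets)
  nsp <- length(g_sets)
  if (length(weights) == 1) weights <- rep(weights, nsp)
  if (length(linewidth_mT) == 1) linewidth_mT <- rep(linewidth_mT, nsp)
  stopifnot(all(weights >= 0), length(weights) == nsp)
  if (is.null(field_mT)) {
    ball <- range(unlist(lapply(g_sets, resonance_field, mw_freq_GHz)))
    pad <- 6 * max(linewidth_mT)
    field_mT <- seq(ball[1] - pad, ball[2] + pad, length.out = n_points)
  }
  grid <- sphere_grid(knots)
  absorb <- numeric(length(field_mT))
  db <- diff(field_mT[1:2])
  for (i in seq_len(nsp)) {
    if (weights[i] == 0) next
    geff <- g_effective(sort(g_sets[[i]]), grid$directions)
    bres <- resonance_field(geff, mw_freq_GHz)
    stick <- numeric(length(field_mT))
    idx <- findInterval(bres, c(field_mT - db / 2, Inf))
    ok <- idx >= 1 & idx <= length(field_mT)
    stick[sort(unique(idx[ok]))] <-
      vapply(sort(unique(idx[ok])),
             function(k) sum(grid$weights[ok][idx[ok] == k]), numeric(1))
    # Gaussian convolution
    sg <- linewidth_mT[i] / (2 * sqrt(2 * log(2)))
    kx <- seq(-4 * sg, 4 * sg, by = db)
    kern <- exp(-kx^2 / (2 * sg^2)); kern <- kern / sum(kern)
    sm <- stats::filter(stick, kern, sides = 2)
    sm[is.na(sm)] <- 0
    absorb <- absorb + weights[i] * as.numeric(sm)
  }
  deriv <- c(0, diff(absorb)) / db
  if (noise > 0) {
    set.seed(seed)
    pp <- max(deriv) - min(deriv)
    deriv <- deriv + stats::rnorm(length(deriv), 0, noise * pp)
  }
  structure(list(field_mT = field_mT, spectrum = deriv,
                 params = list(g_sets = g_sets, weights = weights,
                               linewidth_mT = linewidth_mT,
                               mw_freq_GHz = mw_freq_GHz, noise = noise,
                               seed = seed)),
            class = "cw_spectrum")
}

#' Generate a synthetic HYSCORE dataset with known ground truth
#'
#' Wraps [time_domain()] for the observers of a fixture, adds white
#' Gaussian noise, and stores the generating parameters. Regeneration
#' with the same seed is bit-identical.
#'
#' @param fixture a [heme_fixture()] or fixture name
#' @param observer_names subset of `names(fixture$observers)`
#' @param noise_sigma noise standard deviation (echo units; the
#'   unmodulated echo is 1)
#' @param seed RNG seed
#' @param t_ns,knots forwarded to [time_domain()]
#' @param nuclei optional subset of nucleus labels to include
#' @return A list of class `synthetic_dataset` with `traces` (named list
#'   of `hyscore_trace`), `noise_sigma`, `seed`, `truth`.
#' @export
simulate_dataset <- function(fixture, observer_names = "gz",
                             noise_sigma = 0, seed = 1,
                             t_ns = seq(0, 1008, by = 16), knots = 19,
                             nuclei = NULL) {
  if (is.character(fixture)) fixture <- heme_fixture(fixture)
  stopifnot(inherits(fixture, "heme_fixture"))
  sys <- fixture$system
  if (!is.null(nuclei)) {
    keep <- vapply(sys$nuclei, function(n) n$label %in% nuclei, logical(1))
    sys <- spin_system(sys$g, sys$nuclei[keep])
  }
  set.seed(seed)
  traces <- list()
  for (nm in observer_names) {
    obs <- fixture$observers[[nm]]
    if (is.null(obs)) stop("fixture has no observer '", nm, "'")
    tr <- time_domain(sys, obs, tau_ns = obs$tau_ns[1], t_ns = t_ns,
                      knots = knots)
    if (noise_sigma > 0) {
      tr$trace <- tr$trace +
        matrix(stats::rnorm(length(tr$trace), 0, noise_sigma),
               nrow(tr$trace))
    }
    traces[[nm]] <- tr
  }
  structure(list(traces = traces, noise_sigma = noise_sigma, seed = seed,
                 truth = fixture$truth, name = fixture$name),
            class = "synthetic_dataset")
}
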