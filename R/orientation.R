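#' Observer settings for an orientation-selective experiment
#'
#' Bundles the microwave frequency, the static field (given directly in mT
#' or through a target g-value), the excitation bandwidth that controls
#' orientation selection, and the tau value(s) of the four-pulse sequence.
#'
#' @param mw_freq_GHz microwave frequency in GHz
#' @param field_mT static field in mT (omit if `g_obs` is given)
#' @param g_obs target g-value from which the field is computed
#' @param bandwidth_MHz excitation bandwidth FWHM in MHz; the default
#'   25 MHz corresponds approximately to a 16 ns pi-pulse
#' @param tau_ns tau value(s) of the four-pulse sequence in ns
#' @param label optional label (e.g. `"gz"`)
#' @return An object of class `observer`.
#' @examples
#' observer(9.68, g_obs = 2.443, tau_ns = c(208, 250), label = "gz")
#' @export
observer <- function(mw_freq_GHz, field_mT = NULL, g_obs = NULL,
                     bandwidth_MHz = 25, tau_ns = 250, label = NULL) {
  stopifnot(mw_freq_GHz > 0, bandwidth_MHz > 0, all(tau_ns > 0))
  if (is.null(field_mT)) {
    if (is.null(g_obs)) stop("give either field_mT or g_obs")
    field_mT <- resonance_field(g_obs, mw_freq_GHz)
  }
  stopifnot(field_mT > 0)
  structure(list(mw_freq_GHz = mw_freq_GHz, field_mT = field_mT,
                 bandwidth_MHz = bandwidth_MHz, tau_ns = tau_ns,
                 label = label),
            class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf("<observer%s>  %.4g GHz, B0 = %.2f mT, bandwidth %.3g MHz, tau = %s ns\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$mw_freq_GHz, x$field_mT, x$bandwidth_MHz,
              paste(x$tau_ns, collapse = "/")))
  invisible(x)
}

#' Effective g-value along a direction
#'
#' \eqn{g_{eff}(n) = \sqrt{g_x^2 n_x^2 + g_y^2 n_y^2 + g_z^2 n_z^2}} for a
#' unit vector n in the g-frame.
#'
#' @param g numeric length-3 `(g_x, g_y, g_z)`
#' @param direction unit vector (length 3) or matrix with one unit vector
#'   per row
#' @return Effective g-value(s).
#' @export
g_effective <- function(g, direction) {
  stopifnot(length(g) == 3)
  d <- if (is.matrix(direction)) direction else matrix(direction, nrow = 1)
  nrm <- sqrt(rowSums(d^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("direction must be a unit vector")
  out <- sqrt(d^2 %*% g^2)[, 1]
  if (!is.matrix(direction)) out[1] else out
}

# deterministic equal-area ring grid on the upper hemisphere;
# returns directions (rows) and solid-angle weights summing to 1
sphere_grid <- function(knots = 61) {
  stopifnot(knots >= 2)
  theta <- seq(0, pi / 2, length.out = knots)
  dirs <- NULL
  w <- NULL
  for (i in seq_along(theta)) {
    th <- theta[i]
    nphi <- max(1L, ceiling(2 * (knots - 1) * sin(th) * pi / 2))
    phi <- (seq_len(nphi) - 0.5) / nphi * 2 * pi
    ring <- cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                  rep(cos(th), nphi))
    # ring solid angle ~ sin(theta) dtheta, split equally over phi knots
    wring <- sin(th) * (pi / 2) / (knots - 1)
    if (i == 1 || i == length(theta)) wring <- wring / 2  # trapezoid ends
    if (i == 1) wring <- (1 - cos(theta[2] / 2))           # polar cap
    dirs <- rbind(dirs, ring)
    w <- c(w, rep(wring / nphi, nphi))
  }
  list(directions = dirs, weights = w / sum(w))
}

#' Select contributing orientations at an observer position
#'
#' At a fixed static field in a powder of molecules with anisotropic g,
#' only orientations whose effective g resonates within the excitation
#' bandwidth contribute: "single-crystal-like" sets at the extreme
#' g-values, a closed belt of orientations at intermediate positions.
#' Orientations are drawn from a deterministic equal-area hemispherical
#' grid; each is weighted by its powder (solid-angle) measure times a
#' Gaussian resonance-window profile of FWHM `bandwidth_MHz` centred at
#' the microwave frequency.
#'
#' @param system a [spin_system()] (only `g` is used)
#' @param obs an [observer()]
#' @param knots grid density (number of polar rings); the default gives
#'   about 2400 orientations on the hemisphere
#' @param window_cut weights below `window_cut` times the maximum window
#'   value are dropped
#' @return A list of class `orientation_set` with matrix `directions`
#'   (unit rows), `weights` (normalized to 1 when non-empty) and the
#'   per-orientation `g_eff`. Empty selection gives a zero-row set with a
#'   warning.
#' @export
select_orientations <- function(system, obs, knots = 61,
                                window_cut = 1e-3) {
  stopifnot(inherits(system, "spin_system"), inherits(obs, "observer"))
  grid <- sphere_grid(knots)
  geff <- g_effective(system$g, grid$directions)
  # resonance offset in frequency units at fixed field
  nu <- geff * .const$muB * obs$field_mT * 1e-3 / .const$h / 1e6  # MHz
  offset <- nu - obs$mw_freq_GHz * 1e3
  win <- exp(-4 * log(2) * (offset / obs$bandwidth_MHz)^2)
  keep <- win > window_cut * max(win) & win > 1e-12
  if (!any(keep)) {
    warning("no orientations resonate at this observer position")
    return(structure(list(directions = matrix(numeric(0), 0, 3),
                          weights = numeric(0), g_eff = numeric(0)),
                     class = "orientation_set"))
  }
  w <- grid$weights[keep] * win[keep]
  structure(list(directions = grid$directions[keep, , drop = FALSE],
                 weights = w / sum(w), g_eff = geff[keep]),
            class = "orientation_set")
}

#' @export
print.orientation_set <- function(x, ...) {
  cat(sprintf("<orientation_set>  %d orientations", nrow(x$directions)))
  if (nrow(x$directions) > 0) {
    cat(sprintf(", g_eff in [%.4g, %.4g]", min(x$g_eff), max(x$g_eff)))
  }
  cat("\n")
  invisible(x)
}
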