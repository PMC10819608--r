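# point-dipole prefactor (mu0/4pi) g_e mu_B g_N mu_N / h in MHz * Angstrom^3;
# ~79.06 for 1H
dipole_prefactor <- function(isotope) {
  iso <- isotope_lookup(isotope)
  .const$mu04 * .const$ge * .const$muB * abs(iso$g_n) * .const$muN /
    .const$h * 1e30 * 1e-6
}

#' Point-dipole axial coupling from a metal-nucleus distance
#'
#' Through-space electron-nuclear dipolar coupling with the unpaired
#' electron treated as a point dipole on the metal:
#' \deqn{T = \frac{\mu_0}{4\pi h} g_e \mu_B g_N \mu_N / r^3}
#' so that the orientation-dependent coupling is
#' \eqn{A_{dip}(\theta) = T(3\cos^2\theta - 1)}. The free-electron g is
#' used, which is what reproduces distances quoted from this analysis in
#' the heme literature. A warning is issued below 2.5 A where the
#' point-dipole picture degrades.
#'
#' @param r_A distance in Angstrom (> 0)
#' @param isotope nuclear isotope label
#' @return T in MHz.
#' @examples
#' T_from_r(4.26, "1H")  # ~1.03 MHz
#' @export
T_from_r <- function(r_A, isotope = "1H") {
  if (any(r_A <= 0)) stop("distance must be positive")
  if (any(r_A < 2.5)) {
    warning("point-dipole approximation unreliable below 2.5 A")
  }
  dipole_prefactor(isotope) / r_A^3
}

#' Metal-nucleus distance from a point-dipole coupling
#'
#' Exact inverse of [T_from_r()]: \eqn{r = (C_{iso}/T)^{1/3}} with the
#' same prefactor.
#'
#' @param T_MHz axial anisotropic hyperfine coupling in MHz (> 0)
#' @param isotope nuclear isotope label
#' @return r in Angstrom.
#' @examples
#' r_from_T(5.60, "1H")  # ~2.42 A
#' r_from_T(2.60, "1H")  # ~3.12 A
#' @export
r_from_T <- function(T_MHz, isotope = "1H") {
  if (any(T_MHz <= 0)) stop("coupling must be positive")
  r <- (dipole_prefactor(isotope) / T_MHz)^(1 / 3)
  if (any(r < 2.5)) {
    warning("point-dipole approximation unreliable below 2.5 A")
  }
  r
}

#' Orientation-dependent dipolar coupling
#'
#' \eqn{A_{dip}(\theta) = T (3\cos^2\theta - 1)}; +2T along the
#' inter-spin vector, -T perpendicular to it, zero at the magic angle.
#'
#' @param T_MHz axial coupling in MHz
#' @param theta_deg angle between the field and the inter-spin vector
#' @return Coupling in MHz.
#' @export
Adip_at_angle <- function(T_MHz, theta_deg) {
  T_MHz * (3 * cos(theta_deg * pi / 180)^2 - 1)
}

#' Rescale hyperfine quantities between isotopes
#'
#' Hyperfine couplings scale with the nuclear g-factor, so parameters
#' determined for one isotope transfer to another of the same element by
#' multiplication with \eqn{g_n(to)/g_n(from)}. Magnitudes are returned
#' with the sign of the ratio reported separately, since ESEEM
#' frequencies are insensitive to the absolute sign.
#'
#' @param value coupling value(s) in MHz (scalar, vector or an
#'   [interaction_tensor()])
#' @param from,to isotope labels
#' @return For numeric input, a numeric of the same shape with attribute
#'   `"ratio_sign"`; for a tensor, a rescaled [interaction_tensor()].
#' @examples
#' isotope_rescale(5.60, "1H", "2H")    # 0.860
#' isotope_rescale(3.57, "14N", "15N")  # 5.01 (ratio is negative)
#' @export
isotope_rescale <- function(value, from, to) {
  fr <- isotope_lookup(from); t2 <- isotope_lookup(to)
  ratio <- t2$g_n / fr$g_n
  if (inherits(value, "interaction_tensor")) {
    if (value$kind != "hyperfine") {
      stop("only hyperfine tensors rescale with the nuclear g-factor")
    }
    return(interaction_tensor(value$principal * abs(ratio), value$euler,
                              "hyperfine"))
  }
  out <- abs(value * ratio) * sign(value)
  attr(out, "ratio_sign") <- sign(ratio)
  out
}

#' Place a nucleus in the g-frame from its axial hyperfine tensor
#'
#' Under the point-dipole model the unique axis of an axial hyperfine
#' tensor points from the metal to the nucleus, so the Euler angles
#' (alpha, beta) of the tensor frame double as the spherical placement of
#' the nucleus: distance r from T by [r_from_T()], polar angle theta =
#' beta (from the heme normal, g_z), azimuth phi = alpha (from g_x in
#' the heme plane). Angles are folded to theta in [0, 90] and phi in
#' (-90, 90] - the dipolar interaction cannot distinguish the symmetry-
#' related positions.
#'
#' @param T_MHz axial anisotropic coupling in MHz
#' @param beta_deg Euler beta of the hyperfine frame, degrees
#' @param alpha_deg Euler alpha, degrees
#' @param isotope isotope label
#' @param label optional nucleus label carried into reports
#' @return A list of class `geometry_solution`: `r_A`, `theta_deg`,
#'   `phi_deg`, `label`, `source`.
#' @examples
#' locate_nucleus(5.60, 22, 0, "1H", "H1")  # r = 2.42 A, theta 22, phi 0
#' @export
locate_nucleus <- function(T_MHz, beta_deg, alpha_deg = 0, isotope = "1H",
                           label = NULL) {
  r <- r_from_T(T_MHz, isotope)
  th <- abs(((beta_deg + 180) %% 360) - 180)   # to [0, 180]
  if (th > 90) th <- 180 - th                  # fold: +/- r equivalent
  ph <- ((alpha_deg + 90) %% 180) - 90
  if (ph == -90) ph <- 90
  structure(list(r_A = r, theta_deg = th, phi_deg = ph,
                 label = label,
                 source = sprintf("T = %.3g MHz, beta = %.3g, alpha = %.3g",
                                  T_MHz, beta_deg, alpha_deg)),
            class = "geometry_solution")
}

#' @export
print.geometry_solution <- function(x, ...) {
  cat(sprintf("%s r = %.3f A, theta = %.1f deg, phi = %.1f deg  (%s)\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$r_A, x$theta_deg, x$phi_deg, x$source))
  invisible(x)
}

#' Compare EPR-derived placements with crystal-structure references
#'
#' @param solutions list of [locate_nucleus()] results (must carry
#'   labels)
#' @param refs data frame with columns `label`, `r_A`, `theta_deg`,
#'   `phi_deg` (NA allowed); see [structure_references()]
#' @return Data frame with per-nucleus EPR and reference values and
#'   deviations `dr_A`, `dtheta_deg`, `dphi_deg`; unmatched labels are
#'   retained with NA references.
#' @export
compare_to_structure <- function(solutions, refs) {
  if (length(solutions) == 0 || nrow(refs) == 0) {
    return(data.frame(label = character(0), r_epr = numeric(0),
                      r_xray = numeric(0), dr_A = numeric(0),
                      dtheta_deg = numeric(0), dphi_deg = numeric(0)))
  }
  out <- do.call(rbind, lapply(solutions, function(s) {
    i <- match(s$label, refs$label)
    data.frame(label = s$label,
               r_epr = s$r_A, theta_epr = s$theta_deg, phi_epr = s$phi_deg,
               r_xray = if (is.na(i)) NA_real_ else refs$r_A[i],
               theta_xray = if (is.na(i)) NA_real_ else refs$theta_deg[i],
               phi_xray = if (is.na(i)) NA_real_ else refs$phi_deg[i])
  }))
  out$dr_A <- out$r_epr - out$r_xray
  out$dtheta_deg <- out$theta_epr - out$theta_xray
  out$dphi_deg <- out$phi_epr - out$phi_xray
  rownames(out) <- NULL
  out
}

#' Crystal-structure reference positions of active-site protons
#'
#' Distances and angles of the nearest protons to the heme iron taken
#' from diffraction models: the two water protons added to the
#' substrate-free structure, the closer cysteine beta proton, and the
#' imidazole 2-/5-position protons of an imidazole complex of a related
#' P450. Read-only fixture data used by [compare_to_structure()].
#'
#' @return Data frame `label`, `r_A`, `theta_deg`, `phi_deg`,
#'   `provenance`.
#' @export
structure_references <- function() {
  data.frame(
    label = c("H1", "H2", "H3", "H4"),
    r_A = c(2.9, 2.7, 3.078, 3.142),
    theta_deg = c(23, 19, 45, 41),
    phi_deg = c(5, 0, 4, NA),
    provenance = c("CYP116B5hd crystal structure, modeled water protons",
                   "CYP116B5hd crystal structure, modeled water protons",
                   "CYP116B5hd crystal structure, proximal cysteine H-beta",
                   "P450cam-imidazole complex, imidazole H(2)/H(5)"),
    stringsAsFactors = FALSE
  )
}

#' Imidazole plane orientation from the 14N quadrupole tensor
#'
#' For heme-coordinated imidazole the smallest-magnitude principal axis
#' of the 14N quadrupole tensor is normal to the imidazole plane, and the
#' tensor's Euler angle alpha gives the in-plane projection of that
#' normal measured from g_x. The projection of the imidazole plane
#' itself is therefore rotated by 90 degrees:
#' \eqn{\phi_{plane} = \alpha' - 90} wrapped to (-90, 90].
#'
#' @param q_alpha_deg Euler alpha of the imidazole 14N quadrupole tensor,
#'   degrees
#' @return Angle between g_x and the imidazole-plane projection,
#'   degrees in (-90, 90].
#' @examples
#' imidazole_plane_angle(65)  # -25
#' imidazole_plane_angle(30)  # -60
#' @export
imidazole_plane_angle <- function(q_alpha_deg) {
  a <- (q_alpha_deg - 90) %% 180
  ifelse(a > 90, a - 180, a)
}
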