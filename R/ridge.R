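#' Transform ridge coordinates to the squared-frequency plane
#'
#' Element-wise squaring of (nu_alpha, nu_beta) correlation coordinates.
#' For an axial hyperfine tensor the powder ridge becomes an exact
#' straight line in the (nu_alpha^2, nu_beta^2) plane, which is the basis
#' of the Dikanov analysis.
#'
#' @param points data frame or matrix with two columns of positive
#'   frequencies in MHz (nu_alpha, nu_beta)
#' @return Data frame with columns `nu_a2`, `nu_b2` in MHz^2.
#' @export
nu2_transform <- function(points) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2)
  if (any(p <= 0)) stop("all frequencies must be positive")
  data.frame(nu_a2 = p[, 1]^2, nu_b2 = p[, 2]^2)
}

#' Generate an axial-hyperfine powder ridge
#'
#' Evaluates the closed-form I = 1/2 correlation frequencies over a grid
#' of field angles theta, the full ridge an axial tensor traces in a
#' powder. Used to generate synthetic ridges and to score candidate
#' (a_iso, T) branches.
#'
#' @param a_iso,T_ax hyperfine parameters in MHz
#' @param nu_I nuclear Larmor frequency in MHz
#' @param theta_deg vector of angles in degrees
#' @return Data frame `nu_alpha`, `nu_beta`, `theta_deg`.
#' @export
ridge_points <- function(a_iso, T_ax, nu_I,
                         theta_deg = seq(0, 90, by = 2)) {
  v <- vapply(theta_deg, function(th) closed_form_I12(a_iso, T_ax, th, nu_I),
              numeric(2))
  data.frame(nu_alpha = v[1, ], nu_beta = v[2, ], theta_deg = theta_deg)
}

# slope/intercept of the nu^2 line implied by (a, T, nu_I); from the
# closed form, nu_alpha^2 and nu_beta^2 are both linear in cos^2(theta):
#   slope Q = (2a + T - 4 nu_I) / (2a + T + 4 nu_I)
#   intercept G = (nu_I - (a-T)/2)^2 - Q (nu_I + (a-T)/2)^2
nu2_line <- function(a, T_ax, nu_I) {
  s <- 2 * a + T_ax
  Q <- (s - 4 * nu_I) / (s + 4 * nu_I)
  u <- a - T_ax
  G <- (nu_I - u / 2)^2 - Q * (nu_I + u / 2)^2
  c(slope = Q, intercept = G)
}

# invert a (slope, intercept) pair to the (a, T) candidates; quadratic in
# u = a - T gives two roots per line orientation
invert_nu2_line <- function(slope, intercept, nu_I) {
  if (abs(1 - slope) < 1e-12) return(NULL)
  s <- 4 * nu_I * (1 + slope) / (1 - slope)   # = 2a + T
  # (1-Q)/4 u^2 - nu_I (1+Q) u + nu_I^2 (1-Q) - G = 0
  aa <- (1 - slope) / 4
  bb <- -nu_I * (1 + slope)
  cc <- nu_I^2 * (1 - slope) - intercept
  disc <- bb^2 - 4 * aa * cc
  if (disc < 0) return(NULL)
  u <- c((-bb + sqrt(disc)) / (2 * aa), (-bb - sqrt(disc)) / (2 * aa))
  data.frame(a_iso = (s + u) / 3, T_ax = (s - 2 * u) / 3)
}

#' Fit a Dikanov ridge and invert to hyperfine parameters
#'
#' Fits a straight line through points in the squared-frequency plane by
#' total least squares (both coordinates are measured quantities) and
#' inverts slope and intercept to candidate (a_iso, T) pairs. All
#' algebraically admissible branches are returned - the assignment of the
#' two coordinates to the alpha/beta manifolds is unknown, so the
#' axis-swapped line is inverted too, and each quadratic gives two roots.
#' Branches are scored by regenerating the ridge they imply and measuring
#' its distance to the data; the best-scoring branch comes first.
#'
#' @param points2 output of [nu2_transform()] (columns `nu_a2`, `nu_b2`),
#'   or a two-column matrix of squared frequencies in MHz^2
#' @param nu_I nuclear Larmor frequency in MHz
#' @return A data frame of class `ridge_fit`, one row per branch:
#'   `a_iso`, `T_ax` (MHz), `branch` label, `rmsd_MHz` (ridge-overlap
#'   score, lower is better), `r_squared` of the line fit, `nu_I`.
#'   Branches are sorted by `rmsd_MHz`; `a_iso` sign relative to T is not
#'   determined by the ridge alone (sign-flipped duplicates are
#'   equivalent and not enumerated separately).
#' @examples
#' rp <- ridge_points(0.79, 2.60, 12.05)
#' fit_ridge(nu2_transform(rp[, 1:2]), 12.05)
#' @export
fit_ridge <- function(points2, nu_I) {
  p <- as.matrix(points2)[, 1:2, drop = FALSE]
  stopifnot(nrow(p) >= 2)
  if (max(stats::sd(p[, 1]), stats::sd(p[, 2]), na.rm = TRUE) < 1e-9) {
    stop("ridge too short for unique fit (degenerate point cloud)")
  }
  ctr <- colMeans(p)
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (abs(v[2]) < 1e-12 && abs(v[1]) < 1e-12) {
    stop("ridge too short for unique fit (degenerate point cloud)")
  }
  tot <- sum((sweep(p, 2, ctr))^2)
  resid <- if (ncol(pc$x) > 1) sum(pc$x[, 2]^2) else 0
  r2 <- 1 - resid / tot
  branches <- list()
  lines <- list()
  ctr <- unname(ctr)
  if (abs(v[2]) > 1e-12) {
    q <- unname(v[1] / v[2])                # d nu_a2 / d nu_b2
    lines$fwd <- c(slope = q, intercept = ctr[1] - q * ctr[2])
  }
  if (abs(v[1]) > 1e-12) {
    q <- unname(v[2] / v[1])                # axes exchanged
    lines$swap <- c(slope = q, intercept = ctr[2] - q * ctr[1])
  }
  # lines$fwd: nu_a2 = Q nu_b2 + G with data as given;
  # lines$swap: same after exchanging the two coordinates
  for (nm in names(lines)) {
    ln <- lines[[nm]]
    cand <- invert_nu2_line(ln["slope"], ln["intercept"], nu_I)
    if (is.null(cand)) next
    for (i in seq_len(nrow(cand))) {
      branches[[length(branches) + 1]] <-
        data.frame(a_iso = cand$a_iso[i], T_ax = cand$T_ax[i],
                   branch = paste0(nm, i))
    }
  }
  if (length(branches) == 0) stop("no admissible (a_iso, T) branch found")
  br <- do.call(rbind, branches)
  # score each branch by distance between its regenerated ridge and the data
  obs <- sqrt(p)
  br$rmsd_MHz <- vapply(seq_len(nrow(br)), function(i) {
    rp <- ridge_points(br$a_iso[i], br$T_ax[i], nu_I,
                       theta_deg = seq(0, 90, by = 1))
    d <- vapply(seq_len(nrow(obs)), function(k) {
      min(sqrt((rp$nu_alpha - obs[k, 1])^2 + (rp$nu_beta - obs[k, 2])^2),
          sqrt((rp$nu_beta - obs[k, 1])^2 + (rp$nu_alpha - obs[k, 2])^2))
    }, numeric(1))
    sqrt(mean(d^2))
  }, numeric(1))
  br$r_squared <- r2
  br$nu_I <- nu_I
  br <- br[order(br$rmsd_MHz), , drop = FALSE]
  rownames(br) <- NULL
  class(br) <- c("ridge_fit", "data.frame")
  br
}
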