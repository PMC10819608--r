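# Spin operator matrices for arbitrary I (complex), in the |I, m> basis
# ordered m = I, I-1, ..., -I.
spin_matrices <- function(I) {
  d <- as.integer(round(2 * I + 1))
  m <- I - (seq_len(d) - 1)
  Iz <- diag(m)
  Ip <- matrix(0, d, d)
  for (k in seq_len(d - 1)) {
    # <m+1| I+ |m> with m = m[k+1]
    Ip[k, k + 1] <- sqrt(I * (I + 1) - m[k + 1] * (m[k + 1] + 1))
  }
  Im <- t(Ip)
  list(x = (Ip + Im) / 2, y = (Ip - Im) / (2i), z = Iz + 0i, d = d)
}

# Nuclear sub-Hamiltonian (MHz) in electron manifold m_s for one nucleus.
# The electron spin is treated to first order: its quantization axis is
# u = g.B_hat / |g.B_hat|, and the hyperfine field seen by the nucleus is
# m_s * (u^T A). The nuclear Zeeman term is -nu_I (B_hat . I); the
# quadrupole term I.Q.I is added for I = 1.
nuclear_hamiltonian <- function(nuc, ms, b_hat, g, field_mT) {
  A <- tensor_lab_matrix(nuc$A)
  nu_I <- larmor_frequency(nuc$isotope, field_mT) * sign(nuc$isotope$g_n)
  gb <- g * b_hat
  u <- gb / sqrt(sum(gb^2))
  hv <- ms * as.vector(u %*% A) - nu_I * b_hat
  S <- spin_matrices(nuc$isotope$spin)
  H <- hv[1] * S$x + hv[2] * S$y + hv[3] * S$z
  if (!is.null(nuc$Q)) {
    Q <- tensor_lab_matrix(nuc$Q)
    ops <- list(S$x, S$y, S$z)
    for (i in 1:3) for (j in 1:3) {
      if (Q[i, j] != 0) H <- H + Q[i, j] * (ops[[i]] %*% ops[[j]])
    }
  }
  H
}

#' Exact nuclear transition frequencies in the two electron manifolds
#'
#' Diagonalizes the nuclear sub-Hamiltonian of one coupled nucleus in each
#' electron-spin manifold (m_s = +1/2, -1/2). The electron Zeeman
#' interaction dominates at the fields considered (0.28-1.2 T), so the
#' electron is treated to first order with quantization axis along
#' \eqn{g \hat B}; the nuclear problem (Zeeman + hyperfine + quadrupole)
#' is solved exactly. For I = 1/2 there is a single transition per
#' manifold; for I = 1 the two single-quantum (sq) transitions and their
#' sum, the double-quantum (dq) transition, are returned.
#'
#' @param nuc a [nucleus()]
#' @param field_mT static field in mT
#' @param direction field direction in the g-frame (unit vector)
#' @param g g principal values `(g_x, g_y, g_z)`
#' @return A list of class `manifold_frequencies` with one element per
#'   manifold (`ms = +1/2` first). Each holds `ms`, a data frame
#'   `transitions` (columns `type`, `freq_MHz`), the level energies
#'   `energies` and the eigenvector matrix `vectors` (columns are
#'   eigenstates, ascending energy) used for amplitude computations.
#' @examples
#' n1 <- nucleus("14N",
#'   interaction_tensor(c(-4.90, -4.80, -5.10), c(90, 0, 0), "hyperfine"),
#'   interaction_tensor(c(0.90, -0.60, -0.30), c(90, 0, 0), "quadrupole"))
#' mf <- manifold_frequencies(n1, 283.1, c(0, 0, 1), c(1.923, 2.253, 2.443))
#' @export
manifold_frequencies <- function(nuc, field_mT, direction,
                                 g = c(1, 1, 1) * 2.0023) {
  stopifnot(inherits(nuc, "nucleus"), field_mT > 0)
  b_hat <- direction / sqrt(sum(direction^2))
  out <- lapply(c(0.5, -0.5), function(ms) {
    H <- nuclear_hamiltonian(nuc, ms, b_hat, g, field_mT)
    e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
    idx <- order(e$values)
    vals <- e$values[idx]
    vecs <- e$vectors[, idx, drop = FALSE]
    tr <- if (length(vals) == 2) {
      data.frame(type = "single", freq_MHz = vals[2] - vals[1])
    } else {
      data.frame(type = c("sq1", "sq2", "dq"),
                 freq_MHz = c(vals[2] - vals[1], vals[3] - vals[2],
                              vals[3] - vals[1]))
    }
    list(ms = ms, transitions = tr, energies = vals, vectors = vecs)
  })
  structure(out, class = "manifold_frequencies")
}

#' Closed-form I = 1/2 nuclear frequencies for an axial hyperfine tensor
#'
#' The textbook two-spin (S = 1/2, I = 1/2) expressions with secular and
#' pseudo-secular parts
#' \eqn{A(\theta) = a_{iso} + T(3\cos^2\theta - 1)},
#' \eqn{B(\theta) = 3T\sin\theta\cos\theta}:
#' \deqn{\nu_{\alpha,\beta} = \sqrt{(\nu_I \mp A/2)^2 + (B/2)^2}}
#' where theta is the angle between the field and the unique hyperfine
#' axis. Serves as an independent cross-check of the exact
#' diagonalization.
#'
#' @param a_iso isotropic coupling, MHz
#' @param T_ax axial anisotropic coupling, MHz
#' @param theta_deg field angle from the unique axis, degrees
#' @param nu_I nuclear Larmor frequency, MHz
#' @return Named numeric `c(nu_alpha, nu_beta)` in MHz.
#' @examples
#' closed_form_I12(-0.09, 5.60, 22, 12.05)  # ~(16.7, 8.2)
#' @export
closed_form_I12 <- function(a_iso, T_ax, theta_deg, nu_I) {
  th <- theta_deg * pi / 180
  A <- a_iso + T_ax * (3 * cos(th)^2 - 1)
  B <- 3 * T_ax * sin(th) * cos(th)
  c(nu_alpha = sqrt((nu_I - A / 2)^2 + (B / 2)^2),
    nu_beta  = sqrt((nu_I + A / 2)^2 + (B / 2)^2))
}

#' Quadrupole coupling constant K and asymmetry eta
#'
#' From the three traceless principal values: K is half the largest
#' absolute principal value, eta the difference of the other two over the
#' largest.
#'
#' @param q_principal numeric length-3 traceless principal values, MHz
#' @return Named numeric `c(K, eta)`.
#' @export
quadrupole_K <- function(q_principal) {
  stopifnot(length(q_principal) == 3)
  o <- order(abs(q_principal))
  qz <- q_principal[o[3]]
  c(K = abs(qz) / 2,
    eta = abs(q_principal[o[1]] - q_principal[o[2]]) / abs(qz))
}

#' Approximate double-quantum frequencies for I = 1
#'
#' The standard strong-coupling estimate
#' \deqn{\nu_{dq\pm} = 2\sqrt{(\nu_I \pm A/2)^2 + K^2(3 + \eta^2)}}
#' used to seed and validate the exact diagonalization; dq-dq correlation
#' ridges of strongly coupled 14N lie near lines intercepting the axes at
#' \eqn{4\nu_I}.
#'
#' @param A_sec secular hyperfine coupling along the field, MHz
#' @param K quadrupole coupling constant, MHz (see [quadrupole_K()])
#' @param eta quadrupole asymmetry parameter
#' @param nu_I nuclear Larmor frequency, MHz
#' @return Named numeric `c(dq_plus, dq_minus)` in MHz.
#' @examples
#' dq_estimate(5.10, 0.45, 1/3, 0.871)  # ~(7.02, 3.71)
#' @export
dq_estimate <- function(A_sec, K, eta, nu_I) {
  A_sec <- abs(A_sec)
  c(dq_plus  = 2 * sqrt((nu_I + A_sec / 2)^2 + K^2 * (3 + eta^2)),
    dq_minus = 2 * sqrt((nu_I - A_sec / 2)^2 + K^2 * (3 + eta^2)))
}

#' Classify the hyperfine coupling regime at an observer position
#'
#' Compares the effective secular hyperfine coupling |A_eff| with twice
#' the nuclear Larmor frequency at the observer field: weak when
#' |A_eff| < 2 nu_I, strong when |A_eff| > 2 nu_I, near-cancellation when
#' the two agree within `tol_frac`. The regime fixes the quadrant in
#' which correlation peaks dominate: (+,+) for weak, (-,+) for strong.
#'
#' @param nuc a [nucleus()]
#' @param obs an [observer()]
#' @param g g principal values
#' @param direction field direction in the g-frame; defaults to the axis
#'   whose resonance field is closest to the observer field
#' @param tol_frac relative tolerance for the cancellation condition
#' @return A list of class `coupling_regime` with `label` (one of
#'   `"weak"`, `"strong"`, `"near-cancellation"`), `A_eff_MHz` and
#'   `two_nu_I_MHz`.
#' @export
classify_regime <- function(nuc, obs, g, direction = NULL,
                            tol_frac = 0.25) {
  stopifnot(inherits(nuc, "nucleus"), inherits(obs, "observer"))
  if (is.null(direction)) {
    ax <- diag(3)
    bres <- resonance_field(g, obs$mw_freq_GHz)
    direction <- ax[which.min(abs(bres - obs$field_mT)), ]
  }
  b_hat <- direction / sqrt(sum(direction^2))
  A <- tensor_lab_matrix(nuc$A)
  gb <- g * b_hat
  u <- gb / sqrt(sum(gb^2))
  A_eff <- sqrt(sum(as.vector(u %*% A)^2))
  two_nu <- 2 * larmor_frequency(nuc$isotope, obs$field_mT)
  label <- if (abs(A_eff - two_nu) <= tol_frac * two_nu) {
    "near-cancellation"
  } else if (A_eff > two_nu) "strong" else "weak"
  structure(list(label = label, A_eff_MHz = A_eff, two_nu_I_MHz = two_nu),
            class = "coupling_regime")
}

#' @export
print.coupling_regime <- function(x, ...) {
  cat(sprintf("%s coupling (|A_eff| = %.3g MHz, 2 nu_I = %.3g MHz)\n",
              x$label, x$A_eff_MHz, x$two_nu_I_MHz))
  invisible(x)
}
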