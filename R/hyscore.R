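# ---- nuclear propagators ----------------------------------------------------

# U(t) = exp(-2*pi*i H t), H in MHz, t in microseconds, via eigendecomposition
propagator_eigen <- function(H) {
  e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  V <- e$vectors
  function(t_us) {
    V %*% (exp(-2i * pi * e$values * t_us) * Conj(t(V)))
  }
}

# analytic 2x2 propagator for I = 1/2: H = (1/2) hv . sigma, so
# U(t) = cos(pi nu t) 1 - i sin(pi nu t) (n . sigma), nu = |hv|
propagator_pauli <- function(hv) {
  nu <- sqrt(sum(hv^2))
  n <- if (nu > 0) hv / nu else c(0, 0, 1)
  nsig <- matrix(c(n[3], n[1] + 1i * n[2], n[1] - 1i * n[2], -n[3]), 2, 2)
  function(t_us) {
    ph <- pi * nu * t_us
    cos(ph) * diag(2) - 1i * sin(ph) * nsig
  }
}

# per-nucleus pair of propagator factories (ms = +1/2, -1/2)
nucleus_propagators <- function(nuc, b_hat, g, field_mT,
                                method = c("auto", "eigen")) {
  method <- match.arg(method)
  lapply(c(0.5, -0.5), function(ms) {
    H <- nuclear_hamiltonian(nuc, ms, b_hat, g, field_mT)
    if (method == "auto" && nuc$isotope$spin == 0.5) {
      # hv components recoverable from H = (1/2) hv.sigma
      hv <- c(2 * Re(H[1, 2]), -2 * Im(H[1, 2]), 2 * Re(H[1, 1]))
      propagator_pauli(hv)
    } else {
      propagator_eigen(H)
    }
  })
}

# Ideal-pulse four-pulse (HYSCORE) echo modulation for one orientation.
# Ua/Ub: propagator factories for the two manifolds (dimension d);
# returns matrix over t1 x t2. Only the echo-forming coherence-transfer
# pathway is retained (electron coherence of opposite order during the
# two tau periods, populations during t1/t2, manifolds exchanged by the
# pi pulse); the counter-rotating pathway dephases under the
# inhomogeneous electron linewidth and is dropped, as in a phase-cycled
# measurement. Exact for ideal pulses; tau-dependent blind spots are
# contained in the formula.
four_pulse_trace <- function(Ua, Ub, tau_us, t1_us, t2_us) {
  d <- nrow(Ua(0))
  Uat <- Ua(tau_us); Ubt <- Ub(tau_us)
  B1 <- Ubt %*% Conj(t(Uat))      # coherence acquired over the first tau
  W <- Conj(t(Ubt)) %*% Uat       # refocusing over the final tau
  U1a <- lapply(t1_us, Ua); U1b <- lapply(t1_us, Ub)
  U2a <- lapply(t2_us, Ua); U2b <- lapply(t2_us, Ub)
  out <- matrix(0, length(t1_us), length(t2_us))
  for (i in seq_along(t1_us)) {
    M1 <- U1b[[i]] %*% B1 %*% Conj(t(U1b[[i]]))
    M2 <- U1a[[i]] %*% B1 %*% Conj(t(U1a[[i]]))
    for (j in seq_along(t2_us)) {
      PQ <- U2a[[j]] %*% M1 %*% Conj(t(U2a[[j]])) +
            U2b[[j]] %*% M2 %*% Conj(t(U2b[[j]]))
      out[i, j] <- Re(sum(W * t(PQ))) / (2 * d)
    }
  }
  out
}

#' Synthesize a four-pulse HYSCORE time-domain trace
#'
#' Simulates the normalized echo amplitude of the sequence
#' pi/2 - tau - pi/2 - t1 - pi - t2 - pi/2 - tau - echo over a uniform
#' (t1, t2) grid, summed over the orientations selected at the observer
#' position. Pulses are ideal; within each orientation the modulation of
#' all nuclei is combined exactly (product space), so combination
#' frequencies of multi-nuclear sets are present. I = 1/2 nuclei use
#' closed-form (Pauli) propagators; I = 1 nuclei use numerical
#' eigendecomposition of the 3-level sub-Hamiltonians. tau-dependent
#' blind spots arise naturally from the sequence. A system with no nuclei
#' returns a constant unit echo.
#'
#' @param system a [spin_system()]
#' @param obs an [observer()] (its first tau value is used unless `tau_ns`
#'   is given)
#' @param tau_ns tau in ns
#' @param t_ns uniform time grid in ns used for both t1 and t2
#' @param knots orientation grid density passed to [select_orientations()]
#' @param orientations optionally, a precomputed `orientation_set`
#' @param propagator `"auto"` (analytic for I = 1/2) or `"eigen"` (force
#'   numerical propagation everywhere; used for cross-validation)
#' @return A list of class `hyscore_trace`: `trace` (matrix t1 x t2),
#'   `t_ns`, `tau_ns`, `observer`.
#' @export
time_domain <- function(system, obs, tau_ns = obs$tau_ns[1],
                        t_ns = seq(0, 2032, by = 16), knots = 31,
                        orientations = NULL,
                        propagator = c("auto", "eigen")) {
  propagator <- match.arg(propagator)
  stopifnot(inherits(system, "spin_system"), tau_ns > 0)
  dt_us <- if (length(t_ns) > 1) diff(t_ns[1:2]) * 1e-3 else 16e-3
  if (length(t_ns) > 2 && max(abs(diff(diff(t_ns)))) > 1e-9) {
    stop("time grid must be uniform")
  }
  if (length(system$nuclei) == 0) {
    return(structure(list(trace = matrix(1, length(t_ns), length(t_ns)),
                          t_ns = t_ns, tau_ns = tau_ns, observer = obs),
                     class = "hyscore_trace"))
  }
  ors <- if (is.null(orientations)) select_orientations(system, obs, knots)
         else orientations
  if (nrow(ors$directions) == 0) {
    warning("empty orientation selection; returning zero trace")
    return(structure(list(trace = matrix(0, length(t_ns), length(t_ns)),
                          t_ns = t_ns, tau_ns = tau_ns, observer = obs),
                     class = "hyscore_trace"))
  }
  # Nyquist guard against the largest nuclear frequency on the grid
  nu_max <- 0
  for (k in seq_len(nrow(ors$directions))) {
    for (nuc in system$nuclei) {
      mf <- manifold_frequencies(nuc, obs$field_mT, ors$directions[k, ],
                                 system$g)
      nu_max <- max(nu_max, mf[[1]]$transitions$freq_MHz,
                    mf[[2]]$transitions$freq_MHz)
    }
  }
  if (nu_max > 1 / (2 * dt_us)) {
    stop(sprintf("Nyquist violation: max nuclear frequency %.2f MHz exceeds %.2f MHz for dt = %g ns",
                 nu_max, 1 / (2 * dt_us), dt_us * 1e3))
  }
  t_us <- t_ns * 1e-3
  tau_us <- tau_ns * 1e-3
  acc <- matrix(0, length(t_ns), length(t_ns))
  for (k in seq_len(nrow(ors$directions))) {
    b_hat <- ors$directions[k, ]
    Ua <- NULL; Ub <- NULL
    for (nuc in system$nuclei) {
      pr <- nucleus_propagators(nuc, b_hat, system$g, obs$field_mT,
                                propagator)
      for (rep in seq_len(nuc$n_equivalent)) {
        Ua <- if (is.null(Ua)) pr[[1]] else local({
          ua0 <- Ua; p <- pr[[1]]
          function(t_us) kronecker(ua0(t_us), p(t_us))
        })
        Ub <- if (is.null(Ub)) pr[[2]] else local({
          ub0 <- Ub; p <- pr[[2]]
          function(t_us) kronecker(ub0(t_us), p(t_us))
        })
      }
    }
    acc <- acc + ors$weights[k] *
      four_pulse_trace(Ua, Ub, tau_us, t_us, t_us)
  }
  structure(list(trace = acc, t_ns = t_ns, tau_ns = tau_ns, observer = obs),
            class = "hyscore_trace")
}

#' Blind-spot factor of the four-pulse sequence
#'
#' Cross peaks correlating frequencies `nu1` and `nu2` are suppressed in
#' proportion to \eqn{\sin(\pi\nu_1\tau)\sin(\pi\nu_2\tau)}; a zero of
#' either factor is a blind spot. Summing magnitude spectra recorded at
#' several tau values reduces the worst-case suppression.
#'
#' @param nu_MHz frequency (or vector) in MHz
#' @param tau_ns tau in ns
#' @return Suppression factor(s) in `[-1, 1]`.
#' @export
blind_spot_factor <- function(nu_MHz, tau_ns) {
  sin(pi * nu_MHz * tau_ns * 1e-3)
}

# ---- frequency-domain peak maps --------------------------------------------

#' Enumerate HYSCORE correlation peaks of a spin system
#'
#' For every selected orientation and nucleus, computes the exact nuclear
#' transition frequencies in both electron manifolds and emits all
#' cross-manifold correlations, weighted by the orientation measure and a
#' transition-moment amplitude (for I = 1/2 the standard modulation depth
#' \eqn{k = (\nu_I B / (\nu_\alpha\nu_\beta))^2}; for I = 1 eigenvector
#' overlap products). The quadrant follows the coupling regime of the
#' nucleus: (+,+) for weak coupling, (-,+) for strong. The aggregated
#' point cloud traces the powder ridges; mirror partners (nu2, nu1) are
#' included.
#'
#' @param system a [spin_system()]
#' @param obs an [observer()]
#' @param knots orientation grid density
#' @param orientations optionally, a precomputed `orientation_set`
#' @return A data frame of class `cross_peak_list` with columns
#'   `nu1_MHz`, `nu2_MHz`, `quadrant` (`"++"` or `"-+"`), `nucleus`,
#'   `type`, `amplitude`.
#' @export
cross_peaks <- function(system, obs, knots = 31, orientations = NULL) {
  stopifnot(inherits(system, "spin_system"), inherits(obs, "observer"))
  ors <- if (is.null(orientations)) select_orientations(system, obs, knots)
         else orientations
  if (nrow(ors$directions) == 0) {
    warning("empty orientation selection; returning empty peak list")
    return(structure(data.frame(nu1_MHz = numeric(0), nu2_MHz = numeric(0),
                                quadrant = character(0),
                                nucleus = character(0), type = character(0),
                                amplitude = numeric(0)),
                     class = c("cross_peak_list", "data.frame")))
  }
  rows <- list()
  for (nuc in system$nuclei) {
    reg <- classify_regime(nuc, obs, system$g)
    quad <- if (reg$label == "strong") "-+" else "++"
    for (k in seq_len(nrow(ors$directions))) {
      b_hat <- ors$directions[k, ]
      w <- ors$weights[k]
      mf <- manifold_frequencies(nuc, obs$field_mT, b_hat, system$g)
      ta <- mf[[1]]$transitions; tb <- mf[[2]]$transitions
      if (nuc$isotope$spin == 0.5) {
        # modulation depth from the two effective-field vectors
        Ha <- nuclear_hamiltonian(nuc, 0.5, b_hat, system$g, obs$field_mT)
        Hb <- nuclear_hamiltonian(nuc, -0.5, b_hat, system$g, obs$field_mT)
        wa <- c(2 * Re(Ha[1, 2]), -2 * Im(Ha[1, 2]), 2 * Re(Ha[1, 1]))
        wb <- c(2 * Re(Hb[1, 2]), -2 * Im(Hb[1, 2]), 2 * Re(Hb[1, 1]))
        na <- sqrt(sum(wa^2)); nb <- sqrt(sum(wb^2))
        kdep <- if (na > 0 && nb > 0) {
          cr <- c(wa[2] * wb[3] - wa[3] * wb[2],
                  wa[3] * wb[1] - wa[1] * wb[3],
                  wa[1] * wb[2] - wa[2] * wb[1])
          sum(cr^2) / (na^2 * nb^2)
        } else 0
        rows[[length(rows) + 1]] <- data.frame(
          nu1_MHz = ta$freq_MHz, nu2_MHz = tb$freq_MHz, quadrant = quad,
          nucleus = nuc$label, type = "single-single",
          amplitude = w * kdep)
      } else {
        M <- Conj(t(mf[[1]]$vectors)) %*% mf[[2]]$vectors
        pair_idx <- list(sq1 = c(1, 2), sq2 = c(2, 3), dq = c(1, 3))
        for (pa in names(pair_idx)) for (pb in names(pair_idx)) {
          ia <- pair_idx[[pa]]; ib <- pair_idx[[pb]]
          amp <- abs(M[ia[1], ib[1]])^2 * abs(M[ia[2], ib[2]])^2 +
                 abs(M[ia[1], ib[2]])^2 * abs(M[ia[2], ib[1]])^2
          rows[[length(rows) + 1]] <- data.frame(
            nu1_MHz = ta$freq_MHz[ta$type == pa],
            nu2_MHz = tb$freq_MHz[tb$type == pb],
            quadrant = quad, nucleus = nuc$label,
            type = paste0(pa, "-", pb), amplitude = w * amp)
        }
      }
    }
  }
  pk <- do.call(rbind, rows)
  mirror <- pk
  mirror$nu1_MHz <- pk$nu2_MHz
  mirror$nu2_MHz <- pk$nu1_MHz
  out <- rbind(pk, mirror)
  rownames(out) <- NULL
  structure(out, class = c("cross_peak_list", "data.frame"))
}

#' Summarize ridge point clouds into representative peak coordinates
#'
#' Cross-peak clouds from [cross_peaks()] are condensed per nucleus,
#' transition type and quadrant to the amplitude-weighted position of
#' their densest region (weighted mean of points whose amplitude is
#' within `top_frac` of the per-group maximum), so simulated coordinates
#' are comparable with printed experimental peak maxima.
#'
#' @param peaks a `cross_peak_list`
#' @param top_frac amplitude window defining the ridge crest
#' @return Data frame with one row per (nucleus, type, quadrant) on the
#'   `nu1 >= nu2` side, columns `nu1_MHz`, `nu2_MHz`, `amplitude`.
#' @export
ridge_extrema <- function(peaks, top_frac = 0.8) {
  stopifnot(inherits(peaks, "data.frame"))
  pk <- peaks[peaks$nu1_MHz >= peaks$nu2_MHz, , drop = FALSE]
  grp <- interaction(pk$nucleus, pk$type, pk$quadrant, drop = TRUE)
  out <- do.call(rbind, lapply(split(pk, grp), function(d) {
    keep <- d$amplitude >= top_frac * max(d$amplitude)
    d <- d[keep, , drop = FALSE]
    wsum <- sum(d$amplitude)
    data.frame(nucleus = d$nucleus[1], type = d$type[1],
               quadrant = d$quadrant[1],
               nu1_MHz = if (wsum > 0) sum(d$nu1_MHz * d$amplitude) / wsum
                         else mean(d$nu1_MHz),
               nu2_MHz = if (wsum > 0) sum(d$nu2_MHz * d$amplitude) / wsum
                         else mean(d$nu2_MHz),
               amplitude = max(d$amplitude))
  }))
  rownames(out) <- NULL
  out
}

#' Combination peaks between nuclear frequencies
#'
#' Multi-nuclear (or multi-quantum) combination cross peaks: one
#' coordinate is a sum of double-quantum frequencies in one electron
#' manifold, correlated with a dq frequency (or the proton Larmor
#' frequency) in the other manifold.
#'
#' Rules: `"2dq_same"` emits 2 dq(N) sums, only for nuclei flagged with
#' `n_equivalent >= 2`; `"dq_sum_pair"` emits dq(N) + dq(N') sums over
#' distinct nucleus pairs; `"larmor_plus_dq"` emits nu_larmor +/- dq
#' combinations with the Larmor frequency supplied via `larmor_MHz`.
#'
#' @param freqs named list, one element per nucleus, each a list with
#'   `dq` = numeric length-2 (dq frequency in the two manifolds) and
#'   `n_equivalent`; the helper [dq_table()] builds it from a
#'   [spin_system()]
#' @param rules character subset of
#'   `c("2dq_same", "dq_sum_pair", "larmor_plus_dq")`
#' @param larmor_MHz Larmor frequency used by `"larmor_plus_dq"`
#' @return Data frame with `nu1_MHz`, `nu2_MHz`, `quadrant`, `nucleus`,
#'   `type`, `amplitude` (unit placeholder amplitudes; positions are the
#'   contract).
#' @export
combination_peaks <- function(freqs,
                              rules = c("2dq_same", "dq_sum_pair"),
                              larmor_MHz = NULL) {
  rules <- match.arg(rules, c("2dq_same", "dq_sum_pair", "larmor_plus_dq"),
                     several.ok = TRUE)
  rows <- list()
  add <- function(nu1, nu2, nucl, type) {
    rows[[length(rows) + 1]] <<- data.frame(
      nu1_MHz = nu1, nu2_MHz = nu2, quadrant = "-+", nucleus = nucl,
      type = type, amplitude = 1)
  }
  nms <- names(freqs)
  if ("2dq_same" %in% rules) {
    for (nm in nms) {
      f <- freqs[[nm]]
      if (!is.null(f$n_equivalent) && f$n_equivalent >= 2) {
        add(2 * f$dq[1], f$dq[2], nm, "2dq-dq")
        add(2 * f$dq[2], f$dq[1], nm, "2dq-dq")
      }
    }
  }
  if ("dq_sum_pair" %in% rules && length(nms) >= 2) {
    cmb <- utils::combn(nms, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- freqs[[cmb[1, k]]]; b <- freqs[[cmb[2, k]]]
      nm <- paste(cmb[1, k], cmb[2, k], sep = "+")
      add(a$dq[1] + b$dq[1], a$dq[2], nm, "dqsum-dq")
      add(a$dq[1] + b$dq[1], b$dq[2], nm, "dqsum-dq")
      add(a$dq[2] + b$dq[2], a$dq[1], nm, "dqsum-dq")
      add(a$dq[2] + b$dq[2], b$dq[1], nm, "dqsum-dq")
    }
  }
  if ("larmor_plus_dq" %in% rules) {
    if (is.null(larmor_MHz)) stop("larmor_plus_dq requires larmor_MHz")
    for (nm in nms) {
      f <- freqs[[nm]]
      add(larmor_MHz + f$dq[1], larmor_MHz - f$dq[2], nm, "larmor+dq")
      add(larmor_MHz + f$dq[2], larmor_MHz - f$dq[1], nm, "larmor+dq")
    }
  }
  if (length(rows) == 0) {
    return(data.frame(nu1_MHz = numeric(0), nu2_MHz = numeric(0),
                      quadrant = character(0), nucleus = character(0),
                      type = character(0), amplitude = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Double-quantum frequency table of a spin system
#'
#' Computes, for each I = 1 nucleus, the dq frequency in both electron
#' manifolds at a given field direction, in the format consumed by
#' [combination_peaks()].
#'
#' @param system a [spin_system()]
#' @param field_mT static field in mT
#' @param direction field direction in the g-frame
#' @return Named list with `dq` (length 2, manifolds +1/2 then -1/2) and
#'   `n_equivalent` per I = 1 nucleus.
#' @export
dq_table <- function(system, field_mT, direction) {
  out <- list()
  for (nuc in system$nuclei) {
    if (nuc$isotope$spin != 1) next
    mf <- manifold_frequencies(nuc, field_mT, direction, system$g)
    out[[nuc$label]] <- list(
      dq = c(mf[[1]]$transitions$freq_MHz[mf[[1]]$transitions$type == "dq"],
             mf[[2]]$transitions$freq_MHz[mf[[2]]$transitions$type == "dq"]),
      n_equivalent = nuc$n_equivalent)
  }
  out
}
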