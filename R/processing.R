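#' Process a 2D time trace into a magnitude spectrum
#'
#' Applies the standard HYSCORE processing chain: per-trace polynomial
#' baseline subtraction (along t1, then along t2), apodization with a
#' Hamming window, zero-filling to the next power of two times
#' `zerofill`, two-dimensional Fourier transformation, and the magnitude
#' (absolute-value) spectrum. Frequency axes cover both signs so peaks
#' can be read in the (+,+) and (-,+) quadrants.
#'
#' @param trace a `hyscore_trace` from [time_domain()], or a plain matrix
#'   (then `dt_ns` must be given)
#' @param dt_ns time step in ns (taken from the trace object if present)
#' @param poly_order baseline polynomial order (default 3)
#' @param window apodization window, `"hamming"` or `"none"`
#' @param zerofill zero-fill factor (grid is padded to
#'   `zerofill * 2^ceiling(log2(n))`)
#' @return A list of class `spectrum2d`: `f1_MHz`, `f2_MHz` (symmetric
#'   about 0), non-negative `magnitude` matrix, and `params` recording
#'   the processing settings.
#' @export
process_2d <- function(trace, dt_ns = NULL, poly_order = 3,
                       window = c("hamming", "none"), zerofill = 2) {
  window <- match.arg(window)
  if (inherits(trace, "hyscore_trace")) {
    dt_ns <- diff(trace$t_ns[1:2])
    m <- trace$trace
  } else {
    m <- as.matrix(trace)
    if (is.null(dt_ns)) stop("dt_ns required for a plain matrix input")
  }
  n1 <- nrow(m); n2 <- ncol(m)
  if (min(n1, n2) < poly_order + 2) {
    stop("trace too short for baseline polynomial of order ", poly_order)
  }
  debase <- function(y) {
    x <- seq_along(y) / length(y)
    X <- outer(x, 0:poly_order, `^`)
    as.numeric(y - X %*% qr.coef(qr(X), y))
  }
  # baseline along t1 (columns of constant t2), then along t2
  m <- apply(m, 2, debase)
  m <- t(apply(m, 1, debase))
  if (window == "hamming") {
    w1 <- signal::hamming(n1); w2 <- signal::hamming(n2)
    m <- m * (w1 %o% w2)
  }
  npad <- function(n) zerofill * 2^ceiling(log2(n))
  p1 <- npad(n1); p2 <- npad(n2)
  pm <- matrix(0, p1, p2)
  pm[seq_len(n1), seq_len(n2)] <- m
  sp <- stats::fft(pm)
  mag <- Mod(sp)[c((p1 / 2 + 1):p1, 1:(p1 / 2)),
                 c((p2 / 2 + 1):p2, 1:(p2 / 2))]
  dt_us <- dt_ns * 1e-3
  f1 <- ((-p1 / 2):(p1 / 2 - 1)) / (p1 * dt_us)
  f2 <- ((-p2 / 2):(p2 / 2 - 1)) / (p2 * dt_us)
  structure(list(f1_MHz = f1, f2_MHz = f2, magnitude = mag,
                 params = list(dt_ns = dt_ns, poly_order = poly_order,
                               window = window, zerofill = zerofill)),
            class = "spectrum2d")
}

#' Sum magnitude spectra recorded at several tau values
#'
#' Blind spots depend on tau; summing the magnitude spectra of several
#' tau values restores suppressed correlations. All spectra must share
#' frequency axes.
#'
#' @param spectra list of `spectrum2d` objects
#' @return A `spectrum2d` with summed magnitude.
#' @export
sum_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  out <- spectra[[1]]
  if (length(spectra) > 1) {
    for (s in spectra[-1]) {
      stopifnot(length(s$f1_MHz) == length(out$f1_MHz))
      out$magnitude <- out$magnitude + s$magnitude
    }
  }
  out$params$n_summed <- length(spectra)
  out
}

#' Pick peaks from a 2D magnitude spectrum
#'
#' Finds local maxima above a relative threshold, merges maxima closer
#' than `min_sep_MHz` (keeping the strongest), and returns them sorted by
#' amplitude.
#'
#' @param spectrum a `spectrum2d`
#' @param threshold_rel relative threshold in (0, 1), fraction of the
#'   global maximum
#' @param min_sep_MHz merge radius in MHz
#' @param positive_only restrict to the f1 >= 0, f2 >= 0 region (the
#'   magnitude spectrum is centro-symmetric, so one half-plane carries
#'   all information; quadrant signs are assigned during interpretation)
#' @return Data frame with `nu1_MHz`, `nu2_MHz`, `amplitude`.
#' @export
pick_peaks <- function(spectrum, threshold_rel = 0.1, min_sep_MHz = 0.5,
                       positive_only = TRUE) {
  stopifnot(inherits(spectrum, "spectrum2d"),
            threshold_rel > 0, threshold_rel < 1)
  m <- spectrum$magnitude
  f1 <- spectrum$f1_MHz; f2 <- spectrum$f2_MHz
  thr <- threshold_rel * max(m)
  n1 <- nrow(m); n2 <- ncol(m)
  cand <- which(m >= thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    i0 <- max(1, i - 1); i1 <- min(n1, i + 1)
    j0 <- max(1, j - 1); j1 <- min(n2, j + 1)
    keep[k] <- m[i, j] >= max(m[i0:i1, j0:j1])
  }
  cand <- cand[keep, , drop = FALSE]
  pk <- data.frame(nu1_MHz = f1[cand[, 1]], nu2_MHz = f2[cand[, 2]],
                   amplitude = m[cand])
  if (positive_only) {
    pk <- pk[pk$nu1_MHz >= 0 & pk$nu2_MHz >= 0, , drop = FALSE]
  }
  pk <- pk[order(-pk$amplitude), , drop = FALSE]
  # greedy merge within min_sep
  sel <- rep(TRUE, nrow(pk))
  for (k in seq_len(nrow(pk))) {
    if (!sel[k]) next
    if (k < nrow(pk)) {
      d <- sqrt((pk$nu1_MHz[-(1:k)] - pk$nu1_MHz[k])^2 +
                (pk$nu2_MHz[-(1:k)] - pk$nu2_MHz[k])^2)
      sel[-(1:k)][d < min_sep_MHz] <- FALSE
    }
  }
  out <- pk[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
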