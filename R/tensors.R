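#' Euler rotation matrix (z-y-z, passive)
#'
#' Builds the rotation matrix \eqn{R(\alpha,\beta,\gamma) =
#' R_z(\gamma) R_y(\beta) R_z(\alpha)} used to relate the g-frame to an
#' interaction eigenframe. The convention is passive z-y-z: a tensor with
#' principal values `d` and frame angles `(a, b, c)` has g-frame matrix
#' \eqn{R^T \mathrm{diag}(d) R}. With `(90, 0, 0)` the x and y principal
#' values are interchanged in the g-frame, which is the convention under
#' which heme 14N tensor tables in the HYSCORE literature are reported.
#'
#' @param alpha,beta,gamma angles in degrees
#' @return 3x3 orthonormal rotation matrix.
#' @examples
#' euler_matrix(90, 0, 0)  # z-rotation by 90 degrees
#' @export
euler_matrix <- function(alpha, beta = 0, gamma = 0) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(b) {
    b <- b * pi / 180
    matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  }
  rz(gamma) %*% ry(beta) %*% rz(alpha)
}

#' Construct an interaction tensor
#'
#' A hyperfine or nuclear-quadrupole tensor given by its three principal
#' values (MHz) and the Euler angles (degrees) orienting its eigenframe
#' relative to the g-frame (see [euler_matrix()] for the convention).
#' Quadrupole tensors must be traceless.
#'
#' @param principal numeric length-3, principal values in MHz
#' @param euler numeric length-3, `(alpha, beta, gamma)` in degrees
#' @param kind `"hyperfine"` or `"quadrupole"`
#' @return An object of class `interaction_tensor`.
#' @examples
#' interaction_tensor(c(-4.90, -4.80, -5.10), c(90, 0, 0), "hyperfine")
#' @export
interaction_tensor <- function(principal, euler = c(0, 0, 0),
                               kind = c("hyperfine", "quadrupole")) {
  kind <- match.arg(kind)
  stopifnot(length(principal) == 3, length(euler) == 3,
            all(is.finite(principal)), all(is.finite(euler)))
  if (kind == "quadrupole" && abs(sum(principal)) > 1e-6) {
    stop("quadrupole tensor must be traceless (|trace| <= 1e-6 MHz), got trace ",
         signif(sum(principal), 4), " MHz")
  }
  structure(list(principal = as.numeric(principal),
                 euler = as.numeric(euler), kind = kind),
            class = "interaction_tensor")
}

#' Tensor matrix in the g-frame
#'
#' Rotates an interaction tensor from its eigenframe into the g-frame:
#' \eqn{M = R(\alpha,\beta,\gamma)^T \mathrm{diag}(p) R(\alpha,\beta,\gamma)}.
#'
#' @param t an [interaction_tensor()]
#' @return Symmetric 3x3 matrix in MHz.
#' @examples
#' tensor_lab_matrix(interaction_tensor(c(1, 2, 3)))  # diagonal
#' @export
tensor_lab_matrix <- function(t) {
  stopifnot(inherits(t, "interaction_tensor"))
  R <- euler_matrix(t$euler[1], t$euler[2], t$euler[3])
  m <- t(R) %*% diag(t$principal) %*% R
  (m + t(m)) / 2  # enforce exact symmetry against rounding
}

#' Axial hyperfine tensor from (a_iso, T)
#'
#' Convenience constructor for the axial hyperfine tensors used for
#' protons and deuterons: principal values
#' \eqn{(a_{iso} - T,\; a_{iso} - T,\; a_{iso} + 2T)} with the unique axis
#' along the eigenframe z, tilted into the g-frame by the Euler angles.
#'
#' @param a_iso isotropic coupling in MHz
#' @param T_ax axial anisotropic coupling T in MHz
#' @param alpha,beta Euler angles in degrees (no gamma is needed for an
#'   axial tensor)
#' @return An [interaction_tensor()] of kind hyperfine.
#' @export
axial_hyperfine <- function(a_iso, T_ax, alpha = 0, beta = 0) {
  interaction_tensor(c(a_iso - T_ax, a_iso - T_ax, a_iso + 2 * T_ax),
                     c(alpha, beta, 0), "hyperfine")
}

#' Define a coupled nucleus
#'
#' @param isotope isotope label or [isotope_lookup()] result
#' @param A hyperfine [interaction_tensor()]
#' @param Q quadrupole [interaction_tensor()], required iff the nuclear
#'   spin I > 1/2 (pass `NULL` for I = 1/2)
#' @param label optional name used in peak lists (e.g. `"H1"`, `"N1"`)
#' @param n_equivalent number of magnetically equivalent nuclei sharing
#'   this tensor set (heme nitrogens come in equivalent pairs)
#' @return An object of class `nucleus`.
#' @export
nucleus <- function(isotope, A, Q = NULL, label = NULL, n_equivalent = 1) {
  iso <- isotope_lookup(isotope)
  stopifnot(inherits(A, "interaction_tensor"))
  if (iso$spin > 0.5 && is.null(Q)) {
    stop("isotope ", iso$name, " has I = ", iso$spin,
         " and requires a quadrupole tensor Q")
  }
  if (iso$spin == 0.5 && !is.null(Q)) {
    stop("I = 1/2 isotope ", iso$name, " cannot carry a quadrupole tensor")
  }
  if (!is.null(Q)) stopifnot(inherits(Q, "interaction_tensor"))
  structure(list(isotope = iso, A = A, Q = Q,
                 label = if (is.null(label)) iso$name else label,
                 n_equivalent = as.integer(n_equivalent)),
            class = "nucleus")
}

#' Construct a spin system
#'
#' One electron spin S = 1/2 with rhombic g and a list of coupled nuclei.
#' The g-frame axes are named so that x carries the smallest and z the
#' largest principal g-value (in low-spin hemes g_z lies along the heme
#' normal); inputs in any order are re-sorted with a warning.
#'
#' @param g numeric length-3 of positive principal g-values, ideally
#'   ordered `(g_x, g_y, g_z)` ascending
#' @param nuclei list of [nucleus()] objects
#' @return An object of class `spin_system` with elements `g`
#'   (ascending, `(g_x, g_y, g_z)`) and `nuclei`.
#' @examples
#' ss <- spin_system(c(1.923, 2.253, 2.443),
#'                   list(nucleus("1H", axial_hyperfine(-0.09, 5.6, 0, 22))))
#' @export
spin_system <- function(g, nuclei = list()) {
  stopifnot(length(g) == 3, all(g > 0))
  if (is.unsorted(g)) {
    warning("g principal values re-sorted to ascending (g_x <= g_y <= g_z)")
    g <- sort(g)
  }
  if (inherits(nuclei, "nucleus")) nuclei <- list(nuclei)
  stopifnot(all(vapply(nuclei, inherits, logical(1), "nucleus")))
  structure(list(g = as.numeric(g), nuclei = nuclei), class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system>  g = (%.4g, %.4g, %.4g)  [x, y, z]\n",
              x$g[1], x$g[2], x$g[3]))
  for (nuc in x$nuclei) {
    cat(sprintf("  %-4s %-3s A = (%s) MHz, euler (%s) deg%s%s\n",
                nuc$label, nuc$isotope$name,
                paste(signif(nuc$A$principal, 4), collapse = ", "),
                paste(nuc$A$euler, collapse = ", "),
                if (!is.null(nuc$Q))
                  sprintf(", Q = (%s) MHz",
                          paste(signif(nuc$Q$principal, 4), collapse = ", "))
                else "",
                if (nuc$n_equivalent > 1)
                  sprintf(" x%d equivalent", nuc$n_equivalent) else ""))
  }
  invisible(x)
}

# ---- JSON serialization -----------------------------------------------------

#' Serialize a spin system to JSON
#'
#' Principal values are stored in MHz and angles in degrees; the document
#' round-trips losslessly through [spin_system_from_json()].
#'
#' @param system a [spin_system()]
#' @param path optional file path; if omitted the JSON string is returned
#' @return JSON string (invisibly, if written to `path`).
#' @export
spin_system_to_json <- function(system, path = NULL) {
  stopifnot(inherits(system, "spin_system"))
  doc <- list(
    g = system$g,
    nuclei = lapply(system$nuclei, function(n) {
      out <- list(isotope = n$isotope$name, label = n$label,
                  n_equivalent = n$n_equivalent,
                  A = list(principal = n$A$principal, euler = n$A$euler))
      if (!is.null(n$Q)) {
        out$Q <- list(principal = n$Q$principal, euler = n$Q$euler)
      }
      out
    })
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a spin system from JSON
#'
#' @param path file path or a JSON string produced by
#'   [spin_system_to_json()]
#' @return A [spin_system()].
#' @export
spin_system_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  nuclei <- lapply(doc$nuclei, function(n) {
    A <- interaction_tensor(unlist(n$A$principal), unlist(n$A$euler),
                            "hyperfine")
    Q <- if (!is.null(n$Q)) {
      interaction_tensor(unlist(n$Q$principal), unlist(n$Q$euler),
                         "quadrupole")
    }
    nucleus(n$isotope, A, Q, label = n$label,
            n_equivalent = if (is.null(n$n_equivalent)) 1 else n$n_equivalent)
  })
  spin_system(unlist(doc$g), nuclei)
}
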