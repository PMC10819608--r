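#' Physical constants (CODATA 2018)
#'
#' Fundamental constants used throughout the package, pinned to the CODATA
#' 2018 adjustment so that printed-value regression tests are stable across
#' platforms and releases.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{bohr_magneton}{\eqn{\mu_B} in J/T}
#'     \item{nuclear_magneton}{\eqn{\mu_N} in J/T}
#'     \item{planck}{\eqn{h} in J s}
#'     \item{mu0_over_4pi}{\eqn{\mu_0/4\pi} in T^2 m^3 / J}
#'     \item{free_electron_g}{\eqn{g_e}, dimensionless}
#'     \item{codata}{the CODATA release the values are taken from}
#'   }
#' @examples
#' physical_constants()$free_electron_g
#' @export
physical_constants <- function() {
  list(
    bohr_magneton    = 9.2740100783e-24,
    nuclear_magneton = 5.0507837461e-27,
    planck           = 6.62607015e-34,
    mu0_over_4pi     = 1e-7,
    free_electron_g  = 2.00231930436256,
    codata           = "CODATA-2018"
  )
}

# internal shorthand; never mutated
.const <- list(
  muB  = 9.2740100783e-24,
  muN  = 5.0507837461e-27,
  h    = 6.62607015e-34,
  mu04 = 1e-7,
  ge   = 2.00231930436256
)

# nuclear g-factors (signed) and spins; standard isotope tables
.isotopes <- data.frame(
  name = c("1H", "2H", "14N", "15N"),
  spin = c(0.5, 1, 1, 0.5),
  g_n  = c(5.5856946893, 0.8574382338, 0.4037610, -0.5663778),
  stringsAsFactors = FALSE
)

#' Look up a magnetic isotope
#'
#' Registry of the nuclei handled by the simulation engine. Nuclear
#' g-factors are signed (15N is negative).
#'
#' @param name isotope label, one of `"1H"`, `"2H"`, `"14N"`, `"15N"`
#' @return An object of class `isotope`: a list with `name`, `spin`
#'   (1/2 or 1) and signed dimensionless `g_n`.
#' @examples
#' isotope_lookup("1H")$g_n
#' isotope_lookup("15N")$spin
#' @export
isotope_lookup <- function(name) {
  if (inherits(name, "isotope")) return(name)
  i <- match(name, .isotopes$name)
  if (is.na(i)) {
    stop("unknown isotope '", name, "'; supported: ",
         paste(.isotopes$name, collapse = ", "))
  }
  structure(list(name = .isotopes$name[i], spin = .isotopes$spin[i],
                 g_n = .isotopes$g_n[i]),
            class = "isotope")
}

#' @export
print.isotope <- function(x, ...) {
  cat(sprintf("<isotope %s>  I = %s, g_n = %+.7f\n", x$name,
              format(x$spin), x$g_n))
  invisible(x)
}

#' Nuclear Larmor frequency
#'
#' \eqn{\nu_I = |g_n| \mu_N B_0 / h}, the free nuclear precession frequency
#' at a given static field.
#'
#' @param isotope an isotope label or [isotope_lookup()] result
#' @param field_mT static magnetic field in millitesla (non-negative)
#' @return Larmor frequency in MHz.
#' @examples
#' larmor_frequency("1H", 283.1)   # ~12.05 MHz
#' larmor_frequency("14N", 283.1)  # ~0.871 MHz
#' @export
larmor_frequency <- function(isotope, field_mT) {
  iso <- isotope_lookup(isotope)
  if (any(field_mT < 0)) stop("field must be non-negative")
  abs(iso$g_n) * .const$muN * field_mT * 1e-3 / .const$h / 1e6
}

#' Resonance field for a given effective g-value
#'
#' Converts an effective g-value and microwave frequency to the resonant
#' static field, \eqn{B_0 = h\nu_{mw}/(g_{eff}\mu_B)}. Used to place
#' observer positions at the principal g-values of a powder spectrum.
#'
#' @param g_eff effective g-value (> 0)
#' @param mw_freq_GHz microwave frequency in GHz (> 0)
#' @return Field in mT.
#' @examples
#' resonance_field(2.443, 9.68)  # ~283.1 mT
#' @export
resonance_field <- function(g_eff, mw_freq_GHz) {
  if (any(g_eff <= 0) || any(mw_freq_GHz <= 0)) {
    stop("g_eff and mw_freq must be positive")
  }
  .const$h * mw_freq_GHz * 1e9 / (g_eff * .const$muB) * 1e3
}
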