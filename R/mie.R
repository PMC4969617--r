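#' @section Mie machinery:
#' Cross-sections are computed from partial-wave (Mie) coefficients
#' \eqn{a_n, b_n}. The solid-sphere path uses the logarithmic-derivative
#' downward recurrence for the internal Riccati--Bessel ratio, which is
#' numerically stable for strongly absorbing media; the coated-sphere
#' path matches the tangential-field impedance ratios at both interfaces
#' with the shell's standing-wave functions kept as explicit
#' \eqn{\psi,\chi} pairs computed by stable (downward for \eqn{\psi},
#' upward for \eqn{\chi}) recurrences.
#' @name mie-internals
#' @keywords internal
NULL

#' Wiscombe series truncation order
#'
#' `n_max = ceil(x + 4 x^(1/3) + 2)` for size parameter `x`.
#'
#' @param x Size parameter (dimensionless, > 0).
#' @return Integer truncation order.
#' @export
n_max_wiscombe <- function(x) {
  stopifnot(is.finite(x), x > 0)
  as.integer(ceiling(x + 4 * x^(1 / 3) + 2))
}

# Riccati-Bessel psi_n, chi_n and derivatives for REAL argument, n = 0..nmax.
# psi_n(x) = x j_n(x) via half-integer Bessel J; chi_n(x) = -x y_n(x).
riccati_real <- function(x, nmax) {
  n <- 0:nmax
  fac <- sqrt(pi * x / 2)
  psi <- fac * besselJ(x, n + 0.5)
  chi <- -fac * besselY(x, n + 0.5)
  list(psi = psi, chi = chi,
       dpsi = ricatti_deriv(psi, x),
       dchi = ricatti_deriv(chi, x))
}

# f'_n = f_{n-1} - (n/z) f_n for n >= 1; f'_0 from f'_0(psi)=cos etc. is
# never used downstream (sums start at n = 1), so slot 1 is NA.
ricatti_deriv <- function(f, z) {
  nmax <- length(f) - 1L
  n <- 1:nmax
  c(NA_real_ * f[1L], f[n] - (n / z) * f[n + 1L])
}

# Logarithmic derivative D_n(z) = psi'_n(z)/psi_n(z), n = 1..nmax,
# downward recurrence D_{n-1} = n/z - 1/(D_n + n/z) started at zero
# nmax + 15 + |z| orders above the highest order used.
log_derivative_down <- function(z, nmax) {
  nstart <- nmax + 15L + as.integer(ceiling(Mod(z)))
  D <- complex(nstart + 1L)                 # D[i] holds D_{i-1}(z)
  for (n in nstart:1L) {
    D[n] <- n / z - 1 / (D[n + 1L] + n / z)
  }
  D[2:(nmax + 1L)]
}

# psi_n and chi_n (and derivatives) for COMPLEX argument, n = 0..nmax.
# psi by Miller downward recurrence normalised at psi_0 = sin(z);
# chi by upward recurrence (the growing solution, stable upward).
riccati_complex <- function(z, nmax) {
  nstart <- nmax + 15L + as.integer(ceiling(Mod(z)))
  p <- complex(nstart + 2L)
  p[nstart + 2L] <- 0 + 0i
  p[nstart + 1L] <- 1e-30 + 0i
  for (n in nstart:1L) {           # p[n] ~ psi_{n-1} unnormalised
    p[n] <- (2 * n + 1) / z * p[n + 1L] - p[n + 2L]
  }
  psi <- p[1:(nmax + 1L)] * (sin(z) / p[1L])
  chi <- complex(nmax + 1L)
  chi[1L] <- cos(z)
  if (nmax >= 1L) chi[2L] <- cos(z) / z + sin(z)
  if (nmax >= 2L) {
    for (n in 1:(nmax - 1L)) {
      chi[n + 2L] <- (2 * n + 1) / z * chi[n + 1L] - chi[n]
    }
  }
  list(psi = psi, chi = chi,
       dpsi = ricatti_deriv_c(psi, z),
       dchi = ricatti_deriv_c(chi, z))
}

ricatti_deriv_c <- function(f, z) {
  nmax <- length(f) - 1L
  n <- 1:nmax
  c(NA_complex_, f[n] - (n / z) * f[n + 1L])
}

#' Partial-wave coefficients for a solid sphere
#'
#' Computes the Mie coefficients \eqn{a_n, b_n} for a homogeneous sphere
#' of size parameter `x` and refractive index `m` relative to the
#' medium, using the logarithmic-derivative downward recurrence.
#'
#' @param x Size parameter \eqn{2\pi n_{med} R / \lambda} (> 0).
#' @param m Complex refractive index relative to the medium.
#' @param n_max Truncation order; defaults to [n_max_wiscombe()].
#' @return Tibble with columns `n`, `a`, `b` (complex).
#' @export
#' @examples
#' mie_solid(0.5, complex(real = 1.5, imaginary = 0.1))
mie_solid <- function(x, m, n_max = NULL) {
  if (!is.finite(x) || x <= 0) abort("size parameter x must be finite and > 0")
  m <- as.complex(m)
  if (!is.finite(Re(m)) || !is.finite(Im(m))) abort("index m must be finite")
  n_max <- n_max %||% n_max_wiscombe(x)
  stopifnot(n_max >= 1L)
  n <- 1:n_max
  if (identical(m, as.complex(1))) {            # index-matched: no scatterer
    return(tibble::tibble(n = n, a = complex(n_max), b = complex(n_max)))
  }
  rb <- riccati_real(x, n_max)
  xi <- rb$psi - 1i * rb$chi
  D <- log_derivative_down(m * x, n_max)
  psi_n <- rb$psi[n + 1L]; psi_nm1 <- rb$psi[n]
  xi_n <- xi[n + 1L]; xi_nm1 <- xi[n]
  ta <- D / m + n / x
  tb <- D * m + n / x
  a <- (ta * psi_n - psi_nm1) / (ta * xi_n - xi_nm1)
  b <- (tb * psi_n - psi_nm1) / (tb * xi_n - xi_nm1)
  tibble::tibble(n = n, a = a, b = b)
}

#' Partial-wave coefficients for a coated (core--shell) sphere
#'
#' Matches tangential-field impedance ratios at the core and outer
#' interfaces. The shell standing wave is carried as an explicit
#' \eqn{\psi - A\chi} pair whose components are computed with stable
#' recurrences, so metallic (strongly absorbing) shells do not overflow.
#'
#' @param x_core,x_outer Size parameters of core and outer boundaries;
#'   `0 < x_core < x_outer`.
#' @param m_core,m_shell Complex refractive indices relative to the
#'   medium.
#' @param n_max Truncation order; defaults to [n_max_wiscombe()] at
#'   `x_outer`.
#' @return Tibble with columns `n`, `a`, `b` (complex).
#' @export
mie_coated <- function(x_core, x_outer, m_core, m_shell, n_max = NULL) {
  if (!is.finite(x_core) || !is.finite(x_outer) ||
      x_core <= 0 || x_core >= x_outer) {
    abort("need 0 < x_core < x_outer (coated-sphere geometry)")
  }
  m_core <- as.complex(m_core); m_shell <- as.complex(m_shell)
  if (any(!is.finite(c(Re(m_core), Im(m_core), Re(m_shell), Im(m_shell))))) {
    abort("refractive indices must be finite")
  }
  n_max <- n_max %||% n_max_wiscombe(x_outer)
  stopifnot(n_max >= 1L)
  n <- 1:n_max
  i1 <- n + 1L                      # index of order n in 0-based arrays
  u <- riccati_complex(m_core * x_core, n_max)   # core,   at core boundary
  v <- riccati_complex(m_shell * x_core, n_max)  # shell,  at core boundary
  w <- riccati_complex(m_shell * x_outer, n_max) # shell,  at outer boundary
  yb <- riccati_real(x_outer, n_max)             # medium, at outer boundary
  xi <- yb$psi - 1i * yb$chi
  dxi <- yb$dpsi - 1i * yb$dchi

  m1 <- m_core; m2 <- m_shell
  # TM (a-type): continuity of psi'/(m psi) across each interface
  A <- (m1 * u$psi[i1] * v$dpsi[i1] - m2 * u$dpsi[i1] * v$psi[i1]) /
       (m1 * u$psi[i1] * v$dchi[i1] - m2 * u$dpsi[i1] * v$chi[i1])
  # TE (b-type): continuity of m psi'/psi
  B <- (m2 * u$psi[i1] * v$dpsi[i1] - m1 * u$dpsi[i1] * v$psi[i1]) /
       (m2 * u$psi[i1] * v$dchi[i1] - m1 * u$dpsi[i1] * v$chi[i1])

  Ua <- w$psi[i1] - A * w$chi[i1]
  dUa <- w$dpsi[i1] - A * w$dchi[i1]
  Ub <- w$psi[i1] - B * w$chi[i1]
  dUb <- w$dpsi[i1] - B * w$dchi[i1]

  a <- (m2 * Ua * yb$dpsi[i1] - dUa * yb$psi[i1]) /
       (m2 * Ua * dxi[i1] - dUa * xi[i1])
  b <- (Ub * yb$dpsi[i1] - m2 * dUb * yb$psi[i1]) /
       (Ub * dxi[i1] - m2 * dUb * xi[i1])
  tibble::tibble(n = n, a = a, b = b)
}

#' Cross-sections from partial-wave coefficients
#'
#' Standard Mie sums: \eqn{C_{ext} = (2\pi/k^2)\sum (2n+1)\,\Re(a_n+b_n)}
#' and \eqn{C_{sca} = (2\pi/k^2)\sum (2n+1)(|a_n|^2+|b_n|^2)} with
#' \eqn{k = 2\pi n_{med}/\lambda}; \eqn{C_{abs} = C_{ext} - C_{sca}}.
#' A tiny negative \eqn{C_{abs}} (relative magnitude below `1e-6`) is
#' clamped to zero; anything larger signals an unconverged series and is
#' an error.
#'
#' @param coefficients Tibble from [mie_solid()] or [mie_coated()].
#' @param wavelength_nm Vacuum wavelength in nm.
#' @param medium_index Real refractive index of the surrounding medium.
#' @return One-row tibble with `C_abs_nm2`, `C_sca_nm2`, `C_ext_nm2`.
#' @export
cross_sections <- function(coefficients, wavelength_nm, medium_index) {
  stopifnot(all(c("n", "a", "b") %in% names(coefficients)),
            is.finite(wavelength_nm), wavelength_nm > 0,
            is.finite(medium_index), medium_index > 0)
  n <- coefficients$n
  a <- coefficients$a
  b <- coefficients$b
  k <- 2 * pi * medium_index / wavelength_nm      # nm^-1
  pref <- 2 * pi / k^2                            # nm^2
  c_ext <- pref * sum((2 * n + 1) * Re(a + b))
  c_sca <- pref * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  c_abs <- c_ext - c_sca
  if (c_abs < 0) {
    scale <- max(c_sca, abs(c_ext), .Machine$double.eps)
    if (abs(c_abs) <= 1e-6 * scale) {
      c_abs <- 0
    } else {
      abort(paste0("C_abs is negative beyond numerical tolerance; the ",
                   "partial-wave series has not converged (raise n_max)"))
    }
  }
  tibble::tibble(C_abs_nm2 = c_abs, C_sca_nm2 = c_sca, C_ext_nm2 = c_ext)
}

#' Partial-wave coefficients for a particle specification
#'
#' Resolves materials at `wavelength_nm`, forms size parameters and
#' relative indices, and dispatches to [mie_solid()] or [mie_coated()].
#'
#' @inheritParams cross_sections
#' @param particle A [particle_spec()].
#' @param n_max Optional truncation override.
#' @return Tibble of coefficients as from [mie_solid()].
#' @export
mie_coefficients <- function(particle, wavelength_nm, medium_index = 1.33,
                             n_max = NULL) {
  stopifnot(inherits(particle, "particle_spec"))
  k_factor <- 2 * pi * medium_index / wavelength_nm
  x_outer <- k_factor * particle$outer_radius_nm
  m_shell <- interpolate_index(particle$shell_material, wavelength_nm) /
    medium_index
  if (particle$kind == "solid") {
    mie_solid(x_outer, m_shell, n_max = n_max)
  } else {
    x_core <- k_factor * particle$core_radius_nm
    m_core <- interpolate_index(particle$core_material, wavelength_nm) /
      medium_index
    mie_coated(x_core, x_outer, m_core, m_shell, n_max = n_max)
  }
}
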