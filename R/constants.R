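# CODATA 2018 constants (SI)
.phys <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  Navo = 6.02214076e23      # Avogadro constant, 1/mol
)

#' Bjerrum length
#'
#' Separation at which two unit charges in a uniform dielectric interact with
#' thermal energy kBT.  This is the single point where SI electrostatics is
#' converted to the package's internal units (lengths in Angstrom, energies
#' in kBT, charges in units of e); every Coulomb energy downstream is
#' \code{q_i q_j lB / r}.
#'
#' @param eps relative dielectric constant of the solvent (dimensionless).
#' @param temperature absolute temperature, K.
#' @return Bjerrum length in Angstrom (about 7.2 A for water at 298.15 K).
#' @examples
#' bjerrum_length(78, 298.15)
#' @export
bjerrum_length <- function(eps = 78, temperature = 298.15) {
  if (!is.numeric(eps) || length(eps) != 1 || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a positive number")
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a positive number")
  lb_m <- .phys$e^2 / (4 * pi * .phys$eps0 * eps * .phys$kB * temperature)
  lb_m * 1e10
}

#' Convert a molar salt concentration to a number density
#'
#' @param c0 concentration in mol/L.
#' @return number density in Angstrom^-3.
#' @export
number_density <- function(c0) {
  c0 * .phys$Navo * 1e-27
}

#' Debye screening length of a symmetric z:z electrolyte
#'
#' @param z salt valence (1 or 2 for the systems studied here).
#' @param c0 bulk salt concentration, mol/L.
#' @inheritParams bjerrum_length
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(z, c0, eps = 78, temperature = 298.15) {
  if (c0 <= 0) stop("'c0' must be positive")
  lB <- bjerrum_length(eps, temperature)
  kappa2 <- 4 * pi * lB * 2 * number_density(c0) * z^2
  1 / sqrt(kappa2)
}

# inverse Debye length, A^-1
inv_debye <- function(z, c0, eps = 78, temperature = 298.15) {
  1 / debye_length(z, c0, eps, temperature)
}

# 1 nN * 1 A = 1e-19 J expressed in kBT at the given temperature
nn_angstrom_in_kbt <- function(temperature = 298.15) {
  1e-19 / (.phys$kB * temperature)
}

# spring constant nN/A -> kBT/A^2 (same numeric factor as above)
spring_kbt <- function(k_nn, temperature = 298.15) {
  k_nn * nn_angstrom_in_kbt(temperature)
}
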