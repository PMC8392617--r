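# Action-revised transition-state quantities: Boltzmann activated
# fractions, kT/h rate constants, forward/reverse ratios, and the radial
# action of vibrationally excited states.

#' Boltzmann fraction of molecules in an activated state
#'
#' `N*/N0 = exp(-eps/(R T))` for a molar activation energy `eps` — the
#' relative concentration of the activated transition state when the
#' energy to reach it (taken as the bond enthalpy to break, for an
#' uncatalysed reaction) is `eps`.
#'
#' @param eps_kJ_mol Activation energy, kJ/mol (>= 0).
#' @param T Temperature, K.
#' @return Dimensionless fraction in (0, 1].
#' @examples
#' activated_fraction(436, 1000)  # ~1.7e-23: H2 bond rupture at 1000 K
#' @export
activated_fraction <- function(eps_kJ_mol, T) {
  stopifnot(eps_kJ_mol >= 0, T > 0)
  exp(-eps_kJ_mol * 1000 / (.R * T))
}

#' Universal attempt frequency kT/h
#'
#' @param T Temperature, K.
#' @return Frequency in s^-1 (about 6.25e12 at 300 K).
#' @examples
#' universal_frequency(300)
#' @export
universal_frequency <- function(T) {
  stopifnot(T > 0)
  .k * T / .h
}

#' Forward and reverse transition-state rate constants
#'
#' `k_f = (kT/h) exp(-eps_f/RT)` and `k_r = (kT/h) exp(-eps_r/RT)` with
#' unit transmission coefficient; the ratio `k_f/k_r =
#' exp((eps_r - eps_f)/RT)`.  When the activation energies are the bond
#' enthalpies of the bonds broken in each direction (the default when a
#' reaction with a bond inventory is supplied), `eps_r - eps_f` equals the
#' negative bond reaction enthalpy and the ratio is the enthalpic part of
#' the equilibrium constant.
#'
#' @param T Temperature, K.
#' @param eps_f,eps_r Forward / reverse activation energies, kJ/mol.
#'   Default to the reactant / product bond totals of `rxn`.
#' @param rxn Optional [reaction()] with a bond inventory.
#' @param bonds Bond-enthalpy table used with `rxn` (defaults to the
#'   built-in table).
#' @return Object of class `activation_result`: list with `T`,
#'   `universal_freq` (s^-1), `eps_f`, `eps_r` (kJ/mol), `fraction_f`,
#'   `fraction_r`, `k_f`, `k_r` (s^-1) and `ratio` (= `k_f/k_r`).
#' @examples
#' rate_constants(298.15, rxn = rxn_haber())
#' @export
rate_constants <- function(T, eps_f = NULL, eps_r = NULL, rxn = NULL,
                           bonds = default_registry()$bonds) {
  if (!is.null(rxn)) {
    ae <- bond_activation_energies(rxn, bonds)
    if (is.null(eps_f)) eps_f <- ae$forward
    if (is.null(eps_r)) eps_r <- ae$reverse
  }
  if (is.null(eps_f) || is.null(eps_r))
    stop("eps_f and eps_r must be given (or derivable from rxn)",
         call. = FALSE)
  nu <- universal_frequency(T)
  f_f <- activated_fraction(eps_f, T)
  f_r <- activated_fraction(eps_r, T)
  structure(list(T = T, universal_freq = nu, eps_f = eps_f, eps_r = eps_r,
                 fraction_f = f_f, fraction_r = f_r,
                 k_f = nu * f_f, k_r = nu * f_r,
                 ratio = exp((eps_r - eps_f) * 1000 / (.R * T))),
            class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf("<activation_result> at %g K (kT/h = %.4g /s)\n",
              x$T, x$universal_freq))
  cat(sprintf("  forward: eps = %g kJ/mol, N*/N0 = %.4g, k_f = %.4g /s\n",
              x$eps_f, x$fraction_f, x$k_f))
  cat(sprintf("  reverse: eps = %g kJ/mol, N*/N0 = %.4g, k_r = %.4g /s\n",
              x$eps_r, x$fraction_r, x$k_r))
  cat(sprintf("  k_f/k_r = %.4g\n", x$ratio))
  invisible(x)
}

#' Radial action of vibrationally excited states
#'
#' For a mode of wavenumber `nu` at temperature `T`, level `n` lies
#' `n h c nu` above the zero point and is occupied in the ratio
#' `N0/Nn = exp(n x)` with `x = Theta_vib/T`.  Equating the Boltzmann
#' depletion with a translational expansion, the excited molecule's mean
#' separation radius (and translational action) grows by
#' `r_n/r_0 = (N0/Nn)^(1/3)`, and the translational ergal shift
#' `kT ln (r_n/r_0)^3` recovers exactly the vibrational excitation energy
#' `n h c nu` — the identities the table asserts per row.
#'
#' @param wavenumber Mode wavenumber, cm^-1.
#' @param T Temperature, K.
#' @param n_levels Highest excitation level (>= 1).
#' @return data.frame with one row per level `n = 0 ... n_levels`:
#'   `n`, `delta_eps_J` (J per molecule above zero point),
#'   `occupancy_ratio` (`N0/Nn`), `volume_ratio` (equal to it),
#'   `radius_ratio` and `ergal_shift_J`.
#' @examples
#' radial_excitation_table(667, 288, 1)  # CO2 bending mode: ratio 28.0
#' @export
radial_excitation_table <- function(wavenumber, T, n_levels) {
  stopifnot(wavenumber > 0, T > 0, n_levels >= 1)
  n <- 0:n_levels
  x <- .hc_k * wavenumber / T
  occupancy <- exp(n * x)
  radius <- occupancy^(1/3)
  data.frame(n = n,
             delta_eps_J = n * .h * 2.99792458e10 * wavenumber,
             occupancy_ratio = occupancy,
             volume_ratio = occupancy,
             radius_ratio = radius,
             ergal_shift_J = .k * T * log(radius^3))
}
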