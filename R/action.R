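# Action variables, quantum numbers and partition factors at a state point.
#
# Translational action  @_t = (3 k T I_t)^(1/2) / z_t^(1/3),  I_t = m r_t^2
# Rotational action     @_r = (2 k T I_r)^(1/2)   (linear rotors)
# normalised by hbar these give the quantum numbers n_t and j_r; the
# entropy assembly consumes n_t^3 and a rotational partition factor
# (j_r^2/sigma for linear rotors, the classical asymmetric-rotor factor
# for nonlinear ones).

#' Mean molecular volume and separation radius
#'
#' The volume allotted to one molecule of an ideal gas, `a^3 = kT/p`, and
#' the mean separation radius `r_t = a/2`.
#'
#' @param cond A [thermo_conditions()].
#' @return List with `a3` (m^3) and `r_t` (m).
#' @examples
#' mean_volume_and_radius(thermo_conditions(1000))
#' @export
mean_volume_and_radius <- function(cond) {
  stopifnot(inherits(cond, "thermo_conditions"))
  a3 <- .k * cond$T / cond$p
  list(a3 = a3, r_t = a3^(1/3) / 2)
}

#' Translational action and quantum number
#'
#' Evaluates the translational action `@_t = sqrt(3 k T m r_t^2) /
#' z_t^(1/3)` and the corresponding quantum numbers `n_t = @_t/hbar`
#' (z_t-corrected) and `n_t_raw = sqrt(3 k T I_t)/hbar` (uncorrected; the
#' convention used when counting virtual quanta).
#'
#' @param cond A [thermo_conditions()].
#' @param molar_mass Molar mass in Da.
#' @return List with `at` (J s), `n_t`, `n_t_raw` (dimensionless) and
#'   `I_t` (kg m^2).
#' @examples
#' translational_action(thermo_conditions(1000), 2.016)$n_t_raw  # ~288
#' @export
translational_action <- function(cond, molar_mass) {
  stopifnot(molar_mass > 0)
  r_t <- mean_volume_and_radius(cond)$r_t
  m <- molar_mass * .amu
  I_t <- m * r_t^2
  at_raw <- sqrt(3 * .k * cond$T * I_t)
  at <- at_raw / .z_t^(1/3)
  list(at = at, n_t = at / .hbar, n_t_raw = at_raw / .hbar, I_t = I_t)
}

#' Rotational action and partition factor
#'
#' For linear rotors the action is `@_r = sqrt(2 k T I_r)` and the
#' partition factor entering the entropy assembly is `j_r^2/sigma =
#' 2 k T I_r / (sigma hbar^2)`, identical to the classical linear-rotor
#' partition function `8 pi^2 I k T / (sigma h^2)`.  For nonlinear rotors
#' the classical asymmetric-rotor factor
#' `(sqrt(pi)/sigma) * sqrt(T^3 / (Theta_A Theta_B Theta_C))` is used and
#' no single action is defined (`ar` is `NA`).
#'
#' @param spec A [molecule_spec()]; must not be monatomic.
#' @param T Temperature in K.
#' @return List with `ar` (J s, `NA` for nonlinear) and `rot_factor`
#'   (dimensionless).
#' @examples
#' reg <- default_registry()
#' rotational_action(reg$species$H2, 1000)$rot_factor  # ~5.7
#' @export
rotational_action <- function(spec, T) {
  stopifnot(inherits(spec, "molecule_spec"), T > 0)
  if (spec$geometry == "monatomic")
    stop("monatomic species have no rotational action", call. = FALSE)
  if (spec$geometry == "linear") {
    I_r <- spec$principal_inertias[1]
    ar <- sqrt(2 * .k * T * I_r)
    list(ar = ar, rot_factor = 2 * .k * T * I_r / (spec$sigma * .hbar^2))
  } else {
    theta <- characteristic_temperatures(spec)$theta_rot
    list(ar = NA_real_,
         rot_factor = sqrt(pi) / spec$sigma * sqrt(T^3 / prod(theta)))
  }
}

#' Vibrational entropy sum, thermal energy and heat capacity
#'
#' Per mode `i` with degeneracy `g_i` and `x_i = Theta_vib,i / T`:
#' \itemize{
#'   \item `fvib = sum g_i * (x_i/(exp(x_i)-1) - log(1-exp(-x_i)))`
#'     (dimensionless; enters the entropy as `R * fvib`),
#'   \item `evib = R * sum g_i * Theta_i/(exp(x_i)-1)` (J/mol),
#'   \item `cvib = R * sum g_i * x_i^2/(2*(cosh(x_i)-1))` (J mol^-1 K^-1).
#' }
#' All three vanish for monatomic species and in the `T -> 0` limit; per
#' nondegenerate mode `cvib -> R` as `T -> Inf`.
#'
#' @param spec A [molecule_spec()].
#' @param T Temperature in K.
#' @return List with `fvib`, `evib`, `cvib`.
#' @examples
#' reg <- default_registry()
#' vibrational_terms(reg$species$CO2, 288)
#' @export
vibrational_terms <- function(spec, T) {
  stopifnot(inherits(spec, "molecule_spec"), T > 0)
  if (is.null(spec$vib_modes))
    return(list(fvib = 0, evib = 0, cvib = 0))
  theta <- .hc_k * spec$vib_modes[, 1]
  g <- spec$vib_modes[, 2]
  x <- theta / T
  em1 <- expm1(x)
  list(fvib = sum(g * (x / em1 - log1p(-exp(-x)))),
       evib = .R * sum(g * theta / em1),
       cvib = .R * sum(g * x^2 / (2 * (cosh(x) - 1))))
}
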