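# Absolute molar state functions per species and state point.
#
# Entropy assembly:  S/R = c + ln(n_t^3 * rot_factor * q_e) + fvib
# with c = 5/2 (monatomic; rot_factor absent), 7/2 (linear), 4 (nonlinear:
# 3/2 translational + 3/2 rotational + 1 pV).  Enthalpy H = c*RT + Evib
# with the same c; E = H - RT; G = H - ST; A = E - ST = G - RT.

.geom_const <- c(monatomic = 2.5, linear = 3.5, nonlinear = 4)

#' Absolute molar entropy of a gas species
#'
#' Assembles the absolute (third-law) entropy from the translational,
#' rotational, vibrational and electronic partition factors:
#' `S = R * (c + ln(n_t^3 * rot_factor * q_e) + fvib)` with
#' `c = 5/2, 7/2, 4` for monatomic, linear and nonlinear species.
#' Only the translational quantum number responds to pressure, so
#' `dS/d(ln p)` at fixed temperature is exactly `-R`.
#'
#' @param spec A [molecule_spec()].
#' @param cond A [thermo_conditions()].
#' @return Entropy in J K^-1 mol^-1.
#' @examples
#' reg <- default_registry()
#' species_entropy(reg$species$H2, thermo_conditions(1000))  # ~165.5
#' @export
species_entropy <- function(spec, cond) {
  species_thermo(spec, cond)$S
}

#' Full thermodynamic state of a gas species
#'
#' Computes entropy `S`, entropic energy `ST = S*T`, enthalpy
#' `H = c*RT + Evib`, internal energy `E = H - RT`, absolute Gibbs energy
#' `G = H - ST` and Helmholtz energy `A = E - ST`, together with the action
#' quantum numbers and the ergal partition of [ergal_partition()].  `G` and
#' `A` are absolute (zero when the quantum numbers are of order one), so
#' they are large and negative in ordinary gas regimes.
#'
#' @inheritParams species_entropy
#' @return Object of class `species_thermo`: a list with `name`, `T`, `p`,
#'   `S` (J/K/mol), `ST`, `H`, `E`, `G`, `A` (J/mol), `Se` (electronic
#'   entropy `R ln q_e`, J/K/mol), `Cvib` (J/K/mol), `n_t`, `n_t_raw`,
#'   `rot_factor`, `fvib` (dimensionless), `Evib` (J/mol) and the ergal
#'   fields `ergal_t`, `ergal_r` (J/mol), `mean_quantum_t` (J).
#' @examples
#' reg <- default_registry()
#' species_thermo(reg$species$O2, thermo_conditions(1000))
#' @export
species_thermo <- function(spec, cond) {
  stopifnot(inherits(spec, "molecule_spec"),
            inherits(cond, "thermo_conditions"))
  T <- cond$T
  tr <- translational_action(cond, spec$molar_mass)
  rot_factor <- if (spec$geometry == "monatomic") 1
                else rotational_action(spec, T)$rot_factor
  vib <- vibrational_terms(spec, T)
  cgeom <- .geom_const[[spec$geometry]]

  S <- .R * (cgeom + log(tr$n_t^3 * rot_factor * spec$q_e) + vib$fvib)
  ST <- S * T
  H <- cgeom * .R * T + vib$evib
  E <- H - .R * T
  G <- H - ST
  A <- E - ST

  ergal_t <- .R * T * 3 * log(tr$n_t)
  ergal_r <- if (spec$geometry == "monatomic") 0 else .R * T * log(rot_factor)

  structure(list(name = spec$name, T = T, p = cond$p,
                 S = S, ST = ST, H = H, E = E, G = G, A = A,
                 Se = .R * log(spec$q_e), Cvib = vib$cvib,
                 n_t = tr$n_t, n_t_raw = tr$n_t_raw,
                 rot_factor = rot_factor, fvib = vib$fvib, Evib = vib$evib,
                 ergal_t = ergal_t, ergal_r = ergal_r,
                 mean_quantum_t = ergal_t / (.NA * tr$n_t_raw)),
            class = "species_thermo")
}

#' @export
print.species_thermo <- function(x, ...) {
  cat(sprintf("<species_thermo> %s at %g K, %g Pa\n", x$name, x$T, x$p))
  cat(sprintf("  S  = %10.3f J/K/mol   ST = %10.3f kJ/mol\n",
              x$S, x$ST / 1000))
  cat(sprintf("  H  = %10.3f kJ/mol    E  = %10.3f kJ/mol\n",
              x$H / 1000, x$E / 1000))
  cat(sprintf("  G  = %10.3f kJ/mol    A  = %10.3f kJ/mol\n",
              x$G / 1000, x$A / 1000))
  cat(sprintf("  n_t = %.1f (raw %.1f)  rot_factor = %.4g  fvib = %.4g\n",
              x$n_t, x$n_t_raw, x$rot_factor, x$fvib))
  invisible(x)
}

#' @export
as.data.frame.species_thermo <- function(x, ...) {
  data.frame(name = x$name, T_K = x$T, p_Pa = x$p,
             S_J_K_mol = x$S, ST_kJ_mol = x$ST / 1000,
             H_kJ_mol = x$H / 1000, E_kJ_mol = x$E / 1000,
             G_kJ_mol = x$G / 1000, A_kJ_mol = x$A / 1000,
             n_t = x$n_t, n_t_raw = x$n_t_raw,
             rot_factor = x$rot_factor, fvib = x$fvib,
             stringsAsFactors = FALSE)
}

#' Partition of the configurational work (ergal) into virtual quanta
#'
#' The work-like part of the entropic energy — the ergal, the negative of
#' the absolute Gibbs energy — splits into a translational part
#' `RT ln n_t^3` (z_t-corrected) and a rotational part `RT ln rot_factor`.
#' Dividing the per-molecule translational ergal by the uncorrected
#' translational quantum count `n_t_raw` gives the mean energy of the
#' virtual quanta sustaining the translational action field.
#'
#' @inheritParams species_entropy
#' @return List with `ergal_t`, `ergal_r` (J/mol), `ergal_t_molecule`,
#'   `ergal_r_molecule` (J per molecule), `quanta_t` (= `n_t_raw`) and
#'   `mean_quantum_t` (J per quantum).
#' @examples
#' reg <- default_registry()
#' ergal_partition(reg$species$H2, thermo_conditions(1000))
#' @export
ergal_partition <- function(spec, cond) {
  st <- species_thermo(spec, cond)
  list(ergal_t = st$ergal_t, ergal_r = st$ergal_r,
       ergal_t_molecule = st$ergal_t / .NA,
       ergal_r_molecule = st$ergal_r / .NA,
       quanta_t = st$n_t_raw,
       mean_quantum_t = st$mean_quantum_t)
}
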