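# Species definitions and derived geometric quantities.

#' Define a gas species by its molecular constants
#'
#' A `molecule_spec` holds everything needed to evaluate the partition
#' factors of an ideal-gas species: molar mass, geometry class, rotational
#' inertia (given directly or derivable from atom masses and bond lengths),
#' vibrational modes, rotational symmetry number and electronic degeneracy.
#'
#' Geometry classes and their requirements:
#' \describe{
#'   \item{monatomic}{no inertia, no vibrational modes.}
#'   \item{linear}{exactly one rotational inertia, either supplied in
#'     `principal_inertias` or derived from `atom_masses` + `bond_lengths`
#'     (two atoms: reduced-mass rigid rotor; three or more collinear atoms:
#'     inertia about the centre of mass).}
#'   \item{nonlinear}{exactly three principal inertias, supplied directly.}
#' }
#'
#' If both atom geometry and a stored inertia are given for a linear
#' species, they must agree within 15% (tabulated inertias are rounded).
#'
#' @param name Species label, e.g. `"H2O"`.
#' @param molar_mass Molar mass in Da (g/mol). Must be positive.
#' @param geometry One of `"monatomic"`, `"linear"`, `"nonlinear"`.
#' @param atom_masses Optional numeric vector of atom masses in Da, in
#'   chain order for linear molecules.
#' @param bond_lengths Optional numeric vector of bond lengths in pm
#'   between neighbouring atoms (length `length(atom_masses) - 1`).
#' @param principal_inertias Optional numeric vector of principal moments
#'   of inertia in kg m^2 (length 1 for linear, 3 for nonlinear).
#' @param vib_modes Optional two-column matrix or data.frame: wavenumber in
#'   cm^-1 and integer degeneracy, one row per distinct vibrational mode.
#' @param sigma Rotational symmetry number (positive integer, default 1).
#' @param q_e Electronic degeneracy (integer >= 1, default 1).
#' @return An object of class `molecule_spec`.
#' @examples
#' o2 <- molecule_spec("O2", 32, "linear", atom_masses = c(16, 16),
#'                     bond_lengths = 121, vib_modes = cbind(1580, 1),
#'                     sigma = 2, q_e = 3)
#' characteristic_temperatures(o2)
#' @seealso [default_registry()], [characteristic_temperatures()]
#' @export
molecule_spec <- function(name, molar_mass,
                          geometry = c("monatomic", "linear", "nonlinear"),
                          atom_masses = NULL, bond_lengths = NULL,
                          principal_inertias = NULL, vib_modes = NULL,
                          sigma = 1L, q_e = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0)
    stop("molar_mass must be a single positive number (Da)", call. = FALSE)
  if (sigma < 1 || sigma != round(sigma))
    stop("sigma must be a positive integer", call. = FALSE)
  if (q_e < 1 || q_e != round(q_e))
    stop("q_e must be an integer >= 1", call. = FALSE)

  if (!is.null(vib_modes)) {
    vib_modes <- as.matrix(vib_modes)
    if (ncol(vib_modes) != 2L)
      stop("vib_modes must have two columns: wavenumber (cm^-1), degeneracy",
           call. = FALSE)
    colnames(vib_modes) <- c("wavenumber", "degeneracy")
    if (any(vib_modes[, 1] <= 0))
      stop("all wavenumbers must be > 0", call. = FALSE)
    if (any(vib_modes[, 2] < 1) || any(vib_modes[, 2] != round(vib_modes[, 2])))
      stop("all degeneracies must be integers >= 1", call. = FALSE)
  }

  if (geometry == "monatomic") {
    if (!is.null(principal_inertias) || !is.null(vib_modes))
      stop("monatomic species take no inertia and no vibrational modes",
           call. = FALSE)
  } else if (geometry == "linear") {
    derivable <- !is.null(atom_masses) && !is.null(bond_lengths)
    if (is.null(principal_inertias) && !derivable)
      stop("linear species need one principal inertia or atom_masses + ",
           "bond_lengths to derive it", call. = FALSE)
    if (!is.null(principal_inertias) && length(principal_inertias) != 1L)
      stop("linear species take exactly one principal inertia", call. = FALSE)
    if (derivable) {
      derived <- .inertia_from_geometry(atom_masses, bond_lengths)
      if (!is.null(principal_inertias) &&
          abs(derived / principal_inertias - 1) > 0.15)
        stop(sprintf(paste0("stored inertia (%.3e) disagrees with the value ",
                            "derived from geometry (%.3e) by more than 15%%"),
                     principal_inertias, derived), call. = FALSE)
      if (is.null(principal_inertias)) principal_inertias <- derived
    }
  } else {  # nonlinear
    if (is.null(principal_inertias) || length(principal_inertias) != 3L)
      stop("nonlinear species take exactly three principal inertias",
           call. = FALSE)
  }
  if (!is.null(principal_inertias) && any(principal_inertias <= 0))
    stop("principal inertias must be > 0", call. = FALSE)

  structure(list(name = name, molar_mass = molar_mass, geometry = geometry,
                 atom_masses = atom_masses, bond_lengths = bond_lengths,
                 principal_inertias = principal_inertias,
                 vib_modes = vib_modes,
                 sigma = as.integer(sigma), q_e = as.integer(q_e)),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("<molecule_spec> %s: %g Da, %s, sigma=%d, q_e=%d\n",
              x$name, x$molar_mass, x$geometry, x$sigma, x$q_e))
  if (!is.null(x$principal_inertias))
    cat("  I (kg m^2):", format(x$principal_inertias, digits = 4), "\n")
  if (!is.null(x$vib_modes))
    cat("  modes (cm^-1 x deg):",
        paste(sprintf("%gx%d", x$vib_modes[, 1], x$vib_modes[, 2]),
              collapse = ", "), "\n")
  invisible(x)
}

.inertia_from_geometry <- function(atom_masses, bond_lengths) {
  if (length(atom_masses) == 2L) {
    inertia_diatomic(atom_masses[1], atom_masses[2], bond_lengths[1])
  } else {
    inertia_linear_polyatomic(atom_masses, bond_lengths)
  }
}

#' Moment of inertia of a diatomic rigid rotor
#'
#' `I = mu * r^2` with reduced mass `mu = m1 m2 / (m1 + m2)`.
#'
#' @param m1,m2 Atom masses in Da.
#' @param r Bond length in pm.
#' @return Moment of inertia in kg m^2.
#' @examples
#' inertia_diatomic(16, 16, 121)  # O2
#' @export
inertia_diatomic <- function(m1, m2, r) {
  stopifnot(m1 > 0, m2 > 0, r > 0)
  mu <- m1 * m2 / (m1 + m2) * .amu
  mu * (r * 1e-12)^2
}

#' Moment of inertia of a linear polyatomic molecule
#'
#' Places the atoms on a line at the cumulative bond distances, finds the
#' centre of mass and returns `sum(m_i * (z_i - z_cm)^2)`.
#'
#' @param atom_masses Atom masses in Da, in chain order (at least 3).
#' @param bond_lengths Bond lengths in pm between neighbours
#'   (length `length(atom_masses) - 1`).
#' @return Moment of inertia about the centre of mass, kg m^2.
#' @examples
#' inertia_linear_polyatomic(c(16, 12, 16), c(122, 122))  # CO2
#' @export
inertia_linear_polyatomic <- function(atom_masses, bond_lengths) {
  if (length(atom_masses) < 3L)
    stop("need at least 3 atoms; use inertia_diatomic() for two",
         call. = FALSE)
  if (length(bond_lengths) != length(atom_masses) - 1L)
    stop("bond_lengths must have one entry per neighbouring pair",
         call. = FALSE)
  m <- atom_masses * .amu
  z <- c(0, cumsum(bond_lengths * 1e-12))
  z_cm <- sum(m * z) / sum(m)
  sum(m * (z - z_cm)^2)
}

#' Characteristic rotational and vibrational temperatures
#'
#' `Theta_rot = hbar^2 / (2 I k)` for each rotational inertia and
#' `Theta_vib = h c nu / k` for each vibrational mode (degenerate modes are
#' repeated per their degeneracy in the returned vector's attribute).
#'
#' @param spec A [molecule_spec()].
#' @return List with numeric vectors `theta_rot` and `theta_vib` (K), both
#'   empty for monatomic species. `theta_vib` carries the mode degeneracies
#'   as the `"degeneracy"` attribute.
#' @examples
#' reg <- default_registry()
#' characteristic_temperatures(reg$species$O2)$theta_rot  # about 2.07 K
#' @export
characteristic_temperatures <- function(spec) {
  stopifnot(inherits(spec, "molecule_spec"))
  if (spec$geometry == "monatomic")
    return(list(theta_rot = numeric(0), theta_vib = numeric(0)))
  theta_rot <- .hbar^2 / (2 * spec$principal_inertias * .k)
  theta_vib <- numeric(0)
  if (!is.null(spec$vib_modes)) {
    theta_vib <- .hc_k * spec$vib_modes[, 1]
    attr(theta_vib, "degeneracy") <- as.integer(spec$vib_modes[, 2])
  }
  list(theta_rot = theta_rot, theta_vib = theta_vib)
}

#' Thermodynamic state point
#'
#' @param T Temperature in K (> 0).
#' @param p Pressure in Pa (> 0); defaults to 101325 Pa (1 atm).
#' @return List of class `thermo_conditions` with elements `T` and `p`.
#' @examples
#' thermo_conditions(1000)
#' @export
thermo_conditions <- function(T, p = .p_std) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("T must be a single positive temperature in K", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("p must be a single positive pressure in Pa", call. = FALSE)
  structure(list(T = T, p = p), class = "thermo_conditions")
}
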