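# Built-in species/bond registry and the plain-text configuration loader.
#
# Configuration schema (YAML):
#
#   species:
#     - name: CO             # required, unique
#       molar_mass: 28.01    # Da, required
#       geometry: linear     # monatomic | linear | nonlinear
#       atom_masses: [12.011, 15.999]   # Da, optional
#       bond_lengths: [112.8]           # pm, optional
#       principal_inertias: [1.45e-46]  # kg m^2, optional
#       vib_modes:           # list of [wavenumber cm^-1, degeneracy]
#         - [2143, 1]
#       sigma: 1             # optional, default 1
#       q_e: 1               # optional, default 1
#   bonds:
#     C#O: 1072              # mean bond enthalpy at 298 K, kJ/mol
#
# Unknown fields are rejected; species names duplicating built-ins (or each
# other) are an error.

.species_fields <- c("name", "molar_mass", "geometry", "atom_masses",
                     "bond_lengths", "principal_inertias", "vib_modes",
                     "sigma", "q_e")

#' Built-in registry of common gas species and mean bond enthalpies
#'
#' Species: H, H2, N2, O2, NH3, CO2, H2O, N2O and CH4, defined by molar
#' mass, bond lengths or principal moments of inertia, vibrational
#' wavenumbers with degeneracies, rotational symmetry number and electronic
#' degeneracy (3 for ground-state O2).  Bonds: mean bond enthalpies at
#' 298 K in kJ/mol under ASCII labels (`"H-H"`, `"O=O"`, `"N#N"`, ...).
#'
#' NH3 is stored with four nondegenerate vibrational modes (3337, 950,
#' 3447, 1627 cm^-1); the doubly degenerate physical assignment of the two
#' e-symmetry modes can be restored by building a custom [molecule_spec()].
#' Atomic H is stored with `q_e = 1`.
#'
#' @return List with elements `species` (named list of [molecule_spec()])
#'   and `bonds` (named numeric vector, kJ/mol).
#' @examples
#' reg <- default_registry()
#' names(reg$species)
#' reg$bonds[["N#N"]]
#' @export
default_registry <- function() {
  sp <- list(
    molecule_spec("H", 1.008, "monatomic"),
    molecule_spec("H2", 2.016, "linear", atom_masses = c(1.008, 1.008),
                  bond_lengths = 74, vib_modes = cbind(4161, 1), sigma = 2),
    molecule_spec("N2", 28.014, "linear", atom_masses = c(14.007, 14.007),
                  bond_lengths = 110, vib_modes = cbind(2358, 1), sigma = 2),
    molecule_spec("O2", 32, "linear", atom_masses = c(16, 16),
                  bond_lengths = 121, vib_modes = cbind(1580, 1), sigma = 2,
                  q_e = 3),
    molecule_spec("NH3", 17, "nonlinear",
                  principal_inertias = c(2.9638, 2.9638, 4.5176) * 1e-47,
                  vib_modes = cbind(c(3337, 950, 3447, 1627), 1), sigma = 3),
    molecule_spec("CO2", 44, "linear", atom_masses = c(16, 12, 16),
                  bond_lengths = c(122, 122),
                  vib_modes = cbind(c(1388, 667, 2349), c(1, 2, 1)),
                  sigma = 2),
    molecule_spec("H2O", 18, "nonlinear",
                  principal_inertias = c(1.024, 1.920, 2.947) * 1e-47,
                  vib_modes = cbind(c(3652, 1595, 3756), 1), sigma = 2),
    molecule_spec("N2O", 44, "linear", atom_masses = c(14, 14, 16),
                  bond_lengths = c(112, 119),
                  vib_modes = cbind(c(2224, 1285, 589), c(1, 1, 2)),
                  sigma = 1),
    molecule_spec("CH4", 16, "nonlinear",
                  principal_inertias = c(5.27, 5.27, 5.27) * 1e-47,
                  vib_modes = cbind(c(2914, 1526, 3020, 1306), c(1, 2, 3, 3)),
                  sigma = 12)
  )
  names(sp) <- vapply(sp, `[[`, "", "name")
  bonds <- c("H-H" = 436, "C-H" = 413, "N-H" = 391, "O-H" = 463,
             "C=O" = 745, "C-O" = 358, "C-N" = 305, "O-O" = 146,
             "O=O" = 498, "O-N" = 201, "N=N" = 418, "N#N" = 945,
             "N=O" = 607)
  list(species = sp, bonds = bonds)
}

#' Load a species/bond registry from a plain-text configuration
#'
#' Parses a YAML configuration (see the schema at the top of this file's
#' source, or the package README) and merges it with the built-in registry
#' from [default_registry()].  Units are fixed per field: Da, pm, kg m^2,
#' cm^-1, kJ/mol.
#'
#' @param config_text Configuration as a single string, or `NULL`.
#' @param file Path to a configuration file (used if `config_text` is
#'   `NULL`).
#' @return Registry list with `species` and `bonds`, built-ins included.
#' @examples
#' reg <- load_registry("bonds:\n  C#O: 1072\n")
#' reg$bonds[["C#O"]]
#' @export
load_registry <- function(config_text = NULL, file = NULL) {
  reg <- default_registry()
  cfg <- if (!is.null(config_text)) {
    if (!nzchar(trimws(config_text))) NULL else yaml::yaml.load(config_text)
  } else if (!is.null(file)) {
    yaml::read_yaml(file)
  } else NULL
  if (is.null(cfg)) return(reg)
  if (!is.list(cfg))
    stop("configuration must be a YAML mapping", call. = FALSE)
  extra <- setdiff(names(cfg), c("species", "bonds"))
  if (length(extra))
    stop("unknown top-level field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (s in cfg$species) {
    if (is.null(s$name))
      stop("species entry is missing the 'name' field", call. = FALSE)
    bad <- setdiff(names(s), .species_fields)
    if (length(bad))
      stop(sprintf("species '%s': unknown field(s): %s", s$name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    if (s$name %in% names(reg$species))
      stop(sprintf("duplicate species '%s'", s$name), call. = FALSE)
    vm <- s$vib_modes
    if (!is.null(vm))
      vm <- do.call(rbind, lapply(vm, function(row) {
        if (length(row) != 2L)
          stop(sprintf("species '%s': each vib_modes entry must be ",
                       "[wavenumber, degeneracy]", s$name), call. = FALSE)
        as.numeric(row)
      }))
    reg$species[[s$name]] <- molecule_spec(
      name = s$name, molar_mass = s$molar_mass,
      geometry = if (is.null(s$geometry)) "monatomic" else s$geometry,
      atom_masses = .num_or_null(s$atom_masses),
      bond_lengths = .num_or_null(s$bond_lengths),
      principal_inertias = .num_or_null(s$principal_inertias),
      vib_modes = vm,
      sigma = if (is.null(s$sigma)) 1L else s$sigma,
      q_e = if (is.null(s$q_e)) 1L else s$q_e)
  }
  if (!is.null(cfg$bonds)) {
    b <- unlist(cfg$bonds)
    if (!is.numeric(b) || any(b <= 0))
      stop("bond enthalpies must be positive numbers (kJ/mol)",
           call. = FALSE)
    reg$bonds[names(b)] <- b
  }
  reg
}

.num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
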