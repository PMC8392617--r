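# Reaction-level energetics: bond-enthalpy dH with Kirchhoff temperature
# correction, T*dS from the species state functions, dG(T), equilibrium
# constants, temperature scans and the dG = 0 crossing.

#' Define a gas-phase reaction
#'
#' Stoichiometry is given as named integer vectors of species names (which
#' must resolve in the registry used for evaluation).  The reference
#' reaction enthalpy can either be supplied directly (`dH_ref`, kJ/mol at
#' `T_ref`) or derived from a bond inventory: for each species, the bonds
#' it contains with their counts, priced by the registry's mean
#' bond-enthalpy table.
#'
#' @param reactants,products Named integer vectors, e.g.
#'   `c(N2 = 1, H2 = 3)`.
#' @param bond_inventory Named list mapping species name to a named numeric
#'   vector of bond counts, e.g. `list(NH3 = c("N-H" = 3))`.  Species with
#'   no bonds (atoms) may be omitted.
#' @param dH_ref Optional reference reaction enthalpy in kJ/mol at `T_ref`
#'   (overrides the bond inventory).
#' @param T_ref Reference temperature for `dH_ref` / the bond table, K.
#' @param name Optional reaction label.
#' @return Object of class `reaction`.
#' @examples
#' rxn_haber()
#' @export
reaction <- function(reactants, products, bond_inventory = NULL,
                     dH_ref = NULL, T_ref = 298.15, name = NULL) {
  .check_stoich(reactants, "reactants")
  .check_stoich(products, "products")
  if (!is.null(bond_inventory) && !length(bond_inventory))
    bond_inventory <- NULL
  if (is.null(bond_inventory) && is.null(dH_ref))
    stop("either a bond_inventory or dH_ref must be given", call. = FALSE)
  if (is.null(name))
    name <- paste(.side_label(reactants), "<=>", .side_label(products))
  structure(list(reactants = reactants, products = products,
                 bond_inventory = bond_inventory, dH_ref = dH_ref,
                 T_ref = T_ref, name = name),
            class = "reaction")
}

.check_stoich <- function(side, what) {
  if (is.null(names(side)) || any(!nzchar(names(side))))
    stop(what, " must be a named vector of stoichiometric coefficients",
         call. = FALSE)
  if (any(side < 1) || any(side != round(side)))
    stop(what, " coefficients must be positive integers", call. = FALSE)
}

.side_label <- function(side)
  paste(ifelse(side > 1, paste0(side, " "), ""), names(side),
        sep = "", collapse = " + ")

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction>", x$name, "\n")
  invisible(x)
}

#' Built-in example reactions
#'
#' `rxn_h2_dissociation()`: H2 <=> 2 H.  `rxn_water_formation()`:
#' 2 H2 + O2 <=> 2 H2O.  `rxn_haber()`: N2 + 3 H2 <=> 2 NH3.  All carry
#' bond inventories priced by the built-in bond table.
#'
#' @return A [reaction()].
#' @examples
#' bond_reaction_enthalpy(rxn_haber(), default_registry()$bonds)  # -93
#' @export
rxn_h2_dissociation <- function()
  reaction(c(H2 = 1), c(H = 2),
           bond_inventory = list(H2 = c("H-H" = 1)),
           name = "H2 <=> 2 H")

#' @rdname rxn_h2_dissociation
#' @export
rxn_water_formation <- function()
  reaction(c(H2 = 2, O2 = 1), c(H2O = 2),
           bond_inventory = list(H2 = c("H-H" = 1), O2 = c("O=O" = 1),
                                 H2O = c("O-H" = 2)),
           name = "2 H2 + O2 <=> 2 H2O")

#' @rdname rxn_h2_dissociation
#' @export
rxn_haber <- function()
  reaction(c(N2 = 1, H2 = 3), c(NH3 = 2),
           bond_inventory = list(N2 = c("N#N" = 1), H2 = c("H-H" = 1),
                                 NH3 = c("N-H" = 3)),
           name = "N2 + 3 H2 <=> 2 NH3")

.side_bond_total <- function(side, inventory, bonds) {
  total <- 0
  for (sp in names(side)) {
    inv <- inventory[[sp]]
    if (is.null(inv)) next
    missing <- setdiff(names(inv), names(bonds))
    if (length(missing))
      stop("unknown bond label(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    total <- total + side[[sp]] * sum(inv * bonds[names(inv)])
  }
  total
}

#' Bond-enthalpy totals of each side of a reaction
#'
#' The summed mean bond enthalpies of all reactant bonds and of all
#' product bonds — the activation energies needed to atomise each side.
#'
#' @param rxn A [reaction()] with a bond inventory.
#' @param bonds Named bond-enthalpy vector (kJ/mol), e.g.
#'   `default_registry()$bonds`.
#' @return List with `forward` (reactant bond total, kJ/mol) and `reverse`
#'   (product bond total, kJ/mol).
#' @examples
#' bond_activation_energies(rxn_haber(), default_registry()$bonds)
#' @export
bond_activation_energies <- function(rxn, bonds) {
  stopifnot(inherits(rxn, "reaction"))
  if (is.null(rxn$bond_inventory))
    stop("reaction has no bond inventory", call. = FALSE)
  list(forward = .side_bond_total(rxn$reactants, rxn$bond_inventory, bonds),
       reverse = .side_bond_total(rxn$products, rxn$bond_inventory, bonds))
}

#' Reaction enthalpy from mean bond enthalpies
#'
#' `dH = sum(reactant bond enthalpies) - sum(product bond enthalpies)`:
#' breaking every reactant bond costs the first sum, forming the product
#' bonds releases the second, so a negative value means heat released
#' (exothermic).
#'
#' @inheritParams bond_activation_energies
#' @return Reaction enthalpy in kJ/mol at the bond table's reference
#'   temperature (298 K for the built-in table).
#' @examples
#' reg <- default_registry()
#' bond_reaction_enthalpy(rxn_haber(), reg$bonds)            # -93
#' bond_reaction_enthalpy(rxn_h2_dissociation(), reg$bonds)  # +436
#' @export
bond_reaction_enthalpy <- function(rxn, bonds) {
  if (!is.null(rxn$dH_ref)) return(rxn$dH_ref)
  ae <- bond_activation_energies(rxn, bonds)
  ae$forward - ae$reverse
}

.resolve_species <- function(rxn, registry) {
  wanted <- unique(c(names(rxn$reactants), names(rxn$products)))
  missing <- setdiff(wanted, names(registry$species))
  if (length(missing))
    stop("species not in registry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  registry$species[wanted]
}

# signed stoichiometry: products positive, reactants negative
.signed_nu <- function(rxn) {
  nu <- c(-rxn$reactants, rxn$products)
  names(nu) <- c(names(rxn$reactants), names(rxn$products))
  nu
}

#' Reaction energetics at one temperature
#'
#' Evaluates, with every species at pressure `p`:
#' \itemize{
#'   \item `dS = sum(nu_i S_i)` and `TdS` from [species_thermo()],
#'   \item `dH(T) = dH_ref + sum(nu_i (H_i(T) - H_i(T_ref)))` (Kirchhoff
#'     correction of the bond-enthalpy reference over the package's own
#'     `c*RT + Evib` enthalpies),
#'   \item `dG = dH - T dS + RT ln q` for reaction quotient `q`,
#'   \item `lnK = -dG0/(RT)` with `dG0` the standard (`q = 1`) value.
#' }
#'
#' @param rxn A [reaction()].
#' @param T Temperature in K.
#' @param registry Registry from [default_registry()] or [load_registry()].
#' @param p Pressure of every species, Pa (standard state, default 1 atm).
#' @param q Reaction quotient (default 1 = standard conditions).
#' @return One-row data.frame with columns `T_K`, `dS_J_K_mol`,
#'   `TdS_kJ_mol`, `dH_kJ_mol`, `dG_kJ_mol`, `lnK`, `log10K`.
#' @examples
#' reaction_profile(rxn_h2_dissociation(), 1000, default_registry())
#' @export
reaction_profile <- function(rxn, T, registry = default_registry(),
                             p = .p_std, q = 1) {
  stopifnot(inherits(rxn, "reaction"), T > 0, q > 0)
  species <- .resolve_species(rxn, registry)
  nu <- .signed_nu(rxn)
  dH_ref <- bond_reaction_enthalpy(rxn, registry$bonds)  # kJ/mol at T_ref

  thermo_T <- lapply(species, species_thermo, cond = thermo_conditions(T, p))
  thermo_ref <- lapply(species, species_thermo,
                       cond = thermo_conditions(rxn$T_ref, p))
  dS <- sum(nu * vapply(thermo_T[names(nu)], `[[`, 0, "S"))
  dH <- dH_ref + sum(nu * (vapply(thermo_T[names(nu)], `[[`, 0, "H") -
                           vapply(thermo_ref[names(nu)], `[[`, 0, "H"))) / 1000
  dG0 <- dH - T * dS / 1000
  lnK <- -dG0 * 1000 / (.R * T)
  dG <- dG0 + .R * T * log(q) / 1000
  data.frame(T_K = T, dS_J_K_mol = dS, TdS_kJ_mol = T * dS / 1000,
             dH_kJ_mol = dH, dG_kJ_mol = dG, lnK = lnK,
             log10K = lnK / log(10))
}

#' Temperature scan of a reaction
#'
#' Runs [reaction_profile()] over an ascending temperature grid.
#'
#' @inheritParams reaction_profile
#' @param T_grid Ascending numeric vector of temperatures, K.
#' @return data.frame with one [reaction_profile()] row per temperature,
#'   plus per-species entropy columns `S_<name>` (J/K/mol).
#' @examples
#' reaction_scan(rxn_haber(), seq(400, 1000, 100))
#' @export
reaction_scan <- function(rxn, T_grid, registry = default_registry(),
                          p = .p_std) {
  if (!length(T_grid))
    stop("temperature grid is empty", call. = FALSE)
  if (is.unsorted(T_grid, strictly = TRUE))
    stop("temperature grid must be strictly ascending", call. = FALSE)
  species <- .resolve_species(rxn, registry)
  rows <- lapply(T_grid, function(T) {
    row <- reaction_profile(rxn, T, registry, p)
    S <- vapply(species, function(sp)
      species_thermo(sp, thermo_conditions(T, p))$S, 0)
    names(S) <- paste0("S_", names(species))
    cbind(row, as.data.frame(as.list(S)))
  })
  do.call(rbind, rows)
}

#' Temperature at which the reaction Gibbs energy crosses zero
#'
#' Bisection on `dG(T)` from [reaction_profile()] to |dG| < `tol` J/mol.
#' At the returned temperature the equilibrium constant is 1 by
#' construction (all species at the standard pressure `p`).
#'
#' @inheritParams reaction_profile
#' @param bracket Length-2 numeric vector of temperatures (K) with
#'   opposite `dG` signs at the ends.
#' @param tol Convergence tolerance on |dG|, J/mol (default 1).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return List with `T_eq` (K), `dG_J_mol` at `T_eq` and `iterations`.
#' @examples
#' find_equilibrium_T(rxn_haber(), c(300, 700))$T_eq  # about 450 K
#' @export
find_equilibrium_T <- function(rxn, bracket, registry = default_registry(),
                               p = .p_std, tol = 1, max_iter = 200) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  dG <- function(T) reaction_profile(rxn, T, registry, p)$dG_kJ_mol * 1000
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- dG(lo); f_hi <- dG(hi)
  if (sign(f_lo) == sign(f_hi))
    stop("dG does not change sign over the bracket", call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- dG(mid)
    if (abs(f_mid) < tol)
      return(list(T_eq = mid, dG_J_mol = f_mid, iterations = i))
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  list(T_eq = mid, dG_J_mol = f_mid, iterations = max_iter)
}
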