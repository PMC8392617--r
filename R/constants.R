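# Physical constants (CODATA 2018). All SI.

.k      <- 1.380649e-23        # Boltzmann, J/K (exact)
.h      <- 6.62607015e-34      # Planck, J s (exact)
.hbar   <- .h / (2 * pi)
.NA     <- 6.02214076e23       # Avogadro, 1/mol (exact)
.R      <- .k * .NA            # gas constant, J/(mol K)
.amu    <- 1e-3 / .NA          # kg per Dalton (molar-mass convention)
.hc_k   <- .h * 2.99792458e8 / .k * 100  # cm K: Theta_vib = hc*nu/k
.p_std  <- 101325              # standard pressure, Pa ("1 atm")
.z_t    <- 8 * 1.085^3         # translational symmetry/velocity constant

#' Physical constants used throughout the package
#'
#' Returns the CODATA-2018 constant set the package computes with, plus the
#' translational correction constant `z_t = 2^3 * 1.085^3` that folds the
#' octant symmetry of translational motion and the ratio of root-mean-square
#' to mean molecular speed into the translational action.
#'
#' @return Named list with elements `k` (Boltzmann constant, J/K), `h`
#'   (Planck constant, J s), `hbar` (J s), `R` (molar gas constant,
#'   J mol^-1 K^-1), `N_A` (Avogadro constant, mol^-1), `hc_k` (second
#'   radiation constant hc/k in cm K, so `Theta_vib = hc_k * wavenumber`),
#'   `amu` (kg per Dalton), `p_std` (standard pressure, 101325 Pa) and
#'   `z_t` (dimensionless, about 10.218).
#' @examples
#' phys_constants()$z_t
#' @export
phys_constants <- function() {
  list(k = .k, h = .h, hbar = .hbar, R = .R, N_A = .NA,
       hc_k = .hc_k, amu = .amu, p_std = .p_std, z_t = .z_t)
}
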