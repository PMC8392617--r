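# Species definitions, inertias and characteristic temperatures.

test_that("diatomic inertia reproduces the rigid-rotor characteristic temperatures", {
  # O2: 16/16 Da at 121 pm -> Theta_rot 2.07 K; N2: 14.007/14.007 at 110 pm -> 2.86 K
  I_o2 <- inertia_diatomic(16, 16, 121)
  I_n2 <- inertia_diatomic(14.007, 14.007, 110)
  theta <- function(I) kc$hbar^2 / (2 * I * kc$k)
  expect_within(theta(I_o2), 2.07, 0.005)
  expect_within(theta(I_n2), 2.86, 0.005)
  # equal masses: I = (m/2) r^2
  expect_equal(inertia_diatomic(7, 7, 150),
               7 / 2 * kc$amu * (150e-12)^2, tolerance = 1e-12)
})

test_that("linear polyatomic inertia matches a brute-force centre-of-mass oracle", {
  # oracle: explicit coordinates, weighted mean, plain sum
  oracle <- function(m_da, bonds_pm) {
    m <- m_da * kc$amu
    z <- cumsum(c(0, bonds_pm)) * 1e-12
    sum(m * (z - weighted.mean(z, m))^2)
  }
  # CO2 is symmetric: closed form 2 m_O r^2
  I_co2 <- inertia_linear_polyatomic(c(16, 12, 16), c(122, 122))
  expect_equal(I_co2, 2 * 16 * kc$amu * (122e-12)^2, tolerance = 1e-12)
  expect_equal(I_co2, oracle(c(16, 12, 16), c(122, 122)), tolerance = 1e-12)
  expect_within(I_co2, 7.91e-46, 0.005e-46)
  # asymmetric N2O against the oracle
  expect_equal(inertia_linear_polyatomic(c(14, 14, 16), c(112, 119)),
               oracle(c(14, 14, 16), c(112, 119)), tolerance = 1e-12)
  expect_error(inertia_linear_polyatomic(c(14, 14, 16), 112), "one entry")
})

test_that("characteristic temperatures follow from wavenumbers and inertias", {
  th_co2 <- characteristic_temperatures(reg$species$CO2)
  # bending mode 667 cm^-1 -> hc*667/k = 959.66 K
  expect_within(th_co2$theta_vib[2], 959.66, 0.05)
  expect_equal(attr(th_co2$theta_vib, "degeneracy"), c(1L, 2L, 1L))
  # H2 stretch 4161 cm^-1 -> 5986.8 K (from Table 1, not the tabulated 6210)
  expect_within(characteristic_temperatures(reg$species$H2)$theta_vib[1],
                5986.8, 0.5)
  expect_identical(characteristic_temperatures(reg$species$H),
                   list(theta_rot = numeric(0), theta_vib = numeric(0)))
  # monotonicity: Theta_rot decreases with I, Theta_vib increases with nu
  I <- seq(1e-47, 1e-45, length.out = 20)
  expect_true(all(diff(kc$hbar^2 / (2 * I * kc$k)) < 0))
  nu <- seq(100, 4000, length.out = 20)
  expect_true(all(diff(kc$hc_k * nu) > 0))
})

test_that("spec validation enforces geometry, symmetry and mode invariants", {
  expect_error(molecule_spec("X", -1, "monatomic"), "molar_mass")
  expect_error(molecule_spec("X", 1, "monatomic", sigma = 0), "sigma")
  expect_error(molecule_spec("X", 1, "monatomic", q_e = 0.5), "q_e")
  expect_error(molecule_spec("X", 1, "monatomic",
                             vib_modes = cbind(100, 1)), "monatomic")
  expect_error(molecule_spec("X", 2, "linear"), "linear species need")
  expect_error(molecule_spec("X", 18, "nonlinear",
                             principal_inertias = 1e-47), "three")
  expect_error(molecule_spec("X", 2, "linear", principal_inertias = 1e-47,
                             vib_modes = cbind(-5, 1)), "wavenumbers")
  expect_error(molecule_spec("X", 2, "linear", principal_inertias = 1e-47,
                             vib_modes = cbind(100, 0)), "degeneracies")
  # stored inertia inconsistent with geometry by more than 15%
  expect_error(molecule_spec("O2", 32, "linear", atom_masses = c(16, 16),
                             bond_lengths = 121,
                             principal_inertias = 3e-46), "disagrees")
  # within 15% is accepted and the stored value kept
  ok <- molecule_spec("O2", 32, "linear", atom_masses = c(16, 16),
                      bond_lengths = 121, principal_inertias = 1.9e-46)
  expect_equal(ok$principal_inertias, 1.9e-46)
})

test_that("derived diatomic inertia round-trips through the spec", {
  # building from bond length and re-deriving gives the same Theta_rot exactly
  h2 <- reg$species$H2
  I_direct <- inertia_diatomic(1.008, 1.008, 74)
  expect_identical(h2$principal_inertias, I_direct)
  expect_identical(characteristic_temperatures(h2)$theta_rot,
                   kc$hbar^2 / (2 * I_direct * kc$k))
})

test_that("built-in registry carries the tabulated species and bonds", {
  expect_setequal(names(reg$species),
                  c("H", "H2", "N2", "O2", "NH3", "CO2", "H2O", "N2O", "CH4"))
  expect_equal(reg$species$O2$q_e, 3L)
  expect_equal(reg$species$O2$sigma, 2L)
  expect_equal(reg$species$CH4$sigma, 12L)
  expect_equal(nrow(reg$species$CH4$vib_modes), 4L)
  expect_equal(unname(reg$bonds[c("H-H", "N#N", "N-H", "O-H", "O=O")]),
               c(436, 945, 391, 463, 498))
  expect_true(all(reg$bonds > 0))
})

test_that("registry loader merges, validates and rejects bad configurations", {
  # empty config -> built-ins only
  expect_identical(names(load_registry("")$species), names(reg$species))
  expect_identical(load_registry()$bonds, reg$bonds)
  # a new species is usable downstream
  cfg <- paste(
    "species:",
    "  - name: CO",
    "    molar_mass: 28.01",
    "    geometry: linear",
    "    atom_masses: [12.011, 15.999]",
    "    bond_lengths: [112.8]",
    "    vib_modes:",
    "      - [2143, 1]",
    "bonds:",
    "  C#O: 1072", sep = "\n")
  reg2 <- load_registry(cfg)
  expect_s3_class(reg2$species$CO, "molecule_spec")
  expect_equal(unname(reg2$bonds[["C#O"]]), 1072)
  expect_gt(species_entropy(reg2$species$CO, thermo_conditions(298.15)), 0)
  # duplicates and unknown fields are named errors
  expect_error(load_registry("species:\n  - name: H2\n    molar_mass: 2\n"),
               "duplicate species 'H2'")
  expect_error(load_registry(
    "species:\n  - name: X\n    molar_mass: 2\n    colour: blue\n"),
    "unknown field")
  expect_error(load_registry("nonsense: 1\n"), "unknown top-level")
  expect_error(load_registry("bonds:\n  X-X: -4\n"), "positive")
})
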