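# actmech

Gas-phase thermochemistry and reaction kinetics computed directly from
molecular constants.

`actmech` is for anyone who wants absolute ideal-gas thermodynamics —
entropy, entropic energy, enthalpy, Helmholtz and Gibbs energies — from
nothing but a molecule's mass, geometry, vibrational wavenumbers,
rotational symmetry number and electronic degeneracy, and from those the
thermodynamics and transition-state kinetics of gas reactions such as
H₂ ⇌ 2H, 2H₂ + O₂ ⇌ 2H₂O and N₂ + 3H₂ ⇌ 2NH₃ (the ammonia synthesis).
No lookup of standard-state tables is needed.

## The model in brief

The entropy is assembled from *action quantum numbers* — molecular
action (J·s) normalised by ħ:

    S/R = c + ln(n_t³ · Q_r · q_e) + f_vib,     c = 5/2, 7/2, 4
                                                (monatomic/linear/nonlinear)

with the translational quantum number `n_t = sqrt(3kT·m·r_t²)/(ħ·z_t^⅓)`
built from the mean molecular separation `r_t = (kT/p)^⅓/2`, the
classical rotational partition factor `Q_r` (`2kTI/(σħ²)` linear;
`(√π/σ)·sqrt(T³/(Θ_AΘ_BΘ_C))` nonlinear), and the harmonic vibrational
sum `f_vib`.  The translational term is numerically the Sackur–Tetrode
entropy (offset 0.009 J K⁻¹ mol⁻¹, a constant).  Then `ST = S·T`,
`H = c·RT + E_vib`, `G = H − ST`, `A = G − RT` — absolute values, zero
when the quantum numbers are of order one.

Reactions price ΔH from mean bond enthalpies (negative = exothermic),
Kirchhoff-correct it in temperature, take ΔS from the species
assemblies, and report `ΔG = ΔH − TΔS`, `ln K = −ΔG°/RT`, temperature
scans and the ΔG = 0 crossing.  Transition-state quantities use the
Boltzmann activated fraction `exp(−ε/RT)` (ε = bond enthalpy to break)
and the universal frequency `kT/h`.

## Worked example

```r
library(actmech)
reg <- default_registry()      # H, H2, N2, O2, NH3, CO2, H2O, N2O, CH4

species_entropy(reg$species$H2, thermo_conditions(1000, 101325))
#> [1] 165.5702      # J K^-1 mol^-1, absolute, at 1000 K and 1 atm

scan <- reaction_scan(rxn_haber(), seq(400, 600, 100))
round(scan[, c("T_K", "dH_kJ_mol", "TdS_kJ_mol", "dG_kJ_mol", "lnK")], 3)
#>   T_K dH_kJ_mol TdS_kJ_mol dG_kJ_mol    lnK
#> 1 400   -97.452    -83.630   -13.822  4.156
#> 2 500  -101.399   -108.950     7.551 -1.816
#> 3 600  -104.967   -134.649    29.682 -5.950

find_equilibrium_T(rxn_haber(), c(300, 700))$T_eq
#> [1] 465.1306      # K: the dG = 0 point, K_p = 1 with all gases at 1 atm

activated_fraction(436, 1000)  # H-H bond rupture fraction at 1000 K
#> [1] 1.683223e-23
```

Reading: at 400 K ammonia formation is downhill (ΔG < 0); by 500 K the
entropy cost `TΔS` of condensing four molecules into two outweighs the
93 kJ/mol bond-enthalpy release, so the sign flips, with equilibrium at
465 K.  The activated fraction says that without catalysis only ~2 in
10²³ H₂ molecules carry enough energy to break the H–H bond at 1000 K.

A command-line interface is installed as `exec/actmech`:

```sh
actmech species H2 --T 1000 --p 1atm
actmech scan --reaction haber --T-start 400 --T-stop 1000 --T-step 100 --find-eq 300 700
actmech radial --wavenumber 667 --T 288 --levels 2
```

Custom species and bond enthalpies load from a small YAML schema (see
`?load_registry` and `?load_reaction`).

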