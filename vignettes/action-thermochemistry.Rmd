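---
title: "Gas-phase thermochemistry from molecular action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas-phase thermochemistry from molecular action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actmech)
```

## The model

`actmech` computes absolute thermodynamic state functions for ideal-gas
species directly from molecular constants, using an *action* formulation
of the standard statistical-mechanical partition functions.  The action of
a molecular trajectory — a scalar with dimensions of angular momentum,
J s — normalised by the reduced Planck constant gives dimensionless
quantum numbers, and the entropy is assembled from their logarithms:

$$\frac{S}{R} = c \;+\; \ln\!\left(n_t^3 \, Q_r \, q_e\right) \;+\; f_{vib},$$

where

* $n_t = \sqrt{3kT\,I_t}\,/(\hbar\, z_t^{1/3})$ is the translational
  quantum number, with translational inertia $I_t = m\,r_t^2$ built from
  the mean separation radius $r_t = a/2$, $a^3 = kT/p$ being the volume
  allotted to one molecule.  The constant $z_t = 2^3(1.085)^3 \approx
  10.218$ folds the octant symmetry of translational motion and the
  root-mean-square-to-mean speed ratio of the Maxwell distribution into
  the action.
* $Q_r$ is the rotational partition factor: $2kTI_r/(\sigma\hbar^2)$ for
  a linear rotor (algebraically identical to the classical
  $8\pi^2 I k T/(\sigma h^2)$), and the classical asymmetric-rotor factor
  $(\sqrt{\pi}/\sigma)\sqrt{T^3/(\Theta_A\Theta_B\Theta_C)}$ for a
  nonlinear one, with $\Theta = \hbar^2/(2Ik)$.
* $f_{vib} = \sum_i g_i\left[x_i/(e^{x_i}-1) - \ln(1-e^{-x_i})\right]$
  is the harmonic-oscillator vibrational sum over modes with
  $x_i = \Theta_{vib,i}/T$ and $\Theta_{vib} = hc\tilde\nu/k$.
* $q_e$ is the electronic degeneracy (3 for ground-state O$_2$), and
  $c = 5/2,\, 7/2,\, 4$ for monatomic, linear and nonlinear species
  (translational $3/2$, rotational $0,\,1,\,3/2$, plus $1$ for the $pV$
  term).

The remaining state functions follow by identity: $ST$ (the *entropic
energy*, the total thermal energy sustaining the system),
$H = cRT + E_{vib}$, $E = H - RT$, and the **absolute** free energies
$G = H - ST$ and $A = E - ST$, which are zero when the quantum numbers
are of order one and large and negative for any ordinary gas.  The
work-like part of the entropic energy — Clausius's *ergal*, the negative
of the absolute Gibbs energy — partitions into $RT\ln n_t^3$
(translational) and $RT\ln Q_r$ (rotational); dividing the per-molecule
translational ergal by the uncorrected quantum count
$n_{t,raw} = \sqrt{3kTI_t}/\hbar$ gives the mean energy of the virtual
quanta sustaining the translational action field.  (An alternative
book-keeping that divides by $n_t^3$ instead exists; this package
implements only the per-$n_{t,raw}$ convention.)

The translational term is numerically equivalent to the Sackur–Tetrode
entropy: the ratio of the two partition arguments is exactly
$(6\pi)^{3/2}/(8 z_t) = 1.00111$, i.e. a constant offset of
0.0093 J K$^{-1}$ mol$^{-1}$ — this equivalence is enforced as a test
over a grid of masses, temperatures and pressures.

## Reaction thermodynamics

Reaction enthalpies are priced from mean bond enthalpies at 298 K:
$\Delta H = \sum(\text{reactant bonds}) - \sum(\text{product bonds})$,
negative when heat is released.  At other temperatures a Kirchhoff
correction over the package's own enthalpy model is applied,

$$\Delta H(T) = \Delta H_{ref} + \sum_i \nu_i\,[H_i(T) - H_i(T_{ref})],$$

the entropy change is summed from the species assemblies, and
$\Delta G = \Delta H - T\Delta S$, $\ln K = -\Delta G^\circ/RT$, with all
species at 1 atm (the standard state used throughout; a reaction
quotient $q$ adds $RT\ln q$).  Because $T\,dS/dT = dH/dT = C_p$ holds
analytically in this model, the van 't Hoff relation
$d\ln K/d(1/T) = -\Delta H/R$ is satisfied; a finite-difference test
checks it to 2%.

```{r haber}
scan <- reaction_scan(rxn_haber(), seq(400, 1000, 100))
round(scan[, 1:7], 3)
find_equilibrium_T(rxn_haber(), c(300, 700))$T_eq
```

The ammonia-synthesis equilibrium ($\Delta G = 0$, $K_p = 1$ with all
gases at 1 atm) falls near 465 K with the built-in constants — consistent
with the classical result that the reaction is poised near 450 K — and
hydrogen dissociation (H$_2 \rightleftharpoons$ 2H) crosses just above
4000 K:

```{r h2}
find_equilibrium_T(rxn_h2_dissociation(), c(3000, 5000))$T_eq
```

## Transition states and radial excitation

For an uncatalysed reaction the activated fraction is the Boltzmann
factor of the bond enthalpy to be broken, $N^*/N_0 = e^{-\varepsilon/RT}$,
and rate constants use the universal attempt frequency $kT/h$ with unit
transmission coefficient: $k_f = (kT/h)\,e^{-\varepsilon_f/RT}$.  The
forward/reverse ratio $e^{(\varepsilon_r - \varepsilon_f)/RT}$ is then
exactly the enthalpic part of the equilibrium constant — catalysis is
modelled only as a user-supplied reduced $\varepsilon$.

```{r tst}
activated_fraction(436, 1000)          # H-H rupture at 1000 K
rate_constants(298.15, rxn = rxn_haber())$ratio
```

A vibrationally excited molecule at level $n$ of a mode $\tilde\nu$ is
depleted by $e^{n x}$ and, expressed translationally, occupies a radius
larger by $(e^{nx})^{1/3}$; the translational ergal shift
$kT\ln(r_n/r_0)^3$ recovers $n h c \tilde\nu$ identically:

```{r radial}
radial_excitation_table(667, 288, 2)   # CO2 bending mode
```

## Parameters, defaults and conventions

* **Constants**: CODATA 2018 ($k$, $h$, $N_A$ exact; $R = kN_A$).
  Standard pressure 101325 Pa.
* **$z_t$** is always computed as $8 \times 1.085^3 = 10.2183$; rounded
  transcriptions of this constant found in the literature differ in the
  fourth digit, worth under 0.01 J/K in entropy.
* **Characteristic temperatures** are always derived from the stored
  wavenumbers and inertias, never taken from secondary tabulations, so a
  species definition has a single source of truth.
* **Symmetry**: one factor of $\sigma$ divides the rotational partition
  factor.  Formulations that square a $\sigma$-divided rotational action
  would double-count it; the single-$\sigma$ convention is the one that
  matches both the classical rotor and experimental third-law entropies.
* **Registry defaults**: the built-in species use the printed constants
  of the source compilation, including integer atomic-mass sums for the
  polyatomics (H$_2$O = 18 Da) and four nondegenerate vibrational modes
  for NH$_3$ (3337, 950, 3447, 1627 cm$^{-1}$).  The physical assignment
  of the two NH$_3$ e-symmetry modes is doubly degenerate; users wanting
  it can pass their own `molecule_spec()`.  Atomic H is stored with
  $q_e = 1$, ignoring the doublet ground state, again matching the
  tabulated convention; both choices move entropies by well under
  1 J K$^{-1}$ mol$^{-1}$ below 1000 K.
* **Heat-capacity line**: the vibrational heat capacity is the molar
  $C_{vib} = R\sum_i g_i x_i^2/(2(\cosh x_i - 1))$, which equals the
  familiar Einstein form $R x^2 e^x/(e^x-1)^2$.

## Numerical choices

* Vibrational sums use `expm1`/`log1p` to stay accurate for
  high-frequency modes at low temperature, and all three vibrational
  quantities go to zero smoothly as $T \to 0$.
* The $\Delta G = 0$ crossing is found by bisection (derivative-free and
  robust against the slight curvature of $\Delta G(T)$), to
  $|\Delta G| < 1$ J/mol within at most 200 iterations.
* Activated fractions for barriers above roughly 1500 kJ/mol at ambient
  temperature underflow double precision to zero; the forward/reverse
  *ratio* is therefore always computed in closed form from
  $\varepsilon_r - \varepsilon_f$ rather than as a quotient of rates.
* Degenerate modes are handled by integer degeneracy counts, exactly
  equivalent to repeating the mode.

## What the built-in registry does and does not represent

The registry is a small, self-contained set of rigid-rotor /
harmonic-oscillator constants.  It reproduces third-law gas entropies to
a few tenths of a J K$^{-1}$ mol$^{-1}$ over 300–6000 K, which is ample
for equilibrium-temperature estimates, but it deliberately excludes:
anharmonicity and vibration–rotation coupling, low-temperature quantum
rotation (ortho/para H$_2$ below ~100 K, where the classical rotor
factor is wrong), electronically excited states beyond a constant
ground-state degeneracy, isotopologues, hindered rotors, and any
non-ideality or fugacity correction.  Mean bond enthalpies are
transferable averages, so reaction enthalpies derived from them carry a
few kJ/mol of intrinsic uncertainty — visible, for example, in the
ammonia equilibrium temperature, which shifts by roughly 15 K per
5 kJ/mol of $\Delta H_{ref}$.  Coupled simultaneous equilibria (e.g. the
full H$_2$O/H$_2$/O$_2$/H/O system at high temperature) are out of
scope: each reaction is treated with its species held at the stated
standard pressure.

All quantitative statements in this vignette are computed by the code
shown or checked by the package's test suite; the test fixtures are the
printed reference cells discussed above, never values fitted after the
fact.
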