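# Example species/bond registry extension.
# Units are fixed per field: Da, pm, kg m^2, cm^-1, kJ/mol.
species:
  - name: CO
    molar_mass: 28.01
    geometry: linear
    atom_masses: [12.011, 15.999]
    bond_lengths: [112.8]
    vib_modes:
      - [2143, 1]
    sigma: 1
    q_e: 1
  - name: Ar
    molar_mass: 39.948
    geometry: monatomic
bonds:
  C#O: 1072
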