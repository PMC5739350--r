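compartments:
  normal:
    volume: 10.0
    fluid_fraction: 0.1
  blood:
    volume: 1.0
    fluid_fraction: 1.0
  tumor:
    f_vasc: 0.04
    f_int0: 0.5
    f_int_min: 0.25
    lambda: 1.2
    cell_volume_um3: 905.0
populations:
  muscle:
    compartment: normal
    cells_per_cm3: 2000000.0
    receptors:
      VEGFR1: 10000.0
      VEGFR2: 2000.0
      NRP1: 20000.0
      NRP2: 0.0
  ec_normal:
    compartment: normal
    cells_per_cm3: 1.0e+07
    receptors:
      VEGFR1: 10000.0
      VEGFR2: 10000.0
      NRP1: 20000.0
      NRP2: 0.0
  ec_blood:
    compartment: blood
    cells_per_cm3: 5.0e+07
    receptors:
      VEGFR1: 10000.0
      VEGFR2: 10000.0
      NRP1: 20000.0
      NRP2: 0.0
  ec_tumor:
    compartment: tumor
    cells_per_cm3: 5.0e+07
    receptors:
      VEGFR1: 10000.0
      VEGFR2: 10000.0
      NRP1: 20000.0
      NRP2: 0.0
  tumor_cell:
    compartment: tumor
    cells_per_cm3: .na.real
    from_geometry: yes
    receptors:
      VEGFR1: 1000.0
      VEGFR2: 1000.0
      NRP1: 20000.0
      NRP2: 0.0
ligands:
  mVEGF120:
    origin: mouse
    heparin: no
  mVEGF164:
    origin: mouse
    heparin: yes
  hVEGF121:
    origin: human
    heparin: no
  hVEGF165:
    origin: human
    heparin: yes
kinetics:
  kon_VEGFR1: 3.0e+07
  koff_VEGFR1: 0.0001
  kon_VEGFR2: 1.0e+07
  koff_VEGFR2: 0.0001
  kon_NRP: 3200000.0
  koff_NRP: 0.001
  kon_GAG: 420000.0
  koff_GAG: 0.01
  kon_sR1: 2.2e+07
  koff_sR1: 0.001
  kon_a2m: 7000.0
  koff_a2m: 0.0001
  kc_on: 1.0e+10
  kc_off: 0.01
  k_int: 0.0001
secretion:
  tumor_cell:
    hVEGF121: 1.3e-19
    hVEGF165: 4.0e-19
  muscle:
    mVEGF120: 4.0e-20
    mVEGF164: 1.2e-19
  ec_normal:
    mVEGF120: 1.0e-20
    mVEGF164: 3.0e-20
  ec_blood:
    mVEGF120: 1.0e-20
    mVEGF164: 3.0e-20
  ec_tumor:
    mVEGF120: 2.0e-20
    mVEGF164: 6.0e-20
soluble:
  sR1_secretion:
    normal: 1.0e-22
    blood: 5.0e-22
    tumor: 2.0e-22
  sR1_clearance: 1.0e-05
  a2m_conc: 6.0e-09
  a2m_turnover: 1.0e-05
  gag_density:
    normal: 7.5e-13
    tumor: 7.5e-13
clearance:
  ligand: 0.002
transport:
  perm_ligand:
    normal: 3.0e-06
    tumor: 1.0e-05
  perm_sR1:
    normal: 1.0e-07
    tumor: 5.0e-07
  perm_drug:
    normal: 4.0e-07
    tumor: 4.0e-06
  lymph_flow: 2.0e-05
drug:
  kon: 54000.0
  koff: 2.19e-05
  k_clear: 5.73e-07
  mw: 149000.0
  body_mass: 0.02
  affinity_reported_pM: 4456.0
  extravasate: yes
growth:
  k0: 1.2e-06
  k1: 4.0e-07
  psi: 20.0
  Ang0: ~
  C_Ang: 1.0
  variant: model1
  V0: 0.02
rules:
  couple_nrp: yes
  triples: yes
  ang_include_nrp2: no
provenance:
  published:
  - compartments$tumor$cell_volume_um3
  - kinetics (none)
  - drug$kon
  - drug$koff
  - drug$k_clear
  - growth$psi
  note: All other values are package defaults standing in for the source study's unpublished
    supplementary tables.
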