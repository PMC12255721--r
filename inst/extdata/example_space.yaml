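# Example reaction-condition search space: a small Suzuki-style screen.
# Ligands carry a descriptor table (see ligand_descriptors.csv); solvents
# carry boiling points used by the temperature feasibility rule.
parameters:
  - name: ligand
    role: categorical
    values: [PPh3, PCy3, XPhos, SPhos, dppf]
    descriptors: ligand_descriptors.csv
  - name: precatalyst
    role: categorical
    values: [NiCl2_dme, NiBr2_diglyme, Ni_COD2]
  - name: base
    role: categorical
    values: [K3PO4, K2CO3, CsF]
  - name: solvent
    role: categorical
    values: [MeOH, THF, dioxane, toluene]
    boiling_point:
      MeOH: 65
      THF: 66
      dioxane: 101
      toluene: 111
  - name: temperature
    role: temperature
    values: [40, 60, 80, 100]
feasibility:
  - kind: max_temperature_le_boiling_point
    scope: [solvent]
featurization:
  ligand: descriptor
  precatalyst: one_hot
  base: one_hot
  solvent: one_hot
  temperature: numeric
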