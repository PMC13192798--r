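# Resource-holdout scan: one species on 10 carbon sources with a nitrogen
# budget (5.5 biomass units) between typical background budgets and the full
# carbon budget (8.39), so nitrogen limitation appears when the focal carbon
# is added. Run: crmge scan --config scan_carbon_holdout.yaml --out out/
model:
  family: single_species_multicarbon
  species:
    - {id: sp, mu: 1.0, Y: 1.0, x0: 0.01}
  carbons:
    - {id: C1,  C0: 1.1, r: 0.85, Y: 0.34, K: 0.1}
    - {id: C2,  C0: 1.2, r: 0.90, Y: 0.38, K: 0.1}
    - {id: C3,  C0: 1.3, r: 0.95, Y: 0.42, K: 0.1}
    - {id: C4,  C0: 1.4, r: 1.00, Y: 0.46, K: 0.1}
    - {id: C5,  C0: 1.5, r: 1.05, Y: 0.50, K: 0.1}
    - {id: C6,  C0: 1.6, r: 1.10, Y: 0.54, K: 0.1}
    - {id: C7,  C0: 1.7, r: 1.15, Y: 0.58, K: 0.1}
    - {id: C8,  C0: 1.8, r: 1.20, Y: 0.62, K: 0.1}
    - {id: C9,  C0: 1.9, r: 1.25, Y: 0.66, K: 0.1}
    - {id: C10, C0: 2.0, r: 1.30, Y: 0.70, K: 0.1}
  nitrogen: {N0: 6.875, rN: 30, YN: 0.8, KN: 0.01}
focal:
  kind: carbon_source
  id: C10
backgrounds:
  mode: exhaustive
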