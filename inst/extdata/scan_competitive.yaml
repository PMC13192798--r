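# Focal-species scan of a 10-species competitive community.
# Run: crmge fit --config scan_competitive.yaml --out out/
model:
  family: competitive
  KM: 1.0
  C0: 10.0
  species:
    - {id: s1,  mu: 1.05, Y: 0.5, beta: 0.15, x0: 0.01}
    - {id: s2,  mu: 0.92, Y: 0.5, beta: 0.55, x0: 0.01}
    - {id: s3,  mu: 1.12, Y: 0.5, beta: 0.30, x0: 0.01}
    - {id: s4,  mu: 0.85, Y: 0.5, beta: 0.80, x0: 0.01}
    - {id: s5,  mu: 1.00, Y: 0.5, beta: 0.45, x0: 0.01}
    - {id: s6,  mu: 0.95, Y: 0.5, beta: 0.65, x0: 0.01}
    - {id: s7,  mu: 1.20, Y: 0.5, beta: 0.25, x0: 0.01}
    - {id: s8,  mu: 0.88, Y: 0.5, beta: 0.70, x0: 0.01}
    - {id: s9,  mu: 1.08, Y: 0.5, beta: 0.40, x0: 0.01}
    - {id: s10, mu: 1.15, Y: 0.5, beta: 0.90, x0: 0.01}
focal:
  kind: species
  id: s10
backgrounds:
  mode: exhaustive
n_bins: 20
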