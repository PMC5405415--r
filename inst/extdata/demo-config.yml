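# Demonstration configuration: a 2D membrane system with the standard
# rotational affinity E = 0.04 and a moderately potent ligand.
dimension: 2D
rates:
  d_plus: 10.0     # um^2 mol^-1 s^-1 (scaled demo units)
  d_minus: 8.0     # s^-1
  e_plus: 1.0      # s^-1
  e_minus: 25.0    # s^-1
  k_plus: 1.0      # s^-1
  k_minus: 0.2     # s^-1
totals:
  R_total: 1.0
  L_total: 1.0
seed: 1
panel:
  n: 6
  fold_k_plus: 1000
  fold_k_minus: 10
  k_plus_max: 0.2   # binding on-rates stay well below e- = 25 s^-1
  jitter_sd: 0
assays:
  simulate:
    t_end: 20
    n_times: 101
  tf:
    n: 1000
  af:
    n_receptors: 60
    n_ligands: 60
    contact_area: 1.0
    contact_times: [1, 3, 6, 12]
    cycles: 100
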