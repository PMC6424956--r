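# Example run configuration: one shuttle peptide, the 200/800 uL transwell
# geometry, and a clean protonated-only instrument model.
peptides:
- name: HAI
  sequence: HAIYPRH
  n_terminus: acetyl_light
  c_terminus: amide
assay:
  v_donor_ul: 200.0
  v_acceptor_ul: 800.0
  time_s: 7200.0
  area_cm2: 1.12
  c_donor0_um: 200.0
sim:
  resolution: 10000.0
  noise_sd: 0.0
  baseline_level: 0.0
  adduct_abundances:
    H: 1.0
  intensity_scale: 100.0
  step: 0.01
quant:
  adducts: H
  correct_overlap: yes
seed: 1
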