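# Demo run: three strains spanning the three growth patterns, one pairwise
# pH contrast each, small synthetic transcriptomes. Completes in well under
# a minute on one CPU.
strains: [EUNS-26, ACAF-21, NPAL-12]
ph: [4.7, 7.0, 8.2]
seed: 20
n_perm: 1000
mu_true:
  - {strain: EUNS-26, ph: 4.7, mu: 0.60}
  - {strain: EUNS-26, ph: 7.0, mu: 0.25}
  - {strain: EUNS-26, ph: 8.2, mu: 0.20}
  - {strain: ACAF-21, ph: 4.7, mu: 0.30}
  - {strain: ACAF-21, ph: 7.0, mu: 0.35}
  - {strain: ACAF-21, ph: 8.2, mu: 0.40}
  - {strain: NPAL-12, ph: 4.7, mu: -0.30}
  - {strain: NPAL-12, ph: 7.0, mu: 0.40}
  - {strain: NPAL-12, ph: 8.2, mu: 0.45}
contrasts:
  - {strain: EUNS-26, low_ph: 4.7, high_ph: 8.2}
  - {strain: ACAF-21, low_ph: 4.7, high_ph: 8.2}
  - {strain: NPAL-12, low_ph: 7.0, high_ph: 8.2}
growth:
  n_wells: 8
de:
  n_genes: 1000
  n_sets: 40
  set_size_range: [5, 20]
  frac_enriched_sets: 0.15
  frac_depleted_sets: 0.15
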