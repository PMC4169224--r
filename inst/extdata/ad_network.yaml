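name: ad_default
species:
- name: glucose
  role: substrate_product
- name: butyrate
  role: substrate_product
- name: propionate
  role: substrate_product
- name: acetate
  role: substrate_product
- name: hydrogen
  role: substrate_product
- name: methane
  role: substrate_product
- name: sugar_degraders
  role: degrader
- name: butyrate_degraders
  role: degrader
- name: propionate_degraders
  role: degrader
- name: acetate_degraders
  role: degrader
- name: hydrogen_degraders
  role: degrader
reactions:
- name: r1
  substrate: glucose
  degrader: sugar_degraders
  mu_max: 1.25
  K: 500.0
  products:
    butyrate: 0.117
    propionate: 0.243
    acetate: 0.369
    hydrogen: 0.171
    sugar_degraders: 0.1
  kinetics: monod
- name: r2
  substrate: butyrate
  degrader: butyrate_degraders
  mu_max: 0.833
  K: 200.0
  products:
    acetate: 0.752
    hydrogen: 0.188
    butyrate_degraders: 0.06
  kinetics: monod
- name: r3
  substrate: propionate
  degrader: propionate_degraders
  mu_max: 0.542
  K: 100.0
  products:
    acetate: 0.5472
    hydrogen: 0.4128
    propionate_degraders: 0.04
  kinetics: monod
- name: r4
  substrate: acetate
  degrader: acetate_degraders
  mu_max: 0.333
  K: 150.0
  products:
    methane: 0.95
    acetate_degraders: 0.05
  kinetics: monod
- name: r5
  substrate: hydrogen
  degrader: hydrogen_degraders
  mu_max: 0.35
  K: 150.0
  products:
    methane: 0.94
    hydrogen_degraders: 0.06
  kinetics: monod
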