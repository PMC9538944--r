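# Built-in species and chemical parameter sets.
# Masses in kg wet weight, temperatures in degC, fractions unitless,
# hepatocellularity in 10^6 cells per g liver.
species:
  trout_reference:
    body_mass: 0.010
    temperature: 15
    lipid_fraction: 0.05
    liver_fraction: 0.015
    hepatocellularity: 510
    hepatic_flow_fraction: 0.259
    do_saturation: 0.90
    growth_regime: cold
  trout_study:
    body_mass: 0.0185
    temperature: 12
    lipid_fraction: 0.0908
    liver_fraction: 0.015
    hepatocellularity: 510
    hepatic_flow_fraction: 0.259
    do_saturation: 0.91
    growth_regime: cold
  carp_study:
    body_mass: 0.0446
    temperature: 21
    lipid_fraction: 0.0957
    liver_fraction: 0.0174
    hepatocellularity: 510
    hepatic_flow_fraction: 0.259
    do_saturation: 0.77
    growth_regime: warm
chemicals:
  MXC:
    log_kow: 5.08
  BaP:
    log_kow: 5.99
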