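# Flattened 6 MV beam-line preset; the filter profile is designed at load
# by design_flattening_filter() at its defaults.
source:
  mean_energy: 7.5        # MeV
  energy_spread_sigma: 0.4  # MeV
  spot_fwhm_mm: 1.0
head:
  mode: flat
  field_cm: 10
  target_thickness_mm: 1
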