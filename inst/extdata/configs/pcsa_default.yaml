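# Primary Care Scoring Algorithm — default weight configuration.
# The published flow diagram of the algorithm is not machine-readable in
# all copies; these are the documented fallback point values (blood vessels
# at 2 points is stated in the text). Edit here, never in code.
algorithm: pcsa
gate: true
weights:
  dermal_melanin: 2
  collagen_holes: 1
  erythematous_blush: 1
  blood_displacement: 1
  blood_vessels: 2
  size_term: 1
  age_term: 1
suspicious_threshold: 3
size_threshold_mm: 6
age_band_edge_years: 50
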