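# Moncrieff scoring system — default weight configuration (no gate, no
# blood-vessels term). Point values follow the same fallback convention as
# the PCSA config.
algorithm: mss
gate: false
weights:
  dermal_melanin: 2
  collagen_holes: 1
  erythematous_blush: 1
  blood_displacement: 1
  size_term: 1
  age_term: 1
suspicious_threshold: 3
size_threshold_mm: 6
age_band_edge_years: 50
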