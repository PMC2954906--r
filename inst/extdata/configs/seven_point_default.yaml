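# 7-point melanoma checklist — three major items at 2 points, four minor
# at 1 point, referral at a total of 3 or more. The checklist's own
# diameter item conventionally uses a 7 mm cut, kept separate from the
# SIAscopic rules' 6 mm size term.
algorithm: seven_point
gate: false
weights:
  change_in_size: 2
  irregular_shape: 2
  irregular_colour: 2
  diameter_ge_7mm: 1
  inflammation: 1
  oozing_or_crusting: 1
  change_in_sensation: 1
suspicious_threshold: 3
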