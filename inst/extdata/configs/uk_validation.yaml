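# UK validation cohort (the held-out third of the UK sample). Prevalence
# entries are the published diagnosis counts (n = 208), normalised at
# load. suspicious_given_diagnosis chosen so the expected suspicious count
# is ~6, the reported number.
name: uk_validation
n_lesions: 208
seed: 20060101
prevalence:
  naevus: 159
  seborrhoeic_keratosis: 39
  melanoma: 2
  dermatofibroma: 6
  haemangioma: 2
suspicious_given_diagnosis:
  melanoma: 1.0
  naevus: 0.011
  seborrhoeic_keratosis: 0.04
  dermatofibroma: 0.10
  haemangioma: 0.02
age_distribution: {mean: 44.9, sd: 15, min: 18}
diameter_distribution:
  default: {meanlog: 1.504, sdlog: 0.45}     # median ~4.5 mm
  melanoma: {meanlog: 2.08, sdlog: 0.40}     # median ~8 mm
  lentigo_maligna: {meanlog: 2.30, sdlog: 0.40}
  seborrhoeic_keratosis: {meanlog: 1.95, sdlog: 0.50}
  basal_cell_carcinoma: {meanlog: 1.80, sdlog: 0.40}
  solar_lentigo: {meanlog: 1.70, sdlog: 0.40}
suspicious_feature_rate: 1.0
benign_feature_rate: 1.0
feature_profiles:
  default:
    dermal_melanin: 0.06
    collagen_holes: 0.04
    erythematous_blush: 0.05
    blood_displacement: 0.03
    blood_vessels: 0.05
    collagen_white_dots: 0.015
    cerebriform_melanin: 0.01
    blood_lacunes: 0.005
    change_in_size: 0.10
    irregular_shape: 0.12
    irregular_colour: 0.12
    diameter_ge_7mm: 0.15
    inflammation: 0.05
    oozing_or_crusting: 0.03
    change_in_sensation: 0.06
  melanoma:
    dermal_melanin: 0.90
    collagen_holes: 0.75
    erythematous_blush: 0.65
    blood_displacement: 0.65
    blood_vessels: 0.65
    collagen_white_dots: 0.02
    cerebriform_melanin: 0.02
    change_in_size: 0.70
    irregular_shape: 0.70
    irregular_colour: 0.80
    diameter_ge_7mm: 0.70
    inflammation: 0.30
    oozing_or_crusting: 0.25
    change_in_sensation: 0.30
  lentigo_maligna:
    dermal_melanin: 0.80
    collagen_holes: 0.50
    erythematous_blush: 0.45
    blood_displacement: 0.40
    blood_vessels: 0.45
    change_in_size: 0.50
    irregular_shape: 0.60
    irregular_colour: 0.70
    diameter_ge_7mm: 0.80
  seborrhoeic_keratosis:
    dermal_melanin: 0.545
    collagen_holes: 0.08
    erythematous_blush: 0.06
    blood_displacement: 0.04
    blood_vessels: 0.10
    collagen_white_dots: 0.60
    cerebriform_melanin: 0.50
    blood_lacunes: 0.01
    change_in_size: 0.15
    irregular_shape: 0.20
    irregular_colour: 0.25
    diameter_ge_7mm: 0.50
    oozing_or_crusting: 0.08
  haemangioma:
    dermal_melanin: 0.02
    erythematous_blush: 0.30
    blood_vessels: 0.30
    blood_lacunes: 0.90
  basal_cell_carcinoma:
    dermal_melanin: 0.15
    collagen_holes: 0.20
    erythematous_blush: 0.30
    blood_displacement: 0.10
    blood_vessels: 0.50
    change_in_size: 0.40
    diameter_ge_7mm: 0.35
    inflammation: 0.25
    oozing_or_crusting: 0.30
  angiokeratoma:
    dermal_melanin: 0.10
    erythematous_blush: 0.20
    blood_vessels: 0.30
    blood_lacunes: 0.60
  dermatofibroma:
    dermal_melanin: 0.10
    collagen_holes: 0.10
  solar_lentigo:
    dermal_melanin: 0.08
    irregular_colour: 0.20
    diameter_ge_7mm: 0.40
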