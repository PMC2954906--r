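# Lesion CSV format reference

UTF-8, comma-separated, one header row; column names exactly as below.
Boolean fields accept `true/false/1/0/yes/no` (case-insensitive); empty
fields are missing values. Missing values are never imputed.

| column | type | required | notes |
|---|---|---|---|
| `lesion_id` | string | yes | unique within the file |
| `dataset_tag` | enum | no | `uk_development`, `uk_validation`, `australian_validation`, `other` (default) |
| `dermal_melanin` | bool | yes | melanin detected below the epidermis |
| `collagen_holes` | bool | yes | focal deficits on the collagen view |
| `erythematous_blush` | bool | yes | increased dermal blood around the lesion |
| `blood_displacement` | bool | yes | blood pushed out beneath the lesion |
| `blood_vessels` | bool | yes | visible vessels on the blood view |
| `collagen_white_dots` | bool | yes | analogue of milia-like cysts (seborrhoeic keratosis) |
| `cerebriform_melanin` | bool | yes | brain-like ridged melanin pattern (seborrhoeic keratosis) |
| `blood_lacunes` | bool | yes | pooled-blood lakes (haemangioma) |
| `change_in_size` … `change_in_sensation` | bool | block-optional | the seven checklist items; supply all seven columns or none; within a row, all or none |
| `diameter_mm` | positive real | one of the two | lesion diameter in mm |
| `diameter_gt_6mm` | bool | one of the two | must equal `diameter_mm > 6` when both given |
| `age_years` | non-negative int | one of the two | patient age |
| `age_band` | enum | one of the two | `<50` or `>=50` |
| `sex` | enum | no | `male`, `female`, `unknown` (default) |
| `reference_diagnosis` | enum | yes | one of: naevus, seborrhoeic keratosis, solar lentigo, basal cell carcinoma, melanoma, angiokeratoma, dermatofibroma, lentigo maligna, haemangioma, lentigo simplex, ephilis, papilloma (any case; spaces or underscores) |
| `reference_tier` | enum | yes | `histopathology`, `in_person_expert`, `image_expert` |
| `reference_suspicious` | bool | yes | reference standard: lesion warrants referral, excision or short-term monitoring |

Scored CSVs (output of `score`) append `<algorithm>_gate`,
`<algorithm>_score`, `<algorithm>_classification` columns; a gated lesion
has an empty score and classification `benign`.
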