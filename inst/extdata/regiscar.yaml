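# RegiSCAR DRESS validation score. Category bands: total <= +1 excluded,
# +2..+3 possible, +4 probable, >= +5 definite. The causality inclusion
# gate used by ALDRESS is a total strictly greater than +2 (the
# positivity_threshold below).
algorithm: regiscar
description: RegiSCAR DRESS diagnostic validation score
positivity_threshold: 2
items:
  - id: fever_ge_38_5
    description: Fever >= 38.5 C.
    levels: {"yes": 0, "no": -1, unknown: -1}
  - id: lymphadenopathy
    description: Enlarged lymph nodes (>= 2 sites, > 1 cm).
    levels: {"yes": 1, "no": 0, unknown: 0}
  - id: eosinophilia
    description: Eosinophilia (moderate 0.7-1.5e9/L or 10-19.9%; marked above).
    levels: {none: 0, moderate: 1, marked: 2, unknown: 0}
  - id: atypical_lymphocytes
    description: Atypical lymphocytes on smear.
    levels: {"yes": 1, "no": 0, unknown: 0}
  - id: skin_extent_gt50
    description: Rash extent over 50% of body surface area.
    levels: {"yes": 1, "no": 0, unknown: 0}
  - id: rash_suggestive
    description: Rash morphology suggestive of DRESS.
    levels: {"yes": 1, "no": -1, unknown: 0}
  - id: biopsy_suggestive
    description: Skin biopsy suggestive of DRESS.
    levels: {"yes": 0, "no": -1, not_done: 0}
  - id: organ_involvement
    description: Internal organ involvement.
    levels: {none: 0, one: 1, two_or_more: 2}
  - id: resolution_ge_15_days
    description: Resolution in 15 days or more.
    levels: {"yes": 0, "no": -1, unknown: -1}
  - id: alternative_causes_excluded
    description: >
      At least three alternative causes (blood cultures, serologies, ANA)
      excluded.
    levels: {"yes": 1, "no": 0, unknown: 0}
bands:
  - {name: excluded, min: -4, max: 1}
  - {name: possible, min: 2, max: 3}
  - {name: probable, min: 4, max: 4}
  - {name: definite, min: 5, max: 9}
binary_map:
  excluded: unrelated
  possible: related
  probable: related
  definite: related
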