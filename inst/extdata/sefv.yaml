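# SEFV: Spanish Pharmacovigilance System causality algorithm
# (Karch-Lasagna-derived, seven factors). Positivity rule for the DRESS
# validation setting: related iff net score > 6 (strict). Category bands
# follow the published unlikely/conditional/possible/probable/definite map.
algorithm: sefv
description: Spanish Pharmacovigilance System seven-factor causality score
positivity_threshold: 6
items:
  - id: chronology
    description: >
      Latency from drug start to reaction onset (1-7 d compatible; 8-21 d
      partially compatible; beyond 21 d incompatible; onset on/before the
      start excludes the drug).
    levels:
      compatible: 2
      partially_compatible: 1
      incompatible: 0
      excluding: -1
  - id: literature
    description: Prior literature association (notoriety) of the drug.
    levels:
      well_known: 2
      occasionally_reported: 1
      unknown: 0
  - id: withdrawal
    description: Clinical course after drug withdrawal (dechallenge).
    levels:
      improved_after_withdrawal: 2
      not_improved: -2
      not_withdrawn: 0
      unassessable: 0
  - id: rechallenge
    description: Outcome of re-exposure.
    levels:
      positive: 3
      negative: -1
      not_done: 0
  - id: alternative_causes
    description: Alternative (infectious) explanation for the reaction.
    levels:
      positive: -3
      screens_negative: 1
      not_recorded: 0
  - id: contributing_factors
    description: Predisposing factors favouring the reaction.
    levels:
      present: 1
      none: 0
  - id: complementary_explorations
    description: Supportive complementary tests (LTT / patch test).
    levels:
      supportive: 1
      none: 0
bands:
  - {name: unlikely, min: -7, max: 0}
  - {name: conditional, min: 1, max: 3}
  - {name: possible, min: 4, max: 5}
  - {name: probable, min: 6, max: 7}
  - {name: definite, min: 8, max: 12}
binary_map:
  unlikely: unrelated
  conditional: unrelated
  possible: related
  probable: related
  definite: related
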