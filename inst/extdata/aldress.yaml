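# ALDRESS: DRESS-specific drug causality score.
# Positivity rule: related iff net score > 7 (strict).
# The point allocation below is this package's documented convention,
# constrained by the published positivity threshold and by the requirement
# that a textbook single-drug DRESS presentation (compatible chronology,
# improvement after withdrawal, well-known drug, infectious alternatives
# excluded) classifies as related. Edit freely; load_score_table() validates.
algorithm: aldress
description: DRESS-specific causality score (RegiSCAR-gated)
positivity_threshold: 7
items:
  - id: chronology
    description: >
      Latency from drug start to reaction onset against the typical DRESS
      window of two to eight weeks (15-56 d compatible; 8-14 or 57-90 d
      partially compatible; 1-7 or >90 d incompatible; onset on/before the
      start excludes the drug).
    levels:
      compatible: 3
      partially_compatible: 1
      incompatible: -3
      excluding: -4
  - id: dechallenge
    description: Clinical course after drug withdrawal.
    levels:
      improved_after_withdrawal: 2
      not_improved: -2
      not_withdrawn: 0
      unassessable: 0
  - id: rechallenge
    description: Outcome of deliberate or accidental re-exposure.
    levels:
      positive: 3
      negative: -2
      not_done: 0
  - id: notoriety
    description: Strength of the prior drug-DRESS literature association.
    levels:
      well_known: 2
      occasionally_reported: 1
      unknown: 0
  - id: alternative_cause
    description: >
      Alternative infectious aetiology from the microbiology screen: any
      positive pathogen counts against the drug; a fully negative screen
      supports it; an absent work-up is neutral.
    levels:
      positive: -2
      screens_negative: 1
      not_recorded: 0
  - id: immunology
    description: >
      LTT and epicutaneous patch test; a positive LTT outweighs a positive
      patch test, combined support capped at +3.
    levels:
      ltt_positive: 3
      patch_positive: 2
      negative: -1
      not_done: 0
  - id: concomitant
    description: >
      Penalty when another suspect drug in the same patient carries at
      least equal notoriety.
    levels:
      present: -1
      none: 0
bands:
  - {name: unlikely, min: -12, max: 0}
  - {name: possible, min: 1, max: 7}
  - {name: probable, min: 8, max: 11}
  - {name: definite, min: 12, max: 14}
binary_map:
  unlikely: unrelated
  possible: unrelated
  probable: related
  definite: related
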