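# Curation rules mapping the 1987-format attribute list onto the canonical
# 20-attribute schema. Applied in order: pattern renames, exact renames,
# drops, pairwise merges (set union), binarization, additions. Every step is
# skipped when already applied, so curation is idempotent.
source_variables:
  - cap-shape
  - cap-surface
  - cap-color
  - "bruises?"
  - odor
  - gill-attachment
  - gill-spacing
  - gill-size
  - gill-color
  - stalk-shape
  - stalk-root
  - stalk-surface-above-ring
  - stalk-surface-below-ring
  - stalk-color-above-ring
  - stalk-color-below-ring
  - veil-type
  - veil-color
  - ring-number
  - ring-type
  - spore-print-color
  - population
  - habitat
rename_patterns:
  - pattern: "stalk"
    replacement: "stem"
renames:
  "bruises?": does-bruise-or-bleed
drops:
  - odor
  - gill-size
  - stem-shape
  - population
merges:
  - sources: [stem-surface-above-ring, stem-surface-below-ring]
    target: stem-surface
  - sources: [stem-color-above-ring, stem-color-below-ring]
    target: stem-color
binarize:
  - source: ring-number
    target: has-ring
    counts:
      "n": 0
      "o": 1
      "t": 2
additions:
  - season
  - cap-diameter
  - stem-height
  - stem-width
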