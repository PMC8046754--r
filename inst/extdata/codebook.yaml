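# Canonical variable schema and codebook.
#
# Nominal categories are encoded as "full category name: single letter".
# Lengths are centimeters except stem-width, which is millimeters.
# The secondary schema is the binary class plus 17 nominal and 3 metrical
# attributes; the primary schema prepends the multinomial classes family
# and name.
colors: &colors
  brown: "n"
  buff: "b"
  gray: "g"
  green: "r"
  pink: "p"
  purple: "u"
  red: "e"
  white: "w"
  yellow: "y"
  blue: "l"
  orange: "o"
  black: "k"
surfaces: &surfaces
  fibrous: "i"
  grooves: "g"
  scaly: "y"
  smooth: "s"
  shiny: "h"
  leathery: "l"
  silky: "k"
  sticky: "t"
  wrinkled: "w"
  fleshy: "e"
variables:
  - name: family
    kind: nominal
    role: class-multinomial
  - name: name
    kind: nominal
    role: class-multinomial
  - name: class
    kind: nominal
    role: class-binary
    codebook:
      edible: "e"
      poisonous: "p"
  - name: cap-diameter
    kind: metrical
    role: attribute
    unit: cm
  - name: cap-shape
    kind: nominal
    role: attribute
    codebook:
      bell: "b"
      conical: "c"
      convex: "x"
      flat: "f"
      sunken: "s"
      spherical: "p"
      others: "o"
  - name: cap-surface
    kind: nominal
    role: attribute
    codebook: *surfaces
  - name: cap-color
    kind: nominal
    role: attribute
    codebook: *colors
  - name: does-bruise-or-bleed
    kind: nominal
    role: attribute
    codebook:
      bruises-or-bleeds: "t"
      "no": "f"
  - name: gill-attachment
    kind: nominal
    role: attribute
    codebook:
      adnate: "a"
      adnexed: "x"
      decurrent: "d"
      free: "e"
      sinuate: "s"
  - name: gill-spacing
    kind: nominal
    role: attribute
    codebook:
      close: "c"
      distant: "d"
  - name: gill-color
    kind: nominal
    role: attribute
    codebook: *colors
  - name: stem-height
    kind: metrical
    role: attribute
    unit: cm
  - name: stem-width
    kind: metrical
    role: attribute
    unit: mm
  - name: stem-root
    kind: nominal
    role: attribute
    codebook:
      bulbous: "b"
      swollen: "s"
      club: "c"
      cup: "u"
      equal: "e"
      rhizomorphs: "z"
      rooted: "r"
  - name: stem-surface
    kind: nominal
    role: attribute
    codebook: *surfaces
  - name: stem-color
    kind: nominal
    role: attribute
    codebook: *colors
  - name: veil-type
    kind: nominal
    role: attribute
    codebook:
      partial: "p"
      universal: "u"
  - name: veil-color
    kind: nominal
    role: attribute
    codebook: *colors
  - name: has-ring
    kind: nominal
    role: attribute
    codebook:
      ring: "t"
      "no": "f"
  - name: ring-type
    kind: nominal
    role: attribute
    codebook:
      cobwebby: "c"
      evanescent: "e"
      flaring: "r"
      grooved: "g"
      large: "l"
      pendant: "p"
      sheathing: "s"
      zone: "z"
      scaly: "y"
      movable: "m"
  - name: spore-print-color
    kind: nominal
    role: attribute
    codebook: *colors
  - name: habitat
    kind: nominal
    role: attribute
    codebook:
      grasses: "g"
      leaves: "l"
      meadows: "m"
      paths: "p"
      heaths: "h"
      urban: "u"
      waste: "w"
      woods: "d"
  - name: season
    kind: nominal
    role: attribute
    codebook:
      spring: "s"
      summer: "u"
      autumn: "a"
      winter: "w"
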