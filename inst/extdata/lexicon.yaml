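# Keyword lexicon for rule-based attribute extraction from field-guide prose.
#
# Anchors are the section nouns that scope a sentence; each anchor exposes
# keyword classes (slots) that map matched keywords to schema variables.
# Keywords are matched as whole lower-cased tokens; hyphenated color
# compounds ("red-brown") split into their constituent color codes when both
# halves are color keywords. Triggers are regular expressions evaluated over
# the whole description, first match wins per variable.
anchors:
  cap: "\\bcaps?\\b"
  gill: "\\bgills?\\b"
  veil: "\\bveils?\\b"
  stem: "\\bstems?\\b"
  ring: "\\brings?\\b"
  spore: "\\bspore[ -]?prints?\\b"
slots:
  cap:
    shape: cap-shape
    surface: cap-surface
    color: cap-color
  gill:
    attachment: gill-attachment
    spacing: gill-spacing
    color: gill-color
  veil:
    color: veil-color
  stem:
    root: stem-root
    surface: stem-surface
    color: stem-color
  ring:
    ringtype: ring-type
  spore:
    color: spore-print-color
keyword_classes:
  shape:
    bell: "b"
    bell-shaped: "b"
    conical: "c"
    convex: "x"
    flat: "f"
    flattened: "f"
    sunken: "s"
    spherical: "p"
    irregular: "o"
    others: "o"
  surface:
    fibrous: "i"
    grooved: "g"
    grooves: "g"
    scaly: "y"
    smooth: "s"
    shiny: "h"
    leathery: "l"
    silky: "k"
    sticky: "t"
    wrinkled: "w"
    fleshy: "e"
  color:
    brown: "n"
    buff: "b"
    gray: "g"
    grey: "g"
    green: "r"
    pink: "p"
    purple: "u"
    red: "e"
    white: "w"
    yellow: "y"
    blue: "l"
    orange: "o"
    black: "k"
  attachment:
    adnate: "a"
    adnexed: "x"
    decurrent: "d"
    free: "e"
    sinuate: "s"
  spacing:
    close: "c"
    crowded: "c"
    distant: "d"
  root:
    bulbous: "b"
    swollen: "s"
    club-shaped: "c"
    clubbed: "c"
    cup-like: "u"
    cupped: "u"
    equal: "e"
    rhizomorphic: "z"
    rhizomorphs: "z"
    rooted: "r"
    rooting: "r"
  ringtype:
    cobwebby: "c"
    evanescent: "e"
    flaring: "r"
    grooved: "g"
    large: "l"
    pendant: "p"
    sheathing: "s"
    zoned: "z"
    scaly: "y"
    movable: "m"
habitat_keywords:
  grasses: "g"
  grass: "g"
  leaves: "l"
  litter: "l"
  meadows: "m"
  meadow: "m"
  paths: "p"
  path: "p"
  heaths: "h"
  heath: "h"
  urban: "u"
  waste: "w"
  woods: "d"
  woodland: "d"
season_keywords:
  spring: "s"
  summer: "u"
  autumn: "a"
  fall: "a"
  winter: "w"
triggers:
  veil-type:
    - pattern: "universal veil|enclosed in a"
      code: "u"
    - pattern: "\\bpartial\\b"
      code: "p"
  does-bruise-or-bleed:
    - pattern: "(?:does not|do not|never)[^.]*\\b(?:bruise|bleed)"
      code: "f"
    - pattern: "\\bbruis|\\bbleed"
      code: "t"
  has-ring:
    - pattern: "no ring|without a ring|lacks a ring"
      code: "f"
    - pattern: "\\brings?\\b"
      code: "t"
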