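---
title: "From field-guide prose to simulated mushroom data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From field-guide prose to simulated mushroom data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mushroomsim)
library(dplyr)
```

## The problem

Attribute-based edibility classification of mushrooms has long leaned on a
single 1987 table of hypothetical gilled mushrooms covering 23 species from
two families. `mushroomsim` implements a pipeline for building a broader
data set of the same shape from field-guide text, in five stages:

1. **Extraction** — parse an HTML field guide into species records.
2. **Curation** — map the extracted variables onto the canonical
   20-attribute schema derived from the 1987 format.
3. **Simulation** — generate hypothetical individual mushrooms (the
   *secondary data*) from the species-level *primary data*.
4. **Quality control** — class balance, missingness filtering, imputation,
   and a mixed-type association matrix.
5. **Evaluation** — four binary classifiers with cross-validated
   accuracy, precision, recall, F2 and ROC/AUC.

Because the source book is copyrighted, the package ships a deterministic
fixture generator that emits synthetic field-guide documents in the same
HTML dialect, with ground truth attached. Every stage is exercised against
that generator.

## Data model

The *primary data* holds one row per species. Nominal attributes are
**sets** of single-letter codes (`[x, f]` — the species' cap can be convex
or flat), quantitative attributes are **intervals** (`[10:20]` cm).
Edibility is binary: `e` edible, `p` poisonous, where `p` deliberately
absorbs inedible and unknown-edibility species (the cautious default). The
*secondary data* holds one row per hypothetical mushroom, with a single
code or value per attribute.

The canonical schema is 1 binary class + 17 nominal + 3 metrical
attributes (cap-diameter and stem-height in cm, stem-width in mm); the
primary table prepends `family` and `name` as multinomial classes. The
codebook ships as `inst/extdata/codebook.yaml`; letters follow the
1987-format conventions where a category exists there (convex `x`,
edible `e`, ...). Categories named "none" were deliberately left out of the
prose-facing codebooks so that no keyword is a generic English word.

Files are delimited with `;` because set literals contain commas; the
reader auto-detects `,` vs `;` from the header line. Measurements are
written at 2-decimal precision — sub-hundredth precision is not meaningful
for field measurements in cm/mm.

## Extraction

A book entry has six structured parts: a header paragraph (HTML class
`chapterHeadA`, matched case-insensitively) carrying the species name and,
for a family's first species, the family name; then body paragraphs
(`paraNoIndent`) with the description prose, the size attributes, the
habitat, the season, and an edibility statement that always opens with
*edible*, *inedible* or *poisonous*.

The description parser is anchored on section nouns — *cap*, *gills*,
*veil*, *stem*, *ring*, *spore print*. A keyword found in a sentence is
attributed to the **nearest anchor noun of that sentence**, with ties going
to the following anchor. The tie rule encodes that English descriptors
precede their noun: in

> "The entire young fruit body is enclosed in a white veil which leaves
> fragments (which may wash off) on the shiny red, marginally grooved cap."

*white* must attach to the following *veil* (veil-color `w`) while *shiny
red, marginally grooved* attach to *cap* (cap-surface `{g, h}`, cap-color
`e`):

```{r}
hits <- extract_nominals(paste(
  "The entire young fruit body is enclosed in a white veil which leaves",
  "fragments (which may wash off) on the shiny red, marginally grooved cap."))
hits[lengths(hits) > 0]
```

A preceding-anchor rule fails on exactly this sentence, which is why
attribution is distance-based rather than direction-based. Keywords in
sentences without an anchor are discarded. Variables that prose expresses
as phrases rather than adjectives — veil-type (`"enclosed in a"` implies a
universal veil), does-bruise-or-bleed, has-ring — are matched by
regular-expression triggers over the whole description, first match wins.
Hyphenated compounds split into two color codes only when both halves are
codebook colors, so "red-brown" yields `{e, n}` while "bell-shaped" stays
whole. When the same variable is hit twice, the hits are unioned into the
set — the natural reading of set-valued attributes.

Sizes are listed in appearing order (cap diameter, stem height, stem
width); measurements are attributed to the cap or stem segment of the size
sentence so that capless or stemless entries cannot shift the assignment.
A single stated mean $\mu$ becomes the interval
$[(1 - \tfrac14)\mu,\ (1 + \tfrac14)\mu]$. Species without a cap — and, by
default, without a stem — are excluded by `exclude_unsupported()`, since
the 1987-style record structure presumes cap, gills and stem.

The keyword lexicon (`inst/extdata/lexicon.yaml`) is data, not code: it is
seeded from the codebook's category names plus a synonym table
(grey/gray, grooved/grooves, fall/autumn, ...) and can be replaced to suit
another book's vocabulary.

## Curation

`apply_curation()` applies a declarative rule set
(`inst/extdata/curation_rules.yaml`) mapping the 22-attribute 1987 list
onto the canonical schema: *stalk* becomes *stem* in all names, *bruises?*
becomes *does-bruise-or-bleed*, `odor`/`gill-size`/`stem-shape`/
`population` are dropped (prose text cannot support them), the
above-/below-ring surface and color pairs merge by set union, and
`ring-number` is binarized into `has-ring` (any positive ring count maps
to `t`, a zero count to `f`; a missing ring mention stays missing rather
than becoming `f`, because absence of information is not information of
absence). `season` and the three size attributes are added. Every rule
skips when already applied, making curation idempotent; a rename whose old
and new names are both absent is a configuration error.
`consistency_check()` is report-only: out-of-codebook codes, inverted
ranges, empty edibility, duplicate names.

## Simulation

Each species contributes `n_per_species` hypothetical entries (default
353, the per-species count of the 1987 data; 173 species × 353 = 61,069
rows). Nominal codes are drawn uniformly and independently per variable
from the species' set; class, name and family carry over unchanged, so the
species-level class balance is preserved exactly.

The three quantitative traits are correlated. With cap diameter $a$, stem
height $b$, stem width $c$, the assumed covariance over standard normals
is

$$
COV = \begin{bmatrix} 1 & 0.5 & 0.5 \\ 0.5 & 1 & 0.7 \\ 0.5 & 0.7 & 1 \end{bmatrix},
$$

the stem-related pair correlating more strongly. Independent
$N(0,1)$ triples $z$ are colored by the lower Cholesky factor $L$
($COV = LL^\top$, entries 1/0.5/0.87/0.5/0.52/0.69 at 2 decimals), and the
three components of one entry share one triple:

```{r}
round(covariance_model()$chol, 2)
```

One covariance model is shared by all species — a deliberate,
documented simplification, overridable per run via
`simulation_config(covariance = covariance_model(your_matrix))`.

**Interval rescaling.** A colored draw $z$ must land in the species'
$[\min, \max]$. The half-shift transform $x = \tfrac12(z + 1)$ followed by
$x \cdot (\max - \min) + \min$ recentres the sample on the interval
midpoint (mean 0.5 before the affine map), but covers the interval with
only $2\Phi(1) - 1 \approx 68.3\%$ probability. For the stated contract
that ≈99.7% of draws fall inside the interval, the band that must map onto
$[0, 1]$ is $\pm3\sigma$, i.e. $x = \tfrac12(z/3 + 1)$. The package
implements both conventions: the default `three_sigma` mode honours the
99.7% coverage contract; `half_shift` reproduces the plain half-shift.
The divergence is asserted in the test suite rather than hidden. In both
modes out-of-interval draws are **kept** (no clipping — clipping would
spike the interval endpoints), and a degenerate interval $\min = \max$
yields the constant. Stemless species get stem values of exactly 0.

Reproducibility: one root seed; each species draws from a substream
derived from (seed, species index), so appending species never perturbs
earlier species' draws. Whether rows should additionally be shuffled
across species is left off by default (`shuffle_rows`), and missing
nominal sets propagate as missing values to be handled by QC, since
neither choice is forced by the data format.

## Quality control

- **Balance**: exact poisonous/edible fractions on counts
  (`ratio_p + ratio_e = 1` exactly).
- **Missingness filter**: variables with *strictly more than* 50% missing
  values are removed (a variable at exactly 50% survives — the rule is
  "more than").
- **Imputation**: most-frequent single imputation; ties break to the
  lexicographically smallest mode so results are deterministic.
- **Association matrix**: entry $(i, j)$ is the association of variable
  $i$ given $j$ — Theil's U for nominal pairs,
  $U(x|y) = (H(x) - H(x|y))/H(x)$ with natural-log entropies (U is
  invariant to the base), $|r|$ for metrical pairs, and the correlation
  ratio $\eta$ for mixed pairs. The nominal block may be asymmetric;
  everything lives in $[0, 1]$ for the clipped sequential gray palette
  (1 = black). $\eta$ is this package's choice for mixed pairs: a full
  heat map needs *some* mixed measure and $\eta$ is the standard
  between-group-variance share; it is a design decision, not an inference
  about what the original analysis used, and the same caveat applies to
  the natural-log entropy base. A variable with zero entropy (or zero
  dispersion) is fully predictable and scores 1 by convention.

## Classification and evaluation

Nominal variables are one-hot encoded (indicator columns of a variable sum
to 1 per row), metrical variables pass through, and the class is label
encoded `p` → 1, `e` → 0. `family`/`name` are identifiers, not features.
Training uses an 80/20 split sampled without replacement and stratified
five-fold cross-validation; folds are stratified by class (fold sizes
differ by at most 1) because stratification stabilises the F2 mean on
imbalanced folds. The four classifiers — naive Bayes, logistic regression,
LDA, random forest — are standard library implementations
(`e1071`, `stats::glm`, `MASS::lda`, `randomForest`) with library-default
hyperparameters; the package contributes the harness, not the learners.
Two numerical guards keep degenerate encodings inside the fits:
zero-variance columns are dropped, the Gaussian naive-Bayes per-class
standard deviations are floored at $10^{-3}$, and columns that are
constant within classes (i.e. perfect discriminators, which LDA would
otherwise reject) receive a tiny deterministic per-column wobble
($10^{-3}\sin(ij)$) so they stay in — and dominate — the discriminant.

A mushroom is classified poisonous when its predicted probability is
**at or above** 0.5 — the boundary case goes to the cautious side. Metrics
are accuracy, precision, recall and F2 (the F-beta score at $\beta = 2$,
weighting recall twice as heavily as precision because false negatives —
poisonous labelled edible — are the dangerous error). ROC points are
computed from the probabilities before thresholding, ordered by descending
threshold with ties grouped, and AUC is the trapezoid area over distinct
cut-points; the implementation is cross-checked against an external ROC
library in the tests. Cross-validated metrics are reported as mean and
standard deviation across folds; the dispersion is reported as σ (standard
deviation), the scale on which "no variance" claims are made. CV runs on
the full encoded table by default (the alternative — CV inside the 80%
training split — is available by subsetting before calling `crossval()`).

`direct_mapping()` aligns two data sets variable-by-variable for
cross-corpus comparison: matching names merge side by side; an unmatched
variable is either zero-filled on the other side or renamed into an
existing one, per configuration.

## The fixture generator

`generate_primary()` emits species with codebook-valid sets, 2-decimal
intervals, a controllable poisonous fraction (default 0.55 over 173
species in 23 families, the species-level balance of the study
conditions), controllable per-variable missingness, and optionally a
number of capless/stemless species for exercising the exclusion filter.
`generate_book()` renders the table as prose, one sentence per anchor noun
— which is what makes the full-pipeline round trip
(`generate_book` → `extract_primary` → `apply_curation` reproduces the
table **exactly**) a fair test of the extractor's attribution logic rather
than a fuzzy approximation.

What the generator does *not* emulate, and what passing tests therefore do
not show: real guide prose attaches several attributes to one sentence,
uses vocabulary beyond any fixed lexicon, and correlates nominal
attributes across variables (a convex cap usually comes with a smooth
surface); the generator writes unambiguous single-anchor sentences,
samples sets independently, and never produces contradictory text. Results
on fixtures bound the extractor's behaviour on clean input; they say
nothing about recall on messy prose.

`generate_nonlinear_labels()` supports the separability experiments: an
XOR rule over two nominal indicators is not linearly separable in one-hot
space (LDA and logistic regression sit at chance), while a random forest
recovers it; a linear rule is separable by all four classifiers. In the
packaged XOR fixture the two XOR variables get full `{t, f}` sets — so
they vary *within* species — and the remaining nominal attributes are held
constant across species; otherwise every species-specific nominal pattern
is a spurious feature that the class (which depends only on the XOR pair)
cannot justify, and finite-sample forests waste splits on it. Holding the
background constant isolates exactly the property under test:
non-linear separability.

## Problem sizes and numerical choices

Statistical checks in the tests and acceptance script use sizes chosen so
Monte-Carlo error sits well inside the asserted tolerances: $10^6$ draws
for interval coverage (binomial s.e. ≈ 0.005 percentage points against a
±0.05 tolerance), $10^5$ for correlation recovery (s.e. ≈ 0.002–0.003
against ±0.01) and for the resized-sample mean (s.e. ≈ 0.0005 against
±0.005). Separability fixtures use 8–40 species × 60–250 entries; the
full-size table (173 × 353 = 61,069 rows) is simulated in about a second.
Cholesky factorization rejects matrices with an eigenvalue below
$-10^{-10}$ and reconstructs $LL^\top$ to $10^{-12}$ for the default
model.

## Known limitations

- The extractor is a rule-based system for a specific prose dialect, not
  general NLP; its lexicon must be adapted per book.
- Nominal variables are simulated independently within a species; real
  trait correlations (shape with surface over the organism's age) are not
  modelled.
- One covariance matrix for all species is a simplification; per-species
  covariances would need field observations.
- Set-valued attributes do not distinguish alternative
  (*either grooved or shiny*) from simultaneous (*grooved and shiny*)
  characteristics; uniform sampling treats both as alternatives.
- Binary edibility is a deliberately coarse target; the primary table
  retains `family` and `name` so multinomial tasks remain possible.
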