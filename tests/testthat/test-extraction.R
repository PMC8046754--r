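worked_sentence <- paste(
  "The entire young fruit body is enclosed in a white veil which leaves",
  "fragments (which may wash off) on the shiny red, marginally grooved cap.")

test_that("the worked description sentence extracts the four attributes", {
  hits <- extract_nominals(worked_sentence)
  expect_equal(hits[["cap-surface"]], c("g", "h"))
  expect_equal(hits[["cap-color"]], "e")
  expect_equal(hits[["veil-type"]], "u")
  expect_equal(hits[["veil-color"]], "w")
  # everything else stays missing
  others <- setdiff(names(hits), c("cap-surface", "cap-color", "veil-type", "veil-color"))
  expect_true(all(lengths(hits[others]) == 0))
})

test_that("compound colors split into constituent codes", {
  hits <- extract_nominals("The red-brown cap is smooth.")
  expect_equal(hits[["cap-color"]], c("n", "e"))
  # a hyphenated token that is not two colors stays whole
  hits2 <- extract_nominals("The bell-shaped cap is white.")
  expect_equal(hits2[["cap-shape"]], "b")
})

test_that("empty prose yields all-missing attributes", {
  hits <- extract_nominals("")
  expect_true(all(lengths(hits) == 0))
})

test_that("keywords attach to the nearest anchor in the sentence", {
  hits <- extract_nominals("The yellow gills sit beneath the white cap.")
  expect_equal(hits[["gill-color"]], "y")
  expect_equal(hits[["cap-color"]], "w")
  expect_length(hits[["stem-color"]], 0)
})

test_that("parse_book finds headers case-insensitively and in order", {
  doc <- paste0(
    "<html><body>",
    '<p class="ChapterHeadA">Family-01 — Alpha (Fungus a)</p>',
    '<p class="paraNoIndent">The flat cap is red. Size: cap 2-3 cm across; ',
    "stem 1-2 cm tall and 3-4 mm thick. Habitat: woods. Season: summer. Edible.</p>",
    '<p class="CHAPTERHEADA">Beta</p>',
    '<p class="paranoindent">The convex cap is white. Size: cap 4-5 cm across; ',
    "stem 2-3 cm tall and 5-6 mm thick. Habitat: meadows. Season: autumn. Poisonous.</p>",
    '<p class="chapterheada">Gamma (Fungus g)</p>',
    "</body></html>")
  expect_warning(entries <- parse_book(doc), "no body paragraph")
  expect_equal(entries$name_en, c("Alpha", "Beta"))
  expect_equal(entries$family, c("Family-01", "Family-01"))  # carried forward
  expect_equal(entries$name_la, c("Fungus a", NA))
})

test_that("a body-only document yields an empty entry list", {
  doc <- '<html><body><p class="paraNoIndent">Just prose.</p></body></html>'
  entries <- parse_book(doc)
  expect_equal(nrow(entries), 0)
})

test_that("size parsing handles ranges, stated means and stemless species", {
  r <- parse_size("Size: cap 3-8 cm across; stem 5-10 cm tall and 8-12 mm thick.")
  expect_equal(unname(r[["cap-diameter"]]), c(3, 8))
  expect_equal(unname(r[["stem-height"]]), c(5, 10))
  expect_equal(unname(r[["stem-width"]]), c(8, 12))
  # a single stated mean becomes [(1 - 1/4) mu, (1 + 1/4) mu]
  m <- parse_size("Size: cap about 8 cm across.")
  expect_equal(unname(m[["cap-diameter"]]), c(6, 10))
  expect_null(m[["stem-height"]])
  expect_null(m[["stem-width"]])
})

test_that("edibility parses by its leading word", {
  expect_equal(parse_edibility("Edible and good."), "e")
  expect_equal(parse_edibility("Inedible."), "p")
  expect_equal(parse_edibility("Poisonous, deadly."), "p")
  expect_error(parse_edibility("Tasty."), class = "mushroomsim_extraction_error")
  expect_error(parse_edibility(""), class = "mushroomsim_extraction_error")
})

test_that("exclusion filter removes capless and stemless species with a count", {
  pt <- generate_primary(fixture_config(n_species = 10, n_families = 2,
                                        seed = 21, n_unsupported = 2))
  suppressMessages(kept <- exclude_unsupported(pt))
  expect_equal(nrow(kept), 8)
  expect_equal(attr(kept, "n_excluded"), 2)
  empty <- pt[0, ]
  suppressMessages(none <- exclude_unsupported(empty))
  expect_equal(nrow(none), 0)
})

test_that("extraction round-trips fixture documents exactly", {
  for (seed in c(2, 13)) {
    pt <- small_primary(seed = seed, n_species = 15, n_families = 4,
                        missingness = 0.1)
    got <- extract_primary(generate_book(pt))
    got <- apply_curation(got)
    expect_identical(names(got), names(pt))
    for (v in names(pt)) {
      expect_true(all(purrr::map2_lgl(pt[[v]], got[[v]], identical)),
                  label = sprintf("seed %d, column %s recovered", seed, v))
    }
  }
})

test_that("extraction is deterministic and order-independent across entries", {
  pt <- small_primary(seed = 31, n_species = 8, n_families = 2)
  doc <- generate_book(pt)
  a <- extract_primary(doc)
  b <- extract_primary(doc)
  expect_identical(a, b)
  # reversing within-family blocks preserves per-species results
  rev_pt <- pt[rev(seq_len(nrow(pt))), ]
  attr(rev_pt, "cap_mean") <- rev(attr(pt, "cap_mean"))
  got <- extract_primary(generate_book(rev_pt))
  got <- got[match(pt$name, got$name), ]
  for (v in setdiff(names(pt), "family")) {
    expect_true(all(purrr::map2_lgl(pt[[v]], got[[v]], identical)),
                label = sprintf("column %s order-independent", v))
  }
})

test_that("relative increase over the 1987 data reproduces the headline shares", {
  expect_equal(round(100 * relative_increase(173, 23)), 87)
  expect_equal(round(100 * relative_increase(23, 2)), 91)
})
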