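#' Keyword lexicon for attribute extraction
#'
#' The extractor is anchored on the section nouns cap, gills, veil, stem,
#' ring and spore print: a keyword found in a sentence is attributed to the
#' nearest anchor noun of that sentence, and the anchor decides which
#' variable the keyword fills (a color next to "cap" is a cap-color, next
#' to "gills" a gill-color). Variables that prose expresses as phrases
#' rather than section-scoped adjectives (veil-type, does-bruise-or-bleed,
#' has-ring) are matched by regular-expression triggers over the whole
#' description. The lexicon is a versioned package config seeded from the
#' codebook's category names plus a synonym table, and can be replaced to
#' adapt the extractor to another book's vocabulary.
#'
#' @param file Optional path to an alternative lexicon YAML.
#' @return A list with elements `anchors`, `slots`, `keyword_classes`,
#'   `habitat_keywords`, `season_keywords` and `triggers`.
#' @export
mushroom_lexicon <- function(file = NULL) {
  file <- file %||% ms_extdata("lexicon.yaml")
  lex <- yaml::read_yaml(file)
  lex$habitat_keywords <- unlist(lex$habitat_keywords)
  lex$season_keywords <- unlist(lex$season_keywords)
  lex$keyword_classes <- map(lex$keyword_classes, unlist)
  lex
}

#' Parse a field-guide document into book entries
#'
#' A book entry has six structured parts: the species name (English, with
#' the Latin name in parentheses, and the family name only on the first
#' species of a family), the free-prose description, the size attributes,
#' the habitat, the season, and the edibility statement. Species headers
#' are `<p>` tags whose `class` attribute is `"chapterHeadA"`
#' (case-insensitive); the body paragraphs that follow carry
#' `"paraNoIndent"`. The family is carried forward from the last
#' family-bearing header; a header with no following body paragraph is
#' skipped with a warning.
#'
#' @param document HTML text, a file path, or an `xml2` document.
#' @return A tibble with one row per book entry: `name_en`, `name_la`,
#'   `family`, `description`, `size_text`, `habitat_text`, `season_text`,
#'   `edibility_text`.
#' @export
parse_book <- function(document) {
  doc <- if (inherits(document, "xml_document")) {
    document
  } else if (length(document) == 1L && !grepl("<", document, fixed = TRUE) &&
             file.exists(document)) {
    xml2::read_html(document)
  } else {
    xml2::read_html(paste(document, collapse = "\n"))
  }
  nodes <- xml2::xml_find_all(doc, "//p")
  classes <- tolower(map_chr(nodes, function(n) xml2::xml_attr(n, "class") %||% ""))
  texts <- map_chr(nodes, xml2::xml_text)
  entries <- list()
  current_family <- NA_character_
  i <- 1L
  while (i <= length(nodes)) {
    if (classes[i] != "chapterheada") {
      i <- i + 1L
      next
    }
    header <- parse_entry_header(texts[i])
    if (!is.na(header$family)) current_family <- header$family
    # collect the consecutive body paragraphs that follow
    j <- i + 1L
    body <- character(0)
    while (j <= length(nodes) && classes[j] == "paranoindent") {
      body <- c(body, texts[j])
      j <- j + 1L
    }
    if (length(body) == 0) {
      warn(sprintf("book entry '%s' has no body paragraph; skipped", header$name_en))
      i <- j
      next
    }
    parts <- split_entry_parts(paste(body, collapse = " "))
    entries[[length(entries) + 1L]] <- tibble(
      name_en = header$name_en, name_la = header$name_la,
      family = current_family, !!!parts
    )
    i <- j
  }
  if (length(entries) == 0) {
    return(tibble(name_en = character(0), name_la = character(0),
                  family = character(0), description = character(0),
                  size_text = character(0), habitat_text = character(0),
                  season_text = character(0), edibility_text = character(0)))
  }
  bind_rows(entries)
}

parse_entry_header <- function(text) {
  text <- stringr::str_trim(text)
  family <- NA_character_
  if (stringr::str_detect(text, stringr::fixed("—"))) {
    parts <- stringr::str_split_fixed(text, stringr::fixed("—"), 2)
    family <- stringr::str_trim(parts[1, 1])
    text <- stringr::str_trim(parts[1, 2])
  }
  m <- stringr::str_match(text, "^(.*?)\\s*(?:\\(([^)]*)\\))?$")
  list(name_en = stringr::str_trim(m[1, 2]),
       name_la = if (is.na(m[1, 3]) || !nzchar(m[1, 3])) NA_character_ else m[1, 3],
       family = family)
}

split_sentences <- function(text) {
  s <- stringr::str_trim(stringr::str_split_1(text, "(?<=\\.)\\s+"))
  s[nzchar(s)]
}

split_entry_parts <- function(body) {
  sentences <- split_sentences(body)
  is_size <- stringr::str_detect(sentences, stringr::regex("^Size\\b", ignore_case = TRUE))
  is_habitat <- stringr::str_detect(sentences, stringr::regex("\\bHabitat\\b", ignore_case = TRUE))
  is_season <- stringr::str_detect(sentences, stringr::regex("\\bSeason\\b", ignore_case = TRUE))
  is_edibility <- stringr::str_detect(
    sentences, stringr::regex("^(Edible|Inedible|Poisonous)\\b", ignore_case = TRUE))
  pick <- function(mask) {
    if (any(mask)) paste(sentences[mask], collapse = " ") else ""
  }
  rest <- !(is_size | is_habitat | is_season | is_edibility)
  list(description = pick(rest), size_text = pick(is_size),
       habitat_text = pick(is_habitat), season_text = pick(is_season),
       edibility_text = pick(is_edibility))
}

#' Extract nominal attribute sets from description prose
#'
#' Applies the lexicon to free prose: every keyword token is attributed to
#' the nearest anchor noun within its sentence (ties go to the following
#' anchor, since English descriptors precede their noun), and the anchor's
#' slot table maps the keyword class to a schema variable. Hyphenated color
#' compounds like "red-brown" contribute both constituent codes. Trigger
#' variables (veil-type, does-bruise-or-bleed, has-ring) are matched over
#' the whole text, first matching pattern wins. Variables with no hit are
#' returned as missing (`character(0)`).
#'
#' @param description Prose text.
#' @param lexicon A lexicon from [mushroom_lexicon()].
#' @param schema A schema tibble.
#' @return A named list: nominal variable -> character vector of codes.
#' @examples
#' lex <- mushroom_lexicon()
#' hits <- extract_nominals(
#'   "The entire young fruit body is enclosed in a white veil which leaves
#'    fragments (which may wash off) on the shiny red, marginally grooved cap.",
#'   lex)
#' hits[["cap-surface"]]  # "g" "h"
#' @export
extract_nominals <- function(description, lexicon = mushroom_lexicon(),
                             schema = mushroom_schema("primary")) {
  vars <- setdiff(attribute_names(schema, "nominal"), c("habitat", "season"))
  out <- setNames(rep(list(character(0)), length(vars)), vars)
  text <- tolower(description %||% "")
  if (!nzchar(stringr::str_trim(text))) return(out)

  for (v in names(lexicon$triggers)) {
    for (trig in lexicon$triggers[[v]]) {
      if (stringr::str_detect(text, stringr::regex(trig$pattern))) {
        out[[v]] <- trig$code
        break
      }
    }
  }

  for (sentence in split_sentences(text)) {
    anchor_pos <- list()
    for (a in names(lexicon$anchors)) {
      loc <- stringr::str_locate_all(sentence, stringr::regex(lexicon$anchors[[a]]))[[1]]
      if (nrow(loc) > 0) anchor_pos[[a]] <- loc[, "start"]
    }
    if (length(anchor_pos) == 0) next
    anchors <- tibble(
      anchor = rep(names(anchor_pos), lengths(anchor_pos)),
      pos = unlist(anchor_pos)
    )
    token_loc <- stringr::str_locate_all(sentence, "[a-z]+(?:-[a-z]+)*")[[1]]
    for (k in seq_len(nrow(token_loc))) {
      token <- stringr::str_sub(sentence, token_loc[k, 1], token_loc[k, 2])
      hits <- token_hits(token, lexicon)
      if (nrow(hits) == 0) next
      d <- abs(anchors$pos - token_loc[k, 1])
      follows <- anchors$pos > token_loc[k, 1]
      best <- order(d, !follows)[1]      # nearest anchor, ties to the following one
      slots <- lexicon$slots[[anchors$anchor[best]]]
      for (h in seq_len(nrow(hits))) {
        target <- slots[[hits$class[h]]]
        if (!is.null(target) && target %in% names(out)) {
          out[[target]] <- c(out[[target]], hits$code[h])
        }
      }
    }
  }

  for (v in names(out)) {
    valid <- schema_codes(schema, v)
    out[[v]] <- valid[valid %in% out[[v]]]
  }
  out
}

token_hits <- function(token, lexicon) {
  colors <- lexicon$keyword_classes$color
  # compound colors split on "-" only when both halves are codebook colors
  if (stringr::str_detect(token, "-")) {
    halves <- stringr::str_split_1(token, "-")
    if (length(halves) == 2 && all(halves %in% names(colors))) {
      return(tibble(class = "color", code = unname(colors[halves])))
    }
  }
  hits <- list()
  for (cls in names(lexicon$keyword_classes)) {
    kw <- lexicon$keyword_classes[[cls]]
    if (token %in% names(kw)) {
      hits[[length(hits) + 1L]] <- tibble(class = cls, code = unname(kw[[token]]))
    }
  }
  if (length(hits) == 0) tibble(class = character(0), code = character(0))
  else bind_rows(hits)
}

#' Parse the size attributes of a book entry
#'
#' Size attributes are listed in appearing order: cap diameter (cm), stem
#' height (cm), stem width (mm). A stated min-max pair becomes the interval
#' directly; a single stated mean \eqn{\mu} becomes the interval
#' \eqn{[(1 - 1/4)\mu, (1 + 1/4)\mu]}. A stemless entry (no stem
#' measurements) leaves the stem ranges absent.
#'
#' @param size_text The size sentence of a book entry.
#' @return A named list of `c(min, max)` ranges (or `NULL`) for
#'   `cap-diameter`, `stem-height` and `stem-width`.
#' @examples
#' parse_size("Size: cap about 8 cm across.")[["cap-diameter"]]  # 6 10
#' @export
parse_size <- function(size_text) {
  out <- list(`cap-diameter` = NULL, `stem-height` = NULL, `stem-width` = NULL)
  text <- tolower(size_text %||% "")
  if (!nzchar(stringr::str_trim(text))) return(out)
  pat <- "([0-9]+(?:\\.[0-9]+)?)(?:\\s*[-–:]\\s*([0-9]+(?:\\.[0-9]+)?))?\\s*(cm|mm)"
  m <- stringr::str_match_all(text, pat)[[1]]
  loc <- stringr::str_locate_all(text, pat)[[1]]
  if (nrow(m) == 0) {
    warn(sprintf("no parseable measurements in size text '%s'", size_text))
    return(out)
  }
  to_range <- function(k) {
    lo <- suppressWarnings(as.numeric(m[k, 2]))
    hi <- suppressWarnings(as.numeric(m[k, 3]))
    rng <- if (is.na(hi)) {
      mu <- lo                                  # single stated mean
      c(min = (1 - 1 / 4) * mu, max = (1 + 1 / 4) * mu)
    } else {
      c(min = lo, max = hi)
    }
    if (anyNA(rng) || rng[1] > rng[2]) {
      warn(sprintf("unparseable measurement '%s' in size text", m[k, 1]))
      return(NULL)
    }
    rng
  }
  cap_at <- stringr::str_locate(text, "\\bcaps?\\b")[1, 1]
  stem_at <- stringr::str_locate(text, "\\bstems?\\b")[1, 1]
  if (!is.na(cap_at) || !is.na(stem_at)) {
    # attribute measurements to the cap/stem segment they follow
    cap_ks <- which(!is.na(cap_at) & loc[, 1] > cap_at &
                      (is.na(stem_at) | loc[, 1] < stem_at | stem_at < cap_at))
    stem_ks <- which(!is.na(stem_at) & loc[, 1] > stem_at)
    cap_ks <- setdiff(cap_ks, stem_ks)
    if (length(cap_ks) > 0) out[["cap-diameter"]] <- to_range(cap_ks[1])
    if (length(stem_ks) > 0) out[["stem-height"]] <- to_range(stem_ks[1])
    if (length(stem_ks) > 1) out[["stem-width"]] <- to_range(stem_ks[2])
  } else {
    # fall back to appearing order: cap diameter, stem height, stem width
    for (k in seq_len(min(nrow(m), 3L))) out[[k]] <- to_range(k)
  }
  out
}

#' Parse the edibility statement
#'
#' The edibility part always starts with "edible", "inedible" or
#' "poisonous"; inedible species (and those of unknown edibility) fall
#' under the poisonous class.
#'
#' @param edibility_text The edibility sentence.
#' @return `"e"` or `"p"`.
#' @export
parse_edibility <- function(edibility_text) {
  first <- tolower(stringr::str_match(
    stringr::str_trim(edibility_text %||% ""), "^([A-Za-z]+)")[1, 2])
  if (is.na(first)) {
    abort("empty edibility text", class = "mushroomsim_extraction_error")
  }
  if (first == "edible") return("e")
  if (first %in% c("inedible", "poisonous")) return("p")
  abort(sprintf("unrecognized edibility statement starting with '%s'", first),
        class = "mushroomsim_extraction_error")
}

match_keywords_after <- function(text, marker, keywords) {
  lower <- tolower(text %||% "")
  if (!nzchar(stringr::str_trim(lower))) return(character(0))
  loc <- stringr::str_locate(lower, stringr::regex(marker))
  sub <- if (is.na(loc[1, 1])) lower else stringr::str_sub(lower, loc[1, 2] + 1L)
  tokens <- stringr::str_extract_all(sub, "[a-z]+")[[1]]
  codes <- unname(keywords[tokens[tokens %in% names(keywords)]])
  unique(codes)
}

#' Assemble a species record from a parsed book entry
#'
#' Combines the part parsers: nominal attributes from the description,
#' metrical ranges from the size sentence, habitat and season by matching
#' the possible category names in the sub-string following the section
#' marker, and the edibility class.
#'
#' @param entry One row of [parse_book()] output.
#' @param lexicon A lexicon from [mushroom_lexicon()].
#' @param schema A schema tibble.
#' @return A one-row primary tibble.
#' @export
assemble_record <- function(entry, lexicon = mushroom_lexicon(),
                            schema = mushroom_schema("primary")) {
  nominals <- extract_nominals(entry$description, lexicon, schema)
  sizes <- parse_size(entry$size_text)
  habitat <- match_keywords_after(entry$habitat_text, "habitat", lexicon$habitat_keywords)
  season <- match_keywords_after(entry$season_text, "season", lexicon$season_keywords)
  cls <- parse_edibility(entry$edibility_text)
  row <- tibble(family = entry$family, name = entry$name_en, class = cls)
  for (v in attribute_names(schema)) {
    value <- if (v %in% names(sizes)) {
      sizes[[v]]
    } else if (v == "habitat") {
      valid <- schema_codes(schema, v)
      valid[valid %in% habitat]
    } else if (v == "season") {
      valid <- schema_codes(schema, v)
      valid[valid %in% season]
    } else {
      nominals[[v]]
    }
    row[[v]] <- list(value)
  }
  row
}

#' Extract a raw primary table from a field-guide document
#'
#' Convenience wrapper: [parse_book()] then [assemble_record()] per entry.
#'
#' @inheritParams parse_book
#' @inheritParams assemble_record
#' @return A primary tibble, one row per book entry.
#' @export
extract_primary <- function(document, lexicon = mushroom_lexicon(),
                            schema = mushroom_schema("primary")) {
  entries <- parse_book(document)
  if (nrow(entries) == 0) {
    abort("no book entries found in document", class = "mushroomsim_extraction_error")
  }
  bind_rows(map(seq_len(nrow(entries)),
                function(i) assemble_record(entries[i, ], lexicon, schema)))
}

#' Exclude species the secondary-data structure cannot represent
#'
#' The 1987-style structure only applies to mushrooms having a cap and a
#' stem, so species without a cap (no cap-diameter range) and, by default,
#' stemless species are excluded. The number of removals is attached as the
#' `n_excluded` attribute and reported as a message.
#'
#' @param table A primary tibble.
#' @param require_stem Also exclude stemless species (default `TRUE`).
#' @return The filtered table with attribute `n_excluded`.
#' @export
exclude_unsupported <- function(table, require_stem = TRUE) {
  if (nrow(table) == 0) {
    attr(table, "n_excluded") <- 0L
    return(table)
  }
  capless <- map_lgl(table[["cap-diameter"]], is.null)
  stemless <- map_lgl(table[["stem-height"]], is.null) &
    map_lgl(table[["stem-width"]], is.null)
  drop <- capless | (require_stem & stemless)
  out <- table[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  message(sprintf("excluded %d of %d species (no cap%s)", sum(drop), nrow(table),
                  if (require_stem) " or no stem" else ""))
  out
}

#' Relative species/family increase over a reference data set
#'
#' The share of the new data not covered by the reference:
#' `(new - old) / new`. With 173 species vs the reference's 23 this is
#' 87%, and 91% for 23 vs 2 families.
#'
#' @param new,old Counts in the new and reference data.
#' @return A fraction in `[0, 1]`.
#' @export
relative_increase <- function(new, old) {
  stopifnot(new > 0, old >= 0)
  (new - old) / new
}
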