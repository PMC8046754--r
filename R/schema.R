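#' Variable schema and codebook
#'
#' The schema describes every variable of the mushroom tables: its kind
#' (`nominal` or `metrical`), its role (`attribute`, `class-binary` or
#' `class-multinomial`), its measurement unit for metrical variables
#' (centimeters, except stem-width in millimeters) and, for nominal
#' variables, the codebook mapping full category names to single-letter
#' codes (e.g. convex: `x`). The canonical secondary schema holds the binary
#' edibility class (`e` = edible, `p` = poisonous, where poisonous also
#' covers inedible and unknown edibility) plus 17 nominal and 3 metrical
#' attributes; the primary schema prepends the multinomial classes `family`
#' and `name`.
#'
#' @param which `"secondary"` (class + 20 attributes) or `"primary"`
#'   (adds `family` and `name`).
#' @param file Optional path to an alternative codebook YAML; defaults to
#'   the codebook shipped with the package.
#' @return A tibble with one row per variable: `name`, `kind`, `role`,
#'   `unit` and a `codebook` list-column of named character vectors
#'   (full category name -> code).
#' @examples
#' sch <- mushroom_schema()
#' nrow(sch)                       # 21 columns: class + 20 attributes
#' sch$codebook[[which(sch$name == "season")]]
#' @export
mushroom_schema <- function(which = c("secondary", "primary"), file = NULL) {
  which <- match.arg(which)
  file <- file %||% ms_extdata("codebook.yaml")
  key <- paste0(which, "::", normalizePath(file))
  if (!is.null(the_schema_cache[[key]])) {
    return(the_schema_cache[[key]])
  }
  raw <- yaml::read_yaml(file)
  vars <- raw$variables
  sch <- tibble(
    name = map_chr(vars, "name"),
    kind = map_chr(vars, "kind"),
    role = map_chr(vars, "role"),
    unit = map_chr(vars, function(v) v$unit %||% NA_character_),
    codebook = map(vars, function(v) {
      cb <- unlist(v$codebook %||% list())
      if (is.null(cb)) cb <- character(0)
      cb
    })
  )
  if (which == "secondary") {
    sch <- filter(sch, .data$role != "class-multinomial")
  }
  validate_schema(sch)
  the_schema_cache[[key]] <- sch
  sch
}

validate_schema <- function(schema) {
  for (i in seq_len(nrow(schema))) {
    cb <- schema$codebook[[i]]
    nm <- schema$name[i]
    if (schema$kind[i] == "metrical") {
      if (length(cb) > 0) abort(sprintf("metrical variable '%s' must not carry a codebook", nm))
      if (is.na(schema$unit[i])) abort(sprintf("metrical variable '%s' must carry a unit", nm))
    } else if (length(cb) > 0) {
      if (any(nchar(cb) != 1L)) abort(sprintf("codes of '%s' must be single characters", nm))
      if (anyDuplicated(cb)) abort(sprintf("duplicated codes in codebook of '%s'", nm))
      if (anyDuplicated(names(cb))) abort(sprintf("duplicated category names in codebook of '%s'", nm))
    }
  }
  metr <- schema$name[schema$kind == "metrical"]
  expected <- c("cap-diameter", "stem-height", "stem-width")
  if (!setequal(metr, expected)) {
    abort("metrical variables must be exactly cap-diameter, stem-height and stem-width")
  }
  if (schema$unit[schema$name == "stem-width"] != "mm") {
    abort("stem-width must be reported in millimeters")
  }
  invisible(schema)
}

schema_row <- function(schema, variable) {
  i <- match(variable, schema$name)
  if (is.na(i)) abort(sprintf("variable '%s' is not in the schema", variable))
  schema[i, ]
}

#' @rdname mushroom_schema
#' @param schema A schema tibble.
#' @param variable A variable name.
#' @return `schema_codes()`: the character vector of valid codes, in
#'   codebook order.
#' @export
schema_codes <- function(schema, variable) {
  unname(schema_row(schema, variable)$codebook[[1]])
}

attribute_names <- function(schema, kind = NULL) {
  out <- filter(schema, .data$role == "attribute")
  if (!is.null(kind)) out <- filter(out, .data$kind == !!kind)
  out$name
}

#' The 1987-format source schema
#'
#' The attribute list of the classic 1987 hypothetical-mushroom data
#' (22 nominal attributes plus the binary class), used as the source side
#' of the curation rules. Codebooks for attributes shared with the
#' canonical schema are reused; 1987-only attributes get their historical
#' codebooks.
#'
#' @return A schema tibble (see [mushroom_schema()]).
#' @export
schema_1987 <- function() {
  can <- mushroom_schema("secondary")
  cb <- function(v) schema_row(can, v)$codebook[[1]]
  specs <- list(
    list("class", cb("class")),
    list("cap-shape", c(bell = "b", conical = "c", convex = "x", flat = "f",
                        knobbed = "k", sunken = "s")),
    list("cap-surface", c(fibrous = "f", grooves = "g", scaly = "y", smooth = "s")),
    list("cap-color", cb("cap-color")),
    list("bruises?", c(yes = "t", no = "f")),
    list("odor", c(almond = "a", anise = "l", creosote = "c", fishy = "y",
                   foul = "f", musty = "m", none = "n", pungent = "p", spicy = "s")),
    list("gill-attachment", c(attached = "a", descending = "d", free = "f", notched = "n")),
    list("gill-spacing", c(close = "c", crowded = "w", distant = "d")),
    list("gill-size", c(broad = "b", narrow = "n")),
    list("gill-color", cb("gill-color")),
    list("stalk-shape", c(enlarging = "e", tapering = "t")),
    list("stalk-root", cb("stem-root")),
    list("stalk-surface-above-ring", c(fibrous = "f", scaly = "y", silky = "k", smooth = "s")),
    list("stalk-surface-below-ring", c(fibrous = "f", scaly = "y", silky = "k", smooth = "s")),
    list("stalk-color-above-ring", cb("stem-color")),
    list("stalk-color-below-ring", cb("stem-color")),
    list("veil-type", cb("veil-type")),
    list("veil-color", cb("veil-color")),
    list("ring-number", c(none = "n", one = "o", two = "t")),
    list("ring-type", cb("ring-type")),
    list("spore-print-color", cb("spore-print-color")),
    list("population", c(abundant = "a", clustered = "c", numerous = "n",
                         scattered = "s", several = "v", solitary = "y")),
    list("habitat", cb("habitat"))
  )
  tibble(
    name = map_chr(specs, 1),
    kind = "nominal",
    role = c("class-binary", rep("attribute", length(specs) - 1L)),
    unit = NA_character_,
    codebook = map(specs, 2)
  )
}

#' Parse and format set and range literals
#'
#' Primary-data cells hold either a set of single-letter nominal codes
#' written `[x, f]` (a bare letter is read as a singleton set) or a
#' quantitative interval written `[min:max]`. Empty cells and `[]` denote
#' missing values.
#'
#' @param text A single literal string.
#' @param variable,schema When supplied, every parsed code is validated
#'   against the variable's codebook and codes are returned in codebook
#'   order.
#' @return `parse_set_literal()`: a character vector of codes
#'   (`character(0)` = missing). `parse_range_literal()`: a numeric
#'   `c(min, max)` or `NULL` for missing.
#' @examples
#' parse_set_literal("[x, f]")
#' parse_range_literal("[10:20]")
#' @export
parse_set_literal <- function(text, variable = NULL, schema = NULL) {
  stopifnot(length(text) == 1L)
  text <- stringr::str_trim(text %||% "")
  if (text == "" || text == "[]") return(character(0))
  if (stringr::str_detect(text, "^\\[.*\\]$")) {
    inner <- stringr::str_sub(text, 2L, -2L)
    codes <- stringr::str_trim(stringr::str_split_1(inner, ","))
    codes <- codes[nzchar(codes)]
  } else {
    codes <- text
  }
  codes <- unique(codes)
  if (!is.null(schema) && !is.null(variable)) {
    valid <- schema_codes(schema, variable)
    bad <- setdiff(codes, valid)
    if (length(bad) > 0) {
      abort(sprintf("unknown code '%s' for variable '%s'", bad[1], variable),
            class = "mushroomsim_validation_error")
    }
    codes <- valid[valid %in% codes]
  }
  codes
}

#' @rdname parse_set_literal
#' @export
parse_range_literal <- function(text) {
  stopifnot(length(text) == 1L)
  text <- stringr::str_trim(text %||% "")
  if (text == "" || text == "[]") return(NULL)
  m <- stringr::str_match(text, "^\\[\\s*([^:\\]]+)\\s*:\\s*([^:\\]]+)\\s*\\]$")
  if (is.na(m[1, 1])) {
    abort(sprintf("cannot parse range literal '%s'", text),
          class = "mushroomsim_parse_error")
  }
  bounds <- suppressWarnings(as.numeric(m[1, 2:3]))
  if (anyNA(bounds)) {
    abort(sprintf("non-numeric bounds in range literal '%s'", text),
          class = "mushroomsim_parse_error")
  }
  if (bounds[1] > bounds[2]) {
    abort(sprintf("inverted range literal '%s': min > max", text),
          class = "mushroomsim_validation_error")
  }
  c(min = bounds[1], max = bounds[2])
}

fmt_num <- function(x) {
  # 2-decimal measurement precision, trailing zeros trimmed ("10", "1.5")
  out <- sprintf("%.2f", round(x, 2))
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

#' @rdname parse_set_literal
#' @param codes A character vector of codes.
#' @export
format_set_literal <- function(codes) {
  if (length(codes) == 0) return("")
  paste0("[", paste(codes, collapse = ", "), "]")
}

#' @rdname parse_set_literal
#' @param range A numeric `c(min, max)` or `NULL`.
#' @export
format_range_literal <- function(range) {
  if (is.null(range) || length(range) == 0) return("")
  paste0("[", fmt_num(range[1]), ":", fmt_num(range[2]), "]")
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (stringr::str_count(header, ";") >= stringr::str_count(header, ",")) ";" else ","
}

read_delim_chr <- function(path) {
  delim <- detect_delim(path)
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), trim_ws = TRUE, progress = FALSE,
                    show_col_types = FALSE)
}

#' Read and write the primary-data CSV dialect
#'
#' The primary data is a species-level table: one row per mushroom species
#' with three class columns (`family`, `name`, `class`) followed by
#' set-valued nominal attributes (`[x, f]`) and interval-valued metrical
#' attributes (`[10:20]`). Because set literals contain commas the writer
#' defaults to a `;` field delimiter; the reader auto-detects `,` vs `;`
#' from the header line. Missing values are empty cells. In memory, nominal
#' attributes are list-columns of character code vectors and metrical
#' attributes are list-columns of `c(min, max)` pairs.
#'
#' @param path File path.
#' @param schema The schema the file must conform to.
#' @return `read_primary_csv()`: a primary tibble.
#' @export
read_primary_csv <- function(path, schema = mushroom_schema("primary")) {
  raw <- read_delim_chr(path)
  class_cols <- schema$name[schema$role != "attribute"]
  missing_classes <- setdiff(class_cols, names(raw))
  if (length(missing_classes) > 0) {
    abort(sprintf("missing class column(s): %s", paste(missing_classes, collapse = ", ")),
          class = "mushroomsim_schema_error")
  }
  unknown <- setdiff(names(raw), schema$name)
  if (length(unknown) > 0) {
    abort(sprintf("column(s) not in schema: %s", paste(unknown, collapse = ", ")),
          class = "mushroomsim_schema_error")
  }
  out <- raw
  for (v in names(raw)) {
    row <- schema_row(schema, v)
    if (row$role != "attribute") next
    if (row$kind == "nominal") {
      out[[v]] <- map(raw[[v]], parse_set_literal, variable = v, schema = schema)
    } else {
      out[[v]] <- map(raw[[v]], parse_range_literal)
    }
  }
  out
}

#' @rdname read_primary_csv
#' @param table A primary tibble.
#' @param delim Field delimiter used on write.
#' @return `write_primary_csv()`: the input `table`, invisibly.
#' @export
write_primary_csv <- function(table, path, delim = ";",
                              schema = mushroom_schema("primary")) {
  out <- table
  for (v in names(table)) {
    row <- schema_row(schema, v)
    if (row$role != "attribute") {
      out[[v]] <- dplyr::coalesce(as.character(table[[v]]), "")
      next
    }
    if (row$kind == "nominal") {
      out[[v]] <- map_chr(table[[v]], format_set_literal)
    } else {
      out[[v]] <- map_chr(table[[v]], format_range_literal)
    }
  }
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(table)
}

#' Read and write the secondary-data CSV dialect
#'
#' Secondary (simulated) data holds one hypothetical mushroom per row with
#' a single code per nominal variable and a single value per metrical
#' variable; set or interval literals are a format error here. Missing
#' values are empty cells (`NA` in memory); metrical values are written at
#' 2-decimal precision.
#'
#' @inheritParams read_primary_csv
#' @return `read_secondary_csv()`: a secondary tibble.
#' @export
read_secondary_csv <- function(path, schema = mushroom_schema("secondary")) {
  raw <- read_delim_chr(path)
  if (!"class" %in% names(raw)) {
    abort("missing class column 'class'", class = "mushroomsim_schema_error")
  }
  out <- raw
  for (v in names(raw)) {
    if (!v %in% schema$name) {
      if (v %in% c("family", "name")) next
      abort(sprintf("column '%s' not in schema", v), class = "mushroomsim_schema_error")
    }
    row <- schema_row(schema, v)
    bracketed <- stringr::str_detect(raw[[v]], "^\\[.*\\]$")
    if (any(bracketed)) {
      abort(sprintf("set/interval literal '%s' found in secondary file column '%s'",
                    raw[[v]][which(bracketed)[1]], v),
            class = "mushroomsim_format_error")
    }
    if (row$kind == "metrical") {
      out[[v]] <- suppressWarnings(as.numeric(dplyr::na_if(raw[[v]], "")))
    } else {
      vals <- dplyr::na_if(raw[[v]], "")
      if (row$role == "attribute" || row$role == "class-binary") {
        valid <- schema_codes(schema, v)
        bad <- setdiff(vals[!is.na(vals)], valid)
        if (length(bad) > 0) {
          abort(sprintf("unknown code '%s' for variable '%s'", bad[1], v),
                class = "mushroomsim_validation_error")
        }
      }
      out[[v]] <- vals
    }
  }
  out
}

#' @rdname read_secondary_csv
#' @param table A secondary tibble.
#' @param delim Field delimiter used on write.
#' @export
write_secondary_csv <- function(table, path, delim = ";",
                                schema = mushroom_schema("secondary")) {
  out <- table
  for (v in names(table)) {
    if (v %in% schema$name && schema_row(schema, v)$kind == "metrical") {
      out[[v]] <- ifelse(is.na(table[[v]]), "", sprintf("%.2f", table[[v]]))
    } else {
      out[[v]] <- dplyr::coalesce(as.character(table[[v]]), "")
    }
  }
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(table)
}
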