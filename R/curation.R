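#' Curation rule set
#'
#' Rules are data, not code, so alternative source books can supply their
#' own. The packaged rule set maps the 1987 attribute list onto the
#' canonical 20-attribute schema: `stalk` becomes `stem` everywhere,
#' `bruises?` is amended to `does-bruise-or-bleed`, `odor`, `gill-size`,
#' `stem-shape` and `population` are dropped (the prose text carries too
#' little information for them), the above/below-ring surface and color
#' pairs are merged by set union, `ring-number` is binarized into
#' `has-ring`, and `season` plus the three metrical size attributes are
#' added.
#'
#' @param file Optional path to an alternative rules YAML.
#' @return A list with elements `source_variables`, `rename_patterns`,
#'   `renames`, `drops`, `merges`, `binarize`, `additions`.
#' @export
curation_rules <- function(file = NULL) {
  file <- file %||% ms_extdata("curation_rules.yaml")
  yaml::read_yaml(file)
}

#' Apply curation rules to a raw primary table
#'
#' Applies pattern renames, exact renames, drops, set-union merges,
#' binarization and column additions, in that order. Every step skips when
#' it has already been applied, so curation is idempotent; a rename rule
#' whose old and new names are both absent is a configuration error. If the
#' table lacks `family`/`name` they are added as (empty) multinomial class
#' columns. Edibility is never altered.
#'
#' @param raw_table A primary tibble in the source schema.
#' @param rules A rule set from [curation_rules()].
#' @param schema The destination schema.
#' @return A primary tibble in the canonical schema column order.
#' @export
apply_curation <- function(raw_table, rules = curation_rules(),
                           schema = mushroom_schema("primary")) {
  tb <- raw_table

  for (pr in rules$rename_patterns %||% list()) {
    names(tb) <- gsub(pr$pattern, pr$replacement, names(tb), fixed = TRUE)
  }

  for (old in names(rules$renames %||% list())) {
    new <- rules$renames[[old]]
    if (old %in% names(tb)) {
      names(tb)[names(tb) == old] <- new
    } else if (!new %in% names(tb)) {
      abort(sprintf("rename rule '%s' -> '%s': neither variable exists", old, new),
            class = "mushroomsim_config_error")
    }
  }

  tb <- tb[, setdiff(names(tb), rules$drops %||% character(0)), drop = FALSE]

  for (mg in rules$merges %||% list()) {
    present <- intersect(mg$sources, names(tb))
    if (length(present) == 0) {
      if (!mg$target %in% names(tb)) {
        abort(sprintf("merge rule for '%s': no source variable exists", mg$target),
              class = "mushroomsim_config_error")
      }
      next
    }
    target_codes <- if (mg$target %in% schema$name) schema_codes(schema, mg$target) else character(0)
    merged <- map(seq_len(nrow(tb)), function(i) {
      codes <- unique(unlist(map(present, function(v) tb[[v]][[i]])))
      c(target_codes[target_codes %in% codes], setdiff(codes, target_codes))
    })
    tb <- tb[, setdiff(names(tb), present), drop = FALSE]
    tb[[mg$target]] <- merged
  }

  for (bz in rules$binarize %||% list()) {
    if (!bz$source %in% names(tb)) {
      if (!bz$target %in% names(tb)) {
        abort(sprintf("binarize rule '%s' -> '%s': neither variable exists",
                      bz$source, bz$target),
              class = "mushroomsim_config_error")
      }
      next
    }
    counts <- unlist(bz$counts)
    tb[[bz$target]] <- map(tb[[bz$source]], function(codes) {
      if (length(codes) == 0) return(character(0))
      n_rings <- counts[codes]
      unique(c(if (any(n_rings > 0)) "t", if (any(n_rings == 0)) "f"))
    })
    tb <- tb[, setdiff(names(tb), bz$source), drop = FALSE]
  }

  for (v in rules$additions %||% character(0)) {
    if (v %in% names(tb)) next
    kind <- schema_row(schema, v)$kind
    tb[[v]] <- if (kind == "nominal") rep(list(character(0)), nrow(tb))
               else rep(list(NULL), nrow(tb))
  }

  for (v in c("name", "family")) {
    if (!v %in% names(tb)) tb <- bind_cols(tibble(!!v := NA_character_), tb)
  }

  ordering <- intersect(schema$name, names(tb))
  tb[, c(ordering, setdiff(names(tb), ordering)), drop = FALSE]
}

#' Apply curation rules to a list of variable names
#'
#' The schema-level counterpart of [apply_curation()]: useful for checking
#' that the rules turn the 22-attribute 1987 list into the canonical
#' 17 nominal + 3 metrical attributes.
#'
#' @param variables Character vector of source attribute names (defaults to
#'   the rule set's `source_variables`).
#' @param rules A rule set from [curation_rules()].
#' @return The curated character vector of variable names.
#' @export
curate_variable_names <- function(variables = NULL, rules = curation_rules()) {
  vars <- variables %||% rules$source_variables
  for (pr in rules$rename_patterns %||% list()) {
    vars <- gsub(pr$pattern, pr$replacement, vars, fixed = TRUE)
  }
  for (old in names(rules$renames %||% list())) {
    vars[vars == old] <- rules$renames[[old]]
  }
  vars <- setdiff(vars, rules$drops %||% character(0))
  for (mg in rules$merges %||% list()) {
    if (any(vars %in% mg$sources)) {
      vars <- setdiff(vars, mg$sources)
      if (!mg$target %in% vars) vars <- c(vars, mg$target)
    }
  }
  for (bz in rules$binarize %||% list()) {
    vars[vars == bz$source] <- bz$target
  }
  unique(c(vars, rules$additions %||% character(0)))
}

#' Consistency report for a primary table
#'
#' Report-only quality check: lists out-of-codebook codes, inverted
#' metrical ranges, empty edibility classes and duplicated species names.
#' The table itself is never modified.
#'
#' @param table A primary tibble.
#' @param schema A schema tibble.
#' @return A tibble of findings with columns `finding`, `variable`, `row`
#'   and `detail` (zero rows for a clean table).
#' @export
consistency_check <- function(table, schema = mushroom_schema("primary")) {
  findings <- list()
  add <- function(finding, variable, row, detail) {
    findings[[length(findings) + 1L]] <<- tibble(
      finding = finding, variable = variable, row = row, detail = detail)
  }
  for (v in intersect(attribute_names(schema, "nominal"), names(table))) {
    valid <- schema_codes(schema, v)
    for (i in seq_len(nrow(table))) {
      bad <- setdiff(table[[v]][[i]], valid)
      if (length(bad) > 0) {
        add("out-of-codebook code", v, i, paste(bad, collapse = ", "))
      }
    }
  }
  for (v in intersect(attribute_names(schema, "metrical"), names(table))) {
    for (i in seq_len(nrow(table))) {
      r <- table[[v]][[i]]
      if (!is.null(r) && r[1] > r[2]) {
        add("inverted range", v, i, sprintf("[%s:%s]", r[1], r[2]))
      }
    }
  }
  if ("class" %in% names(table)) {
    empty <- which(is.na(table$class) | !nzchar(table$class))
    for (i in empty) add("empty edibility", "class", i, "")
  }
  if ("name" %in% names(table)) {
    dup <- which(duplicated(table$name) & !is.na(table$name))
    for (i in dup) add("duplicate species name", "name", i, table$name[i])
  }
  if (length(findings) == 0) {
    return(tibble(finding = character(0), variable = character(0),
                  row = integer(0), detail = character(0)))
  }
  bind_rows(findings)
}
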