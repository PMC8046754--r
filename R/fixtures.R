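#' Fixture generator configuration
#'
#' Controls the synthetic primary table standing in for a curated
#' field-guide extraction: number of species and families (defaults mirror
#' the 173 species from 23 families of the study conditions), poisonous
#' species fraction (0.55), per-variable missingness, nominal set sizes and
#' metrical interval ranges, plus the number of species the 1987-style
#' structure cannot represent (capless/stemless), which the exclusion
#' filter later removes.
#'
#' @param n_species,n_families Species and family counts
#'   (`n_species >= n_families >= 1`).
#' @param p_ratio Fraction of poisonous species.
#' @param missingness Scalar or named numeric of per-variable missing
#'   fractions for nominal attributes.
#' @param seed Integer seed.
#' @param set_sizes Candidate nominal set sizes, drawn uniformly.
#' @param n_unsupported Species generated without a cap or without a stem.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_species = 173, n_families = 23, p_ratio = 0.55,
                           missingness = 0, seed = 1L, set_sizes = 1:3,
                           n_unsupported = 0) {
  if (!(n_species >= n_families && n_families >= 1)) {
    abort("need n_species >= n_families >= 1")
  }
  if (p_ratio < 0 || p_ratio > 1 || any(missingness < 0) || any(missingness > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  if (n_unsupported > n_species) abort("n_unsupported exceeds n_species")
  structure(list(n_species = as.integer(n_species),
                 n_families = as.integer(n_families),
                 p_ratio = p_ratio, missingness = missingness,
                 seed = as.integer(seed), set_sizes = set_sizes,
                 n_unsupported = as.integer(n_unsupported)),
            class = "fixture_config")
}

singleton_vars <- c("does-bruise-or-bleed", "veil-type", "has-ring")

#' Generate a synthetic primary table
#'
#' Emits species records with codebook-valid nominal sets, valid 2-decimal
#' metrical intervals, the requested poisonous/edible balance and
#' missingness, deterministically under the seed. Species are grouped
#' contiguously by family (as in a field guide). Binary-style variables
#' (does-bruise-or-bleed, veil-type, has-ring) get singleton sets, and
#' ring-type is only populated when has-ring is `t`. A quarter of the
#' supported species carry a "mean-style" cap interval
#' \eqn{[(3/4)\mu, (5/4)\mu]} around an integer mean, matching prose that
#' states a single size.
#'
#' @param config A [fixture_config()].
#' @param schema A schema tibble.
#' @return A primary tibble of `n_species` rows.
#' @export
generate_primary <- function(config = fixture_config(),
                             schema = mushroom_schema("primary")) {
  set.seed(config$seed)
  n <- config$n_species
  f <- config$n_families

  counts <- rep(1L, f)
  if (n > f) {
    extra <- table(factor(sample.int(f, n - f, replace = TRUE), levels = seq_len(f)))
    counts <- counts + as.integer(extra)
  }
  families <- rep(sprintf("Family-%02d", seq_len(f)), counts)
  n_p <- round(config$p_ratio * n)
  cls <- sample(c(rep("p", n_p), rep("e", n - n_p)))
  unsupported <- rep("", n)
  if (config$n_unsupported > 0) {
    idx <- sample.int(n, config$n_unsupported)
    unsupported[idx] <- rep_len(c("capless", "stemless"), config$n_unsupported)
  }

  tb <- tibble(family = families,
               name = sprintf("Species-%03d", seq_len(n)),
               class = cls)

  miss_frac <- function(v) {
    m <- config$missingness
    if (length(m) == 1 && is.null(names(m))) return(unname(m))
    if (v %in% names(m)) unname(m[[v]]) else 0
  }

  rand_interval <- function(lo, hi, mean_style = FALSE) {
    if (mean_style) {
      mu <- 4 * sample.int(5, 1)               # integer mean, quarter-rule interval
      return(list(range = c(min = 0.75 * mu, max = 1.25 * mu), mean = mu))
    }
    a <- round(stats::runif(1, lo, hi), 1)
    b <- round(a + stats::runif(1, 0.5, hi - lo), 1)
    list(range = c(min = a, max = b), mean = NA_real_)
  }

  cap_mean <- rep(NA_real_, n)
  for (v in attribute_names(schema)) {
    row <- schema_row(schema, v)
    if (row$kind == "metrical") {
      vals <- vector("list", n)
      for (i in seq_len(n)) {
        if (v == "cap-diameter") {
          if (unsupported[i] == "capless") next
          iv <- rand_interval(1, 12, mean_style = stats::runif(1) < 0.25)
          vals[[i]] <- iv$range
          cap_mean[i] <- iv$mean
        } else {
          if (unsupported[i] == "stemless") next
          iv <- if (v == "stem-height") rand_interval(2, 15) else rand_interval(2, 25)
          vals[[i]] <- iv$range
        }
      }
      tb[[v]] <- vals
      next
    }
    codes <- schema_codes(schema, v)
    vals <- map(seq_len(n), function(i) {
      if (stats::runif(1) < miss_frac(v)) return(character(0))
      k <- if (v %in% singleton_vars) 1L else {
        sizes <- config$set_sizes[config$set_sizes <= length(codes)]
        sizes[sample.int(length(sizes), 1)]
      }
      sel <- codes[sort(sample.int(length(codes), k))]
      sel
    })
    tb[[v]] <- vals
  }

  # ring-type is only meaningful when a ring is present
  tb[["ring-type"]] <- map2(tb[["has-ring"]], tb[["ring-type"]], function(hr, rt) {
    if (identical(hr, "t")) rt else character(0)
  })
  attr(tb, "cap_mean") <- cap_mean
  attr(tb, "unsupported") <- unsupported
  tb
}

join_words <- function(words) {
  if (length(words) == 1) return(words)
  paste(paste(head(words, -1), collapse = ", "), "and", words[length(words)])
}

lexicon_word <- function(lexicon, class, code) {
  kw <- lexicon$keyword_classes[[class]]
  names(kw)[match(code, kw)]
}

category_names <- function(schema, variable, codes) {
  cb <- schema_row(schema, variable)$codebook[[1]]
  names(cb)[match(codes, cb)]
}

species_prose <- function(rec, lexicon, schema, cap_mean = NA_real_) {
  g <- function(v) rec[[v]][[1]]
  words <- function(class, codes) map_chr(codes, function(cd) lexicon_word(lexicon, class, cd))
  s <- character(0)

  shp <- g("cap-shape"); srf <- g("cap-surface"); col <- g("cap-color")
  if (length(c(shp, srf, col)) > 0) {
    subject <- if (length(shp) > 0) {
      sprintf("The %s cap", join_words(words("shape", shp)))
    } else "The cap"
    pred <- join_words(c(words("surface", srf), words("color", col)))
    s <- c(s, if (nzchar(pred)) sprintf("%s is %s.", subject, pred)
              else sprintf("%s is unremarkable.", subject))
  }
  att <- g("gill-attachment"); spc <- g("gill-spacing"); gcl <- g("gill-color")
  if (length(c(att, spc, gcl)) > 0) {
    s <- c(s, sprintf("The gills are %s.", join_words(c(
      words("attachment", att), words("spacing", spc), words("color", gcl)))))
  }
  bb <- g("does-bruise-or-bleed")
  if (length(bb) > 0) {
    s <- c(s, if (bb == "t") "It bruises or bleeds when damaged."
              else "It does not bruise or bleed.")
  }
  rt <- g("stem-root"); ssrf <- g("stem-surface"); scol <- g("stem-color")
  if (length(c(rt, ssrf, scol)) > 0) {
    s <- c(s, sprintf("The stem is %s.", join_words(c(
      words("root", rt), words("surface", ssrf), words("color", scol)))))
  }
  vt <- g("veil-type"); vcl <- g("veil-color")
  if (length(c(vt, vcl)) > 0) {
    colw <- if (length(vcl) > 0) paste0(join_words(words("color", vcl)), " ") else ""
    s <- c(s, if (identical(vt, "u")) {
      sprintf("The young fruit body is enclosed in a %sveil.", colw)
    } else if (identical(vt, "p")) {
      sprintf("A partial %sveil is present.", colw)
    } else {
      sprintf("A %sveil is present.", colw)
    })
  }
  hr <- g("has-ring"); rtp <- g("ring-type")
  if (length(hr) > 0) {
    s <- c(s, if (hr == "t") {
      if (length(rtp) > 0) sprintf("It bears a %s ring.", join_words(words("ringtype", rtp)))
      else "It bears a ring."
    } else "There is no ring.")
  }
  spc2 <- g("spore-print-color")
  if (length(spc2) > 0) {
    s <- c(s, sprintf("The spore print is %s.", join_words(words("color", spc2))))
  }

  size_bits <- character(0)
  cap <- g("cap-diameter")
  if (!is.null(cap)) {
    size_bits <- if (!is.na(cap_mean)) {
      sprintf("cap about %s cm across", fmt_num(cap_mean))
    } else {
      sprintf("cap %s-%s cm across", fmt_num(cap[1]), fmt_num(cap[2]))
    }
  }
  sh <- g("stem-height"); sw <- g("stem-width")
  if (!is.null(sh) && !is.null(sw)) {
    size_bits <- c(size_bits, sprintf("stem %s-%s cm tall and %s-%s mm thick",
                                      fmt_num(sh[1]), fmt_num(sh[2]),
                                      fmt_num(sw[1]), fmt_num(sw[2])))
  }
  if (length(size_bits) > 0) {
    s <- c(s, sprintf("Size: %s.", paste(size_bits, collapse = "; ")))
  }
  hab <- g("habitat")
  if (length(hab) > 0) {
    s <- c(s, sprintf("Habitat: %s.", join_words(category_names(schema, "habitat", hab))))
  }
  sea <- g("season")
  if (length(sea) > 0) {
    s <- c(s, sprintf("Season: %s.", join_words(category_names(schema, "season", sea))))
  }
  s <- c(s, if (rec$class == "e") "Edible and good." else "Poisonous.")
  paste(s, collapse = " ")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a synthetic field-guide document from a primary table
#'
#' Writes one `chapterHeadA` header and one `paraNoIndent` body paragraph
#' per species, in the same HTML dialect the extractor consumes. The family
#' name appears only in the header of a family's first species, and the
#' prose is composed from the lexicon with one sentence per anchor noun, so
#' extraction can invert the document back to the generating table.
#'
#' @param table A primary tibble from [generate_primary()].
#' @param lexicon A lexicon from [mushroom_lexicon()].
#' @param schema A schema tibble.
#' @param path Optional file to write the document to.
#' @return The HTML document as a single string (invisibly if `path` is
#'   given).
#' @export
generate_book <- function(table, lexicon = mushroom_lexicon(),
                          schema = mushroom_schema("primary"), path = NULL) {
  cap_mean <- attr(table, "cap_mean") %||% rep(NA_real_, nrow(table))
  paras <- character(0)
  prev_family <- ""
  for (i in seq_len(nrow(table))) {
    rec <- table[i, ]
    latin <- sprintf("Fungus fictus %d", i)
    header <- if (!identical(rec$family, prev_family) && !is.na(rec$family)) {
      sprintf("%s — %s (%s)", rec$family, rec$name, latin)
    } else {
      sprintf("%s (%s)", rec$name, latin)
    }
    prev_family <- rec$family
    paras <- c(paras,
               sprintf('<p class="chapterHeadA">%s</p>', html_escape(header)),
               sprintf('<p class="paraNoIndent">%s</p>',
                       html_escape(species_prose(rec, lexicon, schema, cap_mean[i]))))
  }
  doc <- paste0("<html><head><title>Synthetic field guide</title></head><body>\n",
                paste(paras, collapse = "\n"), "\n</body></html>\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Reassign the class column by a stated rule
#'
#' Supports separability experiments on simulated tables: an `xor` rule
#' (class is poisonous iff exactly one of two nominal indicator conditions
#' holds — not linearly separable in one-hot space), a `linear` rule (class
#' determined by a single code, linearly separable) and a `constant` rule.
#'
#' @param table A secondary tibble.
#' @param rule A list: `type` (`"xor"`, `"linear"`, `"constant"`),
#'   `variables` (two names for xor, one for linear), `codes` (matching
#'   codes), `value` (class for constant rule).
#' @return The table with its `class` column reassigned.
#' @export
generate_nonlinear_labels <- function(table, rule) {
  for (v in rule$variables %||% character(0)) {
    if (!v %in% names(table)) {
      abort(sprintf("rule references absent variable '%s'", v),
            class = "mushroomsim_config_error")
    }
  }
  table$class <- switch(rule$type,
    xor = {
      a <- table[[rule$variables[1]]] == rule$codes[1]
      b <- table[[rule$variables[2]]] == rule$codes[2]
      ifelse(xor(a, b), "p", "e")
    },
    linear = ifelse(table[[rule$variables[1]]] == rule$codes[1], "p", "e"),
    constant = rep(rule$value %||% "p", nrow(table)),
    abort(sprintf("unknown rule type '%s'", rule$type))
  )
  table
}
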