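is_missing_cell <- function(x) {
  if (is.list(x)) return(map_lgl(x, function(v) is.null(v) || length(v) == 0))
  if (is.character(x)) return(is.na(x) | !nzchar(dplyr::coalesce(x, "")))
  is.na(x)
}

qc_columns <- function(table) {
  setdiff(names(table), c("family", "name"))
}

#' Class balance of a table
#'
#' Exact poisonous/edible fractions of the binary `class` column, computed
#' on counts so the two ratios sum to 1 exactly.
#'
#' @param table A tibble with a `class` column of `"e"`/`"p"` codes.
#' @return A one-row tibble with `n`, `ratio_p` and `ratio_e`.
#' @export
class_balance <- function(table) {
  if (nrow(table) == 0) abort("cannot compute class balance of an empty table")
  cls <- table$class
  tibble(n = length(cls),
         ratio_p = sum(cls == "p") / length(cls),
         ratio_e = sum(cls == "e") / length(cls))
}

#' Missing-value fraction per variable
#'
#' Empty cells (`NA`, empty strings, empty sets, absent ranges) count as
#' missing. Identifier columns `family`/`name` are skipped.
#'
#' @param table A primary or secondary tibble.
#' @return A tibble with columns `variable` and `fraction`.
#' @export
missing_fraction <- function(table) {
  vars <- qc_columns(table)
  tibble(variable = vars,
         fraction = map_dbl(vars, function(v) mean(is_missing_cell(table[[v]]))))
}

#' Drop variables with too many missing values
#'
#' Removes variables whose missing fraction is strictly greater than the
#' threshold (more than 50% missing by default), limiting the dilution of
#' downstream analyses. Removed variables are reported in the `dropped`
#' attribute.
#'
#' @param table A primary or secondary tibble.
#' @param threshold Maximum tolerated missing fraction (default 0.5).
#' @return The table without the high-missingness variables, with
#'   attribute `dropped`.
#' @export
drop_high_missing <- function(table, threshold = 0.5) {
  mf <- missing_fraction(table)
  drop <- mf$variable[mf$fraction > threshold]
  out <- table[, setdiff(names(table), drop), drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

modal_value <- function(x) {
  tab <- table(x)
  if (length(tab) == 0) return(NULL)
  modes <- names(tab)[tab == max(tab)]
  sort(modes)[1]          # deterministic tie-break: lexicographically smallest
}

#' Most-frequent single imputation
#'
#' Replaces every missing cell by its variable's modal value (ties broken
#' to the lexicographically smallest mode, for determinism). High-missing
#' variables must have been dropped first; a variable with all values
#' missing is an error.
#'
#' @param table A secondary tibble (single-valued cells).
#' @return The table with no missing values left.
#' @export
impute_most_frequent <- function(table) {
  out <- table
  for (v in qc_columns(table)) {
    miss <- is_missing_cell(out[[v]])
    if (!any(miss)) next
    if (all(miss)) {
      abort(sprintf("variable '%s' is entirely missing; it should have been dropped", v))
    }
    mode <- modal_value(out[[v]][!miss])
    if (is.numeric(out[[v]])) mode <- as.numeric(mode)
    out[[v]][miss] <- mode
  }
  out
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))        # natural log; Theil's U is scale invariant
}

#' Theil's U (uncertainty coefficient)
#'
#' The asymmetric association U(x|y) = (H(x) - H(x|y)) / H(x) between two
#' nominal columns, with Shannon entropies in natural log. A constant `x`
#' (H(x) = 0) is fully predictable, so U is defined as 1 by convention.
#'
#' @param x,y Equal-length vectors of nominal codes.
#' @return A value in `[0, 1]`.
#' @examples
#' x <- c("a", "a", "b", "b")
#' theils_u(x, x)                 # 1
#' theils_u(x, c("u", "v", "u", "v"))  # 0: independent
#' @export
theils_u <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) == 0) abort("x and y must be non-empty")
  hx <- shannon_entropy(prop.table(table(x)))
  if (hx == 0) return(1)
  joint <- table(x, y)
  py <- prop.table(margin.table(joint, 2))
  hx_given_y <- sum(map_dbl(seq_along(py), function(j) {
    col <- joint[, j]
    if (sum(col) == 0) return(0)
    py[j] * shannon_entropy(col / sum(col))
  }))
  u <- (hx - hx_given_y) / hx
  min(max(u, 0), 1)
}

#' Correlation ratio between a nominal and a metrical variable
#'
#' eta = sqrt(between-group sum of squares / total sum of squares): the
#' share of the metrical variable's dispersion explained by the nominal
#' grouping. A metrical variable with zero total dispersion is fully
#' predictable and yields 1.
#'
#' @param categories Nominal codes.
#' @param values Numeric values, same length.
#' @return A value in `[0, 1]`.
#' @export
correlation_ratio <- function(categories, values) {
  if (length(categories) != length(values)) abort("inputs must have equal length")
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  if (ss_total == 0) return(1)
  groups <- split(values, categories)
  ss_between <- sum(map_dbl(groups, function(g) length(g) * (mean(g) - grand)^2))
  sqrt(ss_between / ss_total)
}

#' Mixed-type pairwise association matrix
#'
#' Entry (i, j) is the association of variable i given variable j:
#' Theil's U for a nominal pair (so the nominal block may be asymmetric),
#' the absolute Pearson correlation for a metrical pair, and the
#' correlation ratio for a mixed pair. All entries live in `[0, 1]` and the
#' diagonal is 1, matching the clipped sequential palette of the heat map.
#'
#' @param table An imputed secondary tibble (identifier columns
#'   `family`/`name` are skipped).
#' @return An object of class `association_matrix` wrapping the square
#'   numeric matrix.
#' @export
association_matrix <- function(table) {
  vars <- qc_columns(table)
  is_num <- map_lgl(vars, function(v) is.numeric(table[[v]]))
  k <- length(vars)
  m <- matrix(1, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      xi <- table[[vars[i]]]
      xj <- table[[vars[j]]]
      m[i, j] <- if (!is_num[i] && !is_num[j]) {
        theils_u(xi, xj)
      } else if (is_num[i] && is_num[j]) {
        if (sd(xi) == 0 || sd(xj) == 0) 1 else abs(cor(xi, xj))
      } else if (is_num[i]) {
        correlation_ratio(xj, xi)
      } else {
        correlation_ratio(xi, xj)
      }
    }
  }
  structure(list(matrix = m, variables = vars), class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Pairwise association matrix over %d variables\n", length(x$variables)))
  print(round(x$matrix, 2))
  invisible(x)
}

#' @rdname association_matrix
#' @param x An `association_matrix`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble with `variable`, `given` and
#'   `association`.
#' @export
tidy.association_matrix <- function(x, ...) {
  m <- x$matrix
  tidyr::expand_grid(variable = rownames(m), given = colnames(m)) |>
    mutate(association = as.vector(t(m)))
}

#' @rdname association_matrix
#' @param object An `association_matrix`.
#' @export
autoplot.association_matrix <- function(object, ...) {
  df <- tidy(object)
  df$variable <- factor(df$variable, levels = rev(object$variables))
  df$given <- factor(df$given, levels = object$variables)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$given, y = .data$variable,
                                   fill = .data$association)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "gray85", high = "black", limits = c(0, 1)) +
    ggplot2::labs(x = "given variable", y = "variable", fill = "association") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Render the association heat map and its matrix
#'
#' Writes a PNG heat map (sequential gray palette clipped so 1 is black)
#' plus the matrix itself as a CSV next to it.
#'
#' @param matrix An `association_matrix`.
#' @param path Output PNG path; the CSV replaces the extension with
#'   `.csv`.
#' @param width,height Image size in inches.
#' @return The two file paths, invisibly.
#' @export
render_heatmap <- function(matrix, path, width = 8, height = 7) {
  p <- autoplot(matrix)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  csv_path <- paste0(tools::file_path_sans_ext(path), ".csv")
  df <- as_tibble(matrix$matrix, rownames = "variable")
  readr::write_csv(df, csv_path, progress = FALSE)
  invisible(c(path, csv_path))
}

#' Read back an association-matrix CSV
#'
#' @param path CSV written by [render_heatmap()].
#' @return An `association_matrix`.
#' @export
read_association_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$variable
  structure(list(matrix = m, variables = df$variable), class = "association_matrix")
}
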