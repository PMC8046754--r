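#' Covariance model for the three quantitative traits
#'
#' Cap diameter (a), stem height (b) and stem width (c) are simulated as
#' correlated standard normals. The default covariance matrix has unit
#' diagonal with COV(a,b) = COV(a,c) = 0.5 and COV(b,c) = 0.7 (the stem
#' related quantities correlate somewhat stronger); its lower Cholesky
#' factor L (COV = L L') induces the correlation on independent N(0, 1)
#' draws. One shared model is used for all species, overridable per run.
#'
#' @param cov A symmetric positive semi-definite matrix (default: the
#'   package's assumed 3x3 covariance).
#' @return An object of class `covariance_model` with elements `cov` and
#'   `chol` (the lower factor).
#' @examples
#' m <- covariance_model()
#' round(m$chol, 2)
#' @export
covariance_model <- function(cov = default_covariance()) {
  L <- cholesky_lower(cov)
  structure(list(cov = cov, chol = L), class = "covariance_model")
}

#' @rdname covariance_model
#' @export
default_covariance <- function() {
  matrix(c(1, 0.5, 0.5,
           0.5, 1, 0.7,
           0.5, 0.7, 1), nrow = 3, byrow = TRUE,
         dimnames = list(c("cap-diameter", "stem-height", "stem-width"),
                         c("cap-diameter", "stem-height", "stem-width")))
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("Covariance model over (cap-diameter, stem-height, stem-width)\n")
  print(x$cov)
  cat("lower Cholesky factor:\n")
  print(round(x$chol, 4))
  invisible(x)
}

#' Lower-triangular Cholesky factor
#'
#' Factorizes a symmetric positive semi-definite covariance matrix as
#' COV = L L' with L lower triangular. A matrix with a negative eigenvalue
#' is rejected with an error naming the offending eigenvalue.
#'
#' @param cov A symmetric matrix.
#' @param tol Eigenvalue tolerance for the positive semi-definite check.
#' @return The lower-triangular matrix L.
#' @examples
#' round(cholesky_lower(default_covariance()), 2)
#' @export
cholesky_lower <- function(cov, tol = 1e-10) {
  if (!isSymmetric(unname(cov))) {
    abort("covariance matrix must be symmetric",
          class = "mushroomsim_decomposition_error")
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf("covariance matrix is not positive semi-definite: eigenvalue %.6g < 0",
                  min(ev)),
          class = "mushroomsim_decomposition_error")
  }
  ridge <- if (min(ev) < tol) diag(tol, nrow(cov)) else 0
  t(chol(cov + ridge))
}

#' Draw correlated standard-normal triples
#'
#' Generates `n` rows of L z where z is a vector of independent N(0, 1)
#' draws, so the empirical correlation matrix converges to the covariance
#' model as n grows.
#'
#' @param n Number of rows.
#' @param L Lower Cholesky factor (or a [covariance_model()]).
#' @return An `n x ncol(L)` numeric matrix.
#' @export
sample_correlated_normals <- function(n, L = covariance_model()) {
  if (inherits(L, "covariance_model")) L <- L$chol
  stopifnot(n >= 1)
  z <- matrix(rnorm(n * ncol(L)), nrow = n)
  out <- z %*% t(L)
  colnames(out) <- rownames(L)
  out
}

#' Rescale standard-normal draws onto a species interval
#'
#' In the default `three_sigma` mode the draw is first mapped as
#' x = (z/3 + 1) / 2, so the +/-3 sigma band of N(0, 1) covers the unit
#' interval and about 99.7% of draws land inside; then
#' x = x * (max - min) + min places it in the species' \[min, max\]. The
#' `half_shift` mode applies x = (z + 1) / 2 without the division by 3,
#' which covers \[min, max\] with only about 68.3% probability
#' (2 pnorm(1) - 1). Both modes recentre the sample on the interval
#' midpoint (mean 0.5 before the affine map) and neither clips
#' out-of-interval draws. A degenerate interval min = max yields the
#' constant min.
#'
#' @param z Numeric vector of standard-normal draws.
#' @param range Numeric `c(min, max)`.
#' @param mode `"three_sigma"` (default) or `"half_shift"`.
#' @return Numeric vector of rescaled values.
#' @examples
#' rescale_to_range(0, c(10, 20))            # midpoint 15
#' rescale_to_range(3, c(10, 20))            # 20, the 3-sigma edge
#' @export
rescale_to_range <- function(z, range, mode = c("three_sigma", "half_shift")) {
  mode <- match.arg(mode)
  stopifnot(length(range) == 2, range[1] <= range[2])
  x <- if (mode == "three_sigma") (z / 3 + 1) / 2 else (z + 1) / 2
  unname(x * (range[2] - range[1]) + range[1])
}

#' Simulation configuration
#'
#' @param n_per_species Hypothetical entries per species (default 353, the
#'   per-species count of the 1987 data).
#' @param seed Integer root seed; per-species substreams are derived from
#'   (seed, species index) so adding a species does not perturb earlier
#'   species' draws.
#' @param covariance A [covariance_model()].
#' @param coverage_mode Interval-rescaling mode, see [rescale_to_range()].
#' @param shuffle_rows Shuffle the output rows across species (default
#'   `FALSE`).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_species = 353, seed = 1L,
                              covariance = covariance_model(),
                              coverage_mode = c("three_sigma", "half_shift"),
                              shuffle_rows = FALSE) {
  stopifnot(n_per_species >= 1)
  structure(list(n_per_species = as.integer(n_per_species),
                 seed = as.integer(seed), covariance = covariance,
                 coverage_mode = match.arg(coverage_mode),
                 shuffle_rows = isTRUE(shuffle_rows)),
            class = "simulation_config")
}

species_seed <- function(seed, index) {
  # deterministic substream per species, kept inside 32-bit integer range
  (as.numeric(seed) * 48271 + index * 16807) %% 2147483647
}

#' Simulate hypothetical mushroom entries for one species
#'
#' Nominal codes are drawn uniformly and independently per variable from
#' the species' nominal set (a missing set propagates as missing); the
#' three metrical values of one entry share one correlated normal triple,
#' rescaled onto the species' intervals. Stemless species get stem values
#' of exactly 0. Class, name and family are carried over unchanged.
#'
#' @param record A one-row primary tibble.
#' @param config A [simulation_config()].
#' @param n Number of entries (defaults to `config$n_per_species`).
#' @param schema A schema tibble.
#' @return A secondary tibble of `n` hypothetical entries.
#' @export
simulate_species <- function(record, config = simulation_config(),
                             n = config$n_per_species,
                             schema = mushroom_schema("primary")) {
  if (is.null(record[["cap-diameter"]][[1]])) {
    abort(sprintf("species '%s' has no cap-diameter range; it should have been excluded",
                  record$name),
          class = "mushroomsim_simulation_error")
  }
  out <- tibble(.rows = n)
  for (v in c("family", "name", "class")) {
    if (v %in% names(record)) out[[v]] <- rep(record[[v]], n)
  }
  metr <- sample_correlated_normals(n, config$covariance)
  metr_idx <- c(`cap-diameter` = 1L, `stem-height` = 2L, `stem-width` = 3L)
  for (v in attribute_names(schema)) {
    row <- schema_row(schema, v)
    if (row$kind == "metrical") {
      rng <- record[[v]][[1]]
      out[[v]] <- if (is.null(rng)) {
        rep(0, n)                                 # stemless species
      } else {
        round(rescale_to_range(metr[, metr_idx[[v]]], rng, config$coverage_mode), 2)
      }
    } else {
      codes <- record[[v]][[1]]
      out[[v]] <- if (length(codes) == 0) {
        rep(NA_character_, n)
      } else {
        codes[sample.int(length(codes), n, replace = TRUE)]
      }
    }
  }
  out
}

#' Simulate the secondary table from a primary table
#'
#' Processes species in table order, each with its own RNG substream
#' derived from the root seed and the species index, and stacks
#' `n_per_species` hypothetical entries per species (173 species x 353
#' entries = 61,069 rows). Deterministic under a fixed seed.
#'
#' @param primary A primary tibble (curated, unsupported species excluded).
#' @param config A [simulation_config()].
#' @param schema A schema tibble.
#' @return A secondary tibble with `nrow(primary) * n_per_species` rows.
#' @export
simulate_table <- function(primary, config = simulation_config(),
                           schema = mushroom_schema("primary")) {
  stopifnot(nrow(primary) > 0)
  pieces <- map(seq_len(nrow(primary)), function(i) {
    set.seed(species_seed(config$seed, i))
    simulate_species(primary[i, ], config, schema = schema)
  })
  out <- bind_rows(pieces)
  if (config$shuffle_rows) {
    set.seed(species_seed(config$seed, 0L))
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  }
  out
}
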