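#' Numerically encode a secondary table
#'
#' The binary class is label encoded (`p` = 1, `e` = 0), nominal variables
#' are one-hot encoded (the indicator columns of one variable sum to 1 per
#' row) and metrical variables pass through unchanged. Identifier columns
#' `family`/`name` are not features and are skipped. Encoding levels
#' default to the codes observed in the table; pass the `levels` of a
#' previously encoded dataset to transform new data consistently — a code
#' unseen at transform time is an error naming the variable and code.
#'
#' @param table An imputed secondary tibble with a `class` column.
#' @param levels Optional named list, variable -> character vector of
#'   codes, fixing the one-hot layout.
#' @return An object of class `encoded_dataset`: list with the feature
#'   matrix `x`, the 0/1 label vector `y`, a `feature_map` tibble tracing
#'   one-hot columns to (variable, code), and `levels`.
#' @export
encode <- function(table, levels = NULL) {
  if (!"class" %in% names(table)) abort("table must have a 'class' column")
  y <- ifelse(table$class == "p", 1L, 0L)
  vars <- setdiff(names(table), c("family", "name", "class"))
  cols <- list()
  fmap <- list()
  lvls <- list()
  for (v in vars) {
    col <- table[[v]]
    if (is.numeric(col)) {
      cols[[v]] <- col
      fmap[[length(fmap) + 1L]] <- tibble(column = v, variable = v, code = NA_character_)
      next
    }
    lv <- if (!is.null(levels) && v %in% names(levels)) levels[[v]] else sort(unique(col))
    unseen <- setdiff(unique(col), lv)
    if (length(unseen) > 0) {
      abort(sprintf("unseen code '%s' for variable '%s' at transform time",
                    unseen[1], v),
            class = "mushroomsim_encoding_error")
    }
    lvls[[v]] <- lv
    for (code in lv) {
      cn <- paste0(v, "=", code)
      cols[[cn]] <- as.numeric(col == code)
      fmap[[length(fmap) + 1L]] <- tibble(column = cn, variable = v, code = code)
    }
  }
  x <- do.call(cbind, cols)
  structure(list(x = x, y = y, feature_map = bind_rows(fmap), levels = lvls),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("Encoded dataset: %d rows, %d feature columns, %d poisonous / %d edible\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

encoded_subset <- function(dataset, idx) {
  structure(list(x = dataset$x[idx, , drop = FALSE], y = dataset$y[idx],
                 feature_map = dataset$feature_map, levels = dataset$levels),
            class = "encoded_dataset")
}

#' Train/test split and stratified k folds
#'
#' `split_dataset()` samples the training set without replacement (the
#' Pareto 80/20 split by default); `kfold()` assigns class-stratified folds
#' whose sizes differ by at most one. Both are deterministic under the
#' spec's seed.
#'
#' @param dataset An `encoded_dataset`.
#' @param spec A [split_spec()].
#' @return `split_dataset()`: list with `train` and `test` encoded
#'   datasets. `kfold()`: a list of `k` lists with `train` and `test`.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  n <- length(dataset$y)
  set.seed(spec$seed)
  train_idx <- sort(sample.int(n, size = round(spec$train_fraction * n)))
  list(train = encoded_subset(dataset, train_idx),
       test = encoded_subset(dataset, setdiff(seq_len(n), train_idx)))
}

#' @rdname split_dataset
#' @export
kfold <- function(dataset, spec = split_spec()) {
  n <- length(dataset$y)
  k <- spec$k
  if (k > n) abort(sprintf("cannot make %d folds from %d rows", k, n))
  set.seed(spec$seed)
  # shuffle within class, then deal folds round-robin over the concatenated
  # order: stratified and fold sizes differ by at most 1
  ord <- unlist(map(split(seq_len(n), dataset$y), sample))
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(k), n)
  map(seq_len(k), function(f) {
    list(train = encoded_subset(dataset, which(fold_of != f)),
         test = encoded_subset(dataset, which(fold_of == f)))
  })
}

#' @rdname split_dataset
#' @param train_fraction Fraction of rows used for training.
#' @param k Number of cross-validation folds.
#' @param seed Integer seed.
#' @export
split_spec <- function(train_fraction = 0.8, k = 5L, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, k >= 2)
  structure(list(train_fraction = train_fraction, k = as.integer(k),
                 seed = as.integer(seed)), class = "split_spec")
}

#' F-beta score
#'
#' The weighted harmonic mean of precision and recall,
#' (1 + beta^2) P R / (beta^2 P + R). The F2 score (beta = 2) gives twice
#' as much importance to recall as to precision, penalising the dangerous
#' false negatives (poisonous mushrooms labelled edible). Precision and
#' recall both zero yields 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta Recall weight (default 2).
#' @return A value in `[0, 1]`.
#' @examples
#' fbeta(0.5, 1, beta = 2)  # 0.8333
#' @export
fbeta <- function(precision, recall, beta = 2) {
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

supported_classifiers <- c("naive-bayes", "logistic-regression", "lda", "random-forest")

fit_classifier <- function(train, classifier) {
  classifier <- match.arg(classifier, supported_classifiers)
  if (length(unique(train$y)) < 2) {
    abort("training labels contain a single class", class = "mushroomsim_fit_error")
  }
  keep <- which(apply(train$x, 2, function(col) stats::sd(col) > 0))
  x <- train$x[, keep, drop = FALSE]
  jitter_cols <- integer(0)
  if (classifier == "lda") {
    # LDA rejects predictors that are (near-)constant within groups; a
    # perfect discriminator is exactly that. Give such columns a tiny
    # deterministic wobble so they stay in the model (and dominate it).
    within_sd <- apply(x, 2, function(col) {
      sqrt(mean(map_dbl(split(col, train$y), function(g) {
        if (length(g) < 2) 0 else var(g)
      })))
    })
    jitter_cols <- which(within_sd < 1e-6)
    for (j in jitter_cols) {
      # distinct pattern per column so complementary indicator pairs do not
      # become jointly degenerate
      x[, j] <- x[, j] + 1e-3 * sin(seq_len(nrow(x)) * j)
    }
  }
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(df)))
  fit <- switch(classifier,
    "naive-bayes" = {
      m <- e1071::naiveBayes(df, factor(train$y, levels = c(0, 1)))
      # floor the per-class Gaussian sd so degenerate indicator columns
      # cannot produce infinite densities
      m$tables <- map(m$tables, function(tab) {
        tab[, 2] <- pmax(tab[, 2], 1e-3)
        tab
      })
      m
    },
    "logistic-regression" = suppressWarnings(
      glm(y ~ ., data = cbind(df, y = train$y), family = binomial())),
    "lda" = suppressWarnings(MASS::lda(df, grouping = factor(train$y, levels = c(0, 1)))),
    "random-forest" = randomForest::randomForest(df, factor(train$y, levels = c(0, 1)))
  )
  structure(list(fit = fit, classifier = classifier, keep = keep),
            class = "mushroom_fit")
}

predict_prob <- function(model, dataset) {
  x <- dataset$x[, model$keep, drop = FALSE]
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(df)))
  switch(model$classifier,
    "naive-bayes" = as.numeric(predict(model$fit, df, type = "raw")[, "1"]),
    "logistic-regression" = as.numeric(suppressWarnings(
      predict(model$fit, newdata = df, type = "response"))),
    "lda" = as.numeric(predict(model$fit, df)$posterior[, "1"]),
    "random-forest" = as.numeric(predict(model$fit, df, type = "prob")[, "1"])
  )
}

#' ROC curve and trapezoidal AUC
#'
#' Points are computed from the class-p probabilities before thresholding,
#' ordered by descending threshold with tied scores grouped; the AUC is the
#' trapezoidal area over all distinct cut-points.
#'
#' @param scores Predicted probabilities of class p.
#' @param labels 0/1 labels.
#' @return `roc_curve()`: a tibble with `threshold`, `fpr`, `tpr`.
#'   `auc_trapezoid()`: a single value in `[0, 1]`.
#' @export
roc_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l == 1)
  fp <- cumsum(l == 0)
  keep <- !duplicated(s, fromLast = TRUE)
  n_pos <- max(sum(labels == 1), 1L)
  n_neg <- max(sum(labels == 0), 1L)
  tibble(threshold = c(Inf, s[keep]),
         fpr = c(0, fp[keep]) / n_neg,
         tpr = c(0, tp[keep]) / n_pos)
}

#' @rdname roc_curve
#' @param roc A tibble from `roc_curve()`.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

score_predictions <- function(prob, labels, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)   # probability exactly 0.5 -> poisonous
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  roc <- roc_curve(prob, labels)
  tibble(accuracy = mean(pred == labels),
         precision = precision,
         recall = recall,
         f2 = fbeta(precision, recall, beta = 2),
         auc = auc_trapezoid(roc))
}

#' Train a classifier and score it on held-out data
#'
#' Fits one of the four supported classifiers (naive Bayes, logistic
#' regression, LDA, random forest — standard library implementations; the
#' package contributes the harness) on the training set, predicts the
#' probability of class p per test row, thresholds at `>= 0.5` (a
#' probability of exactly 0.5 is classified poisonous — the cautious side)
#' and reports accuracy, precision, recall, F2, the ROC curve and its
#' trapezoidal AUC.
#'
#' @param train,test `encoded_dataset`s.
#' @param classifier One of `"naive-bayes"`, `"logistic-regression"`,
#'   `"lda"`, `"random-forest"`.
#' @param threshold Class-dividing probability threshold (default 0.5).
#' @return An object of class `classifier_eval` with `metrics` (one-row
#'   tibble) and `roc` (tibble of ROC points).
#' @export
classify_and_score <- function(train, test, classifier, threshold = 0.5) {
  model <- fit_classifier(train, classifier)
  prob <- predict_prob(model, test)
  metrics <- score_predictions(prob, test$y, threshold)
  structure(list(classifier = classifier,
                 metrics = bind_cols(tibble(classifier = classifier), metrics),
                 roc = roc_curve(prob, test$y),
                 prob = prob),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("Classifier evaluation: %s\n", x$classifier))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @rdname classify_and_score
#' @param x,object A `classifier_eval`.
#' @param ... Unused.
#' @export
tidy.classifier_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"classifier",
                      names_to = "metric", values_to = "value")
}

#' @rdname classify_and_score
#' @export
glance.classifier_eval <- function(x, ...) x$metrics

#' @rdname classify_and_score
#' @export
autoplot.classifier_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "gray60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s (AUC = %.3f)", object$classifier,
                                  object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' Evaluate several classifiers on one split
#'
#' @param dataset An `encoded_dataset`.
#' @param spec A [split_spec()].
#' @param classifiers Subset of the four supported classifiers.
#' @param threshold Class-dividing threshold.
#' @return A `metric_report`: list of `classifier_eval`s with a combined
#'   `metrics` tibble; supports `tidy()`, `glance()` and `autoplot()`.
#' @export
evaluate_classifiers <- function(dataset, spec = split_spec(),
                                 classifiers = supported_classifiers,
                                 threshold = 0.5) {
  parts <- split_dataset(dataset, spec)
  evals <- map(classifiers, function(cl) {
    classify_and_score(parts$train, parts$test, cl, threshold)
  })
  names(evals) <- classifiers
  structure(list(evals = evals,
                 metrics = bind_rows(map(evals, "metrics"))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Held-out evaluation\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @rdname evaluate_classifiers
#' @param x,object A `metric_report`.
#' @param ... Unused.
#' @export
tidy.metric_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"classifier",
                      names_to = "metric", values_to = "value")
}

#' @rdname evaluate_classifiers
#' @export
glance.metric_report <- function(x, ...) x$metrics

#' @rdname evaluate_classifiers
#' @export
autoplot.metric_report <- function(object, ...) {
  rocs <- bind_rows(imap(object$evals, function(e, nm) {
    mutate(e$roc, classifier = nm)
  }))
  ggplot2::ggplot(rocs, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "gray60") +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Cross-validated metrics
#'
#' Runs the classifier over the stratified k folds and aggregates each
#' metric to its mean and standard deviation across folds.
#'
#' @inheritParams evaluate_classifiers
#' @param classifier One of the four supported classifiers.
#' @return A tibble with columns `classifier`, `metric`, `mean`, `sd`; the
#'   per-fold metrics are attached as attribute `folds`.
#' @export
crossval <- function(dataset, spec = split_spec(), classifier = "random-forest",
                     threshold = 0.5) {
  folds <- kfold(dataset, spec)
  per_fold <- bind_rows(imap(folds, function(fold, i) {
    eval <- classify_and_score(fold$train, fold$test, classifier, threshold)
    mutate(eval$metrics, fold = i)
  }))
  out <- per_fold |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f2", "auc"),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$classifier, .data$metric) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  attr(out, "folds") <- per_fold
  out
}

#' Align two tables variable-by-variable (direct data mapping)
#'
#' Matching column names are kept side by side; for a variable present on
#' one side only, either a zero-valued column is added to the other side
#' (`policy = "zero_fill"`: no entry there has a corresponding value) or
#' the variable is renamed into a pre-existing one via `renames`
#' (`policy = "rename"`). A cycle in the rename map is a configuration
#' error.
#'
#' @param a,b Data frames (typically one-hot encoded feature frames).
#' @param policy `"zero_fill"` or `"rename"`.
#' @param renames Named character vector, old name -> new name, used by the
#'   rename policy.
#' @return A list with the two aligned tibbles `a` and `b`, sharing the
#'   same columns in the same order.
#' @export
direct_mapping <- function(a, b, policy = c("zero_fill", "rename"),
                           renames = NULL) {
  policy <- match.arg(policy)
  a <- as_tibble(a)
  b <- as_tibble(b)
  if (policy == "rename" && length(renames) > 0) {
    for (old in names(renames)) {
      seen <- old
      target <- renames[[old]]
      while (target %in% names(renames)) {
        if (target %in% seen) {
          abort("cycle in rename mapping", class = "mushroomsim_config_error")
        }
        seen <- c(seen, target)
        target <- renames[[target]]
      }
      for (tb in c("a", "b")) {
        tab <- get(tb)
        if (old %in% names(tab)) {
          if (target %in% names(tab)) {
            abort(sprintf("rename '%s' -> '%s' collides with an existing column",
                          old, target),
                  class = "mushroomsim_config_error")
          }
          names(tab)[names(tab) == old] <- target
          assign(tb, tab)
        }
      }
    }
  }
  all_cols <- union(names(a), names(b))
  fill_zero <- function(tab) {
    for (v in setdiff(all_cols, names(tab))) tab[[v]] <- 0
    tab[, all_cols, drop = FALSE]
  }
  list(a = fill_zero(a), b = fill_zero(b))
}
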