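toy_separated <- function(n = 200, seed = 1) {
  # two distant clusters: every classifier should separate them perfectly
  set.seed(seed)
  tibble::tibble(
    class = rep(c("p", "e"), each = n / 2),
    `cap-diameter` = c(rnorm(n / 2, 100), rnorm(n / 2, 0)),
    `stem-height` = c(rnorm(n / 2, 100), rnorm(n / 2, 0)),
    `cap-color` = rep(c("e", "w"), each = n / 2))
}

test_that("encoding one-hots nominals, passes metricals and label-encodes class", {
  tb <- tibble::tibble(class = c("p", "e", "p"),
                       `cap-shape` = c("x", "f", "x"),
                       `cap-diameter` = c(1.5, 2, 3))
  enc <- encode(tb)
  expect_equal(enc$y, c(1L, 0L, 1L))
  onehot <- enc$x[, c("cap-shape=f", "cap-shape=x")]
  expect_equal(unname(rowSums(onehot)), rep(1, 3))
  expect_equal(unname(enc$x[, "cap-diameter"]), tb$`cap-diameter`)
  # unseen code at transform time errors, naming variable and code
  expect_error(encode(tibble::tibble(class = "e", `cap-shape` = "s",
                                     `cap-diameter` = 1),
                      levels = enc$levels),
               "cap-shape", class = "mushroomsim_encoding_error")
})

test_that("splits and folds are disjoint, exhaustive, sized and deterministic", {
  enc <- encode(toy_separated(100))
  spec <- split_spec(seed = 5)
  parts <- split_dataset(enc, spec)
  expect_equal(length(parts$train$y), 80)
  expect_equal(length(parts$test$y), 20)
  parts2 <- split_dataset(enc, spec)
  expect_identical(parts$train$x, parts2$train$x)

  folds <- kfold(enc, spec)
  expect_length(folds, 5)
  sizes <- purrr::map_int(folds, function(f) length(f$test$y))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 100)
  # stratification keeps fold class balance near the global 50/50
  balance <- purrr::map_dbl(folds, function(f) mean(f$test$y))
  expect_true(all(abs(balance - 0.5) <= 0.05))
  expect_error(kfold(encoded <- encode(toy_separated(4)), split_spec(k = 5)))
})

test_that("F-beta matches its closed form", {
  expect_equal(fbeta(1, 1), 1)
  expect_equal(fbeta(0.3, 0.3), 0.3)                  # P = R = x -> x
  expect_equal(fbeta(0.5, 1, beta = 2), 5 * 0.5 / (4 * 0.5 + 1))
  expect_equal(round(fbeta(0.5, 1, beta = 2), 4), 0.8333)
  expect_equal(fbeta(0.4, 0.8, beta = 1), 2 * 0.4 * 0.8 / 1.2)  # harmonic F1
  expect_equal(fbeta(0, 0), 0)
})

test_that("ROC/AUC behave at the landmarks and agree with an external oracle", {
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auc_trapezoid(roc_curve(as.numeric(y), y)), 1)   # score = label
  expect_equal(auc_trapezoid(roc_curve(rep(0.7, 6), y)), 0.5)   # constant score
  set.seed(77)
  scores <- runif(300)
  labels <- rbinom(300, 1, plogis(3 * (scores - 0.5)))
  ours <- auc_trapezoid(roc_curve(scores, labels))
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("all four classifiers are perfect on separated clusters", {
  enc <- encode(toy_separated(200))
  spec <- split_spec(seed = 3)
  parts <- split_dataset(enc, spec)
  for (cl in c("naive-bayes", "logistic-regression", "lda", "random-forest")) {
    ev <- classify_and_score(parts$train, parts$test, cl)
    expect_equal(ev$metrics$accuracy, 1, label = paste(cl, "accuracy"))
    expect_equal(ev$metrics$auc, 1, label = paste(cl, "auc"))
  }
})

test_that("labels independent of features give chance-level AUC", {
  set.seed(21)
  tb <- tibble::tibble(class = sample(c("p", "e"), 2000, replace = TRUE),
                       `cap-diameter` = rnorm(2000),
                       `cap-color` = sample(c("n", "w", "y"), 2000, replace = TRUE))
  enc <- encode(tb)
  parts <- split_dataset(enc, split_spec(seed = 9))
  ev <- classify_and_score(parts$train, parts$test, "logistic-regression")
  expect_equal(ev$metrics$auc, 0.5, tolerance = 0.05)
})

test_that("a probability of exactly 0.5 is classified poisonous", {
  m <- mushroomsim:::score_predictions(c(0.5, 0.49), c(1, 0))
  expect_equal(m$accuracy, 1)   # 0.5 -> p (true), 0.49 -> e (true)
  m2 <- mushroomsim:::score_predictions(c(0.5, 0.5), c(0, 1))
  expect_equal(m2$accuracy, 0.5)
})

test_that("single-class training labels are rejected", {
  enc <- encode(tibble::tibble(class = rep("p", 10), `cap-diameter` = rnorm(10)))
  expect_error(classify_and_score(enc, enc, "lda"),
               class = "mushroomsim_fit_error")
})

test_that("cross-validation aggregates per-fold metrics; sd is 0 when separable", {
  enc <- encode(toy_separated(200))
  cv <- crossval(enc, split_spec(seed = 13), "lda")
  expect_setequal(unique(cv$metric), c("accuracy", "precision", "recall", "f2", "auc"))
  acc <- cv[cv$metric == "accuracy", ]
  expect_equal(acc$mean, 1)
  expect_equal(acc$sd, 0)
  folds <- attr(cv, "folds")
  expect_equal(nrow(folds), 5)
  expect_identical(crossval(enc, split_spec(seed = 13), "lda"), cv)
})

test_that("tidy, glance and autoplot work on evaluation objects", {
  enc <- encode(toy_separated(120))
  rep <- evaluate_classifiers(enc, split_spec(seed = 2),
                              classifiers = c("lda", "random-forest"))
  td <- generics::tidy(rep)
  expect_true(all(c("classifier", "metric", "value") %in% names(td)))
  expect_equal(nrow(generics::glance(rep)), 2)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  ev <- rep$evals[["lda"]]
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  expect_equal(nrow(generics::glance(ev)), 1)
})

test_that("direct mapping aligns identical schemas and applies both policies", {
  a <- tibble::tibble(x = 1:2, y = 3:4)
  b <- tibble::tibble(x = 5:6, y = 7:8)
  out <- direct_mapping(a, b)
  expect_identical(out$a, a)
  expect_identical(out$b, b)

  b2 <- tibble::tibble(x = 5:6, z = 9:10)
  zf <- direct_mapping(a, b2, policy = "zero_fill")
  expect_identical(names(zf$a), names(zf$b))
  expect_equal(zf$a$z, c(0, 0))          # zero column added
  expect_equal(zf$b$y, c(0, 0))

  rn <- direct_mapping(a, b2, policy = "rename", renames = c(z = "y"))
  expect_identical(sort(names(rn$b)), c("x", "y"))
  expect_equal(rn$b$y, c(9, 10))         # merged under the target name

  expect_error(direct_mapping(a, b2, policy = "rename",
                              renames = c(z = "w", w = "z")),
               class = "mushroomsim_config_error")
})
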