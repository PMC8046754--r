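test_that("the default covariance factors to the reference lower Cholesky", {
  m <- covariance_model()
  expect_equal(unname(round(m$chol, 2)),
               matrix(c(1, 0, 0,
                        0.5, 0.87, 0,
                        0.5, 0.52, 0.69), nrow = 3, byrow = TRUE))
  expect_lt(max(abs(m$chol %*% t(m$chol) - m$cov)), 1e-12)
})

test_that("cholesky_lower handles identity, closed-form 2x2 and rejects non-PSD", {
  expect_equal(cholesky_lower(diag(3)), diag(3))
  r <- 0.999
  L <- cholesky_lower(matrix(c(1, r, r, 1), 2))
  expect_equal(unname(L), matrix(c(1, 0, r, sqrt(1 - r^2)), 2, byrow = TRUE),
               tolerance = 1e-12)
  bad <- matrix(c(1, 2, 2, 1), 2)      # eigenvalue -1
  expect_error(cholesky_lower(bad), "eigenvalue",
               class = "mushroomsim_decomposition_error")
})

test_that("correlated draws recover the model correlations", {
  set.seed(101)
  z <- sample_correlated_normals(100000)
  emp <- cor(z)
  expect_lt(abs(emp[1, 2] - 0.5), 0.01)
  expect_lt(abs(emp[1, 3] - 0.5), 0.01)
  expect_lt(abs(emp[2, 3] - 0.7), 0.01)
  set.seed(102)
  iid <- sample_correlated_normals(100000, diag(3))
  expect_lt(max(abs(cor(iid)[upper.tri(diag(3))])), 0.01)
})

test_that("rescaling maps the normal band onto the interval as specified", {
  expect_equal(rescale_to_range(0, c(10, 20)), 15)       # midpoint
  expect_equal(rescale_to_range(3, c(10, 20)), 20)       # 3-sigma edge
  expect_equal(rescale_to_range(-3, c(10, 20)), 10)
  expect_equal(rescale_to_range(1, c(10, 20), "half_shift"), 20)
  expect_equal(rescale_to_range(0.2, c(5, 5)), 5)        # degenerate interval
  set.seed(103)
  z <- rnorm(1e6)
  x3 <- rescale_to_range(z, c(10, 20))
  expect_equal(mean(x3 >= 10 & x3 <= 20), 0.997, tolerance = 5e-4)
  xl <- rescale_to_range(z, c(10, 20), "half_shift")
  # the literal transform covers the interval with only ~68.3% probability
  expect_equal(mean(xl >= 10 & xl <= 20), 2 * pnorm(1) - 1, tolerance = 2e-3)
  # out-of-interval draws are kept, not clipped
  expect_gt(max(x3), 20)
})

test_that("resized samples are centred on the unit-interval midpoint", {
  set.seed(104)
  z <- rnorm(1e5)
  expect_equal(mean(rescale_to_range(z, c(0, 1))), 0.5, tolerance = 0.005)
  expect_equal(mean(rescale_to_range(z, c(0, 1), "half_shift")), 0.5,
               tolerance = 0.005)
})

test_that("species simulation respects sets, intervals and carried-over classes", {
  sch <- mushroom_schema("primary")
  rec <- tibble::tibble(family = "Amanita Family", name = "Fly Agaric", class = "p")
  for (v in attribute_names(sch)) rec[[v]] <- list(character(0))
  rec[["cap-shape"]] <- list(c("x", "f"))
  rec[["season"]] <- list(c("u", "a", "w"))
  rec[["veil-type"]] <- list("u")
  rec[["cap-diameter"]] <- list(c(min = 10, max = 20))
  rec[["stem-height"]] <- list(c(min = 10, max = 20))
  rec[["stem-width"]] <- list(c(min = 10, max = 25))

  set.seed(7)
  entries <- simulate_species(rec, simulation_config(n_per_species = 10))
  expect_equal(nrow(entries), 10)
  expect_true(all(entries[["cap-shape"]] %in% c("x", "f")))
  expect_true(all(entries[["cap-diameter"]] >= 10 & entries[["cap-diameter"]] <= 20))
  expect_true(all(entries[["veil-type"]] == "u"))      # singleton set
  expect_true(all(entries$class == "p"))
  expect_true(all(is.na(entries[["habitat"]])))        # missing set stays missing

  # uniform sampling law over a 2-code set
  rec2 <- rec
  rec2[["cap-surface"]] <- list(c("g", "h"))
  set.seed(8)
  big <- simulate_species(rec2, simulation_config(n_per_species = 100000))
  expect_equal(mean(big[["cap-surface"]] == "g"), 0.5, tolerance = 0.01)

  # stemless species simulate stem values of exactly 0
  rec3 <- rec
  rec3[["stem-height"]] <- list(NULL)
  rec3[["stem-width"]] <- list(NULL)
  set.seed(9)
  stemless <- simulate_species(rec3, simulation_config(n_per_species = 5))
  expect_true(all(stemless[["stem-height"]] == 0))
  expect_true(all(stemless[["stem-width"]] == 0))

  # a species with no cap range should have been excluded upstream
  rec4 <- rec
  rec4[["cap-diameter"]] <- list(NULL)
  expect_error(simulate_species(rec4, simulation_config(n_per_species = 2)),
               class = "mushroomsim_simulation_error")
})

test_that("one correlated triple is shared within each simulated entry", {
  rec <- tibble::tibble(family = "F", name = "S", class = "e")
  sch <- mushroom_schema("primary")
  for (v in attribute_names(sch)) rec[[v]] <- list(character(0))
  for (v in c("cap-diameter", "stem-height", "stem-width")) {
    rec[[v]] <- list(c(min = 0, max = 10))
  }
  set.seed(11)
  ent <- simulate_species(rec, simulation_config(n_per_species = 50000))
  expect_equal(cor(ent[["stem-height"]], ent[["stem-width"]]), 0.7,
               tolerance = 0.02)
  expect_equal(cor(ent[["cap-diameter"]], ent[["stem-height"]]), 0.5,
               tolerance = 0.02)
})

test_that("table simulation counts, balance and determinism hold", {
  pt <- small_primary(seed = 23, n_species = 6, n_families = 2)
  cfg <- simulation_config(n_per_species = 7, seed = 99)
  sec <- simulate_table(pt, cfg)
  expect_equal(nrow(sec), 6 * 7)
  expect_identical(simulate_table(pt, cfg), sec)
  # per-species class balance of output equals species-level balance exactly
  expect_equal(class_balance(sec)$ratio_p, class_balance(pt)$ratio_p)
  one <- simulate_table(pt[1, ], simulation_config(n_per_species = 1, seed = 3))
  expect_equal(nrow(one), 1)
})

test_that("adding a species does not perturb earlier species' draws", {
  pt <- small_primary(seed = 29, n_species = 6, n_families = 2)
  cfg <- simulation_config(n_per_species = 5, seed = 42)
  first5 <- simulate_table(pt[1:5, ], cfg)
  all6 <- simulate_table(pt, cfg)
  expect_identical(all6[seq_len(nrow(first5)), ], first5)
})
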