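fit_two_var_model <- function(seed = 61, informative = "a", n_bg = 400,
                              n_pres = 80, beta = 1) {
  withr::with_seed(seed, {
    bg <- tibble::tibble(a = rnorm(n_bg), b = rnorm(n_bg))
    pr <- bg[sample.int(n_bg, n_pres, prob = exp(2 * bg[[informative]])), ]
  })
  fit_maxent(pr, bg, beta = beta, classes = "L")
}

test_that("permutation importance isolates the informative variable", {
  m <- fit_two_var_model()
  imp <- permutation_importance(m, n_repeats = 10, seed = 1)
  expect_equal(sum(imp$importance), 100, tolerance = 1e-6)
  # the noise variable b typically gets a zero coefficient under the lasso;
  # if it does, its importance is exactly 0 and a carries 100
  if (unname(m$lambda["b"]) == 0) {
    expect_equal(imp$importance[imp$variable == "b"], 0)
    expect_equal(imp$importance[imp$variable == "a"], 100)
  } else {
    expect_gt(imp$importance[imp$variable == "a"], 90)
  }
})

test_that("two symmetric variables share importance about equally", {
  set.seed(62)
  bg <- tibble::tibble(a = rnorm(600), b = rnorm(600))
  pr <- bg[sample.int(600, 150, prob = exp(bg$a + bg$b)), ]
  m <- fit_maxent(pr, bg, beta = 0.5, classes = "L")
  imp <- permutation_importance(m, n_repeats = 20, seed = 3)
  expect_lt(abs(diff(imp$importance)), 20)
})

test_that("importance is reproducible and invariant to relabeling uninvolved variables", {
  m1 <- fit_two_var_model(seed = 63)
  i1 <- permutation_importance(m1, n_repeats = 5, seed = 9)
  i2 <- permutation_importance(m1, n_repeats = 5, seed = 9)
  expect_identical(i1, i2)

  # identical data with the noise variable renamed
  withr::with_seed(63, {
    bg <- tibble::tibble(a = rnorm(400), zz = rnorm(400))
    pr <- bg[sample.int(400, 80, prob = exp(2 * bg$a)), ]
  })
  m2 <- fit_maxent(pr, bg, beta = 1, classes = "L")
  i3 <- permutation_importance(m2, n_repeats = 5, seed = 9)
  expect_equal(i3$importance, i1$importance)
})

test_that("a flat model yields uniform flagged importances", {
  set.seed(64)
  bg <- tibble::tibble(a = rnorm(100), b = rnorm(100))
  m <- fit_maxent(bg[1:20, ], bg, beta = 1e6, classes = "L")
  imp <- permutation_importance(m, n_repeats = 3, seed = 1)
  expect_true(attr(imp, "flat"))
  expect_equal(imp$importance, c(50, 50))
})

test_that("marginal response curves match the model's closed form", {
  set.seed(65)
  bg <- tibble::tibble(a = rnorm(300), b = rnorm(300))
  pr <- bg[sample.int(300, 70, prob = exp(-(bg$a - 1)^2)), ]
  m <- fit_maxent(pr, bg, beta = 0.5, classes = "LQ", tol = 1e-8)
  curve <- marginal_response(m, "a", n_points = 50, type = "raw")

  # hand computation from the expansion metadata and coefficients
  meta <- m$expansion$meta
  med_b <- median(m$background$b)
  vals <- seq(min(bg$a), max(bg$a), length.out = 50)
  hand <- vapply(vals, function(v) {
    raw <- c(v, med_b, v^2, med_b^2)  # features: a, b, a^2, b^2
    scaled <- (raw - meta$fmin) / (meta$fmax - meta$fmin)
    exp(sum(m$lambda * scaled) - m$normalizer)
  }, 0)
  expect_equal(curve$suitability, hand, tolerance = 1e-12)
  expect_equal(curve$value, vals)

  # all-zero model: constant curve
  m0 <- fit_maxent(pr, bg, beta = 1e6, classes = "L")
  expect_equal(sd(marginal_response(m0, "a")$suitability), 0)
})

test_that("response classification applies the signed rho rule", {
  up <- tibble::tibble(value = 1:10, suitability = (1:10)^2)
  expect_equal(classify_response(up)$class, "positive")
  down <- tibble::tibble(value = 1:10, suitability = rev(1:10))
  expect_equal(classify_response(down)$class, "negative")

  # symmetric hump on a symmetric grid: rho = 0 by antisymmetry
  v <- seq(-1, 1, length.out = 101)
  hump <- tibble::tibble(value = v, suitability = 1 - v^2)
  cl <- classify_response(hump)
  expect_equal(cl$class, "none")
  expect_lt(abs(cl$rho), 0.1)

  flat <- tibble::tibble(value = 1:5, suitability = rep(1, 5))
  expect_equal(classify_response(flat)$class, "none")
})

test_that("classification is invariant to the suitability transform", {
  m <- fit_two_var_model(seed = 66)
  for (v in c("a", "b")) {
    raw_cl <- classify_response(marginal_response(m, v, type = "raw"))
    cll_cl <- classify_response(marginal_response(m, v, type = "cloglog"))
    expect_equal(raw_cl$class, cll_cl$class)
    expect_equal(raw_cl$rho, cll_cl$rho)
  }
})

test_that("variables absent from the model are classed none without a rho", {
  m <- fit_two_var_model(seed = 67)
  if (unname(m$lambda["b"]) == 0) {
    resp <- classify_responses(m)
    row_b <- resp[resp$variable == "b", ]
    expect_equal(row_b$class, "none")
    expect_false(row_b$in_model)
    expect_true(is.na(row_b$rho))
  }
  # informative variable must be classified with a rho
  resp <- classify_responses(m)
  expect_false(is.na(resp$rho[resp$variable == "a"]))
})

test_that("category sums partition the importance total", {
  vars <- tibble::tibble(
    variable = c("crop", "pasture", "soil_sand", "bio1"),
    category = c("land_use", "land_use", "soil", "climate")
  )
  imp1 <- tibble::tibble(variable = "bio1", importance = 100)
  s1 <- sum_by_category(imp1, vars)
  expect_equal(s1$importance[s1$category == "climate"], 100)
  expect_equal(sum(s1$importance), 100)

  imp2 <- tibble::tibble(variable = c("crop", "pasture", "soil_sand"),
                         importance = rep(100 / 3, 3))
  s2 <- sum_by_category(imp2, vars)
  expect_equal(s2$importance[s2$category == "land_use"], 200 / 3)
  expect_equal(s2$importance[s2$category == "soil"], 100 / 3)

  # recount oracle on a random table
  set.seed(68)
  imp3 <- tibble::tibble(variable = vars$variable, importance = runif(4))
  imp3$importance <- 100 * imp3$importance / sum(imp3$importance)
  s3 <- sum_by_category(imp3, vars)
  for (cat in c("land_use", "climate", "soil")) {
    expect_equal(s3$importance[s3$category == cat],
                 sum(imp3$importance[vars$category[match(imp3$variable, vars$variable)] == cat]))
  }
  expect_error(sum_by_category(tibble::tibble(variable = "zz", importance = 1),
                               vars), "uncategorized")
})
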