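test_that("spatial blocks are the median quadrants and translation-invariant", {
  pts <- tibble::tibble(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10))
  b <- make_spatial_blocks(pts)
  expect_setequal(b$fold, 1:4)

  set.seed(51)
  grid <- tidyr::expand_grid(x = seq(0, 900, 100), y = seq(0, 900, 100))
  g <- make_spatial_blocks(grid)
  sizes <- table(g$fold)
  expect_equal(length(sizes), 4)
  # quadrant sizes are balanced up to median-line ties
  expect_lte(max(sizes) - min(sizes), nrow(grid) / 4)
  # recount oracle
  mx <- median(grid$x); my <- median(grid$y)
  expect_equal(sum(g$fold == 1), sum(grid$x <= mx & grid$y <= my))
  expect_equal(sum(g$fold == 4), sum(grid$x > mx & grid$y > my))

  shifted <- make_spatial_blocks(dplyr::mutate(grid, x = x + 5000, y = y - 1e4))
  expect_identical(shifted$fold, g$fold)

  expect_error(make_spatial_blocks(tibble::tibble(x = rep(1, 5), y = rep(2, 5))),
               "identical")
})

test_that("rank AUC matches pair counting with half ties", {
  expect_equal(auc_rank(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(auc_rank(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  expect_equal(auc_rank(c(0.8, 0.3), c(0.5, 0.2)), 0.75)  # 3 of 4 concordant

  # pair-counting oracle on random scores with ties
  set.seed(52)
  p <- sample(seq(0, 1, 0.1), 25, replace = TRUE)
  b <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
  pairs <- outer(p, b, function(a, c) (a > c) + 0.5 * (a == c))
  expect_equal(auc_rank(p, b), mean(pairs))

  # antisymmetry
  expect_equal(auc_rank(p, b) + auc_rank(b, p), 1)
})

test_that("Boyce index ranks habitat use as designed", {
  set.seed(53)
  area <- runif(3000)
  # presences concentrated in the top suitability decile
  top <- runif(400, 0.9, 1)
  expect_gt(boyce_index(top, area), 0.9)

  # presences drawn uniformly from the area scores: near zero
  unif <- sample(area, 1000)
  expect_lt(abs(boyce_index(unif, area)), 0.3)

  # reversing the suitability ranking flips the sign
  b1 <- boyce_index(top, area)
  b2 <- boyce_index(1 - top, 1 - area)
  expect_equal(b2, -b1, tolerance = 0.05)

  # degenerate constant suitabilities are flagged missing
  flat <- boyce_index(rep(0.5, 10), rep(0.5, 100))
  expect_true(is.na(flat))
  expect_true(attr(flat, "degenerate"))
})

test_that("omission rates follow the MTP and ceiling-rule 10% thresholds", {
  tr <- (1:10) / 10
  expect_equal(omission_rates(tr, tr)$or_mtp, 0)
  r <- omission_rates(tr, 0.05)
  expect_equal(r$or_mtp, 1)
  expect_equal(r$or_10, 1)
  # threshold excludes ceiling(0.1 n) lowest training scores
  r2 <- omission_rates(tr, c(0.15, 0.25))
  expect_equal(r2$or_10, 0.5)  # threshold = 0.2; only 0.15 omitted

  set.seed(54)
  tr_big <- runif(5000)
  ev <- runif(5000)
  expect_lt(abs(omission_rates(tr_big, ev)$or_10 - 0.1), 0.02)
})

test_that("AICc follows the standardised-score formula", {
  set.seed(55)
  st <- make_stack(tibble::tibble(a = rnorm(100), b = rnorm(100)), 10, 10)
  bg <- sample_background(st, 60, seed = 1)
  pr <- tibble::as_tibble(st)[sample.int(100, 12, prob = exp(st$a)), ]
  m <- fit_maxent(pr, bg, beta = 1, classes = "L")
  a <- aicc_maxent(m, pr, st)

  # hand recomputation from raw scores and the AICc formula
  raw_grid <- predict(m, tibble::as_tibble(st), type = "raw")
  raw_pres <- predict(m, pr, type = "raw")
  k <- n_nonzero(m)
  n <- nrow(pr)
  logl <- sum(log(raw_pres / sum(raw_grid)))
  expect_equal(a, 2 * k - 2 * logl + 2 * k * (k + 1) / (n - k - 1))

  # uniform model: logL = -n log N, k = 0
  m0 <- fit_maxent(pr, bg, beta = 1e6, classes = "L")
  expect_equal(aicc_maxent(m0, pr, st), 2 * nrow(pr) * log(nrow(st)))

  # k >= n - 1 is undefined
  tiny <- pr[1:2, ]
  expect_true(is.na(aicc_maxent(m, tiny, st)))
})

test_that("candidate selection matches a brute-force scan with tie-breaks", {
  r1 <- tibble::tibble(candidate = 1:2, aicc = c(100, 102), or_10 = c(0.3, 0.1),
                       n_nonzero = c(3, 3), beta = c(1, 2))
  expect_equal(select_best(r1)$candidate, 1)

  r2 <- tibble::tibble(candidate = 1:2, aicc = c(100, 100), or_10 = c(0.2, 0.1),
                       n_nonzero = c(3, 3), beta = c(1, 2))
  expect_equal(select_best(r2)$candidate, 2)

  set.seed(56)
  for (i in 1:10) {
    rep <- tibble::tibble(
      candidate = 1:20,
      aicc = sample(c(100, 105, 110), 20, replace = TRUE),
      or_10 = sample(c(0.1, 0.2), 20, replace = TRUE),
      n_nonzero = sample(2:6, 20, replace = TRUE),
      beta = sample(1:5, 20, replace = TRUE)
    )
    rep$aicc[sample.int(20, 2)] <- NA  # undefined candidates excluded
    chosen <- select_best(rep)
    # naive scan oracle
    valid <- rep[!is.na(rep$aicc), ]
    best <- valid[valid$aicc == min(valid$aicc), ]
    best <- best[best$or_10 == min(best$or_10), ]
    best <- best[best$n_nonzero == min(best$n_nonzero), ]
    best <- best[best$beta == min(best$beta), ]
    expect_equal(chosen$candidate, best$candidate[1])
  }
  expect_error(select_best(tibble::tibble(aicc = NA_real_, or_10 = 1,
                                          n_nonzero = 1, beta = 1)), "AICc")
})

test_that("tuning evaluates candidates under spatial-block cross-validation", {
  set.seed(57)
  st <- generate_landscape(seed = 3, nx = 40, ny = 40, n_landuse = 4,
                           n_soil = 3)
  truth <- niche_truth("sp", "climate_specialist",
                       quadratic = list(bio1 = list(
                         optimum = mean(st$bio1) + 1.5 * sd(st$bio1),
                         curvature = 2)),
                       prevalence = 0.1)
  occ <- generate_species(truth, st, 40, seed = 5)
  pres <- extract_env(st, occ)
  bg <- sample_background(st, 400, seed = 2)
  tuned <- tune_maxent(pres, bg, st,
                       grid = tuning_grid(beta = c(1, 4), classes = "LQ"),
                       tol = 1e-5)
  expect_equal(nrow(tuned$report), 2)
  expect_true(all(tuned$report$test_auc >= 0 & tuned$report$test_auc <= 1))
  expect_true(all(tuned$report$or_mtp >= 0 & tuned$report$or_mtp <= 1))
  expect_true(all(is.finite(tuned$report$aicc)))
  expect_true(all(tuned$report$boyce >= -1 & tuned$report$boyce <= 1,
                  na.rm = TRUE))
  # the final model uses every presence while metrics come from CV
  expect_equal(nrow(tuned$models[[1]]$presences), nrow(pres))
  chosen <- select_best(tuned$report)
  expect_true(chosen$candidate %in% 1:2)
})
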