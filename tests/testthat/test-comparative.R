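test_that("extent of occurrence equals hull area and handles degeneracy", {
  sq <- tibble::tibble(x = c(0, 1e4, 1e4, 0), y = c(0, 0, 1e4, 1e4))
  expect_equal(as.numeric(extent_of_occurrence(sq)), 100)

  line <- tibble::tibble(x = c(0, 5e3, 1e4), y = c(0, 5e3, 1e4))
  e <- extent_of_occurrence(line)
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "degenerate"))

  expect_equal(as.numeric(extent_of_occurrence(sq[1:2, ])), 0)

  # gift-wrapping + shoelace oracle on random point sets
  set.seed(71)
  for (i in 1:5) {
    pts <- tibble::tibble(x = runif(50, 0, 5e4), y = runif(50, 0, 5e4))
    expect_equal(as.numeric(extent_of_occurrence(pts)),
                 brute_hull_area_km2(pts$x, pts$y), tolerance = 1e-10)
  }
})

test_that("EOO is rigid-motion invariant and scales quadratically", {
  set.seed(72)
  pts <- tibble::tibble(x = runif(30, 0, 2e4), y = runif(30, 0, 2e4))
  e0 <- as.numeric(extent_of_occurrence(pts))
  th <- 0.7
  rot <- tibble::tibble(x = cos(th) * pts$x - sin(th) * pts$y + 1e5,
                        y = sin(th) * pts$x + cos(th) * pts$y - 3e4)
  expect_equal(as.numeric(extent_of_occurrence(rot)), e0, tolerance = 1e-10)
  expect_equal(as.numeric(extent_of_occurrence(
    dplyr::mutate(pts, x = 3 * x, y = 3 * y))), 9 * e0, tolerance = 1e-10)
})

test_that("climate deviation is the z-distance of the species mean", {
  # 9-cell grid with hand-computable values
  vals <- tibble::tibble(bio1 = c(4, 6, 8, 10, 10, 10, 12, 14, 16))
  st <- make_stack(vals, nx = 3, ny = 3)
  obs <- vals[c(7, 8, 9), , drop = FALSE]  # species mean = 14
  d <- climate_deviation(obs, st)
  expect_equal(d$deviation, abs(14 - mean(vals$bio1)) / sd(vals$bio1))

  # arithmetic example: national mean 10, sd 2, species mean 13 -> 1.5
  v2 <- tibble::tibble(bio1 = c(8, 12, 8, 12))  # mean 10
  st2 <- make_stack(dplyr::mutate(v2, bio1 = (bio1 - 10) / sd(v2$bio1) * 2 + 10),
                    nx = 2, ny = 2)
  obs2 <- tibble::tibble(bio1 = c(13, 13))
  expect_equal(climate_deviation(obs2, st2)$deviation, 1.5)

  # species at the national mean deviates by zero; signed keeps direction
  obs0 <- tibble::tibble(bio1 = rep(mean(vals$bio1), 4))
  expect_equal(climate_deviation(obs0, st)$deviation, 0)
  ds <- climate_deviation(obs, st, signed = TRUE)
  expect_gt(ds$deviation, 0)

  # affine rescaling of the variable leaves the deviation unchanged
  st_f <- make_stack(dplyr::mutate(vals, bio1 = bio1 * 9 / 5 + 32), 3, 3)
  obs_f <- dplyr::mutate(obs, bio1 = bio1 * 9 / 5 + 32)
  expect_equal(climate_deviation(obs_f, st_f)$deviation, d$deviation)
})

test_that("two-group rank-sum test reproduces exact enumeration", {
  r <- compare_two_groups(c(1, 2, 3, 4, 5, 6), rep(c("LC", "RL"), each = 3))
  expect_equal(r$p_value, 0.1)  # 2/20 orderings as or more extreme, doubled

  # identical groups: p = 1
  same <- compare_two_groups(c(1, 2, 5, 1, 2, 5), rep(c("LC", "RL"), each = 3))
  expect_gte(same$p_value, 0.99)

  # a huge shift reaches the exact minimum two-sided p for n1 = n2 = 4
  big <- compare_two_groups(c(1:4, 101:104), rep(c("LC", "RL"), each = 4))
  expect_equal(big$p_value, 2 / choose(8, 4))

  # all tied values
  tied <- compare_two_groups(rep(7, 8), rep(c("LC", "RL"), each = 4))
  expect_equal(tied$p_value, 1)

  # monotone-transform invariance of the rank test
  set.seed(73)
  v <- c(rnorm(12, 0), rnorm(12, 1))
  g <- rep(c("LC", "RL"), each = 12)
  expect_equal(compare_two_groups(exp(v), g)$p_value,
               compare_two_groups(v, g)$p_value)
})

test_that("Kruskal-Wallis with Dunn post hoc flags planted shifts", {
  set.seed(74)
  null <- kw_dunn(c(rnorm(30), rnorm(30)), rep(c("a", "b"), each = 30))
  expect_lt(null$kruskal$chi_squared, 4)
  expect_gt(null$kruskal$p_value, 0.05)

  x <- c(rnorm(50), rnorm(50), rnorm(50) + 1.5)
  g <- rep(c("a", "b", "c"), each = 50)
  kd <- kw_dunn(x, g)
  expect_lt(kd$kruskal$p_value, 0.001)
  sig <- kd$dunn$p_adjusted < 0.05
  pair <- paste(kd$dunn$group1, kd$dunn$group2)
  expect_false(sig[pair == "a b"])
  expect_true(all(sig[pair %in% c("a c", "b c")]))

  expect_error(kw_dunn(1:3, factor(c("a", "a", "a"), levels = c("a", "b"))),
               "empty")
})

test_that("Holm adjustment matches the step-down hand computation", {
  # sorted p: .01*3 = .03; .03*2 = .06; .04*1 = .04 -> cummax -> .06
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  kd <- kw_dunn(c(rnorm(20), rnorm(20) + 9, rnorm(20) + 0.5),
                rep(c("a", "b", "c"), each = 20))
  expect_equal(kd$dunn$p_adjusted, p.adjust(kd$dunn$p_value, "holm"))
})

test_that("CMH reduces to the continuity-corrected statistic on one stratum", {
  counts <- tibble::tibble(
    variable = "crop",
    status = rep(c("LC", "RL"), each = 2),
    response = rep(c("positive", "negative"), 2),
    n = c(12, 5, 7, 11)
  )
  res <- cmh_response_ratio(counts)
  # hand computation: (|a - E| - 1/2)^2 / V with hypergeometric E and V
  a <- 12; r1 <- 17; r2 <- 18; c1 <- 19; c2 <- 16; n <- 35
  e <- r1 * c1 / n
  v <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  expect_equal(res$cmh$chi_squared, (abs(a - e) - 0.5)^2 / v)
  expect_equal(res$fisher$p_value, fisher.test(matrix(c(12, 7, 5, 11), 2))$p.value)
})

test_that("Fisher post hoc and degenerate strata are handled", {
  # [[3,0],[0,3]]: hypergeometric enumeration gives two-sided p = 0.1
  counts <- tibble::tibble(
    variable = rep(c("v1", "v2"), each = 4),
    status = rep(rep(c("LC", "RL"), each = 2), 2),
    response = rep(c("positive", "negative"), 4),
    n = c(3, 0, 0, 3, 10, 10, 10, 10)
  )
  res <- cmh_response_ratio(counts)
  expect_equal(res$fisher$p_value[res$fisher$variable == "v1"], 0.1)

  # equal odds ratios of one: chi-squared near zero
  eq <- tibble::tibble(
    variable = rep(c("v1", "v2"), each = 4),
    status = rep(rep(c("LC", "RL"), each = 2), 2),
    response = rep(c("positive", "negative"), 4),
    n = c(10, 10, 10, 10, 8, 8, 8, 8)
  )
  expect_lt(cmh_response_ratio(eq)$cmh$chi_squared, 0.1)

  bad <- dplyr::mutate(counts, n = ifelse(variable == "v2", 0, n))
  expect_message(res2 <- cmh_response_ratio(bad), "degenerate")
  expect_equal(res2$cmh$n_strata, 1)
  expect_error(cmh_response_ratio(dplyr::mutate(counts, n = 0)), "degenerate")

  # independent route: stats::mantelhaen.test agrees on multi-stratum input
  set.seed(77)
  multi <- tidyr::expand_grid(variable = c("v1", "v2", "v3"),
                              status = c("LC", "RL"),
                              response = c("positive", "negative"))
  multi$n <- rpois(12, 10) + 1
  ours <- cmh_response_ratio(multi)
  arr <- array(0, c(2, 2, 3))
  for (i in 1:3) {
    d <- multi[multi$variable == paste0("v", i), ]
    arr[, , i] <- stats::xtabs(n ~ status + response, data = d)
  }
  ref <- stats::mantelhaen.test(arr, correct = TRUE)
  expect_equal(ours$cmh$chi_squared, unname(ref$statistic))
  expect_equal(ours$cmh$p_value, ref$p.value)
})

test_that("importance regression recovers planted coefficients", {
  set.seed(75)
  n <- 200
  eoo <- runif(n, 0, 60)
  status <- rep(c("LC", "RL"), each = n / 2)
  y <- 20 + 0.5 * eoo + 10 * (status == "RL") + rnorm(n)
  d <- tibble::tibble(landuse = y, eoo_km2 = eoo, status = status)
  fit <- importance_regression(d, "landuse")
  expect_equal(fit$chosen, "full")
  td <- tidy(fit)
  b1 <- td[td$term == "eoo", ]
  b2 <- td[td$term == "rl", ]
  expect_lt(abs(b1$estimate - 0.5), 1.96 * b1$std_error)
  expect_lt(abs(b2$estimate - 10), 1.96 * b2$std_error)
  # rank-based route agrees on the planted effects
  expect_equal(b1$estimate_rank, 0.5, tolerance = 0.05)
  expect_equal(b2$estimate_rank, 10, tolerance = 1)
  g <- glance(fit)
  expect_gt(g$r_squared, 0.9)
  expect_gt(g$r_squared_rank, 0.5)
  expect_lt(g$p_value, 1e-10)
  expect_lt(g$p_value_rank, 1e-6)
})

test_that("permuted status decouples the status coefficient", {
  set.seed(76)
  n <- 200
  cover <- 0
  for (rep in 1:100) {
    eoo <- runif(n, 0, 60)
    status <- sample(rep(c("LC", "RL"), each = n / 2))
    y <- 20 + 0.5 * eoo + rnorm(n)
    d <- tibble::tibble(imp = y, eoo_km2 = eoo, status = status)
    fit <- lm(imp ~ eoo_km2 + I(status == "RL"), data = d)
    ci <- confint(fit)[3, ]
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("zero-noise regression explains everything", {
  eoo <- seq(1, 50, length.out = 40)
  status <- rep(c("LC", "RL"), 20)
  d <- tibble::tibble(imp = 5 + 2 * eoo + 3 * (status == "RL"),
                      eoo_km2 = eoo, status = status)
  fit <- suppressWarnings(importance_regression(d, "imp"))
  expect_equal(suppressWarnings(glance(fit))$r_squared, 1)
  expect_equal(fit$chosen, "full")
})

test_that("mean location offsets are kilometre differences from the pooled mean", {
  occ <- tibble::tibble(
    species = rep(c("s1", "s2", "s3"), each = 2),
    x = c(0, 0, 1e4, 1e4, 2e4, 2e4),
    y = c(0, 0, 0, 0, 0, 5000 * 6)
  )
  off <- mean_location_offset(occ)
  # hand means: overall x = 1e4, overall y = 5000
  expect_equal(off$km_east, c(-10, 0, 10))
  expect_equal(off$km_north, c(-5, -5, 10))

  one <- mean_location_offset(tibble::tibble(species = "s", x = 0, y = 0),
                              reference = c(0, -5000))
  expect_equal(one$km_north, 5)
  expect_equal(one$km_east, 0)
})
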