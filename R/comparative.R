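#' Extent of occurrence (convex hull area)
#'
#' The Red List range metric: the area of the convex hull around a species'
#' observation points, in the planar CRS, converted to square kilometres.
#' Fewer than three distinct points, or collinear points, give area 0 (the
#' `degenerate` attribute flags it).
#'
#' @param points A data frame with columns `x`, `y` in metres.
#' @return EOO in km2 (scalar).
#' @export
extent_of_occurrence <- function(points) {
  points <- tibble::as_tibble(points)
  xy <- unique(points[, c("x", "y")])
  if (nrow(xy) < 3) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  h <- grDevices::chull(xy$x, xy$y)
  hx <- xy$x[h]
  hy <- xy$y[h]
  # shoelace formula
  n <- length(h)
  a <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
  out <- a / 1e6
  if (out == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Climatic extremeness of a species' observations
#'
#' For each bioclim variable: the species' mean value over its observation
#' cells, expressed as the number of landscape standard deviations it sits
#' away from the landscape mean over the whole (masked) study extent —
#' `|mean_obs - mean_landscape| / sd_landscape`. Set `signed = TRUE` to keep
#' the direction of the deviation.
#'
#' @param observations A data frame holding the climate variable values at
#'   the species' observation cells (e.g. from [extract_env()]).
#' @param stack An [env_stack()]; landscape mean and SD are taken over its
#'   masked cells.
#' @param variables Which climate variables; default every `climate`-category
#'   variable in the stack.
#' @param signed Keep the sign of the deviation (default FALSE, absolute).
#' @return A tibble (`variable`, `deviation`); zero-SD variables return `NA`
#'   with a `degenerate` attribute listing them.
#' @export
climate_deviation <- function(observations, stack, variables = NULL,
                              signed = FALSE) {
  vars <- env_vars(stack)
  if (is.null(variables)) {
    variables <- vars$variable[vars$category == "climate"]
  }
  missing <- setdiff(variables, names(observations))
  if (length(missing) > 0) {
    stop("variable(s) missing from observations: ",
         paste(missing, collapse = ", "))
  }
  landscape <- env_values(stack, variables)
  dev <- vapply(variables, function(v) {
    s <- stats::sd(landscape[[v]])
    if (s == 0) return(NA_real_)
    d <- (mean(observations[[v]]) - mean(landscape[[v]])) / s
    if (signed) d else abs(d)
  }, 0)
  out <- tibble::tibble(variable = variables, deviation = unname(dev))
  if (anyNA(dev)) attr(out, "degenerate") <- variables[is.na(dev)]
  out
}

#' Mean location offset of each species
#'
#' Per species, the offset (km east, km north) of its mean observation
#' location from the mean location of all observations pooled.
#'
#' @param occurrences A data frame with `species`, `x`, `y` (metres).
#' @param reference Optional reference point `c(x, y)`; default the pooled
#'   mean of all records.
#' @return A tibble (`species`, `km_east`, `km_north`).
#' @export
mean_location_offset <- function(occurrences, reference = NULL) {
  occurrences <- tibble::as_tibble(occurrences)
  if (is.null(reference)) {
    reference <- c(mean(occurrences$x), mean(occurrences$y))
  }
  occurrences |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      km_east = (mean(.data$x) - reference[1]) / 1000,
      km_north = (mean(.data$y) - reference[2]) / 1000,
      .groups = "drop"
    )
}

group_mean_se <- function(values, groups) {
  tibble::tibble(group = groups, value = values) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Two-group rank-sum comparison
#'
#' Two-sided Mann-Whitney (rank-sum) test of a per-species quantity between
#' two status groups, exact when both groups have at most 10 untied values,
#' otherwise the normal approximation with tie correction. All values tied
#' returns p = 1.
#'
#' @param values Numeric vector.
#' @param groups A two-level grouping vector aligned with `values`.
#' @return A one-row tibble: `test`, `statistic` (W for the first group
#'   level), `p_value`, plus group means and standard errors.
#' @export
compare_two_groups <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  stopifnot(length(g1) >= 2, length(g2) >= 2)
  if (stats::sd(values) == 0) {
    w <- length(g1) * length(g2) / 2
    p <- 1
  } else {
    exact <- length(g1) <= 10 && length(g2) <= 10 &&
      !any(duplicated(values))
    ht <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = exact, correct = !exact))
    w <- unname(ht$statistic)
    p <- ht$p.value
  }
  ms <- group_mean_se(values, groups)
  tibble::tibble(
    test = "rank-sum", statistic = w, p_value = p,
    group1 = levels(groups)[1], mean1 = ms$mean[1], se1 = ms$se[1],
    n1 = ms$n[1],
    group2 = levels(groups)[2], mean2 = ms$mean[2], se2 = ms$se[2],
    n2 = ms$n[2]
  )
}

#' Kruskal-Wallis test with Dunn's post hoc and Holm correction
#'
#' Kruskal-Wallis chi-squared with tie correction over all groups, followed
#' by pairwise Dunn z-tests on the pooled ranks; the family of pairwise
#' p-values is Holm-adjusted by default.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 non-empty groups).
#' @param holm Apply Holm's step-down adjustment to the Dunn p-values.
#' @return A list: `kruskal` (one-row tibble `chi_squared`, `df`, `p_value`)
#'   and `dunn` (one row per pair: `z`, `p_value`, `p_adjusted`, group means).
#' @export
kw_dunn <- function(values, groups, holm = TRUE) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  stopifnot(nlevels(groups) >= 2)
  kt <- stats::kruskal.test(values, groups)
  kruskal <- tibble::tibble(
    chi_squared = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value
  )

  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  dunn <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    na <- sum(groups == a)
    nb <- sum(groups == b)
    z <- (mean(r[groups == a]) - mean(r[groups == b])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
    tibble::tibble(group1 = a, group2 = b, z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  dunn$p_adjusted <- if (holm) stats::p.adjust(dunn$p_value, "holm") else dunn$p_value
  list(kruskal = kruskal, dunn = dunn)
}

#' Cochran-Mantel-Haenszel test of response ratios across variables
#'
#' Pools per-variable 2 x 2 tables of status (LC/RL) against response
#' direction (positive/negative) into a continuity-corrected CMH chi-squared,
#' asking whether the positive:negative response ratio differs between
#' groups consistently across variables. Each variable then gets a two-sided
#' Fisher's exact post-hoc test, Holm-adjusted across variables. Strata with
#' a degenerate margin (an all-zero row or column) are dropped with a
#' message; all degenerate is an error.
#'
#' @param counts A data frame with columns `variable`, `status`, `response`
#'   (`"positive"`/`"negative"`), `n`.
#' @return A list: `cmh` (one-row tibble) and `fisher` (per-variable tibble
#'   with `p_value`, `p_adjusted`, `odds_ratio`).
#' @export
cmh_response_ratio <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("variable", "status", "response", "n") %in% names(counts)))
  vars <- unique(counts$variable)
  tabs <- lapply(vars, function(v) {
    d <- counts[counts$variable == v, ]
    stats::xtabs(n ~ status + response, data = d)
  })
  ok <- vapply(tabs, function(t) {
    all(dim(t) == c(2, 2)) && all(rowSums(t) > 0) && all(colSums(t) > 0)
  }, TRUE)
  if (!any(ok)) stop("all strata degenerate")
  if (any(!ok)) {
    message("dropping degenerate strata: ", paste(vars[!ok], collapse = ", "))
  }
  # continuity-corrected CMH over 2x2 strata:
  # (|sum(a - E)| - 1/2)^2 / sum(V), hypergeometric E and V per stratum
  # (stats::mantelhaen.test requires >= 2 strata; this handles any K)
  dev <- 0
  vsum <- 0
  for (t in tabs[ok]) {
    n <- sum(t)
    e <- unname(rowSums(t)[1]) * unname(colSums(t)[1]) / n
    dev <- dev + (t[1, 1] - e)
    vsum <- vsum + prod(rowSums(t)) * prod(colSums(t)) / (n^2 * (n - 1))
  }
  chi <- (abs(dev) - 0.5)^2 / vsum
  mh <- list(statistic = chi, parameter = 1,
             p.value = stats::pchisq(chi, 1, lower.tail = FALSE))
  fisher <- purrr::map_dfr(which(ok), function(i) {
    ft <- stats::fisher.test(tabs[[i]])
    tibble::tibble(variable = vars[i], p_value = ft$p.value,
                   odds_ratio = unname(ft$estimate))
  })
  fisher$p_adjusted <- stats::p.adjust(fisher$p_value, "holm")
  list(
    cmh = tibble::tibble(chi_squared = unname(mh$statistic),
                         df = unname(mh$parameter), p_value = mh$p.value,
                         n_strata = sum(ok)),
    fisher = fisher
  )
}

#' Regress category importance on range size and Red List status
#'
#' Fits the three candidate formulas — importance ~ EOO, ~ status,
#' ~ EOO + status — by ordinary least squares and by rank-based
#' (R-estimation, Wilcoxon scores) regression, and picks the candidate with
#' the lowest Gaussian AICc of the parametric fit (k counts intercept,
#' slopes and the variance).
#'
#' @param summaries A data frame with one row per species holding the
#'   response column named by `response`, an `eoo_km2` column and a `status`
#'   column (two levels; RL is coded 1).
#' @param response Name of the importance column to model (e.g.
#'   `"landuse_importance"`).
#' @return An object of class `importance_regression`: the chosen formula,
#'   the OLS and rank-based fits of every candidate, coefficient tables and
#'   fit statistics. Use [tidy()]/[glance()] on it.
#' @export
importance_regression <- function(summaries, response) {
  d <- tibble::as_tibble(summaries)
  stopifnot(nrow(d) >= 10, all(c(response, "eoo_km2", "status") %in% names(d)))
  status <- factor(d$status)
  stopifnot(nlevels(status) == 2)
  dd <- tibble::tibble(
    y = d[[response]],
    eoo = d$eoo_km2,
    rl = as.numeric(status == if ("RL" %in% levels(status)) "RL" else levels(status)[2])
  )
  candidates <- list(
    eoo_only = y ~ eoo,
    status_only = y ~ rl,
    full = y ~ eoo + rl
  )
  ols <- lapply(candidates, function(f) stats::lm(f, data = dd))
  aicc <- vapply(ols, aicc_lm, 0)
  chosen <- names(candidates)[which.min(aicc)]
  rfits <- lapply(candidates, function(f) rank_regression(f, dd))

  structure(
    list(response = response, data = dd, candidates = names(candidates),
         ols = ols, rank = rfits, aicc = aicc, chosen = chosen),
    class = "importance_regression"
  )
}

aicc_lm <- function(fit) {
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1  # + residual variance
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.importance_regression <- function(x, ...) {
  cat("<importance_regression> response:", x$response, "\n")
  cat("  chosen formula (lowest AICc):", x$chosen, "\n")
  print(glance(x))
  invisible(x)
}

# Rank-based linear regression: minimises Jaeckel's dispersion with Wilcoxon
# scores; intercept from the median residual; inference via the usual
# tau-based asymptotics with tau from a kernel estimate of int f^2.
rank_regression <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(formula, data)[, -1, drop = FALSE]
  n <- length(y)
  p <- ncol(x)
  scores <- function(e) {
    sqrt(12) * (rank(e) / (n + 1) - 0.5)
  }
  dispersion <- function(b) {
    e <- y - x %*% b
    sum(scores(e) * e)
  }
  b0 <- stats::coef(stats::lm.fit(cbind(1, x), y))[-1]
  if (p == 1) {
    width <- 10 * max(abs(b0), stats::sd(y) / max(stats::sd(x), 1e-12))
    opt <- stats::optimize(dispersion, interval = b0 + c(-width, width),
                           tol = 1e-10)
    opt <- list(par = opt$minimum, value = opt$objective)
  } else {
    opt <- stats::optim(b0, dispersion, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-10))
  }
  beta <- opt$par
  e <- as.vector(y - x %*% beta)
  intercept <- stats::median(e)
  resid <- e - intercept

  tau <- tau_estimate(resid)
  # drop-in-dispersion test of all slopes against the intercept-only model
  d_full <- opt$value
  d_red <- dispersion_null(y)
  fr <- ((d_red - d_full) / p) / (tau / 2)
  p_model <- stats::pf(fr, p, n - p - 1, lower.tail = FALSE)
  # rank-based R^2 analogue: proportional dispersion reduction
  r2 <- 1 - d_full / d_red

  xc <- scale(x, scale = FALSE)
  xtx_inv <- solve(crossprod(xc))
  se <- tau * sqrt(diag(xtx_inv))
  list(coefficients = c("(Intercept)" = unname(intercept),
                        stats::setNames(as.vector(beta), colnames(x))),
       se = stats::setNames(se, colnames(x)),
       dispersion = d_full, r_squared = r2,
       statistic = fr, p_value = p_model, tau = tau, n = n)
}

dispersion_null <- function(y) {
  n <- length(y)
  a <- sqrt(12) * (rank(y) / (n + 1) - 0.5)
  sum(a * y)
}

# tau = 1 / (sqrt(12) * int f^2), with int f^2 from a Gaussian-kernel density
tau_estimate <- function(resid) {
  d <- stats::density(resid, n = 1024)
  int_f2 <- sum(d$y^2) * diff(d$x[1:2])
  1 / (sqrt(12) * int_f2)
}
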