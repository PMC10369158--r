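#' Feature expansion for maximum-entropy niche models
#'
#' Expands raw environmental values into the model's basis functions: linear
#' (L, identity), quadratic (Q, squares), product (P, pairwise products),
#' hinge (H, forward `max(0, x - k)` and reverse `max(0, k - x)` pieces at
#' `n_knots` knots per direction) and threshold (T, step functions `x > k` at
#' the same knots). Knots are evenly spaced strictly inside the training range
#' of each variable. Every feature is min-max rescaled to \[0, 1\] over the
#' training background, and prediction-time variable values are clamped to
#' the training range, so no feature extrapolates.
#'
#' @param x A data frame of raw variable values (the training background when
#'   building an expansion).
#' @param classes Feature classes, e.g. `"LQH"` or `c("L","Q","H")`; subset of
#'   L, Q, H, P, T.
#' @param n_knots Knots per variable per hinge direction (default 25).
#' @param variables Which columns of `x` to use; default all numeric columns.
#'
#' @return An object of class `maxent_features`: feature metadata, variable
#'   ranges and scaling constants. Use [expand_features()] to apply it.
#' @export
maxent_features <- function(x, classes = "LQH", n_knots = 25,
                            variables = NULL) {
  classes <- parse_classes(classes)
  x <- tibble::as_tibble(x)
  if (is.null(variables)) {
    variables <- names(x)[vapply(x, is.numeric, TRUE)]
    variables <- setdiff(variables, c("cell_id", "x", "y", "year"))
  }
  stopifnot(length(variables) > 0)
  xm <- as.matrix(x[, variables, drop = FALSE])
  rng <- tibble::tibble(
    variable = variables,
    min = apply(xm, 2, min),
    max = apply(xm, 2, max)
  )
  const <- rng$variable[rng$max == rng$min]
  if (length(const) > 0 && length(setdiff(classes, "l")) > 0) {
    warning("constant variable(s), nonlinear features dropped: ",
            paste(const, collapse = ", "))
  }

  meta <- list()
  if ("l" %in% classes) {
    meta$l <- tibble::tibble(type = "linear", var1 = variables,
                             var2 = NA_character_, knot = NA_real_)
  }
  if ("q" %in% classes) {
    meta$q <- tibble::tibble(type = "quadratic",
                             var1 = setdiff(variables, const),
                             var2 = NA_character_, knot = NA_real_)
  }
  if ("p" %in% classes && length(setdiff(variables, const)) >= 2) {
    vv <- setdiff(variables, const)
    pairs <- utils::combn(vv, 2)
    meta$p <- tibble::tibble(type = "product", var1 = pairs[1, ],
                             var2 = pairs[2, ], knot = NA_real_)
  }
  for (cls in intersect(c("h", "t"), classes)) {
    rows <- lapply(setdiff(variables, const), function(v) {
      r <- rng[rng$variable == v, ]
      knots <- seq(r$min, r$max, length.out = n_knots + 2)[-c(1, n_knots + 2)]
      if (cls == "h") {
        tibble::tibble(
          type = rep(c("hinge_fwd", "hinge_rev"), each = n_knots),
          var1 = v, var2 = NA_character_, knot = c(knots, knots))
      } else {
        tibble::tibble(type = "threshold", var1 = v, var2 = NA_character_,
                       knot = knots)
      }
    })
    meta[[cls]] <- dplyr::bind_rows(rows)
  }
  meta <- dplyr::bind_rows(meta)
  meta$feature <- feature_names(meta)

  expansion <- structure(
    list(meta = meta, ranges = rng, classes = classes, n_knots = n_knots,
         variables = variables),
    class = "maxent_features"
  )
  raw <- raw_features(expansion, xm)
  fmin <- apply(raw, 2, min)
  fmax <- apply(raw, 2, max)
  expansion$meta$fmin <- fmin
  expansion$meta$fmax <- fmax
  expansion$meta$active <- fmax > fmin
  expansion
}

parse_classes <- function(classes) {
  cls <- tolower(unlist(strsplit(classes, "")))
  cls <- unique(cls[cls %in% c("l", "q", "h", "p", "t")])
  if (length(cls) == 0) stop("no valid feature classes in ", deparse(classes))
  cls
}

feature_names <- function(meta) {
  ifelse(meta$type == "linear", meta$var1,
  ifelse(meta$type == "quadratic", paste0(meta$var1, "^2"),
  ifelse(meta$type == "product", paste0(meta$var1, ":", meta$var2),
         paste0(meta$type, "(", meta$var1, ",",
                formatC(meta$knot, format = "g", digits = 6), ")"))))
}

# unscaled feature values from a raw variable matrix
raw_features <- function(expansion, xm) {
  meta <- expansion$meta
  out <- matrix(0, nrow(xm), nrow(meta),
                dimnames = list(NULL, meta$feature))
  for (i in seq_len(nrow(meta))) {
    v1 <- xm[, meta$var1[i]]
    out[, i] <- switch(meta$type[i],
      linear = v1,
      quadratic = v1^2,
      product = v1 * xm[, meta$var2[i]],
      hinge_fwd = pmax(0, v1 - meta$knot[i]),
      hinge_rev = pmax(0, meta$knot[i] - v1),
      threshold = as.numeric(v1 > meta$knot[i])
    )
  }
  out
}

#' Apply a feature expansion to new data
#'
#' @param expansion A [maxent_features()] object.
#' @param newdata A data frame containing the expansion's variables.
#' @param clamp Clamp variable values to the training range (default TRUE).
#' @return A numeric matrix, one column per feature, values in \[0, 1\].
#' @export
expand_features <- function(expansion, newdata, clamp = TRUE) {
  newdata <- tibble::as_tibble(newdata)
  missing <- setdiff(expansion$variables, names(newdata))
  if (length(missing) > 0) {
    stop("unknown variable(s) in data: ", paste(missing, collapse = ", "))
  }
  xm <- as.matrix(newdata[, expansion$variables, drop = FALSE])
  if (clamp) {
    for (j in seq_along(expansion$variables)) {
      xm[, j] <- pmin(pmax(xm[, j], expansion$ranges$min[j]),
                      expansion$ranges$max[j])
    }
  }
  raw <- raw_features(expansion, xm)
  scale <- expansion$meta$fmax - expansion$meta$fmin
  scale[scale == 0] <- 1
  sweep(sweep(raw, 2, expansion$meta$fmin), 2, scale, "/")
}

# MaxEnt-style per-feature L1 smoothing: class base rate interpolated on the
# presence sample size, times the feature's presence SD on the 1/sqrt(m) scale.
default_regularization <- function(meta, fp) {
  m <- nrow(fp)
  interp <- function(xs, ys) stats::approx(xs, ys, xout = m, rule = 2)$y
  base <- c(
    linear = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    quadratic = interp(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product = interp(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.05)),
    hinge_fwd = 0.5,
    hinge_rev = 0.5,
    threshold = interp(c(0, 100), c(2, 1))
  )
  sdev <- apply(fp, 2, stats::sd)
  # floor avoids unpenalised separating features
  sdev <- pmax(sdev, 1 / sqrt(m))
  unname(base[meta$type]) * sdev / sqrt(m)
}

#' Fit a maximum-entropy niche model
#'
#' Fits the Gibbs distribution `p(x) proportional to exp(sum_j lambda_j f_j(x))`
#' over the background sample by maximising the L1-penalised log-likelihood
#'
#' `mean_presences(lambda . f) - log Z(lambda) - beta * sum_j s_j |lambda_j|`
#'
#' where `Z` normalises over the background and `s_j` are per-feature
#' smoothing weights with sample-size-dependent, feature-class-dependent
#' defaults in the style of MaxEnt's published defaults (see
#' `regularization`). Optimisation is accelerated proximal gradient (FISTA
#' with backtracking line search and adaptive restart) on the smooth part,
#' with soft-thresholding for the penalty; it runs to a relative objective
#' tolerance of `tol` or `max_iter` iterations, returning the best iterate
#' with `converged = FALSE` if the tolerance is not reached.
#'
#' @param presences,background Data frames of raw environmental values at
#'   presence and background points (any non-variable columns are ignored).
#' @param beta Regularization multiplier (the paper's 1..15 grid); larger
#'   values give sparser, smoother models.
#' @param classes Feature classes as in [maxent_features()].
#' @param n_knots Hinge/threshold knots per variable per direction.
#' @param variables Variable columns to use; default all shared numeric
#'   columns except coordinates/ids.
#' @param regularization Optional numeric vector overriding the per-feature
#'   smoothing `s_j` (recycled if length 1).
#' @param tol Relative convergence tolerance on the penalised objective.
#' @param max_iter Iteration cap.
#'
#' @return An object of class `maxent_model` with elements `expansion`,
#'   `lambda` (named coefficients), `beta`, `normalizer` (log partition over
#'   the training background), `entropy` (of the background distribution),
#'   `presences`, `background`, `converged`, `n_iter`.
#' @seealso [predict.maxent_model()], [tidy.maxent_model()],
#'   [glance.maxent_model()]
#' @export
fit_maxent <- function(presences, background, beta = 1, classes = "LQH",
                       n_knots = 25, variables = NULL, regularization = NULL,
                       tol = 1e-6, max_iter = 500) {
  stopifnot(nrow(presences) >= 1, nrow(background) >= 2, beta >= 0)
  expansion <- maxent_features(background, classes = classes,
                               n_knots = n_knots, variables = variables)
  fb <- expand_features(expansion, background)
  fp <- expand_features(expansion, presences)
  active <- expansion$meta$active
  if (!any(active)) stop("all features are constant over the background")

  s <- if (is.null(regularization)) {
    default_regularization(expansion$meta, fp)
  } else {
    rep_len(regularization, ncol(fb))
  }

  fit <- fit_gibbs_l1(fb[, active, drop = FALSE], fp[, active, drop = FALSE],
                      penalty = beta * s[active], tol = tol,
                      max_iter = max_iter)
  lambda <- stats::setNames(numeric(ncol(fb)), expansion$meta$feature)
  lambda[active] <- fit$lambda

  score_b <- as.vector(fb %*% lambda)
  normalizer <- logsumexp(score_b)
  p <- exp(score_b - normalizer)
  entropy <- -sum(ifelse(p > 0, p * log(p), 0))

  structure(
    list(
      expansion = expansion, lambda = lambda, beta = beta,
      regularization = s, normalizer = normalizer, entropy = entropy,
      presences = tibble::as_tibble(presences)[, expansion$variables,
                                               drop = FALSE],
      background = tibble::as_tibble(background)[, expansion$variables,
                                                 drop = FALSE],
      converged = fit$converged, n_iter = fit$n_iter
    ),
    class = "maxent_model"
  )
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# penalised Gibbs likelihood by FISTA; fb/fp are feature matrices in [0,1]
fit_gibbs_l1 <- function(fb, fp, penalty, tol = 1e-6, max_iter = 500) {
  cmean <- colMeans(fp)
  smooth_obj <- function(lam) {
    logsumexp(as.vector(fb %*% lam)) - sum(cmean * lam)
  }
  smooth_grad <- function(lam) {
    sc <- as.vector(fb %*% lam)
    p <- exp(sc - logsumexp(sc))
    as.vector(crossprod(fb, p)) - cmean
  }
  total_obj <- function(lam) smooth_obj(lam) + sum(penalty * abs(lam))
  soft <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

  j <- ncol(fb)
  lam <- numeric(j)
  z <- lam
  tt <- 1
  lip <- 1
  f_prev <- total_obj(lam)
  best <- list(lambda = lam, value = f_prev)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    g <- smooth_grad(z)
    fz <- smooth_obj(z)
    repeat {
      lam_new <- soft(z - g / lip, penalty / lip)
      dlt <- lam_new - z
      q <- fz + sum(g * dlt) + lip / 2 * sum(dlt^2)
      if (smooth_obj(lam_new) <= q + 1e-12) break
      lip <- lip * 2
      if (lip > 1e12) break
    }
    f_new <- total_obj(lam_new)
    if (f_new > f_prev) {            # adaptive restart
      z <- lam
      tt <- 1
      next
    }
    t_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
    z <- lam_new + ((tt - 1) / t_new) * (lam_new - lam)
    tt <- t_new
    if (f_new < best$value) best <- list(lambda = lam_new, value = f_new)
    if (abs(f_prev - f_new) <= tol * (abs(f_prev) + 1)) {
      lam <- lam_new
      converged <- TRUE
      break
    }
    lam <- lam_new
    f_prev <- f_new
    lip <- lip / 1.5
  }
  if (!converged) {
    lam <- best$lambda
  }
  list(lambda = lam, converged = converged, n_iter = iter)
}

#' Predict suitability from a fitted maximum-entropy model
#'
#' `raw` output is the Gibbs probability `exp(score - normalizer)` (sums to 1
#' over the training background); `cloglog` is
#' `1 - exp(-exp(H + score - normalizer))` with `H` the entropy of the
#' training-background distribution — the bounded suitability transform that
#' is MaxEnt 3.4.1's default output. Both are monotone in the linear score,
#' so they rank cells identically.
#'
#' @param object A `maxent_model`.
#' @param newdata Data frame of environmental values.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector of suitabilities.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("cloglog", "raw"), ...) {
  type <- match.arg(type)
  f <- expand_features(object$expansion, newdata)
  score <- as.vector(f %*% object$lambda) - object$normalizer
  switch(type,
    raw = exp(score),
    cloglog = 1 - exp(-exp(object$entropy + score))
  )
}

#' Number of non-zero model coefficients
#'
#' @param model A `maxent_model`.
#' @param tol Coefficients with absolute value at or below `tol` count as
#'   zero.
#' @return Integer count.
#' @export
n_nonzero <- function(model, tol = 1e-8) {
  sum(abs(model$lambda) > tol)
}

# variables with at least one non-zero feature coefficient
model_variables <- function(model, tol = 1e-8) {
  meta <- model$expansion$meta
  nz <- abs(model$lambda) > tol
  unique(c(meta$var1[nz], meta$var2[nz][!is.na(meta$var2[nz])]))
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("<maxent_model> ", length(x$expansion$variables), " variables, classes ",
      paste(toupper(x$expansion$classes), collapse = ""),
      ", beta = ", x$beta, "\n", sep = "")
  cat("  ", n_nonzero(x), "/", length(x$lambda),
      " non-zero features; entropy ", round(x$entropy, 3),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted model to JSON (and back)
#'
#' Writes expansion metadata, coefficients and normalising constants —
#' everything needed to re-predict identically.
#'
#' @param model A `maxent_model`.
#' @param path File path for the JSON document.
#' @return `write_maxent()` returns `path` invisibly; `read_maxent()` a
#'   `maxent_model` (without the stored training samples).
#' @export
write_maxent <- function(model, path) {
  doc <- list(
    classes = model$expansion$classes,
    n_knots = model$expansion$n_knots,
    variables = model$expansion$variables,
    ranges = model$expansion$ranges,
    meta = model$expansion$meta,
    lambda = unname(model$lambda),
    beta = model$beta,
    regularization = model$regularization,
    normalizer = model$normalizer,
    entropy = model$entropy,
    converged = model$converged
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- tibble::as_tibble(doc$meta)
  meta$knot <- if (is.null(doc$meta$knot)) NA_real_ else as.numeric(meta$knot)
  meta$var2 <- if (is.null(doc$meta$var2)) NA_character_ else as.character(meta$var2)
  expansion <- structure(
    list(meta = meta, ranges = tibble::as_tibble(doc$ranges),
         classes = doc$classes, n_knots = doc$n_knots,
         variables = doc$variables),
    class = "maxent_features"
  )
  structure(
    list(expansion = expansion,
         lambda = stats::setNames(doc$lambda, meta$feature),
         beta = doc$beta, regularization = doc$regularization,
         normalizer = doc$normalizer, entropy = doc$entropy,
         presences = NULL, background = NULL,
         converged = doc$converged, n_iter = NA_integer_),
    class = "maxent_model"
  )
}
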