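#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maximum-entropy model
#'
#' @param x A `maxent_model`.
#' @param all Include zero-coefficient features (default FALSE).
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature`, `type`, `variable`
#'   (`var2` for products), `knot`, `estimate`, `regularization`.
#' @export
tidy.maxent_model <- function(x, all = FALSE, ...) {
  meta <- x$expansion$meta
  out <- tibble::tibble(
    feature = meta$feature, type = meta$type,
    variable = meta$var1, var2 = meta$var2, knot = meta$knot,
    estimate = unname(x$lambda),
    regularization = x$regularization
  )
  if (!all) out <- out[out$estimate != 0, , drop = FALSE]
  out
}

#' Model-level summary of a maximum-entropy fit
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, feature classes, beta, non-zero
#'   feature count, background entropy, convergence.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = if (is.null(x$presences)) NA_integer_ else nrow(x$presences),
    n_background = if (is.null(x$background)) NA_integer_ else nrow(x$background),
    classes = paste(toupper(x$expansion$classes), collapse = ""),
    beta = x$beta,
    n_features = length(x$lambda),
    n_nonzero = n_nonzero(x),
    entropy = x$entropy,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Tidy an importance regression
#'
#' @param x An `importance_regression`.
#' @param model Which candidate; default the AICc-chosen one.
#' @param ... Unused.
#' @return A tibble of coefficients from the parametric (OLS) and rank-based
#'   fits of the candidate: `term`, `estimate`, `std_error`, `p_value`,
#'   `estimate_rank`.
#' @export
tidy.importance_regression <- function(x, model = x$chosen, ...) {
  ols <- x$ols[[model]]
  rk <- x$rank[[model]]
  cf <- summary(ols)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    p_value = cf[, "Pr(>|t|)"],
    estimate_rank = unname(rk$coefficients[rownames(cf)])
  )
}

#' One-row summary of an importance regression
#'
#' @param x An `importance_regression`.
#' @param model Which candidate; default the AICc-chosen one.
#' @param ... Unused.
#' @return A tibble: chosen formula, AICc, parametric and rank-based R2 and
#'   model p-values.
#' @export
glance.importance_regression <- function(x, model = x$chosen, ...) {
  ols <- x$ols[[model]]
  rk <- x$rank[[model]]
  s <- summary(ols)
  f <- s$fstatistic
  tibble::tibble(
    model = model,
    aicc = x$aicc[[model]],
    r_squared = s$r.squared,
    p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
    r_squared_rank = rk$r_squared,
    p_value_rank = rk$p_value,
    n = stats::nobs(ols)
  )
}
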