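#' Permutation importance of model variables
#'
#' For each variable, its values are shuffled jointly across the pooled
#' presence + background sample (other variables untouched) and the drop in
#' training AUC of the model is recorded; drops are averaged over
#' `n_repeats` shuffles, floored at zero, and rescaled so the variable
#' importances sum to 100%.
#'
#' @param model A `maxent_model` (must retain its training samples).
#' @param n_repeats Number of shuffles per variable (default 10).
#' @param seed Integer seed; the shuffles are deterministic given it.
#' @return A tibble (`variable`, `importance`) summing to 100; attribute
#'   `flat` is TRUE when all drops were zero and importances were set
#'   uniform.
#' @export
permutation_importance <- function(model, n_repeats = 10, seed = 1) {
  stopifnot(n_repeats >= 1)
  if (is.null(model$presences)) {
    stop("model does not retain training samples")
  }
  pres <- model$presences
  bg <- model$background
  pooled <- dplyr::bind_rows(pres, bg)
  np <- nrow(pres)
  base_auc <- auc_rank(predict(model, pres, type = "raw"),
                       predict(model, bg, type = "raw"))
  vars <- model$expansion$variables
  drops <- withr::with_seed(seed, {
    vapply(vars, function(v) {
      mean(vapply(seq_len(n_repeats), function(r) {
        perm <- pooled
        perm[[v]] <- sample(perm[[v]])
        s <- predict(model, perm, type = "raw")
        base_auc - auc_rank(s[seq_len(np)], s[-seq_len(np)])
      }, 0))
    }, 0)
  })
  drops <- pmax(drops, 0)
  flat <- FALSE
  if (sum(drops) == 0) {
    flat <- TRUE
    drops <- rep(1, length(vars))
  }
  out <- tibble::tibble(variable = vars,
                        importance = 100 * unname(drops) / sum(drops))
  attr(out, "flat") <- flat
  out
}

#' Marginal response curve of one variable
#'
#' Sweeps the variable over its training range at `n_points` evaluation
#' points while every other variable is pinned at its training-background
#' median, and records the model suitability — the standard marginal response
#' curve.
#'
#' @param model A `maxent_model`.
#' @param variable Variable name (must be in the model's training stack).
#' @param n_points Number of evaluation points (default 100).
#' @param type Output transform, `"cloglog"` (default) or `"raw"`.
#' @return A tibble (`value`, `suitability`).
#' @export
marginal_response <- function(model, variable, n_points = 100,
                              type = "cloglog") {
  rng <- model$expansion$ranges
  if (!variable %in% rng$variable) {
    stop("unknown variable: ", variable)
  }
  if (is.null(model$background)) {
    stop("model does not retain training samples")
  }
  med <- vapply(model$background, stats::median, 0)
  r <- rng[rng$variable == variable, ]
  grid <- tibble::as_tibble(as.list(med))[rep(1, n_points), ]
  grid[[variable]] <- seq(r$min, r$max, length.out = n_points)
  tibble::tibble(
    value = grid[[variable]],
    suitability = predict(model, grid, type = type)
  )
}

#' Classify a response curve as positive, negative or none
#'
#' The Spearman correlation between the variable values and the curve's
#' suitabilities is computed; `rho >= threshold` is a positive response,
#' `rho <= -threshold` negative, anything else (including undefined rho on a
#' constant curve) is no response. Being rank-based, the call is invariant
#' to the choice of suitability transform.
#'
#' @param curve A tibble from [marginal_response()].
#' @param threshold Absolute Spearman threshold (default 0.7).
#' @return A list: `class` (`"positive"`, `"negative"`, `"none"`) and `rho`.
#' @export
classify_response <- function(curve, threshold = 0.7) {
  stopifnot(nrow(curve) >= 3)
  if (stats::sd(curve$suitability) == 0) {
    return(list(class = "none", rho = NA_real_))
  }
  rho <- stats::cor(curve$value, curve$suitability, method = "spearman")
  cls <- if (rho >= threshold) "positive"
         else if (rho <= -threshold) "negative"
         else "none"
  list(class = cls, rho = rho)
}

#' Response classification for every variable of a model
#'
#' Variables absent from the fitted model (all their feature coefficients
#' zero) are classed `"none"` without computing a correlation, matching the
#' convention that an unused variable has no response.
#'
#' @param model A `maxent_model`.
#' @param n_points,type Passed to [marginal_response()].
#' @param threshold Passed to [classify_response()].
#' @return A tibble (`variable`, `class`, `rho`, `in_model`).
#' @export
classify_responses <- function(model, n_points = 100, type = "cloglog",
                               threshold = 0.7) {
  vars <- model$expansion$variables
  used <- model_variables(model)
  purrr::map_dfr(vars, function(v) {
    if (!v %in% used) {
      return(tibble::tibble(variable = v, class = "none", rho = NA_real_,
                            in_model = FALSE))
    }
    cl <- classify_response(
      marginal_response(model, v, n_points = n_points, type = type),
      threshold = threshold)
    tibble::tibble(variable = v, class = cl$class, rho = cl$rho,
                   in_model = TRUE)
  })
}

#' Sum variable importances by predictor category
#'
#' @param importance A tibble (`variable`, `importance`) from
#'   [permutation_importance()].
#' @param vars Variable metadata with `variable` and `category` columns
#'   (e.g. [env_vars()]); must cover every variable in `importance`.
#' @return A tibble (`category`, `importance`) over land_use, climate and
#'   soil, totalling the input's total.
#' @export
sum_by_category <- function(importance, vars) {
  vars <- tibble::as_tibble(vars)
  missing <- setdiff(importance$variable, vars$variable)
  if (length(missing) > 0) {
    stop("uncategorized variable(s): ", paste(missing, collapse = ", "))
  }
  importance |>
    dplyr::left_join(vars[, c("variable", "category")], by = "variable") |>
    dplyr::group_by(category = factor(.data$category,
                                      c("land_use", "climate", "soil"))) |>
    dplyr::summarise(importance = sum(.data$importance), .groups = "drop") |>
    tidyr::complete(.data$category, fill = list(importance = 0))
}
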