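#' Assign presences to spatial validation blocks
#'
#' Splits presence records into the four quadrants defined by the median x
#' and median y of the points — the spatial-block partition used for
#' cross-validation (three quadrants calibrate, one evaluates, rotating).
#' Points exactly on a median line go to the lower-indexed quadrant.
#'
#' @param points A data frame with columns `x`, `y`.
#' @return The input tibble plus an integer `fold` column (1..4); attributes
#'   `split_x`, `split_y` hold the median split coordinates.
#' @export
make_spatial_blocks <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(nrow(points) >= 4)
  if (length(unique(points$x)) == 1 && length(unique(points$y)) == 1) {
    stop("all points identical; no spatial blocks possible")
  }
  mx <- stats::median(points$x)
  my <- stats::median(points$y)
  fold <- ifelse(points$x <= mx,
                 ifelse(points$y <= my, 1L, 3L),
                 ifelse(points$y <= my, 2L, 4L))
  out <- points
  out$fold <- fold
  attr(out, "split_x") <- mx
  attr(out, "split_y") <- my
  out
}

#' Rank-based AUC of presence vs background scores
#'
#' Mann-Whitney AUC: the probability that a random presence outscores a
#' random background point, ties counted one half.
#'
#' @param presence,background Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(presence, background) {
  stopifnot(length(presence) > 0, length(background) > 0)
  r <- rank(c(presence, background))
  n1 <- length(presence)
  n2 <- length(background)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Continuous Boyce index
#'
#' Evaluates how well suitability ranks presences against availability: the
#' suitability range is covered by overlapping moving windows (default 101
#' windows of width one tenth of the range); in each window the
#' predicted-to-expected ratio P/E compares the fraction of evaluation
#' presences to the fraction of the study area falling in the window; the
#' index is the Spearman correlation between P/E and the window midpoint.
#' +1 means suitability ranks habitat use perfectly, 0 is no better than
#' chance, negative values indicate inverted ranking.
#'
#' @param presence Suitabilities at evaluation presences.
#' @param area Suitabilities over the (masked) study area.
#' @param n_windows Number of overlapping windows (default 101).
#' @param window_frac Window width as a fraction of the suitability range
#'   (default 0.1).
#' @return The index in \[-1, 1\], or `NA` (flagged via attribute
#'   `degenerate`) when the area suitabilities are constant.
#' @export
boyce_index <- function(presence, area, n_windows = 101, window_frac = 0.1) {
  stopifnot(length(presence) > 0, length(area) >= 2)
  lo <- min(area)
  hi <- max(area)
  if (hi == lo) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  width <- (hi - lo) * window_frac
  starts <- seq(lo, hi - width, length.out = n_windows)
  mids <- starts + width / 2
  pe <- vapply(starts, function(a) {
    p <- mean(presence >= a & presence <= a + width)
    e <- mean(area >= a & area <= a + width)
    if (e == 0) NA_real_ else p / e
  }, 0)
  ok <- !is.na(pe)
  # drop repeated P/E values (keeping the first), the usual convention for
  # the continuous index: runs of identical ratios (typically zeros below
  # the occupied range) would otherwise flood the rank correlation with ties
  idx <- which(ok)
  ok[idx[duplicated(pe[idx])]] <- FALSE
  if (sum(ok) < 3 || stats::sd(pe[ok]) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(mids[ok], pe[ok], method = "spearman")
}

#' Omission rates at the MTP and 10% training thresholds
#'
#' `or_mtp` is the fraction of evaluation presences scoring below the minimum
#' training presence score; `or_10` uses the threshold that omits the lowest
#' 10% of training scores (the excluded count is `ceiling(0.1 * n_train)`,
#' the threshold is the smallest retained training score).
#'
#' @param train,eval Numeric suitability vectors for calibration and
#'   evaluation presences.
#' @return A tibble with columns `or_mtp`, `or_10`.
#' @export
omission_rates <- function(train, eval) {
  stopifnot(length(train) > 0, length(eval) > 0)
  or_mtp <- mean(eval < min(train))
  n_excl <- ceiling(0.1 * length(train))
  thr10 <- sort(train)[min(n_excl + 1, length(train))]
  tibble::tibble(or_mtp = or_mtp, or_10 = mean(eval < thr10))
}

#' AICc of a maximum-entropy model
#'
#' Raw model scores are standardised to sum to one over the masked study grid
#' (or, optionally, over the training background); the log-likelihood is the
#' sum of log standardised scores at the presence cells, `k` counts non-zero
#' coefficients, and `AICc = 2k - 2 logL + 2k(k+1)/(n-k-1)`. Candidates with
#' `k >= n - 1` have undefined AICc and return `NA`.
#'
#' @param model A `maxent_model`.
#' @param presences Data frame of presence environmental values.
#' @param stack An [env_stack()] giving the masked grid, or a data frame of
#'   environmental values to standardise over.
#' @param scope `"grid"` (default) standardises over `stack`;
#'   `"background"` over the model's training background.
#' @return AICc (scalar, possibly `NA`).
#' @export
aicc_maxent <- function(model, presences, stack,
                        scope = c("grid", "background")) {
  scope <- match.arg(scope)
  n <- nrow(presences)
  k <- n_nonzero(model)
  if (k >= n - 1) return(NA_real_)
  ref <- if (scope == "grid") tibble::as_tibble(stack) else model$background
  raw_ref <- predict(model, ref, type = "raw")
  raw_pres <- predict(model, presences, type = "raw")
  std_pres <- raw_pres / sum(raw_ref)
  log_lik <- sum(log(std_pres))
  aic <- 2 * k - 2 * log_lik
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Default tuning grid of regularization and feature classes
#'
#' @param beta Regularization multipliers (default 1..15).
#' @param classes Feature-class combinations (default the six sets L, LQ, H,
#'   LQH, LQHP, LQHPT).
#' @return A tibble with columns `beta`, `classes`.
#' @export
tuning_grid <- function(beta = 1:15,
                        classes = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT")) {
  stopifnot(length(beta) > 0, length(classes) > 0)
  tidyr::expand_grid(classes = classes, beta = as.numeric(beta))
}

#' Tune a species' model over the candidate grid
#'
#' For every (feature classes, beta) candidate: fits on all presences for
#' training AUC and AICc, and runs 4-fold spatial-block cross-validation
#' (fit on three quadrants, evaluate on the held-out one) for mean test AUC,
#' mean continuous Boyce index and mean omission rates.
#'
#' @param presences Presence records with `x`, `y` and environmental columns
#'   (see [extract_env()]).
#' @param background Background environmental values.
#' @param stack An [env_stack()] (AICc standardisation and Boyce area
#'   suitabilities).
#' @param grid A [tuning_grid()].
#' @param n_knots,tol,max_iter Passed to [fit_maxent()].
#' @param transform Output transform for Boyce suitabilities.
#' @return A list: `report` (one row per candidate: metrics), `models` (the
#'   full-data fits, indexed like the report), `blocks` (fold assignment).
#' @export
tune_maxent <- function(presences, background, stack, grid = tuning_grid(),
                        n_knots = 25, tol = 1e-6, max_iter = 500,
                        transform = "cloglog") {
  presences <- tibble::as_tibble(presences)
  blocks <- make_spatial_blocks(presences)
  env_cols <- intersect(env_vars(stack)$variable, names(presences))
  pres_env <- presences[, env_cols, drop = FALSE]
  bg_env <- tibble::as_tibble(background)[, env_cols, drop = FALSE]
  area_env <- tibble::as_tibble(stack)[, env_cols, drop = FALSE]

  models <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cls <- grid$classes[i]
    b <- grid$beta[i]
    full <- fit_maxent(pres_env, bg_env, beta = b, classes = cls,
                       n_knots = n_knots, tol = tol, max_iter = max_iter)
    models[[i]] <- full
    train_auc <- auc_rank(predict(full, pres_env, type = "raw"),
                          predict(full, bg_env, type = "raw"))
    aicc <- aicc_maxent(full, pres_env, area_env)

    cv <- purrr::map(sort(unique(blocks$fold)), function(f) {
      cal <- pres_env[blocks$fold != f, , drop = FALSE]
      hold <- pres_env[blocks$fold == f, , drop = FALSE]
      if (nrow(cal) < 2 || nrow(hold) < 1) return(NULL)
      m <- fit_maxent(cal, bg_env, beta = b, classes = cls,
                      n_knots = n_knots, tol = tol, max_iter = max_iter)
      s_hold <- predict(m, hold, type = transform)
      s_cal <- predict(m, cal, type = transform)
      tibble::tibble(
        test_auc = auc_rank(predict(m, hold, type = "raw"),
                            predict(m, bg_env, type = "raw")),
        boyce = as.numeric(boyce_index(s_hold,
                                       predict(m, area_env, type = transform))),
        or_mtp = omission_rates(s_cal, s_hold)$or_mtp,
        or_10 = omission_rates(s_cal, s_hold)$or_10
      )
    })
    cv <- dplyr::bind_rows(cv)
    rows[[i]] <- tibble::tibble(
      candidate = i, classes = cls, beta = b, aicc = aicc,
      train_auc = train_auc,
      test_auc = mean(cv$test_auc, na.rm = TRUE),
      boyce = mean(cv$boyce, na.rm = TRUE),
      or_mtp = mean(cv$or_mtp, na.rm = TRUE),
      or_10 = mean(cv$or_10, na.rm = TRUE),
      n_nonzero = n_nonzero(full),
      converged = full$converged
    )
  }
  list(report = dplyr::bind_rows(rows), models = models, blocks = blocks)
}

#' Select the best candidate from an evaluation report
#'
#' Lowest AICc wins; exact AICc ties are broken by lowest 10% training
#' omission rate, then by model simplicity (fewer non-zero coefficients,
#' then lower beta). Candidates with undefined AICc are excluded (logged via
#' the `excluded` attribute).
#'
#' @param report The `report` tibble from [tune_maxent()] (needs columns
#'   `aicc`, `or_10`, `n_nonzero`, `beta`).
#' @return The chosen report row (one-row tibble).
#' @export
select_best <- function(report) {
  report <- tibble::as_tibble(report)
  valid <- report[!is.na(report$aicc), , drop = FALSE]
  if (nrow(valid) == 0) stop("no candidate with defined AICc")
  o <- order(valid$aicc, valid$or_10, valid$n_nonzero, valid$beta)
  out <- valid[o[1], , drop = FALSE]
  attr(out, "excluded") <- report[is.na(report$aicc), , drop = FALSE]
  out
}
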