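#' Aggregate daily climate series to bioclimatic variables
#'
#' Computes the six bioclim variables used as climate predictors — annual mean
#' temperature (bio1), temperature seasonality (bio4), mean temperature of the
#' wettest quarter (bio8), annual precipitation (bio12), precipitation of the
#' driest month (bio14) and precipitation seasonality (bio15) — from daily
#' temperature and precipitation series per cell.
#'
#' The computation path is daily values -> per-year monthly means (temperature)
#' and monthly sums (precipitation) -> multi-year monthly climatology (mean
#' over years) -> bioclim formulas on the 12 climatological months:
#' * bio1 = mean of the 12 monthly mean temperatures (degrees C)
#' * bio4 = 100 x SD of the 12 monthly mean temperatures
#' * bio8 = mean temperature of the wettest consecutive 3-month quarter,
#'   with December-January wraparound; ties go to the earliest start month
#' * bio12 = sum of monthly precipitation (mm/yr)
#' * bio14 = minimum monthly precipitation (mm/month)
#' * bio15 = 100 x SD / mean of monthly precipitation (coefficient of
#'   variation, percent)
#'
#' SDs are sample standard deviations (n - 1). The bio15 denominator is the
#' plain monthly mean by default; set `bio15_denominator = "mean_plus_one"`
#' for the variant that adds 1 mm to stabilise arid cells. Cells whose
#' climatology has zero total precipitation get bio15 = 0 and are flagged in
#' the `zero_precip` attribute of the result.
#'
#' @param daily A data frame with columns `cell_id`, `date` (Date or
#'   yyyy-mm-dd string), `tmean` (degrees C), `precip` (mm/day, non-negative).
#' @param years Optional integer vector restricting which years enter the
#'   climatology. Every used year must be complete (365/366 days per cell).
#' @param bio15_denominator `"mean"` (default) or `"mean_plus_one"`.
#'
#' @return A tibble with columns `cell_id`, `bio1`, `bio4`, `bio8`, `bio12`,
#'   `bio14`, `bio15`; attribute `zero_precip` lists flagged cell ids.
#' @export
compute_bioclim <- function(daily, years = NULL,
                            bio15_denominator = c("mean", "mean_plus_one")) {
  bio15_denominator <- match.arg(bio15_denominator)
  daily <- tibble::as_tibble(daily)
  stopifnot(all(c("cell_id", "date", "tmean", "precip") %in% names(daily)))
  if (any(daily$precip < 0, na.rm = TRUE)) stop("negative precipitation")
  date <- as.Date(daily$date)
  yr <- as.integer(format(date, "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  keep <- yr %in% years
  daily <- daily[keep, , drop = FALSE]
  yr <- yr[keep]
  mo <- as.integer(format(date[keep], "%m"))
  if (nrow(daily) == 0) stop("no data in the requested years")

  # every (cell, year) must cover the full year
  expected <- ifelse(years %% 4 == 0 & (years %% 100 != 0 | years %% 400 == 0),
                     366L, 365L)
  names(expected) <- years
  counts <- dplyr::count(
    tibble::tibble(cell_id = daily$cell_id, year = yr), .data$cell_id, .data$year
  )
  bad <- counts$n != expected[as.character(counts$year)]
  if (any(bad)) {
    stop("incomplete year(s): ",
         paste(unique(paste0("cell ", counts$cell_id[bad], " year ",
                             counts$year[bad])), collapse = "; "))
  }

  monthly <- tibble::tibble(
    cell_id = daily$cell_id, year = yr, month = mo,
    tmean = daily$tmean, precip = daily$precip
  ) |>
    dplyr::group_by(.data$cell_id, .data$year, .data$month) |>
    dplyr::summarise(tmean = mean(.data$tmean),
                     precip = sum(.data$precip), .groups = "drop")
  clim <- monthly |>
    dplyr::group_by(.data$cell_id, .data$month) |>
    dplyr::summarise(tmean = mean(.data$tmean),
                     precip = mean(.data$precip), .groups = "drop")

  out <- clim |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$month, .by_group = TRUE) |>
    dplyr::summarise(
      bio1 = mean(.data$tmean),
      bio4 = 100 * stats::sd(.data$tmean),
      bio8 = wettest_quarter_tmean(.data$tmean, .data$precip),
      bio12 = sum(.data$precip),
      bio14 = min(.data$precip),
      bio15 = precip_seasonality(.data$precip, bio15_denominator),
      .groups = "drop"
    )
  zero <- out$cell_id[out$bio12 == 0]
  attr(out, "zero_precip") <- zero
  out
}

# mean temperature of the wettest consecutive 3-month window (Dec-Jan wrap);
# ties broken by earliest start month
wettest_quarter_tmean <- function(tmean, precip) {
  stopifnot(length(tmean) == 12, length(precip) == 12)
  idx <- cbind(1:12, c(2:12, 1), c(3:12, 1, 2))
  psum <- precip[idx[, 1]] + precip[idx[, 2]] + precip[idx[, 3]]
  start <- which.max(psum)  # first maximum = earliest start
  mean(tmean[idx[start, ]])
}

precip_seasonality <- function(precip, denominator) {
  m <- mean(precip)
  if (denominator == "mean_plus_one") m <- m + 1
  if (m == 0) return(0)
  100 * stats::sd(precip) / m
}

#' Screen variables for collinearity
#'
#' Iteratively removes variables until no retained pair has absolute Pearson
#' correlation above `threshold` (computed over the masked cells). At each
#' step the most-correlated offending pair is found and the member with the
#' larger mean absolute correlation to all other retained variables is
#' dropped; ties drop the variable later in input order. Constant variables
#' (undefined correlation) are dropped first with a warning.
#'
#' @param stack An [env_stack()].
#' @param threshold Correlation cut-off in (0, 1]; default 0.7.
#' @return The screened `env_stack`; attribute `screening_log` is a tibble of
#'   exclusions (`variable`, `reason`, `partner`, `r`).
#' @export
select_uncorrelated <- function(stack, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  vars <- env_vars(stack)$variable
  x <- as.matrix(env_values(stack, vars))
  log <- tibble::tibble(variable = character(), reason = character(),
                        partner = character(), r = numeric())

  const <- vars[apply(x, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))]
  if (length(const) > 0) {
    warning("dropping constant variable(s): ", paste(const, collapse = ", "))
    log <- dplyr::bind_rows(log, tibble::tibble(
      variable = const, reason = "constant", partner = NA_character_, r = NA_real_))
    vars <- setdiff(vars, const)
  }

  repeat {
    if (length(vars) < 2) break
    r <- stats::cor(x[, vars, drop = FALSE])
    diag(r) <- 0
    a <- abs(r)
    if (max(a) <= threshold) break
    ij <- which(a == max(a), arr.ind = TRUE)[1, ]
    pair <- vars[ij]
    mean_abs <- colMeans(a)[pair]
    drop <- if (mean_abs[1] > mean_abs[2]) {
      pair[1]
    } else if (mean_abs[2] > mean_abs[1]) {
      pair[2]
    } else {
      pair[which.max(match(pair, vars))]  # tie: later in input order
    }
    keep_partner <- setdiff(pair, drop)
    log <- dplyr::bind_rows(log, tibble::tibble(
      variable = drop, reason = "correlated", partner = keep_partner,
      r = r[pair[1], pair[2]]))
    vars <- setdiff(vars, drop)
  }

  subset_stack(stack, vars, screening_log = log)
}

subset_stack <- function(stack, variables, screening_log = NULL) {
  vars <- env_vars(stack)
  keep_cols <- c("cell_id", "x", "y", variables)
  out <- env_stack(tibble::as_tibble(stack)[, keep_cols, drop = FALSE],
                   vars[match(variables, vars$variable), , drop = FALSE],
                   attr(stack, "cell_size"),
                   nx = attr(stack, "nx"), ny = attr(stack, "ny"))
  if (!is.null(screening_log)) attr(out, "screening_log") <- screening_log
  out
}

#' Screening log of a collinearity-screened stack
#'
#' @param stack The result of [select_uncorrelated()].
#' @return A tibble of excluded variables with the reason and, for correlated
#'   drops, the retained partner and the offending correlation.
#' @export
screening_log <- function(stack) {
  attr(stack, "screening_log")
}

#' Count land uses per grid cell
#'
#' Adds the "number of land uses" predictor: per cell, the count of land-use
#' percent-cover layers with cover above zero. The new layer is itself tagged
#' as a land-use variable (`n_land_uses`, kind `continuous`), a simple
#' landscape-heterogeneity index.
#'
#' @param stack An [env_stack()].
#' @return The stack with an added `n_land_uses` variable.
#' @export
count_land_uses <- function(stack) {
  vars <- env_vars(stack)
  lu <- vars$variable[vars$category == "land_use" & vars$kind == "percent_cover"]
  if (length(lu) == 0) stop("no land-use percent-cover layers in stack")
  counts <- rowSums(as.matrix(env_values(stack, lu)) > 0)
  cells <- tibble::as_tibble(stack)
  cells$n_land_uses <- as.numeric(counts)
  new_vars <- dplyr::bind_rows(
    vars,
    tibble::tibble(variable = "n_land_uses", category = "land_use",
                   kind = "continuous")
  )
  if ("natural" %in% names(new_vars)) {
    new_vars$natural[new_vars$variable == "n_land_uses"] <- FALSE
  }
  env_stack(cells, new_vars, attr(stack, "cell_size"),
            nx = attr(stack, "nx"), ny = attr(stack, "ny"))
}
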