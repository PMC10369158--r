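#' Study configuration
#'
#' Collects every tunable of the pipeline with defaults at the study's
#' stated values: 300 m thinning, at least 15 thinned records per modeled
#' species, 10,000 background points, regularization multipliers 1..15 over
#' six feature-class sets, 0.7 collinearity cut-off and 0.7 response
#' correlation threshold, cloglog output.
#'
#' @param thin_distance Thinning distance (m).
#' @param thin_restarts Random restarts for the thinning heuristic.
#' @param min_n Minimum thinned records per modeled species.
#' @param n_background Background sample size.
#' @param grid A [tuning_grid()].
#' @param cor_threshold Collinearity screening cut-off.
#' @param rho_threshold Response-classification Spearman threshold.
#' @param n_knots Hinge/threshold knots per variable per direction.
#' @param n_permutations Permutation-importance repeats.
#' @param transform Suitability transform (`"cloglog"` or `"raw"`).
#' @param aicc_scope AICc standardisation: `"grid"` (masked study grid,
#'   default) or `"background"`.
#' @param eoo_records Use `"raw"` (default) or `"thinned"` records for the
#'   extent of occurrence and climate-deviation statistics.
#' @param signed_deviations Keep the sign of climate deviations.
#' @param bio15_denominator Passed to [compute_bioclim()].
#' @param tol,max_iter Maximum-entropy fit controls.
#' @param seed Master seed; per-species seeds derive from it.
#' @return A `study_config` list.
#' @export
study_config <- function(thin_distance = 300, thin_restarts = 100,
                         min_n = 15, n_background = 10000,
                         grid = tuning_grid(), cor_threshold = 0.7,
                         rho_threshold = 0.7, n_knots = 25,
                         n_permutations = 10, transform = "cloglog",
                         aicc_scope = "grid", eoo_records = "raw",
                         signed_deviations = FALSE,
                         bio15_denominator = "mean",
                         tol = 1e-6, max_iter = 500, seed = 1) {
  structure(
    list(thin_distance = thin_distance, thin_restarts = thin_restarts,
         min_n = min_n, n_background = n_background, grid = grid,
         cor_threshold = cor_threshold, rho_threshold = rho_threshold,
         n_knots = n_knots, n_permutations = n_permutations,
         transform = transform, aicc_scope = aicc_scope,
         eoo_records = eoo_records, signed_deviations = signed_deviations,
         bio15_denominator = bio15_denominator,
         tol = tol, max_iter = max_iter, seed = seed),
    class = "study_config"
  )
}

#' Run the per-species modelling chain
#'
#' Thinned records are assumed; the chain is: spatial blocks -> tuning over
#' the candidate grid with spatial-block cross-validation -> AICc selection
#' with omission tie-break -> the selected candidate's full-data fit ->
#' permutation importance, category sums and response classification ->
#' per-species summary statistics (extent of occurrence, climate deviation,
#' natural cover). Deterministic given the config seed.
#'
#' @param species Species id.
#' @param records The species' records: `x`, `y` plus a `retained` column
#'   from thinning (raw records are used for EOO/climate deviation when the
#'   config says so).
#' @param stack The screened [env_stack()].
#' @param background Background environmental values (see
#'   [sample_background()]).
#' @param config A [study_config()].
#' @param species_seed Seed for this species' stochastic steps.
#' @return A list: `model` (chosen `maxent_model`), `report` (evaluation
#'   tibble), `chosen` (selected row), `importance`, `category_importance`,
#'   `responses`, `summary` (one-row tibble).
#' @export
run_species <- function(species, records, stack, background,
                        config = study_config(), species_seed = config$seed) {
  records <- tibble::as_tibble(records)
  thinned <- records[records$retained, , drop = FALSE]
  stopifnot(nrow(thinned) >= config$min_n)
  pres <- extract_env(stack, thinned)
  pres$x <- thinned$x
  pres$y <- thinned$y

  tuned <- tune_maxent(pres, background, stack, grid = config$grid,
                       n_knots = config$n_knots, tol = config$tol,
                       max_iter = config$max_iter,
                       transform = config$transform)
  chosen <- select_best(tuned$report)
  model <- tuned$models[[chosen$candidate]]

  imp <- permutation_importance(model, n_repeats = config$n_permutations,
                                seed = species_seed)
  cat_imp <- sum_by_category(imp, env_vars(stack))
  resp <- classify_responses(model, type = config$transform,
                             threshold = config$rho_threshold)

  stat_records <- if (config$eoo_records == "thinned") thinned else records
  obs_env <- extract_env(stack, stat_records)
  dev <- climate_deviation(obs_env, stack, signed = config$signed_deviations)
  nat <- env_vars(stack)
  nat_layers <- if ("natural" %in% names(nat)) {
    nat$variable[nat$category == "land_use" & nat$natural]
  } else {
    character(0)
  }
  natural_cover <- if (length(nat_layers) > 0) {
    mean(rowSums(obs_env[, nat_layers, drop = FALSE]))
  } else {
    NA_real_
  }

  summary <- tibble::tibble(
    species = species,
    n_raw = nrow(records), n_thinned = nrow(thinned),
    eoo_km2 = as.numeric(extent_of_occurrence(stat_records)),
    mean_x = mean(stat_records$x), mean_y = mean(stat_records$y),
    natural_cover = natural_cover,
    classes = chosen$classes, beta = chosen$beta, aicc = chosen$aicc,
    train_auc = chosen$train_auc, test_auc = chosen$test_auc,
    boyce = chosen$boyce, or_mtp = chosen$or_mtp, or_10 = chosen$or_10,
    n_nonzero = chosen$n_nonzero
  )
  for (i in seq_len(nrow(dev))) {
    summary[[paste0("dev_", dev$variable[i])]] <- dev$deviation[i]
  }
  for (i in seq_len(nrow(cat_imp))) {
    summary[[paste0(cat_imp$category[i], "_importance")]] <-
      cat_imp$importance[i]
  }
  list(model = model, report = tuned$report, chosen = chosen,
       importance = imp, category_importance = cat_imp, responses = resp,
       summary = summary)
}

#' Run the full comparative study
#'
#' Prepares the predictor stack (adds the number-of-land-uses layer, screens
#' collinearity), samples the shared background, thins and filters the
#' occurrence data, fits and selects a model per species, and runs the whole
#' group-comparison layer: LC-vs-RL rank-sum tests of extent of occurrence,
#' location and natural cover; Kruskal-Wallis/Dunn (Holm) comparisons of
#' climate deviations, category importance sums and per-variable
#' importances; Cochran-Mantel-Haenszel response-ratio tests with Fisher
#' post hoc per category; AICc-selected parametric and rank-based
#' regressions of category importance on range size and status; and the
#' European-list variant including the three-way LC/RL/DD comparison.
#'
#' Species are processed independently; execution order does not affect
#' results.
#'
#' @param study A `synthetic_study` (see [generate_study()]) or a list with
#'   `stack`, `occurrences`, `statuses`.
#' @param config A [study_config()].
#' @return A `group_comparison_report`: `summaries` (per-species tibble),
#'   `importance` and `responses` (long tibbles), `comparisons` (the test
#'   layer), `skipped` (species dropped, with reasons), plus the screened
#'   stack and config.
#' @export
run_study <- function(study, config = study_config()) {
  stack <- count_land_uses(study$stack)
  stack <- select_uncorrelated(stack, threshold = config$cor_threshold)
  background <- sample_background(stack, config$n_background,
                                  seed = config$seed)

  occ <- thin_occurrences(study$occurrences,
                          min_distance = config$thin_distance,
                          n_restarts = config$thin_restarts,
                          seed = config$seed)
  modelable <- filter_modelable(occ, min_n = config$min_n)
  all_species <- sort(unique(occ$species))
  skipped <- tibble::tibble(
    species = setdiff(all_species, modelable$species),
    reason = "fewer thinned records than min_n")

  fits <- list()
  for (i in seq_along(modelable$species)) {
    sp <- modelable$species[i]
    rec <- occ[occ$species == sp, , drop = FALSE]
    res <- tryCatch(
      run_species(sp, rec, stack, background, config,
                  species_seed = config$seed + i),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        species = sp, reason = conditionMessage(res)))
    } else {
      fits[[sp]] <- res
    }
  }
  if (length(fits) == 0) stop("no species could be modeled")

  summaries <- purrr::map_dfr(fits, "summary")
  summaries <- dplyr::left_join(summaries, study$statuses, by = "species")
  offsets <- mean_location_offset(study$occurrences)
  summaries <- dplyr::left_join(summaries, offsets, by = "species")
  importance <- purrr::map_dfr(names(fits), function(sp) {
    dplyr::mutate(fits[[sp]]$importance, species = sp, .before = 1)
  })
  responses <- purrr::map_dfr(names(fits), function(sp) {
    dplyr::mutate(fits[[sp]]$responses, species = sp, .before = 1)
  })

  comparisons <- compare_groups(summaries, importance, responses,
                                env_vars(stack))

  structure(
    list(summaries = summaries, importance = importance,
         responses = responses, comparisons = comparisons,
         skipped = skipped, stack = stack, config = config,
         models = lapply(fits, function(f) f$model),
         reports = lapply(fits, function(f) f$report)),
    class = "group_comparison_report"
  )
}

# the full statistical comparison layer over per-species summaries
compare_groups <- function(summaries, importance, responses, vars) {
  out <- list()
  status <- summaries$dutch_status
  two <- length(unique(status)) == 2
  if (!two) {
    warning("a status group is empty; group comparisons skipped")
    return(out)
  }

  out$eoo <- compare_two_groups(summaries$eoo_km2, status)
  out$location_east <- compare_two_groups(summaries$km_east, status)
  out$location_north <- compare_two_groups(summaries$km_north, status)
  if (!all(is.na(summaries$natural_cover))) {
    out$natural_cover <- compare_two_groups(summaries$natural_cover, status)
  }

  dev_cols <- grep("^dev_", names(summaries), value = TRUE)
  out$climate_deviation <- purrr::map_dfr(dev_cols, function(cl) {
    kd <- kw_dunn(summaries[[cl]], status, holm = FALSE)
    tibble::tibble(variable = sub("^dev_", "", cl),
                   chi_squared = kd$kruskal$chi_squared,
                   p_kw = kd$kruskal$p_value,
                   z = kd$dunn$z[1], p_dunn = kd$dunn$p_value[1])
  })
  out$climate_deviation$p_adjusted <-
    stats::p.adjust(out$climate_deviation$p_dunn, "holm")

  cat_cols <- intersect(c("land_use_importance", "climate_importance",
                          "soil_importance"), names(summaries))
  out$category_importance <- purrr::map_dfr(cat_cols, function(cl) {
    kd <- kw_dunn(summaries[[cl]], status, holm = FALSE)
    ms <- group_mean_se(summaries[[cl]], status)
    tibble::tibble(category = sub("_importance$", "", cl),
                   chi_squared = kd$kruskal$chi_squared,
                   p_kw = kd$kruskal$p_value,
                   z = kd$dunn$z[1], p_dunn = kd$dunn$p_value[1],
                   mean_lc = ms$mean[ms$group == "LC"],
                   se_lc = ms$se[ms$group == "LC"],
                   mean_rl = ms$mean[ms$group == "RL"],
                   se_rl = ms$se[ms$group == "RL"])
  })
  out$category_importance$p_adjusted <-
    stats::p.adjust(out$category_importance$p_dunn, "holm")

  # per-variable importance, Holm within each category family
  imp <- dplyr::left_join(importance, summaries[, c("species", "dutch_status")],
                          by = "species")
  imp <- dplyr::left_join(imp, vars[, c("variable", "category")],
                          by = "variable")
  out$variable_importance <- imp |>
    dplyr::group_by(.data$category, .data$variable) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$dutch_status)) < 2) return(tibble::tibble())
      kd <- kw_dunn(d$importance, d$dutch_status, holm = FALSE)
      ms <- group_mean_se(d$importance, d$dutch_status)
      tibble::tibble(chi_squared = kd$kruskal$chi_squared,
                     p_dunn = kd$dunn$p_value[1],
                     mean_lc = ms$mean[ms$group == "LC"],
                     mean_rl = ms$mean[ms$group == "RL"])
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_dunn, "holm")) |>
    dplyr::ungroup()

  # response direction ratios: CMH per category over variable strata
  resp <- dplyr::left_join(responses,
                           summaries[, c("species", "dutch_status")],
                           by = "species")
  resp <- dplyr::left_join(resp, vars[, c("variable", "category")],
                           by = "variable")
  out$response_ratio <- list()
  for (cat in unique(resp$category)) {
    d <- resp[resp$category == cat & resp$class != "none", , drop = FALSE]
    counts <- d |>
      dplyr::count(.data$variable, status = .data$dutch_status,
                   response = .data$class, name = "n") |>
      tidyr::complete(.data$variable,
                      status = unique(summaries$dutch_status),
                      response = c("positive", "negative"),
                      fill = list(n = 0))
    res <- tryCatch(cmh_response_ratio(counts), error = function(e) NULL)
    if (!is.null(res)) out$response_ratio[[cat]] <- res
  }

  # regressions of category importance on EOO + status
  reg_data <- summaries
  reg_data$status <- reg_data$dutch_status
  out$regressions <- list()
  for (cl in cat_cols) {
    out$regressions[[sub("_importance$", "", cl)]] <-
      tryCatch(importance_regression(reg_data, cl), error = function(e) NULL)
  }

  # European-list variant, including the DD three-way comparison
  es <- summaries$european_status
  if (length(unique(es)) >= 2) {
    out$european <- list()
    for (cl in c(cat_cols, "eoo_km2")) {
      kd <- tryCatch(kw_dunn(summaries[[cl]], es), error = function(e) NULL)
      if (!is.null(kd)) {
        kd$means <- group_mean_se(summaries[[cl]], es)
        out$european[[cl]] <- kd
      }
    }
  }
  out
}

#' @export
print.group_comparison_report <- function(x, ...) {
  cat("<group_comparison_report> ", nrow(x$summaries), " species modeled (",
      sum(x$summaries$dutch_status == "LC"), " LC, ",
      sum(x$summaries$dutch_status == "RL"), " RL); ",
      nrow(x$skipped), " skipped\n", sep = "")
  if (!is.null(x$comparisons$category_importance)) {
    cat("summed permutation importance (mean % LC vs RL):\n")
    print(as.data.frame(
      x$comparisons$category_importance[
        , c("category", "mean_lc", "mean_rl", "p_dunn", "p_adjusted")]),
      digits = 3, row.names = FALSE)
  }
  if (!is.null(x$comparisons$eoo)) {
    cat("extent of occurrence: W = ", round(x$comparisons$eoo$statistic, 1),
        ", p = ", signif(x$comparisons$eoo$p_value, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the per-species summary CSV, tidy importance/response CSVs, the
#' evaluation reports, and the comparison layer as JSON plus a
#' human-readable text table.
#'
#' @param report A `group_comparison_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$summaries, file.path(dir, "species_summaries.csv"))
  readr::write_csv(report$importance, file.path(dir, "importance.csv"))
  readr::write_csv(report$responses, file.path(dir, "responses.csv"))
  readr::write_csv(dplyr::bind_rows(report$reports, .id = "species"),
                   file.path(dir, "evaluation.csv"))
  jsonlite::write_json(serialize_comparisons(report$comparisons),
                       file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  invisible(dir)
}

serialize_comparisons <- function(cmp) {
  strip <- function(x) {
    if (inherits(x, "importance_regression")) {
      return(list(chosen = x$chosen, aicc = as.list(x$aicc),
                  tidy = tidy(x), glance = glance(x)))
    }
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  lapply(cmp, strip)
}
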