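#' Generate a synthetic study landscape
#'
#' Builds an environmental predictor stack with the statistical structure the
#' analysis assumes: six smooth broad-scale climate surfaces (linear gradients
#' in rotated directions plus smooth Gaussian-field noise with a long
#' correlation length), patchy land-use percent-cover layers from a spatially
#' clustered softmax allocation (covers per cell sum to at most 100, small
#' covers truncated to zero), and contiguous categorical soil regions encoded
#' as one binary indicator layer per soil type. Gradient directions are spread
#' over half a turn so that no climate pair exceeds the 0.7 collinearity
#' cut-off by construction; a correlation check warns if any retained pair
#' does.
#'
#' @param seed Integer master seed; the landscape is reproducible from it.
#' @param nx,ny Grid dimensions (default 100 x 100; at least ~10,000 cells
#'   recommended for stable background sampling).
#' @param cell_size Cell edge in metres (default 100).
#' @param n_landuse Number of land-use layers (8-12; default 10).
#' @param n_soil Number of soil indicator layers (3-5; default 4).
#' @param climate_length,landuse_length Correlation lengths of the smooth
#'   noise fields, in cells (defaults 40 and 4: climate varies broadly,
#'   land use finely).
#' @return An [env_stack()] whose variable metadata carries a `natural`
#'   column marking natural land-use layers.
#' @export
generate_landscape <- function(seed = 1, nx = 100, ny = 100, cell_size = 100,
                               n_landuse = 10, n_soil = 4,
                               climate_length = 40, landuse_length = 4) {
  stopifnot(n_landuse >= 2, n_soil >= 2)
  lu_names <- c("heather", "semi_natural_grassland", "semi_natural_forest",
                "freshwater", "dunes", "crop", "pasture", "urban",
                "urban_green", "production_forest", "orchard", "fallow")
  lu_natural <- c(TRUE, TRUE, TRUE, TRUE, TRUE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  stopifnot(n_landuse <= length(lu_names))
  soil_names <- c("soil_sand", "soil_peat", "soil_light_clay",
                  "soil_heavy_clay", "soil_loam")
  stopifnot(n_soil <= length(soil_names))

  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  cells <- tibble::tibble(
    cell_id = seq_len(nx * ny),
    x = (col - 0.5) * cell_size,
    y = (row - 0.5) * cell_size
  )
  gx <- as.vector(scale(col))
  gy <- as.vector(scale(row))

  withr::with_seed(seed, {
    # climate: gradient directions theta_k spread over half a turn
    clim_spec <- tibble::tibble(
      variable = c("bio1", "bio4", "bio8", "bio12", "bio14", "bio15"),
      centre = c(9.5, 580, 8.0, 820, 42, 26),
      scale = c(1.1, 55, 1.0, 75, 6, 4)
    )
    clim_raw <- matrix(0, nx * ny, nrow(clim_spec))
    for (k in seq_len(nrow(clim_spec))) {
      theta <- (k - 1) * pi / 6
      g <- cos(theta) * gx + sin(theta) * gy
      # with long correlation lengths a noise field can align with an
      # earlier variable by chance; redraw until the pair stays clear of
      # the collinearity cut-off
      for (try in 1:50) {
        f <- as.vector(scale(smooth_field(nx, ny, climate_length)))
        raw <- (g + f) / sqrt(2)
        if (k == 1 || max(abs(stats::cor(
              raw, clim_raw[, seq_len(k - 1), drop = FALSE]))) <= 0.6) break
      }
      clim_raw[, k] <- raw
      cells[[clim_spec$variable[k]]] <-
        clim_spec$centre[k] + clim_spec$scale[k] * raw
    }
    # precipitation-like variables cannot go negative
    cells$bio12 <- pmax(cells$bio12, 0)
    cells$bio14 <- pmax(cells$bio14, 0)
    cells$bio15 <- pmax(cells$bio15, 0)

    # land use: clustered softmax allocation over latent short-range fields,
    # one extra latent class reserves the remainder (sum < 100)
    lat <- vapply(seq_len(n_landuse + 1), function(k) {
      as.vector(scale(smooth_field(nx, ny, landuse_length)))
    }, numeric(nx * ny))
    w <- exp(2.2 * lat)
    shares <- 100 * w[, seq_len(n_landuse), drop = FALSE] / rowSums(w)
    shares[shares < 2] <- 0
    for (k in seq_len(n_landuse)) {
      cells[[lu_names[k]]] <- shares[, k]
    }

    # soil: quantile bins of one long-range field -> contiguous regions
    for (try in 1:50) {
      sf <- as.vector(scale(smooth_field(nx, ny, climate_length)))
      if (max(abs(stats::cor(sf, clim_raw))) <= 0.55) break
    }
    breaks <- stats::quantile(sf, probs = seq(0, 1, length.out = n_soil + 1))
    bin <- cut(sf, breaks = unique(breaks), include.lowest = TRUE,
               labels = FALSE)
    for (k in seq_len(n_soil)) {
      cells[[soil_names[k]]] <- as.numeric(bin == k)
    }
  })

  vars <- tibble::tibble(
    variable = c(clim_names <- c("bio1", "bio4", "bio8", "bio12", "bio14",
                                 "bio15"),
                 lu_names[seq_len(n_landuse)], soil_names[seq_len(n_soil)]),
    category = c(rep("climate", 6), rep("land_use", n_landuse),
                 rep("soil", n_soil)),
    kind = c(rep("continuous", 6), rep("percent_cover", n_landuse),
             rep("binary_indicator", n_soil)),
    natural = c(rep(FALSE, 6), lu_natural[seq_len(n_landuse)],
                rep(FALSE, n_soil))
  )
  stack <- env_stack(cells, vars, cell_size, nx = nx, ny = ny)

  r <- stats::cor(as.matrix(env_values(stack)))
  diag(r) <- 0
  if (max(abs(r), na.rm = TRUE) > 0.7) {
    warning("generated landscape has a variable pair with |r| > 0.7")
  }
  stack
}

# smooth Gaussian field: white noise on a coarse grid, bilinearly
# interpolated to the full grid; correlation length ~ `length_cells`, capped
# so the coarse grid keeps at least 4x4 nodes (fewer degenerates to a plane)
smooth_field <- function(nx, ny, length_cells) {
  length_cells <- min(length_cells, floor(min(nx, ny) / 3))
  cx <- max(4, ceiling(nx / length_cells) + 1)
  cy <- max(4, ceiling(ny / length_cells) + 1)
  z <- matrix(stats::rnorm(cy * cx), cy, cx)
  xi <- seq(1, cx, length.out = nx)
  yi <- seq(1, cy, length.out = ny)
  x0 <- pmin(floor(xi), cx - 1); fx <- xi - x0
  y0 <- pmin(floor(yi), cy - 1); fy <- yi - y0
  out <- z[y0, x0] * ((1 - fy) %o% (1 - fx)) +
    z[y0 + 1, x0] * (fy %o% (1 - fx)) +
    z[y0, x0 + 1] * ((1 - fy) %o% fx) +
    z[y0 + 1, x0 + 1] * (fy %o% fx)
  as.vector(t(out))  # row-major: x fastest
}

#' Construct a species' niche truth
#'
#' @param species Species id.
#' @param guild `"climate_specialist"` or `"landuse_generalist"`.
#' @param linear Named vector of linear coefficients on landscape-standardised
#'   variables.
#' @param quadratic Named list of quadratic niche terms, each
#'   `list(optimum = <variable units>, curvature = <penalty per squared
#'   landscape SD>)`.
#' @param prevalence Target mean suitability over the landscape.
#' @param status Assigned Red List label (`"RL"`/`"LC"`).
#' @return A `niche_truth` list.
#' @export
niche_truth <- function(species, guild, linear = numeric(0),
                        quadratic = list(), prevalence = 0.15,
                        status = if (guild == "climate_specialist") "RL" else "LC") {
  stopifnot(guild %in% c("climate_specialist", "landuse_generalist"))
  structure(
    list(species = species, guild = guild, linear = linear,
         quadratic = quadratic, prevalence = prevalence, status = status),
    class = "niche_truth"
  )
}

#' Default niche truths for the two guilds
#'
#' Climate specialists get a quadratic niche on one climate variable with the
#' optimum planted 1.5-2.5 landscape SDs away from the landscape mean (so
#' their occurrences sit in climatically extreme, spatially restricted
#' areas) and near-zero land-use coefficients. Land-use generalists get
#' positive linear coefficients on two or three land-use layers and zero
#' climate coefficients, so they track fine-scale habitat and spread across
#' the whole extent.
#'
#' @param stack The landscape the species will live on.
#' @param n_specialist,n_generalist Guild sizes (default 20 each).
#' @param seed Integer seed.
#' @return A list of [niche_truth()] objects.
#' @export
default_truths <- function(stack, n_specialist = 20, n_generalist = 20,
                           seed = 1) {
  vars <- env_vars(stack)
  clim <- vars$variable[vars$category == "climate"]
  lu <- vars$variable[vars$category == "land_use"]
  vals <- env_values(stack)
  withr::with_seed(seed, {
    truths <- list()
    for (i in seq_len(n_specialist)) {
      v <- clim[(i - 1) %% length(clim) + 1]
      u <- stats::runif(1, 1.5, 2.5) * sample(c(-1, 1), 1)
      opt <- mean(vals[[v]]) + u * stats::sd(vals[[v]])
      truths[[length(truths) + 1]] <- niche_truth(
        species = sprintf("specialist_%02d", i),
        guild = "climate_specialist",
        quadratic = stats::setNames(
          list(list(optimum = opt,
                    curvature = stats::runif(1, 1.5, 3))), v),
        prevalence = 0.08
      )
    }
    for (i in seq_len(n_generalist)) {
      k <- sample(2:3, 1)
      lv <- sample(lu, k)
      truths[[length(truths) + 1]] <- niche_truth(
        species = sprintf("generalist_%02d", i),
        guild = "landuse_generalist",
        linear = stats::setNames(stats::runif(k, 0.5, 1.2), lv),
        prevalence = 0.25
      )
    }
    truths
  })
}

# true suitability over the stack: inverse cloglog of the linear predictor,
# intercept calibrated to the target prevalence
true_suitability <- function(truth, stack) {
  vals <- env_values(stack)
  eta <- numeric(nrow(stack))
  for (v in names(truth$linear)) {
    z <- (vals[[v]] - mean(vals[[v]])) / stats::sd(vals[[v]])
    eta <- eta + truth$linear[[v]] * z
  }
  for (v in names(truth$quadratic)) {
    q <- truth$quadratic[[v]]
    z <- (vals[[v]] - q$optimum) / stats::sd(vals[[v]])
    eta <- eta - q$curvature * z^2
  }
  f <- function(b) mean(1 - exp(-exp(b + eta))) - truth$prevalence
  b <- stats::uniroot(f, c(-20, 10))$root
  1 - exp(-exp(b + eta))
}

#' Sample occurrence records from a known niche
#'
#' Presence cells are drawn without replacement with probability proportional
#' to the true suitability (no detection model or sampling bias), and points
#' are jittered uniformly within their cell to emulate observation
#' coordinates.
#'
#' @param truth A [niche_truth()].
#' @param stack The landscape.
#' @param n_obs Number of occurrence records.
#' @param seed Integer seed.
#' @return A tibble (`species`, `x`, `y`, `year`, `cell_id`).
#' @export
generate_species <- function(truth, stack, n_obs, seed = 1) {
  s <- true_suitability(truth, stack)
  if (sum(s > 0) < n_obs) {
    stop("requested n_obs exceeds cells with non-zero suitability")
  }
  cs <- attr(stack, "cell_size")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(stack), n_obs, prob = s)
    tibble::tibble(
      species = truth$species,
      x = stack$x[idx] + stats::runif(n_obs, -cs / 2, cs / 2),
      y = stack$y[idx] + stats::runif(n_obs, -cs / 2, cs / 2),
      year = sample(2004:2019, n_obs, replace = TRUE),
      cell_id = stack$cell_id[idx]
    )
  })
}

#' Configuration for a synthetic study
#'
#' @param seed Master seed; all per-species seeds derive from it.
#' @param nx,ny,cell_size,n_landuse,n_soil Landscape parameters
#'   (see [generate_landscape()]).
#' @param n_specialist,n_generalist Guild sizes.
#' @param n_obs_range Range of per-species record counts, drawn uniformly
#'   (default 30-150).
#' @param mislabel_rate Probability of flipping a species' guild-derived
#'   status label (default 0).
#' @param european_dd_rate Probability a species is Data Deficient on the
#'   European list (default 0.2); otherwise the European status equals the
#'   Dutch one.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, nx = 100, ny = 100, cell_size = 100,
                             n_landuse = 10, n_soil = 4,
                             n_specialist = 20, n_generalist = 20,
                             n_obs_range = c(30, 150), mislabel_rate = 0,
                             european_dd_rate = 0.2) {
  structure(
    list(seed = seed, nx = nx, ny = ny, cell_size = cell_size,
         n_landuse = n_landuse, n_soil = n_soil,
         n_specialist = n_specialist, n_generalist = n_generalist,
         n_obs_range = n_obs_range, mislabel_rate = mislabel_rate,
         european_dd_rate = european_dd_rate),
    class = "synthetic_config"
  )
}

#' Generate a complete synthetic study
#'
#' Landscape, niche truths, occurrence sets and a status table, fully
#' reproducible from `(config, seed)`. Climate specialists are labelled RL
#' and land-use generalists LC (optionally mislabelled at
#' `config$mislabel_rate`); the European status mirrors the Dutch one except
#' for a Data Deficient fraction. With `out_dir` set, every interchange file
#' the pipeline reads is written there (stack CSVs + sidecar,
#' `occurrences.csv`, `statuses.csv`, `truth.json`, `config.json`).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return A `synthetic_study` list: `stack`, `occurrences`, `statuses`,
#'   `truths`, `config`.
#' @export
generate_study <- function(config = synthetic_config(), out_dir = NULL) {
  stack <- generate_landscape(
    seed = config$seed, nx = config$nx, ny = config$ny,
    cell_size = config$cell_size, n_landuse = config$n_landuse,
    n_soil = config$n_soil)
  truths <- default_truths(stack, config$n_specialist, config$n_generalist,
                           seed = config$seed + 1)
  n_sp <- length(truths)
  meta <- withr::with_seed(config$seed + 2, {
    tibble::tibble(
      n_obs = sample(config$n_obs_range[1]:config$n_obs_range[2], n_sp,
                     replace = TRUE),
      mislabel = stats::runif(n_sp) < config$mislabel_rate,
      dd = stats::runif(n_sp) < config$european_dd_rate
    )
  })
  occ <- purrr::map_dfr(seq_len(n_sp), function(i) {
    generate_species(truths[[i]], stack, meta$n_obs[i],
                     seed = config$seed + 100 + i)
  })
  dutch <- vapply(truths, function(t) t$status, "")
  dutch <- ifelse(meta$mislabel, ifelse(dutch == "RL", "LC", "RL"), dutch)
  statuses <- tibble::tibble(
    species = vapply(truths, function(t) t$species, ""),
    dutch_status = dutch,
    european_status = ifelse(meta$dd, "DD", dutch)
  )
  study <- structure(
    list(stack = stack, occurrences = occ, statuses = statuses,
         truths = truths, config = config),
    class = "synthetic_study"
  )
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(study$stack, file.path(out_dir, "stack"))
  write_occurrences(study$occurrences, file.path(out_dir, "occurrences.csv"))
  write_statuses(study$statuses, file.path(out_dir, "statuses.csv"))
  jsonlite::write_json(
    lapply(study$truths, unclass), file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(study$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
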