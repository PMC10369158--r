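# shared fixtures and independent oracles used across test files

# small env_stack from a named list/data frame of variable vectors laid out
# on an nx x ny grid (row-major, 100 m cells)
make_stack <- function(values, nx, ny, categories = NULL, kinds = NULL,
                       cell_size = 100) {
  values <- tibble::as_tibble(values)
  stopifnot(nrow(values) == nx * ny)
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  cells <- tibble::tibble(
    cell_id = seq_len(nx * ny),
    x = (col - 0.5) * cell_size,
    y = (row - 0.5) * cell_size
  )
  cells <- dplyr::bind_cols(cells, values)
  if (is.null(categories)) categories <- rep("climate", ncol(values))
  if (is.null(kinds)) kinds <- rep("continuous", ncol(values))
  vars <- tibble::tibble(variable = names(values), category = categories,
                         kind = kinds)
  env_stack(cells, vars, cell_size, nx = nx, ny = ny)
}

# gift-wrapping convex hull + shoelace area (km2): independent of chull()
brute_hull_area_km2 <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cross <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
               (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cross < 0 || (cross == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("hull failure")
  }
  hx <- pts[hull, 1]
  hy <- pts[hull, 2]
  m <- length(hull)
  if (m < 3) return(0)
  abs(sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy)) / 2 / 1e6
}

# brute-force maximum independent set size for the thinning conflict graph
brute_mis_size <- function(x, y, min_distance) {
  n <- length(x)
  stopifnot(n <= 12)
  d <- as.matrix(stats::dist(cbind(x, y)))
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) >= 2) {
      pairs <- utils::combn(idx, 2)
      ok <- all(d[t(pairs)] > min_distance)
    }
    if (ok) best <- length(idx)
  }
  best
}

# independent (unpenalised) maxent objective for oracle optimisation:
# log sum_bg exp(lam . f) - mean_pres(lam . f)
gibbs_objective <- function(lambda, f_bg, f_pres, penalty = 0) {
  sc <- as.vector(f_bg %*% lambda)
  m <- max(sc)
  m + log(sum(exp(sc - m))) - mean(as.vector(f_pres %*% lambda)) +
    sum(penalty * abs(lambda))
}

# daily series for one cell hitting exact monthly climatology targets
daily_from_monthly <- function(cell_id, year, tmean_monthly, precip_monthly) {
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  mo <- as.integer(format(dates, "%m"))
  ndays <- as.vector(table(mo))
  tibble::tibble(
    cell_id = cell_id,
    date = dates,
    tmean = tmean_monthly[mo],
    precip = precip_monthly[mo] / ndays[mo]
  )
}
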