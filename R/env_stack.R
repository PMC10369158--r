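#' Environmental predictor stack
#'
#' An `env_stack` is a tibble with one row per grid cell inside the study mask
#' and one column per environmental variable, carrying grid geometry and
#' variable metadata as attributes. Cells excluded by the mask are simply not
#' present, so every downstream sampling step (background draws, AICc grids,
#' landscape summaries) automatically respects the mask.
#'
#' Coordinates are planar metric (metres), `x`/`y` give cell centres, and the
#' grid is row-major with 1-based `cell_id = (row - 1) * nx + col`.
#'
#' @param cells A data frame with columns `cell_id`, `x`, `y` and one numeric
#'   column per variable.
#' @param vars A data frame with columns `variable`, `category` (one of
#'   `"land_use"`, `"climate"`, `"soil"`) and `kind` (one of `"percent_cover"`,
#'   `"continuous"`, `"binary_indicator"`). An optional logical `natural`
#'   column marks natural land-use layers used for natural-cover summaries.
#' @param cell_size Cell edge length in metres.
#' @param nx,ny Grid dimensions (columns, rows). Inferred from the coordinate
#'   range when omitted.
#'
#' @return A tibble of class `env_stack`.
#' @export
env_stack <- function(cells, vars, cell_size, nx = NULL, ny = NULL) {
  cells <- tibble::as_tibble(cells)
  vars <- tibble::as_tibble(vars)
  stopifnot(
    all(c("cell_id", "x", "y") %in% names(cells)),
    all(c("variable", "category", "kind") %in% names(vars))
  )
  bad_cat <- setdiff(unique(vars$category), c("land_use", "climate", "soil"))
  if (length(bad_cat) > 0) {
    stop("unknown variable category: ", paste(bad_cat, collapse = ", "))
  }
  bad_kind <- setdiff(unique(vars$kind),
                      c("percent_cover", "continuous", "binary_indicator"))
  if (length(bad_kind) > 0) {
    stop("unknown variable kind: ", paste(bad_kind, collapse = ", "))
  }
  missing_cols <- setdiff(vars$variable, names(cells))
  if (length(missing_cols) > 0) {
    stop("variables missing from cell table: ",
         paste(missing_cols, collapse = ", "))
  }
  pc <- vars$variable[vars$kind == "percent_cover"]
  for (v in pc) {
    if (any(cells[[v]] < 0 | cells[[v]] > 100, na.rm = TRUE)) {
      stop("percent cover out of [0,100] in variable '", v, "'")
    }
  }
  if (is.null(nx)) nx <- length(unique(cells$x))
  if (is.null(ny)) ny <- length(unique(cells$y))
  structure(
    cells,
    class = c("env_stack", class(tibble::tibble())),
    vars = vars,
    cell_size = cell_size,
    nx = nx,
    ny = ny
  )
}

#' Variable metadata of an environment stack
#'
#' @param stack An [env_stack()].
#' @return A tibble with columns `variable`, `category`, `kind` (and `natural`
#'   when present).
#' @export
env_vars <- function(stack) {
  attr(stack, "vars")
}

#' Environmental values at a set of variables
#'
#' @param stack An [env_stack()].
#' @param variables Character vector of variable names; default all.
#' @return A tibble of the requested variable columns (cells in mask order).
#' @export
env_values <- function(stack, variables = NULL) {
  if (is.null(variables)) variables <- env_vars(stack)$variable
  missing <- setdiff(variables, names(stack))
  if (length(missing) > 0) {
    stop("unknown variable(s): ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(stack)[, variables, drop = FALSE]
}

#' Look up stack cells containing points
#'
#' Maps point coordinates to grid cells and returns the matching stack rows.
#' Points falling outside the study mask are dropped with a message giving the
#' dropped count.
#'
#' @param stack An [env_stack()].
#' @param points A data frame with columns `x`, `y` (metres).
#' @param drop_outside Drop points whose cell is not in the mask (default) or
#'   error on them.
#' @return A tibble with the input points' columns plus the stack's variable
#'   columns and `cell_id`.
#' @export
extract_env <- function(stack, points, drop_outside = TRUE) {
  cs <- attr(stack, "cell_size")
  nx <- attr(stack, "nx")
  col <- pmin(pmax(floor(points$x / cs), 0), nx - 1)
  row <- floor(points$y / cs)
  cell_id <- row * nx + col + 1
  idx <- match(cell_id, stack$cell_id)
  keep <- setdiff(names(points), c(env_vars(stack)$variable, "cell_id"))
  out <- dplyr::bind_cols(
    tibble::as_tibble(points)[, keep, drop = FALSE],
    tibble::tibble(cell_id = cell_id),
    tibble::as_tibble(stack)[idx, env_vars(stack)$variable, drop = FALSE]
  )
  n_out <- sum(is.na(idx))
  if (n_out > 0) {
    if (!drop_outside) stop(n_out, " point(s) fall outside the study mask")
    message("dropped ", n_out, " point(s) outside the study mask")
    out <- out[!is.na(idx), , drop = FALSE]
  }
  out
}

#' Sample background points from the study mask
#'
#' Draws cells uniformly without replacement from the masked study area, the
#' presence-background contrast used by the maximum-entropy models.
#'
#' @param stack An [env_stack()].
#' @param n Number of background points (capped at the number of masked cells).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A tibble of background cells with coordinates and variable values.
#' @export
sample_background <- function(stack, n = 10000, seed = 1) {
  n <- min(n, nrow(stack))
  idx <- withr::with_seed(seed, sample.int(nrow(stack), n))
  tibble::as_tibble(stack)[sort(idx), , drop = FALSE]
}

#' @export
print.env_stack <- function(x, ...) {
  v <- env_vars(x)
  cat("<env_stack> ", attr(x, "nx"), "x", attr(x, "ny"),
      " grid, cell ", attr(x, "cell_size"), " m, ",
      nrow(x), " masked cells\n", sep = "")
  cat("  variables: ",
      paste0(v$variable, " [", substr(v$category, 1, 2), "]", collapse = ", "),
      "\n", sep = "")
  NextMethod()
}
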