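#' Read and write the pipeline's interchange files
#'
#' Rasters travel as one CSV per variable (`cell_id,x,y,value`, masked cells
#' only) plus a JSON sidecar holding each variable's category/kind and the
#' grid geometry. Occurrences and statuses are plain CSVs
#' (`species,x,y,year` and `species,dutch_status,european_status`).
#'
#' @param stack An [env_stack()].
#' @param dir Directory to write into (created if needed).
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` returns an
#'   `env_stack`.
#' @name stack_io
NULL

#' @rdname stack_io
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vars <- env_vars(stack)
  cells <- tibble::as_tibble(stack)
  for (v in vars$variable) {
    readr::write_csv(
      tibble::tibble(cell_id = cells$cell_id, x = cells$x, y = cells$y,
                     value = cells[[v]]),
      file.path(dir, paste0(sanitize_name(v), ".csv"))
    )
  }
  sidecar <- list(
    grid = list(cell_size = attr(stack, "cell_size"),
                nx = attr(stack, "nx"), ny = attr(stack, "ny")),
    variables = stats::setNames(
      lapply(seq_len(nrow(vars)), function(i) {
        out <- list(category = vars$category[i], kind = vars$kind[i],
                    file = paste0(sanitize_name(vars$variable[i]), ".csv"))
        if ("natural" %in% names(vars)) out$natural <- isTRUE(vars$natural[i])
        out
      }),
      vars$variable
    )
  )
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname stack_io
#' @export
read_stack <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "stack.json"))
  var_names <- names(sidecar$variables)
  cells <- NULL
  for (v in var_names) {
    d <- readr::read_csv(file.path(dir, sidecar$variables[[v]]$file),
                         show_col_types = FALSE)
    if (is.null(cells)) {
      cells <- d[, c("cell_id", "x", "y")]
    }
    cells[[v]] <- d$value
  }
  vars <- tibble::tibble(
    variable = var_names,
    category = unname(vapply(sidecar$variables, function(v) v$category, "")),
    kind = unname(vapply(sidecar$variables, function(v) v$kind, ""))
  )
  if (any(vapply(sidecar$variables, function(v) !is.null(v$natural), TRUE))) {
    vars$natural <- unname(vapply(sidecar$variables,
                                  function(v) isTRUE(v$natural), TRUE))
  }
  env_stack(cells, vars, sidecar$grid$cell_size,
            nx = sidecar$grid$nx, ny = sidecar$grid$ny)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_-]", "_", x)

#' @rdname stack_io
#' @param occurrences A data frame with columns `species,x,y,year` (plus
#'   `retained` after thinning).
#' @param path File path.
#' @export
write_occurrences <- function(occurrences, path) {
  readr::write_csv(tibble::as_tibble(occurrences), path)
  invisible(path)
}

#' @rdname stack_io
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(species = readr::col_character()))
}

#' @rdname stack_io
#' @param statuses A data frame `species,dutch_status,european_status`.
#' @export
write_statuses <- function(statuses, path) {
  readr::write_csv(tibble::as_tibble(statuses), path)
  invisible(path)
}

#' @rdname stack_io
#' @export
read_statuses <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
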