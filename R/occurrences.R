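#' Spatially thin occurrence records
#'
#' Subsamples records so that no two retained points lie within `min_distance`
#' (Euclidean, planar metres) of each other, reducing the clustering induced
#' by uneven recording effort. Retaining the most records subject to that
#' constraint is a maximum-independent-set problem; a greedy randomised
#' heuristic is restarted `n_restarts` times and the largest retained set is
#' kept (equal sizes: the first found under the seed's shuffle order). The
#' result is deterministic given `seed` and always maximal — no removed record
#' could be added back without violating the distance.
#'
#' @param records A data frame with columns `x`, `y` (metres) and optionally
#'   `species`; with a `species` column each species is thinned independently.
#' @param min_distance Minimum pairwise distance in metres (default 300).
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Integer seed.
#' @return The input tibble plus a logical `retained` column; attributes
#'   `n_raw` and `n_thinned` give per-species counts.
#' @export
thin_occurrences <- function(records, min_distance = 300, n_restarts = 100,
                             seed = 1) {
  stopifnot(min_distance > 0, n_restarts >= 1)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    out <- records
    out$retained <- logical(0)
    return(out)
  }
  if ("species" %in% names(records)) {
    sp <- unique(records$species)
    out <- records
    out$retained <- NA
    for (i in seq_along(sp)) {
      idx <- which(records$species == sp[i])
      out$retained[idx] <- thin_one(records$x[idx], records$y[idx],
                                    min_distance, n_restarts, seed + i - 1)
    }
  } else {
    out <- records
    out$retained <- thin_one(records$x, records$y, min_distance, n_restarts, seed)
  }
  counts <- if ("species" %in% names(out)) {
    dplyr::summarise(dplyr::group_by(out, .data$species),
                     n_raw = dplyr::n(), n_thinned = sum(.data$retained),
                     .groups = "drop")
  } else {
    tibble::tibble(n_raw = nrow(out), n_thinned = sum(out$retained))
  }
  attr(out, "n_raw") <- counts$n_raw
  attr(out, "n_thinned") <- counts$n_thinned
  out
}

thin_one <- function(x, y, min_distance, n_restarts, seed) {
  n <- length(x)
  if (n == 1) return(TRUE)
  d <- as.matrix(stats::dist(cbind(x, y)))
  conflict <- d <= min_distance
  diag(conflict) <- FALSE
  if (!any(conflict)) return(rep(TRUE, n))
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      ord <- sample.int(n)
      keep <- logical(n)
      for (i in ord) {
        if (!any(conflict[i, keep])) keep[i] <- TRUE
      }
      if (is.null(best) || sum(keep) > sum(best)) best <- keep
    }
  })
  best
}

#' Filter species with enough thinned records to model
#'
#' @param occurrences A thinned occurrence tibble (see [thin_occurrences()])
#'   with `species` and `retained` columns.
#' @param min_n Minimum number of retained records (default 15).
#' @return A tibble (`species`, `n_thinned`) of modelable species, sorted by
#'   species id.
#' @export
filter_modelable <- function(occurrences, min_n = 15) {
  occurrences <- tibble::as_tibble(occurrences)
  if (nrow(occurrences) == 0) {
    return(tibble::tibble(species = character(), n_thinned = integer()))
  }
  stopifnot(all(c("species", "retained") %in% names(occurrences)))
  occurrences |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_thinned = sum(.data$retained), .groups = "drop") |>
    dplyr::filter(.data$n_thinned >= min_n) |>
    dplyr::arrange(.data$species)
}

#' Cross-tabulate national against European Red List status
#'
#' @param statuses A data frame with columns `species`, `dutch_status`
#'   (`"LC"` or `"RL"`) and `european_status` (`"LC"`, `"RL"` or `"DD"`).
#' @param species Character vector of species to tabulate (must all appear in
#'   `statuses`).
#' @return A 2 x 3 contingency table (rows `dutch_status` LC/RL, columns
#'   `european_status` LC/RL/DD).
#' @export
cross_tabulate_status <- function(statuses, species) {
  stopifnot(length(species) > 0)
  statuses <- tibble::as_tibble(statuses)
  missing <- setdiff(species, statuses$species)
  if (length(missing) > 0) {
    stop("species missing from status table: ", paste(missing, collapse = ", "))
  }
  s <- statuses[match(species, statuses$species), ]
  table(
    dutch_status = factor(s$dutch_status, levels = c("LC", "RL")),
    european_status = factor(s$european_status, levels = c("LC", "RL", "DD"))
  )
}
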