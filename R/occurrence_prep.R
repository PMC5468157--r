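#' Thin occurrences to one record per grid cell
#'
#' Survey sign data are spatially clumped; to reduce sample-selection bias
#' the model is fitted to at most one presence per cell, chosen uniformly at
#' random among that cell's records. Points falling outside the grid extent
#' are dropped (their count is reported via the `n_dropped_outside`
#' attribute). Output rows are ordered by (row, col), so the retained set is
#' stable across seeds up to the within-cell choice.
#'
#' @param occ data.frame with `x`, `y` point coordinates (km).
#' @param geom geometry descriptor from [grid_geometry()].
#' @param seed integer seed for the within-cell draw.
#' @return data.frame `x`, `y` with one row per occupied cell; attributes
#'   `n_dropped_outside` and `cells` (the retained (row, col) pairs).
#' @export
thin_one_per_cell <- function(occ, geom, seed = 1L) {
  if (is.null(occ) || nrow(occ) == 0) {
    stop("thin_one_per_cell: empty occurrence set", call. = FALSE)
  }
  rc <- cell_of(occ[, c("x", "y")], geom)
  n_out <- sum(!rc$inside)
  keep <- which(rc$inside)
  if (length(keep) == 0) {
    stop("thin_one_per_cell: no occurrence inside the grid extent",
         call. = FALSE)
  }
  cell_id <- (rc$col[keep] - 1L) * geom$n_rows + rc$row[keep]
  set.seed(seed)
  pick <- tapply(keep, cell_id, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  })
  pick <- as.integer(pick)
  ord <- order(rc$row[pick], rc$col[pick])
  pick <- pick[ord]
  out <- data.frame(x = occ$x[pick], y = occ$y[pick])
  attr(out, "n_dropped_outside") <- n_out
  attr(out, "cells") <- data.frame(row = rc$row[pick], col = rc$col[pick])
  out
}

#' Sample target-group background points from the forest mask
#'
#' Background points are drawn uniformly over valid forest cells (cell
#' chosen uniformly with replacement, position jittered within the cell),
#' the target-group device that gives the model the same sampling universe
#' as the survey presences. Nothing is excluded by default — presence cells
#' may be drawn — since the model contrasts presences against availability,
#' not against absences.
#'
#' @param forest 0/1 forest-mask `habgrid`.
#' @param n number of points (default 10000).
#' @param seed integer seed.
#' @param exclude optional data.frame of points whose cells must not be
#'   sampled.
#' @return data.frame `x`, `y` of `n` background points.
#' @export
sample_background <- function(forest, n = 10000, seed = 1L, exclude = NULL) {
  stopifnot(n >= 1)
  geom <- grid_geometry(forest)
  ok <- !is.na(forest$values) & forest$values != 0
  if (!is.null(exclude) && nrow(exclude) > 0) {
    rc <- cell_of(exclude[, c("x", "y")], geom)
    ins <- which(rc$inside)
    ok[cbind(rc$row[ins], rc$col[ins])] <- FALSE
  }
  cells <- which(ok)
  if (length(cells) == 0) {
    stop("sample_background: no eligible forest cell", call. = FALSE)
  }
  set.seed(seed)
  idx <- cells[sample.int(length(cells), n, replace = TRUE)]
  rc <- arrayInd(idx, dim(forest$values))
  cs <- geom$cell_size_km
  ctr <- cell_center(rc[, 1], rc[, 2], geom)
  data.frame(x = ctr[, 1] + stats::runif(n, -0.5, 0.5) * cs,
             y = ctr[, 2] + stats::runif(n, -0.5, 0.5) * cs)
}
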