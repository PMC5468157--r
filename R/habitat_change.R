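#' Binarize a suitability surface into a habitat map
#'
#' A cell is suitable iff its suitability is at least the threshold
#' (inclusive — a cell scoring exactly the cutoff counts as habitat);
#' nodata cells are never suitable and stay invalid.
#'
#' @param suitability `habgrid` of continuous suitability.
#' @param threshold cutoff in (0, 1).
#' @param scenario_label text label carried through reports.
#' @return object of class `habitat_map`: `suitable` (logical matrix),
#'   `valid` (logical matrix), `threshold`, `scenario_label`, grid geometry
#'   fields.
#' @export
binarize <- function(suitability, threshold, scenario_label = "scenario") {
  stopifnot(threshold > 0, threshold < 1)
  v <- suitability$values
  structure(list(
    suitable = !is.na(v) & v >= threshold,
    valid = !is.na(v),
    threshold = threshold, scenario_label = scenario_label,
    cell_size_km = suitability$cell_size_km,
    origin_xy = suitability$origin_xy), class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("<habitat_map> '%s': %.0f km2 suitable of %.0f valid (t = %.4f)\n",
              x$scenario_label, area_km2(x$suitable, x$cell_size_km),
              area_km2(x$valid, x$cell_size_km), x$threshold))
  invisible(x)
}

#' Label connected habitat patches
#'
#' Connected-component labeling of suitable cells under 4- or 8-neighbor
#' connectivity (8 by default downstream: diagonally touching habitat is
#' treated as continuous).
#'
#' @param map a [binarize()] habitat map.
#' @param connectivity 4 or 8.
#' @return object of class `patch_set`: `labels` (integer matrix, 0 = no
#'   patch), `patches` (data.frame id, n_cells, area_km2), plus geometry.
#' @export
label_patches <- function(map, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  suit <- map$suitable
  nr <- nrow(suit); nc <- ncol(suit)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  lab <- 0L
  todo <- which(suit)
  stack_buf <- integer(length(todo))
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    top <- 1L
    stack_buf[1L] <- start
    labels[start] <- lab
    while (top > 0L) {
      cur <- stack_buf[top]; top <- top - 1L
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- c + dc[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        nx <- (cc - 1L) * nr + rr
        if (suit[nx] && labels[nx] == 0L) {
          labels[nx] <- lab
          top <- top + 1L
          stack_buf[top] <- nx
        }
      }
    }
  }
  csz <- map$cell_size_km
  if (lab > 0L) {
    counts <- tabulate(labels[labels > 0L], nbins = lab)
  } else counts <- integer(0)
  structure(list(
    labels = labels,
    patches = data.frame(id = seq_len(lab), n_cells = counts,
                         area_km2 = counts * csz^2),
    connectivity = connectivity, cell_size_km = csz,
    origin_xy = map$origin_xy, threshold = map$threshold,
    scenario_label = map$scenario_label, valid = map$valid),
    class = "patch_set")
}

# Minimum edge-to-edge distance between two patches: closest cell-center
# distance minus one cell size, floored at 0 (adjacent or diagonal cells
# have gap 0).
patch_gap_km <- function(cells_a, cells_b, cell_size_km) {
  # cells_*: two-column (row, col) matrices
  d2min <- Inf
  for (i in seq_len(nrow(cells_a))) {
    d2 <- (cells_b[, 1] - cells_a[i, 1])^2 + (cells_b[, 2] - cells_a[i, 2])^2
    d2min <- min(d2min, min(d2))
  }
  max(0, (sqrt(d2min) - 1) * cell_size_km)
}

#' Filter habitat patches by area and isolation
#'
#' Implements the home-range/dispersal rule: a patch is removed iff it is
#' both small (area below `min_area_km2`) and isolated (minimum edge-to-edge
#' gap to the nearest other retained patch above `max_gap_km`). The rule is
#' applied iteratively to a fixed point, since a removal can isolate further
#' small patches. With `conjunction = FALSE` the two conditions act as
#' independent filters instead (small OR isolated is removed).
#'
#' @param patches a [label_patches()] result.
#' @param min_area_km2 minimum viable patch area (default 4, a minimum
#'   home-range size).
#' @param max_gap_km maximum bridgeable gap (default 0.5, a daily dispersal
#'   distance).
#' @param conjunction if `TRUE` (default) remove only patches failing both
#'   criteria.
#' @return a `habitat_map` containing only the retained patches; attribute
#'   `removed_ids` lists the dropped patch ids.
#' @export
filter_patches <- function(patches, min_area_km2 = 4, max_gap_km = 0.5,
                           conjunction = TRUE) {
  labels <- patches$labels
  csz <- patches$cell_size_km
  ids <- patches$patches$id
  cells <- lapply(ids, function(i) which(labels == i, arr.ind = TRUE))
  area <- patches$patches$area_km2
  retained <- ids
  small <- ids[area < min_area_km2]
  if (!conjunction) {
    # independent filters: drop small patches, then drop isolated ones
    retained <- setdiff(retained, small)
    repeat {
      if (length(retained) <= 1) break
      iso <- vapply(retained, function(i) {
        gaps <- vapply(setdiff(retained, i), function(j)
          patch_gap_km(cells[[i]], cells[[j]], csz), numeric(1))
        min(gaps) > max_gap_km
      }, logical(1))
      if (!any(iso)) break
      retained <- retained[!iso]
    }
  } else {
    repeat {
      small_ret <- intersect(small, retained)
      if (length(small_ret) == 0) break
      drop <- integer(0)
      for (i in small_ret) {
        others <- setdiff(retained, i)
        if (length(others) == 0) {
          drop <- c(drop, i)  # lone small patch: isolated by definition
          next
        }
        gaps <- vapply(others, function(j)
          patch_gap_km(cells[[i]], cells[[j]], csz), numeric(1))
        if (min(gaps) > max_gap_km) drop <- c(drop, i)
      }
      if (length(drop) == 0) break
      retained <- setdiff(retained, drop)
    }
  }
  suit <- matrix(FALSE, nrow(labels), ncol(labels))
  for (i in retained) suit[cells[[i]]] <- TRUE
  out <- structure(list(
    suitable = suit, valid = patches$valid, threshold = patches$threshold,
    scenario_label = patches$scenario_label, cell_size_km = csz,
    origin_xy = patches$origin_xy), class = "habitat_map")
  attr(out, "removed_ids") <- setdiff(ids, retained)
  out
}

#' Four-category habitat change classification
#'
#' Cellwise comparison of two aligned binary habitat maps:
#' suitable in both = unchanged; suitable now only = vulnerable; suitable in
#' the future only = new; suitable in neither = unsuitable. The four
#' categories partition the valid domain.
#'
#' @param current,future `habitat_map`s on the same geometry.
#' @return object of class `change_map`: `category` (integer matrix coded
#'   0 unsuitable, 1 unchanged, 2 vulnerable, 3 new, `NA` invalid),
#'   `areas_km2` (named: unchanged, vulnerable, new, unsuitable), geometry
#'   fields and scenario labels.
#' @export
classify_change <- function(current, future) {
  if (!identical(dim(current$suitable), dim(future$suitable)) ||
      abs(current$cell_size_km - future$cell_size_km) > 1e-9 ||
      any(abs(current$origin_xy - future$origin_xy) > 1e-6)) {
    stop("classify_change: maps are not aligned", call. = FALSE)
  }
  valid <- current$valid & future$valid
  cat_m <- matrix(NA_integer_, nrow(valid), ncol(valid))
  cur <- current$suitable; fut <- future$suitable
  cat_m[valid & cur & fut] <- 1L
  cat_m[valid & cur & !fut] <- 2L
  cat_m[valid & !cur & fut] <- 3L
  cat_m[valid & !cur & !fut] <- 0L
  csz <- current$cell_size_km
  areas <- c(unchanged = sum(cat_m == 1L, na.rm = TRUE),
             vulnerable = sum(cat_m == 2L, na.rm = TRUE),
             new = sum(cat_m == 3L, na.rm = TRUE),
             unsuitable = sum(cat_m == 0L, na.rm = TRUE)) * csz^2
  structure(list(category = cat_m, areas_km2 = areas, valid = valid,
                 cell_size_km = csz, origin_xy = current$origin_xy,
                 scenario_labels = c(current$scenario_label,
                                     future$scenario_label)),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  a <- x$areas_km2
  cat(sprintf(
    "<change_map> %s -> %s: unchanged %.0f, vulnerable %.0f, new %.0f, unsuitable %.0f km2\n",
    x$scenario_labels[1], x$scenario_labels[2], a["unchanged"],
    a["vulnerable"], a["new"], a["unsuitable"]))
  invisible(x)
}

#' Vulnerability indicators from suitable-habitat areas
#'
#' The three range-shift indicators:
#' area change `AC = (A_f - A_c)/A_c * 100`; habitat loss
#' `SH_c = (A_c - A_fc)/A_c * 100` (share of current habitat becoming
#' unsuitable); habitat gain `SH_f = (A_f - A_fc)/A_f * 100` (share of
#' future habitat that is newly gained). `A_c`, `A_f` and `A_fc` are the
#' current, future and overlapping suitable areas. Undefined ratios (zero
#' denominator) are reported as `NA`.
#'
#' @param A_c,A_f,A_fc areas in km^2 with `A_fc <= min(A_c, A_f)`.
#' @return list of class `vuln_indicators`: the three areas, `AC`, `SH_c`,
#'   `SH_f` (percent), and derived `vulnerable_km2`, `new_km2`,
#'   `net_change_km2`.
#' @export
indicators_from_areas <- function(A_c, A_f, A_fc) {
  if (A_fc > min(A_c, A_f) + 1e-9) {
    stop("indicators_from_areas: overlap exceeds a scenario area",
         call. = FALSE)
  }
  structure(list(
    A_c = A_c, A_f = A_f, A_fc = A_fc,
    AC = if (A_c > 0) (A_f - A_c) / A_c * 100 else NA_real_,
    SH_c = if (A_c > 0) (A_c - A_fc) / A_c * 100 else NA_real_,
    SH_f = if (A_f > 0) (A_f - A_fc) / A_f * 100 else NA_real_,
    vulnerable_km2 = A_c - A_fc, new_km2 = A_f - A_fc,
    net_change_km2 = A_f - A_c), class = "vuln_indicators")
}

#' Vulnerability indicators of a change map
#'
#' `A_c` is the unchanged-plus-vulnerable area, `A_f` unchanged-plus-new,
#' `A_fc` the unchanged area; indicators follow from
#' [indicators_from_areas()].
#'
#' @param change a [classify_change()] result.
#' @return a `vuln_indicators` list.
#' @export
indicators <- function(change) {
  a <- change$areas_km2
  indicators_from_areas(A_c = a[["unchanged"]] + a[["vulnerable"]],
                        A_f = a[["unchanged"]] + a[["new"]],
                        A_fc = a[["unchanged"]])
}

#' @export
print.vuln_indicators <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("<vuln_indicators> A_c %.2f, A_f %.2f, A_fc %.2f km2\n",
              x$A_c, x$A_f, x$A_fc))
  cat(sprintf("  AC %s, SH_c %s, SH_f %s\n", fmt(x$AC), fmt(x$SH_c),
              fmt(x$SH_f)))
  invisible(x)
}

#' Mann-Whitney rank test on two samples
#'
#' Reports the U statistic of the first sample, the tie-corrected normal
#' approximation z with 0.5 continuity correction, a two-sided p, and group
#' summaries. When there are no ties and `n1 * n2 <= exact_limit` the exact
#' U distribution replaces the normal approximation for the p-value (the z
#' is still reported).
#'
#' @param x,y numeric samples.
#' @param exact_limit use the exact null distribution when `n1 * n2` is at
#'   most this (and the data are tie-free).
#' @return list of class `rank_test`: `U`, `z`, `p`, `exact` (logical),
#'   `mean_x`, `sd_x`, `mean_y`, `sd_y`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y, exact_limit = 400) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("mann_whitney: empty group", call. = FALSE)
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- if (sigma2 <= 0 || U == mu) 0 else {
    cc <- 0.5 * sign(U - mu)   # continuity correction toward the mean
    (U - mu - cc) / sqrt(sigma2)
  }
  no_ties <- length(ties) == n
  if (no_ties && n1 * n2 <= exact_limit) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(U = U, z = z, p = p, exact = exact,
                 mean_x = mean(x), sd_x = stats::sd(x),
                 mean_y = mean(y), sd_y = stats::sd(y),
                 n_x = n1, n_y = n2), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "<rank_test> U = %.1f, z = %.3f, p = %.4g%s; group1 %.2f +/- %.2f (n=%d), group2 %.2f +/- %.2f (n=%d)\n",
    x$U, x$z, x$p, if (x$exact) " (exact)" else "",
    x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y))
  invisible(x)
}

#' Elevation contrast between two habitat maps
#'
#' Compares the elevations of suitable cells (one value per cell) under the
#' two scenarios with a Mann-Whitney rank test; the first group is the
#' current scenario.
#'
#' @param current,future `habitat_map`s.
#' @param elevation `habgrid` of elevations on the same geometry.
#' @return a [mann_whitney()] `rank_test`.
#' @export
elevation_contrast <- function(current, future, elevation) {
  e_cur <- elevation$values[current$suitable & !is.na(elevation$values)]
  e_fut <- elevation$values[future$suitable & !is.na(elevation$values)]
  if (length(e_cur) == 0 || length(e_fut) == 0) {
    stop("elevation_contrast: a scenario has no suitable habitat",
         call. = FALSE)
  }
  mann_whitney(e_cur, e_fut)
}

#' Write a change map as a coded ASCII grid
#'
#' Codes: 0 unsuitable, 1 unchanged, 2 vulnerable, 3 new; invalid cells are
#' nodata.
#'
#' @param change a `change_map`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_change_asc <- function(change, path) {
  m <- change$category
  storage.mode(m) <- "double"
  g <- habgrid(m, change$cell_size_km, change$origin_xy, "change_category")
  write_asc(g, path)
}
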