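#' Rasterize reserve polygons to a label grid
#'
#' A cell belongs to a reserve iff its center lies inside the polygon
#' (boundary counts as inside); on overlap the first-listed reserve wins,
#' with a warning. Polygon holes are honored: a center inside a hole ring is
#' outside the reserve.
#'
#' @param reserves a `reserve_set` (see [read_reserves_geojson()] /
#'   [make_reserves()]).
#' @param geom geometry descriptor of the habitat grids.
#' @return list of class `reserve_labels`: `labels` (integer matrix, 0 =
#'   unprotected), `names` (reserve name per label).
#' @export
rasterize_reserves <- function(reserves, geom) {
  nr <- geom$n_rows; nc <- geom$n_cols
  ctr <- cell_center(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr), geom)
  labels <- matrix(0L, nr, nc)
  overlap_warned <- FALSE
  for (i in seq_along(reserves)) {
    f <- reserves[[i]]
    for (ri in seq_along(f$rings)) {
      r <- f$rings[[ri]]
      if (nrow(r) < 4 || any(!is.finite(r))) {
        stop(sprintf("rasterize_reserves: invalid ring in reserve '%s'",
                     f$name), call. = FALSE)
      }
    }
    outer_ring <- f$rings[[1]]
    inside <- sp::point.in.polygon(ctr[, 1], ctr[, 2],
                                   outer_ring[, 1], outer_ring[, 2]) > 0
    if (length(f$rings) > 1) {
      for (h in f$rings[-1]) {
        in_hole <- sp::point.in.polygon(ctr[, 1], ctr[, 2],
                                        h[, 1], h[, 2]) == 1
        inside <- inside & !in_hole
      }
    }
    if (!any(inside)) {
      warning(sprintf("reserve '%s' covers no cell center", f$name))
      next
    }
    taken <- labels[inside] != 0L
    if (any(taken) && !overlap_warned) {
      warning("overlapping reserves: overlap cells labeled to the first listed")
      overlap_warned <- TRUE
    }
    sel <- inside & labels == 0L
    labels[sel] <- i
  }
  structure(list(labels = labels,
                 names = vapply(reserves, `[[`, character(1), "name")),
            class = "reserve_labels")
}

#' Suitable habitat area inside each reserve
#'
#' @param labels a [rasterize_reserves()] result.
#' @param habitat a `habitat_map` on the same geometry.
#' @return data.frame: `reserve`, `area_km2` (suitable area inside the
#'   reserve; 0 for reserves with no overlap).
#' @export
per_reserve_areas <- function(labels, habitat) {
  if (!identical(dim(labels$labels), dim(habitat$suitable))) {
    stop("per_reserve_areas: label grid and habitat map are not aligned",
         call. = FALSE)
  }
  csz <- habitat$cell_size_km
  n_res <- length(labels$names)
  counts <- tabulate(labels$labels[habitat$suitable], nbins = n_res)
  data.frame(reserve = labels$names, area_km2 = counts * csz^2)
}

#' Per-reserve percentage of area change
#'
#' `AC = (future - current) / current * 100`; reserves with no current
#' suitable habitat have undefined change, reported as `NA` (printed "--").
#'
#' @param areas_current,areas_future data.frames from [per_reserve_areas()]
#'   (same reserves, same order or matched by name).
#' @return data.frame: `reserve`, `current_km2`, `future_km2`, `AC_pct`.
#' @export
reserve_change <- function(areas_current, areas_future) {
  i <- match(areas_current$reserve, areas_future$reserve)
  if (anyNA(i)) stop("reserve_change: reserve names do not match",
                     call. = FALSE)
  cur <- areas_current$area_km2
  fut <- areas_future$area_km2[i]
  data.frame(reserve = areas_current$reserve, current_km2 = cur,
             future_km2 = fut,
             AC_pct = ifelse(cur > 0, (fut - cur) / cur * 100, NA_real_))
}

#' Network protection percentages
#'
#' Percentage of suitable habitat lying inside the union of all reserves,
#' per scenario. Computed on the union of labeled cells, so overlapping
#' polygons are not double counted.
#'
#' @param labels a [rasterize_reserves()] result.
#' @param habitat_current,habitat_future `habitat_map`s.
#' @return named numeric: `protected_current_pct`, `protected_future_pct`.
#' @export
network_protection <- function(labels, habitat_current, habitat_future) {
  in_res <- labels$labels != 0L
  pct <- function(hab) {
    tot <- sum(hab$suitable)
    if (tot == 0) stop("network_protection: empty habitat", call. = FALSE)
    100 * sum(hab$suitable & in_res) / tot
  }
  c(protected_current_pct = pct(habitat_current),
    protected_future_pct = pct(habitat_future))
}

#' Consolidated reserve gap report
#'
#' @param labels a [rasterize_reserves()] result.
#' @param habitat_current,habitat_future `habitat_map`s.
#' @return list of class `reserve_report`: `table` (per-reserve areas and
#'   AC), `network` (protection percentages).
#' @export
reserve_report <- function(labels, habitat_current, habitat_future) {
  tab <- reserve_change(per_reserve_areas(labels, habitat_current),
                        per_reserve_areas(labels, habitat_future))
  structure(list(table = tab,
                 network = network_protection(labels, habitat_current,
                                              habitat_future)),
            class = "reserve_report")
}

#' @export
print.reserve_report <- function(x, ...) {
  cat("<reserve_report>\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    ac <- if (is.na(tab$AC_pct[i])) "   --" else sprintf("%8.2f", tab$AC_pct[i])
    cat(sprintf("  %-22s %9.2f %9.2f  %s\n", tab$reserve[i],
                tab$current_km2[i], tab$future_km2[i], ac))
  }
  cat(sprintf("  network: %.2f%% current, %.2f%% future habitat protected\n",
              x$network["protected_current_pct"],
              x$network["protected_future_pct"]))
  invisible(x)
}

#' Synthesize label and habitat grids realizing a per-reserve area table
#'
#' Builds a synthetic rasterized reserve network and a pair of binary
#' habitat maps whose per-reserve suitable areas equal a given table and
#' whose scenario totals equal given network totals, so that overlay
#' arithmetic on published area tables can be exercised through the same
#' raster code path as a real analysis. The spatial arrangement is an
#' arbitrary block layout; only the areas are meaningful. Every area must
#' be an exact multiple of the cell area (0.01 km^2 at the default 0.1-km
#' cell).
#'
#' @param areas data.frame with `reserve`, `current_km2`, `future_km2`.
#' @param total_current_km2,total_future_km2 network-wide suitable areas
#'   (at least the column sums).
#' @param cell_size_km cell edge; 0.1 km represents two-decimal km^2 areas
#'   exactly.
#' @return list: `labels` (a `reserve_labels`), `current`, `future`
#'   (`habitat_map`s).
#' @export
synthetic_reserve_grids <- function(areas, total_current_km2,
                                    total_future_km2, cell_size_km = 0.1) {
  ca <- cell_size_km^2
  to_cells <- function(a) {
    n <- round(a / ca)
    if (any(abs(n * ca - a) > 1e-6)) {
      stop("synthetic_reserve_grids: area not a multiple of the cell area",
           call. = FALSE)
    }
    as.integer(n)
  }
  cur <- to_cells(areas$current_km2)
  fut <- to_cells(areas$future_km2)
  cur_out <- to_cells(total_current_km2) - sum(cur)
  fut_out <- to_cells(total_future_km2) - sum(fut)
  if (cur_out < 0 || fut_out < 0) {
    stop("synthetic_reserve_grids: totals below the column sums", call. = FALSE)
  }
  blocks <- pmax(cur, fut)
  n_cells <- sum(blocks) + max(cur_out, fut_out)
  nc <- 1000L
  nr <- as.integer(ceiling(n_cells / nc))
  n_pad <- nr * nc
  lab <- integer(n_pad)
  s_cur <- logical(n_pad)
  s_fut <- logical(n_pad)
  at <- 0L
  for (i in seq_along(blocks)) {
    if (blocks[i] > 0) lab[at + seq_len(blocks[i])] <- i
    if (cur[i] > 0) s_cur[at + seq_len(cur[i])] <- TRUE
    if (fut[i] > 0) s_fut[at + seq_len(fut[i])] <- TRUE
    at <- at + blocks[i]
  }
  if (cur_out > 0) s_cur[at + seq_len(cur_out)] <- TRUE
  if (fut_out > 0) s_fut[at + seq_len(fut_out)] <- TRUE
  origin <- c(0, nr * cell_size_km)
  mk_map <- function(s, labl) {
    structure(list(suitable = matrix(s, nr, nc),
                   valid = matrix(TRUE, nr, nc), threshold = 0.5,
                   scenario_label = labl, cell_size_km = cell_size_km,
                   origin_xy = origin), class = "habitat_map")
  }
  list(labels = structure(list(labels = matrix(lab, nr, nc),
                               names = as.character(areas$reserve)),
                          class = "reserve_labels"),
       current = mk_map(s_cur, "current"), future = mk_map(s_fut, "future"))
}
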