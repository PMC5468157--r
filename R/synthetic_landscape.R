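#' Scenario specification for the synthetic landscape generator
#'
#' The generator emulates the statistical structure of the real inputs the
#' pipeline was designed for: spatially autocorrelated bioclimatic surfaces
#' on a 1-km equal-area grid, a future scenario derived from the current one
#' by an additive temperature anomaly and a multiplicative precipitation
#' scaling (a mid-range warming pathway), an elevation gradient with ridge
#' noise, a forest mask, and linear-feature density layers held constant
#' between scenarios.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param cell_size_km cell edge, km.
#' @param n_climate_layers number of climate layers; the first half
#'   (rounded up) are temperature-like, the rest precipitation-like.
#' @param autocorrelation_range_cells box-kernel width used to low-pass the
#'   white-noise component of every surface.
#' @param temperature_delta additive future warming, degrees C (default +1.5,
#'   mid-range for a stabilization pathway by mid-century).
#' @param precipitation_scale multiplicative future precipitation factor.
#' @param forest_fraction fraction of cells covered by the forest mask.
#' @param seed integer seed; every generator product is a pure function of
#'   the spec (including this seed).
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_rows = 100, n_cols = 100, cell_size_km = 1,
                          n_climate_layers = 6,
                          autocorrelation_range_cells = 9,
                          temperature_delta = 1.5,
                          precipitation_scale = 0.9,
                          forest_fraction = 0.6,
                          seed = 1L) {
  if (n_rows < 1 || n_cols < 1) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  if (n_climate_layers < 1) stop("need at least one climate layer", call. = FALSE)
  if (forest_fraction <= 0 || forest_fraction > 1) {
    stop("forest_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_km = cell_size_km, n_climate_layers = as.integer(n_climate_layers),
    autocorrelation_range_cells = autocorrelation_range_cells,
    temperature_delta = temperature_delta,
    precipitation_scale = precipitation_scale,
    forest_fraction = forest_fraction, seed = as.integer(seed)
  ), class = "scenario_spec")
}

# Box-smoothed standardized white noise: two separable box passes (kernel
# width w) over reflect-padded noise, then centred and scaled to sd 1.
smooth_field <- function(n_rows, n_cols, range_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  w <- max(1L, as.integer(round(range_cells)))
  if (w > 1L) {
    z <- box_blur(box_blur(z, w), w)
  }
  (z - mean(z)) / stats::sd(z)
}

box_blur <- function(m, w) {
  half <- w %/% 2L
  pad <- function(idx, n) pmin(pmax(idx, 1L), n)  # replicate padding
  nr <- nrow(m); nc <- ncol(m)
  # rows
  out <- matrix(0, nr, nc)
  for (d in (-half):(w - half - 1L)) out <- out + m[pad(seq_len(nr) + d, nr), , drop = FALSE]
  m <- out / w
  # cols
  out <- matrix(0, nr, nc)
  for (d in (-half):(w - half - 1L)) out <- out + m[, pad(seq_len(nc) + d, nc), drop = FALSE]
  out / w
}

#' Generate a synthetic landscape
#'
#' Produces aligned current and future climate stacks, an elevation model
#' decreasing north to south with ridge noise, a forest mask, and river,
#' road and settlement density layers (identical in both scenarios, as
#' future projections of such variables are unavailable in practice).
#' Temperature-like layers follow a lapse rate on elevation plus smooth
#' noise; their future versions add an anomaly field whose mean equals
#' `temperature_delta` exactly. Precipitation-like layers are positive
#' log-smooth fields; their future versions are scaled by a field of mean
#' `precipitation_scale`.
#'
#' @param spec a [scenario_spec()].
#' @return list with `current` and `future` [habstack()]s (climate layers,
#'   `elevation`, `river_density`, `road_density`, `settlement_density`),
#'   `forest` (0/1 `habgrid`), and `geometry`.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols
  rng <- spec$autocorrelation_range_cells
  geom_origin <- c(0, nr * spec$cell_size_km)  # x grows east, y north
  mk <- function(m, name) habgrid(m, spec$cell_size_km, geom_origin, name)

  row_frac <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)

  # elevation: high northern ridge falling to southern lowlands, m
  elev <- 3200 - 2600 * row_frac + 320 * smooth_field(nr, nc, rng)
  elev <- pmax(elev, 220)

  n_temp <- ceiling(spec$n_climate_layers / 2)
  n_prec <- spec$n_climate_layers - n_temp
  temp_base <- c(22, 30, 36, 18, 26, 33)   # recycled if more layers asked
  lapse <- c(6.5, 5.2, 7.0, 6.0, 5.6, 6.8) # degC per km of elevation
  cur <- list()
  for (i in seq_len(n_temp)) {
    b <- temp_base[(i - 1L) %% 6L + 1L]; l <- lapse[(i - 1L) %% 6L + 1L]
    cur[[paste0("temp", i)]] <- b - l * elev / 1000 +
      0.8 * smooth_field(nr, nc, rng)
  }
  prec_base <- c(820, 160, 410, 95, 640, 230) # mm
  for (i in seq_len(n_prec)) {
    b <- prec_base[(i - 1L) %% 6L + 1L]
    cur[[paste0("prec", i)]] <- b *
      exp(0.30 * smooth_field(nr, nc, rng) + 0.25 * (1 - row_frac))
  }

  # future: additive anomaly on temperature (mean exactly the delta),
  # multiplicative field on precipitation (mean exactly the scale)
  # spatial heterogeneity of the change scales with its magnitude, so a
  # null scenario (delta 0, scale 1) leaves the future bit-identical
  fut <- cur
  for (i in seq_len(n_temp)) {
    anom <- spec$temperature_delta * (1 + 0.15 * smooth_field(nr, nc, rng))
    fut[[paste0("temp", i)]] <- cur[[paste0("temp", i)]] + anom
  }
  for (i in seq_len(n_prec)) {
    sc <- 1 + (spec$precipitation_scale - 1) *
      (1 + 0.15 * smooth_field(nr, nc, rng))
    fut[[paste0("prec", i)]] <- cur[[paste0("prec", i)]] * sc
  }

  # static layers: nonnegative smooth densities (km per km^2 style units)
  river <- pmax(0.9 + 0.8 * smooth_field(nr, nc, rng), 0)
  road <- pmax(0.6 + 0.6 * smooth_field(nr, nc, rng), 0)
  settl <- pmax(0.4 + 0.5 * smooth_field(nr, nc, rng), 0)
  static <- list(elevation = elev, river_density = river,
                 road_density = road, settlement_density = settl)

  forest_score <- smooth_field(nr, nc, rng) + 0.5 * (1 - row_frac)
  forest <- (forest_score >=
             stats::quantile(forest_score, 1 - spec$forest_fraction)) * 1

  to_stack <- function(lst) {
    habstack(mapply(mk, lst, names(lst), SIMPLIFY = FALSE))
  }
  list(
    current = to_stack(c(cur, static)),
    future = to_stack(c(fut, static)),
    forest = mk(forest, "forest"),
    geometry = grid_geometry(mk(elev, "elevation"))
  )
}

#' Ground-truth suitability specification
#'
#' The true suitability surface is a logistic-linear model in the generated
#' layers: for each named layer a linear and a quadratic coefficient (on raw
#' layer units), an optional Gaussian elevation term
#' `-((elev - optimum)/breadth)^2`, and an intercept. The default truth is a
#' narrow-niche montane specialist: a Gaussian optimum on the first
#' temperature layer (9.5 C, breadth 1.2 C, written out as its linear and
#' quadratic coefficients), so additive warming moves the suitable band
#' upslope, plus a positive precipitation effect and a broad elevation
#' optimum; road and settlement densities have no effect and act as decoy
#' predictors.
#'
#' @param coefficients named list; each element a length-2 numeric
#'   `c(linear, quadratic)` for the layer of that name.
#' @param elevation_optimum,elevation_breadth Gaussian elevation term in m;
#'   `NA` optimum disables the term.
#' @param intercept logit-scale intercept.
#' @return list of class `truth_spec`.
#' @export
truth_spec <- function(coefficients = list(temp1 = c(2 * 9.5 / 1.44, -1 / 1.44),
                                           prec1 = c(0.004, 0)),
                       elevation_optimum = 1800,
                       elevation_breadth = 600,
                       intercept = -9.5^2 / 1.44 - 3) {
  structure(list(coefficients = coefficients,
                 elevation_optimum = elevation_optimum,
                 elevation_breadth = elevation_breadth,
                 intercept = intercept),
            class = "truth_spec")
}

#' Evaluate true suitability over a stack
#'
#' @param stack a [habstack()] containing every layer named in `truth`.
#' @param truth a [truth_spec()].
#' @return `habgrid` of suitability in \[0, 1\]; nodata propagates.
#' @export
true_suitability <- function(stack, truth) {
  stopifnot(inherits(truth, "truth_spec"))
  geom <- stack$geometry
  eta <- matrix(truth$intercept, geom$n_rows, geom$n_cols)
  for (nm in names(truth$coefficients)) {
    if (is.null(stack$layers[[nm]])) {
      stop(sprintf("true_suitability: layer '%s' not in stack", nm),
           call. = FALSE)
    }
    v <- stack$layers[[nm]]$values
    b <- truth$coefficients[[nm]]
    eta <- eta + b[1] * v + b[2] * v^2
  }
  if (!is.na(truth$elevation_optimum)) {
    if (is.null(stack$layers$elevation)) {
      stop("true_suitability: elevation layer required by truth", call. = FALSE)
    }
    e <- stack$layers$elevation$values
    eta <- eta - ((e - truth$elevation_optimum) / truth$elevation_breadth)^2
  }
  g1 <- stack$layers[[1]]
  habgrid(stats::plogis(eta), g1$cell_size_km, g1$origin_xy, "true_suitability")
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn with replacement from valid forest cells with probability
#' proportional to suitability; each point is jittered uniformly within its
#' cell, so several records can share a cell (keeping downstream one-per-cell
#' thinning meaningful).
#'
#' @param suitability `habgrid` in \[0, 1\].
#' @param forest 0/1 forest-mask `habgrid` on the same geometry.
#' @param n number of points (default 273, a survey-scale sign count).
#' @param seed integer seed.
#' @return data.frame with `x`, `y` (km).
#' @export
sample_occurrences <- function(suitability, forest, n = 273, seed = 1L) {
  stopifnot(n >= 1)
  assert_aligned(list(suitability = suitability, forest = forest))
  geom <- grid_geometry(suitability)
  w <- suitability$values
  w[is.na(w)] <- 0
  w[is.na(forest$values) | forest$values == 0] <- 0
  if (sum(w) <= 0) {
    stop("sample_occurrences: no eligible forest cell with positive suitability",
         call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  rc <- arrayInd(idx, dim(w))
  cs <- geom$cell_size_km
  ctr <- cell_center(rc[, 1], rc[, 2], geom)
  data.frame(x = ctr[, 1] + stats::runif(n, -0.5, 0.5) * cs,
             y = ctr[, 2] + stats::runif(n, -0.5, 0.5) * cs)
}

#' Generate non-overlapping rectangular reserves
#'
#' Places axis-aligned rectangular reserves (snapped to cell edges) at
#' random without overlap; sizes are drawn so the network covers roughly
#' `coverage_fraction` of the extent.
#'
#' @param geom geometry descriptor.
#' @param n_reserves number of reserves (default 19, a realistic provincial
#'   network size).
#' @param seed integer seed.
#' @param coverage_fraction approximate total fraction of the extent covered.
#' @param max_tries placement retries per reserve before giving up.
#' @return `reserve_set`: list of features, each `list(name, rings)` where
#'   `rings[[1]]` is the outer ring as a closed two-column matrix (km).
#' @export
make_reserves <- function(geom, n_reserves = 19, seed = 1L,
                          coverage_fraction = 0.25, max_tries = 2000) {
  stopifnot(n_reserves >= 1)
  set.seed(seed)
  cs <- geom$cell_size_km
  W <- geom$n_cols; H <- geom$n_rows
  target_cells <- coverage_fraction * W * H / n_reserves
  side <- sqrt(target_cells)
  boxes <- matrix(NA_real_, 0, 4) # c0, r0, w, h in cells
  for (i in seq_len(n_reserves)) {
    placed <- FALSE
    for (tr in seq_len(max_tries)) {
      w <- max(1L, round(stats::runif(1, 0.6, 1.5) * side))
      h <- max(1L, round(stats::runif(1, 0.6, 1.5) * side))
      if (w > W || h > H) next
      c0 <- sample.int(W - w + 1L, 1L) - 1L
      r0 <- sample.int(H - h + 1L, 1L) - 1L
      overlap <- FALSE
      if (nrow(boxes) > 0) {
        overlap <- any(c0 < boxes[, 1] + boxes[, 3] & boxes[, 1] < c0 + w &
                       r0 < boxes[, 2] + boxes[, 4] & boxes[, 2] < r0 + h)
      }
      if (!overlap) { boxes <- rbind(boxes, c(c0, r0, w, h)); placed <- TRUE; break }
    }
    if (!placed) {
      stop(sprintf("make_reserves: could not place reserve %d without overlap",
                   i), call. = FALSE)
    }
  }
  x0 <- geom$origin_xy[1]; y0 <- geom$origin_xy[2]
  feats <- lapply(seq_len(n_reserves), function(i) {
    b <- boxes[i, ]
    xs <- x0 + c(b[1], b[1] + b[3], b[1] + b[3], b[1], b[1]) * cs
    ys <- y0 - c(b[2], b[2], b[2] + b[4], b[2] + b[4], b[2]) * cs
    list(name = sprintf("Reserve_%02d", i), rings = list(cbind(xs, ys)))
  })
  structure(feats, class = "reserve_set")
}

#' Write a reserve set as GeoJSON
#' @param reserves a `reserve_set`.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_reserves_geojson <- function(reserves, path) {
  feats <- lapply(reserves, function(f) {
    list(type = "Feature",
         properties = list(name = f$name),
         geometry = list(
           type = "Polygon",
           coordinates = lapply(f$rings, function(r) {
             lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
           })))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reserve polygons from GeoJSON
#'
#' Supports Polygon and MultiPolygon features; the feature's `name` (or
#' `Name`) property names the reserve.
#'
#' @param path `.geojson` file path.
#' @return a `reserve_set`.
#' @export
read_reserves_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$features)) stop("GeoJSON: no features", call. = FALSE)
  feats <- lapply(seq_along(obj$features), function(i) {
    f <- obj$features[[i]]
    nm <- f$properties$name
    if (is.null(nm)) nm <- f$properties$Name
    if (is.null(nm)) nm <- sprintf("feature_%d", i)
    gtype <- f$geometry$type
    polys <- switch(gtype,
      Polygon = list(f$geometry$coordinates),
      MultiPolygon = f$geometry$coordinates,
      stop(sprintf("GeoJSON feature '%s': unsupported geometry %s", nm, gtype),
           call. = FALSE))
    rings <- unlist(lapply(polys, function(p) {
      lapply(p, function(r) {
        do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
      })
    }), recursive = FALSE)
    list(name = nm, rings = rings)
  })
  structure(feats, class = "reserve_set")
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits every layer of both scenarios as `.asc`, the forest mask,
#' `occurrences.csv`, `reserves.geojson`, the true suitability surface and a
#' JSON manifest of the generating spec.
#'
#' @param spec a [scenario_spec()].
#' @param truth a [truth_spec()].
#' @param dir output directory (created).
#' @param n_occurrences number of occurrence points.
#' @return invisibly, the landscape list from [make_landscape()].
#' @export
write_fixture_set <- function(spec, truth = truth_spec(), dir,
                              n_occurrences = 273) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  land <- make_landscape(spec)
  for (scen in c("current", "future")) {
    sdir <- file.path(dir, scen)
    dir.create(sdir, showWarnings = FALSE)
    for (nm in names(land[[scen]]$layers)) {
      write_asc(land[[scen]]$layers[[nm]], file.path(sdir, paste0(nm, ".asc")))
    }
  }
  write_asc(land$forest, file.path(dir, "forest.asc"))
  suit <- true_suitability(land$current, truth)
  write_asc(suit, file.path(dir, "true_suitability.asc"))
  occ <- sample_occurrences(suit, land$forest, n_occurrences,
                            seed = spec$seed + 1L)
  write_points_csv(occ, file.path(dir, "occurrences.csv"))
  res <- make_reserves(land$geometry, seed = spec$seed + 2L)
  write_reserves_geojson(res, file.path(dir, "reserves.geojson"))
  jsonlite::write_json(unclass(spec), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(land)
}
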