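# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: flood fill by frontier dilation,
# pairwise O(n1*n2) score comparisons, ray-casting point-in-polygon,
# exhaustive threshold scans.

# AUC by explicit pair enumeration with half-credit ties.
oracle_auc <- function(pres, bg) {
  tot <- 0
  for (p in pres) tot <- tot + sum(p > bg) + 0.5 * sum(p == bg)
  tot / (length(pres) * length(bg))
}

# Max sensitivity+specificity by exhaustive scan over distinct scores,
# smallest threshold on ties.
oracle_max_sss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  best_t <- NA_real_; best <- -Inf
  for (t in cand) {
    v <- mean(pres >= t) + mean(bg < t)
    if (v > best + 1e-9) { best <- v; best_t <- t }
  }
  list(threshold = best_t, sss = best)
}

# Connected-component labels by repeated frontier dilation from each seed.
oracle_label <- function(suit, connectivity = 8) {
  nr <- nrow(suit); nc <- ncol(suit)
  lab <- matrix(0L, nr, nc)
  cur_lab <- 0L
  if (connectivity == 4) {
    nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    nb <- as.matrix(expand.grid(-1:1, -1:1))
    nb <- nb[rowSums(abs(nb)) > 0, ]
  }
  for (idx in which(suit)) {
    if (lab[idx] != 0L) next
    cur_lab <- cur_lab + 1L
    frontier <- matrix(arrayInd(idx, dim(suit)), ncol = 2)
    lab[idx] <- cur_lab
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        for (k in seq_len(nrow(nb))) {
          r <- frontier[i, 1] + nb[k, 1]; c <- frontier[i, 2] + nb[k, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              suit[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur_lab
            nxt <- rbind(nxt, c(r, c))
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(0, 0, 2) else nxt
    }
  }
  lab
}

# Minimum edge-to-edge gap between two labeled patches, brute force over
# all cell pairs.
oracle_patch_gap <- function(lab, i, j, cell_size) {
  a <- which(lab == i, arr.ind = TRUE)
  b <- which(lab == j, arr.ind = TRUE)
  best <- Inf
  for (u in seq_len(nrow(a))) {
    for (v in seq_len(nrow(b))) {
      d <- sqrt(sum((a[u, ] - b[v, ])^2))
      best <- min(best, d)
    }
  }
  max(0, (best - 1) * cell_size)
}

# Iterative small-and-isolated patch removal simulated independently.
oracle_filter <- function(lab, cell_size, min_area, max_gap) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  area <- vapply(ids, function(i) sum(lab == i) * cell_size^2, numeric(1))
  retained <- ids
  repeat {
    drop <- integer(0)
    for (i in retained) {
      if (area[match(i, ids)] >= min_area) next
      others <- setdiff(retained, i)
      if (length(others) == 0) { drop <- c(drop, i); next }
      gaps <- vapply(others, function(j) oracle_patch_gap(lab, i, j, cell_size),
                     numeric(1))
      if (min(gaps) > max_gap) drop <- c(drop, i)
    }
    if (!length(drop)) break
    retained <- setdiff(retained, drop)
  }
  retained
}

# Ray-casting point-in-polygon (boundary points may go either way; tests
# avoid boundary centers).
oracle_pip <- function(px, py, ring) {
  n <- nrow(ring) - 1
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Small aligned habgrid stack from matrices.
mk_stack <- function(..., cell = 1) {
  ms <- list(...)
  habstack(lapply(names(ms), function(nm) {
    habgrid(ms[[nm]], cell, c(0, nrow(ms[[nm]]) * cell), nm)
  }) |> stats::setNames(names(ms)))
}

# habitat_map straight from a logical matrix.
mk_map <- function(suit, cell = 1, label = "x", valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(suit), ncol(suit))
  structure(list(suitable = suit & valid, valid = valid, threshold = 0.5,
                 scenario_label = label, cell_size_km = cell,
                 origin_xy = c(0, nrow(suit) * cell)), class = "habitat_map")
}

published_reserves <- function() {
  utils::read.csv(system.file("extdata", "qinling_reserves.csv",
                              package = "habvuln"))
}

published_totals <- function() {
  jsonlite::read_json(system.file("extdata", "qinling_scenario_areas.json",
                                  package = "habvuln"), simplifyVector = TRUE)
}
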