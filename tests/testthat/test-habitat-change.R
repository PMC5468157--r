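# ---- binarize ---------------------------------------------------------------

test_that("binarization is inclusive at the threshold and respects nodata", {
  m <- matrix(c(0, 0.2, 0.5, 0.8, NA, 0.5), 2, 3)
  g <- habgrid(m, 1, c(0, 2), "s")
  bm <- binarize(g, 0.5)
  expect_false(any(binarize(habgrid(matrix(0.0001, 2, 2), 1, c(0, 2)),
                            0.5)$suitable))
  expect_true(bm$suitable[1, 2])          # exactly at threshold
  expect_false(bm$suitable[1, 3])         # nodata never suitable
  expect_false(bm$valid[1, 3])
  set.seed(9)
  r <- habgrid(matrix(runif(400), 20, 20), 1, c(0, 20))
  bb <- binarize(r, 0.37)
  expect_equal(sum(bb$suitable), sum(r$values >= 0.37))  # exhaustive scan
})

# ---- patch labeling ---------------------------------------------------------

test_that("connectivity determines whether diagonals join patches", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE
  p4 <- label_patches(mk_map(m), 4)
  p8 <- label_patches(mk_map(m), 8)
  expect_equal(nrow(p4$patches), 2)
  expect_equal(nrow(p8$patches), 1)
  full <- label_patches(mk_map(matrix(TRUE, 5, 5)), 8)
  expect_equal(nrow(full$patches), 1)
  expect_equal(full$patches$area_km2, 25)
})

test_that("labels agree with an independent flood-fill oracle", {
  set.seed(41)
  for (i in 1:6) {
    m <- matrix(runif(400) < 0.45, 20, 20)
    for (conn in c(4, 8)) {
      ps <- label_patches(mk_map(m), conn)
      ol <- oracle_label(m, conn)
      # same partition up to label permutation
      expect_equal(max(ol), nrow(ps$patches))
      key <- paste(ps$labels, ol)
      expect_equal(length(unique(key[m])), max(ol))
      expect_true(all((ps$labels > 0) == m))
      expect_equal(sum(ps$patches$area_km2), sum(m))
    }
  }
})

# ---- patch filtering --------------------------------------------------------

test_that("small isolated patches go, small connected or large ones stay", {
  m <- matrix(FALSE, 10, 10)
  m[1:3, 1] <- TRUE                      # 3 km2, isolated
  f1 <- filter_patches(label_patches(mk_map(m), 8))
  expect_equal(sum(f1$suitable), 0)

  m2 <- matrix(FALSE, 10, 10)
  m2[1:5, 1] <- TRUE                     # 5 km2, isolated but large enough
  f2 <- filter_patches(label_patches(mk_map(m2), 8))
  expect_equal(sum(f2$suitable), 5)

  m3 <- matrix(FALSE, 10, 10)
  m3[1:2, 3:7] <- TRUE                   # 10 km2 anchor
  m3[4:6, 3] <- TRUE                     # 3 km2, gap 0 (adjacent diag? rows 3)
  m3[3, 3] <- FALSE
  p3 <- label_patches(mk_map(m3), 4)
  expect_equal(nrow(p3$patches), 2)
  # gap = (2 - 1) * 1 km = 1 km > 0.5 -> removed
  f3 <- filter_patches(p3)
  expect_equal(sum(f3$suitable), 10)
  # moved adjacent (gap 0): retained
  m4 <- matrix(FALSE, 10, 10)
  m4[1:2, 3:7] <- TRUE
  m4[3:5, 3] <- TRUE
  p4 <- label_patches(mk_map(m4), 4)
  expect_equal(nrow(p4$patches), 1)      # touching -> single patch anyway
  m5 <- matrix(FALSE, 10, 10)
  m5[1:2, 3:7] <- TRUE
  m5[4:6, 8] <- TRUE                     # distance sqrt((4-2)^2+1)... check below
  p5 <- label_patches(mk_map(m5), 8)
  expect_equal(nrow(p5$patches), 2)
  # nearest centers: (2,7)-(4,8): d = sqrt(4+1) = 2.236 -> gap 1.236 -> removed
  expect_equal(sum(filter_patches(p5)$suitable), 10)
})

test_that("filtering agrees with the brute-force oracle and is a fixed point", {
  set.seed(59)
  for (i in 1:8) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    ps <- label_patches(mk_map(m), 8)
    got <- filter_patches(ps, min_area_km2 = 4, max_gap_km = 0.5)
    keep <- oracle_filter(ps$labels, 1, 4, 0.5)
    expect_equal(got$suitable, matrix(ps$labels %in% keep, 20, 20))
    # fixed point
    again <- filter_patches(label_patches(got, 8), 4, 0.5)
    expect_equal(again$suitable, got$suitable)
  }
})

test_that("the disjunctive reading removes small or isolated patches", {
  m <- matrix(FALSE, 8, 8)
  m[1:2, 1:2] <- TRUE                    # 4 km2 but isolated
  m[7:8, 7:8] <- TRUE                    # 4 km2, isolated
  m[5, 5] <- TRUE                        # 1 km2 near nothing
  ps <- label_patches(mk_map(m), 8)
  conj <- filter_patches(ps, 4, 0.5, conjunction = TRUE)
  expect_equal(sum(conj$suitable), 8)    # only the 1-cell patch goes
  disj <- filter_patches(ps, 4, 0.5, conjunction = FALSE)
  expect_equal(sum(disj$suitable), 0)    # all are small-or-isolated
})

# ---- change classification and indicators -----------------------------------

test_that("the four categories partition the valid domain", {
  cur <- mk_map(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  fut <- mk_map(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  ch <- classify_change(cur, fut)
  expect_equal(as.vector(ch$category), c(1L, 2L, 3L, 0L))
  expect_equal(unname(ch$areas_km2), c(1, 1, 1, 1))
  same <- classify_change(cur, cur)
  expect_equal(unname(same$areas_km2[c("vulnerable", "new")]), c(0, 0))
  comp <- classify_change(cur, mk_map(!cur$suitable))
  expect_equal(unname(comp$areas_km2["unchanged"]), 0)
  expect_error(classify_change(cur, mk_map(matrix(TRUE, 3, 3))), "aligned")
  set.seed(71)
  for (i in 1:5) {
    a <- mk_map(matrix(runif(100) < 0.5, 10, 10))
    b <- mk_map(matrix(runif(100) < 0.5, 10, 10))
    ch <- classify_change(a, b)
    expect_identical(sum(ch$areas_km2), area_km2(ch$valid, 1))
  }
})

test_that("indicators reproduce their defining identities", {
  ind <- indicators_from_areas(100, 50, 50)
  expect_equal(ind$AC, -50)
  expect_equal(ind$SH_c, 50)
  expect_equal(ind$SH_f, 0)
  ind0 <- indicators_from_areas(100, 100, 100)
  expect_equal(c(ind0$AC, ind0$SH_c, ind0$SH_f), c(0, 0, 0))
  expect_true(is.na(indicators_from_areas(0, 10, 0)$AC))
  expect_error(indicators_from_areas(10, 10, 11), "overlap")
  # identities on random change maps
  set.seed(83)
  for (i in 1:5) {
    a <- mk_map(matrix(runif(100) < 0.6, 10, 10))
    b <- mk_map(matrix(runif(100) < 0.6, 10, 10))
    ind <- indicators(classify_change(a, b))
    expect_equal(ind$AC, (ind$A_f - ind$A_c) / ind$A_c * 100,
                 tolerance = 1e-9)
    sub <- all(!a$suitable | b$suitable)
    expect_equal(ind$SH_c == 0, sub)
  }
})

# ---- rank test --------------------------------------------------------------

test_that("identical groups give a null Mann-Whitney result", {
  x <- rep(1:5, 4)
  r <- mann_whitney(x, x)
  expect_equal(r$U, length(x)^2 / 2)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
})

test_that("a fully separated pair matches the exact enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_true(r$exact)
  expect_equal(r$p, 1 / 3)  # 2 * P(U <= 0) = 2/6 over all rank arrangements
  expect_equal(r$U, 0)
  # cross-check exact p against base wilcox.test
  set.seed(97)
  x <- rnorm(8); y <- rnorm(9, 0.8)
  expect_equal(mann_whitney(x, y)$p,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("the normal-approximation z matches a permutation oracle", {
  set.seed(113)
  x <- rnorm(30, 0); y <- rnorm(30, 0.6)
  r <- mann_whitney(x, y, exact_limit = 0)
  all_v <- c(x, y)
  rk <- rank(all_v)
  u_obs <- sum(rk[1:30]) - 30 * 31 / 2
  B <- 40000
  u_perm <- replicate(B, {
    idx <- sample(60, 30)
    sum(rk[idx]) - 30 * 31 / 2
  })
  p_perm <- mean(abs(u_perm - 450) >= abs(u_obs - 450))
  z_perm <- qnorm(p_perm / 2)            # magnitude implied by the oracle p
  expect_lt(abs(abs(r$z) - abs(z_perm)), 0.05)
})

test_that("elevation contrast compares suitable-cell elevations", {
  elev <- habgrid(matrix(seq(3000, 1000, length.out = 100), 10, 10), 1,
                  c(0, 10), "elevation")
  cur <- mk_map(matrix(rep(c(TRUE, FALSE), 50), 10, 10))
  fut <- mk_map(matrix(rep(c(FALSE, TRUE), 50), 10, 10))
  r <- elevation_contrast(cur, fut, elev)
  expect_equal(r$n_x, 50)
  expect_equal(r$mean_x, mean(elev$values[cur$suitable]))
  none <- mk_map(matrix(FALSE, 10, 10))
  expect_error(elevation_contrast(none, fut, elev), "no suitable")
})

test_that("coded change maps round-trip through ASCII", {
  cur <- mk_map(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  fut <- mk_map(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  ch <- classify_change(cur, fut)
  f <- withr::local_tempfile(fileext = ".asc")
  write_change_asc(ch, f)
  g <- read_asc(f)
  expect_equal(as.vector(g$values), c(1, 2, 3, 0))
})
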