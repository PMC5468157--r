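# ---- feature expansion ------------------------------------------------------

test_that("feature expansion produces the documented feature set", {
  bg <- data.frame(v = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10))
  fx0 <- build_features(bg, hinge_knots = 0)
  expect_equal(ncol(expand_features(fx0, bg)), 2)  # linear + quadratic
  fx <- build_features(bg, hinge_knots = 3)
  fm <- expand_features(fx, bg)
  expect_equal(ncol(fm), 2 + 2 * length(fx$defs$v$knots))
  expect_true(all(fm >= 0 & fm <= 1))
  # hinge endpoints: forward hinge is 0 at its knot and 1 at the max
  kn <- fx$defs$v$knots[1]
  hf <- expand_features(fx, data.frame(v = c(kn, 10)))[, "v:hf1"]
  expect_equal(unname(hf), c(0, 1))
  # reverse hinge is 1 at the min and 0 at its knot
  hr <- expand_features(fx, data.frame(v = c(0, kn)))[, "v:hr1"]
  expect_equal(unname(hr), c(1, 0))
  # knots strictly increase
  expect_true(all(diff(fx$defs$v$knots) > 0))
})

test_that("constant variables degrade to a flagged degenerate feature", {
  expect_warning(fx <- build_features(data.frame(v = rep(2, 6)), 3),
                 "constant")
  fm <- expand_features(fx, data.frame(v = c(2, 2)))
  expect_equal(ncol(fm), 1)
  expect_equal(sd(fm[, 1]), 0)
})

test_that("out-of-range projection values are clamped into [0, 1]", {
  bg <- data.frame(v = 1:10)
  fx <- build_features(bg, 2)
  fm <- expand_features(fx, data.frame(v = c(-5, 0.5, 25)))
  expect_true(all(fm >= 0 & fm <= 1))
  expect_equal(unname(fm[1, "v:lin"]), 0)
  expect_equal(unname(fm[3, "v:lin"]), 1)
})

# ---- fitting ----------------------------------------------------------------

test_that("with no features the maximum-entropy model is uniform", {
  m <- 8
  mod <- maxent_fit(matrix(0, 3, 0), matrix(0, m, 0))
  expect_equal(mod$entropy, log(m))
  expect_equal(mod$log_z, log(m))
  q <- habvuln:::maxent_raw_scores(mod, matrix(0, m, 0))
  expect_equal(q, rep(1 / m, m))
  expect_equal(sum(q), 1)
})

test_that("one binary feature recovers the closed-form Gibbs distribution", {
  # background: equal counts of states f=0 and f=1. With presence mean p and
  # no penalty the stationarity condition is e^l/(1+e^l) = p, l = logit(p).
  bg <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  pres <- matrix(c(rep(1, 8), rep(0, 2)), ncol = 1)  # presence mean 0.8
  mod <- maxent_fit(pres, bg, beta_multiplier = 0, tol = 1e-12)
  expect_equal(unname(mod$lambda), log(0.8 / 0.2), tolerance = 1e-5)
  q <- habvuln:::maxent_raw_scores(mod, bg)
  expect_equal(sum(q * bg[, 1]), 0.8, tolerance = 1e-6)  # constraint met
  # presence mean 1.0: mass concentrates on the f=1 state as beta -> 0
  pres1 <- matrix(1, 6, 1)
  mass1 <- vapply(c(0.3, 0.1, 0.03), function(b) {
    m <- maxent_fit(pres1, bg, beta_multiplier = b, tol = 1e-12)
    q <- habvuln:::maxent_raw_scores(m, bg)
    sum(q * bg[, 1])
  }, numeric(1))
  expect_true(all(diff(mass1) > 0))
  expect_gt(mass1[3], 0.9)
})

test_that("the fit matches a dense lambda-grid oracle on toy backgrounds", {
  set.seed(101)
  for (case in 1:3) {
    n_feat <- sample(2:3, 1)
    n_state <- sample(c(8, 12, 16), 1)
    bg <- matrix(rbinom(n_state * n_feat, 1, 0.5), n_state, n_feat)
    pres <- bg[sample(n_state, 6, replace = TRUE,
                      prob = (rowSums(bg) + 1)), , drop = FALSE]
    pbar <- colMeans(pres)
    beta <- 1 * apply(bg, 2, sd) / sqrt(nrow(pres))
    mod <- maxent_fit(pres, bg, beta_multiplier = 1, tol = 1e-12)
    # dense grid search over lambda in [-4, 4]^p (the grid only
    # lower-bounds the true maximum, so coarser steps stay valid oracles)
    grid1 <- seq(-4, 4, by = if (n_feat == 2) 0.05 else 0.2)
    lam <- as.matrix(expand.grid(rep(list(grid1), n_feat)))
    sc <- lam %*% t(bg)
    mx <- apply(sc, 1, max)
    logz <- mx + log(rowSums(exp(sc - mx)))
    J <- as.vector(lam %*% pbar) - logz -
      as.vector(abs(lam) %*% beta)
    expect_gte(mod$objective, max(J) - 1e-6)
  }
})

test_that("raising the penalty never increases the active feature count", {
  set.seed(55)
  bg <- data.frame(a = rnorm(300), b = runif(300), c = rnorm(300, 2))
  pr <- data.frame(a = rnorm(40, 1), b = runif(40)^2, c = rnorm(40, 2.5))
  fx <- build_features(bg, 4)
  bgf <- expand_features(fx, bg); prf <- expand_features(fx, pr)
  nz <- vapply(c(0.5, 2, 8), function(b) {
    sum(maxent_fit(prf, bgf, beta_multiplier = b)$lambda != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

# ---- prediction -------------------------------------------------------------

test_that("raw prediction normalizes over the background and logistic is monotone", {
  set.seed(77)
  bg_raw <- data.frame(a = rnorm(200), b = rnorm(200))
  pr_raw <- data.frame(a = rnorm(30, 0.8), b = rnorm(30, -0.5))
  fx <- build_features(bg_raw, 3)
  mod <- maxent_fit(expand_features(fx, pr_raw), expand_features(fx, bg_raw),
                    expansion = fx)
  q <- habvuln:::maxent_raw_scores(mod, expand_features(fx, bg_raw))
  expect_equal(sum(q), 1, tolerance = 1e-9)
  p <- habvuln:::maxent_logistic_scores(mod, expand_features(fx, bg_raw))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(order(q), order(p))
  # q = e^-H maps to exactly 0.5; q = 0 to 0
  eh <- exp(mod$entropy)
  expect_equal(eh * exp(-mod$entropy) / (1 + eh * exp(-mod$entropy)), 0.5)
})

test_that("a single positive linear weight gives monotone raw output", {
  fx <- build_features(data.frame(v = 0:10), hinge_knots = 0)
  mod <- structure(list(lambda = c("v:lin" = 1.7, "v:quad" = 0),
                        log_z = 2, entropy = 1.5, expansion = fx),
                   class = "maxent_model")
  x <- sort(runif(50, 0, 10))
  q <- habvuln:::maxent_raw_scores(mod, expand_features(fx, data.frame(v = x)))
  expect_true(all(diff(q) >= 0))
})

test_that("raster prediction propagates nodata and checks variables", {
  l <- make_landscape(scenario_spec(n_rows = 20, n_cols = 20, seed = 2))
  st <- habstack(l$current$layers[c("temp1", "prec1")])
  st$layers$temp1$values[3, 3] <- NA
  bg_raw <- stack_df <- data.frame(
    temp1 = as.vector(l$current$layers$temp1$values),
    prec1 = as.vector(l$current$layers$prec1$values))
  fx <- build_features(bg_raw[1:100, ], 2)
  mod <- maxent_fit(expand_features(fx, bg_raw[1:20, ]),
                    expand_features(fx, bg_raw[1:100, ]), expansion = fx)
  g <- predict_logistic(mod, st)
  expect_true(is.na(g$values[3, 3]))
  expect_true(all(g$values[!is.na(g$values)] >= 0 &
                  g$values[!is.na(g$values)] <= 1))
  expect_error(predict_raw(mod, habstack(l$current$layers["temp1"])), "prec1")
})

# ---- evaluation -------------------------------------------------------------

test_that("AUC equals the concordant-pair probability", {
  expect_equal(eval_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(eval_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(eval_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(13)
  for (i in 1:10) {
    pres <- sample(seq(0, 1, by = 0.1), 8, replace = TRUE)
    bg <- sample(seq(0, 1, by = 0.1), 15, replace = TRUE)
    expect_equal(eval_auc(pres, bg), oracle_auc(pres, bg))
  }
})

test_that("max-SSS threshold equals the exhaustive candidate scan", {
  r <- threshold_max_sss(rep(0.8, 4), rep(0.2, 6))
  expect_equal(r$threshold, 0.8)
  expect_equal(r$sss, 2)
  same <- threshold_max_sss(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$sss, 1)
  # the documented three-vs-three fixture, against the scan oracle
  o <- oracle_max_sss(c(0.9, 0.6, 0.3), c(0.5, 0.2, 0.1))
  r2 <- threshold_max_sss(c(0.9, 0.6, 0.3), c(0.5, 0.2, 0.1))
  expect_equal(r2$threshold, o$threshold)
  expect_equal(r2$sss, o$sss)
  set.seed(29)
  for (i in 1:20) {
    pres <- round(runif(sample(3:12, 1)), 2)
    bg <- round(runif(sample(3:12, 1)), 2)
    got <- threshold_max_sss(pres, bg)
    want <- oracle_max_sss(pres, bg)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sss, want$sss)
  }
})

# ---- replication, importance, jackknife ------------------------------------

make_fit_fixture <- function(seed = 3, n_rows = 40, n_cols = 40, n_occ = 80,
                             n_bg = 800) {
  l <- make_landscape(scenario_spec(n_rows = n_rows, n_cols = n_cols,
                                    seed = seed))
  suit <- true_suitability(l$current, truth_spec())
  occ <- sample_occurrences(suit, l$forest, n_occ, seed = seed + 1)
  pres <- thin_one_per_cell(occ, l$geometry, seed = seed + 2)
  bg <- sample_background(l$forest, n_bg, seed = seed + 3)
  list(land = l, pres = pres, bg = bg, suit = suit)
}

test_that("a single replicate ensemble equals its one model", {
  fixt <- make_fit_fixture()
  vars <- c("temp1", "prec1", "elevation")
  ens <- run_replicates(fixt$pres, fixt$bg, fixt$land$current,
                        variables = vars, n_rep = 1, seed = 5)
  one <- predict_logistic(ens$models[[1]],
                          habstack(fixt$land$current$layers[vars]))
  expect_equal(ens$mean_suitability$values, one$values, tolerance = 1e-12)
  expect_equal(ens$mean_threshold, ens$evaluation$threshold[1])
  expect_error(run_replicates(fixt$pres[1:3, ], fixt$bg, fixt$land$current,
                              variables = vars), ">= 4")
})

test_that("test-AUC spread shrinks when presences are quadrupled", {
  sds <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    for (k in 1:2) {
      n_occ <- c(40, 160)[k]
      fixt <- make_fit_fixture(seed = 100 + s, n_occ = n_occ, n_bg = 500)
      ens <- run_replicates(fixt$pres, fixt$bg, fixt$land$current,
                            variables = c("temp1", "prec1"), n_rep = 5,
                            seed = s, hinge_knots = 3)
      sds[s, k] <- sd(ens$evaluation$auc_test)
    }
  }
  expect_lt(mean(sds[, 2]), mean(sds[, 1]))
})

test_that("permutation importance isolates the informative variable", {
  set.seed(303)
  bg_raw <- data.frame(signal = rnorm(600), noise = rnorm(600))
  pr_raw <- data.frame(signal = rnorm(80, 1.6), noise = rnorm(80))
  fx <- build_features(bg_raw, 3)
  mod <- maxent_fit(expand_features(fx, pr_raw), expand_features(fx, bg_raw),
                    expansion = fx)
  imp <- permutation_importance(mod, pr_raw, bg_raw, seed = 1)
  expect_equal(sum(imp), 100, tolerance = 1e-9)
  expect_gt(imp["signal"], 90)
  # a variable whose features all carry zero weight cannot matter
  mod0 <- mod
  noise_feats <- grepl("^noise:", names(mod0$lambda))
  mod0$lambda[noise_feats] <- 0
  imp0 <- permutation_importance(mod0, pr_raw, bg_raw, seed = 1)
  expect_equal(unname(imp0["noise"]), 0)
})

test_that("jackknife gains behave as nested-model theory requires", {
  set.seed(404)
  bg_raw <- data.frame(signal = rnorm(400), decoy = rnorm(400))
  pr_raw <- data.frame(signal = rnorm(60, 1.4), decoy = rnorm(60))
  jk <- jackknife_gain(pr_raw, bg_raw, hinge_knots = 3)
  expect_gte(jk$gain_full, 0)
  # a pure-noise variable alone gains ~nothing
  expect_lt(jk$table$gain_only[jk$table$variable == "decoy"], 0.05)
  # dropping features can never raise the penalized optimum
  expect_true(all(jk$table$gain_without <= jk$gain_full + 1e-6))
})
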