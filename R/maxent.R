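#' Feature expansion for the maximum-entropy model
#'
#' Builds linear, quadratic and hinge feature definitions for each
#' continuous variable from its background sample. Linear and quadratic
#' features are the variable scaled to \[0, 1\] by its background min/max
#' (and its square); hinge features come in forward and reverse pairs with
#' `hinge_knots` knots placed at background quantiles, each rising from 0 at
#' the knot to 1 at the variable's background max (forward) or from 1 at the
#' min to 0 at the knot (reverse). Every feature maps the background sample
#' into \[0, 1\]; values beyond the background range are clamped. A constant
#' variable contributes a single degenerate (constant) feature and a
#' warning.
#'
#' @param background data.frame of raw variable values at the background
#'   points (one column per variable).
#' @param hinge_knots number of knots per hinge direction (0 disables hinge
#'   features).
#' @return object of class `feature_expansion`.
#' @export
build_features <- function(background, hinge_knots = 5) {
  background <- as.data.frame(background)
  defs <- list()
  for (nm in names(background)) {
    x <- background[[nm]]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2) {
      warning(sprintf("variable '%s' is constant over the background; %s",
                      nm, "degenerate feature carries no information"))
      defs[[nm]] <- list(min = min(x), max = min(x), knots = numeric(0))
      next
    }
    lo <- min(x); hi <- max(x)
    knots <- numeric(0)
    if (hinge_knots > 0) {
      knots <- unname(stats::quantile(x, (seq_len(hinge_knots)) /
                                        (hinge_knots + 1), type = 7))
      knots <- unique(knots)
      knots <- knots[knots > lo & knots < hi]
    }
    defs[[nm]] <- list(min = lo, max = hi, knots = knots)
  }
  structure(list(defs = defs, hinge_knots = hinge_knots),
            class = "feature_expansion")
}

#' Evaluate a feature expansion on raw variable values
#'
#' @param fx a [build_features()] expansion.
#' @param raw data.frame containing every variable of the expansion.
#' @return numeric matrix, one column per feature, rows matching `raw`;
#'   rows with any `NA` input are all-`NA`.
#' @export
expand_features <- function(fx, raw) {
  raw <- as.data.frame(raw)
  cols <- list()
  for (nm in names(fx$defs)) {
    d <- fx$defs[[nm]]
    if (is.null(raw[[nm]])) {
      stop(sprintf("expand_features: variable '%s' missing from input", nm),
           call. = FALSE)
    }
    x <- raw[[nm]]
    if (d$max == d$min) {          # degenerate: constant feature
      cols[[paste0(nm, ":const")]] <- rep(0.5, length(x)) + 0 * x
      next
    }
    s <- pmin(pmax((x - d$min) / (d$max - d$min), 0), 1)
    cols[[paste0(nm, ":lin")]] <- s
    cols[[paste0(nm, ":quad")]] <- s^2
    for (k in seq_along(d$knots)) {
      kn <- d$knots[k]
      cols[[paste0(nm, ":hf", k)]] <-
        pmin(pmax((x - kn) / (d$max - kn), 0), 1)
      cols[[paste0(nm, ":hr", k)]] <-
        pmin(pmax((kn - x) / (kn - d$min), 0), 1)
    }
  }
  do.call(cbind, cols)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

log_sum_exp <- function(s) {
  m <- max(s)
  m + log(sum(exp(s - m)))
}

#' Fit a presence-background maximum-entropy model
#'
#' Finds the distribution q over the background sample that maximizes the
#' L1-penalized presence log-likelihood
#' \deqn{J(\lambda) = \bar f' \lambda - \log Z(\lambda) -
#'   \sum_j \beta_j |\lambda_j|}
#' where \eqn{\bar f} is the presence mean of each feature and
#' \eqn{Z = \sum_{background} \exp(f(x)'\lambda)}. This is the
#' maximum-entropy distribution subject to (soft) constraints that the
#' model's expected feature values match the presence sample means.
#' Optimization is deterministic cyclic coordinate descent with
#' soft-thresholded Newton steps and per-coordinate backtracking, features
#' visited in fixed column order; convergence when the relative objective
#' change over a full cycle falls below `tol`.
#'
#' Default regularization is \eqn{\beta_j = \beta \cdot s_j / \sqrt{m'}}
#' with \eqn{s_j} the feature's background standard deviation and m' the
#' presence count.
#'
#' @param presences numeric feature matrix of the presence points.
#' @param background numeric feature matrix of the background sample
#'   (same columns).
#' @param beta_multiplier scales the default per-feature L1 penalties.
#' @param max_iter maximum full coordinate cycles.
#' @param tol relative objective-change convergence tolerance.
#' @param expansion optional [build_features()] expansion to embed in the
#'   model for later raster prediction.
#' @return object of class `maxent_model`: `lambda` (weights), `beta`,
#'   `log_z` (log partition over the background sample), `entropy`,
#'   `objective`, `converged`, `n_iter`, `presence_means`, `n_presence`,
#'   `m_background`, `expansion`.
#' @export
maxent_fit <- function(presences, background, beta_multiplier = 1,
                       max_iter = 5000, tol = 1e-7, expansion = NULL) {
  presences <- as.matrix(presences); background <- as.matrix(background)
  if (anyNA(presences) || anyNA(background)) {
    stop("maxent_fit: NA in feature matrices", call. = FALSE)
  }
  n <- nrow(presences); m <- nrow(background)
  if (n < 2) stop("maxent_fit: need >= 2 presences", call. = FALSE)
  p <- ncol(background)
  if (is.null(p)) p <- 0L
  if (p == 0L || m == 0L) {
    # no constraints: the maximum-entropy distribution is uniform
    q <- rep(1 / m, m)
    return(structure(list(
      lambda = numeric(0), beta = numeric(0), log_z = log(m),
      entropy = log(m), objective = -log(m), converged = TRUE, n_iter = 0L,
      presence_means = numeric(0), n_presence = n, m_background = m,
      expansion = expansion), class = "maxent_model"))
  }
  stopifnot(ncol(presences) == p)
  pbar <- colMeans(presences)
  sdj <- apply(background, 2, stats::sd)
  beta <- beta_multiplier * sdj / sqrt(n)
  lambda <- numeric(p)
  s <- rep(0, m)                      # background scores f(x)'lambda
  obj <- function(lam, sc) sum(pbar * lam) - log_sum_exp(sc) -
    sum(beta * abs(lam))
  J <- obj(lambda, s)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    J_prev <- J
    for (j in seq_len(p)) {
      fj <- background[, j]
      w <- exp(s - max(s))
      q <- w / sum(w)
      mu <- sum(q * fj)
      vj <- sum(q * fj^2) - mu^2
      if (vj < 1e-12) next
      g <- pbar[j] - mu
      lam_new <- soft_threshold(lambda[j] + g / vj, beta[j] / vj)
      delta <- lam_new - lambda[j]
      if (delta == 0) next
      # backtrack: features lie in [0,1] so the quadratic model can
      # undershoot the true curvature; halve until the objective gains
      for (bt in 1:30) {
        lam_try <- lambda[j] + delta
        s_try <- s + delta * fj
        J_try <- obj(replace(lambda, j, lam_try), s_try)
        if (J_try >= J - 1e-13) break
        delta <- delta / 2
      }
      if (J_try >= J - 1e-13) {
        lambda[j] <- lambda[j] + delta
        s <- s + delta * fj
        J <- J_try
      }
    }
    if (abs(J - J_prev) < tol * (abs(J_prev) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    w <- exp(s - max(s)); q <- w / sum(w)
    gr <- pbar - as.vector(crossprod(background, q))
    warning(sprintf(
      "maxent_fit: not converged after %d cycles (max |gradient| %.3g)",
      max_iter, max(abs(gr))))
  }
  log_z <- log_sum_exp(s)
  lq <- s - log_z
  q <- exp(lq)
  entropy <- -sum(q * lq)
  structure(list(
    lambda = stats::setNames(lambda, colnames(background)), beta = beta,
    log_z = log_z, entropy = entropy, objective = J, converged = converged,
    n_iter = it, presence_means = pbar, n_presence = n, m_background = m,
    expansion = expansion), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features (%d active), H = %.4f, objective %.6f%s\n",
    length(x$lambda), sum(x$lambda != 0), x$entropy, x$objective,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# Raw maxent output for a feature matrix: exp(score)/Z with Z over the
# fitted background sample, so raw values sum to 1 over that sample.
maxent_raw_scores <- function(model, features) {
  if (length(model$lambda) == 0) {
    return(rep(exp(-model$log_z), nrow(features)))
  }
  as.vector(exp(features %*% model$lambda - model$log_z))
}

maxent_logistic_scores <- function(model, features) {
  q <- maxent_raw_scores(model, features)
  eh <- exp(model$entropy)
  eh * q / (1 + eh * q)
}

stack_raw_df <- function(stack, variables) {
  out <- lapply(stack$layers[variables], function(g) as.vector(g$values))
  as.data.frame(out, optional = TRUE)
}

predict_grid <- function(model, stack, transform) {
  vars <- names(model$expansion$defs)
  if (is.null(vars)) {
    stop("model carries no feature expansion; predict from rasters requires one",
         call. = FALSE)
  }
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing)) {
    stop(sprintf("prediction stack lacks model variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw <- stack_raw_df(stack, vars)
  ok <- stats::complete.cases(raw)
  vals <- rep(NA_real_, nrow(raw))
  if (any(ok)) {
    fm <- expand_features(model$expansion, raw[ok, , drop = FALSE])
    vals[ok] <- transform(model, fm)
  }
  g1 <- stack$layers[[1]]
  geom <- stack$geometry
  habgrid(matrix(vals, geom$n_rows, geom$n_cols), g1$cell_size_km,
          g1$origin_xy, "suitability")
}

#' Raw (relative occurrence rate) prediction over a raster stack
#'
#' Values are normalized over the fitted background sample (they sum to 1
#' over it); nodata propagates from any model variable.
#'
#' @param model a fitted `maxent_model` carrying its feature expansion.
#' @param stack a [habstack()] with all model variables.
#' @return `habgrid` of raw suitability.
#' @export
predict_raw <- function(model, stack) {
  predict_grid(model, stack, maxent_raw_scores)
}

#' Logistic suitability prediction over a raster stack
#'
#' The entropy-calibrated logistic transform
#' \eqn{p = e^H q / (1 + e^H q)} maps raw output q to \[0, 1\], with a
#' typical presence (q = e^{-H}) scoring 0.5; strictly increasing in q, so
#' cell rankings are identical under both outputs.
#'
#' @inheritParams predict_raw
#' @return `habgrid` of suitability in \[0, 1\].
#' @export
predict_logistic <- function(model, stack) {
  predict_grid(model, stack, maxent_logistic_scores)
}

#' Rank-sum AUC for presence vs background scores
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen background point, ties counting one half (equivalent to the
#' Mann-Whitney statistic scaled by n1*n2).
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
eval_auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n2 <- length(background_scores)
  if (n1 == 0 || n2 == 0) stop("eval_auc: empty score list", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Evaluates sensitivity (presence score >= t) plus specificity (background
#' score < t) at every distinct observed score and returns the maximizing
#' threshold; ties are broken toward the smallest threshold, which retains
#' the most habitat.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return list: `threshold`, `sensitivity`, `specificity`, `sss`.
#' @export
threshold_max_sss <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("threshold_max_sss: empty score list", call. = FALSE)
  }
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(background_scores < t), numeric(1))
  sss <- sens + spec
  # ties (to floating-point tolerance) break toward the smallest threshold
  i <- which(sss >= max(sss) - 1e-9)[1]
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i],
       sss = sss[i])
}

#' Replicated subsample fitting and evaluation
#'
#' Repeats an independent random 75/25 presence split `n_rep` times
#' (background shared across replicates), fits the model on each training
#' set, and aggregates: mean cellwise logistic suitability, arithmetic mean
#' of the per-replicate max-SSS training thresholds, and mean and sd of
#' training and test AUC.
#'
#' @param presences data.frame of presence points (`x`, `y`).
#' @param background data.frame of background points (`x`, `y`).
#' @param stack [habstack()] holding the model variables.
#' @param variables character vector of layer names to use as predictors
#'   (default: all layers in `stack`).
#' @param n_rep number of replicates (default 15).
#' @param train_frac training fraction of presences (default 0.75).
#' @param seed integer seed governing all splits.
#' @param hinge_knots,beta_multiplier,max_iter,tol passed to the feature
#'   builder and fitter.
#' @param predict_on optional second stack (same variables) to also average
#'   predictions over, e.g. a future scenario.
#' @return object of class `maxent_ensemble`: `models`, `evaluation`
#'   (data.frame per replicate), `mean_suitability` (`habgrid`),
#'   `mean_suitability_alt` (if `predict_on` given), `mean_threshold`,
#'   `auc_summary`.
#' @export
run_replicates <- function(presences, background, stack,
                           variables = names(stack$layers), n_rep = 15,
                           train_frac = 0.75, seed = 1L, hinge_knots = 5,
                           beta_multiplier = 1, max_iter = 5000, tol = 1e-7,
                           predict_on = NULL) {
  n <- nrow(presences)
  if (n < 4) stop("run_replicates: need >= 4 presences", call. = FALSE)
  n_train <- floor(train_frac * n)
  if (n_train < 2 || n_train >= n) {
    stop("run_replicates: split leaves an empty train or test set",
         call. = FALSE)
  }
  pres_raw <- extract_at(habstack(stack$layers[variables]), presences)
  bg_raw <- extract_at(habstack(stack$layers[variables]), background)
  keep_p <- stats::complete.cases(pres_raw)
  keep_b <- stats::complete.cases(bg_raw)
  pres_raw <- pres_raw[keep_p, , drop = FALSE]
  bg_raw <- bg_raw[keep_b, , drop = FALSE]
  n <- nrow(pres_raw)
  n_train <- floor(train_frac * n)
  fx <- build_features(bg_raw, hinge_knots)
  bg_feat <- expand_features(fx, bg_raw)
  pres_feat <- expand_features(fx, pres_raw)
  grid_raw <- stack_raw_df(stack, variables)
  ok <- stats::complete.cases(grid_raw)
  grid_feat <- expand_features(fx, grid_raw[ok, , drop = FALSE])
  if (!is.null(predict_on)) {
    alt_raw <- stack_raw_df(predict_on, variables)
    ok_alt <- stats::complete.cases(alt_raw)
    alt_feat <- expand_features(fx, alt_raw[ok_alt, , drop = FALSE])
  }
  set.seed(seed)
  geom <- stack$geometry
  acc <- rep(0, geom$n_rows * geom$n_cols)
  acc_alt <- acc
  models <- vector("list", n_rep)
  ev <- data.frame(replicate = seq_len(n_rep), auc_train = NA_real_,
                   auc_test = NA_real_, threshold = NA_real_,
                   sensitivity = NA_real_, specificity = NA_real_)
  for (r in seq_len(n_rep)) {
    tr <- sample.int(n, n_train)
    te <- setdiff(seq_len(n), tr)
    mod <- maxent_fit(pres_feat[tr, , drop = FALSE], bg_feat,
                      beta_multiplier = beta_multiplier,
                      max_iter = max_iter, tol = tol, expansion = fx)
    s_tr <- maxent_logistic_scores(mod, pres_feat[tr, , drop = FALSE])
    s_te <- maxent_logistic_scores(mod, pres_feat[te, , drop = FALSE])
    s_bg <- maxent_logistic_scores(mod, bg_feat)
    th <- threshold_max_sss(s_tr, s_bg)
    ev$auc_train[r] <- eval_auc(s_tr, s_bg)
    ev$auc_test[r] <- eval_auc(s_te, s_bg)
    ev$threshold[r] <- th$threshold
    ev$sensitivity[r] <- th$sensitivity
    ev$specificity[r] <- th$specificity
    pr <- rep(NA_real_, length(acc))
    pr[ok] <- maxent_logistic_scores(mod, grid_feat)
    acc <- acc + pr
    if (!is.null(predict_on)) {
      pa <- rep(NA_real_, length(acc_alt))
      pa[ok_alt] <- maxent_logistic_scores(mod, alt_feat)
      acc_alt <- acc_alt + pa
    }
    models[[r]] <- mod
  }
  g1 <- stack$layers[[1]]
  mean_grid <- habgrid(matrix(acc / n_rep, geom$n_rows, geom$n_cols),
                       g1$cell_size_km, g1$origin_xy, "mean_suitability")
  out <- list(
    models = models, evaluation = ev, mean_suitability = mean_grid,
    mean_threshold = mean(ev$threshold),
    auc_summary = c(train_mean = mean(ev$auc_train),
                    train_sd = stats::sd(ev$auc_train),
                    test_mean = mean(ev$auc_test),
                    test_sd = stats::sd(ev$auc_test)),
    n_presence = n, variables = variables, n_rep = n_rep,
    train_frac = train_frac)
  if (!is.null(predict_on)) {
    out$mean_suitability_alt <- habgrid(
      matrix(acc_alt / n_rep, geom$n_rows, geom$n_cols),
      g1$cell_size_km, g1$origin_xy, "mean_suitability_future")
  }
  structure(out, class = "maxent_ensemble")
}

#' @export
print.maxent_ensemble <- function(x, ...) {
  a <- x$auc_summary
  cat(sprintf(
    "<maxent_ensemble> %d replicates, %d presences, %d variables\n",
    x$n_rep, x$n_presence, length(x$variables)))
  cat(sprintf("  AUC train %.3f +/- %.3f, test %.3f +/- %.3f; mean threshold %.4f\n",
              a["train_mean"], a["train_sd"], a["test_mean"], a["test_sd"],
              x$mean_threshold))
  invisible(x)
}

#' Permutation importance of model variables
#'
#' For each variable, its raw values are permuted jointly across the pooled
#' presence-plus-background points, features are re-derived for that
#' variable only, and the drop in training AUC is recorded; drops (floored
#' at zero) are normalized to sum to 100.
#'
#' @param model fitted `maxent_model` with embedded expansion.
#' @param pres_raw,bg_raw data.frames of raw variable values at presences
#'   and background.
#' @param seed integer seed for the permutations.
#' @return named numeric vector of importances (percent, summing to 100
#'   unless every permutation leaves the AUC unchanged).
#' @export
permutation_importance <- function(model, pres_raw, bg_raw, seed = 1L) {
  fx <- model$expansion
  stopifnot(!is.null(fx))
  vars <- names(fx$defs)
  n <- nrow(pres_raw)
  pooled <- rbind(pres_raw[vars], bg_raw[vars])
  feat <- expand_features(fx, pooled)
  sc <- maxent_logistic_scores(model, feat)
  auc0 <- eval_auc(sc[seq_len(n)], sc[-seq_len(n)])
  set.seed(seed)
  drops <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    perm <- pooled
    perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
    featp <- expand_features(fx, perm)
    scp <- maxent_logistic_scores(model, featp)
    drops[v] <- auc0 - eval_auc(scp[seq_len(n)], scp[-seq_len(n)])
  }
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    warning("permutation_importance: no variable affects the AUC")
    return(drops)
  }
  100 * drops / sum(drops)
}

#' Jackknife training gain per variable
#'
#' Fits, for each variable, a model using only that variable's features and
#' a model leaving that variable out, alongside the full model. Training
#' gain is the penalized mean presence log-likelihood relative to the
#' uniform baseline log(1/m), so the uniform model gains 0 and gains are
#' nonnegative for the full model.
#'
#' @param pres_raw,bg_raw data.frames of raw variable values.
#' @param hinge_knots,beta_multiplier,max_iter,tol fitting controls.
#' @return list: `table` (data.frame variable, gain_only, gain_without) and
#'   `gain_full`.
#' @export
jackknife_gain <- function(pres_raw, bg_raw, hinge_knots = 5,
                           beta_multiplier = 1, max_iter = 5000,
                           tol = 1e-7) {
  vars <- names(bg_raw)
  if (length(vars) < 2) stop("jackknife_gain: need >= 2 variables",
                             call. = FALSE)
  m <- nrow(bg_raw)
  gain_of <- function(v) {
    fx <- build_features(bg_raw[v], hinge_knots)
    mod <- maxent_fit(expand_features(fx, pres_raw[v]),
                      expand_features(fx, bg_raw[v]),
                      beta_multiplier = beta_multiplier,
                      max_iter = max_iter, tol = tol)
    mod$objective + log(m)
  }
  tab <- data.frame(
    variable = vars,
    gain_only = vapply(vars, function(v) gain_of(v), numeric(1)),
    gain_without = vapply(vars, function(v) gain_of(setdiff(vars, v)),
                          numeric(1)))
  list(table = tab, gain_full = gain_of(vars))
}
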