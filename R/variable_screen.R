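#' Pairwise Pearson correlation of layers at sample points
#'
#' Correlations are computed over layer values extracted at the supplied
#' points (typically presences plus background), i.e. over the data the
#' model will actually see rather than the whole raster. A zero-variance
#' layer has undefined correlation with the others; it is reported as `NA`
#' off-diagonal (and flagged via the `zero_variance` attribute) with r = 1
#' to itself.
#'
#' @param stack a [habstack()] of candidate layers.
#' @param sample_points data.frame with `x`, `y`; at least 3 points must
#'   carry valid values in every layer.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(stack, sample_points) {
  vals <- extract_at(stack, sample_points)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3) {
    stop("pairwise_correlation: need >= 3 points valid in all layers",
         call. = FALSE)
  }
  sds <- vapply(vals, stats::sd, numeric(1))
  zv <- names(vals)[sds == 0]
  cm <- suppressWarnings(stats::cor(as.matrix(vals)))
  diag(cm) <- 1
  attr(cm, "zero_variance") <- zv
  cm
}

#' Greedy elimination of strongly correlated variables
#'
#' While any retained pair exceeds the cutoff in absolute correlation, the
#' worst-offending pair is found and one of its members dropped: the one
#' with lower priority when a priority ranking is given, otherwise the one
#' with the larger mean absolute correlation to all other retained
#' variables (ties broken alphabetically). Deterministic.
#'
#' @param corr symmetric correlation matrix with named dimensions.
#' @param cutoff absolute-correlation threshold (default 0.8); a pair is
#'   offending iff |r| > cutoff.
#' @param priority optional character vector of variable names ordered from
#'   most to least important; a higher-priority member of an offending pair
#'   is never the one dropped.
#' @return list of class `screen_report`: `retained` (ordered as in the
#'   input), `eliminated` (data.frame: variable, partner, r), `correlation`
#'   (the input matrix), `cutoff`.
#' @export
eliminate_correlated <- function(corr, cutoff = 0.8, priority = NULL) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  vars <- colnames(corr)
  if (is.null(vars)) stop("correlation matrix must have names", call. = FALSE)
  a <- abs(corr)
  a[is.na(a)] <- 0   # zero-variance layers cannot offend against others
  diag(a) <- 0
  retained <- vars
  elim <- data.frame(variable = character(), partner = character(),
                     r = numeric())
  repeat {
    sub <- a[retained, retained, drop = FALSE]
    if (all(sub <= cutoff)) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- sort(c(retained[w[1]], retained[w[2]]))
    drop_var <- NA_character_
    if (!is.null(priority)) {
      # lower priority (larger rank; unranked counts as lowest) is dropped
      pr <- match(pair, priority)
      pr[is.na(pr)] <- Inf
      if (pr[1] != pr[2]) drop_var <- pair[which.max(pr)]
    }
    if (is.na(drop_var)) {
      mean_r <- rowMeans(sub[pair, , drop = FALSE]) * length(retained) /
        max(1, length(retained) - 1)
      drop_var <- if (mean_r[1] == mean_r[2]) sort(pair)[2] else
        pair[which.max(mean_r)]
    }
    keep_var <- setdiff(pair, drop_var)
    elim <- rbind(elim, data.frame(
      variable = drop_var, partner = keep_var,
      r = corr[drop_var, keep_var]))
    retained <- setdiff(retained, drop_var)
  }
  structure(list(retained = vars[vars %in% retained], eliminated = elim,
                 correlation = corr, cutoff = cutoff),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d retained of %d (|r| cutoff %.2f)\n",
              length(x$retained), ncol(x$correlation), x$cutoff))
  if (nrow(x$eliminated)) {
    for (i in seq_len(nrow(x$eliminated))) {
      cat(sprintf("  dropped %-20s (r = %+.3f with %s)\n",
                  x$eliminated$variable[i], x$eliminated$r[i],
                  x$eliminated$partner[i]))
    }
  }
  invisible(x)
}

#' Retain variables above a permutation-importance cutoff
#'
#' The second screening stage: after a first model fit, only variables whose
#' permutation importance reaches `cutoff_pct` percent are carried into the
#' final model (inclusive threshold).
#'
#' @param importance named numeric vector of permutation importances,
#'   summing to ~100.
#' @param cutoff_pct inclusion threshold in percent (default 1).
#' @return character vector of retained variable names, in input order.
#' @export
refit_top_variables <- function(importance, cutoff_pct = 1.0) {
  if (abs(sum(importance) - 100) > 1) {
    warning("importances do not sum to ~100; interpreting as given")
  }
  keep <- names(importance)[importance >= cutoff_pct]
  if (length(keep) == 0) {
    stop("refit_top_variables: no variable reaches the importance cutoff",
         call. = FALSE)
  }
  keep
}
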