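#' Fit a random-forest cell cycle classifier
#'
#' The central estimator of the package: a classification random forest (CART
#' trees, Gini splitting, bootstrap resampling, `sqrt(P)` candidate features
#' per split, unlimited depth) distinguishing cell cycle (1) from non-cell
#' cycle (0) genes from promoter features. The positive-class probability of a
#' gene is the fraction of trees voting positive. Feature importance is
#' reported both as mean decrease in Gini impurity (MDG, from the training
#' forest) and as out-of-bag permutation importance on the squared-error scale
#' (%IncMSE analogue; `nperm` permutations per feature, averaged).
#'
#' All randomness (bootstrap, feature subsets, permutations) derives from
#' `seed`, so a fit is fully reproducible.
#'
#' @param x numeric feature matrix (genes x features) or a `feature_table`
#'   from [build_feature_table()].
#' @param y binary labels (ignored when `x` is a `feature_table`).
#' @param ntree number of trees (default 500).
#' @param mtry candidate features per split (default `floor(sqrt(P))`).
#' @param min_node minimum node size to attempt a split from (default 1).
#' @param nperm permutations per feature for the permutation importance
#'   (default 10; 0 skips it, leaving `importance$inc_mse` as `NA`).
#' @param seed integer RNG seed.
#' @return object of class `cycle_forest` with elements `trees`, `importance`
#'   (data.frame: feature, mdg, inc_mse), `oob_prob` (out-of-bag positive-vote
#'   fraction per training gene), `feature_names`, `y`, `call` and the
#'   hyperparameters.
#' @seealso [predict.cycle_forest()], [cross_validate()], [importance()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2)
#' y <- as.integer(x[, 1] > 0)
#' fit <- cycle_forest(x, y, ntree = 50, seed = 1)
#' fit
#' @export
cycle_forest <- function(x, y = NULL, ntree = 500, mtry = NULL,
                         min_node = 1, nperm = 10, seed = 1) {
  if (inherits(x, "feature_table")) {
    y <- x$y
    x <- x$X
  }
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2)
    warning("training labels contain a single class")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  fit <- .forest_fit(x, y, as.integer(ntree), as.integer(mtry),
                     as.integer(min_node), as.integer(seed),
                     as.integer(nperm))
  structure(list(
    trees = fit$trees,
    importance = data.frame(feature = colnames(x), mdg = fit$mdg,
                            inc_mse = fit$inc_mse,
                            stringsAsFactors = FALSE),
    oob_prob = setNames(fit$oob_prob, rownames(x)),
    feature_names = colnames(x),
    y = y, ntree = ntree, mtry = mtry, min_node = min_node,
    nperm = nperm, seed = seed, call = match.call()),
    class = "cycle_forest")
}

#' @export
print.cycle_forest <- function(x, ...) {
  oob <- x$oob_prob[!is.na(x$oob_prob)]
  yo <- x$y[!is.na(x$oob_prob)]
  err <- if (length(oob)) mean((oob > 0.5) != (yo == 1)) else NA
  cat("cycle_forest:", x$ntree, "trees, mtry", x$mtry, ",",
      length(x$feature_names), "features,", length(x$y), "genes (",
      sum(x$y), "positive )\n")
  if (is.finite(err)) cat("  OOB error rate:", format(err, digits = 3), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.cycle_forest <- function(object, ...) {
  print(object)
  imp <- importance(object)
  cat("  top features by MDG:\n")
  print(head(imp[, c("feature", "mdg", "relative")], 5), row.names = FALSE)
  invisible(object)
}

#' Predict positive-class probabilities
#'
#' @param object a [cycle_forest()] fit.
#' @param newdata feature matrix with the training feature columns (matched by
#'   name when available), or a `feature_table`.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`: the fraction of trees
#'   voting positive. Deterministic given the model and features.
#' @export
predict.cycle_forest <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  else if (ncol(newdata) != length(object$feature_names))
    stop("newdata does not provide the training features")
  p <- .forest_predict(object$trees, newdata)
  names(p) <- rownames(newdata)
  p
}

#' Feature importance ranking
#'
#' @param object a [cycle_forest()] fit.
#' @param measure `"mdg"` (mean decrease in Gini, default) or `"inc_mse"`
#'   (out-of-bag permutation importance).
#' @return data.frame sorted by decreasing importance with columns `feature`,
#'   `mdg`, `inc_mse` and `relative` (chosen measure divided by its maximum).
#'   Ties are broken lexicographically by feature id for determinism.
#' @export
importance <- function(object, measure = c("mdg", "inc_mse")) {
  stopifnot(inherits(object, "cycle_forest"))
  measure <- match.arg(measure)
  imp <- object$importance
  v <- imp[[measure]]
  mx <- max(v, na.rm = TRUE)
  imp$relative <- if (is.finite(mx) && mx > 0) v / mx else rep(0, length(v))
  imp[order(-v, imp$feature), , drop = FALSE]
}

#' @exportS3Method graphics::plot
plot.cycle_forest <- function(x, n = 20, measure = "mdg", ...) {
  imp <- importance(x, measure)
  imp <- head(imp, n)
  op <- par(mar = c(4, 8, 1, 1))
  on.exit(par(op))
  barplot(rev(imp[[measure]]), names.arg = rev(imp$feature), horiz = TRUE,
          las = 1, xlab = measure, ...)
  invisible(x)
}
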