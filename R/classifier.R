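#' Assemble the gene x feature table
#'
#' Combines TF regulatory-score sets and the motif binding score matrix into
#' one design matrix over the intersection-free union of gene ids: a gene
#' missing from a score source gets 0 in those columns (no missing values).
#' Column order is deterministic: TF columns first, then motif columns, each
#' lexicographic by id.
#'
#' @param reg_sets named list of score sources: each element either a
#'   [standardize_and_call()] `reg_score_set` or a named numeric vector of raw
#'   scores per gene. Names become `tf:` feature ids.
#' @param motif_matrix optional genes x motifs matrix from
#'   [motif_score_matrix()]; columns become `motif:` feature ids.
#' @param labels named binary vector (1 = cell cycle); genes absent from
#'   `labels` are dropped.
#' @param feature_subset `"both"`, `"tf"` or `"motif"`.
#' @return object of class `feature_table`: `gene_ids`, `X` (N x P matrix),
#'   `y`, `feature_type` (named "tf"/"motif" vector partitioning the columns).
#' @export
build_feature_table <- function(reg_sets = NULL, motif_matrix = NULL, labels,
                                feature_subset = c("both", "tf", "motif")) {
  feature_subset <- match.arg(feature_subset)
  if (feature_subset == "tf") motif_matrix <- NULL
  if (feature_subset == "motif") reg_sets <- NULL
  if (is.null(reg_sets) && is.null(motif_matrix))
    stop("no features selected")
  genes <- names(labels)
  if (is.null(genes)) stop("labels must be a named vector")

  cols <- list()
  if (!is.null(reg_sets)) {
    ids <- sort(names(reg_sets))
    for (id in ids) {
      s <- reg_sets[[id]]
      if (inherits(s, "reg_score_set")) s <- s$scores
      v <- setNames(numeric(length(genes)), genes)
      common <- intersect(genes, names(s))
      v[common] <- s[common]
      cols[[paste0("tf:", id)]] <- v
    }
  }
  if (!is.null(motif_matrix)) {
    for (id in sort(colnames(motif_matrix))) {
      v <- setNames(numeric(length(genes)), genes)
      common <- intersect(genes, rownames(motif_matrix))
      v[common] <- motif_matrix[common, id]
      cols[[paste0("motif:", id)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- genes
  ft <- ifelse(grepl("^tf:", colnames(X)), "tf", "motif")
  names(ft) <- colnames(X)
  structure(list(gene_ids = genes, X = X, y = as.integer(labels),
                 feature_type = ft),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$X), "genes x", ncol(x$X), "features (",
      sum(x$feature_type == "tf"), "tf,", sum(x$feature_type == "motif"),
      "motif ),", sum(x$y), "positive\n")
  invisible(x)
}

# internal: subset columns of a feature_table
.subset_features <- function(table, keep) {
  structure(list(gene_ids = table$gene_ids,
                 X = table$X[, keep, drop = FALSE],
                 y = table$y,
                 feature_type = table$feature_type[keep]),
            class = "feature_table")
}

#' ROC curve and AUC from scores and labels
#'
#' Builds the ROC by sweeping 100 equally spaced threshold partitions of the
#' score range (plus the two trivial endpoints) and integrates it with the
#' trapezoid rule. The exact rank-statistic AUC (Mann-Whitney U divided by
#' `n1 * n0`, ties handled by midranks) is reported alongside as `auc_rank`.
#'
#' @param scores numeric score vector (higher = more cell cycle like).
#' @param labels binary labels.
#' @param n_partitions number of threshold partitions (default 100).
#' @return object of class `roc_result`: `roc` (data.frame fpr/tpr, monotone,
#'   from (0,0) to (1,1)), `auc` (trapezoid), `auc_rank` (exact).
#' @export
roc_auc <- function(scores, labels, n_partitions = 100) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  rng <- range(scores)
  thr <- if (rng[1] == rng[2]) rng[1] else
    seq(rng[1], rng[2], length.out = n_partitions + 1)
  # sweep from high to low threshold so fpr/tpr increase
  thr <- sort(unique(thr), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  r <- rank(scores)
  auc_rank <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(roc = roc, auc = auc, auc_rank = auc_rank,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC:", x$n_pos, "pos /", x$n_neg, "neg, AUC (trapezoid) =",
      format(x$auc, digits = 4), ", AUC (rank) =",
      format(x$auc_rank, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.roc_result <- function(x, add = FALSE, ...) {
  if (add) lines(x$roc$fpr, x$roc$tpr, ...)
  else {
    plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "false positive rate",
         ylab = "true positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
    abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' k-fold cross-validation of the forest
#'
#' Genes are partitioned into `k` folds at random, irrespective of their
#' labels (unstratified, matching the original training protocol; set
#' `stratified = TRUE` to balance classes per fold). Each gene is scored
#' exactly once by the forest trained on the other folds; the ROC and AUC are
#' computed from the pooled out-of-fold probabilities.
#'
#' @param table a [build_feature_table()] object.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and tree growth.
#' @param ntree,mtry forest hyperparameters, see [cycle_forest()].
#' @param stratified balance classes across folds (default `FALSE`).
#' @return object of class `cv_result`: `fold` (per-gene assignment), `prob`
#'   (out-of-fold probabilities), `roc`, `auc`, `auc_rank`, `per_fold`
#'   (data.frame of per-fold sensitivity/specificity at probability 0.5).
#' @export
cross_validate <- function(table, k = 10, seed = 1, ntree = 500,
                           mtry = NULL, stratified = FALSE) {
  X <- table$X
  y <- table$y
  n <- nrow(X)
  stopifnot(n >= k)
  set.seed(seed)
  if (stratified) {
    fold <- integer(n)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  prob <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    if (length(unique(y[!test])) < 2)
      warning("fold ", f, ": training split has a single class")
    fit <- cycle_forest(X[!test, , drop = FALSE], y[!test], ntree = ntree,
                        mtry = mtry, nperm = 0, seed = seed + f)
    prob[test] <- predict(fit, X[test, , drop = FALSE])
  }
  rr <- roc_auc(prob, y)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    idx <- fold == f
    tp <- sum(prob[idx] > 0.5 & y[idx] == 1)
    fn <- sum(prob[idx] <= 0.5 & y[idx] == 1)
    tn <- sum(prob[idx] <= 0.5 & y[idx] == 0)
    fp <- sum(prob[idx] > 0.5 & y[idx] == 0)
    data.frame(fold = f,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA)
  }))
  structure(list(fold = fold, prob = setNames(prob, table$gene_ids),
                 y = y, roc = rr$roc, auc = rr$auc, auc_rank = rr$auc_rank,
                 per_fold = per_fold, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold CV:", length(x$y), "genes, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.cv_result <- function(x, ...) {
  plot(structure(list(roc = x$roc, auc = x$auc), class = "roc_result"), ...)
}

#' One-by-one feature ablation
#'
#' Repeatedly removes the currently most important feature: at each step the
#' model is cross-validated on the remaining features, the importance is
#' re-estimated on a forest fit to the full data, and the top feature (ties
#' broken lexicographically) is removed. Stops when one feature remains.
#'
#' @param table a [build_feature_table()] object.
#' @param seed integer seed.
#' @param ntree trees per forest.
#' @param k CV folds.
#' @param measure importance measure used for removal (default `"mdg"`).
#' @return data.frame with one row per step: `n_features` (features in the
#'   model at that step), `auc`, `removed_feature` (the feature removed after
#'   measuring that AUC; `NA` on the final single-feature step).
#' @export
ablate_features <- function(table, seed = 1, ntree = 500, k = 10,
                            measure = "mdg") {
  cur <- table
  out <- list()
  step <- 1
  repeat {
    p <- ncol(cur$X)
    cv <- cross_validate(cur, k = k, seed = seed, ntree = ntree)
    if (p == 1) {
      out[[step]] <- data.frame(n_features = p, auc = cv$auc,
                                removed_feature = NA_character_)
      break
    }
    fit <- cycle_forest(cur, ntree = ntree, nperm = 0, seed = seed)
    imp <- importance(fit, measure)
    top <- imp$feature[1]
    out[[step]] <- data.frame(n_features = p, auc = cv$auc,
                              removed_feature = top)
    cur <- .subset_features(cur, setdiff(colnames(cur$X), top))
    step <- step + 1
  }
  do.call(rbind, out)
}

#' Reduced model from the top-k features
#'
#' Selects the `k_tf` TF features and `k_motif` motif features with the
#' highest importance in the full model, then re-runs cross-validation on the
#' reduced table.
#'
#' @param table a [build_feature_table()] object.
#' @param k_tf,k_motif how many TF / motif features to keep (default 10 each).
#' @param seed,ntree,k see [cross_validate()].
#' @param measure importance measure for the selection (default `"mdg"`).
#' @return list: `cv` (a `cv_result` on the reduced table), `selected`
#'   (character vector of kept feature ids).
#' @export
topk_model <- function(table, k_tf = 10, k_motif = 10, seed = 1,
                       ntree = 500, k = 10, measure = "mdg") {
  fit <- cycle_forest(table, ntree = ntree, nperm = 0, seed = seed)
  imp <- importance(fit, measure)
  tf_rank <- imp$feature[table$feature_type[imp$feature] == "tf"]
  mo_rank <- imp$feature[table$feature_type[imp$feature] == "motif"]
  sel <- c(head(tf_rank, k_tf), head(mo_rank, k_motif))
  sel <- colnames(table$X)[colnames(table$X) %in% sel] # original order
  if (length(sel) == 0) stop("selection is empty")
  red <- .subset_features(table, sel)
  list(cv = cross_validate(red, k = k, seed = seed, ntree = ntree),
       selected = sel)
}

#' Cell cycle phase selection ranges
#'
#' The default Cyclebase-style bins over peak expression time in `[0, 100)`:
#' M/G1 `[95,100) + [0,20)`, G2/M `[80,95)`, G2 `[70,90)`, S `[47,70)`,
#' G1/S `[20,60)`. Ranges may overlap, so one gene can enter several phases.
#'
#' @return named list of two-column matrices (`start`, `end`), one or two
#'   half-open intervals per phase.
#' @export
phase_bin_spec <- function() {
  list(`M/G1` = rbind(c(95, 100), c(0, 20)),
       `G2/M` = rbind(c(80, 95)),
       `G2`   = rbind(c(70, 90)),
       `S`    = rbind(c(47, 70)),
       `G1/S` = rbind(c(20, 60)))
}

#' Phase-specific training tables
#'
#' For each phase, selects the cell cycle genes whose peak time falls in the
#' phase's ranges as positives and pairs them with all negatives; genes may
#' enter several phases because the ranges overlap.
#'
#' @param table a full [build_feature_table()] object.
#' @param peak_time named numeric vector of peak times for the positive genes.
#' @param spec phase ranges, default [phase_bin_spec()].
#' @return named list of `feature_table` objects, one per phase.
#' @export
phase_training_sets <- function(table, peak_time, spec = phase_bin_spec()) {
  genes <- table$gene_ids
  pos <- genes[table$y == 1]
  neg <- genes[table$y == 0]
  pt <- peak_time[pos]
  out <- list()
  for (ph in names(spec)) {
    rng <- spec[[ph]]
    inph <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(rng)))
      inph <- inph | (!is.na(pt) & pt >= rng[r, 1] & pt < rng[r, 2])
    keep <- genes %in% c(pos[inph], neg)
    out[[ph]] <- structure(list(
      gene_ids = genes[keep],
      X = table$X[keep, , drop = FALSE],
      y = table$y[keep],
      feature_type = table$feature_type),
      class = "feature_table")
  }
  out
}

#' Expression-matched negative gene set
#'
#' Draws a negative set whose expression distribution matches the positives:
#' the positive expression distribution is cut into `n_bins` quantile bins and
#' negatives are sampled to reproduce the per-bin counts. Bins that run out of
#' negatives are filled best-effort from adjacent bins (with a warning). Used
#' to decouple the expression-level confounder from genuine binding effects.
#'
#' @param pos_expr named numeric vector: expression of positive genes.
#' @param neg_expr named numeric vector: expression of the negative pool.
#' @param n_bins number of quantile bins (default 10).
#' @param seed integer seed.
#' @return character vector of selected negative gene ids (length `<=`
#'   `length(pos_expr)`).
#' @export
match_expression_negatives <- function(pos_expr, neg_expr, n_bins = 10,
                                       seed = 1) {
  stopifnot(!is.null(names(neg_expr)))
  set.seed(seed)
  br <- quantile(pos_expr, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf
  br[length(br)] <- Inf
  br <- unique(br)
  pos_bin <- cut(pos_expr, br, include.lowest = TRUE)
  neg_bin <- cut(neg_expr, br, include.lowest = TRUE)
  want <- table(pos_bin)
  chosen <- character(0)
  avail <- split(names(neg_expr), neg_bin)
  shortfall <- integer(0)
  mids <- vapply(levels(pos_bin), function(b)
    median(pos_expr[pos_bin == b]), 0)
  for (b in names(want)) {
    nb <- want[[b]]
    pool <- setdiff(avail[[b]], chosen)
    takes <- if (length(pool)) sample(pool, min(nb, length(pool)))
             else character(0)
    if (nb > length(takes)) shortfall[b] <- nb - length(takes)
    chosen <- c(chosen, takes)
  }
  if (length(shortfall) > 0 && sum(shortfall) > 0) {
    warning("expression bins short of negatives; filling ", sum(shortfall),
            " from adjacent bins")
    # per short bin, take the unused negatives nearest that bin's centre
    for (b in names(shortfall)) {
      pool <- setdiff(names(neg_expr), chosen)
      if (!length(pool)) break
      d <- abs(neg_expr[pool] - mids[[b]])
      chosen <- c(chosen,
                  pool[order(d)][seq_len(min(shortfall[[b]], length(pool)))])
    }
  }
  chosen
}
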