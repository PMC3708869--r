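test_that("feature tables assemble with deterministic columns and imputation", {
  labels <- setNames(c(1L, 0L, 1L, 0L), c("g1", "g2", "g3", "g4"))
  reg <- list(tfB = setNames(1:4, names(labels)),
              tfA = setNames(5:8, names(labels)))
  B <- matrix(1, 3, 3, dimnames = list(c("g1", "g2", "g3"),
                                       c("m2", "m1", "m3")))
  tab <- build_feature_table(reg, B, labels)
  expect_equal(dim(tab$X), c(4, 5))
  expect_equal(colnames(tab$X),
               c("tf:tfA", "tf:tfB", "motif:m1", "motif:m2", "motif:m3"))
  expect_equal(unname(tab$X["g4", "motif:m1"]), 0) # missing gene imputed to 0

  tf_only <- build_feature_table(reg, B, labels, "tf")
  expect_true(all(tf_only$feature_type == "tf"))
  expect_equal(ncol(tf_only$X), 2)

  # a gene absent from one score set gets 0 in that column
  reg2 <- list(tfA = setNames(5:7, c("g1", "g2", "g3")))
  tab2 <- build_feature_table(reg2, NULL, labels)
  expect_equal(unname(tab2$X["g4", "tf:tfA"]), 0)
})

test_that("ROC endpoints and AUC behave at the trivial limits", {
  y <- rep(c(1, 0), each = 20)
  r1 <- roc_auc(as.numeric(y), y)
  expect_equal(r1$auc, 1)
  expect_equal(r1$auc_rank, 1)
  r2 <- roc_auc(rep(0.3, 40), y)
  expect_equal(r2$auc, 0.5)
  expect_equal(r2$auc_rank, 0.5)
  expect_equal(r1$roc$fpr[1], 0)
  expect_equal(r1$roc$tpr[nrow(r1$roc)], 1)
})

test_that("trapezoid AUC tracks the exact rank AUC", {
  # 8-point toy
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.3, 0.1)
  y <- c(1, 1, 0, 1, 0, 1, 0, 0)
  r <- roc_auc(sc, y)
  expect_lt(abs(r$auc - r$auc_rank), 0.01)
  # random sets with >= 20 distinct scores
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(30:200, 1)
    sc <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_auc(sc, y)
    expect_lt(abs(r$auc - r$auc_rank), 0.01)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
    expect_gte(r$auc, 0)
    expect_lte(r$auc, 1)
  }
})

test_that("forest separates a planted feature and is reproducible", {
  set.seed(41)
  x <- matrix(rnorm(2000), 200, 10)
  colnames(x) <- sprintf("f%02d", 1:10)
  y <- as.integer(x[, 4] > 0)
  f1 <- cycle_forest(x, y, ntree = 100, seed = 7, nperm = 0)
  f2 <- cycle_forest(x, y, ntree = 100, seed = 7, nperm = 0)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_gte(roc_auc(predict(f1, x), y)$auc, 0.99)
  expect_equal(importance(f1)$feature[1], "f04")
})

test_that("cross-validation hits the separable and null limits", {
  set.seed(42)
  x <- matrix(rnorm(1200), 120, 10)
  colnames(x) <- sprintf("f%02d", 1:10)
  y <- as.integer(x[, 1] > 0)
  labels <- setNames(y, sprintf("g%03d", 1:120))
  tab <- build_feature_table(list(s = setNames(x[, 1], names(labels))),
                             NULL, labels)
  tab$X <- x
  rownames(tab$X) <- names(labels)
  tab$feature_type <- setNames(rep("tf", 10), colnames(x))
  cv <- cross_validate(tab, k = 10, seed = 1, ntree = 100)
  expect_gte(cv$auc, 0.99)
  expect_true(all(table(cv$fold) >= 1))

  # label permutation: mean AUC near chance over a few seeds
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    tabp <- tab
    tabp$y <- sample(tab$y)
    cross_validate(tabp, k = 10, seed = s, ntree = 60)$auc
  }, 0)
  expect_gt(mean(aucs), 0.38)
  expect_lt(mean(aucs), 0.62)
})

test_that("importance finds one informative column among many noise columns", {
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(150 * 51), 150, 51)
    colnames(x) <- sprintf("f%02d", 1:51)
    y <- as.integer(x[, 25] + rnorm(150, 0, 0.4) > 0)
    fit <- cycle_forest(x, y, ntree = 100, seed = seed, nperm = 2)
    imp_mdg <- importance(fit, "mdg")$feature[1]
    imp_mse <- importance(fit, "inc_mse")$feature[1]
    (imp_mdg == "f25") + (imp_mse == "f25")
  }, 0)
  expect_gte(sum(hits >= 1), 10) # top by at least one measure, every seed
  expect_gte(sum(hits == 2), 8)  # top by both in nearly all seeds
})

test_that("duplicated informative columns share importance but beat noise", {
  set.seed(43)
  x <- matrix(rnorm(150 * 20), 150, 20)
  x[, 2] <- x[, 1] # duplicate of the informative feature
  colnames(x) <- sprintf("f%02d", 1:20)
  y <- as.integer(x[, 1] + rnorm(150, 0, 0.3) > 0)
  fit <- cycle_forest(x, y, ntree = 200, seed = 2, nperm = 0)
  imp <- fit$importance
  pair <- sum(imp$mdg[imp$feature %in% c("f01", "f02")])
  expect_gt(pair, max(imp$mdg[!imp$feature %in% c("f01", "f02")]))
})

test_that("no noise column dominates importance across seeds", {
  tops <- vapply(1:5, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(100 * 15), 100, 15)
    colnames(x) <- sprintf("f%02d", 1:15)
    y <- rbinom(100, 1, 0.5)
    importance(cycle_forest(x, y, ntree = 80, seed = seed, nperm = 0))$feature[1]
  }, "")
  expect_gt(length(unique(tops)), 1)
})

test_that("ablation terminates at one feature and collapses when the only
          informative feature is removed", {
  set.seed(44)
  x <- matrix(rnorm(120 * 6), 120, 6)
  colnames(x) <- c("tf:a", "tf:b", "tf:c", "tf:d", "tf:e", "tf:f")
  y <- as.integer(x[, 3] > 0)
  tab <- structure(list(gene_ids = sprintf("g%03d", 1:120), X = x, y = y,
                        feature_type = setNames(rep("tf", 6), colnames(x))),
                   class = "feature_table")
  rownames(tab$X) <- tab$gene_ids
  ab <- ablate_features(tab, seed = 1, ntree = 80, k = 5)
  expect_equal(nrow(ab), 6)
  expect_equal(ab$n_features, 6:1)
  expect_true(is.na(ab$removed_feature[6]))
  expect_equal(ab$removed_feature[1], "tf:c") # informative goes first
  expect_gte(ab$auc[1], 0.95)
  expect_lt(ab$auc[2], 0.7) # collapse after removing the only signal
})

test_that("top-k model reduces to the stated feature subsets", {
  set.seed(45)
  n <- 150
  x <- cbind(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 3), n, 3))
  colnames(x) <- c(paste0("tf:t", 1:4), paste0("motif:m", 1:3))
  y <- as.integer(x[, 1] + 0.5 * x[, 5] + rnorm(n, 0, 0.5) > 0)
  tab <- structure(list(gene_ids = sprintf("g%03d", 1:n), X = x, y = y,
                        feature_type = setNames(c(rep("tf", 4),
                                                  rep("motif", 3)),
                                                colnames(x))),
                   class = "feature_table")
  rownames(tab$X) <- tab$gene_ids

  # k exceeding the catalogue keeps every feature: identical to the full model
  full <- cross_validate(tab, k = 5, seed = 3, ntree = 80)
  tk <- topk_model(tab, k_tf = 10, k_motif = 10, seed = 3, ntree = 80, k = 5)
  expect_setequal(tk$selected, colnames(x))
  expect_equal(tk$cv$auc, full$auc)

  # k_tf = 0 keeps only motif features
  tk0 <- topk_model(tab, k_tf = 0, k_motif = 10, seed = 3, ntree = 80, k = 5)
  expect_true(all(grepl("^motif:", tk0$selected)))
})

test_that("phase bins select peak times exactly as printed", {
  spec <- phase_bin_spec()
  in_phase <- function(pt, ph) {
    rng <- spec[[ph]]
    any(pt >= rng[, 1] & pt < rng[, 2])
  }
  # 50 sits in S (47-70) and, because the printed ranges overlap, in
  # G1/S (20-60) as well - but in no other phase
  expect_true(in_phase(50, "S"))
  expect_true(in_phase(50, "G1/S"))
  expect_false(any(vapply(c("M/G1", "G2/M", "G2"), function(ph)
    in_phase(50, ph), TRUE)))
  expect_true(in_phase(85, "G2"))
  expect_true(in_phase(85, "G2/M"))
  expect_true(in_phase(10, "M/G1"))
  expect_false(in_phase(10, "G1/S"))
  expect_true(in_phase(97, "M/G1"))
  # boundaries are half-open
  expect_true(in_phase(47, "S"))
  expect_true(in_phase(47, "G1/S"))
  expect_false(in_phase(70, "S"))
  expect_true(in_phase(70, "G2"))
})

test_that("phase training sets pair phase positives with all negatives", {
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3)
  colnames(x) <- c("tf:a", "tf:b", "tf:c")
  y <- rep(c(1L, 0L), each = n / 2)
  ids <- sprintf("g%02d", 1:n)
  rownames(x) <- ids
  tab <- structure(list(gene_ids = ids, X = x, y = y,
                        feature_type = setNames(rep("tf", 3), colnames(x))),
                   class = "feature_table")
  pt <- setNames(seq(0, 99, length.out = n / 2), ids[y == 1])
  sets <- phase_training_sets(tab, pt)
  expect_setequal(names(sets), c("M/G1", "G2/M", "G2", "S", "G1/S"))
  for (ph in names(sets)) {
    s <- sets[[ph]]
    expect_equal(sum(s$y == 0), n / 2) # all negatives retained
    rng <- phase_bin_spec()[[ph]]
    pos_ids <- s$gene_ids[s$y == 1]
    expect_true(all(vapply(pt[pos_ids], function(v)
      any(v >= rng[, 1] & v < rng[, 2]), TRUE)))
  }
  # overlap: a gene at 85 sits in both G2 and G2/M
  g85 <- names(pt)[which.min(abs(pt - 85))]
  expect_true(g85 %in% sets$`G2`$gene_ids[sets$`G2`$y == 1] ||
              g85 %in% sets$`G2/M`$gene_ids[sets$`G2/M`$y == 1])
})

test_that("expression matching equalises the distributions", {
  set.seed(46)
  pos <- setNames(rnorm(200, 1.5), sprintf("p%03d", 1:200))
  # identical pool: any sample passes
  pool <- setNames(rnorm(2000, 1.5), sprintf("n%04d", 1:2000))
  sel <- match_expression_negatives(pos, pool, seed = 1)
  expect_gt(ks.test(pos, pool[sel])$p.value, 0.1)

  # shifted but wide pool: matched subset is indistinguishable in most seeds
  ok <- vapply(1:10, function(s) {
    set.seed(100 + s)
    pool2 <- setNames(rnorm(3000, 3.5, 2), sprintf("n%04d", 1:3000))
    sel2 <- match_expression_negatives(pos, pool2, seed = s)
    ks.test(pos, pool2[sel2])$p.value > 0.1
  }, TRUE)
  expect_gte(sum(ok), 9)

  # degenerate pool far below the positives warns
  pool3 <- setNames(rnorm(300, -10, 0.1), sprintf("n%03d", 1:300))
  expect_warning(match_expression_negatives(pos, pool3, seed = 1),
                 "adjacent")
})
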