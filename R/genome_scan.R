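#' Score a TSS catalogue with a trained model
#'
#' Applies a trained [cycle_forest()] to the features of an arbitrary TSS
#' catalogue and packages the per-TSS positive-class probabilities with
#' threshold-indexed summaries.
#'
#' @param model a [cycle_forest()] fit.
#' @param features numeric matrix of features for the catalogue (rows = TSSs,
#'   columns matching the training features).
#' @param tss optional TSS data.frame aligned with `features` rows (provides
#'   `gene_id` and `category` for the summaries).
#' @return object of class `prediction_set`: `prob` (per-TSS probability),
#'   `tss` (the catalogue, possibly `NULL`).
#' @export
predict_tss <- function(model, features, tss = NULL) {
  prob <- predict(model, features)
  if (!is.null(tss)) {
    stopifnot(nrow(tss) == length(prob))
    names(prob) <- tss$gene_id
  }
  structure(list(prob = prob, tss = tss), class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, threshold = 0.7, ...) {
  cat("prediction_set:", length(x$prob), "TSSs,",
      sum(x$prob > threshold), "positive at probability >", threshold, "\n")
  invisible(x)
}

#' Artificial random TSS controls
#'
#' Draws `n` artificial TSSs uniformly over the genome (per-chromosome counts
#' proportional to length), with uniform strand and category `artificial`.
#' Optionally excludes intervals (e.g. +/- 1 kb around real TSSs); the
#' original protocol used plain random locations, so exclusion is off unless
#' given.
#'
#' @param genome named vector of chromosome lengths.
#' @param n number of controls (default 10000).
#' @param seed integer seed.
#' @param exclusion optional data.frame `chrom`, `start`, `end` (0-based
#'   half-open) of forbidden intervals.
#' @return TSS data.frame with `category = "artificial"`, `label = "unknown"`.
#' @export
random_tss <- function(genome, n = 10000, seed = 1, exclusion = NULL) {
  set.seed(seed)
  tot <- sum(genome)
  if (!is.null(exclusion)) {
    excl_len <- sum(pmin(exclusion$end, genome[exclusion$chrom]) -
                    pmax(exclusion$start, 0))
    if (excl_len >= tot)
      stop("exclusion set covers the whole genome")
  }
  offs <- cumsum(c(0, as.numeric(genome)))
  out <- data.frame(chrom = character(0), pos = numeric(0),
                    strand = character(0))
  guard <- 0
  while (nrow(out) < n) {
    m <- n - nrow(out)
    u <- floor(runif(m, 0, tot))
    ci <- findInterval(u, offs, rightmost.closed = FALSE)
    pos <- u - offs[ci]
    cand <- data.frame(chrom = names(genome)[ci], pos = pos,
                       strand = sample(c("+", "-"), m, replace = TRUE),
                       stringsAsFactors = FALSE)
    if (!is.null(exclusion)) {
      bad <- vapply(seq_len(m), function(i) {
        e <- exclusion[exclusion$chrom == cand$chrom[i], , drop = FALSE]
        any(cand$pos[i] >= e$start & cand$pos[i] < e$end)
      }, TRUE)
      cand <- cand[!bad, , drop = FALSE]
    }
    out <- rbind(out, cand)
    guard <- guard + 1
    if (guard > 1000) stop("could not place random TSSs outside exclusion")
  }
  out <- out[seq_len(n), , drop = FALSE]
  out$gene_id <- sprintf("random_%05d", seq_len(n))
  out$category <- "artificial"
  out$label <- "unknown"
  out$peak_time <- NA_real_
  out$expression <- NA_real_
  rownames(out) <- NULL
  out
}

#' Empirical FDR from artificial TSS controls
#'
#' At a probability threshold, `F_real` is the fraction of real TSSs predicted
#' positive and `F_rand` the fraction of artificial (random-location) TSSs
#' predicted positive; the empirical false discovery rate is their ratio
#' `FDR = F_rand / F_real`, and the precision is `PPV = 1 - FDR` when
#' `FDR <= 1`.
#'
#' @param real_prob probabilities of the real TSSs.
#' @param rand_prob probabilities of the artificial controls.
#' @param threshold probability cutoff in `(0, 1)`.
#' @return list: `threshold`, `f_real`, `f_rand`, `fdr`, `ppv` (`NA` when
#'   `fdr > 1`).
#' @export
empirical_fdr <- function(real_prob, rand_prob, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  f_real <- mean(real_prob > threshold)
  f_rand <- mean(rand_prob > threshold)
  if (f_real == 0)
    stop("no positive predictions among real TSSs at threshold ", threshold)
  fdr <- f_rand / f_real
  list(threshold = threshold, f_real = f_real, f_rand = f_rand, fdr = fdr,
       ppv = if (fdr <= 1) 1 - fdr else NA_real_)
}

#' Empirical FDR / PPV curves over a threshold grid
#'
#' @inheritParams empirical_fdr
#' @param thresholds grid (default 0.01 to 0.99 step 0.01).
#' @return data.frame: `threshold`, `n_real_pos`, `f_real`, `f_rand`, `fdr`
#'   (clipped to 1 in `fdr_display`), `ppv`.
#' @export
fdr_curve <- function(real_prob, rand_prob,
                      thresholds = seq(0.01, 0.99, by = 0.01)) {
  rows <- lapply(thresholds, function(t) {
    f_real <- mean(real_prob > t)
    f_rand <- mean(rand_prob > t)
    fdr <- if (f_real > 0) f_rand / f_real else NA_real_
    data.frame(threshold = t, n_real_pos = sum(real_prob > t),
               f_real = f_real, f_rand = f_rand, fdr = fdr,
               fdr_display = pmin(fdr, 1),
               ppv = ifelse(!is.na(fdr) & fdr <= 1, 1 - fdr, NA_real_))
  })
  do.call(rbind, rows)
}

#' Per-category prediction summary
#'
#' Counts and percentages of TSSs predicted positive at a threshold, per
#' category (protein-coding, lincRNA, pseudogene, artificial, ...).
#'
#' @param pred a [predict_tss()] `prediction_set` whose `tss` has `category`.
#' @param threshold probability cutoff (default 0.7, the stringent setting).
#' @return data.frame: `category`, `n`, `n_positive`, `pct_positive`.
#' @export
category_summary <- function(pred, threshold = 0.7) {
  stopifnot(!is.null(pred$tss))
  cat_ <- pred$tss$category
  pos <- pred$prob > threshold
  cats <- unique(cat_)
  do.call(rbind, lapply(cats, function(cc) {
    idx <- cat_ == cc
    data.frame(category = cc, n = sum(idx), n_positive = sum(pos[idx]),
               pct_positive = 100 * mean(pos[idx]))
  }))
}

#' Alternative-promoter report
#'
#' Genes with several TSSs can mix cell cycle regulated and non-regulated
#' promoters (alternative promoter usage). A gene is flagged as a
#' split-promoter gene when the spread of its per-TSS probabilities exceeds
#' `flag_gap`.
#'
#' @param pred a [predict_tss()] `prediction_set` whose `tss` has `gene_id`.
#' @param flag_gap probability spread that triggers the flag (default 0.4).
#' @return data.frame: `gene_id`, `n_tss`, `min_prob`, `max_prob`, `probs`
#'   (comma-separated), `split_promoter` (logical).
#' @export
alternative_promoter_report <- function(pred, flag_gap = 0.4) {
  stopifnot(!is.null(pred$tss))
  by_gene <- split(pred$prob, pred$tss$gene_id)
  do.call(rbind, lapply(names(by_gene), function(g) {
    p <- by_gene[[g]]
    data.frame(gene_id = g, n_tss = length(p),
               min_prob = min(p), max_prob = max(p),
               probs = paste(format(p, digits = 3, trim = TRUE),
                             collapse = ","),
               split_promoter = (max(p) - min(p)) > flag_gap)
  }))
}
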