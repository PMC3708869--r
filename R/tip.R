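#' Characteristic TSS-centred binding profile (TIP)
#'
#' Averages the per-base signal in strand-oriented windows of `2h + 1` bp
#' centred at every TSS into a characteristic binding profile
#' `c[k] = (1/N) * sum_g s_g[k]`, and normalises it into positional weights
#' `w = c / sum(c)`. Windows truncated at chromosome edges are zero padded;
#' '-' strand windows are reversed so the index axis always runs 5' to 3' of
#' the gene.
#'
#' @param track a [signal_track()].
#' @param tss TSS data.frame (see [as_tss_table()]).
#' @param h half-width in bp (default 5000, i.e. a 10 kb window).
#' @param smooth optional moving-average width (odd, in bp) applied to the
#'   averaged profile before normalisation; 0 (default) disables smoothing.
#' @return object of class `binding_profile` with elements `h`, `profile`
#'   (length `2h + 1`), `weights` (sums to 1), `n_genes`, `smooth`.
#' @seealso [regulatory_score()] which consumes the weights.
#' @export
characteristic_profile <- function(track, tss, h = 5000, smooth = 0) {
  stopifnot(nrow(tss) >= 1, h >= 1)
  n <- 2 * h + 1
  acc <- colSums(.signal_windows(track, tss, h))
  prof <- acc / nrow(tss)
  if (smooth > 1) {
    if (smooth %% 2 == 0) stop("smooth width must be odd")
    kern <- rep(1 / smooth, smooth)
    prof <- as.numeric(stats::filter(prof, kern, sides = 2))
    # edge positions lose the full kernel; fall back to partial means
    half <- (smooth - 1) / 2
    for (k in seq_len(half)) {
      prof[k] <- mean(acc[max(1, k - half):(k + half)]) / nrow(tss)
      prof[n - k + 1] <- mean(acc[(n - k + 1 - half):min(n, n - k + 1 + half)]) /
        nrow(tss)
    }
  }
  s <- sum(prof)
  if (s <= 0)
    stop("degenerate profile: signal is zero everywhere around the TSSs")
  structure(list(h = h, profile = prof, weights = prof / s,
                 n_genes = nrow(tss), smooth = smooth),
            class = "binding_profile")
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("binding_profile: h =", x$h, "bp,", x$n_genes, "genes, peak weight at",
      which.max(x$weights) - x$h - 1, "bp from TSS\n")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.binding_profile <- function(x, ...) {
  plot(seq(-x$h, x$h), x$profile, type = "l",
       xlab = "offset from TSS (bp)", ylab = "mean signal", ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' TIP regulatory score of one gene
#'
#' The regulatory score is the weighted sum `r_g = sum_k w[k] * s_g[k]` of the
#' gene's own strand-oriented promoter signal under the characteristic-profile
#' weights: a weighted average, so it always lies between the minimum and
#' maximum signal in the window.
#'
#' @param profile a [characteristic_profile()].
#' @param track a [signal_track()].
#' @param tss_record single-row TSS data.frame (or list) with `chrom`, `pos`,
#'   `strand`.
#' @return numeric scalar.
#' @export
regulatory_score <- function(profile, track, tss_record) {
  s <- signal_window(track, tss_record$chrom[1], tss_record$pos[1],
                     tss_record$strand[1], profile$h)
  sum(profile$weights * s)
}

#' TIP regulatory scores for a whole catalogue
#'
#' @inheritParams regulatory_score
#' @param tss TSS data.frame.
#' @return named numeric vector (names = `gene_id`, one entry per row of
#'   `tss`).
#' @export
regulatory_scores <- function(profile, track, tss) {
  out <- as.numeric(.signal_windows(track, tss, profile$h) %*% profile$weights)
  names(out) <- tss$gene_id
  out
}

#' Standardise regulatory scores and call targets
#'
#' Following the TIP scheme, raw scores are z-transformed over genes, assigned
#' one-sided upper-tail normal p-values and Benjamini-Hochberg adjusted;
#' targets are the genes with `q < q_threshold`.
#'
#' @param scores named numeric vector of raw regulatory scores.
#' @param q_threshold BH-adjusted significance threshold (default 0.01).
#' @param dataset_id identifier of the ChIP experiment.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return object of class `reg_score_set`: `dataset_id`, `scores`, `z`, `p`,
#'   `q`, `targets` (character vector of gene ids).
#' @export
standardize_and_call <- function(scores, q_threshold = 0.01,
                                 dataset_id = "chip",
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 3) stop("need >= 3 genes with finite scores")
  mu <- mean(scores)
  s <- sd(scores)
  if (sd_type == "population")
    s <- sqrt(mean((scores - mu)^2))
  if (s == 0) stop("all scores equal: standard deviation is zero")
  z <- (scores - mu) / s
  p <- pnorm(z, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  structure(list(dataset_id = dataset_id, scores = scores, z = z, p = p,
                 q = q, targets = names(scores)[q < q_threshold],
                 q_threshold = q_threshold),
            class = "reg_score_set")
}

#' @export
print.reg_score_set <- function(x, ...) {
  cat("reg_score_set", x$dataset_id, ":", length(x$scores), "genes,",
      length(x$targets), "targets at q <", x$q_threshold, "\n")
  invisible(x)
}

#' Average promoter signal (peak-free comparator to TIP)
#'
#' Mean per-base signal in the 2 kb (by default) window `[pos - hw, pos + hw)`
#' centred at the TSS. Truncated windows are zero padded and the denominator
#' stays `2 * hw`, keeping scores comparable across genes.
#'
#' @param track a [signal_track()].
#' @param tss_record single-row TSS data.frame with `chrom`, `pos`.
#' @param half_width half-width in bp (default 1000).
#' @return numeric scalar.
#' @export
average_signal <- function(track, tss_record, half_width = 1000) {
  v <- track_values(track, tss_record$chrom[1],
                    tss_record$pos[1] - half_width,
                    tss_record$pos[1] + half_width)
  mean(v)
}

#' Average promoter signal for a whole catalogue
#'
#' @inheritParams average_signal
#' @param tss TSS data.frame.
#' @return named numeric vector.
#' @export
average_signals <- function(track, tss, half_width = 1000) {
  w <- .signal_windows(track, tss, half_width)
  # [pos - hw, pos + hw): drop the last base of the symmetric 2h+1 window
  # (the strand flip is irrelevant to a flat mean over a symmetric window,
  # except for that single trailing base, which we recompute per strand)
  out <- vapply(seq_len(nrow(tss)), function(i) {
    v <- if (tss$strand[i] == "-") rev(w[i, ]) else w[i, ]
    mean(v[seq_len(2 * half_width)])
  }, 0)
  names(out) <- tss$gene_id
  out
}

#' Class contrast of promoter scores (cell cycle vs non-cell cycle)
#'
#' Two-sample t-test of a score vector between the two label classes, the
#' statistic behind the per-TF contrast comparison of regulatory scores versus
#' average signals.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = cell cycle) or logical, same length.
#' @param pooled use the pooled-variance (classic Student) test instead of the
#'   default Welch test.
#' @return list with `t` (statistic, positive when class 1 scores higher) and
#'   `p` (two-sided p-value).
#' @export
score_class_contrast <- function(scores, labels, pooled = FALSE) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop("both classes need >= 2 members")
  ht <- t.test(scores[labels == 1], scores[labels == 0],
               var.equal = pooled)
  list(t = unname(ht$statistic), p = ht$p.value)
}
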