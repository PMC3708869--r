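#' Circular sliding-window enrichment of TF targets over the cell cycle
#'
#' Cell cycle genes are placed on a circle by their peak expression time
#' (0-100 mapped to 0-360 degrees, i.e. `theta = 3.6 * peak_time`). Windows of
#' `window` degrees slide in steps of `step` degrees (defaults 30 and 20:
#' adjacent windows share 10 degrees), wrapping mod 360. Each window gets a
#' one-sided Fisher exact test of the 2x2 table (in-window vs out) x (target
#' vs non-target).
#'
#' @param peak_time named numeric vector of peak times (`[0, 100)`) of the
#'   cell cycle genes.
#' @param targets character vector of target gene ids (subset of the names of
#'   `peak_time`).
#' @param window window size in degrees (default 30).
#' @param step window spacing in degrees (default 20, giving 18 windows).
#' @param alternative Fisher alternative (default `"greater"` = enrichment).
#' @return data.frame with one row per window: `center` (degrees),
#'   `n_in_window`, `n_targets_in_window`, `odds_ratio`, `p`.
#' @export
phase_window_enrichment <- function(peak_time, targets, window = 30,
                                    step = 20, alternative = "greater") {
  stopifnot(!is.null(names(peak_time)))
  theta <- (3.6 * peak_time) %% 360
  is_t <- names(peak_time) %in% targets
  centers <- seq(0, 360 - step, by = step)
  half <- window / 2
  do.call(rbind, lapply(centers, function(cc) {
    d <- (theta - cc + 180) %% 360 - 180 # circular distance in (-180, 180]
    inw <- d >= -half & d < half
    tab <- matrix(c(sum(inw & is_t), sum(inw & !is_t),
                    sum(!inw & is_t), sum(!inw & !is_t)), 2, 2)
    ht <- fisher.test(tab, alternative = alternative)
    data.frame(center = cc, n_in_window = sum(inw),
               n_targets_in_window = sum(inw & is_t),
               odds_ratio = unname(ht$estimate), p = ht$p.value)
  }))
}

#' Fisher overlap test of two gene sets
#'
#' One-sided (enrichment) Fisher exact test of the overlap between a predicted
#' gene set and a reference set within an explicitly supplied universe. The
#' universe is never inferred because the choice drives the p-value.
#'
#' @param predicted,reference character vectors of gene ids (or counts, see
#'   `overlap`).
#' @param universe_size total number of genes in the universe.
#' @param overlap optional: give `predicted`, `reference` and `overlap` as
#'   counts instead of id vectors.
#' @param alternative Fisher alternative (default `"greater"`).
#' @return list: `overlap`, `odds_ratio`, `p`, `table` (the 2x2 matrix).
#' @export
set_overlap_test <- function(predicted, reference, universe_size,
                             overlap = NULL, alternative = "greater") {
  if (is.null(overlap)) {
    n_pred <- length(unique(predicted))
    n_ref <- length(unique(reference))
    ov <- length(intersect(unique(predicted), unique(reference)))
  } else {
    n_pred <- predicted
    n_ref <- reference
    ov <- overlap
  }
  if (universe_size < n_pred + n_ref - ov)
    stop("universe smaller than the union of the sets")
  tab <- matrix(c(ov, n_pred - ov,
                  n_ref - ov, universe_size - n_pred - n_ref + ov), 2, 2)
  ht <- fisher.test(tab, alternative = alternative)
  list(overlap = ov, odds_ratio = unname(ht$estimate), p = ht$p.value,
       table = tab)
}

#' Interaction-partner statistics per gene class
#'
#' For disjoint gene classes (e.g. known cell cycle, predicted cell cycle,
#' predicted non-cell cycle) over an undirected protein-protein interaction
#' network, reports the mean number of partners, mean number of cell cycle
#' partners and mean percentage of cell cycle partners, plus pairwise
#' chi-squared p-values on the aggregate (class) x (partner is / is not cell
#' cycle) counts.
#'
#' @param edges data.frame with columns `a`, `b`: undirected interaction
#'   edges (self loops and duplicate pairs are dropped).
#' @param classes named character vector mapping gene id to class name;
#'   classes must be disjoint by construction.
#' @param cell_cycle_genes character vector defining which partners count as
#'   cell cycle partners.
#' @return list: `per_class` (data.frame class, n_genes, mean_partners,
#'   mean_cc_partners, mean_pct_cc_partners), `pairwise` (data.frame class1,
#'   class2, chisq_p).
#' @export
ppi_partner_stats <- function(edges, classes, cell_cycle_genes) {
  stopifnot(all(c("a", "b") %in% names(edges)))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b),
                paste(edges$b, edges$a))
  edges <- edges[!duplicated(key), , drop = FALSE]
  adj <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  genes <- names(classes)
  npart <- vapply(genes, function(g) length(adj[[g]]), 0)
  nccpart <- vapply(genes, function(g) sum(adj[[g]] %in% cell_cycle_genes), 0)
  pct <- ifelse(npart > 0, 100 * nccpart / npart, NA_real_)
  cls <- unique(classes)
  per_class <- do.call(rbind, lapply(cls, function(cc) {
    idx <- classes == cc
    data.frame(class = cc, n_genes = sum(idx),
               mean_partners = mean(npart[idx]),
               mean_cc_partners = mean(nccpart[idx]),
               mean_pct_cc_partners = mean(pct[idx], na.rm = TRUE))
  }))
  pairs <- if (length(cls) > 1) utils::combn(cls, 2, simplify = FALSE)
           else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    i1 <- classes == pr[1]
    i2 <- classes == pr[2]
    tab <- matrix(c(sum(nccpart[i1]), sum(npart[i1]) - sum(nccpart[i1]),
                    sum(nccpart[i2]), sum(npart[i2]) - sum(nccpart[i2])),
                  2, 2, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
         else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    data.frame(class1 = pr[1], class2 = pr[2], chisq_p = p)
  }))
  list(per_class = per_class, pairwise = pairwise)
}
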