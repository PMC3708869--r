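# shared fixture builders: everything is generated in code, no data files

# a small deterministic track from explicit intervals
toy_track <- function(intervals = NULL, chrom_lengths = c(chr1 = 1000)) {
  if (is.null(intervals))
    intervals <- data.frame(chrom = "chr1", start = c(0, 100, 500),
                            end = c(10, 200, 600), value = c(2.5, 1, 4))
  signal_track(intervals, chrom_lengths)
}

# random non-overlapping intervals on one chromosome
random_intervals <- function(n, len, seed, chrom = "chr1") {
  set.seed(seed)
  cuts <- sort(sample(0:len, 2 * n, replace = FALSE))
  starts <- cuts[seq(1, 2 * n, by = 2)]
  ends <- cuts[seq(2, 2 * n, by = 2)]
  keep <- ends > starts
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             value = round(runif(sum(keep), 0, 10), 3))
}

# brute-force per-base expansion of an interval table: the oracle the
# signal_track representation is checked against
flat_signal <- function(intervals, len) {
  v <- numeric(len)
  for (k in seq_len(nrow(intervals)))
    v[(intervals$start[k] + 1):intervals$end[k]] <- intervals$value[k]
  v
}

toy_tss <- function(n = 4, chrom = "chr1", len = 1000, seed = 1,
                    strand = NULL) {
  set.seed(seed)
  pos <- sort(sample(100:(len - 100), n))
  if (is.null(strand)) strand <- sample(c("+", "-"), n, replace = TRUE)
  as_tss_table(data.frame(
    chrom = chrom, pos = pos, strand = strand,
    gene_id = sprintf("g%02d", seq_len(n)), category = "protein_coding",
    stringsAsFactors = FALSE))
}

toy_pfm <- function(id = "TOY", L = 4, dominant = 10, other = 0) {
  # consensus ACGT repeated
  counts <- matrix(other, L, 4)
  for (i in seq_len(L)) counts[i, ((i - 1) %% 4) + 1] <- dominant
  pfm(id, counts)
}

# sharp test matrix matching the generator's design (dominant 200 vs 1)
sharp_pfm <- function(id = "SHARP", L = 10, seed = 1) {
  set.seed(seed)
  counts <- matrix(1, L, 4)
  for (i in seq_len(L)) counts[i, sample(4, 1)] <- 200
  pfm(id, counts)
}

# a small simulated world with well-separated genes (spacing ~ 8 kb) and a
# balanced label split, the configuration used by classifier-level tests;
# effect sizes stay at the generator defaults
small_world_config <- function(seed, n_genes = 200, spacing = 8000,
                               frac_cell_cycle = 0.5, ...) {
  sim_config(seed = seed, n_chroms = 2,
             chrom_length = n_genes / 2 * spacing + 20000,
             n_genes = c(protein_coding = n_genes),
             frac_cell_cycle = frac_cell_cycle, ...)
}

# feature tables (tf / motif / both) for one simulated bundle
bundle_tables <- function(bundle, h = 2000, upstream = 1000) {
  reg <- tip_feature_sets(bundle$tracks, bundle$tss, h = h)
  proms <- promoter_sequences(bundle$genome, bundle$tss, upstream = upstream)
  names(proms) <- bundle$tss$gene_id
  B <- motif_score_matrix(proms, bundle$pfms)
  labels <- setNames(as.integer(bundle$tss$label == "cell_cycle"),
                     bundle$tss$gene_id)
  list(tf = build_feature_table(reg, NULL, labels, "tf"),
       motif = build_feature_table(NULL, B, labels, "motif"),
       both = build_feature_table(reg, B, labels, "both"),
       reg = reg, B = B, labels = labels)
}

# independent one-sided hypergeometric tail for a 2x2 table
# (a = overlap, with row total r1 = a + b, column total c1 = a + c, n total):
# P(X >= a) computed as an explicit sum of choose() products
hyper_tail <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  ks <- a:min(r1, c1)
  sum(exp(lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)))
}
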