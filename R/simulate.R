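#' Configuration of the synthetic-data generator
#'
#' Builds the parameter set for [simulate_cycle_data()]. Defaults describe a
#' small but complete world: a 2 x 2 Mb toy genome carrying 1000 genes of
#' which ~3% are cell cycle regulated (the genome-wide prevalence the method
#' was built to detect), 20 ChIP-seq signal tracks of which 8 TFs genuinely
#' prefer cell cycle promoters with a 4-fold binding odds multiplier, Gaussian
#' binding peaks (sd 150 bp, height 10 over a lognormal background) centred
#' near the TSS (offset sd 800 bp: binding sites spread well beyond a fixed
#' 2 kb window, which is what makes profile weighting worthwhile), motif
#' instances planted in 40% of positive
#' and 10% of negative promoters for the informative motifs, and an expression
#' level confounder: cell cycle genes are expressed ~1.5 sd higher and
#' expression couples into binding odds.
#'
#' @param seed master seed; every downstream draw derives from it.
#' @param n_chroms,chrom_length genome geometry.
#' @param n_genes named vector of gene counts per category.
#' @param frac_cell_cycle fraction of genes planted as cell cycle regulated.
#' @param n_tfs,n_informative_tfs number of ChIP tracks and how many have a
#'   real class effect.
#' @param tf_effect binding odds multiplier for a cell cycle promoter.
#' @param tf_phase_preference optional named list mapping a TF id (e.g.
#'   `"TF01"`) to a `c(lo, hi)` peak-time range it prefers (boosted odds).
#' @param phase_preference_boost odds multiplier inside the preferred range.
#' @param base_bind_prob binding probability of an uninformative promoter.
#' @param peak_height,peak_sd Gaussian peak shape (height over background,
#'   sd bp).
#' @param peak_offset_sd sd (bp) of the peak centre offset from the TSS.
#' @param background_meanlog,background_sdlog,background_bin lognormal
#'   background: one draw per `background_bin` bp, linearly interpolated.
#' @param n_motifs,n_informative_motifs motif catalogue size and planted
#'   subset.
#' @param motif_length length of generated motifs (bp).
#' @param motif_plant_rates `c(pos, neg)` planting probabilities for the
#'   informative motifs; uninformative motifs are planted at the `neg` rate in
#'   both classes.
#' @param expression_confounder coupling of expression into binding log-odds.
#' @param label_expression_shift expression shift (sd units) of cell cycle
#'   genes.
#' @param knockdown_overlap_rate probability that a true cell cycle gene shows
#'   a division defect in a simulated knockdown screen (background genes hit
#'   at 1/6 of this rate).
#' @param ppi_edges_per_gene,ppi_assortativity random interaction network
#'   density and the odds multiplier for cell cycle / cell cycle edges.
#' @param upstream promoter length used when planting motifs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       chrom_length = 2e6,
                       n_genes = c(protein_coding = 800, lincRNA = 120,
                                   pseudogene = 80),
                       frac_cell_cycle = 0.03,
                       n_tfs = 20,
                       n_informative_tfs = 8,
                       tf_effect = 4,
                       tf_phase_preference = NULL,
                       phase_preference_boost = 4,
                       base_bind_prob = 0.15,
                       peak_height = 10,
                       peak_sd = 150,
                       peak_offset_sd = 800,
                       background_meanlog = 0,
                       background_sdlog = 0.5,
                       background_bin = 25,
                       n_motifs = 15,
                       n_informative_motifs = 5,
                       motif_length = 10,
                       motif_plant_rates = c(pos = 0.4, neg = 0.1),
                       expression_confounder = 0.8,
                       label_expression_shift = 1.5,
                       knockdown_overlap_rate = 0.3,
                       ppi_edges_per_gene = 3,
                       ppi_assortativity = 3,
                       upstream = 1000) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$motif_plant_rates)))
    names(cfg$motif_plant_rates) <- c("pos", "neg")
  rates <- c(frac_cell_cycle, motif_plant_rates, base_bind_prob,
             knockdown_overlap_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_informative_tfs > n_tfs || n_informative_motifs > n_motifs)
    stop("informative subset larger than the catalogue")
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed derived from the master seed (kept below 2^31)
.sub_seed <- function(seed, k) (as.integer(seed) * 7907L + k * 131L) %% 2000000011L

#' Generate one complete synthetic input bundle
#'
#' Produces every input the pipeline consumes, fully reproducible from the
#' config seed: a random genome, a TSS catalogue with planted cell cycle
#' labels (peak times uniform on `[0, 100)`), an expression vector confounded
#' with the label, one signal track per TF with Gaussian binding peaks planted
#' preferentially at cell cycle promoters, TRANSFAC-style motif matrices with
#' instances planted at class-dependent rates, a protein-protein interaction
#' network with cell cycle assortativity, two knockdown hit sets, and a truth
#' record of every planted assignment.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle`: `genome` (DNAStringSet),
#'   `chrom_lengths`, `tss` (TSS data.frame with labels, peak times,
#'   expression), `tracks` (named list of [signal_track()]), `pfms`,
#'   `ppi` (edge data.frame), `knockdown` (list of two id vectors),
#'   `truth` (list: `informative_tfs`, `informative_motifs`, `bound`
#'   gene x TF logical matrix), `config`.
#' @export
simulate_cycle_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$chrom_length < 2 * 5000)
    warning("chromosomes shorter than a default TIP window")

  # --- genome ---------------------------------------------------------------
  set.seed(.sub_seed(cfg$seed, 1L))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    intToUtf8(sample(utf8ToInt("ACGT"), cfg$chrom_length, replace = TRUE)),
    ""))
  names(genome) <- chroms
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  # --- TSS catalogue --------------------------------------------------------
  set.seed(.sub_seed(cfg$seed, 2L))
  n_total <- sum(cfg$n_genes)
  per_chrom <- diff(round(seq(0, n_total, length.out = cfg$n_chroms + 1)))
  margin <- cfg$upstream + 100
  pos <- list()
  for (i in seq_len(cfg$n_chroms)) {
    ng <- per_chrom[i]
    usable <- cfg$chrom_length - 2 * margin
    spacing <- floor(usable / ng)
    if (spacing < 2 * cfg$upstream + 200)
      stop("infeasible geometry: genes too dense for promoter windows")
    base <- margin + spacing * (seq_len(ng) - 1)
    jit <- floor(runif(ng, 0, spacing - 2 * cfg$upstream - 100))
    pos[[i]] <- data.frame(chrom = chroms[i], pos = base + jit)
  }
  tss <- do.call(rbind, pos)
  tss$strand <- sample(c("+", "-"), n_total, replace = TRUE)
  tss$gene_id <- sprintf("g%04d", seq_len(n_total))
  tss$category <- rep(names(cfg$n_genes), cfg$n_genes)[sample(n_total)]
  n_cc <- round(cfg$frac_cell_cycle * n_total)
  cc_idx <- sample(n_total, n_cc)
  tss$label <- "non_cell_cycle"
  tss$label[cc_idx] <- "cell_cycle"
  tss$peak_time <- NA_real_
  tss$peak_time[cc_idx] <- runif(n_cc, 0, 100)
  tss$expression <- rnorm(n_total) +
    cfg$label_expression_shift * (tss$label == "cell_cycle")
  tss <- as_tss_table(tss, chrom_lengths)

  # --- TF signal tracks -----------------------------------------------------
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  informative_tfs <- tf_ids[seq_len(cfg$n_informative_tfs)]
  tracks <- list()
  bound <- matrix(FALSE, n_total, cfg$n_tfs,
                  dimnames = list(tss$gene_id, tf_ids))
  for (t in seq_len(cfg$n_tfs)) {
    eff <- if (tf_ids[t] %in% informative_tfs) cfg$tf_effect else 1
    pref <- cfg$tf_phase_preference[[tf_ids[t]]]
    res <- plant_signal_track(
      tss, chrom_lengths, tf_effect = eff,
      base_bind_prob = cfg$base_bind_prob,
      expression_confounder = cfg$expression_confounder,
      peak_height = cfg$peak_height, peak_sd = cfg$peak_sd,
      peak_offset_sd = cfg$peak_offset_sd,
      background_meanlog = cfg$background_meanlog,
      background_sdlog = cfg$background_sdlog,
      background_bin = cfg$background_bin,
      phase_preference = pref,
      phase_preference_boost = cfg$phase_preference_boost,
      seed = .sub_seed(cfg$seed, 100L + t))
    tracks[[tf_ids[t]]] <- res$track
    bound[, t] <- res$bound
  }

  # --- motifs ---------------------------------------------------------------
  set.seed(.sub_seed(cfg$seed, 3L))
  motif_ids <- sprintf("M%02d", seq_len(cfg$n_motifs))
  informative_motifs <- motif_ids[seq_len(cfg$n_informative_motifs)]
  pfms <- lapply(seq_len(cfg$n_motifs), function(j) {
    # sharp matrices: one strongly dominant base per position, so sampled
    # instances carry <= 1 mismatch ~99% of the time and clear the default
    # MATCH cutoffs (one mismatch at L = 10 keeps mss ~ 0.9, css ~ 0.8)
    counts <- t(vapply(seq_len(cfg$motif_length), function(i) {
      v <- rep(1, 4)
      v[sample(4, 1)] <- 200
      v
    }, numeric(4)))
    pfm(motif_id = motif_ids[j], counts = counts)
  })
  names(pfms) <- motif_ids
  for (j in seq_len(cfg$n_motifs)) {
    rate_pos <- if (motif_ids[j] %in% informative_motifs)
      cfg$motif_plant_rates[["pos"]] else cfg$motif_plant_rates[["neg"]]
    genome <- plant_promoter_motifs(
      genome, tss, pfms[[j]],
      rate_pos = rate_pos, rate_neg = cfg$motif_plant_rates[["neg"]],
      upstream = cfg$upstream, seed = .sub_seed(cfg$seed, 200L + j))
  }

  # --- PPI network ----------------------------------------------------------
  set.seed(.sub_seed(cfg$seed, 4L))
  is_cc <- tss$label == "cell_cycle"
  n_edges <- cfg$ppi_edges_per_gene * n_total
  # draw endpoints; cc-cc edges are over-sampled by the assortativity odds
  w <- ifelse(is_cc, sqrt(cfg$ppi_assortativity), 1)
  a <- sample(tss$gene_id, n_edges, replace = TRUE, prob = w)
  b <- sample(tss$gene_id, n_edges, replace = TRUE, prob = w)
  keep <- a != b
  ppi <- unique(data.frame(a = pmin(a[keep], b[keep]),
                           b = pmax(a[keep], b[keep])))

  # --- knockdown hit sets ---------------------------------------------------
  set.seed(.sub_seed(cfg$seed, 5L))
  bg_rate <- cfg$knockdown_overlap_rate / 6
  knockdown <- lapply(1:2, function(k) {
    hit <- ifelse(is_cc, cfg$knockdown_overlap_rate, bg_rate)
    tss$gene_id[runif(n_total) < hit]
  })
  names(knockdown) <- c("screen1", "screen2")

  structure(list(genome = genome, chrom_lengths = chrom_lengths, tss = tss,
                 tracks = tracks, pfms = pfms, ppi = ppi,
                 knockdown = knockdown,
                 truth = list(informative_tfs = informative_tfs,
                              informative_motifs = informative_motifs,
                              bound = bound),
                 config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle:", length(x$genome), "chromosomes,", nrow(x$tss), "genes (",
      sum(x$tss$label == "cell_cycle"), "cell cycle ),",
      length(x$tracks), "TF tracks,", length(x$pfms), "motifs\n")
  invisible(x)
}

#' Plant a Gaussian-peak ChIP signal track
#'
#' One synthetic ChIP-seq track: a multiplicative lognormal background (one
#' draw per `background_bin` bp, linearly interpolated per base) plus, for
#' each bound gene, a Gaussian peak of the given height and sd centred at a
#' normal-offset distance from the TSS. A gene is bound with probability
#' `plogis(qlogis(base) + label * log(tf_effect) + confounder * expression
#' [+ log(boost) inside a preferred phase range])`.
#'
#' @param tss TSS data.frame with `label`, `peak_time`, `expression`.
#' @param chrom_lengths named chromosome-length vector.
#' @param tf_effect binding odds multiplier for cell cycle genes.
#' @param base_bind_prob baseline binding probability.
#' @param expression_confounder coupling of expression into binding log-odds.
#' @param peak_height,peak_sd,peak_offset_sd peak geometry (bp / signal
#'   units); `peak_height = 0` yields a pure background track.
#' @param background_meanlog,background_sdlog,background_bin background model.
#' @param phase_preference optional `c(lo, hi)` peak-time range with boosted
#'   odds.
#' @param phase_preference_boost odds multiplier in the preferred range.
#' @param seed integer seed.
#' @return list: `track` (a [signal_track()]), `bound` (logical per gene).
#' @export
plant_signal_track <- function(tss, chrom_lengths, tf_effect = 4,
                               base_bind_prob = 0.15,
                               expression_confounder = 0.8,
                               peak_height = 10, peak_sd = 150,
                               peak_offset_sd = 800,
                               background_meanlog = 0, background_sdlog = 0.5,
                               background_bin = 25,
                               phase_preference = NULL,
                               phase_preference_boost = 4,
                               seed = 1) {
  set.seed(seed)
  is_cc <- tss$label == "cell_cycle"
  logit <- qlogis(base_bind_prob) + log(tf_effect) * is_cc +
    expression_confounder * ifelse(is.na(tss$expression), 0, tss$expression)
  if (!is.null(phase_preference)) {
    inpref <- !is.na(tss$peak_time) &
      tss$peak_time >= phase_preference[1] & tss$peak_time < phase_preference[2]
    logit <- logit + log(phase_preference_boost) * inpref
  }
  bound <- runif(nrow(tss)) < plogis(logit)

  sig <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    nb <- ceiling(len / background_bin) + 1
    knots <- rlnorm(nb, background_meanlog, background_sdlog)
    v <- approx(x = (seq_len(nb) - 1) * background_bin, y = knots,
                xout = seq_len(len) - 1)$y
    idx <- which(bound & tss$chrom == ch)
    for (i in idx) {
      centre <- tss$pos[i] + round(rnorm(1, 0, peak_offset_sd))
      if (peak_height <= 0) next
      span <- ceiling(4 * peak_sd)
      lo <- max(centre - span, 0)
      hi <- min(centre + span, len - 1)
      if (hi < lo) next
      d <- (lo:hi) - centre
      v[(lo + 1):(hi + 1)] <- v[(lo + 1):(hi + 1)] +
        peak_height * exp(-d^2 / (2 * peak_sd^2))
    }
    sig[[ch]] <- S4Vectors::Rle(v)
  }
  list(track = .track_from_rle(sig, chrom_lengths), bound = bound)
}

#' Plant motif instances into promoters
#'
#' Inserts instances sampled from the matrix's base frequencies at a uniform
#' offset inside each promoter, with probability `rate_pos` for cell cycle
#' genes and `rate_neg` otherwise. Instances are written on the gene's strand
#' so a strand-aware scan recovers them.
#'
#' @param genome named DNAStringSet (modified copy is returned).
#' @param tss TSS data.frame.
#' @param pfm a [pfm()] matrix.
#' @param rate_pos,rate_neg planting probabilities per class.
#' @param upstream promoter length (bp).
#' @param seed integer seed.
#' @return the genome with instances written in.
#' @export
plant_promoter_motifs <- function(genome, tss, pfm, rate_pos, rate_neg,
                                  upstream = 1000, seed = 1) {
  set.seed(seed)
  L <- nrow(pfm$counts)
  f <- pfm$counts / rowSums(pfm$counts)
  rate <- ifelse(tss$label == "cell_cycle", rate_pos, rate_neg)
  plant <- which(runif(nrow(tss)) < rate)
  if (length(plant) == 0) return(genome)
  np <- length(plant)
  # one column of draws per matrix position, pasted row-wise into instances
  draws <- vapply(seq_len(L), function(k)
    sample(colnames(f), np, replace = TRUE, prob = f[k, ]),
    character(np))
  if (np == 1) draws <- matrix(draws, nrow = 1)
  insts <- do.call(paste0, as.data.frame(draws, stringsAsFactors = FALSE))

  lens <- setNames(Biostrings::width(genome), names(genome))
  len <- lens[tss$chrom[plant]]
  pos <- tss$pos[plant]
  fwd <- tss$strand[plant] == "+"
  lo <- ifelse(fwd, pmax(pos - upstream, 0), pos + 1)
  hi <- ifelse(fwd, pos - L, pmin(pos + upstream, len - 1) - L + 1)
  ok <- hi >= lo
  at <- lo + floor(runif(np, 0, hi - lo + 1)) # 0-based instance start
  val <- Biostrings::DNAStringSet(insts)
  val[!fwd] <- Biostrings::reverseComplement(val[!fwd])
  for (ch in unique(tss$chrom[plant])) {
    sel <- ok & tss$chrom[plant] == ch
    if (!any(sel)) next
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]],
      IRanges::IRanges(start = at[sel] + 1, width = L),
      val[sel])
  }
  genome
}

#' Write a simulated bundle to disk in standard formats
#'
#' Emits genome FASTA, extended TSS BED, per-TF bedGraph tracks, a TRANSFAC
#' matrix file, labels/expression TSV, PPI edge TSV, knockdown hit TSVs and
#' the truth TSV into a directory.
#'
#' @param bundle a [simulate_cycle_data()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  write_tss_bed(bundle$tss, file.path(dir, "tss.bed"))
  for (id in names(bundle$tracks))
    write_signal_track(bundle$tracks[[id]],
                       file.path(dir, "tracks", paste0(id, ".bedgraph")))
  write_transfac(bundle$pfms, file.path(dir, "motifs.transfac"))
  lab <- bundle$tss[, c("gene_id", "label", "peak_time", "expression")]
  write.table(lab, file.path(dir, "labels.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(bundle$ppi, file.path(dir, "ppi.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (k in names(bundle$knockdown))
    writeLines(bundle$knockdown[[k]],
               file.path(dir, paste0("knockdown_", k, ".tsv")))
  truth <- data.frame(
    kind = c(rep("informative_tf", length(bundle$truth$informative_tfs)),
             rep("informative_motif", length(bundle$truth$informative_motifs))),
    id = c(bundle$truth$informative_tfs, bundle$truth$informative_motifs))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
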