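#' Extract a promoter sequence
#'
#' The promoter is the `upstream` bp immediately 5' of the TSS, read on the
#' gene's strand: for a `+` TSS at 0-based position `pos` this is the forward
#' strand interval `[pos - upstream, pos)`; for a `-` TSS it is the reverse
#' complement of `(pos, pos + upstream]`. Sequences are truncated at
#' chromosome ends and returned uppercase.
#'
#' @param genome a named [Biostrings::DNAStringSet] (one entry per chromosome).
#' @param tss_record single-row TSS data.frame with `chrom`, `pos`, `strand`.
#' @param upstream promoter length in bp (default 1000).
#' @return character string of length `<= upstream`.
#' @export
promoter_sequence <- function(genome, tss_record, upstream = 1000) {
  chrom <- tss_record$chrom[1]
  pos <- tss_record$pos[1]
  strand <- tss_record$strand[1]
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- Biostrings::width(genome[chrom])
  if (pos < 0 || pos >= len) stop("TSS outside chromosome ", chrom)
  if (strand == "+") {
    s0 <- max(pos - upstream, 0) # 0-based
    if (pos == 0) return("")
    seq <- Biostrings::subseq(genome[[chrom]], s0 + 1, pos)
  } else {
    e0 <- min(pos + upstream, len - 1) # 0-based inclusive end
    if (e0 <= pos) return("")
    seq <- Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], pos + 2, e0 + 1))
  }
  toupper(as.character(seq))
}

#' Extract promoters for a whole TSS catalogue
#'
#' @inheritParams promoter_sequence
#' @param tss TSS data.frame.
#' @return named character vector (names = gene ids; duplicates allowed for
#'   alternative promoters).
#' @export
promoter_sequences <- function(genome, tss, upstream = 1000) {
  out <- vapply(seq_len(nrow(tss)), function(i)
    promoter_sequence(genome, tss[i, ], upstream), "")
  names(out) <- tss$gene_id
  out
}

# MATCH scoring tables for one pfm: information-weighted frequency scores
# S[i, b] = I(i) * f(i, b), with column 5 (N / unknown base) scoring the
# per-position minimum, plus the attainable min / max window scores.
.match_tables <- function(pfm, pseudocount = 1) {
  counts <- pfm$counts
  f <- (counts + pseudocount) / rowSums(counts + pseudocount)
  info <- rowSums(f * log(4 * f))
  S <- f * info
  S <- cbind(S, apply(S, 1, min)) # column 5: N
  core <- pfm$core_start:(pfm$core_start + pfm$core_len - 1)
  list(S = S,
       smin = sum(apply(S[, 1:4, drop = FALSE], 1, min)),
       smax = sum(apply(S[, 1:4, drop = FALSE], 1, max)),
       core = core,
       cmin = sum(apply(S[core, 1:4, drop = FALSE], 1, min)),
       cmax = sum(apply(S[core, 1:4, drop = FALSE], 1, max)))
}

.dna_to_index <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L # N and other ambiguity codes
  v
}

.revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# score every window of an index vector against precomputed tables
.scan_strand <- function(idx, tab, L) {
  n_off <- length(idx) - L + 1
  if (n_off < 1) return(NULL)
  sc <- numeric(n_off)
  cc <- numeric(n_off)
  for (i in seq_len(L)) {
    v <- tab$S[i, idx[i:(i + n_off - 1)]]
    sc <- sc + v
    if (i %in% tab$core) cc <- cc + v
  }
  mss <- if (tab$smax > tab$smin) (sc - tab$smin) / (tab$smax - tab$smin)
         else rep(1, n_off)
  css <- if (tab$cmax > tab$cmin) (cc - tab$cmin) / (tab$cmax - tab$cmin)
         else rep(1, n_off)
  list(mss = mss, css = css)
}

#' Scan a sequence with one matrix (MATCH similarity scores)
#'
#' Implements MATCH-style scoring: base frequencies with pseudocount, a
#' per-position information weight `I(i) = sum_b f(i,b) ln(4 f(i,b))`, window
#' scores `sum_i I(i) f(i, b_i)`, and min-max normalisation to the matrix
#' similarity score (mss) in `[0, 1]`; the core similarity score (css) applies
#' the same formula to the matrix's core window (5 most informative
#' consecutive positions by default). Both strands are scanned; `N` bases
#' score the per-position minimum. Retained hits satisfy both cutoffs.
#'
#' @param seq promoter sequence (character).
#' @param pfm a [pfm()] object.
#' @param cutoff_mss,cutoff_css score cutoffs; default to the matrix's own.
#' @param pseudocount added to every count cell before frequencies.
#' @return data.frame with columns `offset` (0-based, forward-strand
#'   coordinates of the window start), `strand`, `mss`, `css`, sorted by
#'   offset. Sequences shorter than the matrix give zero rows.
#' @export
match_scan <- function(seq, pfm, cutoff_mss = NULL, cutoff_css = NULL,
                       pseudocount = 1) {
  if (is.null(cutoff_mss)) cutoff_mss <- pfm$cutoff_mss %||% 0.85
  if (is.null(cutoff_css)) cutoff_css <- pfm$cutoff_css %||% 0.75
  L <- nrow(pfm$counts)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      mss = numeric(0), css = numeric(0))
  if (nchar(seq) < L) return(empty)
  tab <- .match_tables(pfm, pseudocount)
  n <- nchar(seq)
  hits <- empty
  fwd <- .scan_strand(.dna_to_index(seq), tab, L)
  if (!is.null(fwd)) {
    keep <- fwd$mss >= cutoff_mss & fwd$css >= cutoff_css
    if (any(keep))
      hits <- rbind(hits, data.frame(offset = which(keep) - 1L, strand = "+",
                                     mss = fwd$mss[keep], css = fwd$css[keep]))
  }
  rev <- .scan_strand(.dna_to_index(.revcomp_chr(seq)), tab, L)
  if (!is.null(rev)) {
    keep <- rev$mss >= cutoff_mss & rev$css >= cutoff_css
    if (any(keep)) {
      # map reverse-complement offsets back to forward coordinates
      off <- n - L - (which(keep) - 1L)
      hits <- rbind(hits, data.frame(offset = off, strand = "-",
                                     mss = rev$mss[keep], css = rev$css[keep]))
    }
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Aggregate motif hits into a promoter score
#'
#' @param mss vector of retained hit scores for one gene x motif pair.
#' @param method `"sum"` (default: the score grows with the number of sites)
#'   or `"max"`.
#' @return numeric scalar; 0 when there are no hits.
#' @export
aggregate_scores <- function(mss, method = c("sum", "max")) {
  method <- match.arg(method)
  if (length(mss) == 0) return(0)
  if (method == "sum") sum(mss) else max(mss)
}

#' Gene x motif binding score matrix
#'
#' Scans every promoter with every matrix and aggregates retained hit scores
#' into the binding score matrix `B` (genes x motifs): `B[i, j]` is the
#' aggregated mss of motif `j` in promoter `i`, exactly 0 when the motif has
#' no retained hit there.
#'
#' @param promoters named character vector of promoter sequences.
#' @param pfms list of [pfm()] objects.
#' @param method aggregation method, see [aggregate_scores()].
#' @param cutoff_mss,cutoff_css optional global cutoff overrides.
#' @return numeric matrix, rownames = promoter names, colnames = motif ids.
#' @export
motif_score_matrix <- function(promoters, pfms, method = c("sum", "max"),
                               cutoff_mss = NULL, cutoff_css = NULL) {
  method <- match.arg(method)
  B <- matrix(0, nrow = length(promoters), ncol = length(pfms),
              dimnames = list(names(promoters),
                              vapply(pfms, function(p) p$motif_id, "")))
  # decode every promoter once; the reverse-complement of the index coding
  # 1..4 = A,C,G,T (5 = N) is 5 - idx on the reversed vector
  idx_fwd <- lapply(promoters, .dna_to_index)
  idx_rev <- lapply(idx_fwd, function(v) {
    r <- 5L - rev(v)
    r[r == 0L] <- 5L
    r
  })
  for (j in seq_along(pfms)) {
    p <- pfms[[j]]
    cm <- cutoff_mss %||% p$cutoff_mss %||% 0.85
    cc <- cutoff_css %||% p$cutoff_css %||% 0.75
    tab <- .match_tables(p)
    L <- nrow(p$counts)
    for (i in seq_along(promoters)) {
      mss <- c(.retained_mss(idx_fwd[[i]], tab, L, cm, cc),
               .retained_mss(idx_rev[[i]], tab, L, cm, cc))
      B[i, j] <- aggregate_scores(mss, method)
    }
  }
  B
}

# retained hit scores of one strand, no bookkeeping (fast path used by
# motif_score_matrix; match_scan keeps offsets and strands)
.retained_mss <- function(idx, tab, L, cutoff_mss, cutoff_css) {
  sc <- .scan_strand(idx, tab, L)
  if (is.null(sc)) return(numeric(0))
  sc$mss[sc$mss >= cutoff_mss & sc$css >= cutoff_css]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
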