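#' Per-base genomic signal track
#'
#' A `signal_track` holds non-negative per-base signal (e.g. ChIP-seq coverage
#' or fold enrichment) over a set of named chromosomes, stored as one
#' [S4Vectors::Rle] per chromosome. Uncovered bases read as 0. All coordinates
#' in this package are 0-based half-open (BED convention); wiggle input, which
#' is 1-based, is converted on read.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open, `value >= 0`). Intervals must not overlap within a
#'   chromosome.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @return An object of class `signal_track` with elements `signal` (named list
#'   of `Rle`) and `chrom_lengths`.
#' @examples
#' tr <- signal_track(data.frame(chrom = "chr1", start = 0, end = 10,
#'                               value = 2.5), c(chr1 = 100))
#' track_values(tr, "chr1", 5, 6) # 2.5
#' @export
signal_track <- function(intervals, chrom_lengths) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  bad <- setdiff(unique(intervals$chrom), names(chrom_lengths))
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (any(intervals$value < 0)) stop("signal values must be >= 0")
  if (any(intervals$start < 0) || any(intervals$start >= intervals$end))
    stop("need 0 <= start < end")
  sig <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) return(S4Vectors::Rle(0, len))
    if (any(iv$end > len))
      stop("interval beyond end of ", ch)
    o <- order(iv$start)
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop("overlapping intervals on ", ch)
    # stitch runs with zero gaps, fully vectorised: for each interval a
    # (gap-before, interval) run pair, plus the trailing gap
    starts <- iv$start
    ends <- iv$end
    gap_before <- starts - c(0, ends[-length(ends)])
    run_len <- c(as.vector(rbind(gap_before, ends - starts)),
                 len - ends[length(ends)])
    run_val <- c(as.vector(rbind(0, iv$value)), 0)
    keep <- run_len > 0
    S4Vectors::Rle(run_val[keep], run_len[keep])
  })
  names(sig) <- names(chrom_lengths)
  structure(list(signal = sig, chrom_lengths = chrom_lengths),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  tot <- sum(vapply(x$signal, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                              S4Vectors::runLength(r)), 0))
  cat("signal_track:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp, total signal",
      format(tot, digits = 6), "\n")
  invisible(x)
}

# internal: build a track directly from per-chromosome Rle list
.track_from_rle <- function(rle_list, chrom_lengths) {
  structure(list(signal = rle_list, chrom_lengths = chrom_lengths),
            class = "signal_track")
}

# internal: extract many strand-oriented 2h+1 windows at once. Decodes each
# needed chromosome to a dense numeric vector once, so per-window cost is a
# plain slice; per-base Rle queries would pay S4 dispatch per gene.
.signal_windows <- function(track, tss, h) {
  n <- 2 * h + 1
  out <- matrix(0, nrow = nrow(tss), ncol = n)
  for (ch in unique(tss$chrom)) {
    dense <- as.numeric(track$signal[[ch]])
    len <- track$chrom_lengths[[ch]]
    for (i in which(tss$chrom == ch)) {
      s <- tss$pos[i] - h
      e <- tss$pos[i] + h + 1
      lo <- max(s, 0)
      hi <- min(e, len)
      if (hi > lo)
        out[i, (lo - s + 1):(hi - s)] <- dense[(lo + 1):hi]
      if (tss$strand[i] == "-") out[i, ] <- rev(out[i, ])
    }
  }
  out
}

#' Query per-base values of a signal track
#'
#' Returns the per-base signal over `[start, end)` (0-based half-open).
#' Portions outside the chromosome are returned as 0 (zero padding), so the
#' result always has length `end - start`.
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval; may extend beyond the
#'   chromosome.
#' @return numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$signal))
    stop("unknown chromosome: ", chrom)
  len <- track$chrom_lengths[[chrom]]
  n <- end - start
  out <- numeric(n)
  s <- max(start, 0)
  e <- min(end, len)
  if (e > s) {
    v <- as.numeric(S4Vectors::window(track$signal[[chrom]], s + 1, e))
    out[(s - start + 1):(e - start)] <- v
  }
  out
}

#' Strand-oriented signal window around a TSS
#'
#' Extracts the signal in the `2h + 1` bp window centred at a TSS, oriented
#' 5' to 3' of the gene: for a '-' strand TSS the window is reversed so that
#' index `h + 1` is always the TSS and larger indices are downstream.
#' Out-of-chromosome positions are zero padded.
#'
#' @param track a [signal_track()].
#' @param chrom,pos,strand TSS coordinates (0-based) and strand ("+" or "-").
#' @param h half-width in bp.
#' @return numeric vector of length `2 * h + 1`.
#' @export
signal_window <- function(track, chrom, pos, strand, h) {
  v <- track_values(track, chrom, pos - h, pos + h + 1)
  if (strand == "-") v <- rev(v)
  v
}

#' Read a signal track from bedGraph or wiggle
#'
#' bedGraph (0-based half-open, 4 columns) is parsed directly with per-line
#' validation; fixedStep/variableStep wiggle (1-based) is read through
#' \pkg{rtracklayer} and converted to the package's 0-based convention.
#' Overlapping input intervals and unknown chromosomes are rejected.
#'
#' @param path file path. Format chosen by extension (`.bedgraph`/`.bg` vs
#'   `.wig`) unless `format` is given.
#' @param genome named vector of chromosome lengths.
#' @param format `"auto"`, `"bedGraph"` or `"wig"`.
#' @return a [signal_track()].
#' @export
read_signal_track <- function(path, genome, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE))
      "wig" else "bedGraph"
  }
  if (format == "bedGraph") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    iv <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), value = numeric(0))
    if (any(keep)) {
      ln <- which(keep)
      fields <- strsplit(trimws(lines[keep]), "[ \t]+")
      nf <- lengths(fields)
      if (any(nf != 4))
        stop("malformed bedGraph line ", ln[which(nf != 4)[1]], " in ", path)
      m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
      start <- suppressWarnings(as.numeric(m[, 2]))
      end <- suppressWarnings(as.numeric(m[, 3]))
      value <- suppressWarnings(as.numeric(m[, 4]))
      bad <- which(is.na(start) | is.na(end) | is.na(value))
      if (length(bad))
        stop("malformed bedGraph line ", ln[bad[1]], " in ", path)
      iv <- data.frame(chrom = m[, 1], start = start, end = end, value = value)
    }
    signal_track(iv, genome)
  } else {
    gr <- rtracklayer::import(path, format = "wig")
    iv <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1, # 1-based -> 0-based
                     end = GenomicRanges::end(gr),
                     value = gr$score)
    signal_track(iv, genome)
  }
}

#' Write a signal track as bedGraph
#'
#' Emits one line per constant-signal run, skipping zero runs, so that
#' [read_signal_track()] of the output reproduces every per-base value
#' bit-exactly.
#'
#' @param track a [signal_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$signal)) {
    r <- track$signal[[ch]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - as.numeric(rl)
    keep <- rv != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                       format(starts[keep], scientific = FALSE, trim = TRUE),
                       format(ends[keep], scientific = FALSE, trim = TRUE),
                       format(rv[keep], digits = 17, trim = TRUE)), con)
  }
  invisible(path)
}
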