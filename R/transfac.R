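#' Read TRANSFAC-format position frequency matrices
#'
#' Parses the TRANSFAC flat-file dialect: records separated by `//`, motif id
#' on the `AC` (fallback `ID`) row, a `P0` (or `PO`) header row naming the four
#' bases, and numbered rows `01..0L` carrying the A/C/G/T counts. Any trailing
#' consensus symbol is ignored. Optional MATCH-style cutoffs are merged from a
#' sidecar TSV (`motif_id`, `cutoff_mss`, `cutoff_css`); motifs without sidecar
#' entries get the package defaults (mss 0.85, css 0.75).
#'
#' @param path TRANSFAC flat file.
#' @param cutoffs optional path to a cutoff TSV, or a data.frame.
#' @param default_mss,default_css fallback score cutoffs in `[0, 1]`.
#' @return list of `pfm` objects: each has `motif_id`, `counts` (L x 4 matrix,
#'   columns A,C,G,T), `core_start`, `core_len` (1-based; the 5 consecutive
#'   most informative positions when not annotated), `cutoff_mss`, `cutoff_css`.
#' @export
read_transfac <- function(path, cutoffs = NULL,
                          default_mss = 0.85, default_css = 0.75) {
  lines <- readLines(path)
  recs <- list()
  cur_id <- NULL
  cur_rows <- list()
  flush <- function() {
    if (length(cur_rows) == 0) return(NULL)
    counts <- do.call(rbind, cur_rows)
    colnames(counts) <- c("A", "C", "G", "T")
    if (any(rowSums(counts) <= 0))
      stop("matrix position with zero total count in ", path)
    pfm(motif_id = if (is.null(cur_id)) sprintf("M%03d", length(recs) + 1)
                   else cur_id,
        counts = counts)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(XX|CC|NA|DE|BF|P0|PO)", ln)) next
    if (grepl("^//", ln)) {
      p <- flush()
      if (!is.null(p)) recs[[length(recs) + 1]] <- p
      cur_id <- NULL
      cur_rows <- list()
      next
    }
    if (grepl("^AC\\s", ln)) {
      cur_id <- trimws(sub("^AC\\s+", "", ln))
      next
    }
    if (grepl("^ID\\s", ln)) {
      if (is.null(cur_id)) cur_id <- trimws(sub("^ID\\s+", "", ln))
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      toks <- strsplit(ln, "\\s+")[[1]][-1]
      num <- suppressWarnings(as.numeric(toks))
      num <- num[!is.na(num)]
      if (length(num) < 4)
        stop("matrix row with fewer than 4 numbers at line ", i, " in ", path)
      cur_rows[[length(cur_rows) + 1]] <- num[1:4]
    }
  }
  p <- flush()
  if (!is.null(p)) recs[[length(recs) + 1]] <- p

  if (!is.null(cutoffs)) {
    ct <- if (is.data.frame(cutoffs)) cutoffs
          else read.table(cutoffs, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    for (k in seq_along(recs)) {
      j <- match(recs[[k]]$motif_id, ct$motif_id)
      if (!is.na(j)) {
        recs[[k]]$cutoff_mss <- ct$cutoff_mss[j]
        recs[[k]]$cutoff_css <- ct$cutoff_css[j]
      }
    }
  }
  for (k in seq_along(recs)) {
    if (is.null(recs[[k]]$cutoff_mss)) recs[[k]]$cutoff_mss <- default_mss
    if (is.null(recs[[k]]$cutoff_css)) recs[[k]]$cutoff_css <- default_css
  }
  names(recs) <- vapply(recs, function(p) p$motif_id, "")
  recs
}

#' Construct a position frequency matrix object
#'
#' @param motif_id motif identifier.
#' @param counts L x 4 non-negative matrix, columns in A,C,G,T order.
#' @param core_start,core_len 1-based core window (defaults to the 5
#'   consecutive positions maximising total information content).
#' @param cutoff_mss,cutoff_css MATCH score cutoffs in `[0, 1]`.
#' @return object of class `pfm`.
#' @export
pfm <- function(motif_id, counts, core_start = NULL, core_len = 5L,
                cutoff_mss = NULL, cutoff_css = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) stop("counts must have 4 columns (A,C,G,T)")
  colnames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) stop("negative counts")
  if (any(rowSums(counts) <= 0)) stop("position with zero total count")
  L <- nrow(counts)
  core_len <- min(core_len, L)
  if (is.null(core_start)) {
    info <- .pfm_information(counts)
    wins <- vapply(seq_len(L - core_len + 1),
                   function(s) sum(info[s:(s + core_len - 1)]), 0)
    core_start <- which.max(wins) # first maximal window: deterministic
  }
  if (core_start < 1 || core_start + core_len - 1 > L)
    stop("core window outside matrix")
  structure(list(motif_id = motif_id, counts = counts,
                 core_start = as.integer(core_start),
                 core_len = as.integer(core_len),
                 cutoff_mss = cutoff_mss, cutoff_css = cutoff_css),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm", x$motif_id, ":", nrow(x$counts), "positions, consensus",
      pfm_consensus(x), "\n")
  invisible(x)
}

# MATCH information vector I(i) = sum_b f(i,b) ln(4 f(i,b)), pseudocount 1
.pfm_information <- function(counts, pseudocount = 1) {
  f <- (counts + pseudocount) / rowSums(counts + pseudocount)
  rowSums(f * log(4 * f))
}

#' Consensus sequence of a position frequency matrix
#'
#' @param x a [pfm()] object.
#' @return character string, the highest-count base per position (ties broken
#'   towards A < C < G < T).
#' @export
pfm_consensus <- function(x) {
  paste(colnames(x$counts)[apply(x$counts, 1, which.max)], collapse = "")
}

#' Write matrices in TRANSFAC flat-file format
#'
#' @param pfms list of [pfm()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(c(sprintf("AC %s", p$motif_id), "XX",
                 "P0      A      C      G      T"), con)
    for (i in seq_len(nrow(p$counts))) {
      writeLines(sprintf("%02d %6s %6s %6s %6s", i,
                         format(p$counts[i, 1], trim = TRUE),
                         format(p$counts[i, 2], trim = TRUE),
                         format(p$counts[i, 3], trim = TRUE),
                         format(p$counts[i, 4], trim = TRUE)), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}
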