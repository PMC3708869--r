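#' @keywords internal
.tss_categories <- c("protein_coding", "lincRNA", "miRNA", "snoRNA", "snRNA",
                     "pseudogene", "artificial")
.tss_labels <- c("cell_cycle", "non_cell_cycle", "unknown")

#' Validate and normalise a TSS table
#'
#' TSS catalogues are plain data.frames with columns `chrom`, `pos` (0-based
#' TSS coordinate), `strand`, `gene_id`, `category` and the optional columns
#' `label` (`cell_cycle` / `non_cell_cycle` / `unknown`), `peak_time`
#' (Cyclebase-style peak expression time in `[0, 100)`, cell cycle genes only)
#' and `expression`. Records are sorted by `(chrom, pos)`; duplicated gene ids
#' are allowed (alternative promoters).
#'
#' @param tss data.frame as described above.
#' @param genome optional named vector of chromosome lengths for bounds checks.
#' @return the validated, sorted data.frame.
#' @export
as_tss_table <- function(tss, genome = NULL) {
  need <- c("chrom", "pos", "strand", "gene_id", "category")
  miss <- setdiff(need, names(tss))
  if (length(miss)) stop("missing TSS columns: ", paste(miss, collapse = ", "))
  if (!all(tss$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(tss$category %in% .tss_categories))
    stop("unknown category: ",
         paste(setdiff(unique(tss$category), .tss_categories), collapse = ", "))
  if (is.null(tss$label)) tss$label <- "unknown"
  if (!all(tss$label %in% .tss_labels)) stop("unknown label value")
  if (is.null(tss$peak_time)) tss$peak_time <- NA_real_
  if (is.null(tss$expression)) tss$expression <- NA_real_
  pt <- tss$peak_time[!is.na(tss$peak_time)]
  if (any(pt < 0 | pt >= 100)) stop("peak_time must lie in [0, 100)")
  if (any(!is.na(tss$peak_time) & tss$label != "cell_cycle"))
    stop("peak_time present for a non-cell_cycle record")
  if (!is.null(genome)) {
    bad <- setdiff(unique(tss$chrom), names(genome))
    if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    if (any(tss$pos < 0 | tss$pos >= genome[tss$chrom]))
      stop("TSS position outside chromosome")
  }
  tss <- tss[order(tss$chrom, tss$pos), , drop = FALSE]
  rownames(tss) <- NULL
  tss
}

#' Read a TSS catalogue from extended BED
#'
#' Consumes a BED6+3 dialect: the six standard BED columns (0-based half-open;
#' the BED name is the gene id) plus optional columns 7-9 holding `category`,
#' `label` and `peak_time` (`.` for absent values). The TSS of a `+` feature is
#' its interval start; the TSS of a `-` feature is `end - 1` (standard BED
#' semantics).
#'
#' @param path BED file path.
#' @param genome optional named chromosome-length vector for bounds checks.
#' @return a TSS data.frame (see [as_tss_table()]), sorted by `(chrom, pos)`.
#' @export
read_tss_bed <- function(path, genome = NULL) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", fill = TRUE,
                    comment.char = "#", quote = "")
  if (ncol(raw) < 6)
    stop("BED6+ required: strand column missing in ", path)
  strand <- raw[[6]]
  if (!all(strand %in% c("+", "-")))
    stop("missing or invalid strand in ", path)
  start <- as.numeric(raw[[2]])
  end <- as.numeric(raw[[3]])
  pos <- ifelse(strand == "+", start, end - 1)
  grab <- function(i) {
    if (ncol(raw) >= i) {
      v <- raw[[i]]
      v[v == "." | v == ""] <- NA
      v
    } else rep(NA_character_, nrow(raw))
  }
  category <- grab(7)
  category[is.na(category)] <- "protein_coding"
  label <- grab(8)
  label[is.na(label)] <- "unknown"
  peak_time <- suppressWarnings(as.numeric(grab(9)))
  tss <- data.frame(chrom = raw[[1]], pos = pos, strand = strand,
                    gene_id = raw[[4]], category = category, label = label,
                    peak_time = peak_time, stringsAsFactors = FALSE)
  as_tss_table(tss, genome)
}

#' Write a TSS catalogue as extended BED6+3
#'
#' Inverse of [read_tss_bed()]: each TSS becomes a 1 bp BED feature anchored so
#' that reading it back recovers the same position and strand.
#'
#' @param tss TSS data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  tss <- as_tss_table(tss)
  start <- ifelse(tss$strand == "+", tss$pos, tss$pos)
  # 1 bp features: [pos, pos+1); for '-' records end-1 == pos as required
  pt <- ifelse(is.na(tss$peak_time), ".",
               format(tss$peak_time, digits = 10, trim = TRUE))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%s\t%s",
                   tss$chrom, as.integer(start), as.integer(start + 1),
                   tss$gene_id, tss$strand, tss$category, tss$label, pt)
  writeLines(lines, path)
  invisible(path)
}
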