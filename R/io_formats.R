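# Readers/writers and coordinate conventions.
#
# Conventions used throughout the package:
#   * internal coordinates are 0-based, half-open everywhere;
#   * allc files are 1-based (the allc standard), BED/BEDPE are 0-based
#     half-open (the BED standard);
#   * every conversion between bp and bin indices goes through pos_to_bin();
#     no other code does coordinate math on raw bp.

#' Convert a 1-based genomic position to a 0-based bin index
#'
#' Bins are 0-based and half-open: bin `b` covers 1-based positions
#' `[b*resolution + 1, (b+1)*resolution]`.
#'
#' @param pos integer vector of 1-based bp positions (`pos >= 1`).
#' @param resolution bin size in bp.
#' @return integer vector of 0-based bin indices.
#' @export
pos_to_bin <- function(pos, resolution) {
  stop_if_not(all(pos >= 1), "positions must be 1-based (pos >= 1)")
  as.integer(floor((as.double(pos) - 1) / resolution))
}

#' Validate an allc methylation table
#'
#' An allc table has columns chrom, pos (1-based), strand, context (3-mer
#' class), mc (methylated count) and cov (total count), plus a trailing
#' methylated flag column when written to disk.
#'
#' @param x a data.frame/data.table with at least the six allc columns.
#' @return the validated table as a `data.table`.
#' @export
allc_table <- function(x) {
  x <- data.table::as.data.table(x)
  need <- c("chrom", "pos", "strand", "context", "mc", "cov")
  stop_if_not(all(need %in% names(x)),
              paste("allc table must have columns:", paste(need, collapse = ", ")))
  bad <- which(x$mc > x$cov | x$mc < 0 | x$pos < 1)
  if (length(bad))
    stop(sprintf("invalid allc record at line %d (need 0 <= mc <= cov, pos >= 1)",
                 bad[1]), call. = FALSE)
  x
}

#' Read an allc file (7-column TSV, 1-based positions)
#' @param path file path.
#' @return a `data.table` with columns chrom, pos, strand, context, mc, cov.
#' @export
read_allc <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "pos", "strand", "context",
                                       "mc", "cov", "methylated"))
  allc_table(x[, c("chrom", "pos", "strand", "context", "mc", "cov")])
}

#' Write an allc file
#' @param table an allc table (see [allc_table()]).
#' @param path output path.
#' @export
write_allc <- function(table, path) {
  x <- allc_table(table)
  out <- data.table::data.table(x$chrom, x$pos, x$strand, x$context, x$mc,
                                x$cov, as.integer(x$mc > 0))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a per-cell contact list (TSV: cell_id, chrom, pos1, pos2; 1-based)
#' @param path file path.
#' @return `data.table` with columns cell_id, chrom, pos1, pos2 (pos1 <= pos2).
#' @export
read_contacts <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         col.names = c("cell_id", "chrom", "pos1", "pos2"))
  validate_contacts(x)
}

validate_contacts <- function(x) {
  x <- data.table::as.data.table(x)
  bad <- which(x$pos1 > x$pos2 | x$pos1 < 1)
  if (length(bad))
    stop(sprintf("invalid contact record at line %d (need 1 <= pos1 <= pos2)",
                 bad[1]), call. = FALSE)
  x
}

#' Write a per-cell contact list
#' @param contacts table with cell_id, chrom, pos1, pos2.
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  data.table::fwrite(validate_contacts(contacts), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval table (0-based half-open)
#' @param path file path to a BED3/4/6 file.
#' @return `data.table` with chrom, start, end and optional name/score/strand.
#' @export
read_intervals <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(x, cn[seq_len(min(ncol(x), 6L))])
  validate_intervals(x)
}

validate_intervals <- function(x) {
  x <- data.table::as.data.table(x)
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(sprintf("invalid interval at line %d (need start < end)", bad[1]),
         call. = FALSE)
  x
}

#' Write an interval table as BED
#' @param intervals table with chrom, start, end (+ optional name/score/strand).
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  x <- validate_intervals(intervals)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  data.table::fwrite(x[, keep, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

# Intervals (0-based half-open) -> GRanges (1-based closed, the Bioconductor
# convention); the +1 here is the single conversion point.
intervals_to_granges <- function(x) {
  x <- data.table::as.data.table(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Convert loop pixels to anchor intervals
#'
#' @param loops table with chrom, bin1, bin2 (0-based bin indices).
#' @param resolution bin size in bp (default 10 kb).
#' @return the input with anchor interval columns start1/end1/start2/end2
#'   (0-based half-open bp).
#' @export
loop_anchor_intervals <- function(loops, resolution = 1e4) {
  x <- data.table::as.data.table(loops)
  x$start1 <- x$bin1 * as.integer(resolution)
  x$end1 <- (x$bin1 + 1L) * as.integer(resolution)
  x$start2 <- x$bin2 * as.integer(resolution)
  x$end2 <- (x$bin2 + 1L) * as.integer(resolution)
  x
}

#' Read loops from a BEDPE-like file with named stat columns
#' @param path file path; first 6 columns are the two anchors (BEDPE),
#'   remaining columns are named statistics (header line required).
#' @param resolution bin size used to recover bin indices.
#' @return `data.table` with chrom, bin1, bin2 plus the stat columns.
#' @export
read_loops <- function(path, resolution = 1e4) {
  x <- data.table::fread(path, header = TRUE, sep = "\t")
  data.table::setnames(x, 1:6, c("chrom", "start1", "end1", "chrom2",
                                 "start2", "end2"))
  stop_if_not(all(x$chrom == x$chrom2), "trans loops are not supported")
  x$bin1 <- pos_to_bin(x$start1 + 1L, resolution)
  x$bin2 <- pos_to_bin(x$start2 + 1L, resolution)
  x[, setdiff(names(x), "chrom2"), with = FALSE]
}

#' Write loops as BEDPE with named stat columns
#' @param loops table with chrom, bin1, bin2 and any stat columns.
#' @param path output path.
#' @param resolution bin size in bp.
#' @export
write_loops <- function(loops, path, resolution = 1e4) {
  x <- loop_anchor_intervals(loops, resolution)
  stat_cols <- setdiff(names(x), c("chrom", "bin1", "bin2",
                                   "start1", "end1", "start2", "end2"))
  out <- data.table::data.table(
    chrom1 = x$chrom, start1 = x$start1, end1 = x$end1,
    chrom2 = x$chrom, start2 = x$start2, end2 = x$end2)
  for (cc in stat_cols) out[[cc]] <- x[[cc]]
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Strand-aware transcription start/end sites
#'
#' TSS is `start` for + genes and `end - 1` for - genes (0-based positions);
#' the gene body is `[start, end)` regardless of strand.
#'
#' @param genes interval table with a strand column.
#' @return input with tss and tes columns (0-based bp).
#' @export
gene_tss_tes <- function(genes) {
  x <- validate_intervals(genes)
  minus <- x$strand == "-"
  x$tss <- ifelse(minus, x$end - 1L, x$start)
  x$tes <- ifelse(minus, x$start, x$end - 1L)
  x
}
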