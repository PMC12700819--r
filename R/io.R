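#' Read a BED file of intervals
#'
#' Thin wrapper around [rtracklayer::import()] returning a `GRanges`
#' (0-based half-open on disk, 1-based closed in memory, as usual for
#' Bioconductor). The strand column, when present, is preserved; for CTCF
#' peaks it encodes motif orientation.
#'
#' @param path path to a BED file (3-6 columns).
#' @return a [GenomicRanges::GRanges] object.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write intervals to BED
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path path to a bedGraph file.
#' @return a `GRanges` with a `score` metadata column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a signal track to bedGraph
#'
#' @param gr a `GRanges` with a numeric `score` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read loops from a BEDPE file
#'
#' Parses the 6+ column BEDPE dialect (0-based half-open starts). Anchor
#' pairs are canonicalized so that anchor1 does not start after anchor2.
#' Malformed records (end <= start) raise an error naming the line.
#'
#' @param path path to a BEDPE file.
#' @return a `loop_table`: data.frame with columns `chrom1,start1,end1,
#'   chrom2,start2,end2` (+ any extra columns), starts 0-based half-open.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6) stop("BEDPE requires at least 6 columns: ", path)
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  bad <- which(df$end1 <= df$start1 | df$end2 <= df$start2)
  if (length(bad)) {
    stop("malformed BEDPE interval(s) at line(s): ",
         paste(bad, collapse = ", "))
  }
  loop_table(df)
}

#' Construct/canonicalize a loop table
#'
#' @param df data.frame with BEDPE-style columns `chrom1,start1,end1,
#'   chrom2,start2,end2`; extra columns are kept.
#' @return a `loop_table` data.frame with anchors in canonical order
#'   (anchor1 start <= anchor2 start on the same chromosome).
#' @export
loop_table <- function(df) {
  stopifnot(all(c("chrom1", "start1", "end1",
                  "chrom2", "start2", "end2") %in% names(df)))
  swap <- df$chrom1 == df$chrom2 & df$start2 < df$start1
  if (any(swap)) {
    tmp <- df[swap, c("start1", "end1")]
    df[swap, c("start1", "end1")] <- df[swap, c("start2", "end2")]
    df[swap, c("start2", "end2")] <- tmp
  }
  class(df) <- c("loop_table", "data.frame")
  df
}

#' Write loops to BEDPE
#'
#' @param loops a `loop_table` (or BEDPE-like data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  utils::write.table(loops, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a contact map to disk
#'
#' `dense` writes a TSV matrix plus a `<path>.bins` TSV bin table;
#' `triplet` writes sparse upper-triangle records `bin1 bin2 count` plus
#' the same bin table. Both round-trip losslessly through
#' [read_contact_map()].
#'
#' @param map a `contact_map`.
#' @param path output path.
#' @param format `"dense"` or `"triplet"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "contact_map"))
  utils::write.table(map$bins, paste0(path, ".bins"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (format == "dense") {
    utils::write.table(map$matrix, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(map$matrix, diag = TRUE) & map$matrix != 0,
                 arr.ind = TRUE)
    trip <- data.frame(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                       count = map$matrix[idx])
    utils::write.table(trip, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' @param path path given to [write_contact_map()].
#' @param format `"dense"` or `"triplet"`.
#' @return a `contact_map`.
#' @export
read_contact_map <- function(path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  bins <- utils::read.table(paste0(path, ".bins"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  n <- nrow(bins)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
    dimnames(m) <- NULL
  } else {
    trip <- utils::read.table(path, header = TRUE, sep = "\t")
    m <- matrix(0, n, n)
    m[cbind(trip$bin1 + 1L, trip$bin2 + 1L)] <- trip$count
    m[cbind(trip$bin2 + 1L, trip$bin1 + 1L)] <- trip$count
  }
  if (nrow(m) != n) stop("bin table and matrix dimensions disagree")
  contact_map(m, resolution = bins$end[1] - bins$start[1],
              chrom = bins$chrom[1], provenance = "file")
}
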