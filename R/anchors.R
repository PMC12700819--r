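#' Bundle genomic annotations used for anchor classification
#'
#' @param tss `GRanges` of transcription start sites (width-1 or small
#'   intervals; a `name` column gives gene ids).
#' @param h3k4me1,h3k27ac `GRanges` of histone-mark peaks; their
#'   intersection (outside promoters) defines enhancers.
#' @param ctcf `GRanges` of CTCF peaks, strand = motif orientation.
#' @param rad21 `GRanges` of cohesin (RAD21) peaks.
#' @return object of class `anchor_annotation`.
#' @export
anchor_annotation <- function(tss, h3k4me1, h3k27ac, ctcf, rad21) {
  structure(list(tss = tss, h3k4me1 = h3k4me1, h3k27ac = h3k27ac,
                 ctcf = ctcf, rad21 = rad21),
            class = "anchor_annotation")
}

#' Classify loop anchors by genomic identity
#'
#' Each anchor (padded by `anchor_pad`) is intersected with promoters
#' (TSS +/- `tss_pad`), enhancers (H3K4me1-H3K27ac peak intersection)
#' and CTCF/cohesin sites (CTCF peaks overlapping RAD21 peaks). In
#' `inclusive` mode, anchors matching several features are resolved
#' hierarchically: promoter > enhancer > CTCF; in `exclusive` mode,
#' anchors overlapping both a cis-regulatory element (promoter or
#' enhancer) and a CTCF/cohesin site are dropped (flagged), so only
#' "pure" anchors remain. Anchors matching nothing are `other`.
#'
#' @param anchors `GRanges` of loop-anchor intervals.
#' @param annotation an [anchor_annotation()].
#' @param mode `"inclusive"` or `"exclusive"`.
#' @param anchor_pad bp added to each side of an anchor (default 1 kb).
#' @param tss_pad promoter half-width around a TSS (default 2 kb).
#' @return data.frame with columns `class` (`promoter`, `enhancer`,
#'   `ctcf`, `other`, or `dropped` in exclusive mode) and logical
#'   indicator columns `is_promoter`, `is_enhancer`, `is_ctcf`.
#' @export
classify_anchors <- function(anchors, annotation,
                             mode = c("inclusive", "exclusive"),
                             anchor_pad = 1000, tss_pad = 2000) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "anchor_annotation"))
  if (any(GenomicRanges::width(anchors) < 1))
    stop("malformed anchor interval(s): ",
         paste(which(GenomicRanges::width(anchors) < 1), collapse = ", "))
  a <- GenomicRanges::resize(anchors,
                             GenomicRanges::width(anchors) + 2 * anchor_pad,
                             fix = "center")
  prom <- GenomicRanges::resize(annotation$tss,
                                2 * tss_pad + 1, fix = "center")
  enh <- GenomicRanges::intersect(annotation$h3k4me1, annotation$h3k27ac,
                                  ignore.strand = TRUE)
  ctcf_coh <- IRanges::subsetByOverlaps(annotation$ctcf,
                                        annotation$rad21,
                                        ignore.strand = TRUE)
  is_p <- IRanges::overlapsAny(a, prom, ignore.strand = TRUE)
  is_e <- IRanges::overlapsAny(a, enh, ignore.strand = TRUE)
  is_c <- IRanges::overlapsAny(a, ctcf_coh, ignore.strand = TRUE)
  cls <- ifelse(is_p, "promoter",
         ifelse(is_e, "enhancer",
         ifelse(is_c, "ctcf", "other")))
  if (mode == "exclusive") {
    cls[(is_p | is_e) & is_c] <- "dropped"
  }
  data.frame(class = cls, is_promoter = is_p, is_enhancer = is_e,
             is_ctcf = is_c, stringsAsFactors = FALSE)
}

#' Classify loops by their anchor classes
#'
#' Applies [classify_anchors()] to both anchors of each loop and maps
#' the pair to a loop class: `P-P`, `E-P`, `E-E`, `E/P-CTCF`,
#' `CTCF-CTCF`, or `other`. In exclusive mode, loops with a dropped
#' anchor are labeled `dropped`.
#'
#' @param loops a `loop_table`.
#' @param annotation an [anchor_annotation()].
#' @inheritParams classify_anchors
#' @param chrom chromosome label to use for anchor `GRanges`.
#' @return the loop table with added columns `class1`, `class2`,
#'   `loop_class`, `mode`.
#' @export
classify_loops <- function(loops, annotation,
                           mode = c("inclusive", "exclusive"),
                           anchor_pad = 1000, tss_pad = 2000,
                           chrom = NULL) {
  mode <- match.arg(mode)
  mk <- function(chr, s, e) {
    GenomicRanges::GRanges(chr, IRanges::IRanges(s + 1, e))
  }
  a1 <- mk(if (is.null(chrom)) loops$chrom1 else chrom,
           loops$start1, loops$end1)
  a2 <- mk(if (is.null(chrom)) loops$chrom2 else chrom,
           loops$start2, loops$end2)
  c1 <- classify_anchors(a1, annotation, mode, anchor_pad, tss_pad)$class
  c2 <- classify_anchors(a2, annotation, mode, anchor_pad, tss_pad)$class
  pairlab <- function(x, y) {
    if (x == "dropped" || y == "dropped") return("dropped")
    k <- sort(c(x, y))
    if (all(k == "promoter")) return("P-P")
    if (all(k == c("enhancer", "promoter"))) return("E-P")
    if (all(k == "enhancer")) return("E-E")
    if (k[1] %in% c("enhancer", "promoter") && k[2] == "ctcf" ||
        k[2] %in% c("enhancer", "promoter") && k[1] == "ctcf")
      return("E/P-CTCF")
    if (all(k == "ctcf")) return("CTCF-CTCF")
    "other"
  }
  loops$class1 <- c1
  loops$class2 <- c2
  loops$loop_class <- mapply(pairlab, c1, c2)
  loops$mode <- mode
  loops
}
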