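TIME_POINTS <- c("PM", "AT", "EG1", "MG1", "LG1")
G1_POINTS <- c("EG1", "MG1", "LG1")

#' Quantify Pol II signal at TSSs across the five time points
#'
#' For each gene, averages the signal of each time-point track within a
#' `window`-bp window centered on the TSS. Genes with multiple TSSs keep
#' only the dominant one: the TSS with the highest Pol II signal summed
#' across the five time points. Genes whose window is not covered by a
#' track are dropped with a warning.
#'
#' @param tracks named list of five `GRanges` bedGraph-style tracks
#'   (names `PM`, `AT`, `EG1`, `MG1`, `LG1`), each with a `score`.
#' @param tss `GRanges` of TSS positions with a `name` column (gene id).
#' @param window window width in bp (default 2500).
#' @return a `polII_matrix`: genes x 5 numeric matrix (rownames = gene),
#'   with attribute `tss` recording the chosen dominant TSS per gene.
#' @export
build_polII_matrix <- function(tracks, tss, window = 2500) {
  stopifnot(identical(sort(names(tracks)), sort(TIME_POINTS)))
  win <- GenomicRanges::resize(tss, window, fix = "center")
  sig <- sapply(TIME_POINTS, function(tp) {
    track_window_mean(tracks[[tp]], win)
  })
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1,
                                       dimnames = list(NULL, TIME_POINTS))
  covered <- rowSums(is.na(sig)) == 0
  if (!all(covered)) {
    warning(sum(!covered), " TSS window(s) outside track coverage; ",
            "gene(s) dropped")
  }
  gene <- as.character(tss$name)
  tot <- rowSums(sig)
  keep <- logical(length(gene))
  for (g in unique(gene[covered])) {
    idx <- which(gene == g & covered)
    keep[idx[which.max(tot[idx])]] <- TRUE
  }
  m <- sig[keep, , drop = FALSE]
  rownames(m) <- gene[keep]
  structure(m, tss = tss[keep], class = c("polII_matrix", class(m)))
}

#' Mean of a piecewise-constant track over query windows
#' @keywords internal
track_window_mean <- function(track, windows) {
  hits <- GenomicRanges::findOverlaps(windows, track)
  out <- rep(NA_real_, length(windows))
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(windows)[qi],
                            IRanges::ranges(track)[si])
  wsum <- tapply(IRanges::width(ov) * track$score[si], qi, sum)
  wcov <- tapply(IRanges::width(ov), qi, sum)
  full <- wcov == GenomicRanges::width(windows)[as.integer(names(wcov))]
  idx <- as.integer(names(wsum))[full]
  out[idx] <- (wsum / wcov)[full]
  out
}

#' Filter active genes and normalize by the G1 mean
#'
#' A gene is active when its signal is at least `active_threshold` (in
#' the units of the input tracks) at every time point except PM. Each
#' surviving row is divided by the mean of its three G1 values
#' (EG1, MG1, LG1).
#'
#' @param matrix a `polII_matrix` (genes x 5).
#' @param active_threshold activity floor applied to AT and the three G1
#'   time points.
#' @return list with `normalized` (active genes x 5 matrix) and
#'   `active` (logical per input gene).
#' @export
normalize_and_filter <- function(matrix, active_threshold = 0.5) {
  stopifnot(ncol(matrix) == 5)
  m <- unclass(matrix)
  act_cols <- setdiff(TIME_POINTS, "PM")
  active <- apply(m[, act_cols, drop = FALSE] >= active_threshold, 1, all)
  m <- m[active, , drop = FALSE]
  g1 <- rowMeans(m[, G1_POINTS, drop = FALSE])
  stopifnot(all(g1 > 0))  # guaranteed by the activity rule
  list(normalized = m / g1, active = active)
}

#' PCA classification of transcriptionally spiking genes
#'
#' Runs PCA on the G1-normalized Pol II matrix (genes as observations,
#' column-mean centered, unscaled). PC1 is oriented so that its loading
#' at AT exceeds the mean loading over the three G1 time points; genes
#' with positive PC1 scores are labeled spiking.
#'
#' @param normalized active-gene normalized matrix (genes x 5), as
#'   returned by [normalize_and_filter()].
#' @return a `spiking_result`: list with `score` (PC1 per gene),
#'   `label` (`spiking`/`nonspiking`), `var_explained` (fraction per
#'   component), `loadings`, `normalized`.
#' @export
pca_classify <- function(normalized) {
  if (nrow(normalized) < 3) stop("need at least 3 active genes for PCA")
  if (all(apply(normalized, 2, stats::sd) < 1e-12))
    stop("zero-variance matrix: PCA is degenerate")
  pc <- stats::prcomp(normalized, center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (load1["AT"] <= mean(load1[G1_POINTS])) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  score <- pc$x[, 1]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(score = score,
                 label = ifelse(score > 0, "spiking", "nonspiking"),
                 var_explained = ve,
                 loadings = pc$rotation,
                 normalized = normalized),
            class = "spiking_result")
}
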