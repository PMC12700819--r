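#' @keywords internal
.loop_to_bins <- function(map, loop) {
  res <- map$resolution
  if (is.data.frame(loop)) {
    p1 <- (loop$start1 + loop$end1) / 2
    p2 <- (loop$start2 + loop$end2) / 2
  } else {
    p1 <- loop[1]; p2 <- loop[2]
  }
  b1 <- floor((p1 - map$bins$start[1]) / res) + 1L
  b2 <- floor((p2 - map$bins$start[1]) / res) + 1L
  cbind(pmin(b1, b2), pmax(b1, b2))
}

#' Local distance-decay background around a loop
#'
#' Builds the expected window used for background-subtracted loop
#' strength: a `(2*halfwidth+1)`-square window centered on the loop where
#' each element at genomic separation `s` is the average of all map
#' elements at separation `s` whose midpoint lies within `flank` bp of
#' the loop midpoint. The background represents distance-dependent random
#' contacts in the absence of a looping mechanism.
#'
#' @param map a `contact_map` (balanced for strength work).
#' @param loop loop position: numeric `c(pos1, pos2)` in bp or a one-row
#'   BEDPE-like data.frame.
#' @param halfwidth window half-width in bins (10 gives the 21 x 21
#'   window used at 500-bp resolution).
#' @param flank background neighborhood half-width in bp (default
#'   100 kb); truncated at the map edge.
#' @return numeric `(2*halfwidth+1)^2` matrix.
#' @export
local_background_matrix <- function(map, loop, halfwidth = 10,
                                    flank = 1e5) {
  stopifnot(inherits(map, "contact_map"))
  bb <- .loop_to_bins(map, loop)
  bi <- bb[1, 1]; bj <- bb[1, 2]
  n <- nrow(map$matrix)
  if (bi - halfwidth < 1 || bj + halfwidth > n ||
      bi + halfwidth > n || bj - halfwidth < 1)
    stop("loop window extends beyond map bounds")
  if (bj - bi <= 2 * halfwidth)
    stop("loop too close to the diagonal for a ", 2 * halfwidth + 1,
         "-bin background window")
  fb <- floor(flank / map$resolution)   # flank in bins
  m <- map$matrix
  w <- 2L * halfwidth + 1L
  bg <- matrix(NA_real_, w, w)
  mid0 <- bi + bj
  # candidate diagonals: separations present in the window
  for (di in -halfwidth:halfwidth) {
    for (dj in -halfwidth:halfwidth) {
      s <- abs((bi + di) - (bj + dj))
      # cells (i, i + s) with midpoint near the loop midpoint
      i_lo <- max(1L, ceiling((mid0 - 2 * fb - s) / 2))
      i_hi <- min(n - s, floor((mid0 + 2 * fb - s) / 2))
      if (i_hi < i_lo) next
      ii <- i_lo:i_hi
      vals <- m[cbind(ii, ii + s)]
      bg[di + halfwidth + 1L, dj + halfwidth + 1L] <-
        mean(vals, na.rm = TRUE)
    }
  }
  bg
}

#' Loop strength of a focal contact
#'
#' Three scores over a `(2*halfwidth+1)`-square window centered on the
#' loop (21 x 21 at 500-bp resolution, i.e. anchors within +/-5 kb):
#' `bg_subtracted` is the summed map signal minus the summed local
#' background; `obs_over_exp` is the summed observed signal divided by
#' the summed background; `total` is the observed sum alone.
#'
#' @inheritParams local_background_matrix
#' @param mode one of `"bg_subtracted"`, `"obs_over_exp"`, `"total"`.
#' @return scalar score (`NA` with a warning when the expected sum is 0
#'   in `obs_over_exp` mode).
#' @export
loop_strength <- function(map, loop, mode = c("bg_subtracted",
                                              "obs_over_exp", "total"),
                          halfwidth = 10, flank = 1e5) {
  mode <- match.arg(mode)
  bb <- .loop_to_bins(map, loop)
  bi <- bb[1, 1]; bj <- bb[1, 2]
  n <- nrow(map$matrix)
  if (bi - halfwidth < 1 || bj + halfwidth > n)
    stop("loop window extends beyond map bounds")
  obs <- map$matrix[(bi - halfwidth):(bi + halfwidth),
                    (bj - halfwidth):(bj + halfwidth)]
  if (mode == "total") return(sum(obs))
  bg <- local_background_matrix(map, loop, halfwidth, flank)
  if (mode == "bg_subtracted") return(sum(obs - bg))
  e <- sum(bg)
  if (!is.finite(e) || e == 0) {
    warning("expected signal is zero; obs/exp undefined")
    return(NA_real_)
  }
  sum(obs) / e
}

#' Simulation-style loop strength at a site pair
#'
#' Mean number of contacts within a 6-kb x 6-kb window (3 x 3 bins at
#' 2-kb resolution) centered on a pair of sites; in relative mode the
#' mean is scaled by the map-wide average number of contacts at the
#' corresponding genomic distance.
#'
#' @param map a `contact_map` (raw counts).
#' @param site_pair numeric `c(pos1, pos2)` in bp.
#' @param window window edge in bp (default 6000).
#' @param relative scale by the mean contact count at that separation?
#' @return scalar score.
#' @export
sim_window_strength <- function(map, site_pair, window = 6000,
                                relative = FALSE) {
  stopifnot(inherits(map, "contact_map"))
  hw <- max(0L, as.integer(round(window / map$resolution / 2 - 0.5)))
  bb <- .loop_to_bins(map, site_pair)
  bi <- bb[1, 1]; bj <- bb[1, 2]
  n <- nrow(map$matrix)
  if (bi - hw < 1 || bj + hw > n || bj - hw < 1 || bi + hw > n)
    stop("window out of map bounds")
  obs <- mean(map$matrix[(bi - hw):(bi + hw), (bj - hw):(bj + hw)])
  if (!relative) return(obs)
  v <- mean_by_separation(map$matrix)
  e <- v[abs(bj - bi) + 1L]
  if (is.na(e) || e == 0) stop("no expected contacts at this separation")
  obs / e
}

#' Aggregate peak analysis (APA) pileup over a loop list
#'
#' Averages per-loop observed/expected windows (expected from the local
#' distance-decay background) over all loops whose window fits in the
#' map. Loops with truncated windows are skipped and counted.
#'
#' @param map a `contact_map`.
#' @param loops a `loop_table` or data.frame of BEDPE-like records.
#' @param window full window size in bp (24 kb for M-to-G1 style plots,
#'   20 kb for depletion-style plots).
#' @param flank background neighborhood (bp) for the expected matrix.
#' @return list with `pileup` (mean obs/exp matrix), `n_used`,
#'   `n_skipped`.
#' @export
apa_pileup <- function(map, loops, window = 24000, flank = 1e5) {
  stopifnot(inherits(map, "contact_map"), nrow(loops) >= 1)
  hw <- as.integer(window / 2 / map$resolution)
  acc <- NULL; used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(loops))) {
    lp <- loops[k, , drop = FALSE]
    oe <- tryCatch({
      bg <- local_background_matrix(map, lp, halfwidth = hw, flank = flank)
      bb <- .loop_to_bins(map, lp)
      obs <- map$matrix[(bb[1, 1] - hw):(bb[1, 1] + hw),
                        (bb[1, 2] - hw):(bb[1, 2] + hw)]
      r <- obs / bg
      r[!is.finite(r)] <- NA_real_
      r
    }, error = function(e) NULL)
    if (is.null(oe)) { skipped <- skipped + 1L; next }
    acc <- if (is.null(acc)) oe else acc + oe
    used <- used + 1L
  }
  if (used == 0L) stop("all loops skipped (windows out of bounds)")
  list(pileup = acc / used, n_used = used, n_skipped = skipped)
}
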