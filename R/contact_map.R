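#' Construct a contact map
#'
#' A `contact_map` bundles a symmetric matrix of contact counts (or
#' balanced weights) with its bin table, resolution and provenance.
#'
#' @param matrix symmetric numeric matrix of counts.
#' @param resolution bin size in bp.
#' @param chrom chromosome label for the bin table.
#' @param start0 genomic start (bp, 0-based) of the first bin.
#' @param weights optional per-bin balancing weights (NA where masked).
#' @param provenance free-text tag (`"simulated"`, `"synthetic"`, ...).
#' @return object of class `contact_map`.
#' @export
contact_map <- function(matrix, resolution, chrom = "sim", start0 = 0,
                        weights = NULL, provenance = "unknown") {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (max(abs(matrix - t(matrix))) > 1e-8 * (1 + max(abs(matrix))))
    stop("contact matrix must be symmetric")
  n <- nrow(matrix)
  bins <- data.frame(chrom = chrom,
                     start = start0 + resolution * (seq_len(n) - 1),
                     end = start0 + resolution * seq_len(n))
  structure(list(matrix = matrix, bins = bins, resolution = resolution,
                 weights = weights, balanced = FALSE,
                 provenance = provenance),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d bins @ %d bp (%s)%s\n", nrow(x$matrix),
              x$resolution, x$provenance,
              if (x$balanced) ", balanced" else ""))
  invisible(x)
}

#' Build a contact map from a 3D polymer trajectory
#'
#' A pair of monomers is in contact in a frame when their spatial distance
#' is at most `radius` monomer diameters; contacts are accumulated over
#' frames and binned into `bin`-monomer bins along both axes (the adopted
#' scale is 4 monomers = 2 kb per bin with a 4-monomer contact radius).
#'
#' @param trajectory a `trajectory3d` (see [run_polymer()]) or a list of
#'   N x 3 coordinate matrices.
#' @param radius contact radius in monomer diameters.
#' @param bin bin width in monomers.
#' @param sigma_kb kb of chromatin per monomer (sets the bp resolution).
#' @return a `contact_map` at resolution `bin * sigma_kb * 1000` bp.
#' @export
contact_map_from_trajectory <- function(trajectory, radius = 4, bin = 4,
                                        sigma_kb = 0.5) {
  frames <- if (inherits(trajectory, "trajectory3d")) trajectory$frames
            else trajectory
  if (length(frames) == 0) stop("trajectory contains no frames")
  n <- nrow(frames[[1]])
  nbins <- n %/% bin
  if (nbins < 2) stop("bin width must divide the chain into >= 2 bins")
  m <- matrix(0, nbins, nbins)
  for (fr in frames) {
    m <- m + contact_count_cpp(fr, radius, bin, nbins)
  }
  contact_map(m, resolution = as.integer(round(bin * sigma_kb * 1000)),
              provenance = "simulated")
}

#' Iterative correction (ICE) balancing of a contact map
#'
#' Finds per-bin weights `w` such that `diag(w) %*% M %*% diag(w)` has
#' equal row sums; all-zero rows are masked (weight `NA`). The balanced
#' matrix is normalized so the mean nonzero row sum is 1.
#'
#' @param map a `contact_map` with non-negative counts.
#' @param max_iter maximum number of iterations.
#' @param tol convergence tolerance on the relative spread of row sums.
#' @return the map with `$matrix` replaced by the balanced matrix,
#'   `$weights` set and `$balanced = TRUE`. Warns (and flags
#'   `$converged = FALSE`) on non-convergence.
#' @export
ice_balance <- function(map, max_iter = 200, tol = 1e-10) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$matrix
  if (any(m < 0)) stop("contact matrix must be non-negative")
  n <- nrow(m)
  mask <- rowSums(m) > 0
  w <- rep(1, n)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    b <- m * tcrossprod(w)
    s <- rowSums(b)
    s_live <- s[mask]
    mu <- mean(s_live)
    if (max(abs(s_live - mu)) <= tol * mu) { conv <- TRUE; break }
    adj <- rep(1, n)
    adj[mask] <- sqrt(s_live / mu)
    w <- w / adj
  }
  if (!conv) warning("ICE balancing did not converge in ", max_iter,
                     " iterations; returning best iterate")
  b <- m * tcrossprod(w)
  mu <- mean(rowSums(b)[mask])
  if (mu > 0) { b <- b / mu; w <- w / sqrt(mu) }
  w[!mask] <- NA_real_
  b[!mask, ] <- NA_real_
  b[, !mask] <- NA_real_
  map$matrix <- b
  map$weights <- w
  map$balanced <- TRUE
  map$converged <- conv
  map
}

#' Mean contact value at each genomic separation
#'
#' @param m square (contact) matrix; `NA` entries ignored.
#' @return numeric vector `v` with `v[s + 1]` the mean over all cells at
#'   separation `s` bins.
#' @keywords internal
mean_by_separation <- function(m) {
  n <- nrow(m)
  sep <- abs(row(m) - col(m))
  ok <- !is.na(m)
  sums <- tapply(m[ok], sep[ok], sum)
  cnts <- tapply(rep(1, sum(ok)), sep[ok], sum)
  v <- rep(NA_real_, n)
  v[as.integer(names(sums)) + 1L] <- sums / cnts
  v
}

#' Contact-probability decay P(s) and its log-log derivative
#'
#' Computes the mean contact value at each genomic separation, averages
#' into log-spaced separation bins (ratio `bin_ratio`, geometric bin
#' centers), normalizes the curve to unit sum, and differentiates
#' log10 P against log10 s by centered differences on a moving-average
#' smoothed curve.
#'
#' @param map a `contact_map` (balanced or raw).
#' @param bin_ratio geometric spacing of separation bins.
#' @param smooth half-width (in log-bins) of the moving-average smoother
#'   applied to log P before differentiating.
#' @param max_sep optional maximum separation (bp) to retain.
#' @return data.frame with columns `s` (bp, geometric bin center), `p`
#'   (normalized contact probability) and `dlogp` (d log P / d log s;
#'   `NA` at the ends). If only one separation bin is present the
#'   derivative is `NA` and attribute `degenerate` is `TRUE`.
#' @export
contact_scaling <- function(map, bin_ratio = 1.12, smooth = 1,
                            max_sep = NULL) {
  stopifnot(inherits(map, "contact_map"))
  v <- mean_by_separation(map$matrix)
  res <- map$resolution
  s_bp <- (seq_along(v) - 1) * res
  keep <- !is.na(v) & v > 0 & s_bp > 0
  if (!is.null(max_sep)) keep <- keep & s_bp <= max_sep
  if (!any(keep)) stop("no positive off-diagonal contacts")
  s_bp <- s_bp[keep]; v <- v[keep]
  lo <- log(min(s_bp)); hi <- log(max(s_bp))
  nb <- max(1L, ceiling((hi - lo) / log(bin_ratio)))
  edges <- exp(seq(lo, hi, length.out = nb + 1))
  idx <- findInterval(s_bp, edges, rightmost.closed = TRUE)
  p <- tapply(v, idx, mean)
  sc <- tapply(s_bp, idx, function(z) exp(mean(log(z))))
  out <- data.frame(s = as.numeric(sc), p = as.numeric(p))
  out <- out[order(out$s), ]
  out$p <- out$p / sum(out$p)
  if (nrow(out) < 3) {
    out$dlogp <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  lp <- log10(out$p); ls <- log10(out$s)
  if (smooth > 0) {
    k <- 2 * smooth + 1
    lp <- stats::filter(lp, rep(1 / k, k), sides = 2)
    lp <- as.numeric(lp)
    # keep raw values at the ends where the smoother is undefined
    nas <- is.na(lp)
    lp[nas] <- log10(out$p)[nas]
  }
  n <- nrow(out)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (lp[3:n] - lp[1:(n - 2)]) / (ls[3:n] - ls[1:(n - 2)])
  out$dlogp <- d
  attr(out, "degenerate") <- FALSE
  out
}

#' Observed/expected transform of a contact matrix
#'
#' Divides each cell by the mean value at its genomic separation.
#'
#' @param m square matrix.
#' @return matrix of observed/expected ratios (`NA` where expected is 0).
#' @keywords internal
obs_over_exp_matrix <- function(m) {
  v <- mean_by_separation(m)
  sep <- abs(row(m) - col(m))
  e <- matrix(v[sep + 1L], nrow(m))
  out <- m / e
  out[e == 0] <- NA_real_
  out
}
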