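#' A/B compartment call by eigendecomposition
#'
#' Computes the leading eigenvector of the correlation matrix of the
#' observed/expected-transformed contact map. The eigenvector sign is
#' oriented so that its correlation with `orientation_track` (e.g. G+C
#' content, an A-compartment correlate) is positive; bins with positive
#' entries are called A, negative B. Masked (all-zero / NA) bins get NA.
#'
#' @param map a balanced `contact_map`.
#' @param orientation_track numeric vector, one value per bin.
#' @return list with `eigenvector` (per-bin, NA at masked bins),
#'   `compartment` (factor A/B/NA), `transitions` (indices of the first
#'   bin of each sign change), `reliable` (FALSE when the eigenvector is
#'   essentially constant), `lambda` (leading eigenvalue).
#' @export
compartment_call <- function(map, orientation_track) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$matrix
  n <- nrow(m)
  stopifnot(length(orientation_track) == n)
  oe <- obs_over_exp_matrix(m)
  live <- which(apply(oe, 1, function(r) sum(is.finite(r)) > 1))
  if (length(live) < 2) stop("contact map is degenerate (rank 0)")
  x <- oe[live, live]
  x[!is.finite(x)] <- NA_real_
  if (stats::sd(x, na.rm = TRUE) < 1e-10) {
    # featureless map: observed/expected is constant, no compartments
    full <- rep(NA_real_, n)
    full[live] <- 0
    return(list(eigenvector = full,
                compartment = factor(rep(NA_character_, n),
                                     levels = c("A", "B")),
                transitions = integer(0), reliable = FALSE,
                lambda = 0))
  }
  cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  ed <- eigen(cc, symmetric = TRUE)
  ev <- ed$vectors[, 1]
  ori <- orientation_track[live]
  s <- suppressWarnings(stats::cor(ev, ori))
  if (is.finite(s) && s < 0) ev <- -ev
  full <- rep(NA_real_, n)
  full[live] <- ev
  reliable <- stats::sd(ev) > 1e-8 * max(1, mean(abs(ev)))
  comp <- rep(NA_character_, n)
  comp[live] <- ifelse(ev > 0, "A", "B")
  sgn <- sign(full)
  trans <- which(diff(sgn[!is.na(sgn)]) != 0) + 1L
  list(eigenvector = full,
       compartment = factor(comp, levels = c("A", "B")),
       transitions = trans, reliable = reliable,
       lambda = ed$values[1])
}

#' Categorize loops by the compartments of their anchors
#'
#' @param loops a `loop_table` (coordinates in bp on the map's bins).
#' @param call result of [compartment_call()].
#' @param map the `contact_map` the call was made on (for bin lookup).
#' @return list with per-loop `label` (`intra-A`, `intra-B`, `inter`,
#'   `unassigned`), `counts` and `fractions` over assigned loops.
#' @export
classify_loop_compartments <- function(loops, call, map) {
  if (nrow(loops) == 0) {
    cnt <- c(`intra-A` = 0L, `intra-B` = 0L, inter = 0L, unassigned = 0L)
    return(list(label = character(0), counts = cnt,
                fractions = cnt[1:3] * NA_real_))
  }
  bb <- .loop_to_bins(map, loops)
  c1 <- as.character(call$compartment[bb[, 1]])
  c2 <- as.character(call$compartment[bb[, 2]])
  lab <- ifelse(is.na(c1) | is.na(c2), "unassigned",
         ifelse(c1 == "A" & c2 == "A", "intra-A",
         ifelse(c1 == "B" & c2 == "B", "intra-B", "inter")))
  cnt <- c(`intra-A` = sum(lab == "intra-A"),
           `intra-B` = sum(lab == "intra-B"),
           inter = sum(lab == "inter"),
           unassigned = sum(lab == "unassigned"))
  assigned <- sum(cnt[1:3])
  frac <- if (assigned > 0) cnt[1:3] / assigned else cnt[1:3] * NA_real_
  list(label = lab, counts = cnt, fractions = frac)
}
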