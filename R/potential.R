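#' Pair-potential parameters for the typed polymer
#'
#' The monomer-monomer interaction is a smooth square-well: a soft repulsive
#' core of height `E_repel` for `r < a`, an attractive well of depth
#' `eps` between `a` and `a_star = 1.5 a` for homotypic pairs, and zero
#' beyond `a_star`. The polynomial shape constants `a0 = sqrt(6/7)` and
#' `E0 = 46656/823543` make the potential continuous with `U(a) = U(a_star)
#' = 0` and well minimum exactly `-eps` at the midpoint of the well.
#'
#' @param E_repel repulsion height at full overlap (kT units).
#' @param a monomer diameter in reduced length units (physical scale
#'   25 nm per monomer of 0.5 kb).
#' @param eps named numeric vector of homotypic affinities (kT) for the
#'   three monomer types; heterotypic affinities are zero.
#' @return object of class `potential_params`.
#' @export
potential_params <- function(E_repel = 3, a = 1,
                             eps = c(A = 0, B = 0.05, C = 0.9)) {
  stopifnot(E_repel >= 0, a > 0, all(eps >= 0),
            all(c("A", "B", "C") %in% names(eps)))
  structure(list(E_repel = E_repel, a = a, a_star = 1.5 * a,
                 a0 = sqrt(6 / 7), E0 = 46656 / 823543,
                 eps = eps[c("A", "B", "C")]),
            class = "potential_params")
}

#' Evaluate the smooth square-well pair potential
#'
#' @param r distance(s) between two monomers (same units as `params$a`).
#' @param eps_i homotypic affinity of the pair (kT); 0 for heterotypic
#'   pairs.
#' @param params a [potential_params()] object.
#' @return potential energy in kT; vectorized over `r`.
#' @export
pair_potential <- function(r, eps_i = 0, params = potential_params()) {
  if (any(r < 0)) stop("distance r must be non-negative")
  stopifnot(eps_i >= 0)
  a <- params$a; a_star <- params$a_star
  a0 <- params$a0; E0 <- params$E0
  u <- numeric(length(r))
  core <- r < a
  if (any(core)) {
    x <- a0 * r[core] / a
    u[core] <- params$E_repel * (1 + (x^2 - 1) * x^12 / E0)
  }
  well <- r >= a & r <= a_star
  if (any(well)) {
    x <- a0 * (r[well] - (a + a_star) / 2) / ((a_star - a) / 2)
    u[well] <- -eps_i * ((x^2 - 1) * x^12 / E0 + 1)
  }
  u
}

#' Radial force -dU/dr of the pair potential
#'
#' Used by tests to cross-check the compiled force kernel against finite
#' differences of [pair_potential()].
#'
#' @inheritParams pair_potential
#' @return radial force (positive = repulsive), vectorized over `r`.
#' @export
pair_force <- function(r, eps_i = 0, params = potential_params()) {
  if (any(r < 0)) stop("distance r must be non-negative")
  a <- params$a; a_star <- params$a_star
  a0 <- params$a0; E0 <- params$E0
  f <- numeric(length(r))
  core <- r < a
  if (any(core)) {
    x <- a0 * r[core] / a
    f[core] <- -params$E_repel / E0 * (14 * x^13 - 12 * x^11) * a0 / a
  }
  well <- r >= a & r <= a_star
  if (any(well)) {
    w <- (a_star - a) / 2
    x <- a0 * (r[well] - (a + a_star) / 2) / w
    f[well] <- eps_i / E0 * (14 * x^13 - 12 * x^11) * a0 / w
  }
  f
}
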