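#' Confinement specification
#'
#' Container volume follows from the prescribed volumetric density:
#' `rho_chr = N * (4/3) * pi * (a/2)^3 / V_container`, i.e. the fraction
#' of container volume occupied by monomer volume. For a sphere this
#' gives radius `R = (N / (8 rho))^(1/3)` (in units of the monomer
#' diameter); for a cylinder of `aspect` height:diameter ratio, radius
#' `Rc = (N / (12 * aspect * rho))^(1/3)` and half-height
#' `H = aspect * Rc`.
#'
#' @param shape `"sphere"`, `"cylinder"`, or `"none"`.
#' @param rho volumetric density in (0, 1).
#' @param aspect cylinder height:diameter ratio.
#' @param wall_k one-sided harmonic wall stiffness (kT / a^2).
#' @param tether tether chain ends to the cylinder poles?
#' @return object of class `confinement_spec`.
#' @export
confinement_spec <- function(shape = c("sphere", "cylinder", "none"),
                             rho = 0.25, aspect = 4, wall_k = 30,
                             tether = FALSE) {
  shape <- match.arg(shape)
  if (shape != "none") stopifnot(rho > 0, rho < 1)
  structure(list(shape = shape, rho = rho, aspect = aspect,
                 wall_k = wall_k, tether = tether),
            class = "confinement_spec")
}

#' Container geometry for `n` monomers at the prescribed density
#'
#' @param spec a [confinement_spec()].
#' @param n number of monomers.
#' @param rho optional density overriding `spec$rho`.
#' @return list with `shape`, `R` (radius), `H` (cylinder half-height,
#'   `NA` for spheres).
#' @export
confinement_geometry <- function(spec, n, rho = NULL) {
  rho <- if (is.null(rho)) spec$rho else rho
  if (spec$shape == "sphere") {
    list(shape = "sphere", R = (n / (8 * rho))^(1 / 3), H = NA_real_)
  } else if (spec$shape == "cylinder") {
    # volume pi Rc^2 (2H) with H = aspect * Rc
    Rc <- (n / (12 * spec$aspect * rho))^(1 / 3)
    list(shape = "cylinder", R = Rc, H = spec$aspect * Rc)
  } else list(shape = "none", R = Inf, H = Inf)
}

#' Initial conformation: confined random walk
#'
#' Builds a unit-bond random walk folded into the container (steps that
#' would leave the wall are redrawn; after 50 failed draws the walker
#' steps back toward the container center). With tethering on, the walk
#' starts near one cylinder pole.
#'
#' @param n number of monomers.
#' @param confinement a [confinement_spec()].
#' @param seed random seed.
#' @return `n` x 3 coordinate matrix.
#' @export
init_conformation <- function(n, confinement = confinement_spec(),
                              seed = 1) {
  geo <- confinement_geometry(confinement, n)
  if (confinement$shape != "none" && confinement$rho >= 1)
    stop("container too small: density must be < 1")
  set.seed(seed)
  inside <- function(p) {
    if (geo$shape == "sphere") sqrt(sum(p^2)) <= geo$R
    else if (geo$shape == "cylinder")
      sqrt(p[1]^2 + p[2]^2) <= geo$R && abs(p[3]) <= geo$H
    else TRUE
  }
  x <- matrix(0, n, 3)
  x[1, ] <- if (confinement$tether && geo$shape == "cylinder")
    c(0, 0, -geo$H * 0.95) else c(0, 0, 0)
  for (i in seq_len(n - 1)) {
    for (try in seq_len(50)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- x[i, ] + u
      if (inside(cand)) break
      cand <- x[i, ] - 0.9 * x[i, ] / max(1, sqrt(sum(x[i, ]^2)))
    }
    x[i + 1, ] <- cand
  }
  x
}

#' Assemble a polymer system
#'
#' @param typing a `monomer_typing` (see [gen_monomer_typing()]) or a
#'   character vector of per-monomer types (`"A"/"B"/"C"`).
#' @param potential a [potential_params()].
#' @param confinement a [confinement_spec()].
#' @param coords optional starting coordinates (default: confined
#'   random walk from `seed`).
#' @param k_bond harmonic bond stiffness (kT / a^2), shared by chain
#'   and bridge bonds.
#' @param dt integrator timestep (reduced units).
#' @param gamma friction coefficient (reduced units).
#' @param seed seed for the initial conformation.
#' @return object of class `polymer_system`.
#' @export
polymer_system <- function(typing, potential = potential_params(),
                           confinement = confinement_spec(),
                           coords = NULL, k_bond = 30, dt = 0.0025,
                           gamma = 1, seed = 1) {
  types <- if (inherits(typing, "monomer_typing")) typing$types
           else as.character(typing)
  stopifnot(all(types %in% c("A", "B", "C")))
  n <- length(types)
  if (is.null(coords)) coords <- init_conformation(n, confinement, seed)
  stopifnot(nrow(coords) == n, all(is.finite(coords)))
  structure(list(coords = coords, types = types, typing = typing,
                 potential = potential, confinement = confinement,
                 k_bond = k_bond, dt = dt, gamma = gamma),
            class = "polymer_system")
}

#' @keywords internal
.conf_row <- function(geo, wall_k) {
  sh <- switch(geo$shape, none = 0, sphere = 1, cylinder = 2)
  c(sh, geo$R, if (is.na(geo$H)) 0 else geo$H, wall_k)
}

#' Run Langevin dynamics of the polymer, optionally driven by extruders
#'
#' Alternates blocks of `steps_per_extrusion` overdamped Langevin steps
#' with updates of the extruder bridge bonds (harmonic, same stiffness
#' as chain bonds). The extruder source may be an
#' `extrusion_trajectory` recorded with `record_bridges = TRUE` (one
#' bridge set per extrusion step), a static loop matrix from
#' [quench_loops()], or `NULL` for a free chain.
#'
#' @param system a [polymer_system()].
#' @param extruder_source `NULL`, an `extrusion_trajectory`, or a
#'   two-column matrix of 0-based quenched loop site pairs.
#' @param n_extrusion_steps number of extrusion-step blocks to run.
#' @param steps_per_extrusion polymer steps per extrusion step
#'   (adopted calibration: 540 steps per 0.5-s extrusion step).
#' @param sample_every record a frame every this many blocks (0 = none).
#' @param seed random seed.
#' @return a `trajectory3d`: list with `frames` (list of coordinate
#'   matrices), `frame_block`, `final`, `system`, and the integration
#'   metadata.
#' @export
run_polymer <- function(system, extruder_source = NULL,
                        n_extrusion_steps, steps_per_extrusion = 540,
                        sample_every = 10, seed = 1) {
  stopifnot(inherits(system, "polymer_system"), n_extrusion_steps >= 1)
  n <- nrow(system$coords)
  type_i <- match(system$types, c("A", "B", "C")) - 1L
  eps <- as.numeric(system$potential$eps)
  bridges <- list(); bridge_block <- integer(0)
  if (inherits(extruder_source, "extrusion_trajectory")) {
    if (is.null(extruder_source$bridge_offsets))
      stop("extrusion trajectory lacks bridges; rerun with ",
           "record_bridges = TRUE")
    if (extruder_source$config$L != n)
      stop("lattice length (", extruder_source$config$L,
           ") must equal polymer length (", n, "); the site-to-monomer ",
           "map is the identity")
    off <- extruder_source$bridge_offsets
    nb <- min(length(off) - 1, n_extrusion_steps)
    bridges <- vector("list", nb)
    for (k in seq_len(nb)) {
      idx <- if (off[k + 1] > off[k]) (off[k] + 1):off[k + 1] else
        integer(0)
      bridges[[k]] <- cbind(extruder_source$bridge_left[idx],
                            extruder_source$bridge_right[idx])
    }
    bridge_block <- seq_len(nb) - 1L
  } else if (is.matrix(extruder_source)) {
    if (nrow(extruder_source) > 0 &&
        max(extruder_source) >= n) stop("loop site outside the chain")
    bridges <- list(extruder_source)
    bridge_block <- 0L
  } else if (!is.null(extruder_source)) {
    stop("unsupported extruder source")
  }
  geo <- confinement_geometry(system$confinement, n)
  conf <- matrix(rep(c(.conf_row(geo, system$confinement$wall_k),
                       0, 0, 0, 0), each = n_extrusion_steps),
                 nrow = n_extrusion_steps)
  tether_k <- rep(if (isTRUE(system$confinement$tether)) system$k_bond
                  else 0, n_extrusion_steps)
  tether_z <- rep(if (is.na(geo$H)) 0 else geo$H, n_extrusion_steps)
  set.seed(seed)
  res <- run_polymer_cpp(system$coords, type_i, eps,
                         system$potential$E_repel, system$k_bond, 1.0,
                         system$dt, system$gamma,
                         as.integer(n_extrusion_steps),
                         as.integer(steps_per_extrusion),
                         bridges, bridge_block, conf,
                         tether_k, tether_z,
                         as.integer(sample_every),
                         system$potential$E_repel > 0 ||
                           any(eps > 0))
  structure(list(frames = res$frames, frame_block = res$frame_block,
                 final = res$final, system = system,
                 steps_per_extrusion = steps_per_extrusion,
                 seed = seed),
            class = "trajectory3d")
}

#' Per-frame conformation summaries
#'
#' @param trajectory a `trajectory3d` or list of coordinate matrices.
#' @param region integer vector of monomer indices to summarize
#'   (default: all).
#' @param confinement optional [confinement_spec()] to check densities
#'   and wall violations against.
#' @param tol wall-violation tolerance in monomer diameters.
#' @return data.frame with per-frame `rg` (radius of gyration), and,
#'   when `confinement` is given, `density` (monomer volume inside the
#'   container / container volume) and `wall_violations`.
#' @export
summarize_conformation <- function(trajectory, region = NULL,
                                   confinement = NULL, tol = 0.5) {
  frames <- if (inherits(trajectory, "trajectory3d")) trajectory$frames
            else trajectory
  if (length(frames) == 0) stop("empty trajectory")
  n <- nrow(frames[[1]])
  if (is.null(region)) region <- seq_len(n)
  if (length(region) == 0) stop("empty region")
  out <- data.frame(frame = seq_along(frames))
  out$rg <- vapply(frames, function(f) {
    x <- f[region, , drop = FALSE]
    mu <- colMeans(x)
    sqrt(mean(rowSums((x - rep(mu, each = nrow(x)))^2)))
  }, numeric(1))
  if (!is.null(confinement) && confinement$shape != "none") {
    geo <- confinement_geometry(confinement, n)
    vol <- if (geo$shape == "sphere") 4 / 3 * pi * geo$R^3
           else 2 * pi * geo$R^2 * geo$H
    stats_ <- vapply(frames, function(f) {
      if (geo$shape == "sphere") {
        r <- sqrt(rowSums(f^2))
        inside <- r <= geo$R
        viol <- sum(r > geo$R + tol)
      } else {
        rr <- sqrt(f[, 1]^2 + f[, 2]^2)
        inside <- rr <= geo$R & abs(f[, 3]) <= geo$H
        viol <- sum(rr > geo$R + tol | abs(f[, 3]) > geo$H + tol)
      }
      c(sum(inside) * pi / 6 / vol, viol)
    }, numeric(2))
    out$density <- stats_[1, ]
    out$wall_violations <- stats_[2, ]
  }
  out
}
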