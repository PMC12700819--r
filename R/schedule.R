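#' Build the canonical M-to-G1 transition schedule
#'
#' Event clock (minutes, t = 0 at the start of data collection):
#' condensins I and II extrude during prometaphase (residence times 3
#' min and 1 h, mean separations 35 kb and 140 kb); over 15-17 min the
#' condensin I level transiently rises (separation 27 kb) and then ramps
#' to zero over 17-20 min; over 25-30 min the confining cylinder height
#' halves while density relaxes from 0.65 to 0.45; at t = 30 condensin
#' II is removed, CTCF sites and A/B affinities activate, and cohesin
#' (10 min residence) starts loading, rising linearly to one extruder
#' per 100 kb at t = 245; over 30-35 min the cylinder crosses over to a
#' sphere at density 0.25 (end tethers released). Collection windows:
#' PM [0,10), AT [20,30), EG1 [55,65), MG1 [115,125), LG1 [235,245).
#' All ramps are linear.
#'
#' @param overrides named list overriding schedule fields (e.g.
#'   `list(d_ci = 40)`); unknown names raise an error.
#' @return object of class `m2g1_schedule`.
#' @export
build_m2g1_schedule <- function(overrides = list()) {
  s <- list(
    tau0 = 0.5, steps_per_extrusion = 540, sigma_kb = 0.5,
    windows = list(PM = c(0, 10), AT = c(20, 30), EG1 = c(55, 65),
                   MG1 = c(115, 125), LG1 = c(235, 245)),
    equil = list(steps_1d = 36000, minutes_3d = 300),
    tau_ci = 180, tau_cii = 3600, tau_cohesin = 600,    # seconds
    d_ci = 35, d_ci_burst = 27, d_cii = 140, d_cohesin = 100,  # kb
    p_step = 0.5, q_ctcf = 0.5,
    t_ci_burst = c(15, 17), t_ci_off = c(17, 20),
    t_compact = c(25, 30), t_crossover = c(30, 35),
    t_ctcf = 30, t_cohesin = c(30, 245), t_end = 245,
    rho_pm = 0.65, rho_mid = 0.45, rho_g1 = 0.25,
    aspect = 4, eps_b = 0.05, eps_c = 0.9,
    ci_ramp_shape = "linear")
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(s))
    if (length(bad)) stop("unknown schedule parameter(s): ",
                          paste(bad, collapse = ", "))
    s[names(overrides)] <- overrides
    if (any(unlist(s[c("rho_pm", "rho_mid", "rho_g1")]) <= 0))
      stop("densities must be positive")
  }
  class(s) <- "m2g1_schedule"
  s
}

#' @keywords internal
.lin <- function(t, t0, t1, v0, v1) {
  v0 + (v1 - v0) * pmin(1, pmax(0, (t - t0) / (t1 - t0)))
}

#' Volumetric density at schedule time t (minutes)
#'
#' @param schedule an `m2g1_schedule`.
#' @param t time in minutes (negative = pre-collection equilibration).
#' @return density; vectorized over `t`.
#' @export
schedule_density <- function(schedule, t) {
  s <- schedule
  ifelse(t < s$t_compact[1], s$rho_pm,
  ifelse(t < s$t_compact[2],
         .lin(t, s$t_compact[1], s$t_compact[2], s$rho_pm, s$rho_mid),
  ifelse(t < s$t_crossover[2],
         .lin(t, s$t_crossover[1], s$t_crossover[2], s$rho_mid,
              s$rho_g1),
         s$rho_g1)))
}

#' Extruder target separations/counts at schedule time t
#'
#' @inheritParams schedule_density
#' @param L_kb lattice length in kb (target count = `L_kb / d`).
#' @return named vector of real-valued target counts for
#'   `condensinI`, `condensinII`, `cohesin`.
#' @export
schedule_targets <- function(schedule, t, L_kb) {
  s <- schedule
  n_ci <- if (t < s$t_ci_burst[1]) L_kb / s$d_ci
          else if (t < s$t_ci_burst[2])
            .lin(t, s$t_ci_burst[1], s$t_ci_burst[2],
                 L_kb / s$d_ci, L_kb / s$d_ci_burst)
          else if (t < s$t_ci_off[2])
            .lin(t, s$t_ci_off[1], s$t_ci_off[2],
                 L_kb / s$d_ci_burst, 0)
          else 0
  n_cii <- if (t < s$t_ctcf) L_kb / s$d_cii else 0
  n_coh <- if (t < s$t_cohesin[1]) 0
           else .lin(t, s$t_cohesin[1], s$t_cohesin[2], 0,
                     L_kb / s$d_cohesin)
  c(condensinI = n_ci, condensinII = n_cii, cohesin = n_coh)
}

#' Extruder species with a nonzero target at time t
#'
#' @inheritParams schedule_density
#' @return character vector of species names.
#' @export
schedule_species <- function(schedule, t) {
  tg <- schedule_targets(schedule, t, L_kb = 1000)
  names(tg)[tg > 0]
}

#' Confinement state at schedule time t
#'
#' Returns the two-wall description used by the polymer engine: during
#' the cylinder-to-sphere crossover both walls are present with
#' complementary stiffness ramps.
#'
#' @inheritParams schedule_density
#' @param n number of monomers.
#' @param aspect0 initial cylinder height:diameter ratio.
#' @param wall_k full wall stiffness.
#' @return list with elements `wallA`, `wallB` (shape, R, H, k),
#'   `tether` (logical) and `rho`.
#' @export
schedule_confinement <- function(schedule, t, n, aspect0 = NULL,
                                 wall_k = 30) {
  s <- schedule
  if (is.null(aspect0)) aspect0 <- s$aspect
  rho <- schedule_density(s, t)
  # cylinder geometry: height ramps to half over t_compact while the
  # radius accommodates the prescribed density
  cyl_geo <- function(rho_t, hfac) {
    # V = pi R^2 (2 H), H = hfac * aspect0 * Rc0 where Rc0 is the
    # full-height radius at this density
    H0 <- aspect0 * (n / (12 * aspect0 * s$rho_pm))^(1 / 3)
    H <- H0 * hfac
    V <- n * pi / 6 / rho_t
    R <- sqrt(V / (2 * pi * H))
    list(shape = 2, R = R, H = H)
  }
  hfac <- .lin(t, s$t_compact[1], s$t_compact[2], 1, 0.5)
  sph_R <- (n / (8 * s$rho_g1))^(1 / 3)
  if (t < s$t_crossover[1]) {
    wallA <- cyl_geo(rho, hfac); wallA$k <- wall_k
    wallB <- list(shape = 0, R = 0, H = 0, k = 0)
    tether <- TRUE
  } else if (t < s$t_crossover[2]) {
    w <- (t - s$t_crossover[1]) / diff(s$t_crossover)
    wallA <- cyl_geo(s$rho_mid, 0.5); wallA$k <- wall_k * (1 - w)
    wallB <- list(shape = 1, R = sph_R, H = 0, k = wall_k * w)
    tether <- FALSE
  } else {
    wallA <- list(shape = 0, R = 0, H = 0, k = 0)
    wallB <- list(shape = 1, R = sph_R, H = 0, k = wall_k)
    tether <- FALSE
  }
  list(wallA = wallA, wallB = wallB, tether = tether, rho = rho)
}

#' Affinities active at schedule time t
#'
#' @inheritParams schedule_density
#' @return named vector `c(A, B, C)` of homotypic affinities (kT).
#' @export
schedule_affinities <- function(schedule, t) {
  c(A = 0, B = if (t >= schedule$t_ctcf) schedule$eps_b else 0,
    C = schedule$eps_c)
}

#' Serialize / restore a schedule (round-trip parameter log)
#'
#' @param schedule an `m2g1_schedule`.
#' @return named list (the full parameter log); feed to
#'   [schedule_from_log()] to reconstruct an identical schedule.
#' @export
schedule_log <- function(schedule) {
  unclass(schedule)
}

#' @rdname schedule_log
#' @param log a list produced by [schedule_log()].
#' @export
schedule_from_log <- function(log) {
  structure(log, class = "m2g1_schedule")
}
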