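#' Lattice configuration for the 1D loop-extrusion engine
#'
#' @param L number of lattice sites (the adopted chromosome is 61,600
#'   sites of 0.5 kb).
#' @param sigma site size in kb.
#' @param tau0 extrusion timestep in seconds.
#' @return object of class `lattice_config`.
#' @export
lattice_config <- function(L, sigma = 0.5, tau0 = 0.5) {
  stopifnot(L >= 2, sigma > 0, tau0 > 0)
  structure(list(L = as.integer(L), sigma = sigma, tau0 = tau0),
            class = "lattice_config")
}

#' Define a loop-extruder species
#'
#' The target number of bound extruders is `N = L * sigma / d_target`;
#' extruders unload stochastically with per-step probability
#' `1 - exp(-tau0 / tau_res)` (exact discretization of an exponential
#' residence time at rate `1/tau_res`).
#'
#' @param name species label.
#' @param tau_res mean residence time in seconds (`Inf` = never unload).
#' @param d_target mean genomic separation between extruders in kb
#'   (`NA`/`Inf` = target count 0).
#' @param p per-leg step probability per timestep; the unobstructed loop
#'   growth velocity is `v = 2 * p * sigma / tau0`.
#' @param respects_ctcf can this species stall at CTCF sites?
#' @param q_stall stall probability at a correctly oriented CTCF site.
#' @return one-row data.frame; rbind rows to build a species table.
#' @export
extruder_species <- function(name, tau_res = Inf, d_target = NA,
                             p = 0.5, respects_ctcf = FALSE,
                             q_stall = 0.5) {
  stopifnot(tau_res > 0, p >= 0, p <= 1, q_stall >= 0, q_stall <= 1,
            is.na(d_target) || d_target > 0)
  data.frame(name = name, tau_res = tau_res, d_target = d_target,
             p = p, respects_ctcf = respects_ctcf, q_stall = q_stall,
             stringsAsFactors = FALSE)
}

#' @keywords internal
.species_targets <- function(species, config) {
  d <- species$d_target
  ifelse(is.na(d) | !is.finite(d), 0, config$L * config$sigma / d)
}

#' Run the 1D loop-extrusion simulation
#'
#' Each timestep applies, in order: stochastic unloading, enforcement of
#' the (possibly time-varying) target count per species (random unload
#' on ramp-down, loading at uniformly drawn adjacent free site pairs on
#' ramp-up; fractional targets are stochastically rounded), then
#' translocation of extruders in a random permutation, each leg stepping
#' outward independently with probability `p` unless stalled, blocked by
#' another leg, or at a lattice end. Blocked steps are lost. A
#' CTCF-respecting leg stepping onto a correctly oriented CTCF site
#' stalls there permanently (until unload) with probability `q_stall`
#' ("+" sites stall legs moving toward lower indices, "-" sites legs
#' moving toward higher indices).
#'
#' @param config a [lattice_config()].
#' @param species species table (rbind of [extruder_species()] rows).
#' @param ctcf `NULL`, or data.frame with columns `site` (0-based
#'   lattice index) and `orientation` (`"+"`/`"-"`).
#' @param n_steps number of extrusion timesteps (>= 1).
#' @param target_schedule `NULL` for constant targets, or a numeric
#'   matrix with `n_steps` rows and one named column per species giving
#'   the (real-valued) target count at each step.
#' @param stride snapshot sampling stride in steps.
#' @param init optional initial [extruder_state()].
#' @param seed random seed (`NULL` = leave RNG state alone).
#' @param record_bridges record leg positions at every step (needed to
#'   drive the 3D polymer engine)?
#' @param quench freeze dynamics: extruders stay exactly where they are.
#' @return an `extrusion_trajectory`: list with `frames` (data.frame:
#'   frame, uid, species, left, right, stall flags), `episodes_steps`
#'   (completed bound-episode durations), `final` ([extruder_state()]),
#'   `config`, `species`, and (optionally) per-step `bridges`.
#' @export
run_extrusion <- function(config, species, ctcf = NULL, n_steps,
                          target_schedule = NULL, stride = 1L,
                          init = NULL, seed = NULL,
                          record_bridges = FALSE, quench = FALSE) {
  stopifnot(inherits(config, "lattice_config"), n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(species)
  if (is.null(target_schedule)) {
    tg <- matrix(rep(.species_targets(species, config), each = n_steps),
                 nrow = n_steps)
  } else {
    stopifnot(is.matrix(target_schedule),
              nrow(target_schedule) == n_steps)
    if (!all(colnames(target_schedule) %in% species$name))
      stop("target schedule references unknown species: ",
           paste(setdiff(colnames(target_schedule), species$name),
                 collapse = ", "))
    tg <- matrix(0, n_steps, ns)
    tg[, match(colnames(target_schedule), species$name)] <-
      target_schedule
  }
  if (is.null(ctcf)) ctcf <- data.frame(site = integer(0),
                                        orientation = character(0))
  if (is.null(init)) {
    init <- list(left = integer(0), right = integer(0),
                 species = integer(0), left_stalled = logical(0),
                 right_stalled = logical(0))
  } else {
    sp <- init$species
    if (is.character(sp)) sp <- match(sp, species$name) - 1L
    init <- list(left = as.integer(init$left),
                 right = as.integer(init$right),
                 species = as.integer(sp),
                 left_stalled = if (is.null(init$left_stalled))
                   rep(FALSE, length(init$left)) else init$left_stalled,
                 right_stalled = if (is.null(init$right_stalled))
                   rep(FALSE, length(init$right)) else init$right_stalled)
  }
  p_unload <- ifelse(is.finite(species$tau_res),
                     1 - exp(-config$tau0 / species$tau_res), 0)
  res <- run_extrusion_cpp(
    config$L, as.integer(n_steps),
    species$p, p_unload, species$respects_ctcf, species$q_stall,
    tg, as.integer(ctcf$site),
    ifelse(as.character(ctcf$orientation) == "+", 1L, -1L),
    init$left, init$right, init$species,
    init$left_stalled, init$right_stalled,
    as.integer(stride), record_bridges, quench)
  frames <- as.data.frame(res$frames)
  frames$species <- species$name[frames$species + 1L]
  final <- res$final
  final$species <- species$name[final$species + 1L]
  class(final) <- "extruder_state"
  out <- list(frames = frames, episodes_steps = res$episodes,
              final = final, config = config, species = species,
              n_steps = n_steps, stride = stride)
  if (record_bridges) {
    out$bridge_left <- res$bridge_left
    out$bridge_right <- res$bridge_right
    out$bridge_offsets <- res$bridge_offsets
  }
  class(out) <- "extrusion_trajectory"
  out
}

#' Construct an extruder state
#'
#' @param left,right 0-based leg positions (`left <= right`).
#' @param species species names or 0-based indices.
#' @param left_stalled,right_stalled stall flags.
#' @return object of class `extruder_state`.
#' @export
extruder_state <- function(left = integer(0), right = integer(0),
                           species = integer(0),
                           left_stalled = rep(FALSE, length(left)),
                           right_stalled = rep(FALSE, length(left))) {
  stopifnot(length(left) == length(right), all(left <= right),
            !anyDuplicated(c(left, right)))
  structure(list(left = as.integer(left), right = as.integer(right),
                 species = species, left_stalled = left_stalled,
                 right_stalled = right_stalled),
            class = "extruder_state")
}

#' Apply one extrusion timestep to a state
#'
#' @inheritParams run_extrusion
#' @param state an [extruder_state()].
#' @return the updated `extruder_state`.
#' @export
step_extrusion <- function(state, config, species, ctcf = NULL,
                           seed = NULL) {
  run_extrusion(config, species, ctcf, n_steps = 1, init = state,
                seed = seed)$final
}

#' Freeze the current loops of a state
#'
#' @param state an [extruder_state()] (or `$final` of a trajectory).
#' @return integer matrix with columns `left`, `right` (0-based site
#'   pairs) to be used as permanent bridges.
#' @export
quench_loops <- function(state) {
  cbind(left = as.integer(state$left), right = as.integer(state$right))
}

#' Mean unobstructed loop-extension velocity from a trajectory
#'
#' Averages d(loop size)/dt over transitions between consecutive
#' snapshots of each extruder in which neither leg is stalled or sitting
#' at a lattice boundary. For a single unobstructed extruder this
#' estimates `v = 2 * p * sigma / tau0`.
#'
#' @param trajectory an `extrusion_trajectory`.
#' @return velocity in kb/s.
#' @export
measure_extension_velocity <- function(trajectory) {
  fr <- trajectory$frames
  if (nrow(fr) == 0) stop("empty trajectory")
  cfg <- trajectory$config
  tot_d <- 0; tot_t <- 0
  for (id in unique(fr$uid)) {
    g <- fr[fr$uid == id, ]
    g <- g[order(g$frame), ]
    if (nrow(g) < 2) next
    ok <- !g$left_stalled & !g$right_stalled &
          g$left > 0 & g$right < cfg$L - 1
    use <- ok[-nrow(g)] & ok[-1]
    dsize <- diff(g$right - g$left)[use]
    dtt <- diff(g$frame)[use]
    tot_d <- tot_d + sum(dsize)
    tot_t <- tot_t + sum(dtt)
  }
  if (tot_t == 0) stop("no unobstructed growth episodes in trajectory")
  (tot_d * cfg$sigma) / (tot_t * cfg$tau0)
}

#' Convert CTCF peaks (BED-style GRanges) to lattice sites
#'
#' @param gr `GRanges` of CTCF peaks with strand = motif orientation.
#' @param config a [lattice_config()].
#' @return data.frame with `site` (0-based) and `orientation`.
#' @export
ctcf_sites_from_granges <- function(gr, config) {
  mid <- (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
  site <- pmin(config$L - 1L,
               as.integer(mid / (config$sigma * 1000)))
  data.frame(site = site,
             orientation = as.character(GenomicRanges::strand(gr)))
}
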