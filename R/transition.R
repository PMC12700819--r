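#' Species table for the M-to-G1 protocol
#'
#' @param schedule an `m2g1_schedule`.
#' @return species table (condensin I, condensin II, cohesin) with the
#'   schedule's residence times; only cohesin respects CTCF.
#' @export
m2g1_species <- function(schedule) {
  rbind(
    extruder_species("condensinI", tau_res = schedule$tau_ci,
                     d_target = schedule$d_ci, p = schedule$p_step),
    extruder_species("condensinII", tau_res = schedule$tau_cii,
                     d_target = schedule$d_cii, p = schedule$p_step),
    extruder_species("cohesin", tau_res = schedule$tau_cohesin,
                     d_target = schedule$d_cohesin, p = schedule$p_step,
                     respects_ctcf = TRUE, q_stall = schedule$q_ctcf))
}

#' Convergent CTCF site pairs on a typed chain
#'
#' Places one convergent pair per fraction pair per locus copy, using
#' the orientation convention of the extrusion engine ("+" stalls legs
#' moving toward lower indices, so the lower site of a pair is "+").
#'
#' @param typing a `monomer_typing`.
#' @param pair_fracs list of length-2 numeric vectors: positions of the
#'   (low, high) site of each pair as fractions of the locus length.
#' @return data.frame with `site` (0-based lattice index),
#'   `orientation`, and `pair` id.
#' @export
gen_ctcf_sites <- function(typing,
                           pair_fracs = list(c(0.15, 0.45),
                                             c(0.55, 0.85))) {
  lay <- typing$layout
  period <- lay$locus_monomers + lay$spacer_monomers
  out <- NULL
  pid <- 0
  for (cp in seq_len(lay$copies) - 1) {
    for (fr in pair_fracs) {
      pid <- pid + 1
      lo <- cp * period + round(fr[1] * lay$locus_monomers)
      hi <- cp * period + round(fr[2] * lay$locus_monomers)
      out <- rbind(out,
                   data.frame(site = c(lo, hi),
                              orientation = c("+", "-"), pair = pid))
    }
  }
  out
}

#' All microcompartment (C-C) anchor pairs within a separation range
#'
#' @param typing a `monomer_typing`.
#' @param sigma_kb kb per monomer.
#' @param min_sep_kb,max_sep_kb genomic separation limits (loops below
#'   10 kb are excluded from strength quantification to leave room for
#'   the local background).
#' @return two-column matrix of bp positions (C-block centers).
#' @export
microcompartment_pairs <- function(typing, sigma_kb = 0.5,
                                   min_sep_kb = 10, max_sep_kb = 300) {
  ctr <- (typing$c_anchors + (typing$layout$c_block - 1) / 2) *
         sigma_kb * 1000
  pr <- t(utils::combn(ctr, 2))
  sep <- abs(pr[, 2] - pr[, 1]) / 1000
  pr[sep >= min_sep_kb & sep <= max_sep_kb, , drop = FALSE]
}

#' Mean relative strength over a set of site pairs
#'
#' Scores every pair with [sim_window_strength()] (6-kb window,
#' relative to the mean contact count at each separation);
#' out-of-bounds pairs are skipped. The `"mean"` estimator averages
#' the per-pair ratios; the `"pooled"` estimator divides the summed
#' observed window counts by the summed expected counts, which is far
#' more stable when individual windows hold few contacts (sparse
#' desk-scale maps).
#'
#' @param map a `contact_map` of raw simulated counts.
#' @param pairs two-column matrix of bp positions.
#' @param window window edge in bp.
#' @param relative scale by distance-expected contacts?
#' @param estimator `"mean"` (mean of per-pair ratios) or `"pooled"`
#'   (ratio of sums).
#' @return mean strength (`NA` if no pair could be scored).
#' @export
mean_pair_strength <- function(map, pairs, window = 6000,
                               relative = TRUE,
                               estimator = c("mean", "pooled")) {
  estimator <- match.arg(estimator)
  if (estimator == "mean" || !relative) {
    vals <- apply(pairs, 1, function(pr) {
      tryCatch(sim_window_strength(map, pr, window, relative),
               error = function(e) NA_real_)
    })
    return(mean(vals, na.rm = TRUE))
  }
  v <- mean_by_separation(map$matrix)
  obs_sum <- 0; exp_sum <- 0
  for (k in seq_len(nrow(pairs))) {
    obs <- tryCatch(sim_window_strength(map, pairs[k, ], window,
                                        relative = FALSE),
                    error = function(e) NA_real_)
    if (is.na(obs)) next
    bb <- .loop_to_bins(map, pairs[k, ])
    e <- v[abs(bb[1, 2] - bb[1, 1]) + 1L]
    if (is.na(e) || e == 0) next
    obs_sum <- obs_sum + obs
    exp_sum <- exp_sum + e
  }
  if (exp_sum == 0) return(NA_real_)
  obs_sum / exp_sum
}

#' @keywords internal
.conf_matrix_from_schedule <- function(schedule, t_min, n, wall_k) {
  K <- length(t_min)
  conf <- matrix(0, K, 8)
  tether <- numeric(K); tz <- numeric(K)
  for (k in seq_len(K)) {
    cs <- schedule_confinement(schedule, t_min[k], n, wall_k = wall_k)
    conf[k, ] <- c(cs$wallA$shape, cs$wallA$R, cs$wallA$H, cs$wallA$k,
                   cs$wallB$shape, cs$wallB$R, cs$wallB$H, cs$wallB$k)
    tether[k] <- if (cs$tether) wall_k else 0
    tz[k] <- if (cs$wallA$shape == 2) cs$wallA$H else 0
  }
  list(conf = conf, tether_k = tether, tether_z = tz)
}

#' Run the full M-to-G1 transition simulation
#'
#' Executes the protocol end to end at a reduced scale: 1D extruder
#' pre-equilibration, 3D equilibration in the tethered cylinder at
#' prometaphase density, then the scheduled event clock (condensin I
#' burst and removal, compaction, condensin II removal, CTCF and A/B
#' affinity activation, cylinder-to-sphere crossover, linear cohesin
#' loading), collecting conformations inside the five labeled windows
#' and building one contact map per window.
#'
#' `scale` compresses all durations; the chain itself is set by
#' `typing` (one locus copy plus spacer is the desk-scale default).
#'
#' @param schedule an `m2g1_schedule`.
#' @param typing a `monomer_typing`.
#' @param seed random seed.
#' @param scale duration scale factor in (0, 1].
#' @param steps_per_extrusion polymer steps per extrusion step.
#' @param ctcf CTCF site data.frame (default [gen_ctcf_sites()]).
#' @param frames_per_window target number of sampled frames per window.
#' @param dt,k_bond,wall_k,gamma polymer integration parameters.
#' @param potential a [potential_params()]; its B affinity is activated
#'   only from the scheduled time on.
#' @return an `m2g1_run`: list with `windows` (per window: `frames`,
#'   `map`), `param_log`, `typing`, `ctcf`, `schedule`, `scale`,
#'   `seed`, `manifest`.
#' @export
run_transition <- function(schedule, typing = gen_monomer_typing(),
                           seed = 1, scale = 0.1,
                           steps_per_extrusion = NULL,
                           ctcf = gen_ctcf_sites(typing),
                           frames_per_window = 25,
                           dt = 0.0025, k_bond = 30, wall_k = 30,
                           gamma = 1,
                           potential = potential_params()) {
  stopifnot(inherits(schedule, "m2g1_schedule"), scale > 0, scale <= 1)
  if (is.null(steps_per_extrusion))
    steps_per_extrusion <- schedule$steps_per_extrusion
  n <- length(typing$types)
  cfg <- lattice_config(n, schedule$sigma_kb, schedule$tau0)
  L_kb <- n * schedule$sigma_kb
  species <- m2g1_species(schedule)
  spm <- 60 / schedule$tau0 * scale      # extrusion steps per minute
  t_pre <- schedule$equil$minutes_3d
  K <- round((t_pre + schedule$t_end) * spm)
  t_of <- function(k) k / spm - t_pre    # unscaled schedule minutes
  set.seed(seed)

  # 1D pre-equilibration at prometaphase parameters
  pm_targets <- schedule_targets(schedule, -t_pre, L_kb)
  n1 <- max(10, round(schedule$equil$steps_1d * scale))
  tg1 <- matrix(rep(pm_targets, each = n1), nrow = n1,
                dimnames = list(NULL, names(pm_targets)))
  eq1 <- run_extrusion(cfg, species, ctcf, n1, target_schedule = tg1,
                       stride = n1)

  # main 1D run over the full clock, recording bridges every step
  tg <- t(vapply(seq_len(K), function(k)
    schedule_targets(schedule, t_of(k), L_kb), numeric(3)))
  colnames(tg) <- names(pm_targets)
  ext <- run_extrusion(cfg, species, ctcf, K, target_schedule = tg,
                       stride = max(1L, K %/% 200), init = eq1$final,
                       record_bridges = TRUE)

  # 3D run: split where the A/B affinities switch on
  t_vec <- t_of(seq_len(K))
  cm <- .conf_matrix_from_schedule(schedule, t_vec, n, wall_k)
  conf0 <- confinement_spec("cylinder", schedule$rho_pm,
                            schedule$aspect, wall_k, tether = TRUE)
  coords <- init_conformation(n, conf0, seed = seed)
  off <- ext$bridge_offsets
  bridges <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- if (off[k + 1] > off[k]) (off[k] + 1):off[k + 1] else
      integer(0)
    bridges[[k]] <- cbind(ext$bridge_left[idx], ext$bridge_right[idx])
  }
  window_len_steps <- 10 * spm
  sample_every <- max(1L, floor(window_len_steps / frames_per_window))
  type_i <- match(typing$types, c("A", "B", "C")) - 1L
  k_switch <- min(K, max(1, round((t_pre + schedule$t_ctcf) * spm)))
  seg <- list(seq_len(k_switch), if (k_switch < K) (k_switch + 1):K
              else integer(0))
  eps_pre <- c(0, 0, schedule$eps_c)
  eps_post <- c(0, schedule$eps_b, schedule$eps_c)
  frames <- list(); frame_block <- integer(0)
  for (si in seq_along(seg)) {
    ks <- seg[[si]]
    if (!length(ks)) next
    res <- run_polymer_cpp(coords, type_i,
                           if (si == 1) eps_pre else eps_post,
                           potential$E_repel, k_bond, 1.0, dt, gamma,
                           length(ks), as.integer(steps_per_extrusion),
                           bridges[ks], seq_along(ks) - 1L,
                           cm$conf[ks, , drop = FALSE],
                           cm$tether_k[ks], cm$tether_z[ks],
                           as.integer(sample_every), TRUE)
    frames <- c(frames, res$frames)
    frame_block <- c(frame_block, res$frame_block + ks[1] - 1L)
    coords <- res$final
  }
  frame_t <- t_of(frame_block)
  windows <- lapply(schedule$windows, function(w) {
    sel <- frame_t >= w[1] & frame_t < w[2]
    if (!any(sel))
      stop("collection window [", w[1], ",", w[2],
           ") received no frames; decrease the sampling stride")
    fs <- frames[sel]
    list(frames = fs, t = frame_t[sel],
         map = contact_map_from_trajectory(fs, radius = 4, bin = 4,
                                           sigma_kb = schedule$sigma_kb))
  })
  log_idx <- unique(round(seq(1, K, length.out = min(K, 500))))
  param_log <- data.frame(
    t = t_vec[log_idx],
    density = schedule_density(schedule, t_vec[log_idx]),
    tg[log_idx, , drop = FALSE],
    eps_B = ifelse(t_vec[log_idx] >= schedule$t_ctcf,
                   schedule$eps_b, 0))
  structure(list(windows = windows, param_log = param_log,
                 typing = typing, ctcf = ctcf, schedule = schedule,
                 scale = scale, seed = seed,
                 manifest = list(seed = seed, scale = scale,
                                 steps_per_extrusion = steps_per_extrusion,
                                 n_monomers = n, n_extrusion_steps = K,
                                 dt = dt, k_bond = k_bond,
                                 wall_k = wall_k)),
            class = "m2g1_run")
}

#' Per-window mean microcompartment and CTCF loop strengths of a run
#'
#' @param run an `m2g1_run`.
#' @param max_sep_kb separation cap for C-C pairs.
#' @param estimator see [mean_pair_strength()].
#' @return data.frame with one row per window: `cc` (mean relative C-C
#'   strength) and `ctcf` (mean relative strength at convergent CTCF
#'   pairs).
#' @export
transition_strengths <- function(run, max_sep_kb = 300,
                                 estimator = "pooled") {
  ccp <- microcompartment_pairs(run$typing,
                                run$schedule$sigma_kb,
                                max_sep_kb = max_sep_kb)
  sig <- run$schedule$sigma_kb * 1000
  cp <- do.call(rbind, lapply(split(run$ctcf, run$ctcf$pair),
                              function(g) (g$site + 0.5) * sig))
  out <- data.frame(window = names(run$windows),
                    cc = NA_real_, ctcf = NA_real_)
  for (i in seq_along(run$windows)) {
    m <- run$windows[[i]]$map
    out$cc[i] <- mean_pair_strength(m, ccp, estimator = estimator)
    out$ctcf[i] <- mean_pair_strength(m, cp, estimator = estimator)
  }
  out
}

#' Steady-state parameter sweep
#'
#' One equilibrated run per grid point per seed: 1D extruder
#' equilibration (optionally followed by a quench that freezes the
#' loops), then 3D Langevin dynamics with active (or quenched)
#' extrusion, a plateau check, and collection of a contact map. Sweeps
#' run without CTCF sites; fixed defaults are one extruder per 100 kb
#' and density 0.25.
#'
#' @param grid data.frame; recognized columns: `rho`, `eps_C`,
#'   `tau_res` (s), `d` (kb), `p`. Missing columns use the defaults.
#' @param typing a `monomer_typing` (the chain for every run).
#' @param seeds integer vector of seeds (one run per grid x seed).
#' @param n_equil_1d 1D equilibration steps.
#' @param blocks_equil,blocks_collect 3D extrusion-step blocks for
#'   equilibration and collection.
#' @param steps_per_extrusion polymer steps per block.
#' @param quench freeze loops after 1D equilibration?
#' @param sample_every frame sampling stride (blocks) during collection.
#' @param dt,k_bond,wall_k integration parameters.
#' @param max_sep_kb separation cap for the C-C strength summary.
#' @param estimator see [mean_pair_strength()]; the pooled estimator
#'   is the stable choice for sparse desk-scale maps.
#' @return list with `summary` (one row per run: grid values, seed,
#'   `cc_strength`, `equilibrated`) and `maps` (list of contact maps).
#' @export
run_steady_state <- function(grid, typing, seeds = 1:5,
                             n_equil_1d = 20000,
                             blocks_equil = 400, blocks_collect = 400,
                             steps_per_extrusion = 60,
                             quench = FALSE, sample_every = 5,
                             dt = 0.0025, k_bond = 30, wall_k = 30,
                             max_sep_kb = 300, estimator = "pooled") {
  stopifnot(nrow(grid) >= 1)
  defaults <- list(rho = 0.25, eps_C = 0.9, tau_res = 600, d = 100,
                   p = 0.5)
  for (nm in names(defaults))
    if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  n <- length(typing$types)
  rows <- list(); maps <- list(); ri <- 0
  for (g in seq_len(nrow(grid))) {
    for (sd in seeds) {
      ri <- ri + 1
      res <- .steady_state_one(grid[g, ], typing, sd, n_equil_1d,
                               blocks_equil, blocks_collect,
                               steps_per_extrusion, quench,
                               sample_every, dt, k_bond, wall_k,
                               max_sep_kb, estimator)
      rows[[ri]] <- cbind(grid[g, ], seed = sd,
                          cc_strength = res$cc_strength,
                          equilibrated = res$equilibrated)
      maps[[ri]] <- res$map
    }
  }
  list(summary = do.call(rbind, rows), maps = maps)
}

#' @keywords internal
.steady_state_one <- function(par, typing, seed, n_equil_1d,
                              blocks_equil, blocks_collect,
                              steps_per_extrusion, quench,
                              sample_every, dt, k_bond, wall_k,
                              max_sep_kb, estimator = "pooled") {
  n <- length(typing$types)
  cfg <- lattice_config(n, 0.5, 0.5)
  sp <- extruder_species("generic", tau_res = par$tau_res,
                         d_target = par$d, p = par$p)
  set.seed(seed)
  eq1 <- run_extrusion(cfg, sp, NULL, n_equil_1d, stride = n_equil_1d)
  K <- blocks_equil + blocks_collect
  pot <- potential_params(eps = c(A = 0, B = 0.05, C = par$eps_C))
  conf <- confinement_spec("sphere", rho = par$rho, wall_k = wall_k)
  sys <- polymer_system(typing, pot, conf, k_bond = k_bond, dt = dt,
                        seed = seed)
  if (quench) {
    src <- quench_loops(eq1$final)
  } else {
    src <- run_extrusion(cfg, sp, NULL, K, init = eq1$final,
                         stride = K, record_bridges = TRUE)
  }
  traj <- run_polymer(sys, src, n_extrusion_steps = K,
                      steps_per_extrusion = steps_per_extrusion,
                      sample_every = sample_every, seed = seed + 1000)
  keep <- traj$frame_block > blocks_equil
  frames <- traj$frames[keep]
  summ <- summarize_conformation(traj)
  eqflag <- .plateau_check(summ$rg)
  if (!eqflag)
    warning("equilibration diagnostics have not plateaued (seed ",
            seed, ")")
  map <- contact_map_from_trajectory(frames, radius = 4, bin = 4)
  ccp <- microcompartment_pairs(typing, max_sep_kb = max_sep_kb)
  list(cc_strength = mean_pair_strength(map, ccp,
                                        estimator = estimator),
       map = map, equilibrated = eqflag)
}

#' Windowed plateau check on an equilibration diagnostic
#'
#' Relative change of the windowed mean over the last third of the
#' series must be below `tol`.
#'
#' @param x numeric diagnostic series (e.g. radius of gyration).
#' @param tol relative-change tolerance.
#' @return logical.
#' @keywords internal
.plateau_check <- function(x, tol = 0.02) {
  x <- x[is.finite(x)]
  if (length(x) < 6) return(TRUE)
  last3 <- x[seq(floor(2 * length(x) / 3) + 1, length(x))]
  half <- length(last3) %/% 2
  m1 <- mean(last3[seq_len(half)])
  m2 <- mean(last3[seq(half + 1, length(last3))])
  abs(m2 - m1) <= tol * abs(m1)
}

#' Spatial cluster sizes of microcompartment anchors
#'
#' For each frame, C-anchor centers closer than `cutoff` monomer
#' diameters are linked and connected components are extracted;
#' clusters of at least two anchors are collected across frames.
#'
#' @param frames list of coordinate matrices.
#' @param typing a `monomer_typing`.
#' @param cutoff linkage distance in monomer diameters (default 2: two
#'   anchors whose centers are within twice the attraction midpoint).
#' @return list with `sizes` (all multi-anchor cluster sizes) and
#'   `median_size`.
#' @export
anchor_cluster_sizes <- function(frames, typing, cutoff = 2.0) {
  ctr <- typing$c_anchors + (typing$layout$c_block - 1) %/% 2
  sizes <- integer(0)
  for (f in frames) {
    x <- f[ctr, , drop = FALSE]
    d <- as.matrix(stats::dist(x))
    adj <- d <= cutoff
    seen <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(x))) {
      if (seen[i]) next
      comp <- i; frontier <- i; seen[i] <- TRUE
      while (length(frontier)) {
        nb <- which(adj[frontier[1], ] & !seen)
        seen[nb] <- TRUE
        comp <- c(comp, nb)
        frontier <- c(frontier[-1], nb)
      }
      if (length(comp) >= 2) sizes <- c(sizes, length(comp))
    }
  }
  list(sizes = sizes,
       median_size = if (length(sizes)) stats::median(sizes) else
         NA_real_)
}
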