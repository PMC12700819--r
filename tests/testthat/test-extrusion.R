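one_species <- function(p = 0.5, tau = Inf, d = NA, ctcf = FALSE,
                        q = 0.5) {
  extruder_species("x", tau_res = tau, d_target = d, p = p,
                   respects_ctcf = ctcf, q_stall = q)
}

# keep a single pre-placed extruder alive without loading new ones
hold_one <- function(n_steps) {
  matrix(1, n_steps, 1, dimnames = list(NULL, "x"))
}

test_that("unobstructed loop growth velocity equals 2*p*sigma/tau0", {
  cfg <- lattice_config(30000, sigma = 0.5, tau0 = 0.5)
  tr <- run_extrusion(cfg, one_species(p = 0.5), NULL, 12000,
                      target_schedule = hold_one(12000), stride = 10,
                      seed = 11)
  expect_equal(measure_extension_velocity(tr), 1.0, tolerance = 0.02)
  tr2 <- run_extrusion(cfg, one_species(p = 1), NULL, 3000,
                       target_schedule = hold_one(3000), stride = 5,
                       seed = 12)
  expect_equal(measure_extension_velocity(tr2), 2.0, tolerance = 0.02)
})

test_that("p = 0 freezes leg positions; only load/unload acts", {
  cfg <- lattice_config(100)
  init <- extruder_state(left = 40, right = 50, species = "x")
  tr <- run_extrusion(cfg, one_species(p = 0), NULL, 200,
                      target_schedule = hold_one(200), init = init,
                      seed = 3)
  expect_true(all(tr$frames$left == 40))
  expect_true(all(tr$frames$right == 50))
})

test_that("two-site lattice pins both legs at the boundaries", {
  cfg <- lattice_config(2)
  init <- extruder_state(left = 0, right = 1, species = "x")
  tr <- run_extrusion(cfg, one_species(p = 1), NULL, 50,
                      target_schedule = hold_one(50), init = init,
                      seed = 4)
  expect_true(all(tr$frames$left == 0 & tr$frames$right == 1))
})

test_that("occupancy exclusivity and leg ordering hold after every step", {
  cfg <- lattice_config(300)
  sp <- one_species(p = 0.5, tau = 60, d = 15)   # crowded lattice
  tr <- run_extrusion(cfg, sp, NULL, 400, stride = 1, seed = 5)
  for (f in split(tr$frames, tr$frames$frame)) {
    expect_true(all(f$left <= f$right))
    expect_false(anyDuplicated(c(f$left, f$right)) > 0)
  }
})

test_that("steady-state bound count fluctuates around L*sigma/d", {
  cfg <- lattice_config(4000, sigma = 0.5)   # 2 Mb
  sp <- one_species(p = 0.5, tau = 100, d = 100)  # N = 20
  tr <- run_extrusion(cfg, sp, NULL, 100000, stride = 50, seed = 6)
  counts <- table(tr$frames$frame)
  counts <- counts[as.integer(names(counts)) > 20000]
  expect_equal(mean(counts), 20, tolerance = 0.05)
})

test_that("residence times are geometric with mean tau_res", {
  cfg <- lattice_config(4000)
  sp <- one_species(p = 0, tau = 50, d = 100)
  tr <- run_extrusion(cfg, sp, NULL, 60000, stride = 60000, seed = 7)
  ep <- tr$episodes_steps
  expect_gt(length(ep), 1e4)
  tau0 <- cfg$tau0
  expect_equal(mean(ep) * tau0, 50, tolerance = 0.05)
  # sup distance between empirical and geometric CDFs
  q <- 1 - exp(-tau0 / 50)
  ks <- max(abs(ecdf(ep)(1:600) - pgeom(0:599, q)))
  expect_lt(ks, 0.05)
})

test_that("engine matches an enumerated Markov chain on a 6-site lattice", {
  # one extruder on 6 sites, CTCF "+" at site 1 (stalls left-moving
  # legs), p = 0.4, q = 0.5, no load/unload. The oracle enumerates the
  # per-leg outcome distributions analytically and takes the 3-step
  # transition-matrix power; the engine is run as a Monte Carlo.
  L <- 6; p <- 0.4; q <- 0.5; ctcf_site <- 1
  states <- expand.grid(l = 0:(L - 1), r = 0:(L - 1), sl = 0:1,
                        sr = 0:1)
  states <- states[states$l < states$r, ]
  key <- function(l, r, sl, sr) paste(l, r, sl, sr)
  rownames(states) <- key(states$l, states$r, states$sl, states$sr)
  ns <- nrow(states)
  # leg outcome distribution: list of (newpos, newstall, prob)
  left_out <- function(l, sl, r) {
    if (sl == 1) return(list(list(l, 1, 1)))
    dest <- l - 1
    if (dest < 0 || dest == r) return(list(list(l, 0, 1)))
    if (dest == ctcf_site) {
      list(list(l, 0, 1 - p), list(dest, 1, p * q),
           list(dest, 0, p * (1 - q)))
    } else list(list(l, 0, 1 - p), list(dest, 0, p))
  }
  right_out <- function(r, sr, l) {
    if (sr == 1) return(list(list(r, 1, 1)))
    dest <- r + 1
    if (dest > L - 1 || dest == l) return(list(list(r, 0, 1)))
    list(list(r, 0, 1 - p), list(dest, 0, p))   # no "-" sites here
  }
  TM <- matrix(0, ns, ns, dimnames = list(rownames(states),
                                          rownames(states)))
  for (s in seq_len(ns)) {
    st <- states[s, ]
    for (lo in left_out(st$l, st$sl, st$r))
      for (ro in right_out(st$r, st$sr, lo[[1]])) {
        # legs move sequentially (left first), so the right leg sees
        # the left leg's new position; with l < r this cannot collide
        TM[s, key(lo[[1]], ro[[1]], lo[[2]], ro[[2]])] <-
          TM[s, key(lo[[1]], ro[[1]], lo[[2]], ro[[2]])] +
          lo[[3]] * ro[[3]]
      }
  }
  expect_equal(unname(rowSums(TM)), rep(1, ns))
  start <- key(2, 3, 0, 0)
  p3 <- (TM %*% TM %*% TM)[start, ]

  cfg <- lattice_config(L)
  sp <- one_species(p = p, ctcf = TRUE, q = q)
  ctcf <- data.frame(site = ctcf_site, orientation = "+")
  M <- 40000
  set.seed(8)
  init <- extruder_state(left = 2, right = 3, species = "x")
  tallies <- setNames(numeric(ns), rownames(states))
  for (rep in seq_len(M)) {
    fin <- run_extrusion(cfg, sp, ctcf, 3,
                         target_schedule = hold_one(3),
                         init = init)$final
    k <- key(fin$left, fin$right, as.integer(fin$left_stalled),
             as.integer(fin$right_stalled))
    tallies[k] <- tallies[k] + 1
  }
  freq <- tallies / M
  se <- sqrt(pmax(p3 * (1 - p3), 1e-6) / M)
  expect_true(all(abs(freq - p3) < 4 * se + 0.002))
})

test_that("a leg approaching an oriented CTCF site stalls with prob q", {
  cfg <- lattice_config(10)
  sp <- one_species(p = 1, ctcf = TRUE, q = 0.5)
  ctcf <- data.frame(site = 1, orientation = "+")
  set.seed(9)
  stalls <- replicate(2000, {
    fin <- run_extrusion(cfg, sp, ctcf, 1,
                         target_schedule = hold_one(1),
                         init = extruder_state(2, 3, "x"))$final
    fin$left_stalled
  })
  expect_equal(mean(stalls), 0.5, tolerance = 4 * sqrt(0.25 / 2000) / 0.5)
  # wrongly oriented site does not stall
  ctcf2 <- data.frame(site = 1, orientation = "-")
  set.seed(10)
  stalls2 <- replicate(300, {
    run_extrusion(cfg, sp, ctcf2, 1, target_schedule = hold_one(1),
                  init = extruder_state(2, 3, "x"))$final$left_stalled
  })
  expect_false(any(stalls2))
})

test_that("quenching freezes loops and yields distinct configurations", {
  st <- extruder_state(left = c(10, 100), right = c(40, 250),
                       species = c("x", "x"))
  expect_equal(quench_loops(st),
               cbind(left = c(10L, 100L), right = c(40L, 250L)))
  expect_equal(nrow(quench_loops(extruder_state())), 0)
  # frozen dynamics: loop sizes unchanged under further stepping
  cfg <- lattice_config(500)
  sp <- one_species(p = 0.5, tau = 100, d = 50)
  tr <- run_extrusion(cfg, sp, NULL, 2000, stride = 2000, seed = 11)
  qz <- run_extrusion(cfg, sp, NULL, 100, init = tr$final, stride = 1,
                      seed = 12, quench = TRUE)
  first <- qz$frames[qz$frames$frame == 0, c("left", "right")]
  last <- qz$frames[qz$frames$frame == 100, c("left", "right")]
  expect_equal(sort(first$left), sort(last$left))
  expect_equal(sort(first$right), sort(last$right))
  # independent equilibrated runs give distinct loop configurations
  loops <- lapply(1:10, function(s)
    quench_loops(run_extrusion(cfg, sp, NULL, 2000, stride = 2000,
                               seed = 100 + s)$final))
  expect_equal(length(unique(lapply(loops, function(m)
    paste(m[order(m[, 1]), ], collapse = ",")))), 10)
})

test_that("trajectories are reproducible and schedules are validated", {
  cfg <- lattice_config(200)
  sp <- one_species(p = 0.5, tau = 30, d = 20)
  a <- run_extrusion(cfg, sp, NULL, 300, seed = 13)
  b <- run_extrusion(cfg, sp, NULL, 300, seed = 13)
  expect_identical(a$frames, b$frames)
  bad <- matrix(1, 10, 1, dimnames = list(NULL, "nosuch"))
  expect_error(run_extrusion(cfg, sp, NULL, 10, target_schedule = bad),
               "unknown species")
  # target beyond available site pairs raises with a diagnostic
  cfg2 <- lattice_config(10)
  sp2 <- one_species(p = 0, d = 0.5)   # target = 10 > 10/2
  expect_error(run_extrusion(cfg2, sp2, NULL, 5),
               "exceeds|free adjacent")
})

test_that("lowering a species target unloads extruders immediately", {
  cfg <- lattice_config(1000)
  sp <- one_species(p = 0.2, tau = Inf, d = 20)   # 25 extruders
  tg <- matrix(c(rep(25, 50), rep(5, 50)), ncol = 1,
               dimnames = list(NULL, "x"))
  tr <- run_extrusion(cfg, sp, NULL, 100, target_schedule = tg,
                      stride = 1, seed = 14)
  counts <- tapply(tr$frames$uid, tr$frames$frame, length)
  expect_equal(unname(counts[["50"]]), 25)
  expect_equal(unname(counts[["51"]]), 5)
  expect_equal(unname(counts[["100"]]), 5)
})
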