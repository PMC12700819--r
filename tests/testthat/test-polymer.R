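no_interaction <- potential_params(E_repel = 0,
                                   eps = c(A = 0, B = 0, C = 0))

test_that("confined random-walk initial conformations respect geometry", {
  conf <- confinement_spec("sphere", rho = 0.25)
  R <- confinement_geometry(conf, 100)$R
  expect_equal(R, (100 / (8 * 0.25))^(1 / 3))
  x <- init_conformation(100, conf, seed = 2)
  expect_true(all(sqrt(rowSums(x^2)) <= R + 1e-9))
  # bond lengths at the harmonic equilibrium
  x2 <- init_conformation(2, conf, seed = 3)
  expect_equal(sqrt(sum(diff(x2)^2)), 1, tolerance = 1e-9)
  # determinism
  expect_identical(init_conformation(50, conf, seed = 4),
                   init_conformation(50, conf, seed = 4))
  expect_error(init_conformation(10, confinement_spec("sphere", 1.2)))
})

test_that("free-chain bond statistics match the Boltzmann average", {
  # harmonic bond k = 30, no nonbonded forces; oracle is the 1D radial
  # integral <r^2> = int r^4 e^{-k(r-1)^2/2} / int r^2 e^{-k(r-1)^2/2}
  sys <- polymer_system(rep("A", 40), no_interaction,
                        confinement_spec("none"), k_bond = 30,
                        dt = 5e-4, seed = 5)
  tr <- run_polymer(sys, NULL, n_extrusion_steps = 360,
                    steps_per_extrusion = 200, sample_every = 2,
                    seed = 6)
  fs <- tr$frames[-(1:40)]
  msb <- mean(sapply(fs, function(f) mean(rowSums(diff(f)^2))))
  k <- 30
  num <- integrate(function(r) r^4 * exp(-k / 2 * (r - 1)^2), 0, 10)$value
  den <- integrate(function(r) r^2 * exp(-k / 2 * (r - 1)^2), 0, 10)$value
  expect_equal(msb, num / den, tolerance = 0.02)
})

test_that("trajectories are bit-identical under identical seeds", {
  sys <- polymer_system(rep("A", 30), potential_params(),
                        confinement_spec("sphere", 0.2), dt = 0.01,
                        seed = 7)
  a <- run_polymer(sys, NULL, 20, 50, sample_every = 5, seed = 8)
  b <- run_polymer(sys, NULL, 20, 50, sample_every = 5, seed = 8)
  expect_identical(a$frames, b$frames)
})

test_that("a bridged pair stays closer than an unbridged control", {
  n <- 220
  mk <- function(bridge) {
    sys <- polymer_system(rep("A", n), potential_params(),
                          confinement_spec("none"), dt = 0.01, seed = 9)
    run_polymer(sys, bridge, 80, 60, sample_every = 2, seed = 10)
  }
  bridged <- mk(cbind(10L, 210L))
  free <- mk(NULL)
  dist_ij <- function(tr) mean(sapply(tr$frames[-(1:10)], function(f)
    sqrt(sum((f[11, ] - f[211, ])^2))))
  expect_lt(dist_ij(bridged), 0.5 * dist_ij(free))
})

test_that("excluded-volume chain has a swollen Rg scaling exponent", {
  pot <- potential_params(eps = c(A = 0, B = 0, C = 0))  # repulsion only
  sys <- polymer_system(rep("A", 150), pot, confinement_spec("none"),
                        dt = 0.01, seed = 11)
  tr <- run_polymer(sys, NULL, 500, 300, sample_every = 5, seed = 12)
  fs <- tr$frames[-(1:40)]
  seps <- c(8, 16, 32, 64)
  msd <- sapply(seps, function(s) {
    mean(sapply(fs, function(f) {
      i <- seq(1, 150 - s, by = 3)
      mean(rowSums((f[i + s, , drop = FALSE] -
                    f[i, , drop = FALSE])^2))
    }))
  })
  nu <- coef(lm(log(msd) ~ log(seps)))[2] / 2
  expect_gt(nu, 0.5)
  expect_lt(nu, 0.68)
})

test_that("homotypic attraction produces focal C-C enrichment; none without", {
  ty <- mini_typing(locus = 330, spacer = 110,
                    anchors = seq(30, 300, 30))
  run_map <- function(epsC) {
    pot <- potential_params(eps = c(A = 0, B = 0, C = epsC))
    sys <- polymer_system(ty, pot, confinement_spec("sphere", 0.35),
                          dt = 0.005, seed = 13)
    tr <- run_polymer(sys, NULL, 2000, 60, sample_every = 10,
                      seed = 14)
    contact_map_from_trajectory(tr$frames[-(1:60)])
  }
  pairs <- microcompartment_pairs(ty, max_sep_kb = 160)
  s_off <- mean_pair_strength(run_map(0), pairs, window = 2000)
  s_on <- mean_pair_strength(run_map(1.2), pairs, window = 2000)
  expect_equal(s_off, 1, tolerance = 0.2)   # no interaction: null
  expect_gt(s_on, 1.2)
  expect_gt(s_on, s_off + 0.15)
})

test_that("conformation summaries give closed-form Rg and density checks", {
  f0 <- list(matrix(0, 10, 3))
  expect_equal(summarize_conformation(f0)$rg, 0)
  f2 <- list(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(summarize_conformation(f2)$rg, 1)
  expect_error(summarize_conformation(f2, region = integer(0)),
               "empty region")
  # equilibrated confined chain sits near the prescribed density
  conf <- confinement_spec("sphere", rho = 0.25, wall_k = 50)
  sys <- polymer_system(rep("A", 300), potential_params(), conf,
                        dt = 0.005, seed = 15)
  tr <- run_polymer(sys, NULL, 300, 60, sample_every = 10, seed = 16)
  s <- summarize_conformation(tr, confinement = conf)
  expect_equal(mean(tail(s$density, 5)), 0.25, tolerance = 0.1)
  expect_true(all(tail(s$wall_violations, 5) <= 0.02 * 300))
})

test_that("mismatched lattice and polymer lengths are rejected", {
  cfg <- lattice_config(50)
  sp <- extruder_species("x", tau_res = Inf, d_target = 25)
  tr <- run_extrusion(cfg, sp, NULL, 10, record_bridges = TRUE,
                      seed = 17)
  sys <- polymer_system(rep("A", 40), potential_params(),
                        confinement_spec("none"), seed = 18)
  expect_error(run_polymer(sys, tr, 10, 10), "identity|length")
})
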