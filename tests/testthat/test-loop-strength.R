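test_that("local background reproduces pure distance-decay fields exactly", {
  g <- gen_synthetic_map(n_bins = 240, base = 150, decay_exponent = -1,
                         noise = "none", seed = 31)
  loop <- c(60, 120) * 500    # bins 61 and 121
  bg <- local_background_matrix(g$map, loop)
  obs <- g$map$matrix[51:71, 111:131]
  expect_equal(bg, obs, tolerance = 1e-12)
  expect_equal(loop_strength(g$map, loop, "bg_subtracted"), 0,
               tolerance = 1e-8)
  expect_equal(loop_strength(g$map, loop, "obs_over_exp"), 1,
               tolerance = 1e-10)
})

test_that("uniform maps give constant background windows", {
  mu <- contact_map(matrix(7, 80, 80), 500)
  bg <- local_background_matrix(mu, c(20 * 500, 60 * 500))
  expect_true(all(bg == 7))
})

test_that("background equals brute-force same-separation averaging", {
  map <- random_symmetric_map(200, seed = 32)
  bi <- 80; bj <- 140
  bg <- local_background_matrix(map, c((bi - 0.5) * 500,
                                       (bj - 0.5) * 500))
  oracle <- brute_background(map, bi, bj, 10, 1e5)
  expect_equal(bg, oracle, tolerance = 1e-12)
  # translation equivariance of windowed scores
  shift <- 13
  m2 <- map$matrix[(1 + shift):200, (1 + shift):200]
  map2 <- contact_map(m2, 500)
  s1 <- loop_strength(map, c((bi - 0.5) * 500, (bj - 0.5) * 500),
                      "total")
  s2 <- loop_strength(map2, c((bi - shift - 0.5) * 500,
                              (bj - shift - 0.5) * 500), "total")
  expect_equal(s1, s2)
})

test_that("background subtraction is invariant under added decay fields", {
  map <- random_symmetric_map(200, seed = 33)
  loop <- c(70 * 500, 130 * 500)
  s0 <- loop_strength(map, loop, "bg_subtracted")
  sep <- abs(outer(1:200, 1:200, "-"))
  decay <- 50 * pmax(sep, 1)^-0.8
  map2 <- contact_map(map$matrix + decay, 500)
  s1 <- loop_strength(map2, loop, "bg_subtracted")
  expect_equal(s0, s1, tolerance = 1e-8)
})

test_that("planted uniform excess is recovered by all three scores", {
  e <- 5
  g <- gen_synthetic_map(n_bins = 300, base = 400, decay_exponent = -1,
                         loops = data.frame(bin1 = 100, bin2 = 200,
                                            excess = e),
                         noise = "none", seed = 34)
  loop <- c(99.5 * 500, 199.5 * 500)
  bgsub <- loop_strength(g$map, loop, "bg_subtracted")
  # the background window absorbs a small part of the planted excess
  expect_equal(bgsub, 441 * e, tolerance = 0.10)
  oe <- loop_strength(g$map, loop, "obs_over_exp")
  bg <- local_background_matrix(g$map, loop)
  # the local background absorbs a few percent of the planted excess
  expect_equal(oe, 1 + 441 * e / sum(bg), tolerance = 0.06)
  tot <- loop_strength(g$map, loop, "total")
  expect_equal(tot - bgsub, sum(bg), tolerance = 1e-8)
  # null map: additive score ~ 0, ratio score ~ 1
  g0 <- gen_synthetic_map(n_bins = 300, base = 400,
                          decay_exponent = -1, seed = 35)
  b0 <- ice_balance(g0$map)
  expect_equal(loop_strength(b0, loop, "obs_over_exp"), 1,
               tolerance = 0.05)
})

test_that("loops near the diagonal or map edge are rejected", {
  map <- random_symmetric_map(100, seed = 36)
  expect_error(loop_strength(map, c(5 * 500, 50 * 500), "total"),
               "bounds")
  expect_error(local_background_matrix(map, c(40 * 500, 45 * 500)),
               "close to the diagonal")
})

test_that("simulation-window strength handles flat and spiked maps", {
  mu <- contact_map(matrix(3, 100, 100), 2000)
  expect_equal(sim_window_strength(mu, c(40, 80) * 2000), 3)
  expect_equal(sim_window_strength(mu, c(40, 80) * 2000,
                                   relative = TRUE), 1)
  m <- matrix(2, 100, 100)
  m[41, 81] <- m[81, 41] <- 20    # one cell at 10x on uniform
  mm <- contact_map(m, 2000)
  expect_equal(sim_window_strength(mm, c(40.5, 80.5) * 2000), 4)
  expect_error(sim_window_strength(mu, c(0, 99) * 2000), "bounds")
  # brute-force 3x3 mean and distance scaling on a random map
  rmap <- random_symmetric_map(100, seed = 37)
  rmap$resolution <- 2000
  bi <- 30; bj <- 70
  got <- sim_window_strength(rmap, c((bi - 0.5) * 2000,
                                     (bj - 0.5) * 2000),
                             relative = TRUE)
  obs <- mean(rmap$matrix[(bi - 1):(bi + 1), (bj - 1):(bj + 1)])
  sep <- abs(outer(1:100, 1:100, "-"))
  expd <- mean(rmap$matrix[sep == (bj - bi)])
  expect_equal(got, obs / expd, tolerance = 1e-12)
})

test_that("APA pileups center planted enrichment and stay flat on nulls", {
  loops <- data.frame(bin1 = c(60, 120, 200), bin2 = c(110, 190, 260),
                      excess = 6)
  g <- gen_synthetic_map(n_bins = 320, base = 300, decay_exponent = -1,
                         loops = loops, loop_halfwidth = 2,
                         noise = "none", seed = 38)
  lt <- loop_table(data.frame(chrom1 = "sim",
                              start1 = (loops$bin1 - 1) * 500,
                              end1 = loops$bin1 * 500,
                              chrom2 = "sim",
                              start2 = (loops$bin2 - 1) * 500,
                              end2 = loops$bin2 * 500))
  ap <- apa_pileup(g$map, lt, window = 10000)
  ctr <- (nrow(ap$pileup) + 1) / 2
  expect_equal(ap$n_used, 3)
  expect_gt(ap$pileup[ctr, ctr], 1.5)
  # enrichment is confined to the planted square: everything beyond
  # its halfwidth (+1 margin) stays at the background ratio
  off <- abs(row(ap$pileup) - ctr) > 3 | abs(col(ap$pileup) - ctr) > 3
  expect_gt(ap$pileup[ctr, ctr], max(ap$pileup[off]) * 1.2)
  # null map: flat pileup ~ 1
  g0 <- gen_synthetic_map(n_bins = 320, base = 300,
                          decay_exponent = -1, noise = "none",
                          seed = 39)
  ap0 <- apa_pileup(g0$map, lt, window = 10000)
  expect_equal(max(abs(ap0$pileup - 1)), 0, tolerance = 1e-8)
  # loops without full window coverage are skipped and counted
  lt2 <- rbind(lt, data.frame(chrom1 = "sim", start1 = 500,
                              end1 = 1000, chrom2 = "sim",
                              start2 = 5000, end2 = 5500))
  ap2 <- apa_pileup(g$map, lt2, window = 10000)
  expect_equal(ap2$n_skipped, 1)
  expect_error(apa_pileup(g$map, lt2[4, ], window = 10000),
               "skipped")
})

test_that("planted loops above noise are recovered with positive scores", {
  # 20 replicates, excess ~ 3x the local background noise SD
  hits <- 0; total <- 0
  for (rep in 1:20) {
    base <- 200
    loops <- data.frame(bin1 = c(60, 140), bin2 = c(110, 200),
                        excess = 3 * sqrt(base / 50))
    g <- gen_synthetic_map(n_bins = 260, base = base,
                           decay_exponent = -0.7, loops = loops,
                           seed = 100 + rep)
    for (k in 1:2) {
      s <- loop_strength(g$map, c((loops$bin1[k] - 0.5) * 500,
                                  (loops$bin2[k] - 0.5) * 500),
                         "bg_subtracted")
      total <- total + 1
      if (s > 0) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})
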