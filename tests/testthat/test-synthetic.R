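test_that("generators are pure functions of seed and parameters", {
  a <- gen_annotations(seed = 71)
  b <- gen_annotations(seed = 71)
  expect_identical(a$manifest, b$manifest)
  expect_true(identical(S4Vectors::as.data.frame(a$annotation$ctcf),
                        S4Vectors::as.data.frame(b$annotation$ctcf)))
  m1 <- gen_synthetic_map(n_bins = 60, seed = 72)
  m2 <- gen_synthetic_map(n_bins = 60, seed = 72)
  expect_identical(m1$map$matrix, m2$map$matrix)
  p1 <- gen_polII_series(seed = 73)
  p2 <- gen_polII_series(seed = 73)
  expect_identical(p1$matrix, p2$matrix)
})

test_that("annotation round trip through BED recovers manifest classes", {
  g <- gen_annotations(region_length = 1.5e6, n_genes = 8,
                       n_enhancers = 10, n_ctcf = 10,
                       cre_ctcf_frac = 0, seed = 74)
  man <- g$manifest
  # with no CRE/CTCF co-location, inclusive and exclusive agree
  feats <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(c(man$tss_pos, man$enh_pos, man$ctcf_pos),
                     width = 1))
  inc <- classify_anchors(feats, g$annotation, "inclusive")
  exc <- classify_anchors(feats, g$annotation, "exclusive")
  expect_identical(inc$class, exc$class)
  expect_equal(inc$class,
               rep(c("promoter", "enhancer", "ctcf"),
                   c(length(man$tss_pos), length(man$enh_pos),
                     length(man$ctcf_pos))))
  # write -> read round trip preserves intervals
  tmp <- tempfile(fileext = ".bed")
  write_bed(g$annotation$ctcf, tmp)
  back <- read_bed(tmp)
  expect_equal(GenomicRanges::start(back),
               GenomicRanges::start(g$annotation$ctcf))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(g$annotation$ctcf)))
  expect_error(gen_annotations(region_length = 1e5, n_genes = 50,
                               n_enhancers = 50, n_ctcf = 50),
               "infeasible")
})

test_that("monomer typing reproduces the adopted chromosome layout", {
  ty <- gen_monomer_typing()
  expect_length(ty$types, 61600)
  expect_equal(1.925e6 / 500, 3850)   # locus monomers at 0.5 kb each
  # C blocks sit where planted, 3 monomers wide, flanked by non-C
  ty2 <- gen_monomer_typing(copies = 2, locus_monomers = 500,
                            spacer_monomers = 100,
                            c_anchor_starts = c(100, 200), ab_block = 0)
  expect_length(ty2$types, 1200)
  expect_equal(ty2$types[100:102], rep("C", 3))
  expect_false(ty2$types[99] == "C" || ty2$types[103] == "C")
  expect_equal(ty2$c_anchors, c(100L, 200L, 700L, 800L))
  # spacers are neutral A
  expect_true(all(ty2$types[501:600] == "A"))
  expect_warning(gen_monomer_typing(copies = 1, locus_monomers = 100,
                                    spacer_monomers = 0,
                                    c_anchor_starts = c(10, 11)),
                 "merged")
})

test_that("synthetic maps honor their planted ground truth", {
  # zero-noise mode returns the expected matrix exactly
  g <- gen_synthetic_map(n_bins = 80, noise = "none", seed = 75)
  expect_identical(g$map$matrix, g$expected)
  expect_equal(g$map$matrix, t(g$map$matrix))
  # Poisson mode is symmetric with the right mean
  g2 <- gen_synthetic_map(n_bins = 150, base = 500, seed = 76)
  expect_equal(g2$map$matrix, t(g2$map$matrix))
  sep5 <- abs(outer(1:150, 1:150, "-")) == 5
  expect_equal(mean(g2$map$matrix[sep5]), mean(g2$expected[sep5]),
               tolerance = 0.05)
  expect_error(gen_synthetic_map(n_bins = 50,
                                 loops = data.frame(bin1 = 2, bin2 = 30,
                                                    excess = 1)),
               "out of bounds")
})

test_that("Pol II generator calibrates to its planted fraction and null", {
  # null: no spiking structure; classifier finds at most a noise floor
  g0 <- gen_polII_series(n_genes = 200, spiking_fraction = 0,
                         seed = 77)
  nf0 <- normalize_and_filter(g0$matrix)
  res0 <- pca_classify(nf0$normalized)
  expect_lte(mean(res0$label == "spiking"), 0.6)  # no structure: ~chance
  # amplitude 1 (no spike): recovery is at chance
  g1 <- gen_polII_series(n_genes = 200, spiking_fraction = 0.4,
                         amplitude = 1, seed = 78)
  res1 <- pca_classify(normalize_and_filter(g1$matrix)$normalized)
  truth1 <- g1$labels[normalize_and_filter(g1$matrix)$active]
  expect_lt(abs(mean(res1$label == truth1) - 0.5), 0.2)
  # planted fraction recovered within 5 points
  g2 <- gen_polII_series(n_genes = 300, spiking_fraction = 0.38,
                         amplitude = 2, cv = 0.1, seed = 79)
  res2 <- pca_classify(normalize_and_filter(g2$matrix)$normalized)
  expect_lt(abs(mean(res2$label == "spiking") - 0.38), 0.05)
})
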