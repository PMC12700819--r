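# Small fixtures shared across test files; everything is generated in
# code, nothing is read from disk.

mini_typing <- function(copies = 1, locus = 770, spacer = 770,
                        anchors = seq(50, 720, 50)) {
  gen_monomer_typing(copies = copies, locus_monomers = locus,
                     spacer_monomers = spacer,
                     c_anchor_starts = anchors)
}

# symmetric random count matrix
random_symmetric_map <- function(n, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m <- m + t(m)
  contact_map(m, resolution = 500, provenance = "synthetic")
}

# brute-force local background oracle: plain loops over all map cells
brute_background <- function(map, bi, bj, hw, flank_bp) {
  m <- map$matrix
  n <- nrow(m)
  fb <- floor(flank_bp / map$resolution)
  w <- 2 * hw + 1
  bg <- matrix(NA_real_, w, w)
  for (di in -hw:hw) for (dj in -hw:hw) {
    s <- abs((bi + di) - (bj + dj))
    vals <- c()
    for (i in seq_len(n)) {
      j <- i + s
      if (j > n) next
      if (abs((i + j) - (bi + bj)) <= 2 * fb) vals <- c(vals, m[i, j])
    }
    bg[di + hw + 1, dj + hw + 1] <- mean(vals)
  }
  bg
}
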