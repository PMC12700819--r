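#' Generate synthetic genomic annotations
#'
#' Places TSSs, enhancers (emitted as coincident H3K4me1 + H3K27ac
#' peaks), and CTCF sites (with random motif orientation and matched
#' RAD21 peaks) on non-overlapping slots of a regular grid, so every
#' feature has an unambiguous class. A fraction of cis-regulatory
#' elements additionally receives a co-located CTCF/RAD21 peak to
#' exercise the inclusive/exclusive classification logic.
#'
#' @param region_length region size in bp.
#' @param n_genes,n_enhancers,n_ctcf feature counts.
#' @param cre_ctcf_frac fraction of CREs co-located with CTCF/RAD21.
#' @param chrom chromosome label.
#' @param slot_spacing grid spacing in bp; must exceed the promoter and
#'   anchor pads so classes cannot bleed into each other.
#' @param seed random seed.
#' @return list with `annotation` (an [anchor_annotation()]) and
#'   `manifest` (slot positions and true class of every feature).
#' @export
gen_annotations <- function(region_length = 2e6, n_genes = 10,
                            n_enhancers = 15, n_ctcf = 12,
                            cre_ctcf_frac = 0.2, chrom = "chrS",
                            slot_spacing = 10000, seed = 1) {
  set.seed(seed)
  slots <- seq(slot_spacing, region_length - slot_spacing,
               by = slot_spacing)
  n_feat <- n_genes + n_enhancers + n_ctcf
  if (n_feat > length(slots))
    stop("infeasible feature density: ", n_feat, " features for ",
         length(slots), " slots")
  pos <- sample(slots, n_feat)
  tss_pos <- pos[seq_len(n_genes)]
  enh_pos <- pos[n_genes + seq_len(n_enhancers)]
  ctcf_pos <- pos[n_genes + n_enhancers + seq_len(n_ctcf)]
  gr <- function(p, w) {
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = pmax(1, p - w %/% 2), width = w))
  }
  tss <- gr(tss_pos, 1)
  tss$name <- sprintf("gene%03d", seq_len(n_genes))
  # CREs optionally co-bound by CTCF/RAD21
  cre_pos <- c(tss_pos, enh_pos)
  n_co <- round(cre_ctcf_frac * length(cre_pos))
  co_pos <- if (n_co > 0) sample(cre_pos, n_co) else numeric(0)
  ctcf_all <- c(ctcf_pos, co_pos)
  ctcf <- gr(ctcf_all, 200)
  GenomicRanges::strand(ctcf) <- sample(c("+", "-"), length(ctcf_all),
                                        replace = TRUE)
  ann <- anchor_annotation(
    tss = tss,
    h3k4me1 = gr(enh_pos, 500),
    h3k27ac = gr(enh_pos, 500),
    ctcf = ctcf,
    rad21 = gr(ctcf_all, 300))
  manifest <- list(seed = seed, region_length = region_length,
                   chrom = chrom,
                   tss_pos = tss_pos, enh_pos = enh_pos,
                   ctcf_pos = ctcf_pos, cre_ctcf_pos = co_pos)
  list(annotation = ann, manifest = manifest)
}

#' Generate a typed monomer sequence (A/B/C block layout)
#'
#' Default layout mirrors the simulated chromosome: `copies` tandem
#' repeats of a 3,850-monomer annotated locus, each followed by a
#' 3,850-monomer neutral (A-type) spacer, for 61,600 monomers total at
#' 0.5 kb per monomer. Within each locus, microcompartment (C-type)
#' blocks of 3 monomers (1.5 kb) sit at `c_anchor_starts`, on an
#' alternating A/B background of `ab_block`-monomer segments.
#'
#' @param copies number of locus + spacer repeats.
#' @param locus_monomers monomers per annotated locus (3,850 = 1.925 Mb).
#' @param spacer_monomers monomers per neutral spacer.
#' @param c_anchor_starts 1-based start offsets of C blocks within a
#'   locus; overlapping blocks are merged with a warning.
#' @param c_block C-block width in monomers (3 = 1.5 kb).
#' @param ab_block A/B background block width in monomers (0 = all A).
#' @return a `monomer_typing`: list with `types` (character vector),
#'   `c_anchors` (global 1-based start index of every C block),
#'   `layout` parameters.
#' @export
gen_monomer_typing <- function(copies = 8, locus_monomers = 3850,
                               spacer_monomers = 3850,
                               c_anchor_starts = seq(50, 3800, by = 50),
                               c_block = 3, ab_block = 700) {
  stopifnot(copies >= 1, locus_monomers >= 1, spacer_monomers >= 0)
  c_anchor_starts <- sort(unique(as.integer(c_anchor_starts)))
  stopifnot(all(c_anchor_starts >= 1),
            all(c_anchor_starts + c_block - 1 <= locus_monomers))
  if (length(c_anchor_starts) > 1 &&
      any(diff(c_anchor_starts) < c_block)) {
    warning("overlapping C blocks merged")
    keep <- c(TRUE, diff(c_anchor_starts) >= c_block)
    c_anchor_starts <- c_anchor_starts[keep]
  }
  locus <- if (ab_block > 0) {
    blk <- rep(c("A", "B"),
               length.out = ceiling(locus_monomers / ab_block))
    rep(blk, each = ab_block)[seq_len(locus_monomers)]
  } else rep("A", locus_monomers)
  for (s in c_anchor_starts) locus[s:(s + c_block - 1)] <- "C"
  unit <- c(locus, rep("A", spacer_monomers))
  types <- rep(unit, copies)
  period <- locus_monomers + spacer_monomers
  c_anchors <- as.integer(outer(c_anchor_starts,
                                (seq_len(copies) - 1) * period, `+`))
  structure(list(types = types, c_anchors = sort(c_anchors),
                 layout = list(copies = copies,
                               locus_monomers = locus_monomers,
                               spacer_monomers = spacer_monomers,
                               c_block = c_block, ab_block = ab_block)),
            class = "monomer_typing")
}

#' Generate a synthetic contact map with planted structure
#'
#' The expected matrix is `base * max(s, 1)^decay_exponent` at
#' separation `s` bins, multiplied by a compartment checkerboard factor
#' (`1 + comp_amp` within a block label, `1 - comp_amp` across), plus a
#' uniform excess planted over a `(2*loop_halfwidth+1)`-square window at
#' each planted loop. Counts are Poisson-sampled (or returned exactly in
#' `"none"` noise mode) and symmetrized.
#'
#' @param n_bins number of bins.
#' @param resolution bin size in bp.
#' @param base expected count at separation 1 bin.
#' @param decay_exponent power-law exponent of distance decay (< 0).
#' @param loops `NULL` or data.frame with columns `bin1`, `bin2`
#'   (1-based), `excess` (expected extra counts per cell).
#' @param loop_halfwidth half-width (bins) of the planted excess square.
#' @param blocks `NULL` or per-bin compartment labels (`"A"`/`"B"`).
#' @param comp_amp checkerboard amplitude in `[0, 1)`.
#' @param noise `"poisson"` or `"none"`.
#' @param seed random seed.
#' @return list with `map` (a `contact_map`, provenance `"synthetic"`),
#'   `expected` matrix, and `manifest` (all planted ground truth).
#' @export
gen_synthetic_map <- function(n_bins = 200, resolution = 500, base = 100,
                              decay_exponent = -1, loops = NULL,
                              loop_halfwidth = 10, blocks = NULL,
                              comp_amp = 0.3,
                              noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  set.seed(seed)
  s <- abs(outer(seq_len(n_bins), seq_len(n_bins), `-`))
  e <- base * pmax(s, 1)^decay_exponent
  if (!is.null(blocks)) {
    stopifnot(length(blocks) == n_bins, comp_amp >= 0, comp_amp < 1)
    same <- outer(blocks, blocks, `==`)
    e <- e * ifelse(same, 1 + comp_amp, 1 - comp_amp)
  }
  if (!is.null(loops)) {
    stopifnot(all(c("bin1", "bin2", "excess") %in% names(loops)),
              all(loops$excess >= 0))
    hw <- loop_halfwidth
    for (k in seq_len(nrow(loops))) {
      bi <- loops$bin1[k]; bj <- loops$bin2[k]
      if (bi - hw < 1 || bj + hw > n_bins || bj - hw < 1 || bi + hw > n_bins)
        stop("planted loop ", k, " out of bounds")
      ii <- (bi - hw):(bi + hw); jj <- (bj - hw):(bj + hw)
      e[ii, jj] <- e[ii, jj] + loops$excess[k]
      e[jj, ii] <- e[jj, ii] + loops$excess[k]
    }
  }
  if (any(e < 0)) stop("negative expected counts")
  if (noise == "poisson") {
    up <- upper.tri(e, diag = TRUE)
    m <- matrix(0, n_bins, n_bins)
    m[up] <- stats::rpois(sum(up), e[up])
    m <- m + t(m) - diag(diag(m))
  } else m <- e
  manifest <- list(seed = seed, n_bins = n_bins, resolution = resolution,
                   base = base, decay_exponent = decay_exponent,
                   loops = loops, loop_halfwidth = loop_halfwidth,
                   blocks = blocks, comp_amp = comp_amp, noise = noise)
  list(map = contact_map(m, resolution, provenance = "synthetic"),
       expected = e, manifest = manifest)
}

#' Generate a synthetic Pol II time course with a spiking subpopulation
#'
#' Nonspiking genes have flat G1-level profiles with low PM signal;
#' spiking genes are elevated at AT (by `amplitude`) and, half as
#' strongly, at EG1. Each gene has a log-normal overall expression
#' level, and every value carries multiplicative log-normal noise of
#' coefficient of variation `cv`.
#'
#' @param n_genes number of genes.
#' @param spiking_fraction fraction of spiking genes (default 0.38).
#' @param amplitude AT signal relative to the G1 steady state.
#' @param cv multiplicative noise coefficient of variation.
#' @param base_level median G1-level signal (track units).
#' @param seed random seed.
#' @return list with `matrix` (genes x 5 `polII_matrix`-style matrix),
#'   `labels` (`spiking`/`nonspiking`), `manifest`.
#' @export
gen_polII_series <- function(n_genes = 100, spiking_fraction = 0.38,
                             amplitude = 2, cv = 0.1, base_level = 2,
                             seed = 1) {
  stopifnot(spiking_fraction >= 0, spiking_fraction <= 1)
  set.seed(seed)
  n_spike <- round(spiking_fraction * n_genes)
  spike <- sample(c(rep(TRUE, n_spike), rep(FALSE, n_genes - n_spike)))
  prof_ns <- c(PM = 0.3, AT = 1, EG1 = 1, MG1 = 1, LG1 = 1)
  prof_sp <- c(PM = 0.3, AT = amplitude, EG1 = 1 + (amplitude - 1) / 2,
               MG1 = 1, LG1 = 1)
  level <- base_level * stats::rlnorm(n_genes, 0, 0.3)
  sdlog <- sqrt(log(1 + cv^2))
  m <- t(vapply(seq_len(n_genes), function(i) {
    p <- if (spike[i]) prof_sp else prof_ns
    p * level[i] * stats::rlnorm(5, -sdlog^2 / 2, sdlog)
  }, numeric(5)))
  colnames(m) <- TIME_POINTS
  rownames(m) <- sprintf("gene%04d", seq_len(n_genes))
  list(matrix = m,
       labels = ifelse(spike, "spiking", "nonspiking"),
       manifest = list(seed = seed, n_genes = n_genes,
                       spiking_fraction = spiking_fraction,
                       amplitude = amplitude, cv = cv,
                       base_level = base_level))
}
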