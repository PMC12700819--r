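---
title: "Modeling microcompartment dynamics across the mitosis-to-G1 transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microcompartment dynamics across the mitosis-to-G1 transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`chromodyn` simulates how kilobase-scale focal contacts between
cis-regulatory elements — *microcompartments* — form, peak and decay as
chromosomes exit mitosis. The model couples two layers:

1. **1D loop extrusion.** SMC complexes (condensin I, condensin II,
   cohesin) are two-legged extruders on a lattice of 0.5-kb sites. An
   extruder loads at two adjacent free sites; each leg then steps
   outward independently with probability $p$ per timestep
   $\tau_0 = 0.5$ s, giving an unobstructed loop-growth velocity
   $v = 2p\sigma/\tau_0$ (1 kb/s at $p = 0.5$). Legs are blocked by
   other legs and the lattice ends; extruders unload at rate
   $1/\tau_\mathrm{res}$; a cohesin leg stepping onto a convergently
   oriented CTCF site stalls there with probability $q = 0.5$. The
   target number of bound extruders per species is $L\sigma/d$ for mean
   separation $d$.

2. **3D block-copolymer dynamics.** Each lattice site is one monomer
   ($a$ = 25 nm ≙ 0.5 kb) of a harmonic bead-spring chain. Monomers
   are typed A (neutral/active background), B (inactive compartment) or
   C (microcompartment anchors, 1.5-kb blocks), and homotypic pairs
   interact through a smooth square-well potential: a soft repulsive
   core of height $E_\mathrm{rep} = 3\,k_BT$ below the monomer
   diameter, an attractive well of depth $\epsilon_i$
   ($\epsilon_A = 0$, $\epsilon_B = 0.05$, $\epsilon_C = 0.9\,k_BT$)
   between $a$ and $1.5a$, and zero beyond. Extruder legs bridge their
   two monomers with a harmonic bond. The chain is confined to a
   sphere or 4:1 cylinder whose volume realizes a prescribed
   volumetric density $\rho_\mathrm{chr}$ (the fraction of container
   volume occupied by monomer spheres). 540 polymer steps correspond
   to one 0.5-s extrusion step.

The M-to-G1 protocol drives both layers from a minutes-based clock:
condensins I+II in a dense cylinder ($\rho = 0.65$, ends tethered to
the poles) model prometaphase; condensin I transiently peaks
(separation 35 → 27 kb over 15–17 min) and is removed by 20 min; the
cylinder halves in height while density relaxes to 0.45 (25–30 min);
at 30 min condensin II is removed, CTCF sites and the B-type affinity
activate, cohesin begins loading (linearly up to one per 100 kb at 245
min), and the confinement crosses over to a sphere at $\rho = 0.25$
(30–35 min). Conformations are collected in five windows — PM [0,10),
AT [20,30), EG1 [55,65), MG1 [115,125), LG1 [235,245) minutes — and
turned into contact maps (contact radius and bin both 4 monomers =
2 kb). The prometaphase-to-late-G1 density ratio is 0.65/0.25 = 2.6.

## Contact-map statistics

Analysis mirrors standard Micro-C practice:

* **ICE balancing** equalizes row sums of the contact matrix;
  all-zero bins are masked.
* **P(s)** is the mean contact value per genomic separation, averaged
  into log-spaced bins (ratio 1.12, geometric centers); its log-log
  derivative is taken by centered differences on a moving-average
  smoothed curve. The derivative peaks near the mean extruded loop
  size.
* **Loop strengths.** The *background-subtracted* score sums a 21 × 21
  window (500-bp bins) centered on a loop minus a local background
  whose element at separation $s$ averages all map cells at separation
  $s$ within ±100 kb of the loop; the *observed/expected* score is the
  ratio of the two sums; the *total* score is the observed sum alone.
  This background makes the score invariant under any added pure
  distance-decay field. Loops under 10 kb are excluded (no room for
  the background window). Simulated loop strengths use the mean count
  in a 6-kb × 6-kb window, optionally relative to the mean count at
  that separation.
* **APA** averages per-loop observed/expected windows (24-kb default).
* **Anchors** are classified against promoters (TSS ± 2 kb), enhancers
  (H3K4me1 ∩ H3K27ac), and CTCF/cohesin (CTCF ∩ RAD21) with a
  promoter > enhancer > CTCF hierarchy (inclusive mode) or by dropping
  anchors that mix a CRE with CTCF/cohesin (exclusive mode).
* **Compartments** come from the leading eigenvector of the
  correlation matrix of the observed/expected map, sign-oriented by an
  external correlate (e.g. G+C content); A = positive bins.

## The spiking classifier

Pol II signal is averaged in a 2.5-kb window around each gene's
dominant TSS (the TSS with the highest signal summed over the five
time points) at PM, AT, EG1, MG1, LG1. Genes with signal ≥ 0.5 (input
track units) at every point except PM count as active; each active row
is divided by its mean over the three G1 points. PCA (genes as
observations, column-centered, unscaled) then yields PC1; its sign is
fixed so the AT loading exceeds the mean G1 loading, and genes with
PC1 > 0 are called spiking. On a synthetic cohort with a planted
AT-peaked subpopulation this recovers labels and the planted fraction
(see the test suite). Note that on a cohort with *no* planted
structure a sign-based rule necessarily labels about half the genes
positive; the classifier is informative only when spiking structure
dominates the leading component.

## Numerical choices

* **Integrator.** Overdamped dynamics use the Leimkuhler–Matthews
  (BAOAB-limit) scheme — Euler cost, $O(\mathrm{d}t^2)$-accurate
  configurational sampling — in reduced units ($a = 1$, $k_BT = 1$,
  $\gamma = 1$). The square-well's inner wall is steep (curvature up
  to ~2 × 10³ $k_BT/a^2$), so the sampled well occupancy depends on
  the timestep: a two-particle radial-distribution study against the
  exact Boltzmann weight shows the effective homotypic attraction
  converging only below $\mathrm{d}t \approx 2.5\times10^{-3}$, which
  is therefore the default; coarser timesteps systematically weaken
  microcompartments.
* **Unloading** is discretized exactly: per-step probability
  $1 - e^{-\tau_0/\tau_\mathrm{res}}$.
* **Update order** is unload → enforce targets (random unload on
  ramp-down, uniform loading on ramp-up, stochastic rounding of
  fractional targets) → translocation in a random permutation.
  Blocked steps are lost; a stalled leg stays stalled until unload;
  lattice ends are hard walls. "+" CTCF sites stall legs moving toward
  lower indices (convergent capture).
* **Ramps** are linear; the condensin I burst is a linear up-then-down
  ramp. The cylinder-to-sphere crossover ramps the old wall's
  stiffness down while the new wall's ramps up (30–35 min), and the
  end tethers release when the crossover starts.
* **Walls** are one-sided harmonic penalties (default
  30 $k_BT/a^2$). A soft wall lets roughly one monomer layer
  penetrate, so realized core densities sit a few percent below the
  nominal $\rho_\mathrm{chr}$.
* **Potential cutoff.** The printed attraction branch diverges beyond
  its outer zero at $1.5a$; it is truncated to zero there.
* **Strength estimators.** Per-pair relative strengths (observed
  window / expected at that separation) can be averaged two ways;
  the default for sweep and transition summaries is the *pooled*
  estimator (summed observed over summed expected, as in aggregate
  pileups), because the mean of per-pair ratios is dominated by shot
  noise when desk-scale windows hold only a handful of contacts.
* **Coordinates** are 0-based half-open on disk (BED/BEDPE/bedGraph),
  1-based closed in `GRanges`; bin membership is by interval start.
* **Degenerate inputs.** Maps with a single off-diagonal separation
  flag the P(s) derivative as undefined; uniform maps yield an
  unreliable compartment call; zero-variance Pol II matrices raise.

## Synthetic data and what tests show

The generators produce every input the pipeline needs with a
ground-truth manifest: annotations on a spaced grid (unambiguous
classes, optional CRE/CTCF co-location), typed monomer chains (the
full-scale layout is eight 3,850-monomer annotated loci alternating
with neutral spacers, 61,600 monomers; C blocks default to 25-kb
spacing, matching the observed anchor density of roughly 40 per Mb),
contact maps with power-law decay, planted loop excesses, planted
checkerboards and Poisson noise, and Pol II time courses with a
spiking subpopulation (log-normal noise, CV 0.1). Passing tests show
the statistics recover planted structure under these idealized noise
models; real Micro-C maps add mappability, fragment-level and
coverage biases that the generators deliberately do not emulate.

## Desk-scale problem sizes

Full-scale runs (61,600 monomers, 10⁶-step equilibration, ≥10
replicates) are available through the same functions, but defaults in
tests and the acceptance script use reduced conditions chosen once:
one 770-monomer locus copy plus equal spacer (1,540 monomers;
0.77 Mb), 25–100 polymer steps per extrusion step, duration scale
0.02–0.05 for transition runs, and 10³–2×10³ extrusion-step blocks
for steady-state sweeps. At this scale the qualitative physics
(microcompartment enrichment with affinity, densification, extrusion
antagonism, AT peak) is reproducible, while absolute strengths are
weaker than at full scale because microphase separation has less time
to coarsen — sweep magnitudes should be read with that in mind.

## Known limitations

One-sided extrusion, extruder bypassing, cohesin-CTCF residence
coupling, hydrodynamics, nucleosome-scale structure and
transcription-coupled feedback on affinities are out of scope. The
affinities are constant in time, so late-G1 weakening of
microcompartments driven by factor rebinding is not modeled; the
protocol captures it only through density and extrusion changes.
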