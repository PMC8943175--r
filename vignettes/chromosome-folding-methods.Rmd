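---
title: "Hi-C restrained polymer folding and 3D colocalization: methods"
author: "chromofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hi-C restrained polymer folding and 3D colocalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

chromofold folds one chromosome as a bead-spring polymer in reduced
units: lengths in $\sigma$, energies in $\epsilon$, mass $m = 1$, time
in $\tau = \sigma\sqrt{m/u}$ with $u = \epsilon$.  One bead represents
one fixed-size genomic bin (5 kb by default, so a ~63 Mb human
chromosome is a chain of roughly 12,600 beads; desk-scale analyses in
this vignette and in the test suite use 60-200 beads).

Three potentials act on the chain:

* **Bonded (FENE + WCA).**  Consecutive beads interact through
  $U(r) = -\tfrac12 \kappa R_0^2 \ln\!\left[1 - (r/R_0)^2\right]
  + 4\epsilon^{*}\!\left[(\sigma/r)^{12} - (\sigma/r)^{6} + \tfrac14\right]
  \;(r \le 2^{1/6}\sigma)$,
  with $\kappa = 30\,\epsilon^{*}/\sigma^2$ and $R_0 = 20\,\sigma$.
  The spring constant and the repulsive core place the equilibrium
  bond length at $0.99\,\sigma$ while allowing extreme transient
  stretching up to $R_0$.  The quarter shift makes the energy, not
  just the force, continuous at the cutoff; the same shift is used for
  the bonded and nonbonded core, so both vanish smoothly at
  $2^{1/6}\sigma$.
* **Nonbonded (WCA).**  All bead pairs other than bonded neighbors
  repel through the truncated-and-shifted Lennard-Jones potential with
  strength $\epsilon$ - excluded volume only, no attraction.  Bonded
  neighbors are excluded because their repulsive core already lives in
  the bonded term; restrained pairs are *not* excluded, their rest
  length ($2.2\,\sigma$) keeps them outside the cutoff at equilibrium.
* **Hi-C restraints.**  Selected contact pairs $(i, j)$ feel
  $U(r) = K (r - r_0)^2$ with $K = 1\,\epsilon/\sigma^2$ and
  $r_0 = 2.2\,\sigma$.

`force_field_params()` carries these constants as plain numbers with
the defaults above; rescaling all lengths by $s$ and the two spring
constants by $1/s^2$ rescales every derived length by $s$ (a tested
invariant).

# The folding pipeline

`fold_chromosome()` runs four stages, each with a seed derived
deterministically from one master seed:

1. **Initial chain.**  A self-avoiding random walk (`sarw_chain()`):
   uniformly random unit steps of the equilibrium bond length
   ($0.99\,\sigma$), rejecting any bead placed within an excluded
   radius ($0.9\,\sigma$, chosen just under the bond length so the
   walk emulates the hard core without stalling) of an earlier bead,
   with bounded backtracking.  Collision checks scan all previous
   beads with a squared-distance early exit; at the chain lengths this
   package targets a cell grid would add bookkeeping without
   measurable gain.
2. **Restraint selection.**  `select_restraints()` turns the contact
   matrix into harmonic bonds.  The default keeps every nonzero
   contact with $|i - j| > 1$ ("used directly"); a top-quantile rule
   (deterministic tie-break: count descending, then indices) and a
   count threshold are available for dense matrices.
3. **Monte Carlo connection.**  Metropolis single-bead Gaussian moves
   (scale $0.5\,\sigma$, temperature 1) on the full system energy
   drive every restrained pair to within the activation radius
   (default $r_0$).  Satisfaction is *sticky*: a pair counts as
   connected the first time it dips below the activation radius, after
   which its bond is preserved - pairs fluctuate around
   $r_0 = 2.2\,\sigma$, so requiring all pairs to sit below
   $2.2\,\sigma$ simultaneously would never terminate.  Two
   accelerations proved necessary and are the package's own design
   choices:
   * an unconnected restraint is temporarily a stiffer, shorter
     spring (default $4K$, rest length $0.8\,r_0$), so its minimum
     lies below the activation radius instead of exactly on it; it
     reverts permanently to $K(r-r_0)^2$ on first connection, hence
     the satisfied end state is governed by the published potential
     alone;
   * the nonbonded repulsion is capped (default $2\,\epsilon$) during
     this stage so the chain can occasionally pass through itself.
     Without the cap the chain gets topologically trapped: on the
     synthetic two-compartment benchmark a misfolded state with
     ~15% of pairs stuck at $3.5{-}5\,\sigma$ survives $10^5$ sweeps,
     although the reference structure proves full satisfaction is
     geometrically possible.
   Restraints can be activated in batches ordered by genomic
   separation (`ramp_stages`), but the default activates all at once:
   measured on the same benchmark, smallest-first ramping performs
   *worse* (local blobs congeal before long-range restraints switch
   on, and single-bead moves translate whole blobs only diffusively).
4. **Minimization, then Langevin dynamics.**  A capped-step steepest
   descent (`minimize_energy()`, displacement cap $0.05\,\sigma$)
   removes the soft overlaps the capped-repulsion MC may leave, so the
   integrator never starts on a near-singular core.  Equilibration
   then uses velocity-Verlet Langevin dynamics in the BAOAB splitting
   - the Ornstein-Uhlenbeck velocity update is exact, and with
   damping 0 the scheme reduces to plain velocity Verlet (energy
   drift over $10^3$ steps at $\Delta t = 10^{-3}\tau$ is below
   $10^{-3}$ relative, a tested invariant).  Defaults follow the
   published set-up: $T = 1$, $\gamma = 1\,\tau^{-1}$,
   $\Delta t = 0.01\,\tau$, Maxwell-Boltzmann initial velocities.  The
   kinetic temperature $m\sum|v|^2/(3N)$ is recorded at every stored
   snapshot.

The result carries the coordinates, binning, restraints, and a report:
sticky satisfaction fraction after MC (1.0 by construction, the stage
errors otherwise), MC sweeps used, median restrained distance after
dynamics, and mean kinetic temperature.

# Mapping marks and measuring colocalization

Peaks (BED, 0-based half-open) map onto beads by binning
(`label_beads()`): `any_overlap` marks a bead when at least 1 bp of a
peak intersects its bin - the default, maximizing sensitivity at 5 kb
resolution - or `min_fraction(f)` requires a covered fraction.
Interval arithmetic is delegated to IRanges/GenomicRanges.

`radial_distribution()` histograms A-to-B bead distances (bin width
$0.5\,\sigma$ up to $20\,\sigma$ by default) and normalizes by a
**label-permutation baseline**: the observed counts are divided by the
mean counts over random reassignments of the B labels across all beads
(default 100 permutations, seeded).  Beads on a connected polymer are
far from uniformly dense, so the ideal-gas shell-volume normalization
is biased; permutation centers $g(r)$ at 1 for spatially random labels
by construction (tested).  The shell-volume variant remains available
as `baseline = "density"`.  Bins whose baseline expectation is zero
yield `NA` rather than a silent 0 or infinity.  `proximity_score()`
averages $g$ over the complete bins below a short-range limit
(default $2\,\sigma$) to order mark pairs by 3D closeness.

`cooccupancy()` counts, on the genome axis, the fraction of peaks of
one set having at least 1 bp of overlap with the other
(`max_gap` relaxes this to within-gap proximity); it is checked
against a quadratic brute-force scan in the tests.

`van_steensel_ccf()` computes the Pearson correlation between channel
A and channel B sampled at integer pixel offsets
$\delta \in [-\Delta, \Delta]$ along one axis, over the overlapping
window only.  Colocalized channels peak at $\delta = 0$, mutually
exclusive channels dip there; constant windows are flagged as
degenerate (`NA`) instead of reported as zero correlation.

# The synthetic-data generator

`make_reference_structure()` emulates the statistical situation the
downstream analyses probe - marks segregated between transcriptionally
distinct spatial compartments - without attempting realistic Hi-C.
Beads are assigned to $k$ compartments in alternating blocks (default
2 compartments, 50-bead blocks); each compartment's beads grow as a
self-avoiding walk confined to a sphere whose radius allots
$4\,\sigma^3$ per bead (dilute enough to grow reliably, compact enough
that within-compartment distances stay well below the
$4R$-separated globule centers).  Block-start beads are seeded on the
facing surface of their globule so inter-block linkers stay below
$R_0$; geometries that cannot honor that bound raise an error.

`contacts_from_structure()` is the deliberately unambiguous inverse of
the folding problem: a binary contact for every pair within
$2.2\,\sigma$ (the restraint rest length), diagonal zero.  An inverse
distance (`power_law`) variant exists for realism experiments.
`make_marked_tracks()` emits one peak per 5 kb bin with probability
0.8 inside a mark's home compartment and 0.1 elsewhere - a strong but
noisy segregation, with the factor and the active mark sharing a home.
`make_image_pair()` renders Gaussian spots with a controllable
fraction of shared centers for the image statistic.

What passing tests on these fixtures show - and what they do not: they
demonstrate that the pipeline recovers planted compartment geometry
(reference vs recovered distance matrices, Spearman $\ge 0.6$), that
restraint satisfaction terminates, and that the RDF orders a factor
closer to its co-compartment mark in at least 9 of 10 seeds.  They do
not show that real Hi-C counts (distance decay, coverage bias, noise)
or real peak calls would behave identically, nor do they validate the
model at full chromosome scale.

# Numerical choices and problem sizes

* Nonbonded interactions use all-pairs distance screening with early
  exit; at the desk-scale sizes the package targets (up to a few
  hundred beads) this outperforms a cell list in practice and is far
  simpler to verify.
* Analytic forces are validated against central finite differences to
  $10^{-5}$ relative on random configurations, and the force sum is
  checked to vanish.
* `equilibrium_bond_length()` brackets the force sign change in
  $(0.5\,\sigma,\ 2^{1/6}\sigma)$ and bisects to $10^{-8}\,\sigma$;
  with a negligible repulsive core the FENE term is monotone and the
  function errors rather than returning a boundary value.
* Test and acceptance problem sizes were chosen so the whole suite
  runs in about a minute: thermostat checks on a 100-bead chain over
  $2\times10^5$ steps, recovery on 200-bead two-compartment problems
  over 3 seeds, RDF discrimination over 10 seeds.  These are the
  package's reference workloads; larger chains fold with the same
  code, only more slowly.
* All randomness flows through explicit integer seeds;
  `fold_chromosome()` derives per-stage seeds from one master seed and
  records them, and every pipeline run writes a JSON manifest
  sufficient to reproduce it exactly.

# Known limitations

* Single chromosome, haploid, no nuclear confinement, no
  trans-chromosomal restraints.
* Restraint strength ignores contact counts (all selected contacts get
  the same $K$); count-weighted springs would be a natural extension.
* The MC stage is a constraint solver, not an equilibrium sampler: the
  pull springs and capped repulsion deliberately break detailed
  balance while pairs are being connected.  Ensemble statistics should
  be read from the Langevin stage, which uses the published potential
  throughout.
* Binary `.hic`/`.mcool`/bigWig formats are not read natively; export
  contacts to COO text and peaks to BED first.
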