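---
title: "Population-based genome structure modeling and the nuclear microenvironment"
author: "nucenv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based genome structure modeling and the nuclear microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucenv)
```

# The model

Ensemble Hi-C measures, for every pair of genomic bins `I`, `J`, the
probability `a_IJ` that the two loci are in contact across a population of
cells. A single contact-probability matrix is compatible with many
different single-cell configurations; `nucenv` deconvolves it into an
explicit population of `M` diploid 3D genome structures whose accumulated
contacts are statistically consistent with the input.

Each chromosome is a chain of spherical beads, one per fixed-size bin
(200 kb by default). The nucleus is a sphere of radius `Rnuc` (default
5,000 nm). Every structure must satisfy three hard constraints:

* **nuclear confinement** — every bead center inside the nucleus,
  `|x| <= Rnuc`;
* **excluded volume** — no two beads closer than `2 Rex`, where the
  excluded-volume radius solves the occupancy balance
  `n_beads * Rex^3 = occupancy * Rnuc^3` (40% occupancy and 30,332 beads
  give `Rex = 118` nm for a full diploid human genome at 200 kb);
* **chain connectivity** — consecutive beads of a chromosome copy within
  `2 Rsoft`, with `Rsoft = 2 Rex`.

Two beads are *in contact* when their center distance is at most
`2 Rsoft = 4 Rex` (472 nm at the default geometry).

Because the genome is diploid and Hi-C is unphased, a haploid pair `(I, J)`
corresponds to several copy combinations: two within-homolog combinations
for a cis pair, four for a trans pair. A binary latent tensor `W` assigns
each required contact to specific structures and specific copy
combinations. Optimization alternates two steps:

* **Assignment step (A-step).** For every pair with `a_IJ` at or above the
  current activation threshold `theta`, the contact must be realized in
  `k = round(a_IJ * M)` structures. In each structure the copy combination
  with the minimal current distance is taken, structures are ranked by that
  distance, and the contact is assigned in the `k` best. Cis assignments
  are restricted to within-homolog combinations. Re-assignment of the copy
  combination is allowed at every A-step, which lets early assignments be
  corrected as the structures take shape.
* **Modeling step (M-step).** Each structure independently minimizes a
  penalty that is zero exactly when all assigned contacts, chain bonds,
  excluded-volume and confinement constraints are satisfied; every term is
  a one-sided harmonic (squared excess beyond the bound).

The schedule runs `theta` from 1 down to 0.01
(`1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01` by default), so optimization
hardness grows gradually: high-probability contacts shape the coarse
architecture before rare contacts are imposed.

## The modeling step in practice

The contract of the M-step is feasibility — a violation score (the
fraction of restraints whose relative excess exceeds 5%) below tolerance —
not a particular dynamical trajectory. `nucenv` implements it as staged
constraint projection: each stage perturbs the coordinates with a Gaussian
kick whose amplitude decays to zero (50 nm at the first stage by default)
and then runs Gauss–Seidel sweeps in which every violated restraint is
projected onto its bound (pairs move symmetrically along their axis;
out-of-envelope beads are rescaled radially). The best configuration seen,
including the input, is kept per structure, so the penalty is
non-increasing by construction. Upper bounds are projected to 95% of the
bound (`projScale = 0.95`) so that constraint interplay does not park
pairs marginally *outside* the contact capture distance; the penalty
itself is always measured against the true bound.

## Random starting configurations

Each chromosome copy starts inside a territory sphere whose volume is the
chromosome's share of the nuclear volume, `r_c = Rnuc (n_c / 2N)^(1/3)`
(radius proportional to the cube root of the bead count); territory
centers are uniform among positions where the sphere fits. Reading the
territory as the chromosome's *nuclear-volume* share matters: territories
sized by bead packing alone would be an order of magnitude smaller,
collapse the chains into dense blobs, and flood the model with spurious
chance contacts.

## Measuring model contact frequencies

Model frequencies use the same capture rule as the restraints
(`d <= 2 Rsoft`). For cis pairs the two within-homolog combinations each
contribute `1/(2M)`. For trans pairs a structure counts as in contact when
*any* of the four copy combinations is, contributing `1/M`. The trans rule
is chosen for self-consistency with the assignment semantics: the A-step
realizes a trans contact through exactly one copy combination per
structure, so a per-combination average over `2M` would cap the model's
trans frequencies near `a/2` and make even a perfectly optimized
population look inconsistent with its own input. Under the
any-combination rule the round trip (simulate a truth population, measure
its matrix, deconvolve, re-measure) is coherent on both cis and trans.

## Diagnostics

* `compareMatrices()` — Pearson/Spearman correlations over the non-zero
  support of the input, genome-wide, per split (cis/trans) and per
  chromosome.
* `restraintResiduals()` — per-restraint `eta = (d - D)/D` against the
  target contact distance `D = 2 Rsoft`; after convergence at the final
  theta, at least 99% of assigned restraints have `eta <= 0.05` on
  realizable inputs.
* `residualRatio()` — per-entry `(f_input - f_model)/f_input` with cis and
  trans summaries.
* `sparseDataExperiment()` — removes a fraction (default 50%) of non-zero
  entries, re-models, and correlates predictions with the held-out values.

# Nuclear bodies and spatial partitions

A chromatin interaction network (CIN) connects the beads of a region
subset whose distance in one structure is within the contact capture
distance. Markov clustering (MCL: alternate expansion — matrix squaring —
and inflation — entrywise power with column renormalization — after adding
self-loops, pruning values below `1e-5`, to idempotency; defaults:
inflation 1.5, at most 100 iterations) fragments each CIN into highly
connected subgraphs, the *spatial partitions*. Partitions below 7 nodes
are discarded by default; each surviving partition reports its member
beads, geometric center (unweighted mean of bead centers), size in Mb
(0.2 Mb per node at 200-kb bins) and inter-chromosomal edge fraction
`ICEF = E_inter / (E_intra + E_inter)`.

Nuclear bodies are predicted as partition centers:

* **speckles** — partitions (larger than three nodes) of A1-annotated
  chromatin (`mode = "a1"`), of the 10% of regions with the lowest mean
  radial position (`mode = "lowest_rad"`, annotation-free), or of A2
  chromatin as a control (`mode = "a2"`);
* **nucleoli** — partitions of NAD/NOR-annotated chromatin, keeping the
  top 25% largest per structure; NOR bins without contact entries can be
  substituted by their nearest restrained bins in sequence.

Network statistics include the maximal-clique enrichment (observed count
over the mean count across CINs rebuilt from random same-size region
subsets in the same structure; 10 shuffles by default), neighborhood
connectivity (mean over nodes of the average neighbor degree, isolated
nodes contributing zero), and a label-by-label neighborhood enrichment
(log2 of observed neighbor fractions over genome-wide label fractions,
500-nm neighborhoods pooled over structures).

# The seventeen structural features

For each haploid region, averaging both homologous copies over all `M`
structures (2M single-cell observations) unless stated otherwise:

| feature | definition | units |
|---|---|---|
| RAD | mean radial position `|x| / Rnuc` | fraction of `Rnuc` |
| RG | local compaction: sum of squared distances of the beads in a 1-Mb window to the window's center of mass | nm² |
| SpD, NuD | mean center-to-center distance to the nearest predicted speckle / nucleolus | nm |
| dRAD, dRG, dSpD, dNuD | `log2(sigma_I / sigma_bar)`: s.d. of the 2M single-cell values over the mean s.d. across the chromosome | log2 ratio |
| ILF | fraction of structures where either copy has `r < 0.5` | [0, 1] |
| SAF, LAF, NAF | fraction of the 2M copies within an association threshold of a speckle (500 nm), the lamina (0.35 Rnuc) or a nucleolus (1,000 nm); distances are bead-surface-to-body-center, or surface-to-envelope for the lamina | [0, 1] |
| S_TSA, L_TSA, N_TSA | simulated TSA-seq: `sig_i = (1/M) sum_m sum_l exp(-R0 d_il)` with distances in µm and `R0 = 4` per µm, normalized as `log2(sig / mean sig)` per copy and then copy-averaged; the lamina uses the per-structure envelope distance `(1 - r) Rnuc` | log2 ratio |
| ICP | mean fraction of 500-nm neighbors on other chromosomes (the homologous copy counts as the same chromosome); empty neighborhoods contribute 0 | [0, 1] |
| TRANS_AB | median over 2M observations of `(n_A + 1)/(n_B + 1)` over other-chromosome 500-nm neighbors, min–max rescaled across regions | [0, 1] |

Notes on deliberately literal choices:

* RG is the plain sum of squared distances (no division, no square root);
  `conventional = TRUE` switches to the root-mean-square form.
* The TSA normalization uses log base 2, matching the convention of the
  experimental signal the simulation emulates; the normalizing mean is
  taken over all per-copy signals, which makes `mean(2^signal) = 1` an
  exact invariant before copy averaging.
* Structures without a predicted body are excluded from SpD/NuD means but
  count as non-associated for SAF/NAF, whose denominators stay fixed at
  2M.
* The trans A/B pseudocount of 1 guards against empty-B neighborhoods;
  rescaling is a global min–max across regions.

# Downstream analysis

`variabilityGroups()` splits A/B-compartment chromatin by the sign of
dRAD (exact zeros fall in the low-variability group). `decileGroups()`
forms equal-count quantile groups with stable tie handling.
`foldChangeEnrichment()` reports `log2(group mean / background mean)` per
feature, with the background restricted to labeled regions and the delta
features linearized as `2^delta` before forming ratios (their log-scale
values straddle zero). `rocDiscrimination()` computes the rank-statistic
AUC (ties count one half). `predictSubcompartments()` z-scores the feature
columns, runs K-means separately on A chromatin (k = 2) and B chromatin
(k = 3 by default), and maps clusters to reference labels by the
permutation maximizing agreement — with at most five labels, exhaustive
search over permutations is exact and cheap.

# The synthetic-data generator

`makeToyTruth()` and `simulatePopulation()` produce ground-truth
populations with a planted nuclear architecture so that every stage of the
package can be validated against known answers without external data. The
toy keeps the physical geometry of a real nucleus — `Rnuc = 5000` nm and
`Rex = 118` nm per 200-kb bead, the full-genome 40%-occupancy value — so
the contact capture distance stays small relative to the nucleus, as in
the real system; a two-chromosome subset then fills only a small part of
the nuclear volume, exactly as a genome subset would.

Regions fall into five architecture classes laid out in contiguous blocks
along two toy chromosomes (6 + 4 Mb at 200 kb, N = 50; a three-chromosome
"medium" preset is also provided):

* **speckle-anchored** (two anchors placed near orthogonal directions at
  radial positions 0.30–0.55 Rnuc, redrawn per structure): with
  probability `pAssoc = 0.9` the whole block copy is drawn within 500 nm
  of its anchor (the association threshold), otherwise it forms a blob
  elsewhere — association is a block-level, domain-like event;
* **nucleolus-anchored**: same mechanism, one anchor;
* **lamina-anchored**: a coherent patch in the peripheral shell
  (thickness 0.15 Rnuc), on the same side as the nearest anchored block of
  the chromosome so chains need not span the nucleus;
* **variable**: flips between a peripheral patch and an interior position
  with probability 0.5 per structure — the bimodal radial behavior that
  drives high dRAD;
* **free**: interpolated between flanking placed blocks with 150-nm
  Gaussian jitter.

Blocks with incompatible radial placement are separated by free buffers
long enough for the chain to bridge them. After placement, chain,
excluded-volume and envelope feasibility is enforced by the optimizer's
own projection relaxer with a weak tether to the sampled positions; the
toy populations are therefore feasible by construction, and the matrices
they produce are realizable. Planted labels map speckle chromatin to A1,
free/variable to A2, nucleolus to B2 and lamina to B3 (compartments A/B
accordingly).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: genome-scale bead counts and genuine 40%
crowding; distance-decay contact statistics of a real polymer (toy decay
comes from territory confinement and chain geometry only); measurement
noise, coverage bias or unmappable regions in the input matrix; more than
two nuclear-body kinds per structure; and continuous, overlapping
subcompartment identities. One known ambiguity is intentional: free (A2)
regions bridging two interior speckle anchors are themselves interior, so
A1 and A2 overlap partially in feature space and an unsupervised
classifier cannot fully separate them on the toy — the classifier's
recovery contract is therefore asserted on explicitly well-separated
planted feature clusters, while the end-to-end toy run is compared
against a majority-class baseline.

# Problem sizes and reproducibility

The packaged validation runs use the small preset (N = 50, 2N = 100
beads): a truth population of 200 structures defines the input matrix,
and the pipeline deconvolves it into M = 100 structures (about 10,000
restraints at the final theta) — on one core this takes a few seconds,
and the full test suite about a minute. Population-size convergence is
checked by comparing generator populations of 400 and 2,000 structures.
All randomness is seeded: the generator, territory initialization,
annealing kicks, shuffle nulls and K-means all derive from explicit seed
arguments, and identical seeds reproduce results bit-exactly.

# Known limitations

* Trans contact frequencies above what a single copy-combination per
  structure can realize are reproduced through the any-combination capture
  rule, not through multi-combination assignment; the per-combination
  phasing of trans contacts is not identifiable from unphased input.
* The relaxer is a feasibility solver, not a thermodynamic sampler;
  structure ensembles should be read as constraint-consistent
  configurations, not Boltzmann samples.
* Bodies are points (partition centers); body shape and volume are out of
  scope.
* Excluded (masked) bins stay in the chain but carry no restraints; their
  features are reported as missing.
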