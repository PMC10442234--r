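# nucenv

Population-based 3D genome modeling from ensemble Hi-C, with a complete
nuclear-microenvironment analysis suite.

Ensemble Hi-C gives, for each pair of genomic bins *I*, *J*, a contact
probability *a<sub>IJ</sub>* averaged over millions of cells. `nucenv`
deconvolves a haploid contact-probability matrix **A** into an explicit
population of *M* diploid 3D structures **X** = {X₁ … X_M} whose
accumulated contacts are statistically consistent with **A**, by
maximum-likelihood estimation over a latent contact tensor **W**
(which copy combination realizes each contact in which structure), subject
to nuclear confinement (|x| ≤ R<sub>nuc</sub>), excluded volume
(d ≥ 2 R<sub>ex</sub>) and chain connectivity (consecutive beads within
2 R<sub>soft</sub>, R<sub>soft</sub> = 2 R<sub>ex</sub>). Optimization
alternates an assignment step (each pair with *a* ≥ θ is assigned to the
round(*a*·*M*) structures where it is cheapest to realize) with a modeling
step (per-structure annealed constraint projection), over a decreasing
θ schedule.

From the resulting structure population the package computes:

* chromatin interaction networks per structure and their Markov-clustering
  **spatial partitions** (sizes, geometric centers, inter-chromosomal edge
  fractions, maximal-clique enrichment, neighborhood connectivity);
* predicted **nuclear speckle** and **nucleolus** locations (partition
  centers of speckle-prone or NAD/NOR chromatin);
* the **17 structural features** of each genomic region's nuclear
  microenvironment: RAD, RG, SpD, NuD, their cell-to-cell variability
  scores (δRAD, δRG, δSpD, δNuD), ILF, SAF, LAF, NAF, simulated TSA-seq
  signals (S-TSA, L-TSA, N-TSA), ICP and the median trans A/B ratio;
* downstream analysis: variability groups (A-LV/A-HV/B-LV/B-HV), decile
  groups, fold-change feature enrichment, ROC discrimination, and
  unsupervised K-means subcompartment prediction from structure alone;
* a synthetic-data module that generates toy genomes and ground-truth
  structure populations with planted architecture (speckle-anchored,
  lamina-anchored, nucleolus-anchored, variable and free chromatin), so
  the whole pipeline is testable end to end without external data.

The methods vignette (`vignettes/population-genome-modeling.Rmd`) gives
the full model description, parameter defaults and design rationale.

## Worked example

Simulate a toy truth population, deconvolve its contact matrix, and
characterize the microenvironment:

```r
library(nucenv)

truth <- makeToyTruth("small")           # 2 chromosomes, N = 50 bins
A     <- syntheticHic(simulatePopulation(truth, M = 200, seed = 11))
A
#> ContactMatrix: 50 x 50 haploid bins, 553 non-zero entries

model <- runPipeline(A, nucleus = truth@nucleus,
                     config = optimizerConfig(M = 100, seed = 1))
tail(attr(model, "log"), 1)
#>   iteration theta nRestraints violationScore correlation
#> 7         7  0.01       10072              0   0.9844335
```

The recovered population reproduces the input at genome-wide Pearson
r = 0.984, with all ~10,000 contact restraints satisfied (violation score
0). Predict speckles without annotations (from the 10% most interior
chromatin), nucleoli from the planted NAD regions, and build the feature
table:

```r
labs <- truthLabels(truth)
spk  <- predictSpeckles(model, "lowest_rad")
ncl  <- predictNucleoli(model, which(labs$subcompartment == "B2"))
tab  <- featureTable(model, spk, ncl, labs$compartment)
head(tab[, c("chrom", "start", "RAD", "SAF", "LAF", "dRAD")], 4)
#>   chrom  start   RAD   SAF   LAF  dRAD
#> 1  chr1      0 0.318 0.225 0.030 0.335
#> 2  chr1 200000 0.303 0.220 0.015 0.252
#> 3  chr1 400000 0.296 0.160 0.005 0.158
#> 4  chr1 600000 0.300 0.110 0.010 0.137
```

Each row is one 200-kb region: its mean radial position (fraction of the
nuclear radius), speckle/lamina association frequencies, and radial
variability score. The five regions with the highest speckle association
are all planted speckle-anchored chromatin:

```r
truth@classes[order(-tab$SAF)[1:5]]
#> [1] "speckle1" "speckle1" "speckle1" "speckle1" "speckle1"
```

A thin command-line wrapper (`exec/nucenv`) exposes the same stages as
subcommands (`synth`, `model`, `partitions`, `bodies`, `features`,
`enrich`, `subcomp`, `compare`), each writing a JSON run report beside
its output.

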