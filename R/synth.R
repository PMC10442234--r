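#' Deterministic toy genome
#'
#' @param chromLengths numeric chromosome lengths in bp (named or unnamed;
#'   unnamed chromosomes are called `chr1`, `chr2`, ...).
#' @param binSize bin size in bp (default 200 kb).
#' @return a [GenomeDefinition-class].
#' @export
makeToyGenome <- function(chromLengths, binSize = 2e5) {
    nm <- names(chromLengths)
    if (is.null(nm)) nm <- paste0("chr", seq_along(chromLengths))
    segmentGenome(data.frame(name = nm, length = as.numeric(chromLengths)),
                  binSize)
}

#' Planted toy nuclear architecture
#'
#' Builds a [SyntheticTruth-class] describing a small genome whose regions
#' fall into architecture classes emulating what population-based models
#' infer from real nuclei: speckle-anchored active clusters (two anchors on
#' roughly opposite sides of the nuclear interior), lamina-anchored
#' peripheral chromatin, nucleolus-anchored chromatin, interior "free"
#' chromatin, and "variable" chromatin alternating between interior and
#' peripheral placements. The toy keeps the physical geometry of a real
#' nucleus (`Rnuc` = 5000 nm, `Rex` = 118 nm per 200-kb bead) so the
#' contact capture distance is small relative to the nucleus; a toy genome
#' subset then fills only part of the nuclear volume, as a genome subset
#' would.
#'
#' @param preset `"small"` (6 + 4 Mb, N = 50) or `"medium"`
#'   (8 + 6 + 4 Mb, N = 90).
#' @param pAssoc probability that an anchored region is drawn within
#'   `anchorRadius` of its anchor in a given structure (default 0.9).
#' @param anchorRadius draw radius around body anchors, nm (default 500,
#'   matching the speckle association threshold).
#' @param shellFrac thickness of the peripheral shell as a fraction of
#'   `Rnuc` (default 0.15).
#' @param mixtureWeight probability that a variable block sits at the
#'   periphery in a given structure (default 0.5).
#' @param noise placement jitter for interpolated regions, nm (default 150).
#' @return a [SyntheticTruth-class].
#' @export
makeToyTruth <- function(preset = c("small", "medium"), pAssoc = 0.9,
                         anchorRadius = 500, shellFrac = 0.15,
                         mixtureWeight = 0.5, noise = 150) {
    preset <- match.arg(preset)
    if (preset == "small") {
        genome <- makeToyGenome(c(6e6, 4e6))
        classes <- c(rep("variable", 2), rep("free", 2), rep("lamina", 5),
                     rep("free", 5), rep("speckle1", 6), rep("free", 5),
                     rep("speckle2", 5),
                     rep("speckle1", 4), rep("free", 5),
                     rep("nucleolus", 4), rep("free", 4), rep("lamina", 3))
    } else {
        genome <- makeToyGenome(c(8e6, 6e6, 4e6))
        classes <- c(rep("variable", 3), rep("free", 3), rep("lamina", 6),
                     rep("free", 5), rep("speckle1", 8), rep("free", 5),
                     rep("speckle2", 10),
                     rep("variable", 3), rep("free", 3), rep("speckle2", 6),
                     rep("free", 5), rep("speckle1", 5), rep("free", 4),
                     rep("lamina", 4),
                     rep("speckle1", 4), rep("free", 5),
                     rep("nucleolus", 4), rep("free", 4), rep("lamina", 3))
    }
    sub <- c(speckle1 = "A1", speckle2 = "A1", free = "A2",
             variable = "A2", lamina = "B3", nucleolus = "B2")[classes]
    comp <- ifelse(sub %in% c("A1", "A2"), "A", "B")
    nucleus <- nucleusModel(Rnuc = 5000, occupancy = 0.40, Rex = 118)
    params <- list(pAssoc = pAssoc, anchorRadius = anchorRadius,
                   shellFrac = shellFrac, mixtureWeight = mixtureWeight,
                   noise = noise,
                   speckleDirs = rbind(c(1, 0, 0), c(0, 0, 1)),
                   speckleRadialRange = c(0.30, 0.55),
                   nucleolusDir = c(0, 1, 0),
                   nucleolusRadialRange = c(0.30, 0.55),
                   dirJitter = 0.15)
    new("SyntheticTruth", genome = genome, nucleus = nucleus,
        classes = unname(classes), subcompartment = unname(sub),
        compartment = unname(comp), params = params)
}

#' @describeIn makeToyTruth planted labels of a truth object
#' @param truth a [SyntheticTruth-class].
#' @export
truthLabels <- function(truth) {
    list(classes = truth@classes, subcompartment = truth@subcompartment,
         compartment = truth@compartment)
}

.jitterDir <- function(base, sd) {
    v <- base + stats::rnorm(3, sd = sd)
    v / sqrt(sum(v^2))
}

# contiguous runs of one class along a chromosome
.classRuns <- function(classes, chrom) {
    r <- rle(paste(chrom, classes, sep = "/"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lapply(seq_along(ends), function(k)
        list(bins = starts[k]:ends[k],
             class = sub("^[^/]*/", "", r$values[k])))
}

#' Simulate a ground-truth structure population with planted architecture
#'
#' For each structure, body anchors are drawn (speckle anchors near their
#' base directions at interior radial positions; one nucleolus anchor),
#' then each chromosome copy is placed class by class: anchored regions
#' fall within `anchorRadius` of their anchor with probability `pAssoc`,
#' lamina blocks occupy a coherent peripheral shell patch, variable blocks
#' flip between a peripheral patch and the interior with probability
#' `mixtureWeight`, and free regions interpolate between their placed
#' neighbors with Gaussian jitter. Chain connectivity, excluded volume and
#' nuclear confinement are then enforced by tethered constraint-projection
#' relaxation (the optimizer's own minimizer).
#'
#' @param truth a [SyntheticTruth-class].
#' @param M number of structures.
#' @param noise placement jitter in nm (defaults to the truth's value).
#' @param seed integer seed.
#' @return a [StructurePopulation-class] with attributes `anchors` (per
#'   structure: speckle anchor matrix and nucleolus anchor),
#'   `speckleMembership` (planted anchor id per haploid bin, `NA` for
#'   non-speckle regions), `realizedMembership` (2N x M: which body cluster
#'   each anchored bead was actually placed in, per structure - off-anchor
#'   block copies get their own id) and `truth`.
#' @export
simulatePopulation <- function(truth, M, noise = NULL, seed = 1L) {
    stopifnot(M >= 1)
    set.seed(seed)
    p <- truth@params
    if (is.null(noise)) noise <- p$noise
    genome <- truth@genome
    nuc <- truth@nucleus
    N <- nBins(genome)
    chrom <- binChrom(genome)
    classes <- truth@classes
    nSpeckles <- nrow(p$speckleDirs)
    if (nuc@Rnuc - nuc@Rex <= p$anchorRadius)
        stop("infeasible packing: anchors do not fit the nucleus")
    coords <- array(NA_real_, dim = c(2L * N, 3L, M))
    anchors <- vector("list", M)
    realized <- matrix(NA_character_, 2L * N, M)
    runs <- .classRuns(classes, chrom)
    shellLo <- (1 - p$shellFrac) * nuc@Rnuc
    shellHi <- nuc@Rnuc - nuc@Rex
    for (m in seq_len(M)) {
        spk <- t(vapply(seq_len(nSpeckles), function(k)
            .jitterDir(p$speckleDirs[k, ], p$dirJitter) *
                stats::runif(1, p$speckleRadialRange[1],
                             p$speckleRadialRange[2]) * nuc@Rnuc,
            numeric(3)))
        ncl <- .jitterDir(p$nucleolusDir, p$dirJitter) *
            stats::runif(1, p$nucleolusRadialRange[1],
                         p$nucleolusRadialRange[2]) * nuc@Rnuc
        anchors[[m]] <- list(speckle = spk, nucleolus = ncl)
        # guide anchor per run: nearest anchored run on the same chromosome
        # keeps peripheral patches on the same side as their chain neighbors
        guideFor <- function(runIdx) {
            me <- runs[[runIdx]]
            ch <- chrom[me$bins[1]]
            best <- NULL
            bestGap <- Inf
            for (other in runs) {
                if (chrom[other$bins[1]] != ch) next
                if (!grepl("^speckle|^nucleolus", other$class)) next
                gap <- min(abs(outer(me$bins, other$bins, `-`)))
                if (gap < bestGap) {
                    bestGap <- gap
                    best <- if (other$class == "nucleolus") ncl
                            else spk[as.integer(sub("speckle", "",
                                                    other$class)), ]
                }
            }
            if (is.null(best)) stats::rnorm(3) else best
        }
        for (copy in 0:1) {
            pos <- matrix(NA_real_, N, 3)
            # anchored / peripheral / variable blocks first
            for (ri in seq_along(runs)) {
                run <- runs[[ri]]
                cls <- run$class
                b <- run$bins
                if (cls == "free") next
                if (grepl("^speckle|^nucleolus", cls)) {
                    anchor <- if (cls == "nucleolus") ncl
                              else spk[as.integer(sub("speckle", "",
                                                      cls)), ]
                    # association is decided per block copy: with
                    # probability pAssoc the whole block sits at its
                    # anchor, otherwise it forms a blob elsewhere
                    if (stats::runif(1) < p$pAssoc) {
                        pos[b, ] <- sweep(
                            .runifBall(length(b), p$anchorRadius), 2,
                            anchor, `+`)
                        realized[b + copy * N, m] <- cls
                    } else {
                        ctr <- .runifBall(1, 0.7 * nuc@Rnuc)
                        pos[b, ] <- sweep(
                            .runifBall(length(b), p$anchorRadius), 2,
                            as.numeric(ctr), `+`)
                        realized[b + copy * N, m] <-
                            paste0(cls, "-off-", ri, "-", copy)
                    }
                } else if (cls == "lamina" ||
                           (cls == "variable" &&
                            stats::runif(1) < p$mixtureWeight)) {
                    patch <- .jitterDir(guideFor(ri), p$dirJitter)
                    for (bb in b)
                        pos[bb, ] <- .jitterDir(patch, p$dirJitter) *
                            stats::runif(1, shellLo, shellHi)
                } else { # interior placement of a variable block
                    ctr <- .jitterDir(guideFor(ri), p$dirJitter) *
                        stats::runif(1, 0.1, 0.4) * nuc@Rnuc
                    pos[b, ] <- sweep(.runifBall(length(b), 2 * noise), 2,
                                      ctr, `+`)
                }
            }
            # free regions: interpolate between placed neighbors
            for (run in runs) {
                if (run$class != "free") next
                b <- run$bins
                ch <- chrom[b[1]]
                left <- b[1] - 1L
                leftPos <- if (left >= 1L && chrom[left] == ch &&
                               !anyNA(pos[left, ]))
                    pos[left, ] else NULL
                right <- b[length(b)] + 1L
                rightPos <- if (right <= N && chrom[right] == ch &&
                                !anyNA(pos[right, ]))
                    pos[right, ] else NULL
                for (j in seq_along(b)) {
                    w <- j / (length(b) + 1)
                    base <- if (!is.null(leftPos) && !is.null(rightPos)) {
                        (1 - w) * leftPos + w * rightPos
                    } else if (!is.null(leftPos)) {
                        leftPos
                    } else if (!is.null(rightPos)) {
                        rightPos
                    } else {
                        as.numeric(.runifBall(1, 0.5 * nuc@Rnuc))
                    }
                    pos[b[j], ] <- base + stats::rnorm(3, sd = noise)
                }
            }
            coords[seq_len(N) + copy * N, , m] <- pos
        }
    }
    # enforce chain / excluded-volume / envelope feasibility
    noContacts <- matrix(integer(), 0, 3)
    bonds <- chainBonds(genome) - 1L
    D <- nuc@contactDistance
    relaxSeed <- as.integer(seed %% 1e6) + 17L
    res <- .cppRelax(coords, bonds, noContacts, D, D, nuc@Rex, nuc@Rnuc,
                     2L, 150L, 0, 0.05, coords, 0.05, relaxSeed)
    res <- .cppRelax(res$coords, bonds, noContacts, D, D, nuc@Rex,
                     nuc@Rnuc, 1L, 400L, 0, 0, NULL, 0.05, relaxSeed + 1L)
    pop <- structurePopulation(genome, nuc, res$coords, seed)
    membership <- rep(NA_integer_, N)
    spkIdx <- grepl("^speckle", classes)
    membership[spkIdx] <- as.integer(sub("speckle", "", classes[spkIdx]))
    attr(pop, "anchors") <- anchors
    attr(pop, "speckleMembership") <- membership
    attr(pop, "realizedMembership") <- realized
    attr(pop, "truth") <- truth
    pop
}

#' Synthetic Hi-C from a simulated population
#'
#' The contact matrix of the generated population under the standard
#' capture rule (`d <= 2 Rsoft`), hence realizable by construction.
#'
#' @param pop a [StructurePopulation-class] from [simulatePopulation()].
#' @return a [ContactMatrix-class].
#' @export
syntheticHic <- function(pop) {
    populationContactFrequencies(pop)
}

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", nBins(object@genome), "bins;",
        "classes:", paste(sprintf("%s=%d",
                                  names(table(object@classes)),
                                  table(object@classes)),
                          collapse = ", "), "\n")
})
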