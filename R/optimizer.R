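#' Optimizer configuration for population-based deconvolution
#'
#' @param M population size (number of structures).
#' @param thetas strictly decreasing activation thresholds; contacts with
#'   probability at least the current theta are restrained, so optimization
#'   hardness grows as theta decreases.
#' @param maxIterPerTheta assignment/modeling iterations per theta.
#' @param nStages annealing stages per modeling step (Gaussian kicks with
#'   amplitude decaying to zero, then projection sweeps).
#' @param sweepsPerStage Gauss-Seidel projection sweeps per stage.
#' @param kickSigma initial kick amplitude, nm.
#' @param violTol stop a theta round when the fraction of restraints with
#'   relative excess above `relTol` drops below this.
#' @param relTol relative excess defining a violated restraint.
#' @param seed integer seed for all pipeline randomness.
#' @return a list of class `OptimizerConfig`.
#' @export
optimizerConfig <- function(M = 100L,
                            thetas = c(1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01),
                            maxIterPerTheta = 4L, nStages = 4L,
                            sweepsPerStage = 60L, kickSigma = 50,
                            violTol = 0.01, relTol = 0.05, seed = 1L) {
    stopifnot(all(diff(thetas) < 0), violTol > 0, M >= 1)
    structure(list(M = as.integer(M), thetas = thetas,
                   maxIterPerTheta = as.integer(maxIterPerTheta),
                   nStages = as.integer(nStages),
                   sweepsPerStage = as.integer(sweepsPerStage),
                   kickSigma = kickSigma, violTol = violTol,
                   relTol = relTol, seed = as.integer(seed)),
              class = "OptimizerConfig")
}

#' Random starting configurations inside chromosome territories
#'
#' Each chromosome copy gets a territory sphere whose volume is the
#' chromosome's share of the nuclear volume,
#' `r_c = Rnuc * (n_c / 2N)^(1/3)` with `n_c` the chromosome's bead count -
#' radius proportional to the cube root of the bead count, as chromosome
#' territories partition the nucleus. Territory centers are placed
#' uniformly so the sphere fits in the nucleus, and beads are sampled
#' uniformly within their territory.
#'
#' @param genome a [GenomeDefinition-class].
#' @param nucleus a [NucleusModel-class].
#' @param M number of structures.
#' @param seed integer seed.
#' @return a [StructurePopulation-class].
#' @export
initializePopulation <- function(genome, nucleus, M, seed = 1L) {
    set.seed(seed)
    N <- nBins(genome)
    chrom <- binChrom(genome)
    counts <- tabulate(chrom)
    rTerr <- nucleus@Rnuc * (counts / (2 * N))^(1 / 3)
    # a territory must be able to pack its beads (random close packing)
    if (any(counts * (nucleus@Rex / rTerr)^3 > 0.64))
        stop("territory cannot fit its beads; the nucleus is too small")
    coords <- array(0, dim = c(2L * N, 3L, M))
    for (m in seq_len(M)) {
        for (copy in 0:1) {
            for (c in seq_along(counts)) {
                ctr <- .runifBall(1, nucleus@Rnuc - rTerr[c])
                idx <- which(chrom == c) + copy * N
                coords[idx, , m] <- sweep(.runifBall(length(idx), rTerr[c]),
                                          2, as.numeric(ctr), `+`)
            }
        }
    }
    structurePopulation(genome, nucleus, coords, seed)
}

# uniform points in a ball of radius r (matrix n x 3)
.runifBall <- function(n, r) {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    v * r * stats::runif(n)^(1 / 3)
}

#' Assignment step (A-step)
#'
#' For every haploid pair with input probability `a >= theta`, the contact
#' must appear in `k = round(a * M)` structures. In each structure the
#' copy combination with the minimal current distance is taken (cis pairs:
#' the two within-homolog combinations; trans pairs: all four), structures
#' are ranked by that distance, and the contact is assigned in the `k` best.
#'
#' @param pop a [StructurePopulation-class].
#' @param A input [ContactMatrix-class] on the same genome.
#' @param theta activation threshold.
#' @return a [ContactAssignment-class].
#' @export
assignmentStep <- function(pop, A, theta) {
    stopifnot(nBins(pop@genome) == nBins(A@genome))
    N <- nBins(pop@genome)
    M <- nStructures(pop)
    e <- A@entries
    excl <- pop@genome@excluded
    act <- e$p >= theta & !excl[e$I] & !excl[e$J]
    e <- e[act, , drop = FALSE]
    chrom <- binChrom(pop@genome)
    cis <- chrom[e$I] == chrom[e$J]
    k <- round(e$p * M)
    keep <- k > 0L
    e <- e[keep, , drop = FALSE]
    cis <- cis[keep]
    k <- k[keep]
    pairs <- data.frame(I = e$I, J = e$J, a = e$p, k = as.integer(k),
                        cis = cis)
    if (!nrow(pairs)) {
        return(new("ContactAssignment",
                   pairs = pairs,
                   contacts = matrix(integer(), 0, 4,
                                     dimnames = list(NULL, c("structure",
                                                             "p", "q",
                                                             "pair"))),
                   theta = theta))
    }
    md <- .cppMinComboDistance(pop@coords,
                               cbind(pairs$I - 1L, pairs$J - 1L), pairs$cis)
    contacts <- vector("list", nrow(pairs))
    comboP <- function(I, combo) ifelse(combo >= 2L, I + N, I)
    comboQ <- function(J, combo) ifelse(combo %% 2L == 1L | combo == 3L,
                                        J + N, J)
    for (r in seq_len(nrow(pairs))) {
        sel <- order(md$dmin[r, ])[seq_len(pairs$k[r])]
        cmb <- md$combo[r, sel]
        contacts[[r]] <- cbind(structure = sel,
                               p = comboP(pairs$I[r], cmb),
                               q = comboQ(pairs$J[r], cmb),
                               pair = r)
    }
    contacts <- do.call(rbind, contacts)
    contacts <- contacts[order(contacts[, "structure"]), , drop = FALSE]
    new("ContactAssignment", pairs = pairs, contacts = contacts,
        theta = theta)
}

#' Modeling step (M-step)
#'
#' Independently relaxes each structure under one-sided harmonic penalties:
#' assigned contacts at `d <= 2 Rsoft`, chain bonds at `d <= 2 Rsoft`,
#' excluded volume at `d >= 2 Rex`, and nuclear confinement `|x| <= Rnuc`.
#' Annealing is staged constraint projection with decaying random kicks;
#' the best (lowest-penalty) configuration seen, including the input, is
#' kept, so the total penalty never increases for a fixed assignment.
#'
#' @param pop a [StructurePopulation-class].
#' @param assignment a [ContactAssignment-class].
#' @param config an [optimizerConfig()] list.
#' @param seed optional integer overriding `config$seed` for the kick noise.
#' @return the relaxed [StructurePopulation-class], with a per-structure
#'   summary in `attr(, "residuals")`: penalties before/after, violated
#'   restraint counts and totals, and the overall violation score (fraction
#'   of restraints violated beyond `relTol`).
#' @export
modelingStep <- function(pop, assignment, config = optimizerConfig(),
                         seed = NULL) {
    nuc <- pop@nucleus
    D <- nuc@contactDistance
    res <- .cppRelax(pop@coords, chainBonds(pop@genome) - 1L,
                     .contactRows(assignment), D, D, nuc@Rex, nuc@Rnuc,
                     config$nStages, config$sweepsPerStage, config$kickSigma,
                     0, NULL, config$relTol,
                     if (is.null(seed)) config$seed else as.integer(seed))
    out <- structurePopulation(pop@genome, nuc, res$coords, pop@seed)
    summary <- data.frame(penaltyBefore = res$penaltyBefore,
                          penaltyAfter = res$penaltyAfter,
                          violations = res$violations,
                          nRestraints = res$nRestraints)
    attr(out, "residuals") <- summary
    attr(out, "violationScore") <- sum(res$violations) /
        max(1, sum(res$nRestraints))
    out
}

.contactRows <- function(assignment) {
    ct <- assignment@contacts
    if (!nrow(ct)) return(matrix(integer(), 0, 3))
    cbind(ct[, "structure"] - 1L, ct[, "p"] - 1L, ct[, "q"] - 1L)
}

#' Run the full A-step/M-step deconvolution pipeline
#'
#' Loops over the decreasing theta schedule; within each theta, alternates
#' assignment and modeling steps until the violation score falls below
#' `config$violTol` or `config$maxIterPerTheta` is reached. Logs theta, the
#' active restraint count, the violation score, and the genome-wide
#' correlation between input and current model contact frequencies.
#'
#' @param A input [ContactMatrix-class].
#' @param genome a [GenomeDefinition-class] (defaults to `A`'s genome).
#' @param nucleus a [NucleusModel-class].
#' @param config an [optimizerConfig()] list.
#' @return a [StructurePopulation-class] with the convergence log in
#'   `attr(, "log")` and the final input/model comparison in
#'   `attr(, "comparison")`.
#' @export
runPipeline <- function(A, genome = A@genome, nucleus,
                        config = optimizerConfig()) {
    set.seed(config$seed)
    pop <- initializePopulation(genome, nucleus, config$M, config$seed)
    log <- list()
    it <- 0L
    for (theta in config$thetas) {
        for (rep in seq_len(config$maxIterPerTheta)) {
            it <- it + 1L
            asg <- assignmentStep(pop, A, theta)
            pop <- modelingStep(pop, asg, config, seed = config$seed + it)
            viol <- attr(pop, "violationScore")
            fcor <- tryCatch(
                compareMatrices(A, populationContactFrequencies(pop))$pearson,
                error = function(e) NA_real_)
            log[[it]] <- data.frame(iteration = it, theta = theta,
                                    nRestraints = nrow(asg@contacts),
                                    violationScore = viol,
                                    correlation = fcor)
            if (viol < config$violTol) break
        }
    }
    attr(pop, "log") <- do.call(rbind, log)
    attr(pop, "comparison") <- tryCatch(
        compareMatrices(A, populationContactFrequencies(pop)),
        error = function(e) NULL)
    attr(pop, "assignment") <- asg
    pop
}

#' Restraint residuals of an assignment
#'
#' For every assigned contact, `eta = (d - D) / D` with `D = 2 Rsoft` the
#' target contact distance and `d` the realized bead distance.
#'
#' @param pop a [StructurePopulation-class].
#' @param assignment a [ContactAssignment-class] consistent with `pop`.
#' @return list with per-restraint `eta` and a `summary` (mean, median,
#'   fraction above 0.05).
#' @export
restraintResiduals <- function(pop, assignment) {
    ct <- assignment@contacts
    D <- pop@nucleus@contactDistance
    if (!nrow(ct))
        return(list(eta = numeric(),
                    summary = data.frame(n = 0L, mean = NA_real_,
                                         median = NA_real_,
                                         fracAbove05 = NA_real_)))
    d <- vapply(seq_len(nrow(ct)), function(r) {
        m <- ct[r, "structure"]
        sqrt(sum((pop@coords[ct[r, "p"], , m] -
                  pop@coords[ct[r, "q"], , m])^2))
    }, 0)
    eta <- (d - D) / D
    list(eta = eta,
         summary = data.frame(n = length(eta), mean = mean(eta),
                              median = stats::median(eta),
                              fracAbove05 = mean(eta > 0.05)))
}

#' Sparse-data imputation experiment
#'
#' Removes a fraction of the non-zero input entries uniformly at random,
#' re-runs the pipeline on the remainder, and reports the correlation
#' between model-derived frequencies and the held-out entries, cis and
#' trans separately.
#'
#' @param A input [ContactMatrix-class].
#' @param nucleus a [NucleusModel-class].
#' @param dropFraction fraction of non-zero entries to remove (paper
#'   protocol: 0.5).
#' @param seed seed for the removal draw.
#' @param config an [optimizerConfig()] list.
#' @return list with `heldOut` (entry data.frame with model values),
#'   `cisPearson`, `transPearson`, `nHeldOut`, and the trained `pop`.
#' @export
sparseDataExperiment <- function(A, nucleus, dropFraction = 0.5, seed = 1L,
                                 config = optimizerConfig()) {
    stopifnot(dropFraction >= 0, dropFraction < 1)
    e <- A@entries
    set.seed(seed)
    nDrop <- round(dropFraction * nrow(e))
    drop <- sort(sample.int(nrow(e), nDrop))
    Asparse <- new("ContactMatrix", genome = A@genome,
                   entries = if (nDrop)
                       e[-drop, , drop = FALSE] else e)
    pop <- runPipeline(Asparse, nucleus = nucleus, config = config)
    Fm <- as.matrix.ContactMatrix(populationContactFrequencies(pop))
    held <- e[drop, , drop = FALSE]
    chrom <- binChrom(A@genome)
    cis <- chrom[held$I] == chrom[held$J]
    held$model <- Fm[cbind(held$I, held$J)]
    corOr <- function(x, y) if (length(x) >= 3L) stats::cor(x, y) else NA_real_
    list(heldOut = held,
         cisPearson = corOr(held$p[cis], held$model[cis]),
         transPearson = corOr(held$p[!cis], held$model[!cis]),
         nHeldOut = nDrop,
         pop = pop)
}

setMethod("show", "ContactAssignment", function(object) {
    cat("ContactAssignment: theta =", object@theta, "-",
        nrow(object@pairs), "active pairs,",
        nrow(object@contacts), "assigned contacts\n")
})
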