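#' Radial positions of all beads
#'
#' Computes `|x| / Rnuc` per bead and structure; the per-region mean pools both
#' homologous copies over all structures (2M configurations).
#'
#' @param pop a [StructurePopulation-class].
#' @return list with `matrix` (2N x M radial positions) and `mean` (per
#'   haploid region, RAD); excluded bins are `NA` in `mean`.
#' @export
radialPositions <- function(pop) {
    r <- sqrt(apply(pop@coords^2, c(1, 3), sum)) / pop@nucleus@Rnuc
    m <- .regionMean(r, nBins(pop@genome))
    m[pop@genome@excluded] <- NA_real_
    list(matrix = r, mean = m)
}

# mean over 2 copies x M structures per haploid region; NAs skipped
.regionMean <- function(beadByStructure, N) {
    both <- cbind(beadByStructure[seq_len(N), , drop = FALSE],
                  beadByStructure[N + seq_len(N), , drop = FALSE])
    rowMeans(both, na.rm = TRUE)
}

#' Local chromatin compaction (radius-of-gyration statistic)
#'
#' For each bead and structure, the sum of squared distances of the beads in
#' a window (default 1 Mb, centered at the locus, same chromosome copy) to
#' the window's center of mass. The printed formula sums squared distances
#' without dividing or taking a root; set `conventional = TRUE` for the
#' usual root-mean-square form.
#'
#' @param pop a [StructurePopulation-class].
#' @param window window width in bp (odd multiple of the bin size).
#' @param conventional if `TRUE`, return `sqrt(mean(d^2))` instead of
#'   `sum(d^2)`.
#' @return list with `matrix` (2N x M) and `mean` per haploid region.
#' @export
localCompaction <- function(pop, window = 1e6, conventional = FALSE) {
    binSize <- pop@genome@binSize
    half <- (window / binSize - 1) / 2
    if (half != round(half) || half < 0)
        stop("window must be an odd multiple of the bin size")
    N <- nBins(pop@genome)
    chrom <- binChrom(pop@genome)
    M <- nStructures(pop)
    rg <- matrix(NA_real_, 2L * N, M)
    for (copy in 0:1) {
        for (I in seq_len(N)) {
            win <- (I - half):(I + half)
            win <- win[win >= 1 & win <= N]
            win <- win[chrom[win] == chrom[I]]
            beads <- win + copy * N
            for (m in seq_len(M)) {
                xyz <- pop@coords[beads, , m, drop = FALSE]
                dim(xyz) <- c(length(beads), 3L)
                com <- colMeans(xyz)
                d2 <- rowSums(sweep(xyz, 2, com)^2)
                rg[I + copy * N, m] <- if (conventional)
                    sqrt(mean(d2)) else sum(d2)
            }
        }
    }
    m <- .regionMean(rg, N)
    m[pop@genome@excluded] <- NA_real_
    list(matrix = rg, mean = m)
}

# per bead x structure distance to the nearest body center; NA when a
# structure has no bodies
.bodyDistanceMatrix <- function(pop, bodies) {
    n2 <- nBeads(pop@genome)
    M <- nStructures(pop)
    d <- matrix(NA_real_, n2, M)
    for (m in seq_len(M)) {
        bs <- bodies[[m]]
        if (!length(bs)) next
        centers <- do.call(rbind, lapply(bs, `[[`, "center"))
        xyz <- pop@coords[, , m]
        dd <- outer(rowSums(xyz^2), rowSums(centers^2), `+`) -
            2 * xyz %*% t(centers)
        dd[dd < 0] <- 0
        d[, m] <- sqrt(apply(dd, 1, min))
    }
    d
}

#' Distance to the nearest nuclear body (SpD / NuD)
#'
#' Center-to-center distance from each bead to the closest body in each
#' structure; structures without a body are excluded from that region's
#' mean.
#'
#' @param pop a [StructurePopulation-class].
#' @param bodies a `BodyLocations` list (see [predictSpeckles()]).
#' @return list with `matrix` (2N x M, `NA` for body-free structures) and
#'   `mean` per haploid region (nm).
#' @export
bodyDistanceFeatures <- function(pop, bodies) {
    if (all(vapply(bodies, length, 0L) == 0L))
        stop("no bodies in any structure")
    d <- .bodyDistanceMatrix(pop, bodies)
    m <- .regionMean(d, nBins(pop@genome))
    m[pop@genome@excluded] <- NA_real_
    list(matrix = d, mean = m)
}

#' Cell-to-cell variability of a structural feature (delta features)
#'
#' `sigma_I` is the standard deviation of the 2M single-cell values of
#' region I (both copies pooled); `sigma_bar` the mean of `sigma` over all
#' regions of I's chromosome; the variability score is
#' `delta_I = log2(sigma_I / sigma_bar)`.
#'
#' @param singleCell 2N x M single-cell feature matrix.
#' @param genome a [GenomeDefinition-class].
#' @return numeric per haploid region; `NA` where undefined.
#' @export
featureVariability <- function(singleCell, genome) {
    N <- nBins(genome)
    both <- cbind(singleCell[seq_len(N), , drop = FALSE],
                  singleCell[N + seq_len(N), , drop = FALSE])
    sigma <- apply(both, 1, stats::sd, na.rm = TRUE)
    sigma[genome@excluded] <- NA_real_
    chrom <- binChrom(genome)
    sigmaBar <- stats::ave(sigma, chrom,
                           FUN = function(v) mean(v, na.rm = TRUE))
    delta <- log2(sigma / sigmaBar)
    delta[!is.finite(delta)] <- NA_real_
    delta
}

#' Interior localization frequency (ILF)
#'
#' Fraction of structures in which either copy of the region has a radial
#' position below 0.5.
#'
#' @param radialMatrix 2N x M radial-position matrix from
#'   [radialPositions()].
#' @param genome a [GenomeDefinition-class].
#' @return numeric per haploid region in `[0, 1]`.
#' @export
interiorLocalizationFrequency <- function(radialMatrix, genome) {
    N <- nBins(genome)
    interior <- radialMatrix[seq_len(N), , drop = FALSE] < 0.5 |
        radialMatrix[N + seq_len(N), , drop = FALSE] < 0.5
    ilf <- rowMeans(interior)
    ilf[genome@excluded] <- NA_real_
    ilf
}

#' Nuclear-body association frequencies (SAF / LAF / NAF)
#'
#' `AF_I = (n_{d_i < d_t} + n_{d_i' < d_t}) / 2M`, counting structures in
#' which each copy lies within the association threshold of the body.
#' Distances are measured from the bead surface: to the body center for
#' speckles/nucleoli (`d - Rex`), and to the nuclear envelope for the
#' lamina (`Rnuc - |x| - Rex`). Structures without a predicted body count
#' as non-associated (the denominator stays 2M). Default thresholds:
#' 500 nm (speckle), `0.35 * Rnuc` (lamina), 1000 nm (nucleolus).
#'
#' @param pop a [StructurePopulation-class].
#' @param target `"speckle"`, `"lamina"` or `"nucleolus"`.
#' @param bodies `BodyLocations`, required for speckle/nucleolus.
#' @param threshold association threshold `d_t` in nm (defaults as above).
#' @return numeric per haploid region in `[0, 1]`.
#' @export
associationFrequency <- function(pop,
                                 target = c("speckle", "lamina",
                                            "nucleolus"),
                                 bodies = NULL, threshold = NULL) {
    target <- match.arg(target)
    nuc <- pop@nucleus
    if (is.null(threshold))
        threshold <- switch(target, speckle = 500,
                            lamina = 0.35 * nuc@Rnuc, nucleolus = 1000)
    if (target == "lamina") {
        r <- sqrt(apply(pop@coords^2, c(1, 3), sum))
        surf <- nuc@Rnuc - r - nuc@Rex
    } else {
        if (is.null(bodies)) stop("bodies required for ", target)
        if (all(vapply(bodies, length, 0L) == 0L))
            stop("no bodies in any structure")
        surf <- .bodyDistanceMatrix(pop, bodies) - nuc@Rex
        surf[is.na(surf)] <- Inf  # body-free structures: non-associated
    }
    assoc <- surf < threshold
    N <- nBins(pop@genome)
    af <- (rowSums(assoc[seq_len(N), , drop = FALSE]) +
           rowSums(assoc[N + seq_len(N), , drop = FALSE])) /
        (2 * nStructures(pop))
    af[pop@genome@excluded] <- NA_real_
    af
}

#' Simulated TSA-seq signal (S-TSA / N-TSA / L-TSA)
#'
#' Per copy, `sig_i = (1/M) sum_m sum_l exp(-R0 * d_il)` with distances in
#' micrometers and `R0` the per-um decay constant of the tyramide
#' free-radical diffusion (default 4). For the lamina the per-structure
#' distance is `(1 - r) * Rnuc`. Signals are normalized as
#' `log2(sig / mean(sig))` over all per-copy signals, then averaged over the
#' two copies of each region.
#'
#' @param pop a [StructurePopulation-class].
#' @param target `"speckle"`, `"nucleolus"` or `"lamina"`.
#' @param bodies `BodyLocations`, required for speckle/nucleolus.
#' @param R0 decay constant per micrometer.
#' @return list with `signal` (normalized, per haploid region),
#'   `perCopy` (normalized per-copy signals, length 2N) and `raw`
#'   (per-copy raw signals).
#' @export
tsaSignal <- function(pop, target = c("speckle", "nucleolus", "lamina"),
                      bodies = NULL, R0 = 4) {
    target <- match.arg(target)
    stopifnot(R0 > 0)
    n2 <- nBeads(pop@genome)
    M <- nStructures(pop)
    if (target == "lamina") {
        r <- sqrt(apply(pop@coords^2, c(1, 3), sum)) / pop@nucleus@Rnuc
        dUm <- (1 - r) * pop@nucleus@Rnuc / 1000
        raw <- rowMeans(exp(-R0 * dUm))
    } else {
        if (is.null(bodies)) stop("bodies required for ", target)
        sig <- matrix(0, n2, M)
        for (m in seq_len(M)) {
            bs <- bodies[[m]]
            if (!length(bs)) next
            centers <- do.call(rbind, lapply(bs, `[[`, "center"))
            xyz <- pop@coords[, , m]
            dd <- outer(rowSums(xyz^2), rowSums(centers^2), `+`) -
                2 * xyz %*% t(centers)
            dd[dd < 0] <- 0
            sig[, m] <- rowSums(exp(-R0 * sqrt(dd) / 1000))
        }
        raw <- rowMeans(sig)
    }
    if (mean(raw) <= 0) stop("zero mean TSA signal")
    perCopy <- log2(raw / mean(raw))
    N <- nBins(pop@genome)
    signal <- (perCopy[seq_len(N)] + perCopy[N + seq_len(N)]) / 2
    signal[pop@genome@excluded] <- NA_real_
    list(signal = signal, perCopy = perCopy, raw = raw)
}

#' Inter-chromosomal neighborhood probability (ICP)
#'
#' For each copy and structure, the fraction of spatial neighbors (center
#' distance below `radius`) that lie on other chromosomes (the homologous
#' copy counts as the same chromosome); empty neighborhoods contribute 0.
#' `ICP_I` averages over both copies and all structures.
#'
#' @param pop a [StructurePopulation-class].
#' @param radius neighborhood radius, nm (default 500).
#' @return numeric per haploid region in `[0, 1]`.
#' @export
interChromosomalProbability <- function(pop, radius = 500) {
    cnt <- .cppNeighborCounts(pop@coords, binChrom(pop@genome),
                              integer(nBins(pop@genome)), radius)
    tot <- cnt$intra + cnt$inter
    frac <- ifelse(tot > 0, cnt$inter / tot, 0)
    icp <- .regionMean(frac, nBins(pop@genome))
    icp[pop@genome@excluded] <- NA_real_
    icp
}

#' Median trans A/B ratio
#'
#' For each copy and structure, the trans neighborhood collects
#' other-chromosome beads within `radius`; the ratio is
#' `(n_A + eps) / (n_B + eps)` with pseudocount `eps = 1`. The per-region
#' value is the median over all 2M observations, then min-max rescaled to
#' `[0, 1]` across regions.
#'
#' @param pop a [StructurePopulation-class].
#' @param abLabels character per haploid bin, `"A"` or `"B"`.
#' @param radius neighborhood radius, nm (default 500).
#' @param eps pseudocount guarding against division by zero.
#' @return list with `rescaled` (in `[0, 1]`), `median` (raw per-region
#'   medians) and `matrix` (2N x M ratios).
#' @export
transABRatio <- function(pop, abLabels, radius = 500, eps = 1) {
    N <- nBins(pop@genome)
    if (any(is.na(abLabels) & !pop@genome@excluded) ||
        !all(abLabels[!pop@genome@excluded] %in% c("A", "B")))
        stop("every non-excluded region must be labeled A or B")
    lab <- ifelse(is.na(abLabels), 0L, ifelse(abLabels == "A", 1L, 2L))
    cnt <- .cppNeighborCounts(pop@coords, binChrom(pop@genome),
                              as.integer(lab), radius)
    ratio <- (cnt$A + eps) / (cnt$B + eps)
    both <- cbind(ratio[seq_len(N), , drop = FALSE],
                  ratio[N + seq_len(N), , drop = FALSE])
    med <- apply(both, 1, stats::median)
    med[pop@genome@excluded] <- NA_real_
    rng <- range(med, na.rm = TRUE)
    rescaled <- if (diff(rng) > 0)
        (med - rng[1]) / diff(rng) else med * 0
    list(rescaled = rescaled, median = med, matrix = ratio)
}

#' Assemble the 17-feature table of the nuclear microenvironment
#'
#' Computes RAD, RG, SpD, NuD, their variability scores (dRAD, dRG, dSpD,
#' dNuD), ILF, SAF, LAF, NAF, S_TSA, L_TSA, N_TSA, ICP and TRANS_AB per
#' haploid region and returns them as a BED-like data.frame. Excluded bins
#' carry missing values.
#'
#' @param pop a [StructurePopulation-class].
#' @param speckles `BodyLocations` for speckles.
#' @param nucleoli `BodyLocations` for nucleoli.
#' @param abLabels character per haploid bin, `"A"` or `"B"`.
#' @return data.frame with `chrom`, `start`, `end` and the 17 feature
#'   columns.
#' @export
featureTable <- function(pop, speckles, nucleoli, abLabels) {
    if (missing(speckles) || is.null(speckles))
        stop("missing prerequisite: speckle bodies")
    if (missing(nucleoli) || is.null(nucleoli))
        stop("missing prerequisite: nucleolus bodies")
    if (missing(abLabels) || is.null(abLabels))
        stop("missing prerequisite: A/B compartment labels")
    genome <- pop@genome
    rad <- radialPositions(pop)
    rg <- localCompaction(pop)
    spd <- bodyDistanceFeatures(pop, speckles)
    nud <- bodyDistanceFeatures(pop, nucleoli)
    out <- binTable(genome)
    out$RAD <- rad$mean
    out$RG <- rg$mean
    out$SpD <- spd$mean
    out$NuD <- nud$mean
    out$dRAD <- featureVariability(rad$matrix, genome)
    out$dRG <- featureVariability(rg$matrix, genome)
    out$dSpD <- featureVariability(spd$matrix, genome)
    out$dNuD <- featureVariability(nud$matrix, genome)
    out$ILF <- interiorLocalizationFrequency(rad$matrix, genome)
    out$SAF <- associationFrequency(pop, "speckle", speckles)
    out$LAF <- associationFrequency(pop, "lamina")
    out$NAF <- associationFrequency(pop, "nucleolus", nucleoli)
    out$S_TSA <- tsaSignal(pop, "speckle", speckles)$signal
    out$L_TSA <- tsaSignal(pop, "lamina")$signal
    out$N_TSA <- tsaSignal(pop, "nucleolus", nucleoli)$signal
    out$ICP <- interChromosomalProbability(pop)
    out$TRANS_AB <- transABRatio(pop, abLabels)$rescaled
    out
}

#' Write a feature table as a BED-like TSV
#' @param table data.frame from [featureTable()].
#' @param path output path.
#' @export
writeFeatureTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#' @param path input path.
#' @export
readFeatureTable <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}
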