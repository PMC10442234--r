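#' Build a chromatin interaction network for one structure
#'
#' Vertices are the selected diploid beads; an edge connects two beads whose
#' center distance is at most `2 * Rsoft` in that structure.
#'
#' @param pop a [StructurePopulation-class].
#' @param structure structure index (1-based).
#' @param subset diploid bead indices forming the node set; use
#'   [expandToBeads()] to expand haploid bins to both copies.
#' @return an [igraph::graph] with vertex attributes `bead`, `bin`, `chrom`.
#' @export
buildCIN <- function(pop, structure, subset) {
    stopifnot(length(subset) > 0)
    xyz <- pop@coords[subset, , structure, drop = FALSE]
    dim(xyz) <- c(length(subset), 3L)
    E <- .cppEdges(xyz, pop@nucleus@contactDistance)
    g <- igraph::make_empty_graph(n = length(subset), directed = FALSE)
    if (nrow(E)) g <- igraph::add_edges(g, t(E))
    bi <- beadIndex(pop@genome)
    igraph::V(g)$bead <- subset
    igraph::V(g)$bin <- bi$bin[subset]
    igraph::V(g)$chrom <- bi$chrom[subset]
    g
}

#' Expand haploid bin indices to both diploid copies
#' @param genome a [GenomeDefinition-class].
#' @param bins haploid bin indices.
#' @export
expandToBeads <- function(genome, bins) {
    c(bins, bins + nBins(genome))
}

#' Markov clustering (MCL) of a network
#'
#' Implements the MCL flow simulation: add self-loops, column-normalize,
#' then iterate expansion (matrix squaring) and inflation (entrywise power
#' followed by column renormalization), pruning values below `prune`, until
#' the matrix is (numerically) idempotent. Clusters are read off attractor
#' rows; overlapping attractor supports are merged, so clusters never span
#' disconnected components.
#'
#' @param network an [igraph::graph].
#' @param inflation inflation exponent (default 1.5).
#' @param expansion expansion power (default 2).
#' @param prune drop matrix values below this between iterations.
#' @param maxIter maximum iterations; non-convergence returns the current
#'   interpretation with a warning.
#' @return integer membership vector (1-based cluster ids per vertex).
#' @export
markovCluster <- function(network, inflation = 1.5, expansion = 2,
                          prune = 1e-5, maxIter = 100L) {
    n <- igraph::vcount(network)
    stopifnot(n > 0)
    A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
    A <- methods::as(A, "dMatrix")
    M <- A + Matrix::Diagonal(n)
    M <- M %*% Matrix::Diagonal(n, 1 / Matrix::colSums(M))
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        Mold <- M
        for (e in seq_len(expansion - 1L)) M <- M %*% M
        M@x <- M@x^inflation
        M@x[M@x < prune] <- 0
        M <- Matrix::drop0(M)
        cs <- Matrix::colSums(M)
        cs[cs == 0] <- 1
        M <- M %*% Matrix::Diagonal(n, 1 / cs)
        if (max(abs(M - Mold)) < 1e-8) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("MCL did not converge within maxIter; using current state")
    # attractors: rows with non-negligible diagonal mass
    attr <- which(Matrix::diag(M) > prune)
    if (!length(attr)) attr <- seq_len(n)
    membership <- integer(n)
    clusterOf <- integer(0)
    nextId <- 0L
    for (a in attr) {
        support <- which(M[a, ] > prune)
        support <- union(support, a)
        ids <- unique(membership[support])
        ids <- ids[ids > 0L]
        if (!length(ids)) {
            nextId <- nextId + 1L
            membership[support] <- nextId
        } else {
            keep <- min(ids)
            membership[support] <- keep
            if (length(ids) > 1L)
                membership[membership %in% setdiff(ids, keep)] <- keep
        }
    }
    if (any(membership == 0L)) {
        for (v in which(membership == 0L)) {
            owner <- which(M[, v] > prune)
            owner <- owner[membership[owner] > 0L]
            if (length(owner)) {
                membership[v] <- membership[owner[1]]
            } else {
                nextId <- nextId + 1L
                membership[v] <- nextId
            }
        }
    }
    as.integer(factor(membership))
}

#' Spatial partitions of a region subset across a structure population
#'
#' Per structure: build the CIN over the subset, Markov-cluster it, drop
#' clusters below `minNodes` (default 7, the smallest-25% cutoff), and
#' report each surviving partition's members, geometric center, size in Mb
#' (0.2 Mb per node at 200-kb bins) and inter-chromosomal edge fraction
#' `ICEF = E_inter / (E_intra + E_inter)`.
#'
#' @param pop a [StructurePopulation-class].
#' @param bins haploid bin indices defining the subset (expanded to both
#'   copies).
#' @param inflation MCL inflation.
#' @param minNodes minimum partition size in nodes.
#' @param structures structure indices (default all).
#' @return list of per-structure lists of partitions; each partition is a
#'   list with `beads`, `center`, `nNodes`, `sizeMb`, `icef`.
#' @export
spatialPartitions <- function(pop, bins, inflation = 1.5, minNodes = 7L,
                              structures = seq_len(nStructures(pop))) {
    subset <- expandToBeads(pop@genome, bins)
    sizePerNode <- pop@genome@binSize / 1e6
    lapply(structures, function(m) {
        g <- buildCIN(pop, m, subset)
        mem <- markovCluster(g, inflation = inflation)
        parts <- list()
        for (cl in unique(mem)) {
            v <- which(mem == cl)
            if (length(v) < minNodes) next
            beads <- igraph::V(g)$bead[v]
            xyz <- pop@coords[beads, , m, drop = FALSE]
            dim(xyz) <- c(length(beads), 3L)
            sub <- igraph::induced_subgraph(g, v)
            ee <- igraph::as_edgelist(sub, names = FALSE)
            chrom <- igraph::V(sub)$chrom
            eInter <- if (nrow(ee))
                sum(chrom[ee[, 1]] != chrom[ee[, 2]]) else 0L
            nE <- nrow(ee)
            parts[[length(parts) + 1L]] <-
                list(beads = beads, center = colMeans(xyz),
                     nNodes = length(v),
                     sizeMb = sizePerNode * length(v),
                     icef = if (nE > 0) eInter / nE else NA_real_)
        }
        parts
    })
}

#' Maximal clique enrichment of a region subset in one structure
#'
#' `MCE = c_obs / mean(c_shuffle)` where `c` counts maximal cliques in the
#' CIN and each shuffle rebuilds the CIN from a random genome-wide region
#' subset of the same size in the same structure.
#'
#' @param pop a [StructurePopulation-class].
#' @param structure structure index.
#' @param bins haploid bin subset (expanded to both copies).
#' @param nShuffles number of shuffles (default 10).
#' @param seed seed for shuffle draws.
#' @return list with `mce`, `cObserved`, `cShuffle`.
#' @export
maximalCliqueEnrichment <- function(pop, structure, bins, nShuffles = 10L,
                                    seed = 1L) {
    stopifnot(nShuffles >= 1L)
    countCliques <- function(b) {
        g <- buildCIN(pop, structure, expandToBeads(pop@genome, b))
        igraph::count_max_cliques(g)
    }
    cObs <- countCliques(bins)
    N <- nBins(pop@genome)
    set.seed(seed)
    cSh <- vapply(seq_len(nShuffles), function(s)
        countCliques(sample.int(N, length(bins))), 0)
    mce <- if (mean(cSh) > 0) cObs / mean(cSh) else NA_real_
    list(mce = mce, cObserved = cObs, cShuffle = cSh)
}

#' Neighborhood connectivity of a network
#'
#' The mean over nodes of the average degree of each node's neighbors;
#' isolated nodes contribute 0.
#'
#' @param network an [igraph::graph].
#' @return a single numeric value.
#' @export
neighborhoodConnectivity <- function(network) {
    stopifnot(igraph::vcount(network) > 0)
    knn <- suppressWarnings(igraph::knn(network)$knn)
    knn[!is.finite(knn)] <- 0
    mean(knn)
}

#' Predict nuclear speckle locations
#'
#' Speckles are placed at geometric centers of spatial partitions of
#' speckle-prone chromatin: mode `"a1"` uses A1-annotated regions, mode
#' `"lowest_rad"` uses the 10% of regions with the lowest mean radial
#' position (no annotations needed), mode `"a2"` uses A2 regions (a control
#' mode). Partitions with more than three nodes are kept.
#'
#' @param pop a [StructurePopulation-class].
#' @param mode `"a1"`, `"lowest_rad"` or `"a2"`.
#' @param annotations character per haploid bin (subcompartment labels);
#'   required for modes `"a1"` and `"a2"`.
#' @param radTable optional precomputed mean radial positions per bin (from
#'   [radialPositions()]); computed on the fly for `"lowest_rad"` if absent.
#' @param inflation MCL inflation.
#' @return list of class `BodyLocations`: per structure, a list of bodies
#'   with `center` and `beads`; plus attributes `kind` and `mode`.
#' @export
predictSpeckles <- function(pop, mode = c("a1", "lowest_rad", "a2"),
                            annotations = NULL, radTable = NULL,
                            inflation = 1.5) {
    mode <- match.arg(mode)
    N <- nBins(pop@genome)
    if (mode %in% c("a1", "a2")) {
        if (is.null(annotations))
            stop("modes 'a1' and 'a2' require subcompartment annotations")
        want <- if (mode == "a1") "A1" else "A2"
        bins <- which(annotations == want)
    } else {
        if (is.null(radTable))
            radTable <- radialPositions(pop)$mean
        bins <- order(radTable)[seq_len(round(0.10 * N))]
    }
    if (!length(bins)) stop("empty region subset for speckle prediction")
    parts <- spatialPartitions(pop, bins, inflation = inflation,
                               minNodes = 4L)
    bodies <- lapply(parts, function(ps)
        lapply(ps, function(p) list(center = p$center, beads = p$beads)))
    structure(bodies, kind = "speckle", mode = mode,
              class = "BodyLocations")
}

#' Predict nucleolus locations from NAD/NOR regions
#'
#' Builds CINs over nucleolus-prone chromatin, Markov-clusters them, and
#' keeps the top 25% largest partitions per structure as nucleoli. When a
#' contact matrix is supplied, NOR regions without any contact entries are
#' substituted by the nearest-in-sequence restrained bins on the same
#' chromosome (up to `norSubstitute` bins).
#'
#' @param pop a [StructurePopulation-class].
#' @param bins haploid bin indices of NAD/NOR regions.
#' @param norBins optional subset of `bins` flagged as NOR.
#' @param contactMatrix optional [ContactMatrix-class] used to detect
#'   unrestrained NOR bins.
#' @param norSubstitute number of nearest restrained bins used as
#'   substitutes (default 25).
#' @param inflation MCL inflation.
#' @return a `BodyLocations` list (see [predictSpeckles()]).
#' @export
predictNucleoli <- function(pop, bins, norBins = integer(),
                            contactMatrix = NULL, norSubstitute = 25L,
                            inflation = 1.5) {
    stopifnot(length(bins) > 0)
    if (length(norBins) && !is.null(contactMatrix)) {
        e <- contactMatrix@entries
        restrained <- sort(unique(c(e$I, e$J)))
        dead <- norBins[!norBins %in% restrained]
        if (length(dead)) {
            chrom <- binChrom(pop@genome)
            subs <- unlist(lapply(unique(chrom[dead]), function(ch) {
                cand <- restrained[chrom[restrained] == ch]
                anchor <- dead[chrom[dead] == ch]
                cand[order(vapply(cand, function(b)
                    min(abs(b - anchor)), 0))][
                        seq_len(min(norSubstitute, length(cand)))]
            }))
            bins <- sort(unique(c(setdiff(bins, dead), subs)))
        }
    }
    parts <- spatialPartitions(pop, bins, inflation = inflation,
                               minNodes = 1L)
    bodies <- lapply(parts, function(ps) {
        if (!length(ps)) return(list())
        sizes <- vapply(ps, function(p) p$nNodes, 0L)
        keep <- order(sizes, decreasing = TRUE)[
            seq_len(max(1L, floor(length(ps) / 4)))]
        lapply(ps[keep], function(p) list(center = p$center,
                                          beads = p$beads))
    })
    structure(bodies, kind = "nucleolus", mode = "nad_nor",
              class = "BodyLocations")
}

#' Neighborhood enrichment between region labels
#'
#' Entry `(s, s')` is `log2` of the observed fraction of `s'`-labeled beads
#' among spatial neighbors of `s`-labeled beads (center distance below
#' `radius`, pooled over structures) over the genome-wide bead fraction of
#' `s'`. Labels with no beads give missing rows/columns.
#'
#' @param pop a [StructurePopulation-class].
#' @param labels character per haploid bin.
#' @param radius neighborhood radius in nm (default 500).
#' @return numeric label-by-label matrix.
#' @export
neighborhoodEnrichment <- function(pop, labels, radius = 500) {
    N <- nBins(pop@genome)
    lev <- sort(unique(labels[!is.na(labels)]))
    beadLab <- factor(rep(labels, 2L), levels = lev)
    M <- nStructures(pop)
    counts <- matrix(0, length(lev), length(lev),
                     dimnames = list(lev, lev))
    for (m in seq_len(M)) {
        xyz <- pop@coords[, , m]
        d <- as.matrix(stats::dist(xyz))
        nb <- d < radius & upper.tri(d)
        idx <- which(nb, arr.ind = TRUE)
        li <- beadLab[idx[, 1]]
        lj <- beadLab[idx[, 2]]
        ok <- !is.na(li) & !is.na(lj)
        tab <- table(li[ok], lj[ok])
        counts <- counts + tab + t(tab)
    }
    globalFrac <- as.numeric(table(beadLab)) / sum(!is.na(beadLab))
    obs <- counts / rowSums(counts)
    enr <- log2(sweep(obs, 2, globalFrac, `/`))
    enr[!is.finite(enr) & !is.na(enr)] <- NA
    enr
}
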