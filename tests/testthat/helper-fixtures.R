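# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (is.null(.fixtures[[name]]))
        assign(name, build(), envir = .fixtures)
    get(name, envir = .fixtures)
}

toyTruth <- function() fixture("truth", function() makeToyTruth("small"))

# ground-truth generator population used by feature/network tests
toyPop <- function() fixture("pop", function()
    simulatePopulation(toyTruth(), M = 100, seed = 11))

# larger generator population whose contact matrix is the pipeline input
toyInput <- function() fixture("input", function()
    syntheticHic(simulatePopulation(toyTruth(), M = 200, seed = 11)))

# deconvolved population from the toy input (the expensive fixture)
modelPop <- function() fixture("model", function()
    runPipeline(toyInput(), nucleus = toyTruth()@nucleus,
                config = optimizerConfig(M = 100, seed = 1)))

toyBodies <- function() fixture("bodies", function() {
    labs <- truthLabels(toyTruth())
    list(speckles = predictSpeckles(toyPop(), "a1",
                                    annotations = labs$subcompartment),
         nucleoli = predictNucleoli(toyPop(),
                                    which(toyTruth()@classes ==
                                          "nucleolus")))
})

toyFeatures <- function() fixture("featureTable", function() {
    b <- toyBodies()
    featureTable(toyPop(), b$speckles, b$nucleoli,
                 truthLabels(toyTruth())$compartment)
})

# planted anchor bodies (the generator's own truth, not predictions)
plantedBodies <- function(pop, kind = c("speckle", "nucleolus")) {
    kind <- match.arg(kind)
    anch <- attr(pop, "anchors")
    bodies <- lapply(anch, function(a) {
        if (kind == "speckle")
            apply(a$speckle, 1, function(cc)
                list(center = cc, beads = integer()), simplify = FALSE)
        else list(list(center = a$nucleolus, beads = integer()))
    })
    structure(bodies, kind = kind, mode = "planted",
              class = "BodyLocations")
}

# one-chromosome genome with nBins bins
lineGenome <- function(nBins, binSize = 2e5) {
    makeToyGenome(nBins * binSize, binSize)
}

# population from an explicit list of (2N x 3) coordinate matrices
handPop <- function(genome, nucleus, structures) {
    coords <- array(0, dim = c(nBeads(genome), 3L, length(structures)))
    for (m in seq_along(structures)) coords[, , m] <- structures[[m]]
    structurePopulation(genome, nucleus, coords)
}

# adjusted Rand index (independent of any clustering package)
adjustedRand <- function(x, y) {
    tab <- table(x, y)
    n <- sum(tab)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    expv <- si * sj / choose(n, 2)
    (sij - expv) / ((si + sj) / 2 - expv)
}

# brute-force maximal clique enumeration (Bron-Kerbosch, no pivoting)
bruteMaxCliques <- function(adj) {
    n <- nrow(adj)
    cliques <- list()
    bk <- function(R, P, X) {
        if (!length(P) && !length(X)) {
            cliques[[length(cliques) + 1L]] <<- sort(R)
            return()
        }
        for (v in P) {
            nb <- which(adj[v, ] == 1)
            bk(c(R, v), intersect(P, nb), intersect(X, nb))
            P <- setdiff(P, v)
            X <- c(X, v)
        }
    }
    bk(integer(), seq_len(n), integer())
    cliques
}

# reference MCL: dense matrix iteration, written independently of the
# package implementation
referenceMCL <- function(adj, inflation, maxIter = 200) {
    n <- nrow(adj)
    M <- adj + diag(n)
    M <- sweep(M, 2, colSums(M), "/")
    for (i in seq_len(maxIter)) {
        old <- M
        M <- M %*% M
        M <- M^inflation
        M <- sweep(M, 2, colSums(M), "/")
        M[M < 1e-12] <- 0
        cs <- colSums(M)
        M <- sweep(M, 2, ifelse(cs == 0, 1, cs), "/")
        if (max(abs(M - old)) < 1e-10) break
    }
    # clusters from attractor rows
    attractors <- which(diag(M) > 1e-6)
    membership <- rep(0L, n)
    cl <- 0L
    for (a in attractors) {
        sup <- which(M[a, ] > 1e-6)
        ids <- setdiff(unique(membership[sup]), 0L)
        if (!length(ids)) {
            cl <- cl + 1L
            membership[sup] <- cl
        } else {
            membership[sup] <- min(ids)
        }
    }
    as.integer(factor(membership))
}

# synthetic feature table with well-separated planted clusters in feature
# space (for testing the subcompartment classifier's recovery)
plantedFeatureTable <- function(nPerClass = 40, seed = 5) {
    set.seed(seed)
    centers <- list(A1 = c(saf = 0.9, rad = 0.3, laf = 0.0, naf = 0.05),
                    A2 = c(saf = 0.2, rad = 0.6, laf = 0.2, naf = 0.05),
                    B2 = c(saf = 0.05, rad = 0.5, laf = 0.1, naf = 0.8),
                    B3 = c(saf = 0.0, rad = 0.9, laf = 0.9, naf = 0.05))
    rows <- lapply(names(centers), function(lab) {
        mu <- centers[[lab]]
        data.frame(ref = lab,
                   ab = if (startsWith(lab, "A")) "A" else "B",
                   SAF = pmin(1, pmax(0, rnorm(nPerClass, mu["saf"], 0.05))),
                   RAD = pmin(1, pmax(0, rnorm(nPerClass, mu["rad"], 0.05))),
                   LAF = pmin(1, pmax(0, rnorm(nPerClass, mu["laf"], 0.05))),
                   NAF = pmin(1, pmax(0, rnorm(nPerClass, mu["naf"], 0.05))))
    })
    do.call(rbind, rows)
}
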