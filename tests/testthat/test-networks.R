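test_that("chromatin interaction networks match brute-force edge enumeration", {
    g <- lineGenome(3)
    nuc <- nucleusModel(Rex = 118)
    D <- nuc@contactDistance
    tight <- rbind(c(0, 0, 0), c(300, 0, 0), c(150, 260, 0),
                   matrix(4000, 3, 3))
    pop <- handPop(g, nuc, list(tight))
    cin <- buildCIN(pop, 1, subset = 1:3)
    expect_equal(igraph::ecount(cin), 3L)  # triangle

    apart <- rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0),
                   matrix(4000, 3, 3))
    cin0 <- buildCIN(handPop(g, nuc, list(apart)), 1, 1:3)
    expect_equal(igraph::ecount(cin0), 0L)

    g5 <- lineGenome(5)
    set.seed(12)
    xs <- rbind(matrix(runif(15, -500, 500), 5, 3), matrix(4000, 5, 3))
    pop5 <- handPop(g5, nuc, list(xs))
    cin5 <- buildCIN(pop5, 1, 1:5)
    dmat <- as.matrix(dist(xs[1:5, ]))
    want <- which(dmat <= D & upper.tri(dmat), arr.ind = TRUE)
    got <- igraph::as_edgelist(cin5)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2])),
                    paste(want[, 1], want[, 2]))
})

test_that("Markov clustering matches components and an independent MCL run", {
    two <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
    mem <- markovCluster(two)
    expect_equal(length(unique(mem)), 2L)
    expect_equal(mem, igraph::components(two)$membership)

    single <- igraph::make_empty_graph(1, directed = FALSE)
    expect_equal(markovCluster(single), 1L)

    # barbell: two 5-cliques joined by one edge, checked against a dense
    # reference MCL implementation
    barbell <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
    barbell <- igraph::add_edges(barbell, c(1, 6))
    for (infl in c(1.5, 2)) {
        mem <- markovCluster(barbell, inflation = infl)
        adj <- as.matrix(igraph::as_adjacency_matrix(barbell))
        ref <- referenceMCL(adj, inflation = infl)
        expect_equal(length(unique(mem)), 2L)
        expect_equal(adjustedRand(mem, ref), 1)
        expect_equal(mem[1:5], rep(mem[1], 5))  # clique stays together
    }

    # clusters never span disconnected components (property)
    set.seed(5)
    for (rep in 1:5) {
        g1 <- igraph::sample_gnp(8, 0.5)
        g2 <- igraph::sample_gnp(6, 0.5)
        gg <- g1 + g2
        mem <- markovCluster(gg)
        comp <- igraph::components(gg)$membership
        crossing <- outer(mem, mem, `==`) & outer(comp, comp, `!=`)
        expect_false(any(crossing))
    }
})

test_that("spatial partitions recover planted clusters and compute ICEF", {
    pop <- toyPop()
    truth <- toyTruth()
    mem <- attr(pop, "speckleMembership")
    real <- attr(pop, "realizedMembership")
    parts <- spatialPartitions(pop, which(!is.na(mem)), minNodes = 4L)
    anch <- attr(pop, "anchors")
    M <- nStructures(pop)

    centerHits <- vapply(seq_len(M), function(m) {
        ps <- parts[[m]]
        if (!length(ps)) return(FALSE)
        ctr <- do.call(rbind, lapply(ps, `[[`, "center"))
        all(apply(anch[[m]]$speckle, 1, function(a)
            min(sqrt(colSums((t(ctr) - a)^2))) < 500))
    }, TRUE)
    expect_gte(mean(centerHits), 0.95)

    aris <- vapply(seq_len(M), function(m) {
        ps <- parts[[m]]
        if (!length(ps)) return(NA_real_)
        bead <- unlist(lapply(ps, `[[`, "beads"))
        cl <- rep(seq_along(ps), vapply(ps, function(p)
            length(p$beads), 0L))
        tr <- real[bead, m]
        adjustedRand(cl[!is.na(tr)], tr[!is.na(tr)])
    }, 0)
    expect_gte(mean(aris, na.rm = TRUE), 0.9)

    # partition size bookkeeping: 0.2 Mb per node, minimum enforced
    allParts <- unlist(parts, recursive = FALSE)
    sizes <- vapply(allParts, `[[`, 0L, "nNodes")
    expect_true(all(sizes >= 4L))
    expect_equal(vapply(allParts, `[[`, 0, "sizeMb"), sizes * 0.2)

    # small clusters are dropped under the default 7-node policy
    partsDefault <- spatialPartitions(pop, which(!is.na(mem)),
                                      structures = 1:5)
    small <- unlist(partsDefault, recursive = FALSE)
    expect_true(all(vapply(small, `[[`, 0L, "nNodes") >= 7L))
})

test_that("ICEF is the inter-chromosomal edge fraction", {
    # 3 intra edges (triangle on chrom a) + 2 inter edges -> ICEF = 0.4
    g <- segmentGenome(data.frame(name = c("a", "b"),
                                  length = c(3 * 2e5, 2 * 2e5)), 2e5)
    nuc <- nucleusModel(Rex = 118)
    x <- cbind(seq(10000, 50000, length.out = 10), 0, 0)  # isolated
    x[1, ] <- c(0, 0, 0)
    x[2, ] <- c(400, 0, 0)
    x[3, ] <- c(200, 350, 0)
    x[4, ] <- c(-300, -300, 0)   # chrom b bead near bead 1 only
    x[5, ] <- c(700, -300, 0)    # chrom b bead near bead 2 only
    pop <- handPop(g, nuc, list(x))
    parts <- spatialPartitions(pop, 1:5, minNodes = 5L,
                               structures = 1)
    expect_equal(length(parts[[1]]), 1L)
    expect_equal(parts[[1]][[1]]$icef, 2 / 5)
    # invariant under relabeling beads within chromosomes
    xPerm <- x
    xPerm[c(1, 3), ] <- x[c(3, 1), ]
    partsP <- spatialPartitions(handPop(g, nuc, list(xPerm)), 1:5,
                                minNodes = 5L, structures = 1)
    expect_equal(partsP[[1]][[1]]$icef, 2 / 5)
})

test_that("maximal clique counts and enrichment match a Bron-Kerbosch oracle", {
    pop <- toyPop()
    N <- nBins(pop@genome)

    # degenerate shuffle: the subset is the whole genome, so every shuffle
    # redraws the same node set -> MCE = 1
    mce <- maximalCliqueEnrichment(pop, 1, seq_len(N), nShuffles = 3,
                                   seed = 1)
    expect_equal(mce$mce, 1)

    # edgeless graph: every node is a maximal clique
    g <- lineGenome(4)
    nuc <- nucleusModel(Rex = 118)
    spread <- cbind(seq(0, by = 3000, length.out = 8), 0, 0)
    cin <- buildCIN(handPop(g, nuc, list(spread)), 1, 1:4)
    expect_equal(igraph::count_max_cliques(cin), 4L)

    # 10-bead fixture against the brute-force enumerator
    set.seed(23)
    g10 <- lineGenome(10)
    xs <- rbind(matrix(runif(30, -600, 600), 10, 3), matrix(9000, 10, 3))
    cin10 <- buildCIN(handPop(g10, nuc, list(xs)), 1, 1:10)
    adj <- as.matrix(igraph::as_adjacency_matrix(cin10))
    expect_equal(igraph::count_max_cliques(cin10),
                 length(bruteMaxCliques(adj)))
})

test_that("neighborhood connectivity averages neighbor degrees", {
    star <- igraph::make_star(4, mode = "undirected")
    expect_equal(neighborhoodConnectivity(star), 2.5)
    ring <- igraph::make_ring(6)  # 2-regular
    expect_equal(neighborhoodConnectivity(ring), 2)
    edge <- igraph::make_graph(c(1, 2), directed = FALSE)
    expect_equal(neighborhoodConnectivity(edge), 1)
    lonely <- igraph::make_empty_graph(3, directed = FALSE)
    expect_equal(neighborhoodConnectivity(lonely), 0)
})

test_that("speckle prediction recovers planted anchors in most structures", {
    pop <- toyPop()
    truth <- toyTruth()
    labs <- truthLabels(truth)
    bodies <- toyBodies()$speckles
    anch <- attr(pop, "anchors")
    M <- nStructures(pop)
    hit <- vapply(seq_len(M), function(m) {
        bs <- bodies[[m]]
        if (!length(bs)) return(FALSE)
        ctr <- do.call(rbind, lapply(bs, `[[`, "center"))
        all(apply(anch[[m]]$speckle, 1, function(a)
            min(sqrt(colSums((t(ctr) - a)^2))) < 500))
    }, TRUE)
    expect_gte(mean(hit), 0.95)

    expect_error(predictSpeckles(pop, "a1"), "annotations")

    # a structure whose largest cluster has three nodes yields no body:
    # 3 beads co-located, everything else spread out
    g <- lineGenome(6)
    nuc <- nucleusModel(Rex = 118)
    x <- cbind(seq(0, by = 3000, length.out = 12), 0, 0)
    x[2, ] <- x[1, ] + c(100, 0, 0)
    x[3, ] <- x[1, ] + c(0, 100, 0)
    tiny <- handPop(g, nuc, list(x))
    ann <- rep("A1", 6)
    b <- predictSpeckles(tiny, "a1", annotations = ann)
    expect_equal(length(b[[1]]), 0L)

    # mode lowest_rad selects the bottom-decile radial bins and finds
    # their cluster without annotations: 20-bin genome, bins 1-2 (= 10%)
    # hug the center, everything else sits at the periphery
    g20 <- lineGenome(20)
    hub <- c(600, 0, 0)
    xr <- matrix(0, 40, 3)
    shellDir <- pracma_rand <- NULL
    set.seed(77)
    for (i in 1:40) {
        v <- rnorm(3); v <- v / sqrt(sum(v^2))
        xr[i, ] <- v * 4500
    }
    for (bead in c(1, 2, 21, 22))
        xr[bead, ] <- hub + runif(3, -100, 100)
    popr <- handPop(g20, nuc, list(xr))
    b2 <- predictSpeckles(popr, "lowest_rad")
    expect_equal(length(b2[[1]]), 1L)
    expect_lt(sqrt(sum((b2[[1]][[1]]$center - hub)^2)), 200)
})

test_that("nucleolus prediction keeps the top quarter of partitions", {
    pop <- toyPop()
    truth <- toyTruth()
    nadBins <- which(truth@classes == "nucleolus")
    bodies <- toyBodies()$nucleoli
    anch <- attr(pop, "anchors")
    M <- nStructures(pop)
    # every predicted nucleolus must sit on a realized nucleolus blob
    # (the anchored cluster, or an off-anchor block copy - also a valid
    # cluster under the top-25% size rule)
    real <- attr(pop, "realizedMembership")
    dist2blob <- vapply(seq_len(M), function(m) {
        bs <- bodies[[m]]
        if (!length(bs)) return(NA_real_)
        ids <- unique(stats::na.omit(real[, m]))
        ids <- ids[grepl("nucleolus", ids)]
        xm <- pop@coords[, , m]
        blobCtr <- t(vapply(ids, function(id)
            colMeans(xm[which(real[, m] == id), , drop = FALSE]),
            numeric(3)))
        max(vapply(bs, function(b)
            min(sqrt(rowSums(sweep(blobCtr, 2, b$center)^2))), 0))
    }, 0)
    expect_lt(mean(dist2blob, na.rm = TRUE), 200)
    expect_gte(mean(dist2blob < 500, na.rm = TRUE), 0.95)

    # 8 well-separated blobs -> floor(8 / 4) = 2 retained
    g <- lineGenome(40)
    nuc <- nucleusModel(Rex = 118)
    x <- matrix(0, 80, 3)
    centers <- cbind(seq(-4200, 4200, length.out = 8), 0, 0)
    for (b in 1:8) {
        idx <- ((b - 1) * 5 + 1):(b * 5)
        x[idx, ] <- sweep(matrix(runif(15, -150, 150), 5, 3), 2,
                          centers[b, ], `+`)
    }
    x[41:80, ] <- cbind(0, seq(-4500, 4500, length.out = 40), 3000)
    blobs <- handPop(g, nuc, list(x))
    bb <- predictNucleoli(blobs, bins = 1:40)
    expect_equal(length(bb[[1]]), 2L)

    # dispersed NAD beads give no bodies only when there are no partitions;
    # single isolated beads still count as singleton partitions, so check
    # the empty-input contract instead
    expect_error(predictNucleoli(pop, integer()))
})

test_that("neighborhood enrichment is signed by spatial segregation", {
    pop <- toyPop()
    labs <- truthLabels(toyTruth())$compartment
    enr <- neighborhoodEnrichment(pop, labs, radius = 500)
    expect_true(all(diag(enr) > 0))
    expect_true(all(enr[upper.tri(enr)] < 0))
    expect_true(all(enr[lower.tri(enr)] < 0))

    # hand-counted two-label fixture
    g <- segmentGenome(data.frame(name = c("a", "b"),
                                  length = c(2 * 2e5, 2 * 2e5)), 2e5)
    nuc <- nucleusModel(Rex = 118)
    x <- cbind(seq(10000, 40000, length.out = 8), 0, 0)  # default: isolated
    x[1, ] <- c(0, 0, 0)      # a1 (X)
    x[2, ] <- c(300, 0, 0)    # a2 (X)
    x[3, ] <- c(0, 300, 0)    # b1 (Y)
    x[4, ] <- c(5000, 5000, 5000)
    popH <- handPop(g, nuc, list(x))
    labsH <- c("X", "X", "Y", "Y")
    enrH <- neighborhoodEnrichment(popH, labsH, radius = 500)
    # neighbors: X-X once (1-2), X-Y twice (1-3, 2-3)
    # obs fraction of Y among X neighbors = 2/4; global Y fraction = 1/2
    expect_equal(enrH["X", "Y"], log2((2 / 4) / (4 / 8)))
    expect_equal(enrH["Y", "X"], log2(1 / (4 / 8)))
})
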