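test_that("radial positions are |x|/Rnuc averaged over 2M configurations", {
    g <- lineGenome(2)
    nuc <- nucleusModel(Rex = 118)  # Rnuc = 5000
    x1 <- rbind(c(0, 0, 0), c(3000, 4000, 0),
                c(1000, 0, 0), c(0, 2500, 0))
    x2 <- rbind(c(500, 0, 0), c(0, 0, 5000),
                c(2000, 0, 0), c(0, 0, 1500))
    pop <- handPop(g, nuc, list(x1, x2))
    r <- radialPositions(pop)
    expect_equal(r$matrix[1, 1], 0)
    expect_equal(r$matrix[2, 1], 1)  # 3-4-5 triangle
    expect_equal(r$mean[1], mean(c(0, 1000, 500, 2000) / 5000))
    expect_equal(r$mean[2], mean(c(5000, 2500, 5000, 1500) / 5000))
})

test_that("local compaction sums squared distances to the window's center", {
    g <- lineGenome(5)
    nuc <- nucleusModel(Rex = 118)
    x <- matrix(0, 10, 3)
    pop <- handPop(g, nuc, list(x))
    rg <- localCompaction(pop, window = 1e6)
    expect_true(all(rg$matrix == 0))  # coincident beads

    # 2-bead truncated window at a chromosome end, beads 2a apart
    g2 <- lineGenome(2)
    a <- 350
    x2 <- rbind(c(0, 0, 0), c(2 * a, 0, 0), c(0, 5000, 0), c(0, 5000, 700))
    pop2 <- handPop(g2, nuc, list(x2))
    rg2 <- localCompaction(pop2, window = 3 * 2e5)
    expect_equal(rg2$matrix[1, 1], 2 * a^2)

    # 5-bead fixture against a direct sum-of-squares oracle
    set.seed(3)
    xs <- matrix(runif(30, -800, 800), 10, 3)
    pop5 <- handPop(g, nuc, list(xs))
    rg5 <- localCompaction(pop5, window = 1e6)
    win <- 1:3  # bin 1: truncated to bins 1..3
    com <- colMeans(xs[win, ])
    expect_equal(rg5$matrix[1, 1],
                 sum(sweep(xs[win, ], 2, com)^2))
    winMid <- 1:5  # bin 3: full window
    comMid <- colMeans(xs[winMid, ])
    expect_equal(rg5$matrix[3, 1], sum(sweep(xs[winMid, ], 2, comMid)^2))
    # conventional flag gives root-mean-square
    rgc <- localCompaction(pop5, window = 1e6, conventional = TRUE)
    expect_equal(rgc$matrix[3, 1],
                 sqrt(mean(rowSums(sweep(xs[winMid, ], 2, comMid)^2))))
    expect_error(localCompaction(pop5, window = 4e5), "odd multiple")
})

test_that("body distances take the nearest body and skip body-free structures", {
    g <- lineGenome(2)
    nuc <- nucleusModel(Rex = 118)
    x <- rbind(c(1000, 0, 0), c(0, 2000, 0), c(0, 0, 3000), c(500, 0, 0))
    pop <- handPop(g, nuc, list(x, x))
    oneBody <- structure(list(
        list(list(center = c(0, 0, 0), beads = integer())),
        list()), class = "BodyLocations")  # structure 2 has no bodies
    bd <- bodyDistanceFeatures(pop, oneBody)
    expect_equal(bd$matrix[1, 1], 1000)
    expect_true(all(is.na(bd$matrix[, 2])))
    expect_equal(bd$mean[1], mean(c(1000, 3000)))  # only structure 1 counts

    twoBodies <- structure(list(
        list(list(center = c(0, 0, 0), beads = integer()),
             list(center = c(0, 1900, 0), beads = integer())),
        list()), class = "BodyLocations")
    bd2 <- bodyDistanceFeatures(pop, twoBodies)
    expect_equal(bd2$matrix[2, 1], 100)  # nearest of the two

    none <- structure(list(list(), list()), class = "BodyLocations")
    expect_error(bodyDistanceFeatures(pop, none), "no bodies")

    # brute-force scan on a random fixture
    set.seed(8)
    xs <- matrix(runif(12, -3000, 3000), 4, 3)
    popR <- handPop(g, nuc, list(xs))
    centers <- matrix(runif(9, -3000, 3000), 3, 3)
    bodies <- structure(list(lapply(seq_len(3), function(k)
        list(center = centers[k, ], beads = integer()))),
        class = "BodyLocations")
    bdR <- bodyDistanceFeatures(popR, bodies)
    for (i in 1:4)
        expect_equal(bdR$matrix[i, 1],
                     min(sqrt(rowSums(sweep(centers, 2, xs[i, ])^2))))
})

test_that("variability scores are log2 of pooled sd over the chromosome mean", {
    g <- lineGenome(3)
    set.seed(4)
    # identical spread in every region -> delta = 0 exactly
    same <- matrix(rep(c(-1, 1), length.out = 40), 6, 40, byrow = TRUE)
    delta0 <- featureVariability(same, g)
    expect_true(all(delta0 == 0))

    # sigma_I = 2 * mean sigma -> delta = 1: construct exact sds
    m <- matrix(0, 6, 50)
    m[1, ] <- rep(c(-2, 2), 25)   # copy 0, bin 1
    m[4, ] <- rep(c(-2, 2), 25)   # copy 1, bin 1
    m[2, ] <- rep(c(-1, 1), 25)
    m[5, ] <- rep(c(-1, 1), 25)
    m[3, ] <- rep(c(-1, 1), 25)
    m[6, ] <- rep(c(-1, 1), 25)
    delta <- featureVariability(m, g)
    sds <- apply(cbind(m[1:3, ], m[4:6, ]), 1, sd)
    expect_equal(delta, log2(sds / mean(sds)))
    expect_equal(delta[2], delta[3])
    expect_gt(delta[1], delta[2])

    # per-chromosome mean of sigma/sigma_bar equals 1 by construction
    rand <- matrix(rnorm(6 * 30, sd = rep(c(1, 3, 7), 2)), 6, 30)
    sigma <- apply(cbind(rand[1:3, ], rand[4:6, ]), 1, sd)
    expect_equal(mean(sigma / mean(sigma)), 1)
    deltaR <- featureVariability(rand, g)
    expect_equal(mean(2^deltaR * mean(sigma)) / mean(sigma), 1,
                 tolerance = 1e-12)
})

test_that("interior localization counts structures where either copy is inside", {
    g <- lineGenome(3)
    M <- 10
    r <- matrix(0.9, 6, M)
    r[1, ] <- 0.3                       # bin 1 copy 0 always interior
    r[2, 1:5] <- 0.2                    # bin 2 copy 0 interior half the time
    r[5, ] <- 0.8                       # bin 2 copy 1 never
    ilf <- interiorLocalizationFrequency(r, g)
    expect_equal(ilf, c(1, 0.5, 0))
})

test_that("association frequencies use surface distances and fixed 2M denominators", {
    g <- lineGenome(2)
    nuc <- nucleusModel(Rex = 118)
    dt <- 500
    # copy 0 of bin 1 always within, copy 1 never
    x <- rbind(c(200, 0, 0), c(3000, 0, 0), c(4000, 0, 0), c(3500, 0, 0))
    pop <- handPop(g, nuc, list(x, x))
    bodies <- structure(list(
        list(list(center = c(0, 0, 0), beads = integer())),
        list(list(center = c(0, 0, 0), beads = integer()))),
        class = "BodyLocations")
    saf <- associationFrequency(pop, "speckle", bodies)
    expect_equal(saf[1], 0.5)
    expect_equal(saf[2], 0)

    # both copies always within
    xin <- rbind(c(100, 0, 0), c(200, 0, 0), c(0, 100, 0), c(0, 200, 0))
    expect_equal(associationFrequency(handPop(g, nuc, list(xin)),
                                      "speckle", structure(list(
        list(list(center = c(0, 0, 0), beads = integer()))),
        class = "BodyLocations")), c(1, 1))

    # surface correction: center distance 560 = surface 442 < 500,
    # center distance 640 = surface 522 > 500
    xb <- rbind(c(560, 0, 0), c(640, 0, 0), c(3000, 0, 0), c(3000, 0, 0))
    safB <- associationFrequency(handPop(g, nuc, list(xb)), "speckle",
        structure(list(list(list(center = c(0, 0, 0), beads = integer()))),
                  class = "BodyLocations"))
    expect_equal(safB, c(0.5, 0))

    # lamina: surface-to-envelope distance Rnuc - |x| - Rex, threshold
    # 0.35 Rnuc = 1750
    xl <- rbind(c(3200, 0, 0), c(3000, 0, 0), c(0, 0, 0), c(0, 0, 0))
    # bead 1: 5000 - 3200 - 118 = 1682 < 1750; bead 2: 1882 > 1750
    laf <- associationFrequency(handPop(g, nuc, list(xl)), "lamina")
    expect_equal(laf, c(0.5, 0))

    # body-free structures count as non-associated with denominator 2M
    popMix <- handPop(g, nuc, list(xin, xin))
    halfBodies <- structure(list(
        list(list(center = c(0, 0, 0), beads = integer())),
        list()), class = "BodyLocations")
    expect_equal(associationFrequency(popMix, "speckle", halfBodies),
                 c(0.5, 0.5))
    expect_error(associationFrequency(pop, "speckle"), "bodies")
})

test_that("simulated TSA-seq follows the exponential decay double sum", {
    g <- lineGenome(3)
    nuc <- nucleusModel(Rex = 118)
    # 3 regions, 1 body, 2 structures: hand evaluation
    x1 <- rbind(c(500, 0, 0), c(1500, 0, 0), c(2500, 0, 0),
                c(1000, 0, 0), c(2000, 0, 0), c(3000, 0, 0))
    x2 <- x1
    x2[, 1] <- x1[, 1] + 200
    pop <- handPop(g, nuc, list(x1, x2))
    bodies <- structure(list(
        list(list(center = c(0, 0, 0), beads = integer())),
        list(list(center = c(0, 0, 0), beads = integer()))),
        class = "BodyLocations")
    ts <- tsaSignal(pop, "speckle", bodies, R0 = 4)
    dUm <- cbind(x1[, 1], x2[, 1]) / 1000
    raw <- rowMeans(exp(-4 * dUm))
    expect_equal(ts$raw, raw)
    expect_equal(ts$perCopy, log2(raw / mean(raw)))
    expect_equal(ts$signal, (ts$perCopy[1:3] + ts$perCopy[4:6]) / 2)
    # mean of 2^(normalized per-copy signal) is 1 before copy averaging
    expect_equal(mean(2^ts$perCopy), 1)
    # monotone: nearer regions have higher signal
    expect_true(all(diff(ts$signal) < 0))

    # all regions equidistant from the body -> normalized signal 0
    xe <- matrix(0, 6, 3)
    xe[, 1] <- 1200 * cos(seq_len(6))
    xe[, 2] <- 1200 * sin(seq_len(6))
    tse <- tsaSignal(handPop(g, nuc, list(xe)), "speckle",
        structure(list(list(list(center = c(0, 0, 0), beads = integer()))),
                  class = "BodyLocations"))
    expect_true(all(abs(tse$signal) < 1e-9))

    # lamina variant uses (1 - r) * Rnuc distances
    tl <- tsaSignal(pop, "lamina", R0 = 4)
    rad <- cbind(x1[, 1], x2[, 1]) / 5000
    rawL <- rowMeans(exp(-4 * (1 - rad) * 5))
    expect_equal(tl$raw, rawL)
})

test_that("ICP counts other-chromosome neighbors, homolog partner as intra", {
    g <- segmentGenome(data.frame(name = c("a", "b"),
                                  length = c(2 * 2e5, 2 * 2e5)), 2e5)
    nuc <- nucleusModel(Rex = 118)
    # bead layout (copy0: a1 a2 b1 b2; copy1: 5..8)
    x <- cbind(seq(10000, 40000, length.out = 8), 0, 0)
    # a1 copy0 with 3 intra + 1 inter neighbors -> contribution 0.25
    x[1, ] <- c(0, 0, 0)
    x[2, ] <- c(300, 0, 0)      # intra (same chrom)
    x[5, ] <- c(0, 300, 0)      # homolog copy of a1: intra
    x[6, ] <- c(-300, 0, 0)     # copy 1 of a2: intra
    x[3, ] <- c(0, -300, 0)     # chrom b: inter
    pop <- handPop(g, nuc, list(x))
    icp <- interChromosomalProbability(pop, radius = 500)
    expect_equal(icp[1], (0.25 + 0) / 2)  # copy1 of bin a1 sees 3 intra

    # all-same-chromosome neighborhood -> 0; all-other -> 1
    g2 <- segmentGenome(data.frame(name = c("a", "b"),
                                   length = c(2e5, 2e5)), 2e5)
    xa <- cbind(seq(10000, 40000, length.out = 4), 0, 0)
    xa[1, ] <- c(0, 0, 0)
    xa[2, ] <- c(200, 0, 0)     # only neighbor is trans
    icp2 <- interChromosomalProbability(handPop(g2, nuc, list(xa)), 500)
    expect_equal(icp2, c(0.5, 0.5))  # one copy all-inter, other copy empty

    # invariant under global rotation
    theta <- 0.7
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0), c(0, 0, 1))
    popRot <- handPop(g, nuc, list(x %*% t(R)))
    expect_equal(interChromosomalProbability(popRot, 500), icp)
})

test_that("trans A/B ratios use a unit pseudocount and min-max rescaling", {
    g <- segmentGenome(data.frame(name = c("a", "b"),
                                  length = c(2e5, 3 * 2e5)), 2e5)
    nuc <- nucleusModel(Rex = 118)
    # bin a1 has trans neighbors 3 A and 1 B -> ratio (3+1)/(1+1) = 2
    x <- cbind(seq(10000, 80000, length.out = 8), 0, 0)
    x[1, ] <- c(0, 0, 0)              # a1 copy 0
    x[2, ] <- c(300, 0, 0)            # b1 (A)
    x[3, ] <- c(0, 300, 0)            # b2 (A)
    x[6, ] <- c(-300, 0, 0)           # b1 copy 1 (A)
    x[7, ] <- c(0, -300, 0)           # b2 copy 1... relabel below
    ab <- c("A", "A", "A", "B")
    # make one of the four neighbors B: use b3 instead of b2 copy1
    x[7, ] <- c(100000, 0, 0)
    x[8, ] <- c(0, -300, 0)           # b3 copy 1 (B)
    pop <- handPop(g, nuc, list(x))
    tr <- transABRatio(pop, ab, radius = 500)
    expect_equal(tr$matrix[1, 1], (3 + 1) / (1 + 1))

    expect_error(transABRatio(pop, c("A", "A", NA, "B")), "labeled")

    # rescaling maps the genome max to 1 and min to 0
    tab <- toyFeatures()
    expect_equal(max(tab$TRANS_AB, na.rm = TRUE), 1)
    expect_equal(min(tab$TRANS_AB, na.rm = TRUE), 0)
})

test_that("the assembled feature table has 17 bounded, reproducible columns", {
    tab <- toyFeatures()
    featCols <- setdiff(names(tab), c("chrom", "start", "end"))
    expect_equal(featCols,
                 c("RAD", "RG", "SpD", "NuD", "dRAD", "dRG", "dSpD",
                   "dNuD", "ILF", "SAF", "LAF", "NAF", "S_TSA", "L_TSA",
                   "N_TSA", "ICP", "TRANS_AB"))
    expect_equal(nrow(tab), nBins(toyTruth()@genome))
    bounded <- c("RAD", "ILF", "SAF", "LAF", "NAF", "ICP", "TRANS_AB")
    for (cn in bounded)
        expect_true(all(tab[[cn]] >= 0 & tab[[cn]] <= 1, na.rm = TRUE),
                    label = cn)
    expect_true(all(tab$SpD >= 0 & tab$NuD >= 0, na.rm = TRUE))

    # recomputing from a saved population is bit-identical
    pop <- toyPop()
    tmp <- tempfile(fileext = ".rds")
    writePopulation(pop, tmp)
    pop2 <- readPopulation(tmp)
    b <- toyBodies()
    tab2 <- featureTable(pop2, b$speckles, b$nucleoli,
                         truthLabels(toyTruth())$compartment)
    expect_identical(tab2, tab)

    # TSV round trip
    tsv <- tempfile(fileext = ".tsv")
    writeFeatureTable(tab, tsv)
    back <- readFeatureTable(tsv)
    expect_equal(back$SAF, tab$SAF, tolerance = 1e-9)

    expect_error(featureTable(pop, NULL, toyBodies()$nucleoli, "A"),
                 "speckle")
})
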