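#' Variability groups from radial-position heterogeneity
#'
#' Splits A- and B-compartment chromatin by the sign of the radial
#' variability score dRAD: A-LV (`dRAD <= 0`), A-HV (`dRAD > 0`), and
#' analogously B-LV / B-HV. Exact zeros fall in the low-variability group.
#'
#' @param table feature table from [featureTable()] (needs `dRAD`).
#' @param abLabels character per region, `"A"` or `"B"`.
#' @return character per region (`"A-LV"`, `"A-HV"`, `"B-LV"`, `"B-HV"`,
#'   `NA` for unlabeled or masked regions).
#' @export
variabilityGroups <- function(table, abLabels) {
    stopifnot("dRAD" %in% names(table))
    hv <- ifelse(table$dRAD > 0, "HV", "LV")
    out <- ifelse(is.na(abLabels) | is.na(hv), NA_character_,
                  paste(abLabels, hv, sep = "-"))
    out
}

#' Equal-count decile (quantile) groups of a per-region signal
#'
#' Regions are ranked by the signal (ties broken by region order, i.e. a
#' stable sort) and split into `nGroups` groups of near-equal size,
#' ascending: `d1` holds the lowest values.
#'
#' @param signal numeric per region (`NA` regions get `NA` groups).
#' @param nGroups number of groups (default 10).
#' @return character per region (`"d1"` ... `"d<nGroups>"`).
#' @export
decileGroups <- function(signal, nGroups = 10L) {
    ok <- which(!is.na(signal))
    if (length(ok) < nGroups)
        stop("fewer regions than groups")
    ord <- ok[order(signal[ok])]  # stable: ties keep region order
    sizes <- diff(floor(seq(0, length(ok), length.out = nGroups + 1)))
    grp <- rep(seq_len(nGroups), sizes)
    out <- rep(NA_character_, length(signal))
    out[ord] <- paste0("d", grp)
    out
}

.DELTA_FEATURES <- c("dRAD", "dRG", "dSpD", "dNuD")

#' Fold-change enrichment of structural features by group
#'
#' Entry `(g, f)` is `log2(mean of feature f over group g / mean over all
#' labeled regions)`. Variability (delta) features are log2 ratios with
#' negative support, so their enrichment uses the linear-scale counterpart
#' `2^delta`. Entries with a non-positive background mean are masked.
#'
#' @param table feature table from [featureTable()].
#' @param groups character per region; `NA` regions are excluded from both
#'   groups and background.
#' @param features feature column names (default: all 17).
#' @return numeric group-by-feature matrix of log2 fold changes.
#' @export
foldChangeEnrichment <- function(table, groups,
                                 features = setdiff(names(table),
                                                    c("chrom", "start",
                                                      "end"))) {
    stopifnot(length(groups) == nrow(table))
    lab <- !is.na(groups)
    vals <- as.matrix(table[features])
    vals[, intersect(features, .DELTA_FEATURES)] <-
        2^vals[, intersect(features, .DELTA_FEATURES)]
    lev <- sort(unique(groups[lab]))
    out <- matrix(NA_real_, length(lev), length(features),
                  dimnames = list(lev, features))
    bg <- colMeans(vals[lab, , drop = FALSE], na.rm = TRUE)
    for (g in lev) {
        inG <- lab & groups == g
        mg <- colMeans(vals[inG, , drop = FALSE], na.rm = TRUE)
        fc <- log2(mg / bg)
        fc[!is.finite(fc) | bg <= 0] <- NA_real_
        out[g, ] <- fc
    }
    out
}

#' ROC discrimination of a binary label by a feature
#'
#' Rank-based AUC: the probability that a positive outranks a negative,
#' with ties counting 0.5; the curve gives TPR/FPR at every threshold.
#'
#' @param values numeric feature values.
#' @param labels logical (or 0/1) per value; `TRUE` = positive.
#' @return list with `auc` and a data.frame `curve` (`threshold`, `tpr`,
#'   `fpr`).
#' @export
rocDiscrimination <- function(values, labels) {
    labels <- as.logical(labels)
    ok <- !is.na(values) & !is.na(labels)
    values <- values[ok]
    labels <- labels[ok]
    n1 <- sum(labels)
    n0 <- sum(!labels)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(values)  # midranks: ties contribute 0.5
    auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- c(Inf, sort(unique(values), decreasing = TRUE))
    curve <- data.frame(threshold = thr,
                        tpr = vapply(thr, function(t)
                            sum(labels & values >= t) / n1, 0),
                        fpr = vapply(thr, function(t)
                            sum(!labels & values >= t) / n0, 0))
    list(auc = auc, curve = curve)
}

#' Structure-based subcompartment prediction by K-means
#'
#' Feature columns are z-scored; A- and B-compartment regions are clustered
#' separately (`kActive` and `kInactive` clusters). Clusters are mapped to
#' reference subcompartment labels by the permutation maximizing agreement,
#' and accuracy plus confusion matrices are reported.
#'
#' @param table feature table from [featureTable()].
#' @param abLabels character per region, `"A"` or `"B"`.
#' @param reference character per region: reference subcompartment labels
#'   (e.g. A1/A2/B1/B2/B3).
#' @param kActive,kInactive cluster counts for A and B chromatin.
#' @param features feature columns to use (default: all 17).
#' @param seed integer seed (K-means initialization).
#' @return list with `predicted` (character per region), `accuracy`
#'   (overall), `accuracyA`, `accuracyB`, and confusion matrices
#'   `confusionA`, `confusionB`.
#' @export
predictSubcompartments <- function(table, abLabels, reference,
                                   kActive = 2L, kInactive = 3L,
                                   features = setdiff(names(table),
                                                      c("chrom", "start",
                                                        "end")),
                                   seed = 1L) {
    vals <- as.matrix(table[features])
    predicted <- rep(NA_character_, nrow(table))
    fit <- function(compartment, k) {
        idx <- which(abLabels == compartment &
                     stats::complete.cases(vals) & !is.na(reference))
        if (length(idx) <= k) stop("k exceeds usable region count")
        x <- scale(vals[idx, , drop = FALSE])
        x <- x[, apply(x, 2, function(v) all(is.finite(v))), drop = FALSE]
        set.seed(seed)
        km <- stats::kmeans(x, centers = k, nstart = 10L, iter.max = 50L)
        labs <- sort(unique(reference[idx]))
        map <- .bestLabelMap(km$cluster, reference[idx], labs)
        pred <- map[km$cluster]
        conf <- table(reference = reference[idx], predicted = pred)
        list(idx = idx, pred = pred,
             accuracy = mean(pred == reference[idx]), confusion = conf)
    }
    a <- fit("A", kActive)
    b <- fit("B", kInactive)
    predicted[a$idx] <- a$pred
    predicted[b$idx] <- b$pred
    nOk <- length(a$idx) + length(b$idx)
    list(predicted = predicted,
         accuracy = (a$accuracy * length(a$idx) +
                     b$accuracy * length(b$idx)) / nOk,
         accuracyA = a$accuracy, accuracyB = b$accuracy,
         confusionA = a$confusion, confusionB = b$confusion)
}

# exhaustive optimal cluster -> label assignment (k is small)
.bestLabelMap <- function(cluster, truth, labs) {
    k <- max(cluster)
    if (length(labs) < k)
        labs <- c(labs, paste0(labs[1], ".extra",
                               seq_len(k - length(labs))))
    perms <- .permutations(seq_along(labs))
    best <- NULL
    bestAcc <- -1
    for (p in perms) {
        map <- labs[p][seq_len(k)]
        acc <- mean(map[cluster] == truth)
        if (acc > bestAcc) {
            bestAcc <- acc
            best <- map
        }
    }
    best
}

.permutations <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in .permutations(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}
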