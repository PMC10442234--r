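#' Construct a ContactMatrix from triplets
#'
#' @param genome a [GenomeDefinition-class].
#' @param I,J 1-based haploid bin indices.
#' @param p contact probabilities in `[0, 1]`.
#' @return a [ContactMatrix-class]; entries are stored upper-triangle with
#'   duplicates resolved by the maximum, diagonal entries dropped.
#' @export
contactMatrix <- function(genome, I, J, p) {
    lo <- pmin(I, J)
    hi <- pmax(I, J)
    keep <- lo != hi & p != 0
    e <- data.frame(I = as.integer(lo[keep]), J = as.integer(hi[keep]),
                    p = as.numeric(p[keep]))
    if (nrow(e)) {
        e <- e[order(e$I, e$J, -e$p), ]
        e <- e[!duplicated(e[c("I", "J")]), ]
        rownames(e) <- NULL
    }
    new("ContactMatrix", genome = genome, entries = e)
}

#' Read a contact-probability matrix from sparse triplet text
#'
#' Rows are `bin_i <TAB> bin_j <TAB> p` with 0-based haploid bin indices.
#' The matrix is symmetrized by taking the maximum of the two triangles;
#' probabilities are clipped to `[0, 1]` (the number of clipped values is
#' reported via a warning); diagonal entries are ignored.
#'
#' @param path triplet file (optionally gzip-compressed).
#' @param genome a [GenomeDefinition-class].
#' @return a [ContactMatrix-class].
#' @export
readContactMatrix <- function(path, genome) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("I", "J", "p"))
    if (!is.numeric(x$p)) stop("non-numeric probability column")
    N <- nBins(genome)
    if (any(x$I < 0 | x$I >= N | x$J < 0 | x$J >= N))
        stop("bin index out of range")
    nClip <- sum(x$p < 0 | x$p > 1)
    if (nClip > 0)
        warning(sprintf("%d probabilities clipped to [0, 1]", nClip))
    contactMatrix(genome, x$I + 1L, x$J + 1L, pmin(1, pmax(0, x$p)))
}

#' Write a ContactMatrix as sparse triplet text (0-based indices)
#' @param cm a [ContactMatrix-class].
#' @param path output path (".gz" suffix writes gzip).
#' @export
writeContactMatrix <- function(cm, path) {
    e <- cm@entries
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    utils::write.table(data.frame(e$I - 1L, e$J - 1L, e$p), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @describeIn contactMatrix dense symmetric matrix of the entries
#' @param cm a [ContactMatrix-class].
#' @export
as.matrix.ContactMatrix <- function(cm) {
    N <- nBins(cm@genome)
    A <- matrix(0, N, N)
    e <- cm@entries
    A[cbind(e$I, e$J)] <- e$p
    A[cbind(e$J, e$I)] <- e$p
    A
}

#' @describeIn contactMatrix number of stored (non-zero) entries
#' @export
nEntries <- function(cm) nrow(cm@entries)

.entrySplit <- function(cm, split = c("all", "cis", "trans")) {
    split <- match.arg(split)
    e <- cm@entries
    if (split == "all" || !nrow(e)) return(e)
    chrom <- binChrom(cm@genome)
    cis <- chrom[e$I] == chrom[e$J]
    if (split == "cis") e[cis, , drop = FALSE] else e[!cis, , drop = FALSE]
}

#' Compare two contact matrices over the support of the first
#'
#' Correlations are computed over the non-zero entries of `A` (restricted to
#' the requested split); the value of `B` at an entry absent from `B` is 0.
#'
#' @param A,B [ContactMatrix-class] objects on the same genome.
#' @param split `"all"`, `"cis"` or `"trans"`.
#' @return list with `pearson`, `spearman`, `n`, and a per-chromosome
#'   data.frame `perChrom` (cis entries by chromosome).
#' @export
compareMatrices <- function(A, B, split = c("all", "cis", "trans")) {
    split <- match.arg(split)
    stopifnot(nBins(A@genome) == nBins(B@genome))
    ea <- .entrySplit(A, split)
    if (!nrow(ea)) stop("no overlapping entries for this split")
    Bm <- as.matrix.ContactMatrix(B)
    va <- ea$p
    vb <- Bm[cbind(ea$I, ea$J)]
    chrom <- binChrom(A@genome)
    cis <- chrom[ea$I] == chrom[ea$J]
    per <- lapply(split(seq_len(nrow(ea))[cis], chrom[ea$I[cis]]), function(k) {
        if (length(k) < 3L) return(c(NA_real_, NA_real_, length(k)))
        c(stats::cor(va[k], vb[k]),
          stats::cor(va[k], vb[k], method = "spearman"), length(k))
    })
    perChrom <- data.frame(chrom = names(per),
                           pearson = vapply(per, `[`, 0, 1),
                           spearman = vapply(per, `[`, 0, 2),
                           n = vapply(per, `[`, 0, 3))
    list(pearson = stats::cor(va, vb),
         spearman = stats::cor(va, vb, method = "spearman"),
         n = length(va), perChrom = perChrom)
}

#' Residual ratios between an input matrix and model-derived frequencies
#'
#' For each entry with input frequency `f_input > 0`, the residual ratio is
#' `(f_input - f_model) / f_input`; summaries are reported for cis and trans
#' entries separately.
#'
#' @param Ainput input [ContactMatrix-class].
#' @param Fmodel model-derived [ContactMatrix-class].
#' @return list with per-entry data.frame `ratios` (`I`, `J`, `cis`, `dr`)
#'   and `summary` (median and mean by cis/trans).
#' @export
residualRatio <- function(Ainput, Fmodel) {
    e <- Ainput@entries
    Fm <- as.matrix.ContactMatrix(Fmodel)
    dr <- (e$p - Fm[cbind(e$I, e$J)]) / e$p
    chrom <- binChrom(Ainput@genome)
    cis <- chrom[e$I] == chrom[e$J]
    summ <- do.call(rbind, lapply(c(cis = TRUE, trans = FALSE), function(z) {
        v <- dr[cis == z]
        data.frame(n = length(v),
                   median = if (length(v)) stats::median(v) else NA_real_,
                   mean = if (length(v)) mean(v) else NA_real_)
    }))
    summ$split <- c("cis", "trans")
    list(ratios = data.frame(I = e$I, J = e$J, cis = cis, dr = dr),
         summary = summ[c("split", "n", "median", "mean")])
}

setMethod("show", "ContactMatrix", function(object) {
    cat("ContactMatrix:", nBins(object@genome), "x", nBins(object@genome),
        "haploid bins,", nrow(object@entries), "non-zero entries\n")
})
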