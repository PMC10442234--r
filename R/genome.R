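#' Segment a genome into fixed-size bins with diploid bead indexing
#'
#' Each chromosome is cut into `ceiling(length / binSize)` consecutive bins;
#' only the terminal bin of a chromosome may be shorter than `binSize`.
#'
#' @param chromSizes data.frame with columns `name` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param binSize bin size in bp (default 200 kb).
#' @param exclude optional `GRanges` of regions to exclude (e.g. unmappable
#'   gaps); bins assigned by majority overlap stay in the chain but are
#'   masked from restraints and features.
#' @return a [GenomeDefinition-class].
#' @examples
#' g <- segmentGenome(data.frame(name = "chr1", length = 1.1e6), 2e5)
#' nBins(g)  # 6 bins, last one 100 kb
#' @export
segmentGenome <- function(chromSizes, binSize = 2e5, exclude = NULL) {
    if (is.numeric(chromSizes) && !is.null(names(chromSizes)))
        chromSizes <- data.frame(name = names(chromSizes),
                                 length = as.numeric(chromSizes))
    stopifnot(is.data.frame(chromSizes),
              all(c("name", "length") %in% names(chromSizes)))
    if (anyDuplicated(chromSizes$name))
        stop("duplicate chromosome name")
    if (any(chromSizes$length <= 0))
        stop("zero- or negative-length chromosome")
    if (binSize <= 0)
        stop("binSize must be positive")
    sl <- stats::setNames(as.integer(chromSizes$length),
                          as.character(chromSizes$name))
    bins <- GenomicRanges::tileGenome(sl, tilewidth = binSize,
                                      cut.last.tile.in.chrom = TRUE)
    excluded <- rep(FALSE, length(bins))
    if (!is.null(exclude)) {
        hit <- IRanges::findOverlaps(bins, exclude)
        if (length(hit)) {
            ov <- GenomicRanges::width(IRanges::pintersect(
                bins[S4Vectors::queryHits(hit)],
                exclude[S4Vectors::subjectHits(hit)]))
            cov <- tapply(ov, S4Vectors::queryHits(hit), sum)
            idx <- as.integer(names(cov))
            excluded[idx] <- cov > GenomicRanges::width(bins)[idx] / 2
        }
    }
    new("GenomeDefinition", bins = bins, binSize = binSize,
        excluded = excluded)
}

#' @describeIn segmentGenome number of haploid bins
#' @param genome a [GenomeDefinition-class]
#' @export
nBins <- function(genome) length(genome@bins)

#' @describeIn segmentGenome number of diploid beads (2N)
#' @export
nBeads <- function(genome) 2L * length(genome@bins)

#' Haploid bin table
#'
#' @param genome a [GenomeDefinition-class].
#' @return data.frame with `chrom`, `start` (0-based), `end` (half-open).
#' @export
binTable <- function(genome) {
    b <- genome@bins
    data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
               start = GenomicRanges::start(b) - 1L,
               end = GenomicRanges::end(b),
               stringsAsFactors = FALSE)
}

#' Chromosome id per haploid bin (integer code in genome order)
#' @param genome a [GenomeDefinition-class].
#' @export
binChrom <- function(genome) {
    as.integer(factor(as.character(GenomicRanges::seqnames(genome@bins)),
                      levels = GenomeInfoDb::seqlevels(genome@bins)))
}

#' Diploid bead index table
#'
#' Beads `1..N` are copy 0 of bins `1..N`, beads `N+1..2N` copy 1.
#'
#' @param genome a [GenomeDefinition-class].
#' @return data.frame with `bead`, `bin`, `copy`, `chrom`.
#' @export
beadIndex <- function(genome) {
    N <- nBins(genome)
    chrom <- as.character(GenomicRanges::seqnames(genome@bins))
    data.frame(bead = seq_len(2L * N),
               bin = rep(seq_len(N), 2L),
               copy = rep(0:1, each = N),
               chrom = rep(chrom, 2L),
               stringsAsFactors = FALSE)
}

#' Consecutive-bead chain bonds for both chromosome copies
#'
#' @param genome a [GenomeDefinition-class].
#' @return integer matrix of bead pairs (1-based), one row per bond.
#' @export
chainBonds <- function(genome) {
    N <- nBins(genome)
    chrom <- binChrom(genome)
    same <- chrom[-N] == chrom[-1]
    i <- which(same)
    rbind(cbind(i, i + 1L), cbind(N + i, N + i + 1L))
}

#' Excluded-volume radius from nuclear geometry
#'
#' Solves the volume balance `n Rex^3 = occupancy * Rnuc^3`, i.e.
#' `Rex = Rnuc (occupancy / n)^(1/3)`: the radius of `n` equal spheres whose
#' total volume is the given fraction of a sphere of radius `Rnuc`.
#'
#' @param Rnuc nuclear radius, nm.
#' @param occupancy genome volume fraction, in (0, 1).
#' @param nBeads number of diploid beads.
#' @return excluded-volume radius in nm.
#' @examples
#' computeExcludedRadius(5000, 0.40, 30332)  # ~118 nm
#' @export
computeExcludedRadius <- function(Rnuc, occupancy, nBeads) {
    if (Rnuc <= 0 || occupancy <= 0 || occupancy >= 1 || nBeads < 1)
        stop("need Rnuc > 0, 0 < occupancy < 1, nBeads >= 1")
    Rnuc * (occupancy / nBeads)^(1 / 3)
}

#' Construct a spherical nucleus model
#'
#' `Rex` defaults to the occupancy-derived value
#' [computeExcludedRadius()]; pass it explicitly to override (e.g. to model
#' a genome subset at the physical bead size of the full genome).
#'
#' @param Rnuc nuclear radius in nm (default 5000).
#' @param occupancy genome volume fraction (default 0.40).
#' @param nBeads diploid bead count (needed unless `Rex` is given).
#' @param Rex optional excluded-volume radius override, nm.
#' @return a [NucleusModel-class].
#' @export
nucleusModel <- function(Rnuc = 5000, occupancy = 0.40, nBeads = NULL,
                         Rex = NULL) {
    if (is.null(Rex)) {
        if (is.null(nBeads))
            stop("provide nBeads or Rex")
        Rex <- computeExcludedRadius(Rnuc, occupancy, nBeads)
    }
    new("NucleusModel", Rnuc = Rnuc, occupancy = occupancy, Rex = Rex,
        Rsoft = 2 * Rex, contactDistance = 4 * Rex)
}

#' Read a chrom.sizes file (two tab-separated columns: name, length)
#' @param path file path.
#' @return data.frame with `name`, `length`.
#' @export
readChromSizes <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
    x
}

#' Read a BED file of labeled regions (3+1 columns)
#'
#' @param path BED path (chrom, start, end, label; 0-based half-open).
#' @return a `GRanges` with metadata column `label`.
#' @export
readBedAnnotations <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(x) < 4L) stop("BED file needs at least 4 columns")
    GenomicRanges::GRanges(x[[1]],
                           IRanges::IRanges(x[[2]] + 1L, x[[3]]),
                           label = as.character(x[[4]]))
}

#' Assign region labels to genome bins by majority overlap
#'
#' A bin gets the label covering the largest part of it; on ties the label of
#' the lower-coordinate annotation wins. Bins with no overlap get `NA`.
#'
#' @param genome a [GenomeDefinition-class].
#' @param annotations `GRanges` with a `label` metadata column (see
#'   [readBedAnnotations()]).
#' @return character vector of length `nBins(genome)`.
#' @export
annotateBins <- function(genome, annotations) {
    bins <- genome@bins
    lab <- rep(NA_character_, length(bins))
    hit <- IRanges::findOverlaps(bins, annotations)
    if (!length(hit)) return(lab)
    q <- S4Vectors::queryHits(hit)
    s <- S4Vectors::subjectHits(hit)
    ov <- GenomicRanges::width(IRanges::pintersect(bins[q], annotations[s]))
    df <- data.frame(bin = q, ov = ov,
                     start = GenomicRanges::start(annotations)[s],
                     label = S4Vectors::mcols(annotations)$label[s])
    df <- df[order(df$bin, -df$ov, df$start), ]
    keep <- !duplicated(df$bin)
    lab[df$bin[keep]] <- df$label[keep]
    lab
}

setMethod("show", "GenomeDefinition", function(object) {
    b <- object@bins
    chr <- GenomeInfoDb::seqlevels(b)
    cat("GenomeDefinition:", length(chr), "chromosome(s),",
        length(b), "bins of", object@binSize, "bp,",
        2L * length(b), "diploid beads\n")
    if (any(object@excluded))
        cat("  excluded bins:", sum(object@excluded), "\n")
})

setMethod("show", "NucleusModel", function(object) {
    cat(sprintf(paste0("NucleusModel: Rnuc = %.0f nm, occupancy = %.2f, ",
                       "Rex = %.1f nm, Rsoft = %.1f nm, contact = %.1f nm\n"),
                object@Rnuc, object@occupancy, object@Rex, object@Rsoft,
                object@contactDistance))
})
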