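#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width tileGenome
#' @importFrom GenomeInfoDb seqlengths seqlevels seqnames
#' @importFrom IRanges IRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

#' GenomeDefinition: fixed-size segmentation of a genome with diploid indexing
#'
#' Chromosomes are segmented into consecutive bins of at most `binSize` bp
#' (0-based, half-open); only the last bin of a chromosome may be shorter.
#' The diploid representation carries two beads per haploid bin: beads
#' `1..N` are copy 0 in bin order, beads `N+1..2N` are copy 1, so
#' bead-to-(bin, copy) is a bijection.
#'
#' @slot bins a [GenomicRanges::GRanges] of haploid bins, in genome order.
#' @slot binSize bin size in bp.
#' @slot excluded logical per bin; excluded bins stay in the chain but carry
#'   no contact restraints and are masked from features.
#' @export
setClass("GenomeDefinition",
    representation(bins = "GRanges", binSize = "numeric",
                   excluded = "logical"))

setValidity("GenomeDefinition", function(object) {
    w <- GenomicRanges::width(object@bins)
    if (any(w > object@binSize))
        return("bin wider than binSize")
    chr <- as.character(GenomicRanges::seqnames(object@bins))
    short <- which(w < object@binSize)
    for (s in short) {
        if (s < length(w) && chr[s + 1L] == chr[s])
            return("short bin not at chromosome end")
    }
    if (length(object@excluded) != length(object@bins))
        return("excluded flag length != bin count")
    TRUE
})

#' NucleusModel: spherical nucleus geometry
#'
#' Holds the nuclear radius, genome occupancy, the bead excluded-volume
#' radius `Rex`, the soft sphere radius `Rsoft = 2 Rex`, and the contact
#' capture distance `2 Rsoft = 4 Rex` (all nm).
#'
#' @slot Rnuc nuclear radius, nm.
#' @slot occupancy genome volume fraction used to derive `Rex`.
#' @slot Rex excluded-volume radius of one bead, nm.
#' @slot Rsoft soft contact radius, nm.
#' @slot contactDistance capture distance for chromatin contacts, nm.
#' @export
setClass("NucleusModel",
    representation(Rnuc = "numeric", occupancy = "numeric", Rex = "numeric",
                   Rsoft = "numeric", contactDistance = "numeric"))

setValidity("NucleusModel", function(object) {
    if (object@Rnuc <= 0 || object@Rex <= 0) return("radii must be positive")
    if (abs(object@Rsoft - 2 * object@Rex) > 1e-6)
        return("Rsoft != 2 * Rex")
    if (abs(object@contactDistance - 2 * object@Rsoft) > 1e-6)
        return("contactDistance != 2 * Rsoft")
    TRUE
})

#' ContactMatrix: sparse symmetric haploid contact probabilities
#'
#' Stored as upper-triangle triplets `(I, J, p)` with `I < J` (1-based bin
#' indices) and probabilities in `[0, 1]`; the diagonal is ignored.
#'
#' @slot genome a [GenomeDefinition-class].
#' @slot entries data.frame with integer columns `I`, `J` and numeric `p`.
#' @export
setClass("ContactMatrix",
    representation(genome = "GenomeDefinition", entries = "data.frame"))

setValidity("ContactMatrix", function(object) {
    e <- object@entries
    if (!all(c("I", "J", "p") %in% names(e))) return("entries need I, J, p")
    N <- length(object@genome@bins)
    if (nrow(e)) {
        if (any(e$I >= e$J)) return("entries must have I < J")
        if (any(e$I < 1L | e$J > N)) return("bin index out of range")
        if (any(e$p < 0 | e$p > 1)) return("probabilities outside [0, 1]")
        if (anyDuplicated(e[c("I", "J")])) return("duplicate entries")
    }
    TRUE
})

#' StructurePopulation: M diploid 3D genome structures
#'
#' @slot genome a [GenomeDefinition-class].
#' @slot nucleus a [NucleusModel-class].
#' @slot coords numeric array `(2N, 3, M)` of bead centers, nm.
#' @slot seed integer seed recorded at creation (provenance).
#' @export
setClass("StructurePopulation",
    representation(genome = "GenomeDefinition", nucleus = "NucleusModel",
                   coords = "array", seed = "integer"))

setValidity("StructurePopulation", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L) return("coords must be (2N, 3, M)")
    if (d[1] != 2L * length(object@genome@bins))
        return("bead count != 2N")
    if (!all(is.finite(object@coords))) return("non-finite coordinates")
    TRUE
})

#' ContactAssignment: homolog-resolved contacts assigned to structures
#'
#' @slot pairs data.frame of active haploid pairs: `I`, `J`, `a` (input
#'   probability), `k` (required structure count), `cis`.
#' @slot contacts integer matrix with columns `structure`, `p`, `q`, `pair`
#'   (1-based diploid bead and pair-row indices).
#' @slot theta activation threshold used.
#' @export
setClass("ContactAssignment",
    representation(pairs = "data.frame", contacts = "matrix",
                   theta = "numeric"))

#' SyntheticTruth: planted architecture for the toy-genome generator
#'
#' @slot genome a [GenomeDefinition-class].
#' @slot nucleus a [NucleusModel-class].
#' @slot classes character per haploid bin: `"speckle<k>"`, `"lamina"`,
#'   `"nucleolus"`, `"variable"` or `"free"`.
#' @slot subcompartment character per bin (A1/A2/B1/B2/B3-style labels).
#' @slot compartment character per bin ("A"/"B").
#' @slot params named list of generator parameters (pAssoc, anchorRadius,
#'   shellFrac, mixtureWeight, noise, anchor directions and radial ranges).
#' @export
setClass("SyntheticTruth",
    representation(genome = "GenomeDefinition", nucleus = "NucleusModel",
                   classes = "character", subcompartment = "character",
                   compartment = "character", params = "list"))
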