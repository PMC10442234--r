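#' Construct a StructurePopulation
#'
#' @param genome a [GenomeDefinition-class].
#' @param nucleus a [NucleusModel-class].
#' @param coords numeric array `(2N, 3, M)` of bead centers in nm.
#' @param seed integer seed recorded for provenance.
#' @return a [StructurePopulation-class].
#' @export
structurePopulation <- function(genome, nucleus, coords, seed = NA_integer_) {
    new("StructurePopulation", genome = genome, nucleus = nucleus,
        coords = coords, seed = as.integer(seed))
}

#' @describeIn structurePopulation number of structures M
#' @param pop a [StructurePopulation-class].
#' @export
nStructures <- function(pop) dim(pop@coords)[3]

#' @describeIn structurePopulation the `(2N, 3, M)` coordinate array (nm)
#' @export
popCoords <- function(pop) pop@coords

.POP_SCHEMA <- "nucenv-population-1"

#' Write / read a structure population container
#'
#' The container is a single binary file of named arrays (serialized with
#' R's native serialization, version 3): `coords`, the genome table and bin
#' size, the nucleus parameters, and metadata including the seed. Round
#' trips are bit-exact for coordinates; files with a different schema
#' version or a missing nucleus group are rejected.
#'
#' @param pop a [StructurePopulation-class].
#' @param path output path.
#' @export
writePopulation <- function(pop, path) {
    obj <- list(schema = .POP_SCHEMA,
                coords = pop@coords,
                genome = list(bins = binTable(pop@genome),
                              binSize = pop@genome@binSize,
                              excluded = pop@genome@excluded),
                nucleus = list(Rnuc = pop@nucleus@Rnuc,
                               occupancy = pop@nucleus@occupancy,
                               Rex = pop@nucleus@Rex),
                meta = list(seed = pop@seed))
    saveRDS(obj, path, version = 3)
    invisible(path)
}

#' @rdname writePopulation
#' @return `readPopulation` returns a [StructurePopulation-class].
#' @export
readPopulation <- function(path) {
    obj <- readRDS(path)
    if (!is.list(obj) || !identical(obj$schema, .POP_SCHEMA))
        stop("not a population container or schema-version mismatch")
    if (is.null(obj$nucleus))
        stop("population container is missing the nucleus group")
    b <- obj$genome$bins
    sizes <- tapply(b$end, factor(b$chrom, levels = unique(b$chrom)), max)
    genome <- segmentGenome(data.frame(name = names(sizes),
                                       length = as.numeric(sizes)),
                            obj$genome$binSize)
    genome@excluded <- obj$genome$excluded
    nuc <- nucleusModel(Rnuc = obj$nucleus$Rnuc,
                        occupancy = obj$nucleus$occupancy,
                        Rex = obj$nucleus$Rex)
    structurePopulation(genome, nuc, obj$coords, obj$meta$seed)
}

#' Contact frequencies of a structure population
#'
#' Two beads are in contact when their center distance is at most
#' `2 * Rsoft` (= 4 Rex). For a cis pair the two within-homolog copy
#' combinations are counted, for a trans pair all four combinations; counts
#' are divided by `2M` and clipped to 1.
#'
#' @param pop a [StructurePopulation-class].
#' @param cutoff contact capture distance in nm; defaults to the nucleus
#'   contact distance.
#' @return a [ContactMatrix-class] of haploid contact frequencies.
#' @export
populationContactFrequencies <- function(pop, cutoff = NULL) {
    if (is.null(cutoff)) cutoff <- pop@nucleus@contactDistance
    Fm <- .cppContactFrequencies(pop@coords, binChrom(pop@genome), cutoff)
    idx <- which(upper.tri(Fm) & Fm > 0, arr.ind = TRUE)
    contactMatrix(pop@genome, idx[, 1], idx[, 2], Fm[idx])
}

setMethod("show", "StructurePopulation", function(object) {
    d <- dim(object@coords)
    cat("StructurePopulation:", d[3], "structures x", d[1], "beads",
        sprintf("(N = %d haploid bins), Rnuc = %.0f nm\n",
                d[1] %/% 2L, object@nucleus@Rnuc))
})
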