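#' @name accessors
#' @title Accessors for regBeacons containers
#' @description Accessor functions for the S4 containers; slots are not part
#'   of the public interface.
#' @param x an object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("hitTable", function(x) standardGeneric("hitTable"))
#' @rdname accessors
#' @export
setGeneric("regionSet", function(x) standardGeneric("regionSet"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setGeneric("hiddenWindows", function(x) standardGeneric("hiddenWindows"))
#' @rdname accessors
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("coreGenes", function(x) standardGeneric("coreGenes"))
#' @rdname accessors
#' @export
setGeneric("regionClasses", function(x) standardGeneric("regionClasses"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("mclClusters", function(x) standardGeneric("mclClusters"))

#' @rdname accessors
setMethod("geneTable", "GenomeSim", function(x) x@genes)
#' @rdname accessors
setMethod("hitTable", "GenomeSim", function(x) x@hits)
#' @rdname accessors
setMethod("regionSet", "GenomeSim", function(x) x@regions)
#' @rdname accessors
setMethod("simTruth", "GenomeSim", function(x) x@truth)
#' @rdname accessors
setMethod("hiddenWindows", "GenomeSim", function(x) x@hidden)
#' @rdname accessors
setMethod("contigLengths", "GenomeSim", function(x) x@contigs)

#' @rdname accessors
setMethod("regionTable", "BgcRegionSet", function(x) x@regions)
#' @rdname accessors
setMethod("coreGenes", "BgcRegionSet", function(x) x@coreGenes)
#' @rdname accessors
setMethod("regionClasses", "BgcRegionSet", function(x) x@classes)

#' @rdname accessors
setMethod("networkNodes", "CoocNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "CoocNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("mclClusters", "MclResult", function(x) x@clusters)

#' @describeIn accessors number of regions in a region set.
#' @export
setMethod("length", "BgcRegionSet", function(x) nrow(x@regions))

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenomes, "genome(s),",
        object@genesPerGenome, "background genes/genome,",
        object@nBgcPerGenome, "BGC(s) of", object@bgcLength, "nt\n")
    cat("  labeled families:",
        paste(sprintf("%s(n=%d, p_in=%.3g)", names(object@familyCounts),
                      object@familyCounts,
                      ifelse(names(object@familyCounts) %in%
                                 names(object@familyPIn),
                             object@familyPIn[names(object@familyCounts)],
                             object@backgroundPIn)),
              collapse = ", "), "\n")
    cat("  background p_in:", object@backgroundPIn,
        " seed:", object@seed, "\n")
})

setMethod("show", "GenomeSim", function(object) {
    cat("GenomeSim:", length(object@contigs), "contig(s),",
        nrow(object@genes), "genes,", nrow(object@hits), "domain hits,",
        nrow(object@regions@regions), "BGC regions")
    if (nrow(object@hidden))
        cat(",", nrow(object@hidden), "hidden window(s)")
    cat("\n")
})

setMethod("show", "BgcRegionSet", function(object) {
    cat("BgcRegionSet with", nrow(object@regions), "region(s) on",
        length(unique(object@regions$contig)), "contig(s);",
        nrow(object@coreGenes), "core gene(s)\n")
})

setMethod("show", "CoocNetwork", function(object) {
    cat("CoocNetwork:", length(object@nodes), "domain node(s),",
        nrow(object@edges), "edge(s)\n")
})

setMethod("show", "MclResult", function(object) {
    sizes <- vapply(object@clusters, length, 1L)
    cat("MclResult:", length(object@clusters), "cluster(s) over",
        sum(sizes), "node(s);", object@iterations, "iteration(s);",
        if (object@converged) "converged" else "NOT converged", "\n")
})
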