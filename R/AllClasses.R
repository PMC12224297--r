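#' @import methods
#' @importFrom stats runif quantile setNames
NULL

#' Simulation configuration for synthetic genomes
#'
#' A \code{SimConfig} describes the statistical structure of a cohort of
#' synthetic bacterial genomes: one contig per genome, a set of disjoint BGC
#' regions, genes labeled with regulator families whose domain content follows
#' a per-family grammar, and a per-family probability of falling inside a BGC
#' interval. The background probability defaults to 0.146, the genome-wide
#' fraction of coding regions inside predicted BGC ranges in \emph{Streptomyces}.
#'
#' @slot nGenomes number of genomes to simulate.
#' @slot genesPerGenome number of background genes per genome (labeled family
#'   genes given by \code{familyCounts} are placed in addition).
#' @slot contigLength contig length in nt (one contig per genome).
#' @slot nBgcPerGenome number of disjoint BGC regions per contig.
#' @slot bgcLength BGC region length in nt (default 20000).
#' @slot familyGrammars named list; for each family, a list of character
#'   vectors, each an ordered domain architecture that genes of the family may
#'   carry.
#' @slot familyCounts named integer; genes per labeled family per genome.
#' @slot familyPIn named numeric; probability that a gene of each family is
#'   placed fully inside a BGC region.
#' @slot backgroundPIn probability for unlabeled (background) genes
#'   (default 0.146).
#' @slot bgcClassWeights named numeric; sampling weights for BGC product
#'   classes.
#' @slot mibigSimilarityLaw function(n) returning n percent similarities in
#'   [0, 100] for each region's best known-cluster match.
#' @slot decoyRate probability that a gene's domain hits gain one overlapping
#'   decoy hit with strictly lower normalized bitscore.
#' @slot hiddenPerGenome number of planted "hidden cluster" windows per genome:
#'   an out-of-BGC small-SARP-like beacon gene, far from all regions,
#'   surrounded by biosynthetic-domain genes.
#' @slot hiddenBiosynGenes number of biosynthetic genes planted around each
#'   hidden beacon.
#' @slot seed integer seed; all generator randomness derives from it.
#' @export
setClass("SimConfig", representation(
    nGenomes = "integer",
    genesPerGenome = "integer",
    contigLength = "integer",
    nBgcPerGenome = "integer",
    bgcLength = "integer",
    familyGrammars = "list",
    familyCounts = "integer",
    familyPIn = "numeric",
    backgroundPIn = "numeric",
    bgcClassWeights = "numeric",
    mibigSimilarityLaw = "function",
    decoyRate = "numeric",
    hiddenPerGenome = "integer",
    hiddenBiosynGenes = "integer",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    probs <- c(object@familyPIn, object@backgroundPIn, object@decoyRate)
    if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
        msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (length(object@bgcClassWeights) == 0L ||
        any(object@bgcClassWeights < 0) || sum(object@bgcClassWeights) <= 0)
        msg <- c(msg, "bgcClassWeights must be nonnegative with positive sum")
    missing <- setdiff(names(object@familyPIn), names(object@familyGrammars))
    if (length(missing))
        msg <- c(msg, paste0("familyGrammars missing for family: ",
                             paste(missing, collapse = ", ")))
    empty <- names(object@familyGrammars)[
        vapply(object@familyGrammars, length, 1L) == 0L]
    if (length(empty))
        msg <- c(msg, paste0("empty grammar for family: ",
                             paste(empty, collapse = ", ")))
    nb <- object@nBgcPerGenome
    need <- as.numeric(nb) * object@bgcLength + max(0L, nb - 1L)
    if (need > object@contigLength)
        msg <- c(msg, sprintf(
            "cannot place %d disjoint regions of %d nt on a %d nt contig",
            nb, object@bgcLength, object@contigLength))
    if (length(msg)) msg else TRUE
})

#' Set of BGC regions with classes, core genes and known-cluster similarity
#'
#' Wraps the per-region interval table (0-based, half-open), the per-region
#' product classes, and the core-gene table whose nearest member defines the
#' class assigned to an in-BGC regulator gene.
#'
#' @slot regions data.frame with columns region_id, contig, start, end,
#'   known_cluster_id (NA allowed), known_similarity_pct (NA allowed).
#' @slot classes named list mapping region_id to a character vector of
#'   product class names.
#' @slot coreGenes data.frame with columns region_id, gene_id, class, start,
#'   end; cores lie within their region.
#' @export
setClass("BgcRegionSet", representation(
    regions = "data.frame",
    classes = "list",
    coreGenes = "data.frame"
))

setValidity("BgcRegionSet", function(object) {
    r <- object@regions
    msg <- character()
    need <- c("region_id", "contig", "start", "end",
              "known_cluster_id", "known_similarity_pct")
    if (!all(need %in% names(r)))
        return(paste("regions must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(r$region_id))
        msg <- c(msg, "region_id must be unique")
    if (nrow(r) && any(r$start >= r$end))
        msg <- c(msg, "regions must satisfy start < end")
    if (!all(names(object@classes) %in% r$region_id))
        msg <- c(msg, "classes names must be region ids")
    cg <- object@coreGenes
    if (nrow(cg)) {
        i <- match(cg$region_id, r$region_id)
        if (anyNA(i))
            msg <- c(msg, "core gene refers to unknown region")
        else if (any(cg$start < r$start[i] | cg$end > r$end[i]))
            msg <- c(msg, "core genes must lie within their region")
    }
    sim <- r$known_similarity_pct
    if (any(!is.na(sim) & (sim < 0 | sim > 100)))
        msg <- c(msg, "known_similarity_pct must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Result of a synthetic-genome simulation
#'
#' Holds the emitted gene table, domain-hit table, BGC regions, the planted
#' hidden-cluster windows (if any) and the ground truth used to generate them.
#'
#' @slot genes data.frame: gene_id, protein_id, contig, start, end, strand,
#'   family (0-based half-open coordinates).
#' @slot hits data.frame of domain hits: protein_id, pfam_accession,
#'   pfam_name, start_aa, end_aa, bitscore, normalized_bitscore.
#' @slot regions a \code{BgcRegionSet}.
#' @slot hidden data.frame of planted hidden windows: contig, start, end,
#'   beacon_gene_id (zero rows when none were requested).
#' @slot truth data.frame: gene_id, family, in_bgc, region_id.
#' @slot contigs named integer of contig lengths.
#' @slot config the generating \code{SimConfig}.
#' @export
setClass("GenomeSim", representation(
    genes = "data.frame",
    hits = "data.frame",
    regions = "BgcRegionSet",
    hidden = "data.frame",
    truth = "data.frame",
    contigs = "integer",
    config = "SimConfig"
))

#' Domain co-occurrence network
#'
#' Nodes are PFAM domains weighted by the number of proteins containing them;
#' an edge joins two domains found together in at least one protein, weighted
#' by the number of such proteins. Containment is the edge count divided by
#' the smaller endpoint frequency, i.e. the proportion of times the rarer
#' domain co-occurs with the commoner one.
#'
#' @slot nodes named numeric: domain name -> protein frequency.
#' @slot edges data.frame: domain_a, domain_b (a < b lexicographically),
#'   count, containment.
#' @export
setClass("CoocNetwork", representation(
    nodes = "numeric",
    edges = "data.frame"
))

setValidity("CoocNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("domain_a", "domain_b", "count", "containment") %in% names(e)))
        return("edges must have columns domain_a, domain_b, count, containment")
    if (is.null(names(object@nodes)) && length(object@nodes))
        return("nodes must be named")
    if (nrow(e)) {
        if (any(e$domain_a == e$domain_b))
            msg <- c(msg, "self-edges are not allowed")
        if (any(e$domain_a > e$domain_b))
            msg <- c(msg, "edges must be stored with domain_a < domain_b")
        if (!all(c(e$domain_a, e$domain_b) %in% names(object@nodes)))
            msg <- c(msg, "edge endpoints must be nodes")
        else {
            lo <- pmin(object@nodes[e$domain_a], object@nodes[e$domain_b])
            if (any(e$count > lo))
                msg <- c(msg, "edge count cannot exceed the smaller node frequency")
            if (any(e$containment <= 0 | e$containment > 1))
                msg <- c(msg, "containment must lie in (0, 1]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Markov Clustering parameters
#'
#' @slot inflation elementwise power applied after expansion (default 6,
#'   producing fine-grained clusters).
#' @slot expansionPower matrix power for the expansion step (default 2).
#' @slot pruneBelow entries below this value are zeroed after inflation
#'   (default 1e-8).
#' @slot maxIter iteration cap (default 200).
#' @slot tol convergence threshold on the max absolute change (default 1e-9).
#' @export
setClass("MclParams", representation(
    inflation = "numeric",
    expansionPower = "integer",
    pruneBelow = "numeric",
    maxIter = "integer",
    tol = "numeric"
))

setValidity("MclParams", function(object) {
    msg <- character()
    if (object@inflation <= 1) msg <- c(msg, "inflation must exceed 1")
    if (object@expansionPower < 2L) msg <- c(msg, "expansionPower must be >= 2")
    if (object@pruneBelow < 0) msg <- c(msg, "pruneBelow must be >= 0")
    if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
    if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
    if (length(msg)) msg else TRUE
})

#' Markov Clustering result
#'
#' @slot clusters list of disjoint character vectors partitioning the node set.
#' @slot iterations number of expansion/inflation iterations performed.
#' @slot converged whether the iteration reached the tolerance before the cap.
#' @slot colSumDeviation per-iteration max |column sum - 1| after inflation
#'   (diagnostic; column stochasticity must be preserved).
#' @export
setClass("MclResult", representation(
    clusters = "list",
    iterations = "integer",
    converged = "logical",
    colSumDeviation = "numeric"
))

setValidity("MclResult", function(object) {
    all_nodes <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(all_nodes))
        return("clusters must be disjoint")
    TRUE
})
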