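#' Default regulator family grammars
#'
#' Ordered domain architectures for the labeled regulator families emitted by
#' the simulator. The SARP grammars follow the published subclass definitions
#' (small: BTAD + Trans_reg_C only; medium adds NB-ARC; large adds TPR_10 or
#' TPR_12; SARP-LAL adds AAA_16 or AAA_22 instead of TPRs). The background
#' grammar draws common single-domain regulators.
#'
#' @return named list of lists of character vectors.
#' @export
defaultFamilyGrammars <- function() {
    list(
        smallSARP = list(c("BTAD", "Trans_reg_C")),
        mediumSARP = list(c("BTAD", "NB-ARC", "Trans_reg_C")),
        largeSARP = list(c("BTAD", "NB-ARC", "TPR_10", "Trans_reg_C"),
                         c("BTAD", "NB-ARC", "TPR_12", "Trans_reg_C")),
        sarpLAL = list(c("BTAD", "NB-ARC", "AAA_16", "Trans_reg_C"),
                       c("BTAD", "NB-ARC", "AAA_22", "Trans_reg_C")),
        luxR_AAA16 = list(c("AAA_16", "GerE")),
        pasLuxRsmall = list(c("PAS", "GerE")),
        pasLuxRlarge = list(c("PAS", "AAA_16", "GerE")),
        tetR_C33 = list(c("TetR_C_33")),
        xre = list(c("HTH_3")),
        background = list(c("TetR_N"), c("HATPase_c"), c("Response_reg"),
                          c("GerE"), c("TetR_N", "HATPase_c"))
    )
}

#' Construct a simulation configuration
#'
#' Defaults encode the study conditions being emulated: 20 kb BGC regions,
#' a 0.146 background probability of a gene lying inside a BGC interval, and
#' an 8 Mb single-contig genome carrying 25 regions, typical of a
#' streptomycete chromosome.
#'
#' @param nGenomes number of genomes.
#' @param genesPerGenome background genes per genome.
#' @param contigLength contig length in nt.
#' @param nBgcPerGenome BGC regions per genome.
#' @param bgcLength region length in nt.
#' @param familyGrammars named list of architecture lists
#'   (see \code{\link{defaultFamilyGrammars}}).
#' @param familyCounts named integer, labeled genes per family per genome.
#' @param familyPIn named numeric, per-family in-BGC probability.
#' @param backgroundPIn in-BGC probability for background genes.
#' @param bgcClassWeights named class sampling weights.
#' @param mibigSimilarityLaw function(n) -> n similarities in [0, 100].
#' @param decoyRate probability of adding one overlapping decoy hit per gene.
#' @param hiddenPerGenome planted hidden-cluster windows per genome.
#' @param hiddenBiosynGenes biosynthetic genes around each hidden beacon.
#' @param seed integer seed.
#' @return a validated \code{\linkS4class{SimConfig}}.
#' @examples
#' cfg <- simConfig(nGenomes = 2, genesPerGenome = 50, seed = 1)
#' @export
simConfig <- function(nGenomes = 5L,
                      genesPerGenome = 200L,
                      contigLength = 8000000L,
                      nBgcPerGenome = 25L,
                      bgcLength = 20000L,
                      familyGrammars = defaultFamilyGrammars(),
                      familyCounts = c(smallSARP = 20L, mediumSARP = 10L,
                                       pasLuxRlarge = 5L, tetR_C33 = 10L),
                      familyPIn = c(smallSARP = 0.82, mediumSARP = 0.576,
                                    pasLuxRlarge = 0.976, tetR_C33 = 0.478),
                      backgroundPIn = 0.146,
                      bgcClassWeights = c(NRPS = 0.2, T1PKS = 0.15,
                                          PKS = 0.15, RiPP = 0.15,
                                          terpene = 0.15, saccharide = 0.05,
                                          other = 0.15),
                      mibigSimilarityLaw = function(n) runif(n, 0, 100),
                      decoyRate = 0.3,
                      hiddenPerGenome = 0L,
                      hiddenBiosynGenes = 8L,
                      seed = 1L) {
    fc <- setNames(as.integer(familyCounts), names(familyCounts))
    new("SimConfig",
        nGenomes = as.integer(nGenomes),
        genesPerGenome = as.integer(genesPerGenome),
        contigLength = as.integer(contigLength),
        nBgcPerGenome = as.integer(nBgcPerGenome),
        bgcLength = as.integer(bgcLength),
        familyGrammars = familyGrammars,
        familyCounts = fc,
        familyPIn = familyPIn,
        backgroundPIn = backgroundPIn,
        bgcClassWeights = bgcClassWeights,
        mibigSimilarityLaw = mibigSimilarityLaw,
        decoyRate = decoyRate,
        hiddenPerGenome = as.integer(hiddenPerGenome),
        hiddenBiosynGenes = as.integer(hiddenBiosynGenes),
        seed = as.integer(seed))
}

emptyRegionTable <- function() {
    data.frame(region_id = character(), contig = character(),
               start = integer(), end = integer(),
               known_cluster_id = character(),
               known_similarity_pct = numeric(),
               stringsAsFactors = FALSE)
}

emptyCoreTable <- function() {
    data.frame(region_id = character(), gene_id = character(),
               class = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

#' Construct a BGC region set
#'
#' @param regions data.frame with region_id, contig, start, end,
#'   known_cluster_id, known_similarity_pct (0-based half-open coordinates).
#' @param classes named list region_id -> character vector of product classes.
#' @param coreGenes data.frame with region_id, gene_id, class, start, end.
#' @return a validated \code{\linkS4class{BgcRegionSet}}.
#' @export
bgcRegionSet <- function(regions = emptyRegionTable(),
                         classes = list(),
                         coreGenes = emptyCoreTable()) {
    regions <- as.data.frame(regions, stringsAsFactors = FALSE)
    coreGenes <- as.data.frame(coreGenes, stringsAsFactors = FALSE)
    new("BgcRegionSet", regions = regions, classes = classes,
        coreGenes = coreGenes)
}

#' Construct a co-occurrence network from node frequencies and edge counts
#'
#' Containment is computed as count divided by the smaller endpoint frequency
#' when not supplied.
#'
#' @param nodes named numeric of node frequencies.
#' @param edges data.frame with domain_a, domain_b, count and optionally
#'   containment.
#' @return a validated \code{\linkS4class{CoocNetwork}}.
#' @export
coocNetwork <- function(nodes = numeric(),
                        edges = data.frame(domain_a = character(),
                                           domain_b = character(),
                                           count = numeric())) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (nrow(edges)) {
        a <- pmin(edges$domain_a, edges$domain_b)
        b <- pmax(edges$domain_a, edges$domain_b)
        edges$domain_a <- a
        edges$domain_b <- b
        if (is.null(edges$containment))
            edges$containment <- edges$count /
                pmin(nodes[edges$domain_a], nodes[edges$domain_b])
        edges <- edges[order(edges$domain_a, edges$domain_b), , drop = FALSE]
        rownames(edges) <- NULL
    } else if (is.null(edges$containment)) {
        edges$containment <- numeric()
    }
    new("CoocNetwork", nodes = nodes, edges = edges)
}

#' Construct MCL parameters
#'
#' @param inflation inflation exponent (> 1); default 6.
#' @param expansionPower expansion matrix power; default 2.
#' @param pruneBelow pruning threshold; default 1e-8.
#' @param maxIter iteration cap; default 200.
#' @param tol convergence tolerance; default 1e-9.
#' @return a validated \code{\linkS4class{MclParams}}.
#' @export
mclParams <- function(inflation = 6, expansionPower = 2L,
                      pruneBelow = 1e-8, maxIter = 200L, tol = 1e-9) {
    new("MclParams", inflation = inflation,
        expansionPower = as.integer(expansionPower),
        pruneBelow = pruneBelow, maxIter = as.integer(maxIter), tol = tol)
}
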