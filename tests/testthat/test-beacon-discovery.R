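beaconFixture <- function(geneStarts, geneEnds, regionStarts, regionEnds,
                          contig = "c1") {
    g <- data.frame(gene_id = sprintf("g%03d", seq_along(geneStarts)),
                    protein_id = sprintf("p%03d", seq_along(geneStarts)),
                    contig = contig, start = as.integer(geneStarts),
                    end = as.integer(geneEnds), strand = "+",
                    family = "smallSARP", stringsAsFactors = FALSE)
    nr <- length(regionStarts)
    ids <- sprintf("r%02d", seq_len(nr))
    rs <- bgcRegionSet(data.frame(region_id = ids,
                                  contig = rep(contig, nr),
                                  start = as.integer(regionStarts),
                                  end = as.integer(regionEnds),
                                  known_cluster_id = rep(NA_character_, nr),
                                  known_similarity_pct = rep(NA_real_, nr),
                                  stringsAsFactors = FALSE),
                       setNames(as.list(rep("NRPS", length(ids))), ids),
                       emptyCore())
    cls <- data.frame(gene_id = g$gene_id, subclass = "SARP_small",
                      stringsAsFactors = FALSE)
    flags <- assignInBgc(g, rs)
    list(genes = g, regions = rs, cls = cls, flags = flags)
}
emptyCore <- function() {
    data.frame(region_id = character(), gene_id = character(),
               class = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

test_that("beacon selection applies the inclusive 20 kb gap threshold", {
    fx <- beaconFixture(c(29000, 30002), c(30000, 31000), 50001, 70001)
    b <- findBeaconGenes(fx$cls, fx$flags, fx$genes, fx$regions)
    # gap 20001 qualifies; gap 19001 does not
    expect_identical(b$gene_id, "g001")
    # exact boundary: gap exactly 20000 is kept
    fx2 <- beaconFixture(29000, 30000, 50000, 70000)
    expect_identical(nrow(findBeaconGenes(fx2$cls, fx2$flags, fx2$genes,
                                          fx2$regions)), 1L)
    fx3 <- beaconFixture(29000, 30001, 50000, 70000)
    expect_identical(nrow(findBeaconGenes(fx3$cls, fx3$flags, fx3$genes,
                                          fx3$regions)), 0L)
    # a contig without regions qualifies trivially
    fx4 <- beaconFixture(100, 1000, integer(), integer())
    expect_identical(nrow(findBeaconGenes(fx4$cls, fx4$flags, fx4$genes,
                                          fx4$regions)), 1L)
})

test_that("beacon gaps equal brute-force minimum over all regions", {
    set.seed(81)
    for (rep in 1:5) {
        rstart <- sort(sample(seq(0, 900000, 25000), 8))
        fxg <- sample(0:950000, 80)
        fx <- beaconFixture(fxg, fxg + 900, rstart, rstart + 20000)
        b <- findBeaconGenes(fx$cls, fx$flags, fx$genes, fx$regions)
        manual <- vapply(seq_len(nrow(fx$genes)), function(i)
            oracleMinGap(fx$genes$start[i], fx$genes$end[i],
                         regionTable(fx$regions)), 0)
        inb <- oracleInBgc(fx$genes, regionTable(fx$regions))
        expect_identical(sort(b$gene_id),
                         sort(fx$genes$gene_id[!inb & manual >= 20000]))
        # every beacon is out-of-BGC
        expect_true(all(!fx$flags$in_bgc[match(b$gene_id,
                                               fx$flags$gene_id)]))
    }
})

test_that("windows are midpoint-centered, clipped and gene-complete", {
    fx <- beaconFixture(c(49700, 40100, 60000, 39000),
                        c(50300, 41000, 60800, 40100),
                        integer(), integer())
    w <- extractWindow(fx$genes[1, ], fx$genes, contigLength = 100000L)
    expect_identical(w$start, 40000L)
    expect_identical(w$end, 60000L)
    expect_false(w$clipped)
    # genes intersecting by >= 1 nt are included, in genomic order
    expect_identical(w$genes[[1]], c("g004", "g002", "g001"))

    # clipping at the contig start is flagged
    fx2 <- beaconFixture(500, 1500, integer(), integer())
    w2 <- extractWindow(fx2$genes[1, ], fx2$genes, contigLength = 100000L)
    expect_true(w2$clipped)
    expect_identical(w2$start, 0L)

    # inclusion equals a brute-force intersection test
    set.seed(82)
    gs <- sample(0:99000, 120)
    fx3 <- beaconFixture(gs, gs + sample(200:2000, 120, replace = TRUE),
                         integer(), integer())
    w3 <- extractWindow(fx3$genes[1, ], fx3$genes, contigLength = 100000L)
    manual <- fx3$genes$gene_id[fx3$genes$start < w3$end &
                                fx3$genes$end > w3$start]
    expect_identical(sort(w3$genes[[1]]), sort(manual))
})

test_that("biosynthetic domain counting is a direct multiset tally", {
    fx <- beaconFixture(c(49000, 50500), c(50000, 51500),
                        integer(), integer())
    hits <- makeHits(c("p001", "p001", "p002", "p002"),
                     c("Condensation", "Condensation", "Methyltransf_12",
                       "TetR_N"),
                     c(10, 100, 10, 200), c(60, 150, 60, 260),
                     c(2, 2, 2, 2))
    w <- extractWindow(fx$genes[1, ], fx$genes, contigLength = 100000L)
    expect_identical(
        countBiosyntheticDomains(w, hits, fx$genes,
                                 c("Condensation", "Methyltransf_12")), 3L)
    expect_identical(countBiosyntheticDomains(w, hits, fx$genes,
                                              "p450"), 0L)
    expect_error(countBiosyntheticDomains(w, hits, fx$genes, character()),
                 "empty")
})

test_that("region similarity combines Jaccard and adjacency components", {
    expect_equal(regionSimilarity(c("A", "B", "C"), c("A", "B", "C")), 1)
    expect_equal(regionSimilarity(c("A", "B"), c("C", "D")), 0)
    expect_equal(regionSimilarity(character(), c("A")), 0)
    expect_equal(regionSimilarity(c("A", "B", "C"), c("B", "C", "D")),
                 0.5 * (2 / 4) + 0.5 * (1 / 3))
    # symmetry over random strings
    set.seed(83)
    for (rep in 1:20) {
        a <- sample(LETTERS[1:6], sample(1:8, 1), replace = TRUE)
        b <- sample(LETTERS[1:6], sample(1:8, 1), replace = TRUE)
        expect_equal(regionSimilarity(a, b), regionSimilarity(b, a))
        expect_gte(regionSimilarity(a, b), 0)
        expect_lte(regionSimilarity(a, b), 1)
        expect_equal(regionSimilarity(a, a), 1)
    }
})

makeRegions <- function(domainLists) {
    out <- data.frame(beacon_gene_id = sprintf("b%02d",
                                               seq_along(domainLists)),
                      stringsAsFactors = FALSE)
    out$domains <- domainLists
    out
}

test_that("region clustering is connected components over the cutoff graph", {
    # no pair above cutoff: all singletons
    r <- makeRegions(list(c("A", "B"), c("C", "D"), c("E", "F")))
    cl <- clusterRegions(r, cutoff = 0.3)
    expect_identical(cl$n_singletons, 3L)
    expect_identical(cl$n_clusters, 0L)
    # chain a-b, b-c joins transitively even when a-c is weak
    r2 <- makeRegions(list(c("A", "B"), c("A", "B", "C"), c("B", "C")))
    cl2 <- clusterRegions(r2, cutoff = 0.3)
    expect_identical(cl2$n_clusters, 1L)
    expect_identical(cl2$n_singletons, 0L)
    expect_identical(length(unique(cl2$labels)), 1L)
    expect_lt(regionSimilarity(c("A", "B"), c("B", "C")), 0.3)

    # random instances match the union-find oracle
    set.seed(84)
    for (rep in 1:5) {
        n <- sample(4:10, 1)
        r3 <- makeRegions(lapply(seq_len(n), function(i)
            sample(LETTERS[1:5], sample(1:6, 1), replace = TRUE)))
        simMat <- matrix(0, n, n)
        for (i in 1:n) for (j in 1:n)
            simMat[i, j] <- regionSimilarity(r3$domains[[i]],
                                             r3$domains[[j]])
        cl3 <- clusterRegions(r3, cutoff = 0.4)
        oc <- oracleComponents(simMat, 0.4)
        expect_identical(partitionSignature(split(seq_len(n), cl3$labels)),
                         partitionSignature(split(seq_len(n), oc)))
    }
})

test_that("raising the cutoff never merges clusters", {
    set.seed(85)
    r <- makeRegions(lapply(1:12, function(i)
        sample(LETTERS[1:5], sample(1:6, 1), replace = TRUE)))
    counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(ct) {
        cl <- clusterRegions(r, cutoff = ct)
        cl$n_clusters + cl$n_singletons
    }, 0L)
    expect_true(all(diff(counts) >= 0))
})

test_that("direct-repeat scan reproduces the published pattern example", {
    seq <- generatePromoter("TTGCAGT", 10, 0, 1,
                            spacerSeq = "ACGTACGTAC")$seq
    hits <- findDirectRepeats(seq)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$unit, "TTGCAGT")
    expect_identical(hits$spacer, 10L)
    expect_identical(hits$first_start, 0L)
    expect_identical(hits$second_start, 17L)
    expect_identical(hits$strand, "+")
})

test_that("degenerate homopolymers hit at every offset", {
    polyA <- strrep("A", 30)
    hits <- findDirectRepeats(polyA, unitLen = 7, spacerMin = 0,
                              spacerMax = 0)
    expect_identical(nrow(hits), 30L - 14L + 1L)
    expect_error(findDirectRepeats(polyA, unitLen = 3), "unitLen")
    expect_error(findDirectRepeats("ACGU"), "A/C/G/T/N")
})

test_that("plus-strand scan equals the brute-force double loop", {
    set.seed(86)
    for (rep in 1:3) {
        seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                     collapse = "")
        got <- findDirectRepeats(seq, unitLen = 5, spacerMin = 0,
                                 spacerMax = 12, strands = "+")
        oracle <- oracleRepeats(seq, 5L, 0L, 12L)
        expect_identical(nrow(got), nrow(oracle))
        key <- function(d) sort(paste(d$first_start, d$second_start,
                                      d$spacer))
        expect_identical(key(got), key(oracle))
    }
})

test_that("N never matches and mismatch budget widens the scan", {
    expect_identical(nrow(findDirectRepeats("NNNNNNNNNNNNNNNNNNNN",
                                            spacerMin = 0, spacerMax = 3)),
                     0L)
    # one mismatch between the copies
    seq <- paste0("TTGCAGT", "ACGTACGTAC", "TTGCATT")
    expect_identical(nrow(findDirectRepeats(seq, spacerMin = 10,
                                            spacerMax = 10)), 0L)
    h <- findDirectRepeats(seq, spacerMin = 10, spacerMax = 10,
                           maxMismatch = 1)
    expect_identical(h$spacer, 10L)
})

test_that("reverse-strand hits map to forward coordinates", {
    # plant a repeat of the reverse-complement unit: scanning the minus
    # strand must find it at the same forward site
    core <- paste0("ACTGCAA", "GGGGGGGGGG", "ACTGCAA")
    seq <- paste0("CCCCC", core, "CCCCC")
    hits <- findDirectRepeats(seq, spacerMin = 10, spacerMax = 10)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$first_start, 5L)
    expect_identical(hits$second_start, 22L)
    expect_identical(hits$strand, "+")
})
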