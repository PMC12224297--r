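simpleRegionSet <- function(starts, ends, contig = "c1",
                            classes = NULL, cores = emptyCoreTable(),
                            sim = rep(NA_real_, length(starts)),
                            cid = rep(NA_character_, length(starts))) {
    ids <- sprintf("r%02d", seq_along(starts))
    if (is.null(classes)) classes <- setNames(as.list(rep("NRPS",
                                                          length(ids))), ids)
    else names(classes) <- ids
    bgcRegionSet(data.frame(region_id = ids, contig = contig,
                            start = as.integer(starts),
                            end = as.integer(ends),
                            known_cluster_id = cid,
                            known_similarity_pct = sim,
                            stringsAsFactors = FALSE),
                 classes, cores)
}

simpleGenes <- function(starts, ends, contig = "c1") {
    n <- length(starts)
    data.frame(gene_id = sprintf("g%03d", seq_len(n)),
               protein_id = sprintf("p%03d", seq_len(n)),
               contig = contig, start = as.integer(starts),
               end = as.integer(ends), strand = "+", family = "x",
               stringsAsFactors = FALSE)
}

test_that("in-BGC membership is full containment", {
    rs <- simpleRegionSet(0, 20000)
    g <- simpleGenes(c(100, 19990, 25000), c(400, 20010, 25600))
    f <- assignInBgc(g, rs)
    expect_identical(f$in_bgc, c(TRUE, FALSE, FALSE))
    expect_identical(f$region_id, c("r01", NA, NA))
    expect_error(assignInBgc(g, rs, knownContigs = "other"),
                 "unknown contig")
})

test_that("containment flags equal the brute-force all-pairs test", {
    set.seed(71)
    for (rep in 1:4) {
        starts <- sort(sample(seq(0, 90000, 100), 12)) * 10
        rs <- simpleRegionSet(starts, starts + sample(2000:9000, 12,
                                                      replace = TRUE))
        gs <- sample(0:995000, 500)
        g <- simpleGenes(gs, gs + sample(200:3000, 500, replace = TRUE))
        f <- assignInBgc(g, rs)
        expect_identical(f$in_bgc, oracleInBgc(g, regionTable(rs)))
    }
})

test_that("in/out ratios reproduce the worked example and the arithmetic", {
    cls <- data.frame(gene_id = sprintf("g%04d", 1:1053),
                      subclass = "SARP_small", stringsAsFactors = FALSE)
    flags <- data.frame(gene_id = cls$gene_id,
                        in_bgc = c(rep(TRUE, 864), rep(FALSE, 189)),
                        region_id = NA_character_, stringsAsFactors = FALSE)
    rec <- inBgcRatio(cls, flags)
    expect_identical(rec$n_in, 864L)
    expect_identical(rec$n_out, 189L)
    expect_identical(formatInRatioPct(rec$in_ratio), 82.1)
    expect_identical(formatInRatioPct(1 - rec$in_ratio), 17.9)

    flags$in_bgc <- rep(FALSE, 1053)
    expect_identical(formatInRatioPct(inBgcRatio(cls, flags)$in_ratio), 0)

    set.seed(72)
    for (rep in 1:10) {
        n <- sample(5:200, 1)
        inb <- runif(n) < runif(1)
        cls2 <- data.frame(gene_id = sprintf("g%03d", 1:n),
                           subclass = sample(c("a", "b"), n, TRUE),
                           stringsAsFactors = FALSE)
        fl <- data.frame(gene_id = cls2$gene_id, in_bgc = inb,
                         region_id = NA_character_)
        rec2 <- inBgcRatio(cls2, fl)
        for (k in seq_len(nrow(rec2))) {
            sel <- cls2$subclass == rec2$subclass[k]
            expect_identical(rec2$n_in[k] + rec2$n_out[k],
                             as.integer(sum(sel)))
            expect_equal(rec2$in_ratio[k], mean(inb[sel]))
        }
    }
})

test_that("nearest core gene decides the class, with gap-0 and fallback", {
    cores <- data.frame(region_id = "r01",
                        gene_id = c("c1", "c2"),
                        class = c("NRPS", "T1PKS"),
                        start = c(1000L, 8000L), end = c(4000L, 12000L),
                        stringsAsFactors = FALSE)
    rs <- simpleRegionSet(0, 20000, cores = cores)
    expect_identical(nearestCoreClass(5000, 5600, "r01", rs)$class, "NRPS")
    inside <- nearestCoreClass(9000, 9500, "r01", rs)
    expect_identical(inside$class, "T1PKS")
    expect_false(inside$fallback)
    fb <- nearestCoreClass(5000, 5600, "r01", simpleRegionSet(0, 20000))
    expect_true(fb$fallback)
    expect_identical(fb$class, "NRPS")
})

test_that("nearest-core search equals brute-force min-gap with tie-breaks", {
    set.seed(73)
    for (rep in 1:30) {
        nc <- sample(1:5, 1)
        cs <- sample(seq(0, 16000, 50), nc)
        cores <- data.frame(region_id = "r01",
                            gene_id = sprintf("c%d", seq_len(nc)),
                            class = sprintf("CL%d", seq_len(nc)),
                            start = as.integer(cs),
                            end = as.integer(cs + sample(500:3000, nc,
                                                         replace = TRUE)),
                            stringsAsFactors = FALSE)
        cores$end <- pmin(cores$end, 20000L)
        rs <- simpleRegionSet(0, 20000, cores = cores)
        gs <- sample(0:19000, 1); ge <- gs + sample(200:900, 1)
        got <- nearestCoreClass(gs, ge, "r01", rs)$class
        gaps <- vapply(seq_len(nc), function(i)
            max(0, cores$start[i] - ge, gs - cores$end[i]), 0)
        best <- which(gaps == min(gaps))
        if (length(best) > 1) best <- best[which.min(cores$start[best])]
        expect_identical(got, cores$class[best])
    }
})

test_that("class distribution counts sum to n_in", {
    sim <- generateGenomes(simConfig(nGenomes = 2, genesPerGenome = 60,
                                     seed = 74))
    g <- geneTable(sim)
    flags <- assignInBgc(g, regionSet(sim))
    arch <- buildArchitectures(hitTable(sim), geneMap = g)
    cls <- classifyRegulators(arch)
    rec <- inBgcRatio(cls, flags)
    cd <- classDistribution(cls, flags, g, regionSet(sim))
    for (k in seq_len(nrow(rec))) {
        expect_identical(sum(cd$count[cd$subclass == rec$subclass[k]]),
                         rec$n_in[k])
    }
})

test_that("function associations respect both MIBiG-style filters", {
    # 12 genes in a region at 49.9% similarity: all unknown
    rs <- simpleRegionSet(c(0, 30000), c(20000, 50000),
                          sim = c(49.9, 80), cid = c("K1", "K2"))
    act <- data.frame(cluster_id = c("K1", "K2"),
                      activity = c("antibacterial", "antifungal"),
                      stringsAsFactors = FALSE)
    gs <- c(rep(1000, 12), rep(31000, 12))
    g <- simpleGenes(gs, gs + 500)
    flags <- assignInBgc(g, rs)
    cls <- data.frame(gene_id = g$gene_id, subclass = "S",
                      stringsAsFactors = FALSE)
    fa <- functionalAssociation(cls, flags, rs, act)
    expect_identical(fa$distribution$activity, "antifungal")
    expect_identical(fa$distribution$count, 12L)
    expect_equal(fa$unknown$unknown_function_fraction, 0.5)

    # pair observed 9 times is dropped; 10 times is kept
    gs9 <- rep(31000, 9)
    g9 <- simpleGenes(gs9, gs9 + 500)
    f9 <- assignInBgc(g9, rs)
    c9 <- data.frame(gene_id = g9$gene_id, subclass = "S",
                     stringsAsFactors = FALSE)
    expect_identical(nrow(functionalAssociation(c9, f9, rs,
                                                act)$distribution), 0L)
    gs10 <- rep(31000, 10)
    g10 <- simpleGenes(gs10, gs10 + 500)
    f10 <- assignInBgc(g10, rs)
    c10 <- data.frame(gene_id = g10$gene_id, subclass = "S",
                      stringsAsFactors = FALSE)
    expect_identical(functionalAssociation(c10, f10, rs,
                                           act)$distribution$count, 10L)
})

test_that("function associations equal a direct tally on synthetic cohorts", {
    sim <- generateGenomes(simConfig(nGenomes = 2, genesPerGenome = 80,
                                     seed = 75))
    g <- geneTable(sim)
    rs <- regionSet(sim)
    act <- syntheticActivityTable(rs, seed = 75)
    flags <- assignInBgc(g, rs)
    cls <- data.frame(gene_id = g$gene_id, subclass = g$family,
                      stringsAsFactors = FALSE)
    fa <- functionalAssociation(cls, flags, rs, act, 50, 3)
    # independent tally under both filters
    r <- regionTable(rs)
    tally <- list()
    for (k in which(flags$in_bgc)) {
        ri <- match(flags$region_id[k], r$region_id)
        if (is.na(r$known_similarity_pct[ri]) ||
            r$known_similarity_pct[ri] < 50) next
        a <- act$activity[act$cluster_id == r$known_cluster_id[ri]]
        if (!length(a)) next
        key <- paste(cls$subclass[k], a, sep = "|")
        tally[[key]] <- (tally[[key]] %||% 0L) + 1L
    }
    tally <- unlist(tally)
    tally <- tally[tally >= 3]
    got <- stats::setNames(fa$distribution$count,
                           paste(fa$distribution$subclass,
                                 fa$distribution$activity, sep = "|"))
    expect_identical(length(got), length(tally))
    expect_equal(got[names(tally)], tally)
})

test_that("filter monotonicity: counts never grow as thresholds rise", {
    sim <- generateGenomes(simConfig(nGenomes = 2, genesPerGenome = 80,
                                     seed = 76))
    g <- geneTable(sim)
    rs <- regionSet(sim)
    act <- syntheticActivityTable(rs, seed = 76)
    flags <- assignInBgc(g, rs)
    cls <- data.frame(gene_id = g$gene_id, subclass = g$family,
                      stringsAsFactors = FALSE)
    totals <- function(minSim, minCount)
        sum(functionalAssociation(cls, flags, rs, act, minSim,
                                  minCount)$distribution$count)
    for (ms in c(0, 25, 50, 75, 100))
        expect_gte(totals(ms, 1), totals(ms + 0.1, 1))
    prev <- Inf
    for (mc in c(1, 2, 5, 10, 50)) {
        cur <- totals(0, mc)
        expect_lte(cur, prev)
        prev <- cur
    }
})

test_that("upper-quartile selection uses inclusive linear interpolation", {
    rec <- function(ratios, n = 100)
        data.frame(subclass = sprintf("s%02d", seq_along(ratios)),
                   n_in = as.integer(round(ratios * n)),
                   n_out = as.integer(n - round(ratios * n)),
                   in_ratio = ratios, stringsAsFactors = FALSE)
    expect_identical(selectUpperQuartile(rec(c(0.1, 0.2, 0.3, 0.9))), "s04")
    expect_identical(selectUpperQuartile(rec(rep(0.4, 5))),
                     sprintf("s%02d", 1:5))
    expect_error(selectUpperQuartile(rec(c(0.1, 0.9))), "fewer than 4")
    # small subclasses are excluded before the percentile
    r <- rec(c(0.1, 0.2, 0.3, 0.4, 0.99))
    r$n_in[5] <- 1L; r$n_out[5] <- 0L
    expect_identical(selectUpperQuartile(r, minGenes = 20),
                     c("s04"))
    # matches a direct percentile computation on random records
    set.seed(77)
    for (rep in 1:10) {
        ratios <- round(runif(16), 3)
        got <- selectUpperQuartile(rec(ratios))
        h <- (16 - 1) * 0.75 + 1
        srt <- sort(ratios)
        thr <- srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] -
                                                 srt[floor(h)])
        expect_identical(got, sprintf("s%02d", which(ratios >= thr)))
    }
})
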