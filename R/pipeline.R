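#' Pipeline run configuration
#'
#' Collects all stage parameters with defaults equal to the study's stated
#' values where one exists: co-occurrence edge filter 100, MCL inflation 6,
#' MIBiG-style similarity threshold 50 percent, association count threshold
#' 10, beacon exclusion distance 20 kb, candidate window 20 kb.
#'
#' @param simConfig a \code{\linkS4class{SimConfig}} to simulate inputs, or
#'   NULL when \code{inputDir} is given.
#' @param inputDir directory of fixture files written by
#'   \code{\link{simulateFixtures}}, or NULL.
#' @param outDir output directory (created if needed).
#' @param minCoocCount co-occurrence edge filter.
#' @param inflation MCL inflation.
#' @param minSimilarityPct known-cluster similarity threshold (percent).
#' @param minAssocCount association count threshold.
#' @param minDistanceNt beacon exclusion distance (nt).
#' @param windowNt candidate window size (nt).
#' @param similarityCutoff region-similarity clustering cutoff.
#' @param quartileMinGenes minimum subclass size for quartile selection.
#' @param targetSubclass subclass used as beacon (default SARP_small).
#' @param rulesetPath subclass ruleset YAML.
#' @param keywordsPath regulatory keyword list.
#' @param pfamMetaPath PFAM metadata TSV.
#' @param seed master seed; every stage derives its own substream.
#' @return a named list of class parameters (validated by
#'   \code{\link{runPipeline}}).
#' @export
runConfig <- function(simConfig = NULL, inputDir = NULL,
                      outDir = tempfile("regbeacons_run_"),
                      minCoocCount = 100L, inflation = 6,
                      minSimilarityPct = 50, minAssocCount = 10L,
                      minDistanceNt = 20000L, windowNt = 20000L,
                      similarityCutoff = 0.3, quartileMinGenes = 20L,
                      targetSubclass = "SARP_small",
                      rulesetPath = extdataPath("subclass_rules.yaml"),
                      keywordsPath = extdataPath("regulatory_keywords.txt"),
                      pfamMetaPath = extdataPath("pfam_meta_synthetic.tsv"),
                      seed = 1L) {
    list(simConfig = simConfig, inputDir = inputDir, outDir = outDir,
         minCoocCount = as.integer(minCoocCount), inflation = inflation,
         minSimilarityPct = minSimilarityPct,
         minAssocCount = as.integer(minAssocCount),
         minDistanceNt = as.integer(minDistanceNt),
         windowNt = as.integer(windowNt),
         similarityCutoff = similarityCutoff,
         quartileMinGenes = as.integer(quartileMinGenes),
         targetSubclass = targetSubclass,
         rulesetPath = rulesetPath, keywordsPath = keywordsPath,
         pfamMetaPath = pfamMetaPath, seed = as.integer(seed))
}

#' Synthetic bioactivity table for a region set
#'
#' Assigns, deterministically given the seed, zero or one activity label to
#' each distinct known-cluster id (about 70 percent receive one), emulating
#' a repository of characterized clusters with partial functional
#' annotation.
#'
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @param seed integer seed.
#' @param labels candidate activity labels.
#' @param pAnnotated probability a cluster id carries an annotation.
#' @return data.frame: cluster_id, activity.
#' @export
syntheticActivityTable <- function(regionSet, seed = 1L,
                                   labels = c("antibacterial", "antifungal",
                                              "cytotoxic", "siderophore"),
                                   pAnnotated = 0.7) {
    ids <- unique(stats::na.omit(regionTable(regionSet)$known_cluster_id))
    withSeed(stageSeed(seed, "activity"), {
        keep <- ids[runif(length(ids)) < pAnnotated]
        data.frame(cluster_id = keep,
                   activity = if (length(keep))
                       sample(labels, length(keep), replace = TRUE)
                   else character(),
                   stringsAsFactors = FALSE)
    })
}

#' Write a simulated cohort to a fixture directory
#'
#' One gene table (GFF3-like TSV), one domtblout file and one region file
#' (TSV and JSON) per genome, plus contig lengths, the ground truth, and a
#' synthetic activity table.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param dir target directory.
#' @return invisibly, the \code{\linkS4class{GenomeSim}} that was written.
#' @export
simulateFixtures <- function(config, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sim <- generateGenomes(config)
    genes <- geneTable(sim); hits <- hitTable(sim)
    rset <- regionSet(sim); r <- regionTable(rset)
    for (ctg in names(contigLengths(sim))) {
        writeGeneTable(genes[genes$contig == ctg, , drop = FALSE],
                       file.path(dir, paste0("genes_", ctg, ".tsv")))
        pid <- genes$protein_id[genes$contig == ctg]
        writeDomtblout(hits[hits$protein_id %in% pid, , drop = FALSE],
                       file.path(dir, paste0("hits_", ctg, ".domtblout")))
        ri <- r$region_id[r$contig == ctg]
        sub <- bgcRegionSet(r[r$contig == ctg, , drop = FALSE],
                            regionClasses(rset)[ri],
                            coreGenes(rset)[
                                coreGenes(rset)$region_id %in% ri, ,
                                drop = FALSE])
        writeBgcRegionsTsv(sub, file.path(dir,
                                          paste0("regions_", ctg, ".tsv")))
        writeBgcRegionsJson(sub, file.path(dir,
                                           paste0("regions_", ctg, ".json")))
    }
    utils::write.table(
        data.frame(contig = names(contigLengths(sim)),
                   length = unname(contigLengths(sim))),
        file.path(dir, "contigs.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(simTruth(sim), file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(syntheticActivityTable(rset, config@seed),
                       file.path(dir, "activities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(hiddenWindows(sim)))
        utils::write.table(hiddenWindows(sim),
                           file.path(dir, "hidden_windows.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(sim)
}

readFixtureDir <- function(dir, pfamMeta) {
    contigs <- utils::read.delim(file.path(dir, "contigs.tsv"),
                                 stringsAsFactors = FALSE)
    cl <- setNames(as.integer(contigs$length), contigs$contig)
    genes <- do.call(rbind, c(lapply(names(cl), function(ctg)
        readGeneTable(file.path(dir, paste0("genes_", ctg, ".tsv")))),
        list(emptyGeneTable())))
    hits <- do.call(rbind, c(lapply(names(cl), function(ctg)
        readDomtblout(file.path(dir, paste0("hits_", ctg, ".domtblout")),
                      pfamMeta)), list(emptyHitTable())))
    rsets <- lapply(names(cl), function(ctg)
        readBgcRegionsJson(file.path(dir, paste0("regions_", ctg, ".json"))))
    regions <- do.call(rbind, c(lapply(rsets, regionTable),
                                list(emptyRegionTable())))
    classes <- do.call(c, c(lapply(rsets, regionClasses), list(list())))
    cores <- do.call(rbind, c(lapply(rsets, coreGenes),
                              list(emptyCoreTable())))
    rownames(genes) <- rownames(hits) <- rownames(regions) <- NULL
    rownames(cores) <- NULL
    actPath <- file.path(dir, "activities.tsv")
    activity <- if (file.exists(actPath))
        utils::read.delim(actPath, stringsAsFactors = FALSE)
    else data.frame(cluster_id = character(), activity = character(),
                    stringsAsFactors = FALSE)
    list(genes = genes, hits = hits,
         regions = bgcRegionSet(regions, classes, cores),
         contigs = cl, activity = activity)
}

#' Run the full regulator-beacon pipeline
#'
#' Executes the stages in order: domain-hit selection and architecture
#' building, co-occurrence network with MCL subclustering, subclass
#' classification, in/out-BGC association with class and function
#' distributions and upper-quartile selection, and beacon-based candidate
#' discovery with similarity clustering. All stage outputs are written under
#' \code{config$outDir}; a deterministic run manifest (config hash, input
#' checksums, per-stage record counts, collected warnings) is returned and
#' written as JSON.
#'
#' @param config list from \code{\link{runConfig}}.
#' @return the manifest, invisibly; stage outputs are files under outDir.
#' @export
runPipeline <- function(config) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    pfamMeta <- readPfamMeta(config$pfamMetaPath)
    warningsLog <- character()
    note <- function(...) warningsLog <<- c(warningsLog, paste0(...))

    inputChecksums <- character()
    if (!is.null(config$inputDir)) {
        files <- sort(list.files(config$inputDir, full.names = TRUE))
        inputChecksums <- tools::md5sum(files)
        names(inputChecksums) <- basename(files)
        inp <- readFixtureDir(config$inputDir, pfamMeta)
    } else {
        if (is.null(config$simConfig))
            stop("config needs either simConfig or inputDir", call. = FALSE)
        sim <- generateGenomes(config$simConfig, pfamMeta)
        inp <- list(genes = geneTable(sim), hits = hitTable(sim),
                    regions = regionSet(sim), contigs = contigLengths(sim),
                    activity = syntheticActivityTable(
                        regionSet(sim), config$simConfig@seed))
    }
    genes <- inp$genes; hits <- inp$hits; rset <- inp$regions

    # stage: domain hits -> regulatory architectures
    keywords <- readKeywords(config$keywordsPath)
    regAcc <- selectRegulatoryPfams(pfamMeta, keywords)
    regProt <- unique(hits$protein_id[hits$pfam_accession %in% regAcc])
    arch <- buildArchitectures(
        hits[hits$protein_id %in% regProt, , drop = FALSE],
        geneMap = genes)
    writeClassification(
        data.frame(protein_id = arch$protein_id, gene_id = arch$gene_id,
                   architecture = vapply(arch$architecture, paste, "",
                                         collapse = ";"),
                   stringsAsFactors = FALSE),
        file.path(config$outDir, "architectures.tsv"))

    # stage: co-occurrence network + MCL
    net <- buildCoocNetwork(arch, config$minCoocCount)
    mcl <- NULL
    if (length(networkNodes(net))) {
        mcl <- withCallingHandlers(
            mclCluster(net, mclParams(inflation = config$inflation)),
            warning = function(w) {
                note("network: ", conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        if (!mcl@converged) note("network: MCL not converged")
    }
    exportNetwork(net, mcl,
                  graphmlPath = file.path(config$outDir, "network.graphml"),
                  tsvPath = file.path(config$outDir, "network_edges.tsv"))

    # stage: classification
    rules <- loadRuleset(config$rulesetPath)
    classification <- classifyRegulators(arch, rules)
    writeClassification(classification,
                        file.path(config$outDir, "classification.tsv"))

    # stage: association
    flags <- assignInBgc(genes, rset, knownContigs = names(inp$contigs))
    records <- inBgcRatio(classification, flags)
    cdist <- classDistribution(classification, flags, genes, rset)
    fa <- functionalAssociation(classification, flags, rset, inp$activity,
                                config$minSimilarityPct,
                                config$minAssocCount)
    selected <- tryCatch(
        selectUpperQuartile(records, config$quartileMinGenes),
        error = function(e) { note("associate: ", conditionMessage(e))
                              character() })
    records$in_pct <- formatInRatioPct(records$in_ratio)
    utils::write.table(records,
                       file.path(config$outDir, "association_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cdist,
                       file.path(config$outDir, "class_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(records = records, selected_upper_quartile = selected,
             function_distribution = fa$distribution,
             unknown_function = fa$unknown),
        file.path(config$outDir, "association_summary.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")

    # stage: beacon discovery
    beacons <- findBeaconGenes(classification, flags, genes, rset,
                               config$targetSubclass, config$minDistanceNt)
    cand <- extractWindows(beacons, genes, arch, inp$contigs,
                           config$windowNt, config$targetSubclass)
    if (any(cand$clipped))
        note("discover: ", sum(cand$clipped), " window(s) clipped")
    cand$biosyn_count <- vapply(seq_len(nrow(cand)), function(k)
        countBiosyntheticDomains(cand[k, , drop = FALSE], hits, genes),
        0L)
    cl <- clusterRegions(cand, config$similarityCutoff)
    cand$cluster_id <- if (nrow(cand)) cl$labels else integer()
    writeCandidateRegions(cand,
                          file.path(config$outDir, "candidate_regions.tsv"))

    cfgForHash <- config[setdiff(names(config), c("outDir", "inputDir"))]
    manifest <- list(
        config_hash = objectHash(cfgForHash),
        input_checksums = as.list(inputChecksums),
        counts = list(
            genes = nrow(genes), domain_hits = nrow(hits),
            regulators = nrow(arch),
            network_nodes = length(networkNodes(net)),
            network_edges = nrow(networkEdges(net)),
            network_clusters = if (is.null(mcl)) 0L
                               else length(mclClusters(mcl)),
            association_records = nrow(records),
            selected_subclasses = length(selected),
            beacons = nrow(beacons), candidates = nrow(cand),
            candidate_clusters = cl$n_clusters,
            candidate_singletons = cl$n_singletons),
        selected_upper_quartile = selected,
        warnings = warningsLog)
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
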