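#' Path to a packaged data file
#' @param file file name under inst/extdata.
#' @return absolute path.
#' @keywords internal
extdataPath <- function(file) {
    p <- system.file("extdata", file, package = "regBeacons")
    if (!nzchar(p)) stop("packaged file not found: ", file, call. = FALSE)
    p
}

#' Default biosynthesis-associated PFAM names
#'
#' Reads the shipped editable list of hallmark secondary-metabolism domains.
#' @return character vector of PFAM domain names.
#' @export
defaultBiosyntheticPfams <- function() {
    x <- readLines(extdataPath("biosynthetic_pfams.txt"))
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
}

emptyGeneTable <- function() {
    data.frame(gene_id = character(), protein_id = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), family = character(),
               stringsAsFactors = FALSE)
}

emptyHitTable <- function() {
    data.frame(protein_id = character(), pfam_accession = character(),
               pfam_name = character(), start_aa = integer(),
               end_aa = integer(), bitscore = numeric(),
               normalized_bitscore = numeric(), stringsAsFactors = FALSE)
}

emptyTruthTable <- function() {
    data.frame(gene_id = character(), family = character(),
               in_bgc = logical(), region_id = character(),
               stringsAsFactors = FALSE)
}

emptyHiddenTable <- function() {
    data.frame(contig = character(), start = integer(), end = integer(),
               beacon_gene_id = character(), stringsAsFactors = FALSE)
}

# Place n disjoint intervals of length len on [0, total) with >= 1 nt gap.
placeDisjoint <- function(n, len, total) {
    if (n == 0L) return(integer())
    free <- total - n * len - (n - 1L)
    offs <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
    offs + (seq_len(n) - 1L) * (len + 1L)
}

# Sample a start so [start, start+len) is fully inside [rs, re)
sampleInside <- function(rs, re, len) {
    rs + sample.int(re - rs - len + 1L, 1L) - 1L
}

# Sample a start on [0, total-len] such that the gene is NOT fully contained
# in any of the regions (straddling a boundary counts as outside).
sampleOutside <- function(len, total, rstart, rend) {
    repeat {
        s <- sample.int(total - len + 1L, 1L) - 1L
        if (!length(rstart) || !any(s >= rstart & (s + len) <= rend))
            return(s)
    }
}

#' Generate synthetic genomes with known ground truth
#'
#' Emits, for each genome, a single-contig gene table, a domain-hit table, a
#' set of disjoint BGC regions with product classes, core genes and
#' known-cluster similarities, and a ground-truth table. Genes of a labeled
#' family fall fully inside a BGC region with the family's configured
#' probability; background genes use the genomic background probability
#' (default 0.146). Each gene's domain hits follow one architecture sampled
#' from its family grammar; with probability \code{decoyRate} a decoy hit is
#' added that overlaps a true hit by at least one residue and has a strictly
#' lower normalized bitscore than every hit it overlaps, so that overlap
#' resolution recovers the true architecture exactly.
#'
#' When \code{hiddenPerGenome > 0}, additional "hidden cluster" windows are
#' planted in inter-region gaps: a small-SARP-like beacon gene at least 20 kb
#' from every region boundary, surrounded by genes carrying
#' biosynthesis-associated domains within 10 kb. These emulate true clusters
#' missed by a rule-based predictor.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param pfamMeta PFAM metadata data.frame (accession, name, ga,
#'   description); defaults to the packaged synthetic table.
#' @return a \code{\linkS4class{GenomeSim}}.
#' @examples
#' sim <- generateGenomes(simConfig(nGenomes = 1, genesPerGenome = 20,
#'                                  seed = 42))
#' head(geneTable(sim))
#' @export
generateGenomes <- function(config, pfamMeta = readPfamMeta()) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    needGram <- names(config@familyCounts)
    if (config@genesPerGenome > 0L) needGram <- c(needGram, "background")
    missGram <- setdiff(needGram, names(config@familyGrammars))
    if (length(missGram))
        stop("familyGrammars missing for counted family: ",
             paste(missGram, collapse = ", "), call. = FALSE)
    grammarDomains <- unique(unlist(config@familyGrammars, use.names = FALSE))
    unknown <- setdiff(grammarDomains, pfamMeta$name)
    if (length(unknown))
        stop("grammar domain(s) missing from PFAM metadata: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    ga <- setNames(pfamMeta$ga, pfamMeta$name)
    acc <- setNames(pfamMeta$accession, pfamMeta$name)
    biosyn <- intersect(defaultBiosyntheticPfams(), pfamMeta$name)

    withSeed(stageSeed(config@seed, "genome"), {
        genesL <- list(); hitsL <- list(); truthL <- list()
        regionsL <- list(); coresL <- list(); classesL <- list()
        hiddenL <- list()
        contigs <- setNames(rep(config@contigLength, config@nGenomes),
                            sprintf("ctg%03d", seq_len(config@nGenomes)))

        for (g in seq_len(config@nGenomes)) {
            contig <- names(contigs)[g]
            nB <- config@nBgcPerGenome
            L <- config@bgcLength
            rstart <- placeDisjoint(nB, L, config@contigLength)
            rend <- rstart + L
            rid <- sprintf("%s_r%03d", contig, seq_len(nB))
            rclass <- if (nB) sample(names(config@bgcClassWeights), nB,
                                     replace = TRUE,
                                     prob = config@bgcClassWeights)
                      else character()
            sim <- pmin(pmax(config@mibigSimilarityLaw(nB), 0), 100)
            kid <- if (nB) sprintf("BGC%07d", sample.int(9999999L, nB))
                   else character()
            regionsL[[g]] <- data.frame(
                region_id = rid, contig = contig,
                start = as.integer(rstart), end = as.integer(rend),
                known_cluster_id = kid, known_similarity_pct = as.numeric(sim),
                stringsAsFactors = FALSE)
            classesL[[g]] <- setNames(as.list(rclass), rid)

            # core genes: 1-3 per region, class matching the region
            cores <- lapply(seq_len(nB), function(i) {
                nc <- sample(1:3, 1L)
                cl <- sample(1000:4000, nc, replace = TRUE)
                cs <- vapply(cl, function(l)
                    sampleInside(rstart[i], rend[i], l), 0L)
                data.frame(region_id = rid[i],
                           gene_id = sprintf("%s_core%d", rid[i], seq_len(nc)),
                           class = rclass[i],
                           start = as.integer(cs),
                           end = as.integer(cs + cl),
                           stringsAsFactors = FALSE)
            })
            coresL[[g]] <- if (nB) do.call(rbind, cores) else emptyCoreTable()

            # gene cohort: labeled families then background
            fams <- c(rep(names(config@familyCounts), config@familyCounts),
                      rep("background", config@genesPerGenome))
            nGene <- length(fams)
            geneIdx <- 0L
            rows <- vector("list", nGene)
            truths <- vector("list", nGene)
            hitRows <- vector("list", nGene)

            emitGene <- function(fam, s, glen, inb, regid, idx) {
                gid <- sprintf("%s_g%05d", contig, idx)
                pid <- sprintf("%s_p%05d", contig, idx)
                row <- data.frame(gene_id = gid, protein_id = pid,
                                  contig = contig, start = as.integer(s),
                                  end = as.integer(s + glen),
                                  strand = sample(c("+", "-"), 1L),
                                  family = fam, stringsAsFactors = FALSE)
                tr <- data.frame(gene_id = gid, family = fam, in_bgc = inb,
                                 region_id = if (inb) regid else NA_character_,
                                 stringsAsFactors = FALSE)
                list(row = row, truth = tr, pid = pid)
            }

            makeHits <- function(pid, arch) {
                n <- length(arch)
                starts <- integer(n); ends <- integer(n)
                cursor <- sample(5:30, 1L)
                for (k in seq_len(n)) {
                    len <- sample(40:200, 1L)
                    starts[k] <- cursor
                    ends[k] <- cursor + len - 1L
                    cursor <- ends[k] + sample(5:30, 1L)
                }
                norm <- runif(n, 1.1, 3.5)
                hits <- data.frame(
                    protein_id = pid, pfam_accession = unname(acc[arch]),
                    pfam_name = arch, start_aa = starts, end_aa = ends,
                    bitscore = unname(ga[arch]) * norm,
                    normalized_bitscore = norm, stringsAsFactors = FALSE)
                if (runif(1) < config@decoyRate && n >= 1L) {
                    k <- sample.int(n, 1L)
                    dname <- sample(setdiff(pfamMeta$name, arch), 1L)
                    ds <- sample(starts[k]:ends[k], 1L)
                    de <- ds + sample(40:150, 1L) - 1L
                    ovl <- which(starts <= de & ends >= ds)
                    dnorm <- min(norm[ovl]) * runif(1, 0.3, 0.9)
                    hits <- rbind(hits, data.frame(
                        protein_id = pid, pfam_accession = unname(acc[dname]),
                        pfam_name = dname, start_aa = ds, end_aa = de,
                        bitscore = unname(ga[dname]) * dnorm,
                        normalized_bitscore = dnorm, stringsAsFactors = FALSE))
                }
                hits
            }

            for (i in seq_along(fams)) {
                fam <- fams[i]
                p <- if (fam %in% names(config@familyPIn))
                    config@familyPIn[[fam]] else config@backgroundPIn
                glen <- sample(seq(300L, 2400L, 3L), 1L)
                inb <- nB > 0L && runif(1) < p
                if (inb) {
                    ri <- sample.int(nB, 1L)
                    s <- sampleInside(rstart[ri], rend[ri], glen)
                    regid <- rid[ri]
                } else {
                    s <- sampleOutside(glen, config@contigLength, rstart, rend)
                    regid <- NA_character_
                }
                geneIdx <- geneIdx + 1L
                eg <- emitGene(fam, s, glen, inb, regid, geneIdx)
                rows[[i]] <- eg$row
                truths[[i]] <- eg$truth
                gram <- config@familyGrammars[[fam]]
                arch <- gram[[sample.int(length(gram), 1L)]]
                hitRows[[i]] <- makeHits(eg$pid, arch)
            }

            # planted hidden windows in inter-region gaps
            if (config@hiddenPerGenome > 0L) {
                margin <- 20000L
                span <- 22000L
                gapStart <- c(0L, rend + 1L)
                gapEnd <- c(rstart - 1L, config@contigLength)
                ok <- which((gapEnd - gapStart) >= (2L * margin + span))
                if (length(ok) < config@hiddenPerGenome)
                    stop("not enough inter-region space to plant ",
                         config@hiddenPerGenome, " hidden window(s)",
                         call. = FALSE)
                picked <- ok[sample.int(length(ok), config@hiddenPerGenome)]
                extraRows <- list(); extraTruth <- list(); extraHits <- list()
                hid <- vector("list", length(picked))
                for (h in seq_along(picked)) {
                    gs <- gapStart[picked[h]]; ge <- gapEnd[picked[h]]
                    lo <- gs + margin + span %/% 2L
                    hi <- ge - margin - span %/% 2L
                    center <- lo + sample.int(hi - lo + 1L, 1L) - 1L
                    blen <- 900L
                    bstart <- center - blen %/% 2L
                    geneIdx <- geneIdx + 1L
                    eg <- emitGene("smallSARP", bstart, blen, FALSE,
                                   NA_character_, geneIdx)
                    extraRows[[length(extraRows) + 1L]] <- eg$row
                    extraTruth[[length(extraTruth) + 1L]] <- eg$truth
                    gram <- config@familyGrammars[["smallSARP"]]
                    if (is.null(gram)) gram <- list(c("BTAD", "Trans_reg_C"))
                    extraHits[[length(extraHits) + 1L]] <-
                        makeHits(eg$pid, gram[[1L]])
                    hid[[h]] <- data.frame(
                        contig = contig,
                        start = as.integer(center - span %/% 2L),
                        end = as.integer(center + span %/% 2L),
                        beacon_gene_id = eg$row$gene_id,
                        stringsAsFactors = FALSE)
                    for (b in seq_len(config@hiddenBiosynGenes)) {
                        off <- sample(c(-9000:-1200, 1200:9000), 1L)
                        glen2 <- sample(600:1800, 1L)
                        geneIdx <- geneIdx + 1L
                        eg2 <- emitGene("biosyn", center + off, glen2, FALSE,
                                        NA_character_, geneIdx)
                        extraRows[[length(extraRows) + 1L]] <- eg2$row
                        extraTruth[[length(extraTruth) + 1L]] <- eg2$truth
                        nbd <- sample(1:2, 1L)
                        extraHits[[length(extraHits) + 1L]] <-
                            makeHits(eg2$pid, sample(biosyn, nbd))
                    }
                }
                rows <- c(rows, extraRows)
                truths <- c(truths, extraTruth)
                hitRows <- c(hitRows, extraHits)
                hiddenL[[g]] <- do.call(rbind, hid)
            }

            genesL[[g]] <- if (length(rows)) do.call(rbind, rows)
                           else emptyGeneTable()
            truthL[[g]] <- if (length(truths)) do.call(rbind, truths)
                           else emptyTruthTable()
            hitsL[[g]] <- if (length(hitRows)) do.call(rbind, hitRows)
                          else emptyHitTable()
        }

        genes <- do.call(rbind, c(genesL, list(emptyGeneTable())))
        hits <- do.call(rbind, c(hitsL, list(emptyHitTable())))
        truth <- do.call(rbind, c(truthL, list(emptyTruthTable())))
        regions <- do.call(rbind, c(regionsL, list(emptyRegionTable())))
        cores <- do.call(rbind, c(coresL, list(emptyCoreTable())))
        hidden <- do.call(rbind, c(hiddenL, list(emptyHiddenTable())))
        rownames(genes) <- rownames(hits) <- rownames(truth) <- NULL
        rownames(regions) <- rownames(cores) <- rownames(hidden) <- NULL
        rset <- bgcRegionSet(regions, do.call(c, c(classesL, list(list()))),
                             cores)
        new("GenomeSim", genes = genes, hits = hits, regions = rset,
            hidden = hidden, truth = truth, contigs = contigs,
            config = config)
    })
}

randomDna <- function(n) {
    if (n == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 0-based start positions of exact (possibly overlapping) copies of unit
occurrenceStarts <- function(seq, unit) {
    if (nchar(seq) < nchar(unit)) return(integer())
    Biostrings::start(
        Biostrings::matchPattern(unit, Biostrings::DNAString(seq))) - 1L
}

#' Generate a promoter sequence with a planted direct repeat
#'
#' Builds \code{flank + unit + spacer-nt + unit + flank}, the spaced
#' direct-repeat layout bound by SARP-family regulators (the published pattern
#' is TTGCAGT-N10-TTGCAGT). Random flanks and spacer are rejection-sampled so
#' the final sequence contains no additional exact copy of the unit: an
#' exhaustive scan finds exactly one spaced repeat.
#'
#' @param unit repeat unit over A/C/G/T.
#' @param spacer number of random nucleotides between the two copies.
#' @param flank number of random nucleotides on each side.
#' @param seed integer seed.
#' @param spacerSeq optional fixed spacer sequence (length must equal
#'   \code{spacer}); still checked for absence of extra unit copies.
#' @return list with \code{seq} (character), and \code{truth} (list with
#'   \code{unit}, \code{spacer}, \code{first_start}, \code{second_start};
#'   0-based).
#' @examples
#' generatePromoter("TTGCAGT", spacer = 10, flank = 0, seed = 1,
#'                  spacerSeq = "ACGTACGTAC")$seq
#' @export
generatePromoter <- function(unit, spacer, flank = 50L, seed = 1L,
                             spacerSeq = NULL) {
    if (!is.character(unit) || length(unit) != 1L || !nzchar(unit) ||
        grepl("[^ACGT]", unit))
        stop("unit must be a non-empty string over A/C/G/T", call. = FALSE)
    if (spacer < 0L) stop("spacer must be >= 0", call. = FALSE)
    if (!is.null(spacerSeq) && nchar(spacerSeq) != spacer)
        stop("spacerSeq length must equal spacer", call. = FALSE)
    u <- nchar(unit)
    flank <- as.integer(flank)
    spacer <- as.integer(spacer)
    planted <- c(flank, flank + u + spacer)
    # random stretches of the construct, 0-based half-open
    randIv <- rbind(c(0L, flank),
                    c(flank + u, flank + u + spacer),
                    c(flank + 2L * u + spacer, 2L * flank + 2L * u + spacer))
    withSeed(stageSeed(seed, "promoter"), {
        attempts <- 0L
        repeat {
            attempts <- attempts + 1L
            if (attempts > 1000L)
                stop("could not build a promoter free of extra unit copies",
                     call. = FALSE)
            sp <- if (is.null(spacerSeq)) randomDna(spacer) else spacerSeq
            lf <- randomDna(flank)
            rf <- randomDna(flank)
            seq <- paste0(lf, unit, sp, unit, rf)
            occ <- occurrenceStarts(seq, unit)
            extra <- setdiff(occ, planted)
            # extra copies are tolerable only when forced by self-overlap of
            # the two planted copies (e.g. unit AA, sequence AAAA); any extra
            # copy touching a random stretch triggers resampling
            bad <- vapply(extra, function(s)
                any(randIv[, 2] > randIv[, 1] &
                    s < randIv[, 2] & (s + u) > randIv[, 1]), TRUE)
            if (!any(bad)) break
            if (!is.null(spacerSeq) && flank == 0L)
                stop("fixed spacer contains an extra copy of the unit",
                     call. = FALSE)
        }
        list(seq = seq,
             truth = list(unit = unit, spacer = as.integer(spacer),
                          first_start = as.integer(flank),
                          second_start = as.integer(flank + nchar(unit) +
                                                        spacer)))
    })
}
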