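#' Find beacon genes: out-of-BGC regulators far from every region
#'
#' Returns genes of the target subclass that are outside every BGC region
#' and whose interval lies at least \code{minDistanceNt} (interval gap,
#' inclusive threshold) from the nearest region boundary on the same contig.
#' Predicted region boundaries are approximate, so a regulator just beyond
#' an edge may still belong to that cluster; the default exclusion of one
#' approximate BGC length (20 kb) keeps only regulators plausibly marking
#' an undetected cluster. Contigs without regions qualify trivially.
#'
#' @param classification classification table.
#' @param flags table from \code{\link{assignInBgc}}.
#' @param genes gene table.
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @param subclass target subclass name (default "SARP_small").
#' @param minDistanceNt minimum gap to any region, nt (default 20000).
#' @return subset of the gene table (with a min_gap_nt column; Inf on
#'   contigs without regions).
#' @export
findBeaconGenes <- function(classification, flags, genes, regionSet,
                            subclass = "SARP_small",
                            minDistanceNt = 20000L) {
    r <- regionTable(regionSet)
    ids <- classification$gene_id[classification$subclass == subclass]
    fi <- match(ids, flags$gene_id)
    ids <- ids[!flags$in_bgc[fi]]
    gi <- match(ids, genes$gene_id)
    if (anyNA(gi))
        stop("classified gene(s) missing from the gene table", call. = FALSE)
    g <- genes[gi, , drop = FALSE]
    minGap <- vapply(seq_len(nrow(g)), function(k) {
        rr <- r[r$contig == g$contig[k], , drop = FALSE]
        if (!nrow(rr)) return(Inf)
        min(intervalGap(g$start[k], g$end[k], rr$start, rr$end))
    }, 0)
    g$min_gap_nt <- minGap
    out <- g[minGap >= minDistanceNt, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Extract a candidate window around a beacon gene
#'
#' The window of total length \code{windowNt} is centered on the beacon
#' gene's midpoint and clipped to contig bounds (clipping is flagged). Genes
#' intersecting the window by at least one nt are included in genomic order,
#' and the window's domain content is the concatenation of their
#' overlap-resolved architectures in gene order.
#'
#' @param beacon one-row gene table entry (the beacon gene).
#' @param genes full gene table.
#' @param architectures architecture table from
#'   \code{\link{buildArchitectures}} (used for the domain string; proteins
#'   without entries contribute nothing).
#' @param contigLength length of the beacon's contig.
#' @param windowNt total window size, nt (default 20000, one approximate
#'   BGC length).
#' @param subclass subclass label carried into the output.
#' @return one-row data.frame: beacon_gene_id, subclass, contig, start, end,
#'   clipped, n_genes, plus list columns genes and domains.
#' @export
extractWindow <- function(beacon, genes, architectures = NULL,
                          contigLength, windowNt = 20000L,
                          subclass = NA_character_) {
    mid <- (beacon$start + beacon$end) %/% 2L
    half <- as.integer(windowNt) %/% 2L
    ws <- mid - half
    we <- ws + as.integer(windowNt)
    clipped <- FALSE
    if (ws < 0L) { ws <- 0L; clipped <- TRUE }
    if (we > contigLength) { we <- as.integer(contigLength); clipped <- TRUE }
    gi <- which(genes$contig == beacon$contig &
                genes$start < we & genes$end > ws)
    gi <- gi[order(genes$start[gi], genes$gene_id[gi])]
    dom <- character()
    if (!is.null(architectures) && length(gi)) {
        ai <- match(genes$protein_id[gi], architectures$protein_id)
        dom <- unlist(architectures$architecture[ai[!is.na(ai)]],
                      use.names = FALSE)
        if (is.null(dom)) dom <- character()
    }
    out <- data.frame(beacon_gene_id = beacon$gene_id, subclass = subclass,
                      contig = beacon$contig, start = ws, end = we,
                      clipped = clipped, n_genes = length(gi),
                      stringsAsFactors = FALSE)
    out$genes <- list(genes$gene_id[gi])
    out$domains <- list(dom)
    out
}

#' Extract windows for every beacon gene
#'
#' @param beacons output of \code{\link{findBeaconGenes}}.
#' @param genes full gene table.
#' @param architectures architecture table.
#' @param contigLengths named integer of contig lengths.
#' @param windowNt total window size, nt.
#' @param subclass subclass label.
#' @return data.frame of candidate regions, one row per beacon.
#' @export
extractWindows <- function(beacons, genes, architectures, contigLengths,
                           windowNt = 20000L, subclass = NA_character_) {
    rows <- lapply(seq_len(nrow(beacons)), function(k)
        extractWindow(beacons[k, , drop = FALSE], genes, architectures,
                      contigLengths[[beacons$contig[k]]], windowNt,
                      subclass))
    if (!length(rows)) {
        out <- data.frame(beacon_gene_id = character(),
                          subclass = character(), contig = character(),
                          start = integer(), end = integer(),
                          clipped = logical(), n_genes = integer(),
                          stringsAsFactors = FALSE)
        out$genes <- list(); out$domains <- list()
        return(out)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Count biosynthesis-associated domain hits in a candidate window
#'
#' Counts, with multiplicity, the window genes' domain hits whose PFAM name
#' lies in the configured biosynthesis-associated set. Windows rich in such
#' domains are more likely to encode secondary rather than primary
#' metabolism.
#'
#' @param region one-row candidate region (from \code{\link{extractWindow}}).
#' @param hits domain-hit table.
#' @param genes gene table (to map gene ids to protein ids).
#' @param biosynPfams character vector of biosynthesis-associated PFAM
#'   names; must be non-empty.
#' @return integer count.
#' @export
countBiosyntheticDomains <- function(region, hits, genes,
                                     biosynPfams = defaultBiosyntheticPfams()) {
    if (!length(biosynPfams))
        stop("biosynthetic PFAM set is empty; configuration missing",
             call. = FALSE)
    gid <- region$genes[[1L]]
    pid <- genes$protein_id[match(gid, genes$gene_id)]
    sum(hits$protein_id %in% pid & hits$pfam_name %in% biosynPfams)
}

adjacentPairs <- function(s) {
    if (length(s) < 2L) return(character())
    unique(paste(s[-length(s)], s[-1L], sep = "\r"))
}

#' Similarity of two candidate regions
#'
#' Mean of (a) the Jaccard index of the two regions' domain sets and (b) an
#' adjacency index, the Jaccard index of their sets of adjacent ordered
#' domain pairs, weighted \code{wJ} and \code{wA} (defaults 0.5/0.5).
#' Symmetric; 1 on identical domain strings; 0 when either region has no
#' domain content or the contents are disjoint.
#'
#' @param a,b character vectors: the regions' ordered domain strings.
#' @param wJ,wA weights of the Jaccard and adjacency components.
#' @return similarity in [0, 1].
#' @export
regionSimilarity <- function(a, b, wJ = 0.5, wA = 0.5) {
    if (!length(a) || !length(b)) return(0)
    sa <- unique(a); sb <- unique(b)
    jac <- length(intersect(sa, sb)) / length(union(sa, sb))
    pa <- adjacentPairs(a); pb <- adjacentPairs(b)
    un <- union(pa, pb)
    adj <- if (length(un)) length(intersect(pa, pb)) / length(un) else
        # two single-domain regions: adjacency carries no information,
        # fall back to set agreement
        jac
    wJ * jac + wA * adj
}

#' Cluster candidate regions by similarity
#'
#' Builds a graph joining regions whose pairwise similarity is at least
#' \code{cutoff} and reports its connected components; size-1 components are
#' singletons.
#'
#' @param regions candidate-region table with a \code{domains} list column.
#' @param cutoff similarity threshold, inclusive (default 0.3).
#' @param wJ,wA weights passed to \code{\link{regionSimilarity}}.
#' @return list: \code{labels} (integer component id per region),
#'   \code{n_clusters} (components of size >= 2), \code{n_singletons}.
#' @export
clusterRegions <- function(regions, cutoff = 0.3, wJ = 0.5, wA = 0.5) {
    n <- nrow(regions)
    if (n == 0L)
        return(list(labels = integer(), n_clusters = 0L, n_singletons = 0L))
    edges <- matrix(integer(), nrow = 2L)
    if (n > 1L) {
        pairs <- utils::combn(n, 2L)
        sim <- apply(pairs, 2L, function(p)
            regionSimilarity(regions$domains[[p[1L]]],
                             regions$domains[[p[2L]]], wJ, wA))
        edges <- pairs[, sim >= cutoff, drop = FALSE]
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (ncol(edges)) g <- igraph::add_edges(g, as.vector(edges))
    comp <- igraph::components(g)
    sizes <- tabulate(comp$membership)
    list(labels = as.integer(comp$membership),
         n_clusters = sum(sizes >= 2L),
         n_singletons = sum(sizes == 1L))
}

#' Scan a sequence for spaced direct repeats
#'
#' Enumerates all position pairs (i, j = i + unitLen + s) with spacerMin <=
#' s <= spacerMax where the two unitLen-mers differ at no more than
#' \code{maxMismatch} positions; N never matches. Both strands are scanned;
#' reverse-strand hits are reported in forward coordinates, and a hit found
#' on both strands at the same site (always the case for exact direct
#' repeats, which are their own mirror) is reported once, on "+". The default
#' exact-match scan (maxMismatch 0) is the reproducible core of the
#' SARP-type TTGCAGT-N10-TTGCAGT binding pattern search.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param unitLen repeat unit length (>= 4; shorter motifs are
#'   uninformative).
#' @param spacerMin,spacerMax spacer range in nt (defaults 0 and 20).
#' @param maxMismatch mismatch budget per unit comparison (default 0).
#' @param strands scan "+", "-" or both (default both).
#' @return data.frame: unit, first_start, second_start (0-based, forward
#'   coordinates), spacer, strand.
#' @export
findDirectRepeats <- function(seq, unitLen = 7L, spacerMin = 0L,
                              spacerMax = 20L, maxMismatch = 0L,
                              strands = c("+", "-")) {
    if (unitLen < 4L)
        stop("unitLen must be >= 4 (uninformative motif)", call. = FALSE)
    if (grepl("[^ACGTN]", seq))
        stop("sequence must be over A/C/G/T/N", call. = FALSE)
    n <- nchar(seq)
    empty <- data.frame(unit = character(), first_start = integer(),
                        second_start = integer(), spacer = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    scanOne <- function(s) {
        x <- strsplit(s, "", fixed = TRUE)[[1]]
        valid <- x != "N"
        rows <- list()
        for (sp in spacerMin:spacerMax) {
            d <- unitLen + sp
            m <- n - d - unitLen + 1L
            if (m < 1L) next
            mism <- integer(m)
            for (k in 0:(unitLen - 1L)) {
                i1 <- seq_len(m) + k
                i2 <- i1 + d
                mism <- mism + as.integer(x[i1] != x[i2] |
                                          !valid[i1] | !valid[i2])
            }
            hit <- which(mism <= maxMismatch)
            for (i in hit)
                rows[[length(rows) + 1L]] <- data.frame(
                    unit = substr(s, i, i + unitLen - 1L),
                    first_start = i - 1L,
                    second_start = i - 1L + d,
                    spacer = sp, stringsAsFactors = FALSE)
        }
        if (!length(rows)) return(NULL)
        do.call(rbind, rows)
    }
    out <- list()
    if ("+" %in% strands) {
        fw <- scanOne(seq)
        if (!is.null(fw)) { fw$strand <- "+"; out <- c(out, list(fw)) }
    }
    if ("-" %in% strands) {
        rc <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(seq)))
        rv <- scanOne(rc)
        if (!is.null(rv)) {
            # map to forward coordinates: a reverse position p (0-based)
            # starts at n - p - unitLen on the forward strand; the pair is
            # reported with the smaller forward start first
            f1 <- n - rv$second_start - unitLen
            rv <- data.frame(unit = rv$unit, first_start = f1,
                             second_start = f1 + unitLen + rv$spacer,
                             spacer = rv$spacer, strand = "-",
                             stringsAsFactors = FALSE)
            out <- c(out, list(rv))
        }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    # an exact direct repeat is its own mirror on the other strand at the
    # same site; keep the forward-strand record when both were found
    key <- paste(res$first_start, res$second_start)
    dupMinus <- res$strand == "-" & key %in% key[res$strand == "+"]
    res <- res[!dupMinus, , drop = FALSE]
    res <- res[order(res$first_start, res$spacer, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Write candidate regions as TSV (plus the BED-like repeat-hit writer)
#'
#' @param regions candidate-region table.
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writeCandidateRegions <- function(regions, path) {
    flat <- regions
    flat$genes <- vapply(regions$genes, paste, "", collapse = ",")
    flat$domains <- vapply(regions$domains, paste, "", collapse = ",")
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write repeat hits as BED-like TSV
#'
#' Columns: contig, start, end (spanning both copies), unit, spacer, strand.
#'
#' @param hits data.frame from \code{\link{findDirectRepeats}}.
#' @param contig contig name recorded in the first column.
#' @param path output file.
#' @param unitLen unit length used in the scan.
#' @return invisibly, the path.
#' @export
writeRepeatHits <- function(hits, contig, path, unitLen = 7L) {
    out <- data.frame(contig = contig, start = hits$first_start,
                      end = hits$second_start + unitLen,
                      unit = hits$unit, spacer = hits$spacer,
                      strand = hits$strand, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
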