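#' Assign genes to containing BGC regions
#'
#' A gene is in-BGC iff its interval is fully contained in a region interval
#' on the same contig (a gene straddling a region boundary is outside; BGC
#' regions extend beyond their core genes by design, so containment is the
#' conservative membership rule). Containment is evaluated with IRanges
#' overlap queries per contig.
#'
#' @param genes gene table (0-based half-open coordinates).
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @param knownContigs optional character vector of valid contig names; genes
#'   on a contig outside this universe raise an error. By default any contig
#'   named in the gene or region tables is valid (a contig without regions is
#'   legitimate: all its genes are outside).
#' @return data.frame: gene_id, in_bgc (logical), region_id (NA when
#'   outside).
#' @export
assignInBgc <- function(genes, regionSet, knownContigs = NULL) {
    stopIfMissingCols(genes, c("gene_id", "contig", "start", "end"),
                      "gene table")
    r <- regionTable(regionSet)
    if (!is.null(knownContigs)) {
        bad <- setdiff(unique(genes$contig), knownContigs)
        if (length(bad))
            stop("gene(s) on unknown contig: ", paste(bad, collapse = ", "),
                 call. = FALSE)
    }
    out <- data.frame(gene_id = genes$gene_id,
                      in_bgc = rep(FALSE, nrow(genes)),
                      region_id = rep(NA_character_, nrow(genes)),
                      stringsAsFactors = FALSE)
    if (!nrow(genes) || !nrow(r)) return(out)
    for (ctg in intersect(unique(genes$contig), unique(r$contig))) {
        gi <- which(genes$contig == ctg)
        ri <- which(r$contig == ctg)
        q <- IRanges::IRanges(start = genes$start[gi] + 1L,
                              end = genes$end[gi])
        s <- IRanges::IRanges(start = r$start[ri] + 1L, end = r$end[ri])
        ov <- IRanges::findOverlaps(q, s, type = "within")
        # regions are disjoint, so at most one containing region per gene
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        first <- !duplicated(qh)
        out$in_bgc[gi[qh[first]]] <- TRUE
        out$region_id[gi[qh[first]]] <- r$region_id[ri[sh[first]]]
    }
    out
}

#' Per-subclass in/out-BGC association records
#'
#' Joins a classification with in/out flags and tallies, per subclass, the
#' number of genes inside and outside BGC regions and the in-BGC ratio
#' (unrounded; use \code{\link{formatInRatioPct}} for the one-decimal
#' half-up percentage used in reports).
#'
#' @param classification table from \code{\link{classifyRegulators}} (or any
#'   data.frame with gene_id and subclass).
#' @param flags table from \code{\link{assignInBgc}}.
#' @return data.frame: subclass, n_in, n_out, in_ratio, sorted by decreasing
#'   in_ratio.
#' @export
inBgcRatio <- function(classification, flags) {
    stopIfMissingCols(classification, c("gene_id", "subclass"),
                      "classification")
    if (nrow(classification) == 0L)
        return(data.frame(subclass = character(), n_in = integer(),
                          n_out = integer(), in_ratio = numeric(),
                          stringsAsFactors = FALSE))
    i <- match(classification$gene_id, flags$gene_id)
    if (anyNA(i))
        stop("every classified gene needs an in/out flag", call. = FALSE)
    inb <- flags$in_bgc[i]
    n_in <- tapply(inb, classification$subclass, sum)
    n_tot <- tapply(inb, classification$subclass, length)
    out <- data.frame(subclass = names(n_in),
                      n_in = as.integer(n_in),
                      n_out = as.integer(n_tot - n_in),
                      stringsAsFactors = FALSE)
    out$in_ratio <- out$n_in / (out$n_in + out$n_out)
    out <- out[order(-out$in_ratio, out$subclass), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Report an in-BGC ratio as a percentage, one decimal, half-up
#' @param ratio ratio in [0, 1].
#' @return numeric percentage rounded half-up to one decimal.
#' @export
formatInRatioPct <- function(ratio) {
    roundHalfUp(100 * ratio, 1L)
}

#' Class of the core gene nearest to an in-BGC regulator gene
#'
#' Among the containing region's core genes, returns the class of the core
#' minimizing the interval gap to the gene (0 when they overlap); ties are
#' broken by the smaller core start. A region without core genes falls back
#' to its first listed product class, flagged in the output.
#'
#' @param geneStart,geneEnd gene interval (0-based half-open).
#' @param regionId containing region id.
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @return list with \code{class} and \code{fallback} (logical).
#' @export
nearestCoreClass <- function(geneStart, geneEnd, regionId, regionSet) {
    cg <- coreGenes(regionSet)
    x <- cg[cg$region_id == regionId, , drop = FALSE]
    if (!nrow(x)) {
        cls <- regionClasses(regionSet)[[regionId]]
        if (is.null(cls) || !length(cls))
            stop("region ", regionId, " has neither cores nor classes",
                 call. = FALSE)
        return(list(class = cls[[1L]], fallback = TRUE))
    }
    gap <- intervalGap(geneStart, geneEnd, x$start, x$end)
    best <- which(gap == min(gap))
    if (length(best) > 1L) best <- best[which.min(x$start[best])]
    list(class = x$class[best], fallback = FALSE)
}

#' Per-subclass distribution of nearest-core-gene classes
#'
#' For every in-BGC gene of each subclass, the class of the nearest core
#' gene in its containing region is tallied; counts per subclass sum to the
#' subclass's n_in.
#'
#' @param classification classification table.
#' @param flags table from \code{\link{assignInBgc}}.
#' @param genes gene table.
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @return data.frame: subclass, class, count, n_fallback.
#' @export
classDistribution <- function(classification, flags, genes, regionSet) {
    i <- match(classification$gene_id, flags$gene_id)
    j <- match(classification$gene_id, genes$gene_id)
    rows <- list()
    for (k in seq_len(nrow(classification))) {
        if (!isTRUE(flags$in_bgc[i[k]])) next
        nc <- nearestCoreClass(genes$start[j[k]], genes$end[j[k]],
                               flags$region_id[i[k]], regionSet)
        rows[[length(rows) + 1L]] <- data.frame(
            subclass = classification$subclass[k], class = nc$class,
            fallback = nc$fallback, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(subclass = character(), class = character(),
                          count = integer(), n_fallback = integer(),
                          stringsAsFactors = FALSE))
    d <- do.call(rbind, rows)
    agg <- stats::aggregate(cbind(count = rep(1L, nrow(d)),
                                  n_fallback = as.integer(d$fallback)),
                            by = list(subclass = d$subclass, class = d$class),
                            FUN = sum)
    agg <- agg[order(agg$subclass, -agg$count, agg$class), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Function (bioactivity) associations under similarity and count filters
#'
#' A (subclass, activity) pair is counted only from in-BGC genes whose
#' containing region matches a known cluster at \code{minSimilarityPct}
#' percent similarity or better (inclusive); pairs observed fewer than
#' \code{minCount} times in total are removed. Genes whose region fails the
#' similarity filter (or has no known-cluster match, or a match without
#' activity annotation) count toward the subclass's unknown-function
#' fraction.
#'
#' @param classification classification table.
#' @param flags table from \code{\link{assignInBgc}}.
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @param activityTable data.frame (cluster_id, activity); a cluster may
#'   carry several activity rows.
#' @param minSimilarityPct similarity threshold, inclusive (default 50).
#' @param minCount minimum pair count, inclusive (default 10).
#' @return list with \code{distribution} (subclass, activity, count) and
#'   \code{unknown} (subclass, n_in, n_unknown, unknown_function_fraction).
#' @export
functionalAssociation <- function(classification, flags, regionSet,
                                  activityTable,
                                  minSimilarityPct = 50, minCount = 10L) {
    stopIfMissingCols(activityTable, c("cluster_id", "activity"),
                      "activity table")
    r <- regionTable(regionSet)
    i <- match(classification$gene_id, flags$gene_id)
    inb <- which(flags$in_bgc[i])
    pairRows <- list()
    unknownTally <- list()
    bump <- function(tab, key, field) {
        if (is.null(tab[[key]]))
            tab[[key]] <- c(n_in = 0L, n_unknown = 0L)
        tab[[key]][field] <- tab[[key]][field] + 1L
        tab
    }
    for (k in inb) {
        sub <- classification$subclass[k]
        unknownTally <- bump(unknownTally, sub, "n_in")
        rid <- flags$region_id[i[k]]
        ri <- match(rid, r$region_id)
        sim <- r$known_similarity_pct[ri]
        cid <- r$known_cluster_id[ri]
        acts <- if (!is.na(sim) && sim >= minSimilarityPct && !is.na(cid))
            activityTable$activity[activityTable$cluster_id == cid]
        else character()
        if (!length(acts)) {
            unknownTally <- bump(unknownTally, sub, "n_unknown")
        } else {
            for (a in acts)
                pairRows[[length(pairRows) + 1L]] <- c(sub, a)
        }
    }
    if (length(pairRows)) {
        m <- do.call(rbind, pairRows)
        key <- paste(m[, 1L], m[, 2L], sep = "\r")
        tab <- table(key)
        tab <- tab[tab >= minCount]
        ab <- strsplit(names(tab), "\r", fixed = TRUE)
        dist <- data.frame(
            subclass = vapply(ab, `[`, "", 1L),
            activity = vapply(ab, `[`, "", 2L),
            count = as.integer(tab), stringsAsFactors = FALSE)
        dist <- dist[order(dist$subclass, -dist$count, dist$activity), ,
                     drop = FALSE]
        rownames(dist) <- NULL
    } else {
        dist <- data.frame(subclass = character(), activity = character(),
                           count = integer(), stringsAsFactors = FALSE)
    }
    unk <- do.call(rbind, c(lapply(names(unknownTally), function(s)
        data.frame(subclass = s,
                   n_in = unknownTally[[s]][["n_in"]],
                   n_unknown = unknownTally[[s]][["n_unknown"]],
                   stringsAsFactors = FALSE)),
        list(data.frame(subclass = character(), n_in = integer(),
                        n_unknown = integer(), stringsAsFactors = FALSE))))
    unk$unknown_function_fraction <- ifelse(unk$n_in > 0,
                                            unk$n_unknown / unk$n_in, NA_real_)
    rownames(unk) <- NULL
    list(distribution = dist, unknown = unk)
}

#' Select subclasses in the upper quartile of in-BGC association
#'
#' Subclasses with fewer than \code{minGenes} genes are excluded first; the
#' 75th percentile of the remaining in-ratios is computed with linear
#' interpolation (inclusive), and subclasses at or above it are returned.
#'
#' @param records data.frame from \code{\link{inBgcRatio}}.
#' @param minGenes minimum subclass size before the percentile is computed
#'   (default 20).
#' @return character vector of selected subclass names.
#' @export
selectUpperQuartile <- function(records, minGenes = 20L) {
    keep <- records[(records$n_in + records$n_out) >= minGenes, ,
                    drop = FALSE]
    if (nrow(keep) < 4L)
        stop("fewer than 4 eligible subclasses; select manually",
             call. = FALSE)
    thr <- stats::quantile(keep$in_ratio, 0.75, type = 7, names = FALSE)
    sort(keep$subclass[keep$in_ratio >= thr])
}
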