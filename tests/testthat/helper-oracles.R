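# Independent oracles and small fixture builders shared across test files.

# quick domain-hit table
makeHits <- function(protein_id, pfam_name, start_aa, end_aa, norm,
                     pfam_accession = pfam_name) {
    data.frame(protein_id = protein_id, pfam_accession = pfam_accession,
               pfam_name = pfam_name, start_aa = as.integer(start_aa),
               end_aa = as.integer(end_aa), bitscore = norm * 20,
               normalized_bitscore = norm, stringsAsFactors = FALSE)
}

# quick architecture table from a list of domain sets
makeProteins <- function(domainSets, ids = sprintf("p%03d",
                                                   seq_along(domainSets))) {
    out <- data.frame(protein_id = ids, gene_id = ids,
                      stringsAsFactors = FALSE)
    out$architecture <- domainSets
    out$domain_set <- lapply(domainSets, function(s) sort(unique(s)))
    out
}

# Exhaustive oracle for overlap resolution: enumerate every subset of hits,
# keep the pairwise non-overlapping ones, and return the subset whose
# greedy-rank sequence (by -normalized score, start, accession) is
# lexicographically smallest, extensions preferred over prefixes.
oracleResolve <- function(hits) {
    n <- nrow(hits)
    ord <- order(-hits$normalized_bitscore, hits$start_aa,
                 hits$pfam_accession)
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    feasible <- function(idx) {
        if (length(idx) < 2L) return(TRUE)
        for (a in seq_along(idx)) for (b in seq_along(idx)) {
            if (a < b) {
                i <- idx[a]; j <- idx[b]
                if (hits$start_aa[i] <= hits$end_aa[j] &&
                    hits$end_aa[i] >= hits$start_aa[j]) return(FALSE)
            }
        }
        TRUE
    }
    best <- NULL
    bestSeq <- NULL
    pad <- n + 1L
    for (mask in 0:(2^n - 1L)) {
        idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
        if (!feasible(idx)) next
        s <- c(sort(rk[idx]), rep(pad, n - length(idx)))
        if (is.null(bestSeq)) {
            best <- idx; bestSeq <- s
        } else {
            d <- which(s != bestSeq)
            if (length(d) && s[d[1L]] < bestSeq[d[1L]]) {
                best <- idx; bestSeq <- s
            }
        }
    }
    out <- hits[best, , drop = FALSE]
    out <- out[order(out$start_aa), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# brute-force co-occurrence tally over all proteins and unordered pairs
oracleCooccurrence <- function(domainSets) {
    counts <- list()
    freq <- list()
    for (s in domainSets) {
        s <- sort(unique(s))
        for (d in s) freq[[d]] <- (freq[[d]] %||% 0) + 1
        if (length(s) >= 2L)
            for (a in seq_len(length(s) - 1L))
                for (b in (a + 1L):length(s)) {
                    key <- paste(s[a], s[b], sep = "|")
                    counts[[key]] <- (counts[[key]] %||% 0) + 1
                }
    }
    list(freq = unlist(freq), counts = unlist(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force all-pairs containment test
oracleInBgc <- function(genes, regions) {
    vapply(seq_len(nrow(genes)), function(i) {
        any(regions$contig == genes$contig[i] &
            genes$start[i] >= regions$start &
            genes$end[i] <= regions$end)
    }, TRUE)
}

# brute-force min interval gap from a gene to a set of regions (same contig)
oracleMinGap <- function(gs, ge, regions) {
    if (!nrow(regions)) return(Inf)
    min(vapply(seq_len(nrow(regions)), function(i)
        max(0, regions$start[i] - ge, gs - regions$end[i]), 0))
}

# brute-force plus-strand spaced-repeat scan (double loop over i and spacer)
oracleRepeats <- function(seq, unitLen, spacerMin, spacerMax,
                          maxMismatch = 0L) {
    x <- strsplit(seq, "")[[1]]
    n <- length(x)
    rows <- list()
    for (i in seq_len(n)) for (s in spacerMin:spacerMax) {
        j <- i + unitLen + s
        if (j + unitLen - 1L > n) next
        a <- x[i:(i + unitLen - 1L)]
        b <- x[j:(j + unitLen - 1L)]
        mm <- sum(a != b | a == "N" | b == "N")
        if (mm <= maxMismatch)
            rows[[length(rows) + 1L]] <- data.frame(
                first_start = i - 1L, second_start = j - 1L, spacer = s,
                stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(first_start = integer(), second_start = integer(),
                          spacer = integer()))
    do.call(rbind, rows)
}

# union-find connected components over a similarity matrix and cutoff
oracleComponents <- function(simMat, cutoff) {
    n <- nrow(simMat)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j && simMat[i, j] >= cutoff) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) {
                m <- min(ri, rj)
                parent[ri] <- m
                parent[rj] <- m
            }
        }
    }
    vapply(seq_len(n), find, 1L)
}

# canonical form of a partition (list of sets) for label-free comparison
partitionSignature <- function(clusters) {
    sig <- sort(vapply(clusters, function(s) paste(sort(s), collapse = ","),
                       ""))
    paste(sig, collapse = ";")
}

# small random hit instance with guaranteed overlaps for oracle tests
randomHitInstance <- function(n) {
    start <- sample(1:80, n, replace = TRUE)
    len <- sample(5:40, n, replace = TRUE)
    makeHits("p1", sprintf("D%02d", seq_len(n)), start, start + len,
             round(runif(n, 0.5, 3), 3),
             sprintf("PF%05d", sample.int(99999, n)))
}

writeTempRuleset <- function(rules) {
    f <- tempfile(fileext = ".yaml")
    yaml::write_yaml(list(rules = rules), f)
    f
}
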