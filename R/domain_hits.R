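#' Parse a domtblout per-domain table
#'
#' Reads the whitespace-delimited per-domain output of a profile-HMM search
#' (23+ columns; target = protein, query = PFAM profile). Envelope
#' coordinates (columns 20-21) define the hit interval; the per-domain
#' bitscore (column 14) is normalized by the profile's gathering (GA)
#' threshold from the metadata table. Version suffixes on accessions
#' (PF00486.32) are stripped before lookup.
#'
#' @param path domtblout file; lines starting with '#' are comments.
#' @param pfamMeta PFAM metadata (accession, name, ga, description).
#' @return data.frame of domain hits: protein_id, pfam_accession, pfam_name,
#'   start_aa, end_aa, bitscore, normalized_bitscore.
#' @export
readDomtblout <- function(path, pfamMeta = readPfamMeta()) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    ga <- setNames(pfamMeta$ga, pfamMeta$accession)
    lines <- readLines(path)
    keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
    idx <- which(keep)
    if (!length(idx)) return(emptyHitTable())
    rows <- lapply(idx, function(i) {
        f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
        if (length(f) < 22L)
            stop("malformed domtblout row at line ", i, call. = FALSE)
        accRaw <- f[5]
        acc <- sub("\\.\\d+$", "", accRaw)
        if (!acc %in% names(ga))
            stop("unknown PFAM accession: ", accRaw, call. = FALSE)
        score <- as.numeric(f[14])
        if (is.na(score) || is.na(suppressWarnings(as.integer(f[20]))) ||
            is.na(suppressWarnings(as.integer(f[21]))))
            stop("malformed domtblout row at line ", i, call. = FALSE)
        data.frame(protein_id = f[1], pfam_accession = acc,
                   pfam_name = f[4],
                   start_aa = as.integer(f[20]), end_aa = as.integer(f[21]),
                   bitscore = score,
                   normalized_bitscore = score / ga[[acc]],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# normalize dashes (en/em -> hyphen), collapse whitespace, lowercase
normalizeKeywordText <- function(x) {
    x <- gsub("–|—", "-", x)
    x <- gsub("[[:space:]]+", " ", x)
    tolower(trimws(x))
}

#' Select regulatory PFAM profiles by description keywords
#'
#' An accession is selected when any keyword matches its description
#' case-insensitively as a substring, after normalizing en/em dashes to
#' hyphens and collapsing whitespace. A keyword carrying a parenthesized
#' abbreviation, such as "helix-turn-helix (HTH)", additionally matches via
#' the phrase without the parenthetical and via the bare abbreviation.
#'
#' @param pfamMeta PFAM metadata table.
#' @param keywords character vector of keywords (non-empty).
#' @return character vector of selected accessions.
#' @export
selectRegulatoryPfams <- function(pfamMeta, keywords) {
    if (length(keywords) == 0L || all(!nzchar(trimws(keywords))))
        stop("keywords must be non-empty", call. = FALSE)
    if (nrow(pfamMeta) == 0L) return(character())
    desc <- normalizeKeywordText(pfamMeta$description)
    pats <- unlist(lapply(keywords, function(k) {
        k <- normalizeKeywordText(k)
        out <- k
        if (grepl("\\(([^)]+)\\)", k)) {
            bare <- trimws(gsub("\\s*\\([^)]*\\)", "", k))
            abbr <- tolower(regmatches(k, regexec("\\(([^)]+)\\)", k))[[1]][2])
            out <- c(out, bare, abbr)
        }
        out
    }))
    pats <- unique(pats[nzchar(pats)])
    hit <- vapply(desc, function(d)
        any(vapply(pats, function(p) grepl(p, d, fixed = TRUE), TRUE)),
        TRUE, USE.NAMES = FALSE)
    pfamMeta$accession[hit]
}

#' Read a keyword list (one per line, '#' comments)
#' @param path keyword file; defaults to the packaged example list.
#' @return character vector of keywords.
#' @export
readKeywords <- function(path = extdataPath("regulatory_keywords.txt")) {
    x <- trimws(readLines(path, encoding = "UTF-8"))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Resolve overlapping domain hits within one protein
#'
#' Candidates are sorted by normalized bitscore descending (ties: lower
#' start, then lexicographic accession) and accepted greedily when they do
#' not overlap any already-accepted hit; overlap means the amino-acid
#' intervals share at least one position. The result is pairwise
#' non-overlapping and idempotent under re-resolution.
#'
#' @param hits data.frame of domain hits for a single protein.
#' @return the retained hits, ordered by start_aa.
#' @export
resolveOverlaps <- function(hits) {
    if (nrow(hits) <= 1L) {
        out <- hits[order(hits$start_aa), , drop = FALSE]
        rownames(out) <- NULL
        return(out)
    }
    if (length(unique(hits$protein_id)) > 1L)
        stop("hits must belong to a single protein", call. = FALSE)
    ord <- order(-hits$normalized_bitscore, hits$start_aa,
                 hits$pfam_accession)
    h <- hits[ord, , drop = FALSE]
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
        acc <- which(keep)
        keep[i] <- !length(acc) ||
            !any(h$start_aa[acc] <= h$end_aa[i] &
                 h$end_aa[acc] >= h$start_aa[i])
    }
    out <- h[keep, , drop = FALSE]
    out <- out[order(out$start_aa), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build per-protein domain architectures
#'
#' Resolves overlaps per protein and emits one record per protein that
#' retains at least one hit: the ordered architecture (domain names by
#' start coordinate, duplicates preserved) and the unordered domain set
#' (duplicates collapsed). Proteins without hits are not regulatory and are
#' not emitted.
#'
#' @param hits domain-hit table (any number of proteins).
#' @param geneMap optional data.frame (protein_id, gene_id) to attach gene
#'   ids; unmapped proteins get NA.
#' @param resolve resolve overlaps first (default TRUE; set FALSE if hits
#'   are already resolved).
#' @return data.frame: protein_id, gene_id, architecture (list column),
#'   domain_set (list column, sorted unique).
#' @export
buildArchitectures <- function(hits, geneMap = NULL, resolve = TRUE) {
    if (nrow(hits) == 0L)
        return(data.frame(protein_id = character(), gene_id = character(),
                          architecture = I(list()), domain_set = I(list()),
                          stringsAsFactors = FALSE))
    parts <- split(hits, hits$protein_id)
    pid <- names(parts)
    archs <- lapply(parts, function(h) {
        r <- if (resolve) resolveOverlaps(h)
             else h[order(h$start_aa), , drop = FALSE]
        r$pfam_name
    })
    gid <- rep(NA_character_, length(pid))
    if (!is.null(geneMap))
        gid <- geneMap$gene_id[match(pid, geneMap$protein_id)]
    out <- data.frame(protein_id = pid, gene_id = gid,
                      stringsAsFactors = FALSE)
    out$architecture <- unname(archs)
    out$domain_set <- lapply(archs, function(a) sort(unique(a)))
    rownames(out) <- NULL
    out
}
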