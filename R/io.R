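#' Read a PFAM metadata table
#'
#' @param path TSV with columns accession, name, ga, description. Defaults to
#'   the packaged synthetic table (real accessions and names, synthetic
#'   gathering thresholds).
#' @return data.frame with those columns; ga numeric.
#' @export
readPfamMeta <- function(path = extdataPath("pfam_meta_synthetic.tsv")) {
    m <- utils::read.delim(path, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
    stopIfMissingCols(m, c("accession", "name", "ga", "description"),
                      "PFAM metadata")
    if (anyDuplicated(m$accession))
        stop("duplicate PFAM accession in metadata", call. = FALSE)
    if (any(!is.finite(m$ga) | m$ga <= 0))
        stop("GA thresholds must be positive", call. = FALSE)
    m
}

#' Write a gene table as GFF3-like TSV
#'
#' Seven columns: contig, source, type (CDS), start, end, strand, attributes
#' (gene_id, protein_id, family). Coordinates are converted from the internal
#' 0-based half-open convention to the 1-based inclusive GFF convention.
#'
#' @param genes gene table (see \code{\link{geneTable}}).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGeneTable <- function(genes, path) {
    stopIfMissingCols(genes, c("gene_id", "protein_id", "contig", "start",
                               "end", "strand", "family"), "gene table")
    out <- data.frame(
        contig = genes$contig, source = "regBeacons", type = "CDS",
        start = genes$start + 1L, end = genes$end, strand = genes$strand,
        attributes = sprintf("gene_id=%s;protein_id=%s;family=%s",
                             genes$gene_id, genes$protein_id, genes$family),
        stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

gffAttr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    sub(paste0("^;?", key, "="), "", m)
}

#' Read a GFF3-like TSV gene table
#'
#' Inverse of \code{\link{writeGeneTable}}; returns 0-based half-open
#' coordinates.
#'
#' @param path input file.
#' @return gene table data.frame.
#' @export
readGeneTable <- function(path) {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "#",
                             col.names = c("contig", "source", "type",
                                           "start", "end", "strand",
                                           "attributes"))
    if (nrow(raw) == 0L) return(emptyGeneTable())
    data.frame(gene_id = gffAttr(raw$attributes, "gene_id"),
               protein_id = gffAttr(raw$attributes, "protein_id"),
               contig = raw$contig,
               start = raw$start - 1L, end = raw$end,
               strand = raw$strand,
               family = gffAttr(raw$attributes, "family"),
               stringsAsFactors = FALSE)
}

#' Write domain hits in the domtblout column layout
#'
#' Emits the 23-column whitespace-delimited per-domain table of profile-HMM
#' searches (target = protein, query = PFAM profile, envelope coordinates in
#' columns 20-21, per-domain bitscore in column 14).
#'
#' @param hits domain-hit table (see \code{\link{hitTable}}).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDomtblout <- function(hits, path) {
    stopIfMissingCols(hits, c("protein_id", "pfam_accession", "pfam_name",
                              "start_aa", "end_aa", "bitscore"),
                      "domain-hit table")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "# --- full sequence ---- --- this domain ---- (per-domain table)",
        "#"), con)
    if (nrow(hits)) {
        lines <- sprintf(
            "%s - %d %s %s %d %.2g %.10g 0.0 %d %d %.2g %.2g %.10g 0.0 %d %d %d %d %d %d 0.90 -",
            hits$protein_id, 9999L, hits$pfam_name, hits$pfam_accession,
            999L, 1e-30, hits$bitscore, seq_len(nrow(hits)), nrow(hits),
            1e-30, 1e-30, hits$bitscore, 1L, 99L,
            hits$start_aa, hits$end_aa, hits$start_aa, hits$end_aa)
        writeLines(lines, con)
    }
    invisible(path)
}

#' Write BGC regions as TSV
#'
#' One row per region; product classes comma-separated; core genes packed as
#' \code{id:class:start:end} separated by commas.
#'
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeBgcRegionsTsv <- function(regionSet, path) {
    r <- regionTable(regionSet)
    cls <- regionClasses(regionSet)
    cg <- coreGenes(regionSet)
    packCores <- function(id) {
        x <- cg[cg$region_id == id, , drop = FALSE]
        if (!nrow(x)) return("")
        paste(sprintf("%s:%s:%d:%d", x$gene_id, x$class, x$start, x$end),
              collapse = ",")
    }
    out <- data.frame(
        region_id = r$region_id, contig = r$contig,
        start = r$start, end = r$end,
        classes = vapply(r$region_id, function(id)
            paste(cls[[id]], collapse = ","), ""),
        core_genes = vapply(r$region_id, packCores, ""),
        known_cluster_id = ifelse(is.na(r$known_cluster_id), "-",
                                  r$known_cluster_id),
        known_similarity_pct = r$known_similarity_pct,
        stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read BGC regions from TSV
#' @param path file written by \code{\link{writeBgcRegionsTsv}}.
#' @return a \code{\linkS4class{BgcRegionSet}}.
#' @export
readBgcRegionsTsv <- function(path) {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
    if (nrow(raw) == 0L) return(bgcRegionSet())
    classes <- setNames(strsplit(raw$classes, ",", fixed = TRUE),
                        raw$region_id)
    cores <- do.call(rbind, c(lapply(seq_len(nrow(raw)), function(i) {
        if (!nzchar(raw$core_genes[i])) return(emptyCoreTable())
        parts <- strsplit(strsplit(raw$core_genes[i], ",", fixed = TRUE)[[1]],
                          ":", fixed = TRUE)
        data.frame(region_id = raw$region_id[i],
                   gene_id = vapply(parts, `[`, "", 1L),
                   class = vapply(parts, `[`, "", 2L),
                   start = as.integer(vapply(parts, `[`, "", 3L)),
                   end = as.integer(vapply(parts, `[`, "", 4L)),
                   stringsAsFactors = FALSE)
    }), list(emptyCoreTable())))
    rownames(cores) <- NULL
    bgcRegionSet(
        data.frame(region_id = raw$region_id, contig = raw$contig,
                   start = raw$start, end = raw$end,
                   known_cluster_id = ifelse(raw$known_cluster_id == "-",
                                             NA_character_,
                                             raw$known_cluster_id),
                   known_similarity_pct = raw$known_similarity_pct,
                   stringsAsFactors = FALSE),
        classes, cores)
}

#' Write BGC regions as JSON
#'
#' Schema: an array of \code{{region_id, contig, start, end, classes[],
#' core_genes[{id, class, start, end}], known_cluster: {id, similarity_pct}}}.
#'
#' @param regionSet a \code{\linkS4class{BgcRegionSet}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeBgcRegionsJson <- function(regionSet, path) {
    r <- regionTable(regionSet)
    cls <- regionClasses(regionSet)
    cg <- coreGenes(regionSet)
    obj <- lapply(seq_len(nrow(r)), function(i) {
        id <- r$region_id[i]
        x <- cg[cg$region_id == id, , drop = FALSE]
        list(region_id = id, contig = r$contig[i],
             start = r$start[i], end = r$end[i],
             classes = as.list(cls[[id]]),
             core_genes = lapply(seq_len(nrow(x)), function(j)
                 list(id = x$gene_id[j], class = x$class[j],
                      start = x$start[j], end = x$end[j])),
             known_cluster = list(
                 id = if (is.na(r$known_cluster_id[i])) NULL
                      else r$known_cluster_id[i],
                 similarity_pct = if (is.na(r$known_similarity_pct[i])) NULL
                                  else r$known_similarity_pct[i]))
    })
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' Read BGC regions from JSON
#' @param path file written by \code{\link{writeBgcRegionsJson}}.
#' @return a \code{\linkS4class{BgcRegionSet}}.
#' @export
readBgcRegionsJson <- function(path) {
    obj <- jsonlite::read_json(path)
    if (!length(obj)) return(bgcRegionSet())
    reg <- do.call(rbind, lapply(obj, function(o) data.frame(
        region_id = o$region_id, contig = o$contig,
        start = as.integer(o$start), end = as.integer(o$end),
        known_cluster_id = if (is.null(o$known_cluster$id)) NA_character_
                           else o$known_cluster$id,
        known_similarity_pct =
            if (is.null(o$known_cluster$similarity_pct)) NA_real_
            else as.numeric(o$known_cluster$similarity_pct),
        stringsAsFactors = FALSE)))
    classes <- setNames(lapply(obj, function(o)
        unlist(o$classes, use.names = FALSE)), reg$region_id)
    cores <- do.call(rbind, c(lapply(obj, function(o) {
        if (!length(o$core_genes)) return(emptyCoreTable())
        do.call(rbind, lapply(o$core_genes, function(g) data.frame(
            region_id = o$region_id, gene_id = g$id, class = g$class,
            start = as.integer(g$start), end = as.integer(g$end),
            stringsAsFactors = FALSE)))
    }), list(emptyCoreTable())))
    rownames(reg) <- rownames(cores) <- NULL
    bgcRegionSet(reg, classes, cores)
}

#' Write promoter sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePromoters <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA file.
#' @return named character vector.
#' @export
readPromoters <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
}
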