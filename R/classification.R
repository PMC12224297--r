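ruleFields <- c("name", "family", "priority", "exact", "required_any",
                "forbidden", "note")

#' Load a subclass ruleset from YAML
#'
#' Each rule block declares name, family, priority (unique, lower evaluated
#' first), exact flag, required_any (a list of domain-name sets, at least one
#' of which must be fully present), and an optional forbidden set. The
#' shipped default ruleset covers the four SARP subclasses plus LuxR-, TetR-,
#' LitR-, XRE-, ScbR-, NrdR- and LexA-type rules.
#'
#' @param path YAML file; defaults to the packaged ruleset.
#' @return a validated list of rules, sorted by priority.
#' @export
loadRuleset <- function(path = extdataPath("subclass_rules.yaml")) {
    obj <- yaml::read_yaml(path)
    rules <- obj$rules
    if (is.null(rules)) return(list())
    for (i in seq_along(rules)) {
        r <- rules[[i]]
        bad <- setdiff(names(r), ruleFields)
        if (length(bad))
            stop("unknown rule field(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
        if (is.null(r$name) || is.null(r$priority) || is.null(r$required_any))
            stop("rule ", i, " must declare name, priority and required_any",
                 call. = FALSE)
        rules[[i]]$exact <- isTRUE(r$exact)
        rules[[i]]$forbidden <- as.character(unlist(r$forbidden))
        rules[[i]]$required_any <- lapply(r$required_any, function(s)
            as.character(unlist(s)))
        if (!length(rules[[i]]$required_any) ||
            any(!vapply(rules[[i]]$required_any, length, 1L)))
            stop("rule '", r$name, "' has an empty required set",
                 call. = FALSE)
    }
    nms <- vapply(rules, `[[`, "", "name")
    pri <- vapply(rules, function(r) as.numeric(r$priority), 0)
    if (anyDuplicated(nms))
        stop("duplicate rule name: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(pri))
        stop("duplicate rule priority: ",
             paste(unique(pri[duplicated(pri)]), collapse = ", "),
             call. = FALSE)
    rules[order(pri)]
}

classifyOne <- function(domainSet, rules) {
    ds <- unique(domainSet)
    for (r in rules) {
        matched <- Filter(function(s) all(s %in% ds), r$required_any)
        if (!length(matched)) next
        if (length(r$forbidden) && any(r$forbidden %in% ds)) next
        if (r$exact &&
            !any(vapply(matched, function(s) setequal(ds, s), TRUE))) next
        return(r)
    }
    NULL
}

#' Classify regulator proteins into named subclasses
#'
#' Rules are tested in priority order against each protein's domain set; the
#' first rule whose required/forbidden/exact constraints hold assigns the
#' subclass, otherwise the protein is reported "unclassified". Exactness
#' compares domain sets (so duplicate copies of a required domain are
#' allowed), meaning any extra domain disqualifies an exact rule but is
#' ignored by non-exact rules.
#'
#' @param proteins architecture table from \code{\link{buildArchitectures}}.
#' @param rules rule list from \code{\link{loadRuleset}}.
#' @return data.frame: protein_id, gene_id, subclass, family, rule.
#' @export
classifyRegulators <- function(proteins, rules = loadRuleset()) {
    n <- nrow(proteins)
    subclass <- character(n); family <- character(n); rule <- character(n)
    for (i in seq_len(n)) {
        r <- classifyOne(proteins$domain_set[[i]], rules)
        if (is.null(r)) {
            subclass[i] <- "unclassified"
            family[i] <- NA_character_
            rule[i] <- NA_character_
        } else {
            subclass[i] <- r$name
            family[i] <- if (is.null(r$family)) NA_character_ else r$family
            rule[i] <- r$name
        }
    }
    data.frame(protein_id = proteins$protein_id,
               gene_id = proteins$gene_id,
               subclass = subclass, family = family, rule = rule,
               stringsAsFactors = FALSE)
}

#' Write a classification table as TSV
#' @param classification output of \code{\link{classifyRegulators}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeClassification <- function(classification, path) {
    utils::write.table(classification, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
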