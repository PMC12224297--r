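#' Build the domain co-occurrence network
#'
#' Every protein contributes one count to each unordered pair of distinct
#' domains in its domain set. Node frequencies count proteins containing the
#' domain over \emph{all} proteins, regardless of which edges survive the
#' count filter. Edges observed fewer than \code{minCount} times are dropped
#' (the default, 100, keeps only the most common association patterns).
#'
#' @param proteins architecture table from \code{\link{buildArchitectures}}.
#' @param minCount minimum co-occurrence count for an edge (default 100).
#' @return a \code{\linkS4class{CoocNetwork}}.
#' @export
buildCoocNetwork <- function(proteins, minCount = 100L) {
    sets <- proteins$domain_set
    all <- unlist(sets, use.names = FALSE)
    nodes <- if (length(all)) {
        tab <- table(all)
        setNames(as.numeric(tab), names(tab))
    } else numeric()
    pairs <- lapply(sets, function(s) {
        s <- sort(unique(s))
        if (length(s) < 2L) return(NULL)
        cmb <- utils::combn(s, 2L)
        paste(cmb[1L, ], cmb[2L, ], sep = "\r")
    })
    keys <- unlist(pairs, use.names = FALSE)
    if (length(keys)) {
        tab <- table(keys)
        ab <- strsplit(names(tab), "\r", fixed = TRUE)
        edges <- data.frame(
            domain_a = vapply(ab, `[`, "", 1L),
            domain_b = vapply(ab, `[`, "", 2L),
            count = as.numeric(tab), stringsAsFactors = FALSE)
        edges <- edges[edges$count >= minCount, , drop = FALSE]
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(domain_a = character(), domain_b = character(),
                            count = numeric(), stringsAsFactors = FALSE)
    }
    coocNetwork(nodes, edges)
}

# weighted adjacency matrix with the MCL self-loop convention: each node's
# loop equals its maximum incident edge weight (1 for isolated nodes)
networkAdjacency <- function(net) {
    nodes <- sort(names(networkNodes(net)))
    n <- length(nodes)
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    e <- networkEdges(net)
    if (nrow(e)) {
        ia <- match(e$domain_a, nodes)
        ib <- match(e$domain_b, nodes)
        A[cbind(ia, ib)] <- e$count
        A[cbind(ib, ia)] <- e$count
    }
    loops <- apply(A, 1L, max)
    diag(A) <- ifelse(loops > 0, loops, 1)
    A
}

colNormalize <- function(M) {
    s <- colSums(M)
    zero <- s == 0
    if (any(zero)) {
        # a fully pruned column keeps its node as its own attractor
        for (j in which(zero)) M[j, j] <- 1
        s <- colSums(M)
    }
    sweep(M, 2L, s, "/")
}

#' Markov Clustering of the co-occurrence network
#'
#' Native MCL: the count-weighted adjacency matrix gains self-loops equal to
#' each node's maximum incident weight (1 for isolated nodes) and is
#' column-normalized; the iteration alternates expansion (matrix power) and
#' inflation (elementwise power followed by column renormalization), pruning
#' entries below \code{pruneBelow}, until the maximum absolute change drops
#' below \code{tol} or \code{maxIter} is reached. Clusters are read from
#' attractor rows of the limit matrix; a node attracted to several attractor
#' systems joins the one with the largest weight, ties going to the
#' lexicographically smallest cluster label.
#'
#' @param net a \code{\linkS4class{CoocNetwork}} (non-empty).
#' @param params a \code{\linkS4class{MclParams}}; the default inflation of 6
#'   yields fine-grained subclusters.
#' @return an \code{\linkS4class{MclResult}}; clusters are sorted character
#'   vectors, ordered by their smallest member.
#' @export
mclCluster <- function(net, params = mclParams()) {
    validObject(params)
    if (length(networkNodes(net)) == 0L)
        stop("network is empty", call. = FALSE)
    M <- colNormalize(networkAdjacency(net))
    nodes <- rownames(M)
    dev <- numeric()
    iter <- 0L
    converged <- FALSE
    while (iter < params@maxIter) {
        iter <- iter + 1L
        E <- M
        for (k in seq_len(params@expansionPower - 1L)) E <- E %*% M
        Inf_ <- E^params@inflation
        Inf_[Inf_ < params@pruneBelow] <- 0
        Mnew <- colNormalize(Inf_)
        dev <- c(dev, max(abs(colSums(Mnew) - 1)))
        if (max(abs(Mnew - M)) < params@tol) {
            M <- Mnew
            converged <- TRUE
            break
        }
        M <- Mnew
    }
    if (!converged)
        warning("MCL did not converge within ", params@maxIter,
                " iterations", call. = FALSE)

    eps <- max(params@pruneBelow, 1e-12)
    attractors <- which(diag(M) > eps)
    if (!length(attractors)) attractors <- seq_along(nodes)
    # attractor systems: attractors supporting each other share a cluster
    sys <- seq_along(attractors)
    for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
        if (i < j && (M[attractors[i], attractors[j]] > eps ||
                      M[attractors[j], attractors[i]] > eps)) {
            old <- sys[j]
            sys[sys == old] <- sys[i]
        }
    }
    sysIds <- unique(sys)
    members <- vector("list", length(sysIds))
    labels <- character(length(sysIds))
    for (k in seq_along(sysIds)) {
        members[[k]] <- attractors[sys == sysIds[k]]
        labels[k] <- min(nodes[members[[k]]])
    }
    assign <- setNames(rep(NA_integer_, length(nodes)), nodes)
    for (k in seq_along(sysIds)) assign[members[[k]]] <- k
    for (j in which(is.na(assign))) {
        w <- vapply(members, function(m) sum(M[m, j]), 0)
        if (max(w) <= eps) {
            # unattracted node: its own singleton
            members <- c(members, list(integer()))
            labels <- c(labels, nodes[j])
            assign[j] <- length(members)
        } else {
            best <- which(w == max(w))
            if (length(best) > 1L) best <- best[order(labels[best])][1L]
            assign[j] <- best
        }
    }
    clusters <- lapply(seq_along(members), function(k)
        sort(nodes[assign == k]))
    clusters <- clusters[vapply(clusters, length, 1L) > 0L]
    clusters <- clusters[order(vapply(clusters, `[`, "", 1L))]
    new("MclResult", clusters = clusters, iterations = iter,
        converged = converged, colSumDeviation = dev)
}

#' Export the network as GraphML and a TSV edge list
#'
#' GraphML carries node frequency and cluster id attributes and edge count
#' and containment; the TSV lists domain_a, domain_b, count, containment,
#' cluster_a, cluster_b. Both re-import exactly.
#'
#' @param net a \code{\linkS4class{CoocNetwork}}.
#' @param clusters optional \code{\linkS4class{MclResult}} (or NULL).
#' @param graphmlPath output GraphML path (NULL to skip).
#' @param tsvPath output TSV path (NULL to skip).
#' @return invisibly, a list of written paths.
#' @export
exportNetwork <- function(net, clusters = NULL, graphmlPath = NULL,
                          tsvPath = NULL) {
    nodes <- sort(names(networkNodes(net)))
    clusterOf <- setNames(rep(NA_character_, length(nodes)), nodes)
    if (!is.null(clusters))
        for (cl in mclClusters(clusters))
            clusterOf[cl] <- min(cl)
    e <- networkEdges(net)
    if (!is.null(graphmlPath)) {
        g <- igraph::make_empty_graph(n = 0, directed = FALSE)
        g <- igraph::add_vertices(g, length(nodes), name = nodes,
                                  frequency = unname(networkNodes(net)[nodes]),
                                  cluster = unname(clusterOf))
        if (nrow(e))
            g <- igraph::add_edges(
                g, rbind(match(e$domain_a, nodes), match(e$domain_b, nodes)),
                count = e$count, containment = e$containment)
        igraph::write_graph(g, graphmlPath, format = "graphml")
    }
    if (!is.null(tsvPath)) {
        out <- data.frame(domain_a = e$domain_a, domain_b = e$domain_b,
                          count = e$count, containment = e$containment,
                          cluster_a = unname(clusterOf[e$domain_a]),
                          cluster_b = unname(clusterOf[e$domain_b]),
                          stringsAsFactors = FALSE)
        utils::write.table(out, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(list(graphml = graphmlPath, tsv = tsvPath))
}

#' Re-import a GraphML network written by \code{\link{exportNetwork}}
#' @param path GraphML file.
#' @return a \code{\linkS4class{CoocNetwork}}.
#' @export
readNetworkGraphml <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    nm <- igraph::vertex_attr(g, "name")
    nodes <- setNames(igraph::vertex_attr(g, "frequency"), nm)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(domain_a = el[, 1L], domain_b = el[, 2L],
                        count = igraph::edge_attr(g, "count"),
                        containment = igraph::edge_attr(g, "containment"),
                        stringsAsFactors = FALSE)
    if (nrow(edges) == 0L)
        edges <- data.frame(domain_a = character(), domain_b = character(),
                            count = numeric(), containment = numeric(),
                            stringsAsFactors = FALSE)
    coocNetwork(nodes, edges)
}
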