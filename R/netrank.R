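#' Read an undirected interaction graph from a TSV edge list
#'
#' Two or three columns: nodeA, nodeB, optional weight (e.g. a STRING
#' combined score). Self-loops and duplicate edges are removed.
#'
#' @param path TSV path (header optional, detected by non-numeric third
#'   column or column names).
#' @param min_weight Drop edges with weight below this threshold before
#'   simplification (ignored for unweighted lists).
#' @return Undirected simple `igraph`.
#' @export
read_edge_list <- function(path, min_weight = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && is.character(df[[1]]) &&
      tolower(df[[1]][1]) %in% c("nodea", "from", "node1", "source")) {
    df <- df[-1, , drop = FALSE]
  }
  if (ncol(df) >= 3) {
    df[[3]] <- as.numeric(df[[3]])
    if (!is.null(min_weight)) df <- df[df[[3]] >= min_weight, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df[, 1:2, drop = FALSE],
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read gene sets from a GMT file
#'
#' One set per line: id, description, then member genes,
#' tab-separated.
#'
#' @param path GMT path.
#' @return Named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed GMT line ", bad[1], " in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Intersect named gene sets with per-region Venn counts
#'
#' @param sets Named list of >= 2 character vectors.
#' @return List: `intersection` (members of every set), `regions` —
#'   data frame of all `2^k - 1` membership patterns with exclusive
#'   counts.
#' @examples
#' intersect_sets(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
#'                     c = c("C", "E")))$intersection
#' @export
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) stop("need >= 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(0L, 1L)), k))[-1, , drop = FALSE]
  codes <- apply(combos, 1, function(r) paste(as.integer(r), collapse = ""))
  regions <- data.frame(pattern = codes,
                        count = vapply(codes, function(cd)
                          sum(pattern == cd), integer(1)),
                        row.names = NULL)
  for (i in seq_len(k)) {
    regions[[names(sets)[i]]] <- substr(regions$pattern, i, i) == "1"
  }
  list(intersection = sort(universe[rowSums(member) == k]),
       regions = regions)
}

#' Cytohubba-style hub scores
#'
#' Computes, per node: `degree`; `closeness` (harmonic centrality, the
#' sum of inverse shortest-path distances, finite on disconnected
#' graphs); `betweenness`; `eccentricity` score (inverse of the node's
#' eccentricity within its connected component, 0 for isolated nodes);
#' `mcc` — maximal clique centrality, the sum of `(|C| - 1)!` over all
#' maximal cliques of size >= 2 containing the node (an edge not
#' contained in a triangle is a maximal 2-clique contributing 1, so
#' tree-like nodes score their degree); and `epc` — edge percolated
#' component, the Monte-Carlo mean size of the node's component after
#' independently retaining each edge with probability `epc_retain`.
#'
#' @param graph Undirected simple `igraph`.
#' @param metrics Which scores to compute.
#' @param epc_iterations Monte-Carlo iterations for EPC.
#' @param epc_retain Edge retention probability for EPC.
#' @param seed Seed for the EPC Monte Carlo (bit-reproducible).
#' @return A `hub_ranking`: data frame, one row per node, one column per
#'   metric, ordered by node name.
#' @export
hub_scores <- function(graph,
                       metrics = c("mcc", "degree", "epc", "eccentricity",
                                   "closeness", "betweenness"),
                       epc_iterations = 1000, epc_retain = 0.5, seed = 1) {
  stopifnot(igraph::vcount(graph) > 0)
  metrics <- match.arg(metrics, several.ok = TRUE)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(graph)))
    igraph::V(graph)$name <- nodes
  }
  out <- data.frame(node = nodes, row.names = NULL)
  if ("degree" %in% metrics) out$degree <- unname(igraph::degree(graph))
  if ("closeness" %in% metrics) {
    out$closeness <- unname(igraph::harmonic_centrality(graph,
                                                        normalized = FALSE))
  }
  if ("betweenness" %in% metrics) {
    out$betweenness <- unname(igraph::betweenness(graph, directed = FALSE))
  }
  if ("eccentricity" %in% metrics) {
    comp <- igraph::components(graph)
    ecc <- numeric(length(nodes))
    for (cid in seq_len(comp$no)) {
      vs <- which(comp$membership == cid)
      if (length(vs) == 1L) { ecc[vs] <- 0; next }
      sub <- igraph::induced_subgraph(graph, vs)
      e <- igraph::eccentricity(sub)
      ecc[vs] <- 1 / e
    }
    out$eccentricity <- ecc
  }
  if ("mcc" %in% metrics) {
    mcc <- stats::setNames(numeric(length(nodes)), nodes)
    cliques <- igraph::max_cliques(graph, min = 2)
    for (cl in cliques) {
      contrib <- factorial(length(cl) - 1)
      nms <- igraph::V(graph)$name[as.integer(cl)]
      mcc[nms] <- mcc[nms] + contrib
    }
    out$mcc <- unname(mcc)
  }
  if ("epc" %in% metrics) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    nv <- length(nodes)
    acc <- numeric(nv)
    with_seed(seed, {
      for (it in seq_len(epc_iterations)) {
        keep <- stats::runif(nrow(el)) < epc_retain
        gk <- igraph::graph_from_edgelist(el[keep, , drop = FALSE],
                                          directed = FALSE)
        gk <- igraph::add_vertices(gk, max(0, nv - igraph::vcount(gk)))
        comp <- igraph::components(gk)
        acc <- acc + comp$csize[comp$membership[seq_len(nv)]]
      }
    })
    out$epc <- acc / epc_iterations
  }
  structure(out, class = c("hub_ranking", "data.frame"))
}

#' Consensus of per-metric top-k hub sets
#'
#' For each metric, the top `k` nodes (ties broken by score descending,
#' then node label ascending); the consensus is the intersection across
#' metrics and may hold fewer than `k` nodes.
#'
#' @param ranking A `hub_ranking` from [hub_scores()].
#' @param k Top-list size (<= node count).
#' @return List: `consensus` (character), `top` (named list of per-metric
#'   top-k character vectors).
#' @export
consensus_top_k <- function(ranking, k = 7) {
  stopifnot(inherits(ranking, "hub_ranking"))
  if (k > nrow(ranking)) stop("k exceeds node count")
  metrics <- setdiff(names(ranking), "node")
  top <- lapply(metrics, function(m) {
    ord <- order(-ranking[[m]], ranking$node)
    ranking$node[ord][seq_len(k)]
  })
  names(top) <- metrics
  list(consensus = sort(Reduce(intersect, top)), top = top)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of query-set overlap with each
#' annotation term, Benjamini-Hochberg adjustment across terms, and a
#' BH-based q-value; a term is significant when raw p < 0.05 and
#' q < 0.05 (both strict).
#'
#' @param query Character vector of genes (must lie in the background).
#' @param annotation Named list of term gene sets (e.g. [read_gmt()]).
#' @param background Character vector, or integer background size
#'   (membership then unchecked beyond term sizes).
#' @param filter Return only significant terms (default) or all.
#' @param p_cut,q_cut Strict significance cutoffs.
#' @return Data frame: `term`, `overlap`, `query_size`, `term_size`,
#'   `background_size`, `p`, `q`, `significant`, plus `genes` (list
#'   column of overlapping genes), ordered by p.
#' @export
hypergeom_enrich <- function(query, annotation, background,
                             filter = TRUE, p_cut = 0.05, q_cut = 0.05) {
  query <- unique(query)
  if (is.numeric(background) && length(background) == 1L) {
    bg_size <- as.integer(background)
    annotation <- lapply(annotation, unique)
  } else {
    background <- unique(background)
    if (!all(query %in% background)) {
      stop("query genes outside the background: ",
           paste(utils::head(setdiff(query, background), 5), collapse = ", "))
    }
    annotation <- lapply(annotation, function(s) unique(s[s %in% background]))
    bg_size <- length(background)
  }
  sizes <- lengths(annotation)
  if (any(sizes > bg_size)) {
    stop("annotation term larger than the background")
  }
  nq <- length(query)
  overlap_genes <- lapply(annotation, function(s) intersect(query, s))
  ov <- lengths(overlap_genes)
  p <- stats::phyper(ov - 1, sizes, bg_size - sizes, nq, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(annotation), overlap = unname(ov),
                    query_size = nq, term_size = unname(sizes),
                    background_size = bg_size, p = unname(p), q = unname(q),
                    row.names = NULL)
  out$significant <- out$p < p_cut & out$q < q_cut
  out$genes <- unname(overlap_genes)
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (filter) out[out$significant, , drop = FALSE] else out
}
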