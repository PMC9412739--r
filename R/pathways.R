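#' Transformation types for deglycosylation pathway graphs
#'
#' Each transformation removes one neutral unit from the parent compound:
#' loss of a glycosyl residue (hexose, deoxyhexose, pentose, hexuronic
#' acid), demalonylation, or dehydration.
#'
#' @return Data frame with `name`, `formula` (the unit removed), `mass`.
#' @export
transformation_table <- function() {
  res <- residue_table()
  map <- c(loss_of_hexose = "Hexose",
           loss_of_deoxyhexose = "Deoxyhexose",
           loss_of_pentose = "Pentose",
           loss_of_hexuronic_acid = "HexuronicAcid",
           demalonylation = "Malonyl",
           dehydration = "Water")
  data.frame(name = names(map),
             formula = res$formula[match(map, res$name)],
             mass = res$mass[match(map, res$name)],
             stringsAsFactors = FALSE)
}

#' Build a deglycosylation transformation graph
#'
#' Directed edge (u, v) is present iff v's formula equals u's formula
#' minus exactly one allowed transformation unit (exact integer element
#' balance) and u and v share an aglycone class. Isomeric children give
#' parallel branches (e.g. Rb1 loses a hexose to either Rd or
#' Gypenoside XVII). Every transformation strictly reduces mass, so the
#' graph is acyclic.
#'
#' @param records A `ginsenoside_library` (or subset of its rows).
#' @param allowed Character vector of transformation names from
#'   [transformation_table()]; default all.
#' @return An `igraph` directed graph; edges carry `transformation` and
#'   `delta_mass` attributes, nodes carry `formula` and `class`.
#' @examples
#' lib <- load_library()
#' g <- build_graph(lib[lib$class == "PPD", ])
#' @export
build_graph <- function(records, allowed = transformation_table()$name) {
  stopifnot(inherits(records, "data.frame"), nrow(records) >= 1)
  tt <- transformation_table()
  tt <- tt[tt$name %in% allowed, , drop = FALSE]
  records <- records[order(records$name), , drop = FALSE]
  fmls <- lapply(records$formula, parse_formula)
  edges <- list()
  for (i in seq_len(nrow(records))) {
    for (k in seq_len(nrow(tt))) {
      child <- tryCatch(
        formula_subtract(fmls[[i]], parse_formula(tt$formula[k])),
        error = function(e) NULL)
      if (is.null(child)) next
      child_s <- format(child)
      hits <- which(vapply(fmls, function(f) format(f) == child_s,
                           logical(1)) &
                    records$class == records$class[i])
      for (j in hits) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = records$name[i], to = records$name[j],
          transformation = tt$name[k], delta_mass = tt$mass[k])
      }
    }
  }
  el <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               transformation = character(0), delta_mass = numeric(0))
  el <- el[order(el$from, el$to, el$transformation), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = records$name, formula = records$formula,
                          class = records$class))
  g
}

#' Enumerate transformation paths between two compounds
#'
#' All simple directed paths from `source` to `sink`, shortest first;
#' each path lists the node sequence and the transformation labels along
#' it.
#'
#' @param graph Graph from [build_graph()].
#' @param source,sink Compound names (must be graph nodes).
#' @param max_len Maximum number of transformation steps.
#' @return List of paths; each has `nodes` (character) and
#'   `transformations` (character, length `length(nodes) - 1`).
#'   `source == sink` yields one empty path.
#' @export
find_paths <- function(graph, source, sink, max_len = 10L) {
  vs <- igraph::V(graph)$name
  for (nm in c(source, sink)) {
    if (!nm %in% vs) stop("node not in graph: ", nm)
  }
  if (source == sink) {
    return(list(list(nodes = source, transformations = character(0))))
  }
  ps <- igraph::all_simple_paths(graph, from = source, to = sink,
                                 mode = "out", cutoff = max_len)
  out <- lapply(ps, function(p) {
    nodes <- names(p)
    trans <- character(length(nodes) - 1L)
    for (i in seq_along(trans)) {
      e <- igraph::get_edge_ids(graph, c(nodes[i], nodes[i + 1L]))
      trans[i] <- igraph::E(graph)$transformation[e]
    }
    list(nodes = nodes, transformations = trans)
  })
  out[order(vapply(out, function(p) length(p$nodes), integer(1)),
            vapply(out, function(p) paste(p$nodes, collapse = ">"),
                   character(1)))]
}

#' Export a transformation graph
#'
#' @param graph Graph from [build_graph()].
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"` (edge list: parent, child,
#'   transformation, delta_mass).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("parent", "child")
    el$delta_mass <- round(el$delta_mass, 6)
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
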