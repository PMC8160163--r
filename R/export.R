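## Graph serialisation: GraphML (via igraph), GEXF 1.2 (via xml2), and a
## plain edge-list CSV. Layout is left to external tools (e.g. Gephi).

#' Convert a correlation graph to an igraph object
#'
#' Node attributes: \code{category} (from the catalog, when the nodes are
#' catalog codes), \code{degree}, \code{pagerank}. Edge attributes:
#' \code{rho}, \code{p}, \code{weight}, \code{sign}.
#'
#' @param graph A \code{correlation_graph}.
#' @param catalog Catalog for the category labels; nodes absent from it get
#'   \code{NA}.
#' @return An undirected \code{igraph} graph.
#' @export
as_igraph <- function(graph, catalog = default_catalog()) {
  ct <- centrality_table(graph)
  vdf <- data.frame(
    name = graph$nodes,
    category = catalog$category[match(graph$nodes, catalog$code)],
    degree = ct$degree[match(graph$nodes, ct$node)],
    pagerank = ct$pagerank[match(graph$nodes, ct$node)],
    stringsAsFactors = FALSE)
  edf <- graph$edges[, c("from", "to", "rho", "p", "weight", "sign"),
                     drop = FALSE]
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Write a correlation graph to GraphML
#'
#' @param graph A \code{correlation_graph}.
#' @param path Output file.
#' @param catalog Catalog for node categories.
#' @return The path, invisibly.
#' @export
write_graphml <- function(graph, path, catalog = default_catalog()) {
  g <- as_igraph(graph, catalog)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a correlation graph to GEXF 1.2
#'
#' Minimal GEXF with node attributes (category, degree, pagerank) and edge
#' attributes (rho, p, sign); edge weight goes in the standard
#' \code{weight} attribute.
#'
#' @inheritParams write_graphml
#' @return The path, invisibly.
#' @export
write_gexf <- function(graph, path, catalog = default_catalog()) {
  ct <- centrality_table(graph)
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  gr <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  natt <- xml2::xml_add_child(gr, "attributes", class = "node")
  for (a in list(c("0", "category", "string"), c("1", "degree", "integer"),
                 c("2", "pagerank", "double"))) {
    xml2::xml_add_child(natt, "attribute", id = a[1], title = a[2],
                        type = a[3])
  }
  eatt <- xml2::xml_add_child(gr, "attributes", class = "edge")
  for (a in list(c("0", "rho", "double"), c("1", "p", "double"),
                 c("2", "sign", "integer"))) {
    xml2::xml_add_child(eatt, "attribute", id = a[1], title = a[2],
                        type = a[3])
  }
  nodes <- xml2::xml_add_child(gr, "nodes")
  cats <- catalog$category[match(graph$nodes, catalog$code)]
  for (i in seq_along(graph$nodes)) {
    nd <- xml2::xml_add_child(nodes, "node", id = graph$nodes[i],
                              label = graph$nodes[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = ifelse(is.na(cats[i]), "", cats[i]))
    xml2::xml_add_child(av, "attvalue", "for" = "1",
                        value = as.character(ct$degree[i]))
    xml2::xml_add_child(av, "attvalue", "for" = "2",
                        value = format(ct$pagerank[i], digits = 12))
  }
  edges <- xml2::xml_add_child(gr, "edges")
  ed <- graph$edges
  for (i in seq_len(nrow(ed))) {
    e <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                             source = ed$from[i], target = ed$to[i],
                             weight = format(ed$weight[i], digits = 12))
    av <- xml2::xml_add_child(e, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = format(ed$rho[i], digits = 12))
    xml2::xml_add_child(av, "attvalue", "for" = "1",
                        value = format(ed$p[i], digits = 12))
    xml2::xml_add_child(av, "attvalue", "for" = "2",
                        value = as.character(ed$sign[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write the edge list as CSV
#'
#' Columns: source, target, rho, p, weight, sign.
#'
#' @inheritParams write_graphml
#' @return The path, invisibly.
#' @export
write_edge_csv <- function(graph, path) {
  ed <- graph$edges
  out <- data.frame(source = ed$from, target = ed$to, rho = ed$rho,
                    p = ed$p, weight = ed$weight, sign = ed$sign,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
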