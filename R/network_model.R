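#' Construct an anatomical network
#'
#' An anatomical network is an undirected, unweighted, simple graph whose
#' nodes are named anatomical elements (e.g. skull bones) and whose edges are
#' physical contacts between them (e.g. sutures, articulations). Node
#' identity is the string label throughout the package; no integer
#' re-indexing is exposed.
#'
#' @param nodes Character vector of unique, non-empty node labels.
#' @param edges Two-column character matrix or data frame of edges, one row
#'   per edge. Direction is ignored and duplicate rows are collapsed (with a
#'   warning). Self-loops are an error.
#' @param laterality Optional named character vector mapping node labels to
#'   `"L"`, `"R"` or `"U"` (unpaired/midline). Nodes not named default to
#'   `"U"`.
#' @return An object of class `anatomical_network`: a list with elements
#'   `nodes` (character), `edges` (two-column character matrix, each row
#'   sorted, no duplicates) and `laterality` (named character vector over all
#'   nodes).
#' @examples
#' net <- anatomical_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' n_edges(net)
#' @export
anatomical_network <- function(nodes, edges = NULL, laterality = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("network must have at least one node")
  if (anyDuplicated(nodes)) stop("duplicate node labels: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (any(!nzchar(nodes))) stop("empty node labels are not allowed")

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edges must have exactly two columns")
    storage.mode(em) <- "character"
    if (any(em[, 1L] == em[, 2L])) {
      bad <- em[em[, 1L] == em[, 2L], 1L]
      stop("self-loop(s) on node(s): ", paste(unique(bad), collapse = ", "))
    }
    unknown <- setdiff(c(em), nodes)
    if (length(unknown)) stop("edge endpoint(s) not declared as nodes: ",
                              paste(unknown, collapse = ", "))
    em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    key <- paste(em[, 1L], em[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate edge(s) collapsed: ",
              sum(duplicated(key)), " removed")
      em <- em[!duplicated(key), , drop = FALSE]
    }
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  dimnames(em) <- NULL

  lat <- setNames(rep("U", length(nodes)), nodes)
  if (!is.null(laterality)) {
    laterality <- laterality[!is.na(laterality)]
    unknown <- setdiff(names(laterality), nodes)
    if (length(unknown)) stop("laterality given for unknown node(s): ",
                              paste(unknown, collapse = ", "))
    bad <- setdiff(unique(laterality), c("L", "R", "U"))
    if (length(bad)) stop("laterality values must be L, R or U; got: ",
                          paste(bad, collapse = ", "))
    lat[names(laterality)] <- laterality
  }

  structure(list(nodes = nodes, edges = em, laterality = lat),
            class = "anatomical_network")
}

#' @export
print.anatomical_network <- function(x, ...) {
  cat("Anatomical network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  sided <- sum(x$laterality != "U")
  if (sided > 0L) cat("  laterality: ", sided, " L/R node(s), ",
                      sum(x$laterality == "U"), " unpaired\n", sep = "")
  invisible(x)
}

#' @rdname anatomical_network
#' @param net An `anatomical_network`.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname anatomical_network
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert to/from igraph
#'
#' Internal bridges to [igraph][igraph::igraph-package] used for file I/O and
#' connectivity checks. Laterality travels as the `"side"` vertex attribute.
#'
#' @param net An `anatomical_network`.
#' @return An undirected [igraph::graph] with vertex attribute `name` and,
#'   when any node is sided, `side`.
#' @keywords internal
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges)) g <- igraph::add_edges(g, t(net$edges))
  if (any(net$laterality != "U")) {
    g <- igraph::set_vertex_attr(g, "side", value = unname(net$laterality))
  }
  g
}

from_igraph <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  }
  if (any(igraph::which_loop(g))) {
    stop("self-loop encountered in input graph")
  }
  em <- igraph::as_edgelist(g, names = TRUE)
  lat <- NULL
  if ("side" %in% igraph::vertex_attr_names(g)) {
    lat <- setNames(igraph::V(g)$side, igraph::V(g)$name)
    lat[is.na(lat) | !(lat %in% c("L", "R"))] <- "U"
  }
  anatomical_network(igraph::V(g)$name, em, lat)
}

#' Read a network from file
#'
#' Supported formats: GraphML (`format = "graphml"`) and headerless
#' two-column comma-separated edge lists (`format = "edgelist-csv"`). A
#' `source,target` header row in the CSV is tolerated and skipped. Edge
#' direction in the source file is ignored; duplicate edges are collapsed
#' with a warning; self-loops are an error. In GraphML the optional node
#' attribute `side` (values `L`/`R`/`U`) carries laterality.
#'
#' @param path Path to the file.
#' @param format One of `"graphml"`, `"edgelist-csv"`. Defaults by file
#'   extension (`.graphml` vs anything else).
#' @return An `anatomical_network`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("a,b", "b,c"), tf)
#' read_network(tf, "edgelist-csv")
#' @export
read_network <- function(path, format = c("auto", "graphml", "edgelist-csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist-csv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(from_igraph(g))
  }
  df <- read.csv(path, header = FALSE, colClasses = "character",
                 strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(df) != 2L) stop("edge-list CSV must have exactly two columns")
  if (nrow(df) && tolower(df[1L, 1L]) == "source" &&
      tolower(df[1L, 2L]) == "target") {
    df <- df[-1L, , drop = FALSE]
  }
  if (!nrow(df)) stop("edge-list CSV contains no edges")
  nodes <- unique(c(df[[1L]], df[[2L]]))
  anatomical_network(nodes, as.matrix(df))
}

#' Write a network to file
#'
#' The GraphML writer emits the `side` node attribute when any node carries
#' laterality. The CSV writer emits a headerless two-column edge list; note
#' that isolated nodes are not representable in an edge list.
#'
#' @param net An `anatomical_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist-csv"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path,
                          format = c("auto", "graphml", "edgelist-csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist-csv"
  }
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    if (length(setdiff(net$nodes, c(net$edges)))) {
      warning("isolated node(s) dropped by edge-list format: ",
              paste(setdiff(net$nodes, c(net$edges)), collapse = ", "))
    }
    write.table(net$edges, path, sep = ",", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Validate a network
#'
#' Reports (never mutates) the basic structural facts the pipeline relies
#' on: simple-graph status, connectivity, and the connected components.
#' Disconnected networks are admissible inputs: they are analyzed as given,
#' with a warning recorded in the report.
#'
#' @param net An `anatomical_network`.
#' @return A list of class `validation_report`: `is_simple`, `is_connected`,
#'   `n_nodes`, `n_edges`, `components` (list of node-label vectors) and
#'   `warnings` (character).
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  components <- split(net$nodes, comp$membership)
  names(components) <- NULL
  warnings <- character(0)
  if (comp$no > 1L) {
    warnings <- c(warnings,
                  sprintf("network is disconnected (%d components); analyzed as given",
                          comp$no))
  }
  structure(list(is_simple = TRUE,  # enforced by the constructor
                 is_connected = comp$no == 1L,
                 n_nodes = length(net$nodes),
                 n_edges = nrow(net$edges),
                 components = components,
                 warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges; %s, %s\n", x$n_nodes, x$n_edges,
              if (x$is_simple) "simple" else "NOT simple",
              if (x$is_connected) "connected"
              else sprintf("disconnected (%d components)", length(x$components))))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

node_degrees <- function(net) {
  d <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

adjacency_list <- function(net) {
  adj <- setNames(vector("list", length(net$nodes)), net$nodes)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  if (nrow(net$edges)) {
    a <- split(net$edges[, 2L], factor(net$edges[, 1L], levels = net$nodes))
    b <- split(net$edges[, 1L], factor(net$edges[, 2L], levels = net$nodes))
    for (v in net$nodes) adj[[v]] <- c(a[[v]], b[[v]])
  }
  adj
}

#' Per-node in/out link counts relative to a node set
#'
#' For every node of the network (members and non-members alike) counts its
#' links to `members` versus to the complement. For a member node, links to
#' other members are `in_links`. This all-node population is what the
#' module-cohesion test (see [cohesion_test()]) is computed over.
#'
#' @param net An `anatomical_network`.
#' @param members Character vector of node labels, a subset of the network
#'   nodes.
#' @return A data frame with columns `node`, `in_links`, `out_links`,
#'   one row per network node (in network node order). For every node,
#'   `in_links + out_links == degree(node)`.
#' @examples
#' net <- anatomical_network(c("a", "b", "c"),
#'                           rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' degree_split(net, c("a", "b"))
#' @export
degree_split <- function(net, members) {
  stopifnot(inherits(net, "anatomical_network"))
  members <- as.character(members)
  unknown <- setdiff(members, net$nodes)
  if (length(unknown)) stop("unknown member label(s): ",
                            paste(unknown, collapse = ", "))
  inm <- net$nodes %in% members
  names(inm) <- net$nodes
  in_links <- setNames(integer(length(net$nodes)), net$nodes)
  out_links <- in_links
  if (nrow(net$edges)) {
    for (r in seq_len(nrow(net$edges))) {
      u <- net$edges[r, 1L]; v <- net$edges[r, 2L]
      if (inm[[v]]) in_links[[u]] <- in_links[[u]] + 1L
      else out_links[[u]] <- out_links[[u]] + 1L
      if (inm[[u]]) in_links[[v]] <- in_links[[v]] + 1L
      else out_links[[v]] <- out_links[[v]] + 1L
    }
  }
  data.frame(node = net$nodes, in_links = unname(in_links),
             out_links = unname(out_links), stringsAsFactors = FALSE)
}
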