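#' Planted-module test network
#'
#' Generates a small random network with known module structure, emulating
#' what the pipeline assumes of anatomical networks: a handful of dense
#' modules, optional shared nodes between consecutive modules (planted
#' covers), and optional exact bilateral symmetry. Edges are independent
#' Bernoulli draws: probability `p_in` for node pairs sharing at least one
#' planted module, `p_out` otherwise.
#'
#' With `bilateral = TRUE` the network is mirrored into `_L`/`_R` halves
#' joined by unpaired midline nodes: nodes shared between modules and the
#' first node of every module stay unpaired and connect identically to both
#' sides (as unpaired skull bones such as the frontal, occipital or vomer
#' do), while all other nodes get an `_L` and an `_R` copy. The base edge
#' draws are applied symmetrically, so the L/R relabeling is an exact graph
#' automorphism. Planted modules then contain both of a pair's sides plus
#' their midline nodes, as bilaterally symmetric anatomical modules do.
#' Binding each module's two sides through its own midline node keeps the
#' planted module the unique local optimum around each of its nodes; without
#' it, one-sided chimeric sets tie exactly with the planted module.
#'
#' @param module_sizes Integer vector of planted module sizes (length >= 1).
#' @param p_in Within-module edge probability.
#' @param p_out Between-module edge probability (`p_out <= p_in`).
#' @param overlap Number of nodes shared between each pair of consecutive
#'   modules (`< min(module_sizes)`).
#' @param bilateral Mirror the network into L/R halves (see Details).
#' @param seed RNG seed; the generator restores the caller's RNG state.
#' @return A list of class `planted_network`: `network` (an
#'   `anatomical_network`), `modules` (list of ground-truth member vectors),
#'   `overlaps` (list of shared-node vectors between consecutive modules) and
#'   `midline` (character vector, bilateral only).
#' @examples
#' pn <- planted_network(c(4, 4), p_in = 1, p_out = 0, seed = 1)
#' n_nodes(pn$network)
#' @export
planted_network <- function(module_sizes, p_in = 1, p_out = 0,
                            overlap = 0L, bilateral = FALSE, seed = NULL) {
  stopifnot(length(module_sizes) >= 1, all(module_sizes >= 1),
            p_out >= 0, p_in <= 1, p_out <= p_in)
  overlap <- as.integer(overlap)
  if (length(module_sizes) > 1L && overlap >= min(module_sizes)) {
    stop("overlap must be smaller than the smallest module")
  }

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))

  # lay the modules along a node sequence; consecutive modules share
  # `overlap` nodes
  k <- length(module_sizes)
  starts <- integer(k); ends <- integer(k)
  pos <- 1L
  for (i in seq_len(k)) {
    starts[i] <- if (i == 1L) 1L else ends[i - 1L] - overlap + 1L
    ends[i] <- starts[i] + module_sizes[i] - 1L
    pos <- ends[i]
  }
  n_base <- ends[k]
  base_ids <- sprintf("v%02d", seq_len(n_base))
  base_modules <- lapply(seq_len(k), function(i) base_ids[starts[i]:ends[i]])
  membership <- lapply(base_ids, function(v)
    which(vapply(base_modules, function(m) v %in% m, logical(1))))
  names(membership) <- base_ids
  shared <- base_ids[lengths(membership) > 1L]

  # one Bernoulli draw per base pair
  pairs <- combn(base_ids, 2L)
  same <- vapply(seq_len(ncol(pairs)), function(j) {
    length(intersect(membership[[pairs[1L, j]]],
                     membership[[pairs[2L, j]]])) > 0L
  }, logical(1))
  prob <- ifelse(same, p_in, p_out)
  drawn <- stats::runif(ncol(pairs)) < prob
  base_edges <- t(pairs[, drawn, drop = FALSE])

  if (!bilateral) {
    net <- anatomical_network(base_ids, base_edges)
    overlaps <- if (k > 1L) lapply(seq_len(k - 1L), function(i)
      intersect(base_modules[[i]], base_modules[[i + 1L]])) else list()
    return(structure(list(network = net, modules = base_modules,
                          overlaps = overlaps, midline = character(0)),
                     class = "planted_network"))
  }

  # mirror: shared (overlap) nodes and each module's first node are midline
  # and stay unpaired; all other nodes get an L and an R copy; base edge
  # draws are applied to both sides
  midline <- union(shared, vapply(base_modules, `[`, character(1), 1L))
  is_mid <- base_ids %in% midline
  expand <- function(v) if (v %in% midline) v else paste0(v, c("_L", "_R"))
  nodes <- unlist(lapply(base_ids, expand))
  lat <- setNames(rep("U", length(nodes)), nodes)
  lat[grepl("_L$", nodes)] <- "L"
  lat[grepl("_R$", nodes)] <- "R"

  mirror_edges <- function(u, v) {
    um <- u %in% midline; vm <- v %in% midline
    if (um && vm) return(rbind(c(u, v)))
    if (um) return(rbind(c(u, paste0(v, "_L")), c(u, paste0(v, "_R"))))
    if (vm) return(rbind(c(paste0(u, "_L"), v), c(paste0(u, "_R"), v)))
    rbind(c(paste0(u, "_L"), paste0(v, "_L")),
          c(paste0(u, "_R"), paste0(v, "_R")))
  }
  edges <- do.call(rbind, lapply(seq_len(nrow(base_edges)), function(r)
    mirror_edges(base_edges[r, 1L], base_edges[r, 2L])))
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)

  net <- anatomical_network(nodes, edges, lat)
  modules <- lapply(base_modules, function(m) sort(unlist(lapply(m, expand))))
  overlaps <- if (k > 1L) lapply(seq_len(k - 1L), function(i)
    intersect(modules[[i]], modules[[i + 1L]])) else list()
  structure(list(network = net, modules = modules, overlaps = overlaps,
                 midline = base_ids[is_mid]),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat("Planted network:", length(x$modules), "module(s)\n")
  print(x$network)
  invisible(x)
}

#' The L/R mirror map of a bilateral network
#'
#' Returns the node relabeling swapping `_L` and `_R` suffixed nodes and
#' fixing the rest; on output of `planted_network(bilateral = TRUE)` this is
#' a graph automorphism.
#'
#' @param nodes Character vector of node labels.
#' @return Named character vector mapping each label to its mirror image.
#' @export
mirror_map <- function(nodes) {
  out <- setNames(nodes, nodes)
  l <- grepl("_L$", nodes)
  r <- grepl("_R$", nodes)
  out[l] <- sub("_L$", "_R", nodes[l])
  out[r] <- sub("_R$", "_L", nodes[r])
  out
}

#' Perturb a network with minimal intraspecific-variation edits
#'
#' Emulates natural specimen-to-specimen variation: `n_rewires`
#' degree-perturbing single-edge swaps (remove one random edge, add one pair
#' that was absent in the input network) and an optional extra node attached
#' to named targets (the accessory-ossicle case). If the graph is complete a
#' swap degenerates to a pure removal, with a warning. The result is always
#' simple.
#'
#' @param net An `anatomical_network`.
#' @param n_rewires Number of edge swaps (`<=` edge count).
#' @param add_node Optional list `list(label =, targets =)` adding one node
#'   attached to the target labels.
#' @param seed RNG seed; the caller's RNG state is restored.
#' @return A perturbed `anatomical_network`.
#' @export
perturb <- function(net, n_rewires = 0L, add_node = NULL, seed = NULL) {
  stopifnot(inherits(net, "anatomical_network"), n_rewires >= 0)
  if (n_rewires > nrow(net$edges)) stop("n_rewires exceeds edge count")

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))

  edges <- net$edges
  edge_key <- function(e) paste(pmin(e[, 1L], e[, 2L]),
                                pmax(e[, 1L], e[, 2L]), sep = "\r")
  all_pairs <- t(combn(net$nodes, 2L))
  for (i in seq_len(n_rewires)) {
    if (!nrow(edges)) stop("no edge left to remove")
    present <- edge_key(all_pairs) %in% edge_key(edges)
    absent <- all_pairs[!present, , drop = FALSE]
    drop_i <- sample.int(nrow(edges), 1L)
    edges <- edges[-drop_i, , drop = FALSE]
    if (nrow(absent)) {
      edges <- rbind(edges, absent[sample.int(nrow(absent), 1L), ])
    } else {
      warning("complete graph: swap degenerates to an edge removal")
    }
  }

  nodes <- net$nodes
  lat <- net$laterality
  if (!is.null(add_node)) {
    stopifnot(is.list(add_node), !is.null(add_node$label),
              length(add_node$targets) >= 1)
    if (add_node$label %in% nodes) stop("added node label already present")
    unknown <- setdiff(add_node$targets, nodes)
    if (length(unknown)) stop("unknown attachment target(s): ",
                              paste(unknown, collapse = ", "))
    nodes <- c(nodes, add_node$label)
    lat <- c(lat, setNames("U", add_node$label))
    edges <- rbind(edges, cbind(add_node$label, add_node$targets))
  }
  anatomical_network(nodes, edges, lat)
}

#' Zachary karate-club benchmark network
#'
#' The canonical 34-node, 78-edge social network, bundled as a plain-text
#' edge list (nodes labeled `v01`..`v34`); a standard benchmark for community
#' detection, useful here as a larger-than-skull smoke test.
#'
#' @return An `anatomical_network` with 34 nodes and 78 edges.
#' @export
karate_fixture <- function() {
  path <- system.file("extdata", "karate.csv", package = "nims",
                      mustWork = TRUE)
  read_network(path, "edgelist-csv")
}

#' Write a planted fixture to disk
#'
#' Emits the network as GraphML next to a ground-truth JSON (module map,
#' overlap list, midline nodes) for use in golden tests.
#'
#' @param pn A [planted_network()] result.
#' @param basepath Path prefix; writes `<basepath>.graphml` and
#'   `<basepath>.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_planted_fixture <- function(pn, basepath) {
  stopifnot(inherits(pn, "planted_network"))
  gpath <- paste0(basepath, ".graphml")
  jpath <- paste0(basepath, ".json")
  write_network(pn$network, gpath, "graphml")
  jsonlite::write_json(list(modules = pn$modules, overlaps = pn$overlaps,
                            midline = pn$midline),
                       jpath, pretty = TRUE)
  invisible(c(gpath, jpath))
}
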