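#' Spin-glass detector configuration
#'
#' Settings for the single-community spin-glass search run around every node.
#' The objective maximized is the local cohesion score (see
#' [local_quality()]); the search is simulated annealing with Metropolis
#' acceptance, one full sweep of single-node toggle proposals per
#' temperature, and a multiplicative cooling schedule.
#'
#' @param gamma Resolution parameter (> 0, dimensionless). Scales the
#'   configuration-model expectation against the realized internal links;
#'   1.0 weighs both equally and is never varied in routine use.
#' @param replicates Independent annealing chains per focal node. The modal
#'   member set across chains is reported together with its agreement
#'   fraction; agreement below 0.6 triggers a warning.
#' @param t_start,t_stop Start and stop temperatures of the annealing
#'   schedule (`t_stop < t_start`).
#' @param cooling Multiplicative temperature factor applied after each sweep
#'   (strictly between 0 and 1).
#' @param seed Master RNG seed. Per-node, per-replicate sub-seeds are derived
#'   from `(seed, node label, replicate)` so results do not depend on node
#'   iteration order.
#' @return A list of class `spinglass_config`.
#' @export
spinglass_config <- function(gamma = 1.0, replicates = 10L,
                             t_start = 1.0, t_stop = 0.01,
                             cooling = 0.99, seed = 1L) {
  stopifnot(gamma > 0, replicates >= 1, t_stop < t_start,
            cooling > 0, cooling < 1)
  structure(list(gamma = gamma, replicates = as.integer(replicates),
                 t_start = t_start, t_stop = t_stop, cooling = cooling,
                 seed = as.integer(seed)),
            class = "spinglass_config")
}

# Deterministic sub-seed from (seed, label, replicate); stays below 2^31.
derive_seed <- function(seed, label, replicate = 0L) {
  M <- 2147483647
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% M
  as.integer((((seed %% M) * 69621) %% M + h * 7919 + replicate * 10007) %% M)
}

#' Local cohesion score of a node set
#'
#' The score of a member set is the number of realized internal links minus
#' `gamma` times their configuration-model expectation,
#' \deqn{q(C) = \ell_{in}(C) - \gamma \sum_{i<j \in C} k_i k_j / (2m),}
#' with \eqn{k_i} node degrees and \eqn{m} the total edge count. The sum
#' equals \eqn{(S^2 - \sum_{i\in C} k_i^2)/(4m)} for \eqn{S} the summed
#' degree of the set. Local (node-level) modules are the maximizers of this
#' score over sets containing a focal node.
#'
#' @param net An `anatomical_network`.
#' @param members Non-empty character vector of member node labels.
#' @param gamma Resolution parameter (> 0).
#' @return The score (a single number, dimensionless).
#' @examples
#' net <- anatomical_network(c("a", "b"), rbind(c("a", "b")))
#' local_quality(net, c("a", "b"))  # 1 - 1*1/(2*1) = 0.5
#' @export
local_quality <- function(net, members, gamma = 1.0) {
  stopifnot(inherits(net, "anatomical_network"), gamma > 0)
  members <- as.character(members)
  if (!length(members)) stop("member set must be non-empty")
  unknown <- setdiff(members, net$nodes)
  if (length(unknown)) stop("unknown member label(s): ",
                            paste(unknown, collapse = ", "))
  m <- nrow(net$edges)
  if (m == 0L) return(0)
  inm <- net$nodes %in% members
  names(inm) <- net$nodes
  l_in <- sum(inm[net$edges[, 1L]] & inm[net$edges[, 2L]])
  deg <- node_degrees(net)[members]
  S <- sum(deg)
  expected <- (S^2 - sum(deg^2)) / (4 * m)
  l_in - gamma * expected
}

#' Node-level module around a focal node
#'
#' Step 1 of the pipeline: stochastically maximizes [local_quality()] over
#' member sets constrained to contain `focal`, by simulated annealing whose
#' move set toggles membership of one non-focal node. `config$replicates`
#' independent chains are run; the modal member set is returned with the
#' fraction of chains that produced it. Ties between equally modal sets are
#' broken toward the lexicographically smallest sorted member list.
#'
#' @param net An `anatomical_network`.
#' @param focal A node label of `net`.
#' @param config A [spinglass_config()].
#' @return A list of class `node_module`: `focal`, `members` (sorted
#'   character vector containing `focal`), `score` (the local quality of the
#'   returned set) and `agreement` (fraction of replicates in (0, 1]).
#' @export
local_module <- function(net, focal, config = spinglass_config()) {
  stopifnot(inherits(net, "anatomical_network"),
            inherits(config, "spinglass_config"))
  focal <- as.character(focal)
  if (!(focal %in% net$nodes)) stop("focal node not in network: ", focal)

  idx <- setNames(seq_along(net$nodes) - 1L, net$nodes)
  adj_chr <- adjacency_list(net)
  adj <- lapply(adj_chr, function(v) unname(idx[v]))
  deg <- unname(node_degrees(net))
  m <- nrow(net$edges)

  keys <- character(config$replicates)
  sets <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(config$seed, focal, r))
    members_i <- sa_local_module_cpp(adj, deg, m, unname(idx[[focal]]),
                                     config$gamma, config$t_start,
                                     config$t_stop, config$cooling)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s <- sort(net$nodes[members_i + 1L])
    sets[[r]] <- s
    keys[r] <- paste(s, collapse = "\r")
  }
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  winner <- sort(top)[1L]  # lexicographic tie-break on the sorted member list
  members <- sets[[match(winner, keys)]]
  agreement <- as.numeric(max(tab)) / config$replicates
  if (agreement < 0.6) {
    warning(sprintf("low replicate agreement (%.2f) for focal node '%s'",
                    agreement, focal))
  }
  structure(list(focal = focal, members = members,
                 score = local_quality(net, members, config$gamma),
                 agreement = agreement),
            class = "node_module")
}

#' @export
print.node_module <- function(x, ...) {
  cat(sprintf("Node-level module [%s]: %d nodes, score %.4f, agreement %.2f\n",
              x$focal, length(x$members), x$score, x$agreement))
  cat(" ", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Node-level modules for every node
#'
#' Runs the local detector once per network node. Sub-seeds are derived from
#' `(config$seed, node label)`, so the result is deterministic given the seed
#' and independent of node iteration order. Any function with the signature
#' `function(net, focal, config)` returning a `node_module` can be plugged in
#' as `detector`, mirroring the strategy's indifference to the particular
#' node-level algorithm.
#'
#' @param net An `anatomical_network`.
#' @param config A [spinglass_config()].
#' @param detector Node-level detector, default [local_module()].
#' @return A list of `node_module` objects, one per node, in network node
#'   order.
#' @export
all_local_modules <- function(net, config = spinglass_config(),
                              detector = local_module) {
  stopifnot(inherits(net, "anatomical_network"))
  lapply(net$nodes, function(v) detector(net, v, config))
}
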