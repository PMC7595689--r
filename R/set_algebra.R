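#' Collect node-level modules against their network universe
#'
#' @param modules List of `node_module` objects.
#' @param universe_size Number of nodes in the analyzed network; the finite
#'   background of the exact intersection test.
#' @return A list of class `module_set`: `modules`, `universe_size`.
#' @export
module_set <- function(modules, universe_size) {
  stopifnot(all(vapply(modules, inherits, logical(1), "node_module")),
            universe_size >= 1)
  structure(list(modules = modules, universe_size = as.integer(universe_size)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("Module set:", length(x$modules), "module(s), universe",
      x$universe_size, "nodes\n")
  for (m in x$modules) {
    cat(sprintf("  [%s] %d nodes: %s\n", m$focal, length(m$members),
                paste(m$members, collapse = ", ")))
  }
  invisible(x)
}

set_key <- function(members) paste(sort(members), collapse = "\r")

#' Remove duplicated node-level modules
#'
#' Step 2: keeps exactly one representative per distinct member set. The
#' retained representative is the module whose focal label is
#' lexicographically smallest within its duplicate group; otherwise the order
#' of first appearance is preserved.
#'
#' @param modules List of `node_module` objects.
#' @return Filtered list of `node_module` objects.
#' @export
drop_duplicates <- function(modules) {
  if (!length(modules)) return(modules)
  keys <- vapply(modules, function(m) set_key(m$members), character(1))
  focals <- vapply(modules, function(m) m$focal, character(1))
  keep <- integer(0)
  for (k in unique(keys)) {
    grp <- which(keys == k)
    keep <- c(keep, grp[order(focals[grp])][1L])
  }
  modules[sort(keep)]
}

#' Remove nested node-level modules
#'
#' Step 3: removes every module whose member set is a strict subset of
#' another module's member set. Duplicates must already have been removed;
#' the result is an antichain under set inclusion.
#'
#' @param modules List of `node_module` objects with distinct member sets.
#' @return Filtered list of `node_module` objects.
#' @export
drop_nested <- function(modules) {
  k <- length(modules)
  if (k < 2L) return(modules)
  sets <- lapply(modules, function(m) m$members)
  keys <- vapply(sets, set_key, character(1))
  if (anyDuplicated(keys)) stop("duplicates present; run drop_duplicates() first")
  nested <- vapply(seq_len(k), function(i) {
    any(vapply(seq_len(k), function(j) {
      i != j && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  modules[!nested]
}

#' Is the network trivially integrated?
#'
#' After Steps 2 and 3, a single surviving module means every node's local
#' neighbourhood is the same set: the network is fully integrated and has no
#' modular structure to analyze. The pipeline short-circuits here.
#'
#' @param collection A [module_set()].
#' @return `TRUE` iff exactly one non-redundant module remains.
#' @export
is_trivially_integrated <- function(collection) {
  stopifnot(inherits(collection, "module_set"))
  length(collection$modules) == 1L
}

#' Exact null distribution of a multi-set intersection size
#'
#' Distribution of \eqn{|S_1 \cap \dots \cap S_k|} when each \eqn{S_i} is an
#' independent uniform random subset of fixed size `sizes[i]` drawn from a
#' universe of `universe_size` elements. Computed by chained convolution: the
#' running intersection of size `s` meets the next random set of size `m`
#' in `Hypergeometric(universe_size, s, m)` elements.
#'
#' @param universe_size Size of the background universe.
#' @param sizes Integer vector (length >= 2) of set sizes, each `<=
#'   universe_size`.
#' @return Numeric probability vector over intersection sizes `0..min(sizes)`
#'   (names are the sizes); sums to 1 within 1e-12.
#' @examples
#' intersection_pmf(4, c(2, 2))  # 1/6, 4/6, 1/6
#' @export
intersection_pmf <- function(universe_size, sizes) {
  universe_size <- as.integer(universe_size)
  sizes <- as.integer(sizes)
  if (length(sizes) < 2L) stop("need at least two set sizes")
  if (any(sizes > universe_size)) stop("set size exceeds universe size")
  if (any(sizes < 0L) || universe_size < 1L) stop("sizes must be non-negative")
  sup <- 0:min(sizes)
  # running intersection starts as S1 itself (point mass at sizes[1]),
  # then folds in each further set through the hypergeometric kernel
  pmf <- as.numeric(seq_along(0:sizes[1L]) - 1L == sizes[1L])
  for (msize in sizes[-1L]) {
    nsup <- 0:min(length(pmf) - 1L, msize)
    new <- vapply(nsup, function(t) {
      s <- seq_along(pmf) - 1L
      sum(pmf * dhyper(t, s, universe_size - s, msize))
    }, numeric(1))
    pmf <- new
  }
  pmf <- pmf[seq_along(sup)]
  names(pmf) <- sup
  pmf
}

#' Exact multi-set intersection tests over all module combinations
#'
#' Step 4: for every combination of two or more modules (\eqn{2^k - k - 1}
#' combinations for `k` modules) computes the observed intersection size, its
#' null expectation `universe_size * prod(sizes/universe_size)`, the fold
#' enrichment, the upper-tail exact p-value `P(X >= observed)` from
#' [intersection_pmf()], and the Bonferroni-corrected p-value (raw p times
#' the number of tested combinations, capped at 1).
#'
#' @param collection A [module_set()] with at least two modules.
#' @param alpha Significance level applied to the corrected p-values.
#' @return A data frame of class `nims_intersections` with one row per
#'   combination: `combo` (labels joined by `" & "`), `degree`, `observed`,
#'   `expected`, `fold_enrichment`, `p_raw`, `p_bonferroni`, `significant`;
#'   the list of constituent label vectors is in the `modules` attribute.
#' @export
supertest <- function(collection, alpha = 0.05) {
  stopifnot(inherits(collection, "module_set"))
  k <- length(collection$modules)
  if (k < 2L) stop("need at least two non-redundant modules")
  N <- collection$universe_size
  labels <- vapply(collection$modules, function(m) m$focal, character(1))
  sets <- lapply(collection$modules, function(m) m$members)
  names(sets) <- labels

  combos <- unlist(lapply(2:k, function(d) {
    asplit(combn(labels, d), 2L)
  }), recursive = FALSE)
  n_tests <- length(combos)

  rows <- lapply(combos, function(cmb) {
    these <- sets[cmb]
    obs <- length(Reduce(intersect, these))
    sizes <- lengths(these)
    expected <- N * prod(sizes / N)
    pmf <- intersection_pmf(N, sizes)
    p_raw <- sum(pmf[as.integer(names(pmf)) >= obs])
    p_raw <- min(1, max(p_raw, .Machine$double.xmin))
    data.frame(combo = paste(cmb, collapse = " & "),
               degree = length(cmb),
               observed = obs,
               expected = expected,
               fold_enrichment = if (expected > 0) obs / expected else NA_real_,
               p_raw = p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * n_tests)
  out$significant <- out$p_bonferroni <= alpha
  attr(out, "modules") <- lapply(combos, as.character)
  attr(out, "n_tests") <- n_tests
  attr(out, "alpha") <- alpha
  class(out) <- c("nims_intersections", "data.frame")
  out
}
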