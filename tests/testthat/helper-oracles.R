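# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and simulation only.

# All-subsets maximizer of the local cohesion score around `focal`.
# Returns the maximum and every set attaining it (ties matter).
exhaustive_best <- function(net, focal, gamma = 1) {
  nodes <- net$nodes
  n <- length(nodes)
  others <- setdiff(nodes, focal)
  deg <- as.numeric(table(factor(c(net$edges), levels = nodes)))
  names(deg) <- nodes
  m <- nrow(net$edges)
  nmask <- 2^length(others)
  M <- matrix(FALSE, nmask, n, dimnames = list(NULL, nodes))
  M[, focal] <- TRUE
  for (j in seq_along(others)) {
    M[, others[j]] <- bitwAnd(0:(nmask - 1), bitwShiftL(1L, j - 1L)) > 0
  }
  lin <- numeric(nmask)
  if (m > 0) {
    for (r in seq_len(m)) {
      lin <- lin + (M[, net$edges[r, 1]] & M[, net$edges[r, 2]])
    }
  }
  q <- if (m > 0) {
    lin - gamma * ((M %*% deg)^2 - M %*% deg^2) / (4 * m)
  } else lin
  best <- max(q)
  list(q = best,
       sets = lapply(which(q >= best - 1e-9), function(i) sort(nodes[M[i, ]])))
}

# Exact pmf of |S_1 cap ... cap S_k| by enumerating every combination of
# subsets (uniform subsets of fixed sizes from a universe of N elements).
# Feasible for N <= 6.
pmf_enumerate <- function(N, sizes) {
  subsets <- lapply(sizes, function(s) {
    cols <- combn(N, s)
    lapply(seq_len(ncol(cols)), function(j) cols[, j])
  })
  counts <- rep(0, min(sizes) + 1L)
  grid <- expand.grid(lapply(subsets, seq_along))
  for (r in seq_len(nrow(grid))) {
    inter <- Reduce(intersect, Map(function(lst, i) lst[[i]],
                                   subsets, as.integer(grid[r, ])))
    counts[length(inter) + 1L] <- counts[length(inter) + 1L] + 1L
  }
  counts / sum(counts)
}

# Monte-Carlo pmf of the same quantity.
pmf_montecarlo <- function(N, sizes, B = 1e5) {
  counts <- rep(0, min(sizes) + 1L)
  for (b in seq_len(B)) {
    inter <- sample.int(N, sizes[1])
    for (s in sizes[-1]) inter <- intersect(inter, sample.int(N, s))
    counts[length(inter) + 1L] <- counts[length(inter) + 1L] + 1L
  }
  counts / B
}

# One-sided signed-rank test by full enumeration of the 2^n sign patterns,
# conditional on the observed midranks (exact for tie-free data).
wilcox_enumerate <- function(d) {
  stopifnot(all(d != 0))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  list(W = W, p = mean(Ws >= W - 1e-9))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

cover_keys <- function(covers) {
  sort(vapply(covers, function(cv) paste(sort(cv$members), collapse = ","),
              character(1)))
}

# small named graphs used in several files
make_k6 <- function() {
  anatomical_network(letters[1:6], t(combn(letters[1:6], 2)))
}

make_barbell <- function() {
  cl <- function(v) t(combn(v, 2))
  anatomical_network(letters[1:8],
                     rbind(cl(letters[1:4]), cl(letters[5:8]), c("d", "e")))
}

make_node_module <- function(focal, members) {
  structure(list(focal = focal, members = sort(members), score = 0,
                 agreement = 1), class = "node_module")
}
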