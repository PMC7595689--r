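#' Select statistically supported merges
#'
#' Step 5. Candidate merges are the Bonferroni-significant combinations from
#' [supertest()], ranked by larger observed overlap first, then smaller
#' corrected p-value, then fewer constituent modules. Candidates are taken
#' greedily: a combination is committed only if none of its modules is
#' already committed to an earlier merge. A significant superset of an
#' accepted merge whose overlap is smaller is recorded among the rejected
#' candidates with reason `"overlap-reducing superset"` — merging more
#' modules at the price of a smaller common core is never preferred.
#'
#' In interactive sessions with `interactive = TRUE` the ranked candidates
#' are printed and each top-ranked available merge must be confirmed at the
#' prompt; in non-interactive sessions the flag only prints the ranking and
#' the greedy selection proceeds.
#'
#' @param records A `nims_intersections` table from [supertest()].
#' @param collection The [module_set()] the records were computed from.
#' @param alpha Significance level on the corrected p-values.
#' @param interactive Ask for confirmation before committing each merge.
#' @return A list of class `merge_plan`: `merges` (list of character vectors
#'   of module labels), `rationale` (data frame with one row per accepted
#'   merge: combo, observed, p_bonferroni, and each constituent's overlap
#'   fraction), and `rejected` (data frame: combo, reason).
#' @export
select_merges <- function(records, collection, alpha = 0.05,
                          interactive = FALSE) {
  stopifnot(inherits(records, "nims_intersections"),
            inherits(collection, "module_set"),
            alpha > 0, alpha < 1)
  combos <- attr(records, "modules")
  sig <- which(records$p_bonferroni <= alpha)
  empty_plan <- structure(
    list(merges = list(),
         rationale = data.frame(combo = character(0), observed = integer(0),
                                p_bonferroni = numeric(0),
                                overlap_fractions = character(0),
                                stringsAsFactors = FALSE),
         rejected = data.frame(combo = character(0), reason = character(0),
                               stringsAsFactors = FALSE)),
    class = "merge_plan")
  if (!length(sig)) return(empty_plan)

  ord <- sig[order(-records$observed[sig], records$p_bonferroni[sig],
                   records$degree[sig])]
  sizes <- setNames(lapply(collection$modules, function(m) m$members),
                    vapply(collection$modules, function(m) m$focal, character(1)))

  if (interactive) {
    message("Ranked merge candidates (significant at alpha = ", alpha, "):")
    for (i in seq_along(ord)) {
      r <- ord[i]
      message(sprintf("  %d. %s  overlap=%d  p_bonf=%.3g", i,
                      records$combo[r], records$observed[r],
                      records$p_bonferroni[r]))
    }
  }

  committed <- character(0)
  merges <- list()
  rationale <- list()
  rejected <- list()
  accepted_idx <- integer(0)
  for (r in ord) {
    cmb <- combos[[r]]
    if (any(cmb %in% committed)) {
      reason <- "module-already-committed"
      for (a in accepted_idx) {
        if (all(combos[[a]] %in% cmb) &&
            records$observed[r] < records$observed[a]) {
          reason <- "overlap-reducing superset"
          break
        }
      }
      rejected[[length(rejected) + 1L]] <-
        data.frame(combo = records$combo[r], reason = reason,
                   stringsAsFactors = FALSE)
      next
    }
    if (interactive && base::interactive()) {
      ans <- readline(sprintf("Commit merge %s? [y/N] ", records$combo[r]))
      if (!tolower(trimws(ans)) %in% c("y", "yes")) {
        rejected[[length(rejected) + 1L]] <-
          data.frame(combo = records$combo[r], reason = "declined-by-user",
                     stringsAsFactors = FALSE)
        next
      }
    }
    merges[[length(merges) + 1L]] <- cmb
    committed <- c(committed, cmb)
    accepted_idx <- c(accepted_idx, r)
    fr <- vapply(cmb, function(l) records$observed[r] / length(sizes[[l]]),
                 numeric(1))
    rationale[[length(rationale) + 1L]] <-
      data.frame(combo = records$combo[r],
                 observed = records$observed[r],
                 p_bonferroni = records$p_bonferroni[r],
                 overlap_fractions = paste(sprintf("%s:%.2f", cmb, fr),
                                           collapse = ", "),
                 stringsAsFactors = FALSE)
  }
  structure(list(merges = merges,
                 rationale = if (length(rationale)) do.call(rbind, rationale)
                             else empty_plan$rationale,
                 rejected = if (length(rejected)) do.call(rbind, rejected)
                            else empty_plan$rejected),
            class = "merge_plan")
}

#' @export
print.merge_plan <- function(x, ...) {
  cat("Merge plan:", length(x$merges), "merge(s)\n")
  if (nrow(x$rationale)) print(x$rationale, row.names = FALSE)
  if (nrow(x$rejected)) {
    cat("Rejected candidates:\n")
    print(x$rejected, row.names = FALSE)
  }
  invisible(x)
}

#' Build final covers from a merge plan
#'
#' One cover per merge group (members are the union of the constituents'
#' member sets) plus one cover per unmerged module. Final modules that share
#' nodes are called covers. Labels join the constituent focal labels with
#' `"+"`.
#'
#' @param collection A [module_set()].
#' @param plan A [select_merges()] plan referring only to modules of
#'   `collection`.
#' @return A list of covers; each is a list of class `cover` with `label`,
#'   `members` (sorted) and `constituents`.
#' @export
build_covers <- function(collection, plan) {
  stopifnot(inherits(collection, "module_set"), inherits(plan, "merge_plan"))
  labels <- vapply(collection$modules, function(m) m$focal, character(1))
  sets <- setNames(lapply(collection$modules, function(m) m$members), labels)
  dangling <- setdiff(unlist(plan$merges), labels)
  if (length(dangling)) stop("merge plan refers to unknown module(s): ",
                             paste(dangling, collapse = ", "))
  covers <- list()
  merged <- character(0)
  for (grp in plan$merges) {
    covers[[length(covers) + 1L]] <-
      structure(list(label = paste(grp, collapse = "+"),
                     members = sort(unique(unlist(sets[grp]))),
                     constituents = grp),
                class = "cover")
    merged <- c(merged, grp)
  }
  for (l in setdiff(labels, merged)) {
    covers[[length(covers) + 1L]] <-
      structure(list(label = l, members = sets[[l]], constituents = l),
                class = "cover")
  }
  covers
}

#' @export
print.cover <- function(x, ...) {
  cat(sprintf("Cover [%s]: %d nodes\n  %s\n", x$label, length(x$members),
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' One-sided Wilcoxon signed-rank test of paired differences
#'
#' The statistical core of the cover cohesion test, exposed so it can be
#' checked independently of any network. Zero differences are dropped;
#' absolute differences are mid-ranked; `W` is the sum of the ranks of the
#' positive differences; the p-value is one-sided against "differences are
#' centered above zero". The exact signed-rank distribution is used when
#' fewer than 50 non-zero differences remain and their absolute values are
#' tie-free, otherwise the normal approximation with continuity correction.
#'
#' @param d Numeric vector of paired differences (here: per-node in-links
#'   minus out-links).
#' @return A list: `W`, `p`, `n_used`, `method`.
#' @examples
#' signed_rank(c(1, 2, 3))   # W = 6, p = 1/8
#' signed_rank(c(1, -1))     # midranks: W = 1.5
#' @export
signed_rank <- function(d) {
  d <- as.numeric(d)
  dnz <- d[d != 0]
  n_used <- length(dnz)
  if (n_used == 0L) stop("signed-rank test undefined: all differences zero")
  ties <- any(duplicated(abs(dnz)))
  wt <- suppressWarnings(wilcox.test(dnz, mu = 0, alternative = "greater",
                                     correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, n_used = n_used,
       method = if (!ties && n_used < 50) "exact" else "normal-approximation")
}

#' Wilcoxon signed-rank cohesion test of a cover
#'
#' Step 6: verifies that a final cover meets the definition of a module — a
#' group of nodes with more links inside than outside the group. For every
#' node of the network (members and non-members alike, see [degree_split()])
#' the paired counts (in-links, out-links) are formed; zero differences are
#' dropped; the remaining absolute differences are mid-ranked; `W` is the sum
#' of ranks of the positive differences. The p-value is one-sided (greater).
#' The exact signed-rank distribution is used when fewer than 50 non-zero
#' pairs remain and their absolute differences are tie-free; otherwise the
#' normal approximation with continuity correction.
#'
#' @param net An `anatomical_network`.
#' @param cover A `cover` object, or a character vector of member labels.
#' @param population Which nodes contribute (in, out) pairs: `"all"` (the
#'   default; every network node) or `"members"` (cover members only). The
#'   all-nodes population is what large-cover statistics on whole anatomical
#'   networks are computed over; the members-only population asks the
#'   narrower question of whether the members themselves look inward.
#' @return A list of class `cohesion_result`: `cover` (label), `W`, `p`,
#'   `n_used`, `method` (`"exact"` or `"normal-approximation"`), and
#'   `splits` (the [degree_split()] table). An error is thrown when every
#'   difference is zero (the test is undefined).
#' @export
cohesion_test <- function(net, cover, population = c("all", "members")) {
  stopifnot(inherits(net, "anatomical_network"))
  population <- match.arg(population)
  if (inherits(cover, "cover")) {
    label <- cover$label
    members <- cover$members
  } else {
    members <- as.character(cover)
    label <- paste(members, collapse = "+")
  }
  splits <- degree_split(net, members)
  if (population == "members") {
    splits <- splits[splits$node %in% members, , drop = FALSE]
  }
  d <- splits$in_links - splits$out_links
  if (all(d == 0)) {
    stop("cohesion test undefined for cover '", label,
         "': all in/out differences are zero")
  }
  sr <- signed_rank(d)
  structure(list(cover = label,
                 W = sr$W,
                 p = sr$p,
                 n_used = sr$n_used,
                 method = sr$method,
                 splits = splits),
            class = "cohesion_result")
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf("Cohesion [%s]: W = %g, one-sided p = %.3g (n = %d, %s)\n",
              x$cover, x$W, x$p, x$n_used, x$method))
  invisible(x)
}

#' Run the full node-based informed modularity pipeline
#'
#' Executes the six steps in order: (1) a local spin-glass module around
#' every node, (2) duplicate removal, (3) nested-module removal, (4) exact
#' intersection tests over all module combinations, (5) merge selection and
#' cover construction, (6) a Wilcoxon cohesion test per final cover. When a
#' single module survives Steps 2–3 the network is fully integrated and the
#' pipeline stops there.
#'
#' @param net An `anatomical_network`.
#' @param config A [spinglass_config()]; its `seed` governs all randomness.
#' @param alpha Significance level for the Bonferroni-corrected intersection
#'   tests.
#' @param interactive Forwarded to [select_merges()].
#' @param detector Node-level detector, forwarded to [all_local_modules()].
#' @param population Pairing population for the cohesion test, forwarded to
#'   [cohesion_test()].
#' @return A list of class `nims_report` with elements `validation`,
#'   `modules_raw`, `modules` (the non-redundant set), `trivially_integrated`,
#'   `intersections`, `plan`, `covers`, `cohesion` (one result per cover;
#'   undefined tests carry `W = NA` with a `note`), `uncovered` (nodes in no
#'   cover), `config`, `alpha`, `seed`.
#' @examples
#' net <- planted_network(c(4, 4), p_in = 1, p_out = 0, seed = 7)$network
#' rep <- run_nims(net, spinglass_config(seed = 1))
#' length(rep$covers)
#' @export
run_nims <- function(net, config = spinglass_config(), alpha = 0.05,
                     interactive = FALSE, detector = local_module,
                     population = c("all", "members")) {
  population <- match.arg(population)
  stopifnot(inherits(net, "anatomical_network"))
  validation <- validate_network(net)

  mods_raw <- all_local_modules(net, config, detector)          # Step 1
  mods <- drop_nested(drop_duplicates(mods_raw))                # Steps 2-3
  collection <- module_set(mods, length(net$nodes))

  report <- list(validation = validation, modules_raw = mods_raw,
                 modules = collection, config = config, alpha = alpha,
                 seed = config$seed)

  if (is_trivially_integrated(collection)) {
    report$trivially_integrated <- TRUE
    report$intersections <- NULL
    report$plan <- NULL
    report$covers <- list()
    report$cohesion <- list()
    report$uncovered <- character(0)
    class(report) <- "nims_report"
    return(report)
  }
  report$trivially_integrated <- FALSE

  records <- supertest(collection, alpha)                       # Step 4
  plan <- select_merges(records, collection, alpha, interactive) # Step 5
  covers <- build_covers(collection, plan)

  cohesion <- lapply(covers, function(cv) {                     # Step 6
    tryCatch(cohesion_test(net, cv, population),
             error = function(e) structure(
               list(cover = cv$label, W = NA_real_, p = NA_real_,
                    n_used = 0L, method = "undefined",
                    note = conditionMessage(e), splits = NULL),
               class = "cohesion_result"))
  })

  report$intersections <- records
  report$plan <- plan
  report$covers <- covers
  report$cohesion <- cohesion
  report$uncovered <- setdiff(net$nodes, unique(unlist(lapply(covers,
                                                              `[[`, "members"))))
  class(report) <- "nims_report"
  report
}

#' @export
print.nims_report <- function(x, ...) {
  print(x$validation)
  cat(length(x$modules_raw), "node-level modules,",
      length(x$modules$modules), "non-redundant\n")
  if (x$trivially_integrated) {
    cat("Network is fully integrated: one module grouping ",
        paste(x$modules$modules[[1]]$members, collapse = ", "), "\n", sep = "")
    return(invisible(x))
  }
  cat(sum(x$intersections$significant), "of", nrow(x$intersections),
      "intersections significant at Bonferroni-corrected alpha =",
      x$alpha, "\n")
  cat(length(x$plan$merges), "merge(s) ->", length(x$covers), "cover(s)\n")
  for (i in seq_along(x$covers)) {
    print(x$covers[[i]])
    print(x$cohesion[[i]])
  }
  if (length(x$uncovered)) {
    cat("Nodes in no cover:", paste(x$uncovered, collapse = ", "), "\n")
  }
  invisible(x)
}
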