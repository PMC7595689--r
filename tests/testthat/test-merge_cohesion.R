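# Two hand-built module configurations mirror the published skull analyses:
# a human-like one (4 modules, two disjoint significant pairs -> facial and
# cranial covers of 13 and 12 bones) and a crocodile-like one (7 modules; a
# vomer pair sharing 20 nodes, a postorbital triple sharing 15, and a 4-way
# extension that shrinks the common core to 8 and must lose to the triple).

human_collection <- function() {
  u <- sprintf("u%02d", 1:21)
  module_set(list(
    make_node_module("Ethmoidal", u[1:11]),
    make_node_module("Frontal", c(u[1:10], u[12], u[13])),
    make_node_module("Sphenoidal", u[12:21]),
    make_node_module("Occipital", c(u[13:21], u[10], u[11]))
  ), 21)
}

crocodile_collection <- function() {
  u <- sprintf("u%02d", 1:40)
  module_set(list(
    make_node_module("RVomer", u[1:21]),
    make_node_module("LVomer", c(u[1:20], u[22])),
    make_node_module("RPostorbital", c(u[23:37], u[1:4])),
    make_node_module("LPostorbital", c(u[23:37], u[5:8])),
    make_node_module("RSquamosal", c(u[23:37], u[9:10])),
    make_node_module("Pterygoid", c(u[23:30], u[11:14])),
    make_node_module("Frontal", u[33:40])
  ), 40)
}

test_that("two disjoint significant pairs are both accepted (human-type)", {
  col <- human_collection()
  rec <- supertest(col)
  expect_equal(nrow(rec), 11L)
  expect_setequal(rec$combo[rec$significant],
                  c("Ethmoidal & Frontal", "Sphenoidal & Occipital"))
  plan <- select_merges(rec, col)
  expect_setequal(vapply(plan$merges, paste, character(1), collapse = "+"),
                  c("Ethmoidal+Frontal", "Sphenoidal+Occipital"))
  covers <- build_covers(col, plan)
  expect_length(covers, 2L)
  expect_setequal(lengths(lapply(covers, `[[`, "members")), c(13L, 12L))
})

test_that("the overlap-reducing superset loses to the triple (crocodile)", {
  col <- crocodile_collection()
  rec <- supertest(col)
  expect_equal(nrow(rec), 2^7 - 7 - 1)  # 120
  plan <- select_merges(rec, col)
  expect_equal(plan$merges,
               list(c("RVomer", "LVomer"),
                    c("RPostorbital", "LPostorbital", "RSquamosal")))
  fourway <- "RPostorbital & LPostorbital & RSquamosal & Pterygoid"
  expect_equal(plan$rejected$reason[plan$rejected$combo == fourway],
               "overlap-reducing superset")
  # 7 modules, 2 merges covering 5 -> 4 covers
  covers <- build_covers(col, plan)
  expect_length(covers, 4L)
  expect_setequal(vapply(covers, `[[`, character(1), "label"),
                  c("RVomer+LVomer", "RPostorbital+LPostorbital+RSquamosal",
                    "Pterygoid", "Frontal"))
})

test_that("no significant record gives an empty plan and identity covers", {
  col <- module_set(list(make_node_module("a", c("a", "b", "c")),
                         make_node_module("d", c("d", "e", "f")),
                         make_node_module("g", c("g", "h", "c"))), 20)
  rec <- supertest(col)
  plan <- select_merges(rec, col)
  expect_length(plan$merges, 0L)
  covers <- build_covers(col, plan)
  expect_length(covers, 3L)
  expect_equal(lapply(covers, `[[`, "members"),
               lapply(col$modules, `[[`, "members"))

  bogus <- plan
  bogus$merges <- list(c("a", "zz"))
  expect_error(build_covers(col, bogus), "unknown module")
})

test_that("every accepted merge is Bonferroni-significant", {
  for (col in list(human_collection(), crocodile_collection())) {
    rec <- supertest(col)
    plan <- select_merges(rec, col)
    for (i in seq_len(nrow(plan$rationale))) {
      expect_lte(plan$rationale$p_bonferroni[i], 0.05)
    }
  }
})

test_that("signed_rank matches its stated conventions", {
  # differences +1,+2,+3: W = 6, p = 1/8 by enumerating 2^3 sign patterns
  sr <- signed_rank(c(1, 2, 3))
  expect_equal(sr$W, 6)
  expect_equal(sr$p, 0.125)
  expect_equal(sr$method, "exact")

  # tied magnitudes +1,-1: midranks -> W = 1.5
  sr2 <- signed_rank(c(1, -1))
  expect_equal(sr2$W, 1.5)
  expect_equal(sr2$method, "normal-approximation")

  # zeros are dropped, not counted
  sr3 <- signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(sr3$n_used, 3L)
  expect_equal(sr3$W, 6)
  expect_equal(sr3$p, 0.125)

  expect_error(signed_rank(c(0, 0)), "all differences zero")
})

test_that("exact signed-rank p matches 2^n enumeration (tie-free, n <= 10)", {
  set.seed(99)
  for (n in c(3, 5, 8, 10)) {
    for (rep in 1:5) {
      mags <- sample(1:50, n)  # distinct magnitudes -> tie-free
      d <- mags * sample(c(-1, 1), n, replace = TRUE)
      sr <- signed_rank(d)
      oracle <- wilcox_enumerate(d)
      expect_equal(sr$W, oracle$W)
      expect_equal(sr$p, oracle$p, tolerance = 1e-12)
      expect_equal(sr$method, "exact")
      expect_lte(sr$W, n * (n + 1) / 2)
      expect_gte(sr$W, 0)
    }
  }
})

test_that("cohesion_test pairs in/out counts over the chosen population", {
  # 4-clique plus two pendants: the clique is strongly cohesive
  cl <- t(combn(letters[1:4], 2))
  net <- anatomical_network(c(letters[1:4], "p", "q"),
                            rbind(cl, c("p", "a"), c("q", "b")))
  res <- cohesion_test(net, letters[1:4])
  # members: a,b have d=+2, c,d have d=+3; pendants d=+1 (linked to members)
  expect_equal(res$n_used, 6L)
  expect_equal(res$W, 21)  # all positive: W = n(n+1)/2
  expect_true(res$p < 0.05)

  resm <- cohesion_test(net, letters[1:4], population = "members")
  expect_equal(resm$n_used, 4L)
  expect_equal(resm$W, 10)

  # degenerate: members = half of a 4-cycle, every difference zero
  cyc <- anatomical_network(letters[1:4],
                            rbind(c("a", "b"), c("b", "c"),
                                  c("c", "d"), c("d", "a")))
  expect_error(cohesion_test(cyc, c("a", "b")), "all in/out differences")
})

test_that("run_nims short-circuits on the fully integrated case", {
  k6 <- make_k6()
  rep <- run_nims(k6, spinglass_config(seed = 1))
  expect_true(rep$trivially_integrated)
  expect_length(rep$modules$modules, 1L)
  expect_equal(rep$modules$modules[[1]]$members, k6$nodes)
  expect_null(rep$intersections)
  expect_length(rep$covers, 0L)
  expect_length(rep$cohesion, 0L)
})

test_that("run_nims recovers planted cliques; members-only cohesion is significant", {
  pn <- planted_network(c(6, 6), p_in = 1, p_out = 0, seed = 3)
  rep <- suppressWarnings(run_nims(pn$network, spinglass_config(seed = 3),
                                   population = "members"))
  expect_length(rep$covers, 2L)
  expect_setequal(cover_keys(rep$covers),
                  sort(vapply(pn$modules, paste, character(1), collapse = ",")))
  for (cr in rep$cohesion) {
    expect_equal(cr$n_used, 6L)
    expect_equal(cr$W, 21)  # all six differences +5: W = n(n+1)/2
    expect_equal(cr$method, "normal-approximation")  # tied magnitudes
    expect_lt(cr$p, 0.05)
  }
  expect_length(rep$uncovered, 0L)
})

test_that("run_nims is deterministic given the seed", {
  pn <- planted_network(c(5, 5), p_in = 0.9, p_out = 0.1, seed = 8)
  r1 <- suppressWarnings(run_nims(pn$network, spinglass_config(seed = 4)))
  r2 <- suppressWarnings(run_nims(pn$network, spinglass_config(seed = 4)))
  expect_identical(cover_keys(r1$covers), cover_keys(r2$covers))
  expect_identical(r1$intersections, r2$intersections)
  expect_identical(vapply(r1$cohesion, `[[`, numeric(1), "p"),
                   vapply(r2$cohesion, `[[`, numeric(1), "p"))
})

test_that("report writer emits the four artifacts", {
  pn <- planted_network(c(4, 4), p_in = 1, p_out = 0, seed = 2)
  rep <- suppressWarnings(run_nims(pn$network, spinglass_config(seed = 2)))
  dir <- tempfile()
  write_nims_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("report.json", "intersections.tsv", "covers.tsv", "cohesion.tsv")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$network$n_nodes, 8L)
  expect_equal(js$seed, 2L)
  covers <- read.delim(file.path(dir, "covers.tsv"))
  expect_setequal(unique(covers$cover),
                  vapply(rep$covers, `[[`, character(1), "label"))
})
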