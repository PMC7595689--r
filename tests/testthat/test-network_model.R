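test_that("construction enforces the simple-graph invariants", {
  net <- anatomical_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)

  expect_error(anatomical_network(c("a", "a"), NULL), "duplicate")
  expect_error(anatomical_network("a", rbind(c("a", "a"))), "self-loop")
  expect_error(anatomical_network(c("a", "b"), rbind(c("a", "z"))),
               "not declared")
  expect_warning(
    net2 <- anatomical_network(c("a", "b"), rbind(c("a", "b"), c("b", "a"))),
    "duplicate edge"
  )
  expect_equal(n_edges(net2), 1L)
})

test_that("edge-list CSV reader handles direction, duplicates and headers", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "b,c"), tf)
  net <- read_network(tf, "edgelist-csv")
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)

  writeLines(c("a,b", "b,a"), tf)
  expect_warning(net2 <- read_network(tf, "edgelist-csv"), "duplicate")
  expect_equal(n_nodes(net2), 2L)
  expect_equal(n_edges(net2), 1L)

  writeLines(c("source,target", "a,b"), tf)
  expect_equal(n_edges(read_network(tf, "edgelist-csv")), 1L)

  writeLines(c("a,a"), tf)
  expect_error(read_network(tf, "edgelist-csv"), "self-loop")
  expect_error(read_network(tempfile(), "edgelist-csv"), "not found")
})

test_that("GraphML reader handles the bundled karate fixture", {
  karate <- karate_fixture()
  tf <- tempfile(fileext = ".graphml")
  write_network(karate, tf, "graphml")
  net <- read_network(tf, "graphml")
  expect_equal(n_nodes(net), 34L)
  expect_equal(n_edges(net), 78L)
})

test_that("write/read round-trip preserves nodes, edges and laterality", {
  for (seed in 1:3) {
    pn <- planted_network(c(4, 3), p_in = 0.8, p_out = 0.2, bilateral = TRUE,
                          overlap = 1, seed = seed)
    net <- pn$network
    for (fmt in c("graphml", "edgelist-csv")) {
      tf <- tempfile(fileext = if (fmt == "graphml") ".graphml" else ".csv")
      if (fmt == "edgelist-csv" &&
          length(setdiff(net$nodes, c(net$edges)))) next  # isolated nodes
      write_network(net, tf, fmt)
      back <- read_network(tf, fmt)
      expect_setequal(back$nodes, net$nodes)
      expect_equal(back$edges[order(back$edges[, 1], back$edges[, 2]), ],
                   net$edges[order(net$edges[, 1], net$edges[, 2]), ])
      if (fmt == "graphml") {
        expect_equal(back$laterality[net$nodes], net$laterality)
      }
    }
  }
})

test_that("validate_network reports connectivity without mutating input", {
  path <- anatomical_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  rep <- validate_network(path)
  expect_true(rep$is_connected)
  expect_length(rep$components, 1L)
  expect_length(rep$warnings, 0L)

  two <- anatomical_network(letters[1:4], rbind(c("a", "b"), c("c", "d")))
  rep2 <- validate_network(two)
  expect_false(rep2$is_connected)
  expect_length(rep2$components, 2L)
  expect_match(rep2$warnings, "disconnected")

  k6 <- make_k6()
  expect_equal(validate_network(k6)$n_edges, 15L)
})

test_that("degree_split counts members-vs-complement links for every node", {
  tri <- anatomical_network(c("a", "b", "c"),
                            rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  ds <- degree_split(tri, c("a", "b"))
  expect_equal(ds$in_links[ds$node == "a"], 1L)
  expect_equal(ds$out_links[ds$node == "a"], 1L)
  # the non-member row exists too
  expect_equal(ds$in_links[ds$node == "c"], 2L)
  expect_equal(ds$out_links[ds$node == "c"], 0L)

  # members = all nodes -> every out_links = 0
  ds_all <- degree_split(tri, tri$nodes)
  expect_true(all(ds_all$out_links == 0L))

  # 4-clique plus pendant attached to a
  cl <- t(combn(letters[1:4], 2))
  net <- anatomical_network(c(letters[1:4], "p"), rbind(cl, c("p", "a")))
  ds2 <- degree_split(net, letters[1:4])
  expect_equal(unlist(ds2[ds2$node == "p", c("in_links", "out_links")]),
               c(in_links = 1L, out_links = 0L))
  expect_equal(unlist(ds2[ds2$node == "a", c("in_links", "out_links")]),
               c(in_links = 3L, out_links = 1L))

  expect_error(degree_split(net, "zz"), "unknown member")
})

test_that("degree_split properties hold on random planted networks", {
  for (seed in 1:5) {
    pn <- planted_network(c(5, 4), p_in = 0.7, p_out = 0.3, seed = seed)
    net <- pn$network
    deg <- table(factor(c(net$edges), levels = net$nodes))
    members <- sample(net$nodes, 4)
    ds <- degree_split(net, members)

    # in + out = degree, for every node
    expect_equal(ds$in_links + ds$out_links,
                 as.integer(deg[ds$node]), ignore_attr = TRUE)

    # sum of member in_links counts each internal edge twice
    internal <- sum(net$edges[, 1] %in% members & net$edges[, 2] %in% members)
    expect_equal(sum(ds$in_links[ds$node %in% members]), 2L * internal)

    # complement swaps the roles
    dsc <- degree_split(net, setdiff(net$nodes, members))
    expect_equal(ds$in_links, dsc$out_links)
    expect_equal(ds$out_links, dsc$in_links)
  }
})
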