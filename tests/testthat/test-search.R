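path_table <- function(codes) {
  n <- length(codes)
  df <- data.frame(donor_res = seq_len(n - 1), donor_base = codes[-n],
                   donor_atom = "N1", acceptor_res = 2:n,
                   acceptor_base = codes[-1], acceptor_atom = "O2",
                   stringsAsFactors = FALSE)
  build_table(as_hbond_set(df))
}

star_table <- function(center, leaves) {
  n <- length(leaves) + 1
  df <- data.frame(donor_res = 1, donor_base = center, donor_atom = "N1",
                   acceptor_res = 2:n, acceptor_base = leaves,
                   acceptor_atom = "O2", stringsAsFactors = FALSE)
  build_table(as_hbond_set(df))
}

test_that("matching equals the exhaustive-assignment oracle", {
  set.seed(101)
  for (rep in 1:60) {
    tab <- random_table(sample(3:8, 1))
    q <- random_query(sample(2:4, 1))
    expect_identical(match_keys(match_pattern(tab, q)),
                     brute_force_matches(tab, q))
  }
})

test_that("matching agrees with an independent graph library on shapes", {
  skip_if_not_installed("igraph")
  set.seed(111)
  for (rep in 1:20) {
    tab <- random_table(sample(4:9, 1))
    qn <- sample(2:4, 1)
    trees <- enumerate_trees(qn)
    tr <- trees[[sample(length(trees), 1)]]
    q <- make_query(tr, rep("*", qn))  # unlabeled, any-multiplicity
    g <- igraph::graph_from_adjacency_matrix(table_adjacency(tab) > 0,
                                             mode = "undirected")
    p <- igraph::graph_from_edgelist(tr$edges, directed = FALSE)
    want <- length(igraph::subgraph_isomorphisms(p, g, method = "lad",
                                                 induced = FALSE))
    expect_equal(length(match_pattern(tab, q)), want)
  }
})

test_that("empty tables and oversized queries give no matches", {
  empty <- build_table(as_hbond_set(data.frame(
    donor_res = integer(), donor_base = character(),
    donor_atom = character(), acceptor_res = integer(),
    acceptor_base = character(), acceptor_atom = character())))
  q <- make_query(enumerate_trees(2)[[1]], c("*", "*"))
  expect_length(match_pattern(empty, q), 0)
  q4 <- make_query(enumerate_trees(4)[[1]], rep("*", 4))
  expect_length(match_pattern(path_table(c("A", "U", "G")), q4), 0)
})

test_that("redundancy filtering collapses order-permuted matches", {
  # symmetric path-3 on a 3-chain: two traversal orders, one hit
  tab <- path_table(c("A", "U", "G"))
  q <- make_query(enumerate_trees(3)[[1]], rep("*", 3))
  raw <- match_pattern(tab, q)
  expect_length(raw, 2)
  hits <- filter_redundant(raw, q)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$n_raw, 2)
  # representative is the lexicographically smallest assignment: the tree's
  # node 1 is its centre (must map to table node 2), nodes 2 and 3 are the
  # two leaves, so the representative is 2,1,3
  expect_equal(hits[[1]]$assignment, c(2L, 1L, 3L))

  # star-4 all-wildcard on a star: |Aut| = 3! leaf permutations, one hit
  tabs <- star_table("G", c("C", "C", "C"))
  qs <- make_query(enumerate_trees(4)[[1]], rep("*", 4))
  raws <- match_pattern(tabs, qs)
  expect_length(raws, factorial(3))
  expect_length(filter_redundant(raws, qs), 1)

  # already-unique matches pass through unchanged (centre label first)
  qlab <- make_query(enumerate_trees(3)[[1]], c("U", "A", "G"))
  rawl <- match_pattern(tab, qlab)
  expect_length(rawl, 1)
  expect_length(filter_redundant(rawl, qlab), 1)
})

test_that("relaxing constraints grows the hit set, tightening shrinks it", {
  set.seed(121)
  for (rep in 1:10) {
    tab <- random_table(sample(4:8, 1), maxmult = 3)
    qn <- sample(2:3, 1)
    tr <- enumerate_trees(qn)[[1]]
    hit_keys <- function(q) {
      vapply(filter_redundant(match_pattern(tab, q), q),
             function(h) paste(h$irns, collapse = ","), "")
    }
    # exact-k edges -> any
    strict <- make_query(tr, rep("*", qn), as.list(rep(2, qn - 1)))
    loose <- make_query(tr, rep("*", qn))
    expect_true(all(hit_keys(strict) %in% hit_keys(loose)))
    # wildcard -> specific base
    lab <- sample(c("A", "C", "G", "U"), 1)
    labs <- rep("*", qn); labs[1] <- lab
    expect_true(all(hit_keys(make_query(tr, labs)) %in% hit_keys(loose)))
  }
})

test_that("monomorphism finds patterns inside denser regions; induced mode
           does not", {
  # triangle of bonds: path-3 query fits as a monomorphism only
  df <- data.frame(donor_res = c(1, 2, 1), donor_base = "G",
                   donor_atom = c("N1", "N1", "N2"),
                   acceptor_res = c(2, 3, 3), acceptor_base = "G",
                   acceptor_atom = "O6", stringsAsFactors = FALSE)
  tab <- build_table(as_hbond_set(df))
  q <- make_query(enumerate_trees(3)[[1]], rep("*", 3))
  expect_length(filter_redundant(match_pattern(tab, q), q), 1)
  expect_length(match_pattern(tab, q, induced = TRUE), 0)
})

test_that("scan censuses a path-5 network correctly", {
  set.seed(131)
  spec <- fixture_spec(c("G", "C", "A", "U", "G"),
                       data.frame(i = 1:4, j = 2:5, nbonds = 1))
  tab <- build_table(detect_hbonds(
    parse_structure(paste(generate_fixture(spec), collapse = "\n"))))
  sc <- scan_table(tab, 2:5)
  counts <- stats::setNames(sc$summary$n_hits, sc$summary$pattern)
  # sub-tree census of a 5-path, countable by hand: 4 pairs, 3 paths-3,
  # 2 paths-4, 0 stars, 1 path-5
  expect_equal(unname(counts["n2.t1"]), 4)
  expect_equal(unname(counts["n3.t1"]), 3)
  expect_equal(sum(counts[grep("^n4", names(counts))]), 2)
  expect_equal(unname(counts["n5.t1"]), 1)  # path shape
  expect_equal(sum(counts[grep("^n5", names(counts))]), 1)
})

test_that("scan of an empty table is all zeros", {
  empty <- build_table(as_hbond_set(data.frame(
    donor_res = integer(), donor_base = character(),
    donor_atom = character(), acceptor_res = integer(),
    acceptor_base = character(), acceptor_atom = character())))
  sc <- scan_table(empty, 2:4)
  expect_true(all(sc$summary$n_hits == 0))
  expect_length(sc$unions, 0)
})

test_that("deterministic output order for matches and hits", {
  set.seed(141)
  tab <- random_table(7)
  q <- random_query(3)
  expect_identical(match_keys(match_pattern(tab, q)),
                   match_keys(match_pattern(tab, q)))
})
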