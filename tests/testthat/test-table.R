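triple_bonds <- function() {
  as_hbond_set(data.frame(
    donor_chain = "A",
    donor_res = c(9, 23, 23, 12), donor_base = c("A", "A", "A", "U"),
    donor_atom = c("N6", "N6", "N6", "N3"),
    acceptor_chain = "A",
    acceptor_res = c(23, 9, 12, 23), acceptor_base = c("A", "A", "U", "A"),
    acceptor_atom = c("N7", "N7", "O4", "N1"),
    stringsAsFactors = FALSE))
}

test_that("the A9.A23.U12 triple builds the expected hub topology", {
  tab <- build_table(triple_bonds())
  expect_equal(nrow(tab$nodes), 3)
  adj <- table_adjacency(tab)
  hub <- "A23"
  expect_setequal(colnames(adj)[adj[hub, ] > 0], c("A9", "U12"))
  expect_true(all(adj[hub, c("A9", "U12")] == 2))
  # IRN is the rank in residue order: A9 -> 1, U12 -> 2, A23 -> 3
  expect_equal(tab$nodes$irn[match(c("A9", "U12", "A23"), tab$nodes$label)],
               c(1L, 2L, 3L))
})

test_that("an empty bond list gives an empty table", {
  tab <- build_table(as_hbond_set(data.frame(
    donor_res = integer(), donor_base = character(),
    donor_atom = character(), acceptor_res = integer(),
    acceptor_base = character(), acceptor_atom = character())))
  expect_equal(nrow(tab$nodes), 0)
  expect_equal(nrow(tab$edges), 0)
  expect_equal(write_table(tab), character())
})

test_that("three bonds in a line force a path with degrees 1,2,1 twice", {
  df <- data.frame(
    donor_res = c(1, 2, 3), donor_base = "G", donor_atom = "N1",
    acceptor_res = c(2, 3, 4), acceptor_base = "C", acceptor_atom = "O2",
    stringsAsFactors = FALSE)
  tab <- build_table(as_hbond_set(df))
  deg <- colSums(table_adjacency(tab) > 0)
  expect_equal(sort(unname(deg)), c(1, 1, 2, 2))
})

test_that("handshake identity holds on random tables", {
  set.seed(61)
  for (rep in 1:10) {
    tab <- random_table(sample(3:9, 1))
    adj <- table_adjacency(tab)
    expect_equal(sum(adj), 2 * sum(tab$edges$nbonds))
    expect_true(all(diag(adj) == 0))
    # irn is a bijection onto 1..n
    expect_setequal(tab$nodes$irn, seq_len(nrow(tab$nodes)))
  }
})

test_that("duplicate identical bond records are dropped with a warning", {
  df <- data.frame(donor_res = c(1, 1), donor_base = "A", donor_atom = "N6",
                   acceptor_res = c(2, 2), acceptor_base = "U",
                   acceptor_atom = "O4", stringsAsFactors = FALSE)
  expect_warning(tab <- build_table(as_hbond_set(df)), "duplicate")
  expect_equal(tab$edges$nbonds, 1L)
})

test_that("the worked bond codes encode and decode as stated", {
  # from U12's perspective: A23 N6 donates to U12 O4 -> "-1604";
  # U12 N3 donates to A23 N1 -> "1311"
  expect_equal(encode_bond(list(donor_atom = "N6", acceptor_atom = "O4"),
                           partner_is_donor = TRUE), "-1604")
  expect_equal(encode_bond(list(donor_atom = "N3", acceptor_atom = "N1"),
                           partner_is_donor = FALSE), "1311")
  d <- decode_bond("-1604")
  expect_equal(d$donor_atom, "N6")
  expect_equal(d$acceptor_atom, "O4")
  expect_true(d$partner_is_donor)
  d2 <- decode_bond("1311")
  expect_equal(d2$donor_atom, "N3")
  expect_equal(d2$acceptor_atom, "N1")
  expect_false(d2$partner_is_donor)
})

test_that("encode/decode round-trips, including the two-digit fallback", {
  set.seed(71)
  for (rep in 1:50) {
    bond <- list(donor_atom = paste0(sample(c("N", "O"), 1), sample(1:9, 1)),
                 acceptor_atom = paste0(sample(c("N", "O"), 1),
                                        sample(1:9, 1)))
    flip <- sample(c(TRUE, FALSE), 1)
    d <- decode_bond(encode_bond(bond, flip))
    expect_equal(d$donor_atom, bond$donor_atom)
    expect_equal(d$acceptor_atom, bond$acceptor_atom)
    expect_equal(d$partner_is_donor, flip)
  }
  # atom positions >= 10 cannot be packed into four digits
  code <- encode_bond(list(donor_atom = "N10", acceptor_atom = "O4"), TRUE)
  expect_equal(code, "-N10>O4")
  d <- decode_bond(code)
  expect_equal(d$donor_atom, "N10")
  expect_true(d$partner_is_donor)
  expect_error(decode_bond("12x4"), "malformed")
})

test_that("text serialization round-trips the graph", {
  graph_view <- function(tab) {
    edges <- lapply(seq_len(nrow(tab$edges)), function(r) {
      e <- tab$edges[r, ]
      b <- e$bonds[[1]]
      list(i = e$i, j = e$j, n = e$nbonds,
           bonds = sort(paste(b$donor_irn, b$donor_atom,
                              b$acceptor_irn, b$acceptor_atom)))
    })
    list(nodes = tab$nodes[, c("irn", "chain", "res_seq", "icode",
                               "base_code")],
         edges = edges)
  }
  set.seed(81)
  for (rep in 1:8) {
    tab <- random_table(sample(2:8, 1), maxmult = 2)
    back <- read_table(write_table(tab))
    expect_equal(graph_view(back), graph_view(tab))
  }
  # worked triple round-trip
  tab <- build_table(triple_bonds())
  expect_equal(graph_view(read_table(write_table(tab))), graph_view(tab))
  # hand-written two-node table
  txt <- c("NODE 1 G B:5 1", "  2 1 1102", "NODE 2 C B:6 1", "  1 1 -1102")
  tab2 <- read_table(txt)
  expect_equal(nrow(tab2$nodes), 2)
  expect_equal(tab2$edges$nbonds, 1L)
  expect_equal(tab2$edges$bonds[[1]]$donor_atom, "N1")
  expect_equal(tab2$edges$bonds[[1]]$acceptor_atom, "O2")
  expect_error(read_table("NODE garbled"), "malformed")
})

test_that("the JSON twin carries the full bond detail", {
  tab <- build_table(triple_bonds())
  js <- jsonlite::fromJSON(write_table_json(tab), simplifyVector = TRUE)
  expect_equal(nrow(js$nodes), 3)
  expect_equal(length(js$edges$i), 2)
})
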