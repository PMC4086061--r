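# Shared test machinery: hand-built structures, random connection tables,
# and the independent exhaustive-assignment matching oracle.

# a basenet_structure assembled directly from atom coordinate lists;
# each base is list(chain, res, icode, code, atoms = data.frame(name,
# element, x, y, z))
make_structure <- function(bases, source_id = "<test>") {
  structure(list(
    source_id = source_id, model_number = 1L,
    bases = lapply(bases, function(b) {
      at <- b$atoms
      at$occupancy <- at$occupancy %||% 1
      at$altloc <- at$altloc %||% ""
      list(chain_id = b$chain %||% "A", res_seq = b$res,
           icode = b$icode %||% "", res_name = b$code, base_code = b$code,
           atoms = at)
    })), class = "basenet_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a template-based base translated/rotated into position
placed_base <- function(code, res, offset = c(0, 0), angle = 0, chain = "A") {
  tpl <- base_template(code)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- sweep(tpl[, 1:2] %*% t(R), 2, offset, `+`)
  list(chain = chain, res = res, code = code,
       atoms = data.frame(name = rownames(tpl),
                          element = attr(tpl, "element"),
                          x = xy[, 1], y = xy[, 2], z = 0,
                          stringsAsFactors = FALSE))
}

# random connection table on n nodes with random multiplicities and labels
random_table <- function(n, p = 0.35, maxmult = 3, max_edges = 15) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- sample(maxmult, 1)
    }
    ne <- sum(adj > 0) / 2
    if (ne >= 1 && ne <= max_edges) break
  }
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j] > 0) {
      for (m in seq_len(adj[i, j])) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor_res = i, donor_base = "A", donor_atom = paste0("N", m),
          acceptor_res = j, acceptor_base = "A",
          acceptor_atom = paste0("O", m), stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  codes <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  df$donor_base <- codes[df$donor_res]
  df$acceptor_base <- codes[df$acceptor_res]
  build_table(as_hbond_set(df))
}

# exhaustive enumeration over all injective assignments: the matching oracle
brute_force_matches <- function(tab, q) {
  Tm <- table_adjacency(tab)
  nt <- nrow(tab$nodes)
  nq <- q$tree$n
  if (nt < nq) return(character())
  ok <- function(assign) {
    for (r in seq_len(nrow(q$tree$edges))) {
      m <- Tm[assign[q$tree$edges[r, 1]], assign[q$tree$edges[r, 2]]]
      cons <- q$constraints[r, ]
      good <- switch(cons$mode, any = m >= 1, exact = m == cons$k,
                     atleast = m >= cons$k)
      if (!good) return(FALSE)
    }
    for (i in seq_len(nq)) {
      if (q$labels[i] != "*" &&
          tab$nodes$base_code[assign[i]] != q$labels[i]) return(FALSE)
    }
    TRUE
  }
  res <- character()
  rec <- function(assign) {
    if (length(assign) == nq) {
      if (ok(assign)) res <<- c(res, paste(assign, collapse = ","))
      return(invisible(NULL))
    }
    for (a in setdiff(seq_len(nt), assign)) rec(c(assign, a))
  }
  rec(integer())
  sort(res)
}

match_keys <- function(matches) {
  sort(vapply(matches, function(m) paste(m$assignment, collapse = ","), ""))
}

# random labeled query over a random tree shape
random_query <- function(qn) {
  trees <- enumerate_trees(qn)
  tr <- trees[[sample(length(trees), 1)]]
  labs <- ifelse(stats::runif(qn) < 0.5, "*",
                 sample(c("A", "C", "G", "U"), qn, replace = TRUE))
  cons <- lapply(seq_len(qn - 1), function(i) {
    if (stats::runif(1) < 0.5) NULL else sample(1:2, 1)
  })
  make_query(tr, labs, cons)
}

# intended edge multiset of a fixture spec as a named count vector
spec_edge_counts <- function(spec) {
  e <- spec$edges
  stats::setNames(e$nbonds, paste(pmin(e$i, e$j), pmax(e$i, e$j)))
}

detected_edge_counts <- function(bonds) {
  key <- paste(pmin(bonds$donor_index, bonds$acceptor_index),
               pmax(bonds$donor_index, bonds$acceptor_index))
  tab <- table(key)
  stats::setNames(as.integer(tab), names(tab))
}
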