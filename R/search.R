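# Ullmann subgraph matching of labeled tree queries against connection
# tables. Semantics are subgraph MONOMORPHISM by default: every query edge
# must be realized, but extra bonds among the matched bases are allowed, so
# e.g. each of two interconnected quadruples is still found inside the
# larger octuple they form. An induced mode forbids such extra edges.

.label_ok <- function(label, base_code) {
  label == WILDCARD | label == base_code
}

.constraint_ok <- function(mult, mode, k) {
  switch(mode,
         any = mult >= 1L,
         exact = mult == k,
         atleast = mult >= k,
         stop("unknown constraint mode '", mode, "'", call. = FALSE))
}

# Ullmann compatibility-matrix refinement: a candidate (i, a) survives only
# if every query neighbour j of i has some distinct candidate b adjacent to
# a under the (i, j) edge constraint. Iterated to fixpoint.
.refine <- function(M, qadj, qcons, Tm) {
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(M))) {
      for (a in which(M[i, ])) {
        ok <- TRUE
        for (jx in seq_along(qadj[[i]])) {
          j <- qadj[[i]][jx]
          cons <- qcons[[i]][[jx]]
          support <- FALSE
          for (b in which(M[j, ])) {
            if (b != a && .constraint_ok(Tm[a, b], cons$mode, cons$k)) {
              support <- TRUE
              break
            }
          }
          if (!support) { ok <- FALSE; break }
        }
        if (!ok) { M[i, a] <- FALSE; changed <- TRUE }
      }
    }
    if (!changed) return(M)
  }
}

#' Match a tree query against a connection table
#'
#' Finds every injective assignment of query nodes to table bases such that
#' each query node's label is compatible (wildcard matches any base) and
#' each query edge maps onto a table edge satisfying its bond-count
#' constraint. Implementation: Ullmann's algorithm - a boolean
#' compatibility matrix over (query node, base) pairs is pruned by node
#' label, partner count and neighbourhood support iterated to fixpoint,
#' then completed by depth-first assignment with re-refinement, candidates
#' taken in ascending IRN for determinism.
#'
#' @param table a `connection_table`.
#' @param query a `query_pattern`.
#' @param induced use induced-subgraph semantics: table edges between the
#'   images of non-adjacent query nodes disqualify the assignment. Default
#'   FALSE (monomorphism).
#' @return list of matches; each match has `assignment` (query node ->
#'   IRN), `bases` (rows of `table$nodes`) and `bonds` (one data frame per
#'   query edge with the realizing hydrogen bonds).
#' @export
match_pattern <- function(table, query, induced = FALSE) {
  stopifnot(inherits(table, "connection_table"),
            inherits(query, "query_pattern"))
  nq <- query$tree$n
  nt <- nrow(table$nodes)
  if (nt < nq) return(list())
  Tm <- table_adjacency(table)

  qedges <- query$tree$edges
  qadj <- vector("list", nq)
  qcons <- vector("list", nq)
  for (r in seq_len(nrow(qedges))) {
    i <- qedges[r, 1]; j <- qedges[r, 2]
    cons <- as.list(query$constraints[r, ])
    qadj[[i]] <- c(qadj[[i]], j); qcons[[i]] <- c(qcons[[i]], list(cons))
    qadj[[j]] <- c(qadj[[j]], i); qcons[[j]] <- c(qcons[[j]], list(cons))
  }
  qdeg <- lengths(qadj)
  tdeg <- colSums(Tm > 0L)

  M <- matrix(FALSE, nq, nt)
  for (i in seq_len(nq)) {
    M[i, ] <- .label_ok(query$labels[i], table$nodes$base_code) &
      tdeg >= qdeg[i]
  }
  M <- .refine(M, qadj, qcons, Tm)
  if (any(rowSums(M) == 0L)) return(list())

  # assignment order: connected sweep starting from the most constrained node
  order_q <- integer(0)
  remaining <- seq_len(nq)
  cur <- remaining[order(-qdeg[remaining], remaining)][1]
  order_q <- cur; remaining <- setdiff(remaining, cur)
  while (length(remaining)) {
    frontier <- remaining[vapply(remaining, function(v)
      any(qadj[[v]] %in% order_q), logical(1))]
    if (!length(frontier)) frontier <- remaining
    cur <- frontier[order(-qdeg[frontier], frontier)][1]
    order_q <- c(order_q, cur); remaining <- setdiff(remaining, cur)
  }

  results <- list()
  assign <- rep(NA_integer_, nq)
  dfs <- function(depth, M) {
    if (depth > nq) {
      results[[length(results) + 1L]] <<- assign
      return(invisible(NULL))
    }
    i <- order_q[depth]
    for (a in which(M[i, ])) {
      if (a %in% assign) next
      ok <- TRUE
      for (jx in seq_along(qadj[[i]])) {
        j <- qadj[[i]][jx]
        if (!is.na(assign[j])) {
          cons <- qcons[[i]][[jx]]
          if (!.constraint_ok(Tm[a, assign[j]], cons$mode, cons$k)) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok && induced) {
        for (j in seq_len(nq)) {
          if (!is.na(assign[j]) && !(j %in% qadj[[i]]) &&
              Tm[a, assign[j]] > 0L) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      assign[i] <<- a
      M2 <- M
      M2[i, ] <- FALSE; M2[i, a] <- TRUE
      M2[-i, a] <- FALSE
      M2 <- .refine(M2, qadj, qcons, Tm)
      if (all(rowSums(M2) > 0L)) dfs(depth + 1L, M2)
      assign[i] <<- NA_integer_
    }
    invisible(NULL)
  }
  dfs(1L, M)

  ekey <- paste(pmin(table$edges$i, table$edges$j),
                pmax(table$edges$i, table$edges$j))
  lapply(results, function(a) {
    bonds <- lapply(seq_len(nrow(qedges)), function(r) {
      u <- a[qedges[r, 1]]; v <- a[qedges[r, 2]]
      table$edges$bonds[[match(paste(min(u, v), max(u, v)), ekey)]]
    })
    list(assignment = a,
         bases = table$nodes[match(a, table$nodes$irn), , drop = FALSE],
         bonds = bonds)
  })
}

#' Collapse order-permuted matches into unique hits
#'
#' A symmetric query retrieves the same base set once per compatible node
#' ordering; this filter keeps one hit per distinct base set, represented
#' by the lexicographically smallest assignment.
#'
#' @param matches output of [match_pattern()] for one query.
#' @param query the query the matches came from (kept on each hit).
#' @return list of hits; each hit has the representative `assignment`, the
#'   sorted `irns`, `bases`, the union of realizing `bonds`, and `n_raw`
#'   (how many raw matches it collapses).
#' @export
filter_redundant <- function(matches, query = NULL) {
  if (length(matches) == 0L) return(list())
  keys <- vapply(matches, function(m)
    paste(sort(m$assignment), collapse = ","), character(1))
  out <- list()
  for (k in unique(keys)) {
    grp <- matches[keys == k]
    reps <- do.call(rbind, lapply(grp, `[[`, "assignment"))
    best <- grp[[do.call(order, as.data.frame(reps))[1]]]
    bonds <- unique(do.call(rbind, best$bonds))
    rownames(bonds) <- NULL
    out[[length(out) + 1L]] <- list(
      query = query, assignment = best$assignment,
      irns = sort(best$assignment),
      bases = best$bases[order(best$assignment), , drop = FALSE],
      bonds = bonds, n_raw = length(grp))
  }
  # deterministic order over hits
  out[order(vapply(out, function(h) paste(h$irns, collapse = ","),
                   character(1)), method = "radix")]
}

# connected unions of hits: two hits are joined when their base sets share
# a base or are linked by any table edge; components with > 1 member are
# larger interaction networks (e.g. two quadruples forming an octuple)
.hit_unions <- function(hits, table) {
  nh <- length(hits)
  if (nh < 2L) return(list())
  Tm <- table_adjacency(table)
  parent <- seq_len(nh)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(nh - 1L)) {
    for (b in (a + 1L):nh) {
      ia <- hits[[a]]$irns; ib <- hits[[b]]$irns
      joined <- length(intersect(ia, ib)) > 0L ||
        any(Tm[ia, ib, drop = FALSE] > 0L)
      if (joined) parent[find(a)] <- find(b)
    }
  }
  comp <- vapply(seq_len(nh), find, integer(1))
  groups <- split(seq_len(nh), comp)
  groups <- groups[lengths(groups) > 1L]
  lapply(unname(groups), function(ix) {
    list(members = ix,
         irns = sort(unique(unlist(lapply(hits[ix], `[[`, "irns")))))
  })
}

#' Scan a structure for every tree pattern of the requested sizes
#'
#' Runs each enumerated tree shape with all-wildcard labels and
#' unconstrained (at least one bond) edges against the table, filters
#' redundant hits, and tallies the per-pattern counts - the summary-first
#' output flow. Overlapping hits are kept, and connected unions of hits
#' (hit base sets that overlap or are bridged by a bond) are reported so
#' that larger composite networks are surfaced.
#'
#' @param table a `connection_table`.
#' @param sizes integer vector, subset of 2:6 by default; any sizes >= 2
#'   are accepted.
#' @param induced passed to [match_pattern()].
#' @return object of class `basenet_scan`: list with `summary` (data frame:
#'   size, type_index, degree sequence, canonical code, n_hits), `hits`
#'   (named list per pattern) and `unions` (connected unions of hits).
#' @export
scan_table <- function(table, sizes = 2:6, induced = FALSE) {
  stopifnot(inherits(table, "connection_table"))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2L)) stop("pattern sizes must be >= 2", call. = FALSE)
  summ <- list(); hits <- list()
  for (n in sizes) {
    for (tr in enumerate_trees(n)) {
      q <- make_query(tr, rep(WILDCARD, n))
      h <- filter_redundant(match_pattern(table, q, induced = induced), q)
      key <- sprintf("n%d.t%d", n, tr$type_index)
      hits[[key]] <- h
      summ[[key]] <- data.frame(
        pattern = key, size = n, type_index = tr$type_index,
        degrees = paste(tr$degrees, collapse = ","),
        canonical_code = tr$canonical_code, n_hits = length(h),
        stringsAsFactors = FALSE)
    }
  }
  all_hits <- unlist(unname(hits), recursive = FALSE)
  structure(list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 hits = hits,
                 unions = .hit_unions(all_hits, table)),
            class = "basenet_scan")
}

#' @export
print.basenet_scan <- function(x, ...) {
  cat("pattern scan summary\n")
  print(x$summary, row.names = FALSE)
  if (length(x$unions)) {
    cat("connected unions of hits:\n")
    for (u in x$unions) {
      cat("  ", length(u$members), "hits over", length(u$irns),
          "bases (irn", paste(u$irns, collapse = ","), ")\n")
    }
  }
  invisible(x)
}
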