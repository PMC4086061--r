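# Query shapes: the free trees on 2..6 nodes (pair, triple, ..., sextuple),
# one representative per isomorphism class, identified by an AHU canonical
# form rooted at the tree centre.

.tree_adjlist <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

.check_tree <- function(edges, n) {
  edges <- as.matrix(edges)
  if (nrow(edges) != n - 1L) stop("not a tree: expected ", n - 1L,
                                  " edges, got ", nrow(edges), call. = FALSE)
  adj <- .tree_adjlist(edges, n)
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen)) stop("not a tree: graph is disconnected", call. = FALSE)
  adj
}

.tree_centers <- function(adj, n) {
  if (n == 1L) return(1L)
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  leaves <- which(deg <= 1L)
  remaining <- n
  while (remaining > 2L) {
    remaining <- remaining - length(leaves)
    nxt <- integer()
    for (v in leaves) {
      alive[v] <- FALSE
      for (w in adj[[v]]) {
        if (alive[w]) {
          deg[w] <- deg[w] - 1L
          if (deg[w] == 1L) nxt <- c(nxt, w)
        }
      }
    }
    leaves <- nxt
  }
  sort(which(alive))
}

.rooted_code <- function(adj, v, parent) {
  kids <- setdiff(adj[[v]], parent)
  if (length(kids) == 0L) return("()")
  sub <- vapply(kids, function(k) .rooted_code(adj, k, v), character(1))
  paste0("(", paste(sort(sub, method = "radix"), collapse = ""), ")")
}

#' Canonical form of a free tree
#'
#' Computes a canonical string for an unlabeled tree: the AHU encoding
#' rooted at the tree centre. Two trees get the same code exactly when they
#' are isomorphic, for any numbering of their nodes. Bicentral trees (two
#' centres) are encoded by the sorted pair of codes of the two halves
#' obtained by cutting the central edge.
#'
#' @param edges two-column matrix/data frame of node index pairs (1-based).
#' @param n number of nodes; defaults to the largest index in `edges`.
#' @return canonical code string.
#' @export
canonical_code <- function(edges, n = max(edges)) {
  edges <- as.matrix(edges)
  adj <- .check_tree(edges, n)
  centers <- .tree_centers(adj, n)
  if (length(centers) == 1L) {
    .rooted_code(adj, centers[1], 0L)
  } else {
    halves <- sort(c(.rooted_code(adj, centers[1], centers[2]),
                     .rooted_code(adj, centers[2], centers[1])),
                   method = "radix")
    paste0("[", halves[1], "|", halves[2], "]")
  }
}

.tree_pattern <- function(edges, n, code = canonical_code(edges, n),
                          type_index = NA_integer_) {
  edges <- as.matrix(edges)
  colnames(edges) <- c("i", "j")
  adj <- .tree_adjlist(edges, n)
  structure(list(n = n, edges = edges, canonical_code = code,
                 type_index = type_index,
                 degrees = sort(lengths(adj), decreasing = TRUE)),
            class = "tree_pattern")
}

#' Enumerate the free trees on n nodes
#'
#' Produces exactly one representative per isomorphism class of trees on
#' `n` unlabeled nodes, deterministically ordered by canonical code, with
#' `type_index` assigned in that order (type I, II, ... within a size
#' class). These are the query shapes: 1 pair, 1 triple, 2 quadruples,
#' 3 quintuples and 6 sextuples. Trees are grown by attaching a leaf to
#' every node of every (n-1)-node tree and de-duplicating by canonical
#' code.
#'
#' @param n node count, at least 2.
#' @return list of `tree_pattern` objects.
#' @examples
#' length(enumerate_trees(6))  # 6
#' @export
enumerate_trees <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("tree size must be an integer >= 2",
                               call. = FALSE)
  trees <- list(matrix(c(1L, 2L), ncol = 2))
  size <- 2L
  while (size < n) {
    grown <- list(); codes <- character()
    for (e in trees) {
      for (v in seq_len(size)) {
        e2 <- rbind(e, c(v, size + 1L))
        code <- canonical_code(e2, size + 1L)
        if (!(code %in% codes)) {
          codes <- c(codes, code)
          grown[[length(grown) + 1L]] <- e2
        }
      }
    }
    trees <- grown
    size <- size + 1L
  }
  codes <- vapply(trees, function(e) canonical_code(e, n), character(1))
  ord <- order(codes, method = "radix")
  out <- vector("list", length(trees))
  for (k in seq_along(ord)) {
    out[[k]] <- .tree_pattern(trees[[ord[k]]], n, codes[ord[k]],
                              type_index = k)
  }
  out
}

.sketch_tree <- function(tree) {
  adj <- .tree_adjlist(tree$edges, tree$n)
  root <- .tree_centers(adj, tree$n)[1]
  lines <- character()
  walk <- function(v, parent, depth) {
    lines <<- c(lines, paste0(strrep("  ", depth),
                              if (depth > 0) "+- " else "", v))
    for (w in sort(setdiff(adj[[v]], parent))) walk(w, v, depth + 1L)
  }
  walk(root, 0L, 0L)
  lines
}

#' @export
print.tree_pattern <- function(x, ...) {
  cat(sprintf("tree on %d nodes (type %s), degree sequence (%s)\n",
              x$n, if (is.na(x$type_index)) "?" else
                as.character(utils::as.roman(x$type_index)),
              paste(x$degrees, collapse = ",")))
  cat("  edges:", paste(apply(x$edges, 1, paste, collapse = "-"),
                        collapse = " "), "\n")
  cat(paste0("  ", .sketch_tree(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Wildcard node label
#' @export
WILDCARD <- "*"

.parse_constraint <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) {
    return(list(mode = "any", k = 1L))
  }
  if (is.character(x)) {
    x <- trimws(x)
    if (x %in% c("any", "*", "")) return(list(mode = "any", k = 1L))
    if (grepl("^>=[0-9]+$", x)) {
      return(list(mode = "atleast", k = as.integer(sub("^>=", "", x))))
    }
    if (grepl("^[0-9]+$", x)) return(list(mode = "exact", k = as.integer(x)))
    stop("cannot parse edge constraint '", x, "'", call. = FALSE)
  }
  if (is.numeric(x)) return(list(mode = "exact", k = as.integer(x)))
  if (is.list(x)) return(list(mode = x$mode, k = as.integer(x$k %||% 1L)))
  stop("cannot parse edge constraint", call. = FALSE)
}

#' Build a labeled tree query
#'
#' Attaches base labels and per-edge bond-count constraints to a tree
#' shape. A node label is a base code or the wildcard `"*"` (matches any
#' library base); an edge constraint is `"any"` (at least one bond, the
#' default), an integer `k` (exactly k bonds) or `">=k"` (at least k).
#'
#' @param tree a `tree_pattern`, or a two-column edge matrix.
#' @param labels character vector, one per node; `"*"` or NA for wildcard.
#' @param constraints optional list/vector of per-edge constraints in the
#'   order of the tree's edge list; NULL means all-`"any"`.
#' @param library base library used to validate labels.
#' @return an object of class `query_pattern`.
#' @examples
#' q <- make_query(enumerate_trees(3)[[1]], c("A", "A", "U"),
#'                 constraints = list(2, 2))
#' @export
make_query <- function(tree, labels, constraints = NULL,
                       library = base_library()) {
  if (!inherits(tree, "tree_pattern")) {
    tree <- .tree_pattern(as.matrix(tree), max(tree))
  }
  labels <- as.character(labels)
  labels[is.na(labels)] <- WILDCARD
  if (length(labels) != tree$n) {
    stop("need ", tree$n, " node labels, got ", length(labels), call. = FALSE)
  }
  bad <- setdiff(labels, c(WILDCARD, names(library)))
  if (length(bad)) {
    stop("unknown base label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ne <- nrow(tree$edges)
  if (is.null(constraints)) constraints <- rep(list(NULL), ne)
  if (length(constraints) != ne) {
    stop("need ", ne, " edge constraints, got ", length(constraints),
         call. = FALSE)
  }
  parsed <- lapply(constraints, .parse_constraint)
  k <- vapply(parsed, `[[`, integer(1), "k")
  if (any(k < 1L)) stop("edge bond counts must be positive", call. = FALSE)
  structure(list(tree = tree, labels = labels,
                 constraints = data.frame(
                   mode = vapply(parsed, `[[`, character(1), "mode"),
                   k = k, stringsAsFactors = FALSE)),
            class = "query_pattern")
}

#' @export
print.query_pattern <- function(x, ...) {
  cat("query on", x$tree$n, "nodes; labels:",
      paste(x$labels, collapse = " "), "\n")
  cons <- ifelse(x$constraints$mode == "any", "any",
                 ifelse(x$constraints$mode == "exact",
                        paste0("=", x$constraints$k),
                        paste0(">=", x$constraints$k)))
  cat("  edges:", paste(sprintf("%d-%d(%s)", x$tree$edges[, 1],
                                x$tree$edges[, 2], cons), collapse = " "), "\n")
  invisible(x)
}
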