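# Connection tables: the per-structure graph of hydrogen-bonded bases.
# Nodes are bases with an internal residue number (IRN); edges carry the
# bond multiplicity and signed donor/acceptor atom-pair codes. The IRN is
# the 1-based rank of a bond-participating residue in structure order; the
# author identity (chain, residue number, insertion code) is kept alongside.

.node_label <- function(base_code, res_seq, icode) {
  paste0(base_code, res_seq, ifelse(nzchar(icode), icode, ""))
}

.empty_table <- function() {
  nodes <- data.frame(irn = integer(), index = integer(), chain = character(),
                      res_seq = integer(), icode = character(),
                      base_code = character(), label = character(),
                      stringsAsFactors = FALSE)
  edges <- data.frame(i = integer(), j = integer(), nbonds = integer())
  edges$bonds <- list()
  structure(list(nodes = nodes, edges = edges), class = "connection_table")
}

#' Build a connection table from a hydrogen-bond list
#'
#' Converts a bond list into the per-structure graph: one node per base
#' taking part in at least one bond, with internal residue numbers (IRN)
#' assigned 1-based in order of first appearance in the structure's residue
#' order, and one edge per unordered base pair carrying its bonds. Exact
#' duplicate bond records are dropped with a warning.
#'
#' @param bonds an `hbond_set` (see [detect_hbonds()], [as_hbond_set()]).
#' @return an object of class `connection_table`: a list with a `nodes` data
#'   frame (`irn`, author identity, `base_code`, `label`) and an `edges`
#'   data frame (`i`, `j` with i < j, `nbonds`, and a `bonds` list column of
#'   per-edge bond data frames keyed by IRN).
#' @export
build_table <- function(bonds) {
  if (!inherits(bonds, "hbond_set")) bonds <- as_hbond_set(bonds)
  if (nrow(bonds) == 0L) return(.empty_table())
  key <- paste(bonds$donor_index, bonds$donor_atom,
               bonds$acceptor_index, bonds$acceptor_atom, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate bond record(s) dropped",
            call. = FALSE)
    bonds <- bonds[!duplicated(key), , drop = FALSE]
  }
  idx <- sort(unique(c(bonds$donor_index, bonds$acceptor_index)))
  irn_of <- function(i) match(i, idx)
  side <- function(pref) {
    pick <- !duplicated(bonds[[paste0(pref, "_index")]])
    data.frame(index = bonds[[paste0(pref, "_index")]][pick],
               chain = bonds[[paste0(pref, "_chain")]][pick],
               res_seq = bonds[[paste0(pref, "_res")]][pick],
               icode = bonds[[paste0(pref, "_icode")]][pick],
               base_code = bonds[[paste0(pref, "_base")]][pick],
               stringsAsFactors = FALSE)
  }
  ident <- rbind(side("donor"), side("acceptor"))
  ident <- ident[!duplicated(ident$index), , drop = FALSE]
  ident <- ident[match(idx, ident$index), , drop = FALSE]
  nodes <- data.frame(irn = seq_along(idx), index = idx,
                      chain = ident$chain, res_seq = ident$res_seq,
                      icode = ident$icode, base_code = ident$base_code,
                      label = .node_label(ident$base_code, ident$res_seq,
                                          ident$icode),
                      stringsAsFactors = FALSE)

  di <- irn_of(bonds$donor_index); ai <- irn_of(bonds$acceptor_index)
  lo <- pmin(di, ai); hi <- pmax(di, ai)
  ekey <- paste(lo, hi, sep = "-")
  bond_rows <- data.frame(donor_irn = di, donor_atom = bonds$donor_atom,
                          acceptor_irn = ai, acceptor_atom = bonds$acceptor_atom,
                          distance = bonds$distance, stringsAsFactors = FALSE)
  groups <- split(seq_len(nrow(bonds)), ekey)
  ord <- order(vapply(groups, function(ix) lo[ix[1]] * 1e6 + hi[ix[1]],
                      numeric(1)))
  groups <- groups[ord]
  edges <- data.frame(
    i = vapply(groups, function(ix) lo[ix[1]], integer(1)),
    j = vapply(groups, function(ix) hi[ix[1]], integer(1)),
    nbonds = lengths(groups))
  edges$bonds <- lapply(groups, function(ix) {
    b <- bond_rows[ix, , drop = FALSE]
    rownames(b) <- NULL
    b
  })
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "connection_table")
}

#' Bond-multiplicity adjacency matrix of a connection table
#'
#' @param table a `connection_table`.
#' @return an integer matrix indexed by IRN; entry (i, j) is the number of
#'   hydrogen bonds between bases i and j.
#' @export
table_adjacency <- function(table) {
  n <- nrow(table$nodes)
  m <- matrix(0L, n, n)
  if (nrow(table$edges)) {
    for (r in seq_len(nrow(table$edges))) {
      e <- table$edges[r, ]
      m[e$i, e$j] <- m[e$j, e$i] <- e$nbonds
    }
  }
  dimnames(m) <- list(table$nodes$label, table$nodes$label)
  m
}

# ---- signed atom-pair bond codes ------------------------------------------

.code_digit <- c(N = "1", O = "0")

.atom_code_parts <- function(atom) {
  el <- substr(atom, 1, 1)
  pos <- sub("^[A-Za-z]+", "", atom)
  list(el = el, pos = pos,
       ok = el %in% names(.code_digit) && nchar(pos) == 1 &&
         grepl("^[0-9]$", pos))
}

#' Encode one hydrogen bond as a signed atom-pair code
#'
#' A bond is written as a signed 4-digit code from the perspective of one
#' endpoint (the listing base): donor element digit, donor atom position,
#' acceptor element digit, acceptor atom position, with element digits
#' 1 = nitrogen and 0 = oxygen. The sign is negative exactly when the
#' partner base (not the listing base) is the donor. For example, from the
#' perspective of a uridine accepting N6 -> O4 from an adenine, the code is
#' "-1604"; the same uridine donating N3 -> N1 gives "1311". Atoms with
#' two-digit positions or elements outside N/O cannot be packed into four
#' digits and fall back to an explicit signed "DONORATOM>ACCEPTORATOM"
#' token.
#'
#' @param bond a list or one-row data frame with `donor_atom` and
#'   `acceptor_atom`.
#' @param partner_is_donor logical: is the donor the partner base (i.e. not
#'   the listing base)?
#' @return a character code.
#' @export
encode_bond <- function(bond, partner_is_donor) {
  d <- .atom_code_parts(bond$donor_atom)
  a <- .atom_code_parts(bond$acceptor_atom)
  sign <- if (isTRUE(partner_is_donor)) "-" else ""
  if (d$ok && a$ok) {
    paste0(sign, .code_digit[[d$el]], d$pos, .code_digit[[a$el]], a$pos)
  } else {
    paste0(sign, bond$donor_atom, ">", bond$acceptor_atom)
  }
}

#' Decode a signed atom-pair bond code
#'
#' Inverse of [encode_bond()]: recovers the donor and acceptor atom names
#' and whether the donor is the partner base.
#'
#' @param code a character code such as `"-1604"`, `"1311"` or `"N6>O4"`.
#' @return a list with `donor_atom`, `acceptor_atom`, `partner_is_donor`.
#' @export
decode_bond <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  partner_is_donor <- startsWith(code, "-")
  body <- sub("^-", "", code)
  if (grepl(">", body, fixed = TRUE)) {
    at <- strsplit(body, ">", fixed = TRUE)[[1]]
    if (length(at) != 2L) stop("malformed bond code '", code, "'", call. = FALSE)
    return(list(donor_atom = at[1], acceptor_atom = at[2],
                partner_is_donor = partner_is_donor))
  }
  if (!grepl("^[0-9]{4}$", body)) {
    stop("malformed bond code '", code, "'", call. = FALSE)
  }
  digit_el <- c(`1` = "N", `0` = "O")
  dl <- digit_el[substr(body, 1, 1)]
  al <- digit_el[substr(body, 3, 3)]
  if (anyNA(c(dl, al))) stop("malformed bond code '", code, "'", call. = FALSE)
  list(donor_atom = paste0(dl, substr(body, 2, 2)),
       acceptor_atom = paste0(al, substr(body, 4, 4)),
       partner_is_donor = partner_is_donor)
}

# codes for one edge seen from node `from`
.edge_codes <- function(edge_bonds, from) {
  vapply(seq_len(nrow(edge_bonds)), function(r) {
    encode_bond(edge_bonds[r, ], partner_is_donor =
                  edge_bonds$donor_irn[r] != from)
  }, character(1))
}

# ---- text serialization ----------------------------------------------------

.fmt_identity <- function(chain, res_seq, icode) {
  paste0(ifelse(nzchar(chain), chain, "."), ":", res_seq,
         ifelse(nzchar(icode), icode, ""))
}

.parse_identity <- function(tok) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed identity '", tok, "'", call. = FALSE)
  chain <- if (parts[1] == ".") "" else parts[1]
  m <- regmatches(parts[2], regexec("^(-?[0-9]+)([A-Za-z]?)$", parts[2]))[[1]]
  if (length(m) == 0L) stop("malformed identity '", tok, "'", call. = FALSE)
  list(chain = chain, res_seq = as.integer(m[2]), icode = m[3])
}

#' Serialize a connection table as text
#'
#' One block per node: a header line `NODE irn base_code chain:resseq
#' n_partners`, then one indented line per partner with the partner IRN, the
#' bond count and the signed atom-pair codes from the listing node's
#' perspective. [read_table()] inverts this losslessly at the graph level
#' (node identities, edge multiplicities, codes); per-bond distances are not
#' part of the text format.
#'
#' @param table a `connection_table`.
#' @return a character vector of lines.
#' @export
write_table <- function(table) {
  out <- character()
  adj_rows <- function(irn) {
    e <- table$edges
    which(e$i == irn | e$j == irn)
  }
  for (r in seq_len(nrow(table$nodes))) {
    nd <- table$nodes[r, ]
    er <- adj_rows(nd$irn)
    out <- c(out, paste("NODE", nd$irn, nd$base_code,
                        .fmt_identity(nd$chain, nd$res_seq, nd$icode),
                        length(er)))
    for (k in er) {
      e <- table$edges[k, ]
      partner <- if (e$i == nd$irn) e$j else e$i
      codes <- .edge_codes(e$bonds[[1]], from = nd$irn)
      out <- c(out, paste(" ", partner, e$nbonds, paste(codes, collapse = " ")))
    }
  }
  out
}

#' Read a connection table from its text serialization
#'
#' @param text character vector of lines (or one string with newlines) as
#'   produced by [write_table()].
#' @return a `connection_table`; bond distances are NA (not serialized).
#' @export
read_table <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- list(); partner_of <- list(); cur <- NA_integer_
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (tok[1] == "NODE") {
      if (length(tok) != 5L) {
        stop("malformed node line ", ln, ": ", lines[ln], call. = FALSE)
      }
      id <- .parse_identity(tok[4])
      cur <- as.integer(tok[2])
      nodes[[length(nodes) + 1L]] <- data.frame(
        irn = cur, chain = id$chain, res_seq = id$res_seq, icode = id$icode,
        base_code = tok[3], stringsAsFactors = FALSE)
    } else {
      if (is.na(cur) || length(tok) < 2L) {
        stop("malformed partner line ", ln, ": ", lines[ln], call. = FALSE)
      }
      partner_of[[length(partner_of) + 1L]] <- list(
        from = cur, to = as.integer(tok[1]), nbonds = as.integer(tok[2]),
        codes = tok[-(1:2)])
    }
  }
  if (length(nodes) == 0L) return(.empty_table())
  nodes <- do.call(rbind, nodes)
  nodes$index <- seq_len(nrow(nodes))
  nodes$label <- .node_label(nodes$base_code, nodes$res_seq, nodes$icode)
  nodes <- nodes[, c("irn", "index", "chain", "res_seq", "icode",
                     "base_code", "label")]

  seen <- character()
  erows <- list()
  for (p in partner_of) {
    i <- min(p$from, p$to); j <- max(p$from, p$to)
    k <- paste(i, j)
    if (k %in% seen) next  # edge appears once from each endpoint
    seen <- c(seen, k)
    if (length(p$codes) != p$nbonds) {
      stop("bond count does not match code count on edge ", i, "-", j,
           call. = FALSE)
    }
    bonds <- do.call(rbind, lapply(p$codes, function(code) {
      d <- decode_bond(code)
      donor <- if (d$partner_is_donor) p$to else p$from
      acceptor <- if (d$partner_is_donor) p$from else p$to
      data.frame(donor_irn = donor, donor_atom = d$donor_atom,
                 acceptor_irn = acceptor, acceptor_atom = d$acceptor_atom,
                 distance = NA_real_, stringsAsFactors = FALSE)
    }))
    erows[[length(erows) + 1L]] <- list(i = i, j = j, bonds = bonds)
  }
  ord <- order(vapply(erows, function(e) e$i * 1e6 + e$j, numeric(1)))
  erows <- erows[ord]
  edges <- data.frame(i = vapply(erows, `[[`, integer(1), "i"),
                      j = vapply(erows, `[[`, integer(1), "j"),
                      nbonds = vapply(erows, function(e) nrow(e$bonds),
                                      integer(1)))
  edges$bonds <- lapply(erows, `[[`, "bonds")
  structure(list(nodes = nodes, edges = edges), class = "connection_table")
}

#' Serialize a connection table as JSON with full bond detail
#'
#' @param table a `connection_table`.
#' @param file optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
write_table_json <- function(table, file = NULL) {
  payload <- list(
    nodes = table$nodes[, c("irn", "chain", "res_seq", "icode",
                            "base_code", "label")],
    edges = lapply(seq_len(nrow(table$edges)), function(r) {
      e <- table$edges[r, ]
      list(i = e$i, j = e$j, nbonds = e$nbonds, bonds = e$bonds[[1]])
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' @export
print.connection_table <- function(x, ...) {
  cat("connection table:", nrow(x$nodes), "base(s),",
      sum(x$edges$nbonds), "hydrogen bond(s) on", nrow(x$edges), "edge(s)\n")
  if (nrow(x$nodes)) cat(paste0("  ", write_table(x), collapse = "\n"), "\n")
  invisible(x)
}
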