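# Hydrogen-bond network comparison of two similar structures (mutant vs
# wild-type, bound vs unbound): atomic-level gained/lost/shared bonds under
# an identity residue mapping on author numbering.

.res_key <- function(chain, res, icode) paste(chain, res, icode, sep = "\r")

.bond_keys <- function(bonds) {
  paste(.res_key(bonds$donor_chain, bonds$donor_res, bonds$donor_icode),
        bonds$donor_atom,
        .res_key(bonds$acceptor_chain, bonds$acceptor_res,
                 bonds$acceptor_icode),
        bonds$acceptor_atom, sep = "\t")
}

.residues_of <- function(x, bonds) {
  if (inherits(x, "basenet_structure")) {
    data.frame(
      chain = vapply(x$bases, `[[`, "", "chain_id"),
      res_seq = vapply(x$bases, function(b) as.integer(b$res_seq), integer(1)),
      icode = vapply(x$bases, `[[`, "", "icode"),
      base_code = vapply(x$bases, `[[`, "", "base_code"),
      stringsAsFactors = FALSE)
  } else {
    df <- rbind(
      data.frame(chain = bonds$donor_chain, res_seq = bonds$donor_res,
                 icode = bonds$donor_icode, base_code = bonds$donor_base,
                 stringsAsFactors = FALSE),
      data.frame(chain = bonds$acceptor_chain, res_seq = bonds$acceptor_res,
                 icode = bonds$acceptor_icode, base_code = bonds$acceptor_base,
                 stringsAsFactors = FALSE))
    df[!duplicated(.res_key(df$chain, df$res_seq, df$icode)), , drop = FALSE]
  }
}

#' Compare the hydrogen-bond networks of two structures
#'
#' Detects (or takes) the base-base hydrogen bonds of two structures and
#' reports which bonds are exclusive to each and which are shared, at
#' atomic resolution: a bond is identified by its (donor residue, donor
#' atom, acceptor residue, acceptor atom) tuple. Residues are paired
#' between the structures by identical author identity (chain, residue
#' number, insertion code); bonds touching a residue present in only one
#' structure are flagged in the `unmatched` column and reported with that
#' structure's exclusive set.
#'
#' @param a,b `basenet_structure` objects, or `hbond_set` bond lists
#'   already detected under the same parameters.
#' @param library,params passed to [detect_hbonds()] when `a`/`b` are
#'   structures. Both structures must be processed with the same criteria.
#' @return object of class `basenet_diff`: list with `only_a`, `only_b`,
#'   `shared` (data frame with `distance_a`/`distance_b`) and
#'   `unmatched_residues` (residues present in exactly one structure,
#'   with a `structure` column saying which).
#' @export
compare_structures <- function(a, b, library = base_library(),
                               params = default_params()) {
  bonds_a <- if (inherits(a, "hbond_set")) a else
    detect_hbonds(a, library, params)
  bonds_b <- if (inherits(b, "hbond_set")) b else
    detect_hbonds(b, library, params)

  res_a <- .residues_of(a, bonds_a)
  res_b <- .residues_of(b, bonds_b)
  ka <- .res_key(res_a$chain, res_a$res_seq, res_a$icode)
  kb <- .res_key(res_b$chain, res_b$res_seq, res_b$icode)
  if (length(intersect(ka, kb)) == 0L) {
    warning("no residues in common between the two structures; ",
            "every bond is exclusive", call. = FALSE)
  }
  unmatched <- rbind(
    cbind(structure = rep("a", sum(!(ka %in% kb))),
          res_a[!(ka %in% kb), , drop = FALSE]),
    cbind(structure = rep("b", sum(!(kb %in% ka))),
          res_b[!(kb %in% ka), , drop = FALSE]))
  rownames(unmatched) <- NULL

  # TRUE when a bond touches a residue absent from the other structure
  flag_unmatched <- function(bonds, other_keys) {
    !(.res_key(bonds$donor_chain, bonds$donor_res, bonds$donor_icode) %in%
        other_keys) |
      !(.res_key(bonds$acceptor_chain, bonds$acceptor_res,
                 bonds$acceptor_icode) %in% other_keys)
  }

  keys_a <- .bond_keys(bonds_a)
  keys_b <- .bond_keys(bonds_b)
  in_both_a <- keys_a %in% keys_b

  only_a <- as.data.frame(bonds_a)[!in_both_a, , drop = FALSE]
  only_a$unmatched <- flag_unmatched(only_a, kb)
  only_b <- as.data.frame(bonds_b)[!(keys_b %in% keys_a), , drop = FALSE]
  only_b$unmatched <- flag_unmatched(only_b, ka)
  rownames(only_a) <- rownames(only_b) <- NULL

  shared <- as.data.frame(bonds_a)[in_both_a, , drop = FALSE]
  shared$distance_a <- shared$distance
  shared$distance_b <- bonds_b$distance[match(keys_a[in_both_a], keys_b)]
  shared$distance <- NULL
  rownames(shared) <- NULL

  structure(list(only_a = only_a, only_b = only_b, shared = shared,
                 unmatched_residues = unmatched),
            class = "basenet_diff")
}

#' @export
print.basenet_diff <- function(x, ...) {
  cat("hydrogen-bond network difference\n")
  cat("  only in A:", nrow(x$only_a), " only in B:", nrow(x$only_b),
      " shared:", nrow(x$shared), "\n")
  if (nrow(x$unmatched_residues)) {
    cat("  residues in one structure only:", nrow(x$unmatched_residues), "\n")
  }
  fmt <- function(df) sprintf(
    "    %s%s %s -> %s%s %s", df$donor_base, df$donor_res, df$donor_atom,
    df$acceptor_base, df$acceptor_res, df$acceptor_atom)
  if (nrow(x$only_a)) cat("  A only:\n", paste(fmt(x$only_a), collapse = "\n"),
                          "\n", sep = "")
  if (nrow(x$only_b)) cat("  B only:\n", paste(fmt(x$only_b), collapse = "\n"),
                          "\n", sep = "")
  invisible(x)
}

#' Write a network difference as a three-section TSV
#'
#' @param diff a `basenet_diff`.
#' @param file output path or `""` for stdout.
#' @return the diff, invisibly.
#' @export
write_diff_tsv <- function(diff, file = "") {
  con <- if (identical(file, "")) stdout() else file(file, "w")
  if (!identical(file, "")) on.exit(close(con))
  for (section in c("only_a", "only_b", "shared")) {
    writeLines(paste0("# ", section), con)
    utils::write.table(diff[[section]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(diff)
}
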