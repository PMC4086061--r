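# Geometric base-base hydrogen bond detection on heavy atoms. Because input
# structures carry no hydrogens, the donor-H criterion is replaced by an
# approach-angle proxy measured at the donor's covalent antecedent; the
# acceptor-side angle is kept as usual. All thresholds are configurable.

#' Hydrogen-bond geometry parameters
#'
#' Heavy-atom criteria for accepting a donor-acceptor contact as a hydrogen
#' bond: a maximum donor-acceptor distance and minimum approach angles at
#' both ends, each measured against the atom's covalently bonded ring
#' antecedent. Defaults are the classical heavy-atom cutoffs: D-A distance
#' of at most 3.9 Angstrom and both angles at least 90 degrees.
#'
#' @param max_da_distance maximum donor-acceptor distance, Angstrom.
#' @param min_ada_angle minimum angle antecedent(D)-D-A, degrees.
#' @param min_daa_angle minimum angle D-A-antecedent(A), degrees.
#' @return an object of class `hbond_params`.
#' @export
hbond_params <- function(max_da_distance = 3.9, min_ada_angle = 90,
                         min_daa_angle = 90) {
  stopifnot(max_da_distance > 0,
            min_ada_angle >= 0, min_ada_angle <= 180,
            min_daa_angle >= 0, min_daa_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_ada_angle = min_ada_angle,
                 min_daa_angle = min_daa_angle),
            class = "hbond_params")
}

#' @rdname hbond_params
#' @export
default_params <- function() hbond_params()

#' @export
print.hbond_params <- function(x, ...) {
  cat(sprintf(paste0("hydrogen-bond criteria: D-A <= %.2f A, ",
                     "angle(DD-D-A) >= %.0f deg, angle(D-A-AA) >= %.0f deg\n"),
              x$max_da_distance, x$min_ada_angle, x$min_daa_angle))
  invisible(x)
}

.vec_angle <- function(a, b, c) {
  # angle a-b-c in degrees
  u <- a - b
  v <- c - b
  cosv <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

.atom_xyz <- function(base, name) {
  i <- match(name, base$atoms$name)
  if (is.na(i)) return(NULL)
  c(base$atoms$x[i], base$atoms$y[i], base$atoms$z[i])
}

.hbond_columns <- c("donor_index", "donor_chain", "donor_res", "donor_icode",
                    "donor_base", "donor_atom",
                    "acceptor_index", "acceptor_chain", "acceptor_res",
                    "acceptor_icode", "acceptor_base", "acceptor_atom",
                    "distance", "angle_at_donor", "angle_at_acceptor")

.empty_hbond_set <- function(params = NULL) {
  df <- data.frame(donor_index = integer(), donor_chain = character(),
                   donor_res = integer(), donor_icode = character(),
                   donor_base = character(), donor_atom = character(),
                   acceptor_index = integer(), acceptor_chain = character(),
                   acceptor_res = integer(), acceptor_icode = character(),
                   acceptor_base = character(), acceptor_atom = character(),
                   distance = numeric(), angle_at_donor = numeric(),
                   angle_at_acceptor = numeric(), stringsAsFactors = FALSE)
  structure(df, class = c("hbond_set", "data.frame"), params = params)
}

#' Detect base-base hydrogen bonds
#'
#' Enumerates donor-acceptor atom pairs between distinct bases and keeps the
#' pairs satisfying the geometric criteria in `params`: D-A distance within
#' the cutoff and both approach angles (antecedent(D)-D-A and
#' D-A-antecedent(A)) at or above their minima. An atom pair qualifying in
#' both directions yields two records only when both directional
#' donor/acceptor role assignments are chemically legal. When a required
#' antecedent atom is missing from the coordinates the candidate bond is
#' skipped with a warning rather than an error.
#'
#' @param structure a `basenet_structure` (hydrogen-free; see
#'   [parse_structure()]).
#' @param library base library providing donors, acceptors and antecedents.
#' @param params an `hbond_params` object.
#' @return an `hbond_set`: a data frame with one row per directed bond,
#'   sorted by (donor base, donor atom, acceptor base, acceptor atom),
#'   carrying residue identities, atom names, the D-A distance and the two
#'   measured angles. The structure-order index of each residue is kept in
#'   `donor_index`/`acceptor_index`.
#' @export
detect_hbonds <- function(structure, library = base_library(),
                          params = default_params()) {
  stopifnot(inherits(structure, "basenet_structure"))
  bases <- structure$bases
  n <- length(bases)
  codes <- vapply(bases, `[[`, "", "base_code")
  missing_codes <- setdiff(unique(codes), names(library))
  if (length(missing_codes)) {
    bad <- which(codes %in% missing_codes)[1]
    stop("base code '", codes[bad], "' of residue ",
         bases[[bad]]$chain_id, ":", bases[[bad]]$res_seq,
         " is not in the base library", call. = FALSE)
  }
  if (n < 2L) return(.empty_hbond_set(params))

  cent <- t(vapply(bases, function(b)
    c(mean(b$atoms$x), mean(b$atoms$y), mean(b$atoms$z)), numeric(3)))
  # pair prefilter: base radius is < 3 A, so centroids farther apart than
  # cutoff + 6 A cannot host a qualifying atom pair
  reach <- params$max_da_distance + 6
  rows <- vector("list", 64L); nr <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sqrt(sum((cent[i, ] - cent[j, ])^2)) > reach) next
      for (dir in list(c(i, j), c(j, i))) {
        di <- dir[1]; ai <- dir[2]
        dbase <- bases[[di]]; abase <- bases[[ai]]
        dlib <- library[[dbase$base_code]]; alib <- library[[abase$base_code]]
        for (datom in intersect(dlib$donors, dbase$atoms$name)) {
          dpos <- .atom_xyz(dbase, datom)
          for (aatom in intersect(alib$acceptors, abase$atoms$name)) {
            apos <- .atom_xyz(abase, aatom)
            dist <- sqrt(sum((dpos - apos)^2))
            if (dist > params$max_da_distance) next
            dant <- .atom_xyz(dbase, dlib$antecedent[[datom]])
            aant <- .atom_xyz(abase, alib$antecedent[[aatom]])
            if (is.null(dant) || is.null(aant)) {
              warning("antecedent atom missing for ",
                      if (is.null(dant)) paste0(dbase$base_code, dbase$res_seq,
                                                " ", datom)
                      else paste0(abase$base_code, abase$res_seq, " ", aatom),
                      "; candidate bond skipped", call. = FALSE)
              next
            }
            ang_d <- .vec_angle(dant, dpos, apos)
            if (ang_d < params$min_ada_angle) next
            ang_a <- .vec_angle(dpos, apos, aant)
            if (ang_a < params$min_daa_angle) next
            nr <- nr + 1L
            if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
            rows[[nr]] <- data.frame(
              donor_index = di, donor_chain = dbase$chain_id,
              donor_res = dbase$res_seq, donor_icode = dbase$icode,
              donor_base = dbase$base_code, donor_atom = datom,
              acceptor_index = ai, acceptor_chain = abase$chain_id,
              acceptor_res = abase$res_seq, acceptor_icode = abase$icode,
              acceptor_base = abase$base_code, acceptor_atom = aatom,
              distance = dist, angle_at_donor = ang_d,
              angle_at_acceptor = ang_a, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (nr == 0L) return(.empty_hbond_set(params))
  df <- do.call(rbind, rows[seq_len(nr)])
  df <- df[order(df$donor_index, df$donor_atom,
                 df$acceptor_index, df$acceptor_atom, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("hbond_set", "data.frame"), params = params)
}

#' Assemble a hydrogen-bond set by hand
#'
#' Builds an `hbond_set` from a plain data frame, e.g. to reproduce a bond
#' listing from the literature without coordinates. Missing identity columns
#' default to blank chain/insertion codes and NA geometry; missing residue
#' indices are assigned by sorting the distinct residues on
#' (chain, residue number, insertion code).
#'
#' @param df data frame with at least `donor_res`, `donor_base`,
#'   `donor_atom`, `acceptor_res`, `acceptor_base`, `acceptor_atom`.
#' @return an `hbond_set`.
#' @export
as_hbond_set <- function(df) {
  need <- c("donor_res", "donor_base", "donor_atom",
            "acceptor_res", "acceptor_base", "acceptor_atom")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  nb <- nrow(df)
  for (side in c("donor", "acceptor")) {
    for (col in paste0(side, c("_chain", "_icode"))) {
      if (is.null(df[[col]])) df[[col]] <- rep("", nb)
    }
  }
  for (col in c("distance", "angle_at_donor", "angle_at_acceptor")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nb)
  }
  if (is.null(df$donor_index) || is.null(df$acceptor_index)) {
    ids <- rbind(
      data.frame(chain = df$donor_chain, res = df$donor_res,
                 icode = df$donor_icode, stringsAsFactors = FALSE),
      data.frame(chain = df$acceptor_chain, res = df$acceptor_res,
                 icode = df$acceptor_icode, stringsAsFactors = FALSE))
    key <- paste(ids$chain, ids$res, ids$icode, sep = "\r")
    uniq <- !duplicated(key)
    u <- ids[uniq, , drop = FALSE]
    ukey <- key[uniq]
    ord <- order(u$chain, u$res, u$icode, method = "radix")
    ranks <- match(key, ukey[ord])
    nb <- nrow(df)
    df$donor_index <- ranks[seq_len(nb)]
    df$acceptor_index <- ranks[nb + seq_len(nb)]
  }
  df <- df[, .hbond_columns, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("hbond_set", "data.frame"), params = NULL)
}

#' @export
print.hbond_set <- function(x, ...) {
  cat(nrow(x), "base-base hydrogen bond(s)\n")
  if (nrow(x)) {
    lab <- sprintf("%s%s%s %s -> %s%s%s %s  %.2f A",
                   x$donor_base, x$donor_res, x$donor_icode, x$donor_atom,
                   x$acceptor_base, x$acceptor_res, x$acceptor_icode,
                   x$acceptor_atom, x$distance)
    cat(paste0("  ", lab, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a hydrogen-bond listing as TSV
#'
#' @param bonds an `hbond_set`.
#' @param file output path or connection; `""` prints to stdout.
#' @return the bond set, invisibly.
#' @export
write_hbonds_tsv <- function(bonds, file = "") {
  utils::write.table(as.data.frame(bonds), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bonds)
}
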