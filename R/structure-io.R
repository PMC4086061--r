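# PDB reading: one model, RNA base residues only, base-moiety heavy atoms,
# alternate locations resolved. Record parsing is delegated to bio3d; a light
# fixed-width pre-check gives line-numbered errors for malformed coordinates.

.pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

.check_coord_fields <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (ln in which(is_atom)) {
    xyz <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
             substr(lines[ln], 47, 54))
    vals <- suppressWarnings(as.numeric(xyz))
    if (anyNA(vals) || !all(is.finite(vals))) {
      stop("malformed coordinate field at line ", ln, ": ",
           trimws(lines[ln]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# select the ATOM/HETATM block of one MODEL (or everything if single-model)
.select_model <- function(lines, model) {
  model_ln <- which(substr(lines, 1, 6) == "MODEL ")
  if (length(model_ln) == 0L) {
    if (model != 1L) {
      stop("model ", model, " not found: file has a single unnumbered model",
           call. = FALSE)
    }
    return(lines)
  }
  nums <- suppressWarnings(as.integer(trimws(substr(lines[model_ln], 7, 14))))
  hit <- model_ln[which(nums == model)]
  if (length(hit) == 0L) {
    stop("model ", model, " not found (models present: ",
         paste(nums, collapse = ", "), ")", call. = FALSE)
  }
  end_ln <- which(substr(lines, 1, 6) == "ENDMDL")
  end <- end_ln[end_ln > hit[1]]
  end <- if (length(end)) end[1] else length(lines)
  lines[(hit[1] + 1L):(end - 1L)]
}

.atom_element <- function(name, elesy) {
  el <- toupper(trimws(elesy))
  derived <- toupper(substr(gsub("[0-9']", "", trimws(name)), 1, 1))
  ifelse(!is.na(el) & nzchar(el), el, derived)
}

#' Parse an RNA structure from PDB-format text
#'
#' Reads PDB-format text (or a file path), keeps one model, and extracts the
#' nucleobase residues recognised by the base library. Only base-moiety heavy
#' atoms are retained: ribose and phosphate atoms (including O2') and all
#' hydrogens are dropped, and for alternate locations the highest-occupancy
#' conformer is kept (ties resolved to altloc 'A', then lexicographically).
#' Residues whose name is not in the library are dropped, never guessed.
#'
#' @param pdb a file path, or PDB-format text (single string or character
#'   vector of lines).
#' @param model MODEL number to keep for multi-model (e.g. NMR) files;
#'   ignored apart from validation for single-model files.
#' @param chains optional character vector of chain identifiers to keep.
#' @param include_dna also keep DA/DC/DG/DT deoxyribonucleotides (mapped to
#'   A/C/G/T base chemistry). Off by default; the tool targets RNA.
#' @param library base library, see [base_library()].
#' @param source_id label stored on the structure; defaults to the file name
#'   when `pdb` is a path.
#' @return an object of class `basenet_structure`: a list with `source_id`,
#'   `model_number` and `bases`, an ordered list (file order) of base nodes.
#'   Each base node carries `chain_id`, `res_seq`, `icode`, `res_name`,
#'   `base_code` and an `atoms` data frame (name, element, x, y, z,
#'   occupancy, altloc).
#' @export
parse_structure <- function(pdb, model = 1L, chains = NULL,
                            include_dna = FALSE, library = base_library(),
                            source_id = NULL) {
  lines <- .pdb_lines(pdb)
  if (is.null(source_id)) {
    source_id <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
      basename(pdb) else "<text>"
  }
  rec <- substr(lines, 1, 6)
  if (!any(rec %in% c("ATOM  ", "HETATM"))) {
    stop("no ATOM/HETATM records in input", call. = FALSE)
  }
  .check_coord_fields(lines)
  lines <- .select_model(lines, as.integer(model))

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdbobj <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
  at <- pdbobj$atom

  at$chain[is.na(at$chain)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]

  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  keys <- unique(key)  # file order
  bases <- list()
  for (k in keys) {
    rows <- at[key == k, , drop = FALSE]
    code <- .resolve_base_code(rows$resid[1], library, include_dna)
    if (is.na(code)) next
    entry <- library[[code]]
    rows$elety <- trimws(rows$elety)
    rows$element <- .atom_element(rows$elety, rows$elesy)
    rows <- rows[!(rows$element %in% c("H", "D")), , drop = FALSE]
    rows <- rows[rows$elety %in% entry$moiety, , drop = FALSE]
    if (nrow(rows) == 0L) next
    # altloc: highest occupancy, tie -> 'A', then lexicographic
    pick <- unlist(lapply(split(seq_len(nrow(rows)), rows$elety), function(ix) {
      r <- rows[ix, , drop = FALSE]
      ord <- order(-r$o, r$alt != "A", r$alt)
      ix[ord[1]]
    }), use.names = FALSE)
    rows <- rows[sort(pick), , drop = FALSE]
    bases[[length(bases) + 1L]] <- list(
      chain_id = rows$chain[1], res_seq = rows$resno[1], icode = rows$insert[1],
      res_name = trimws(rows$resid[1]), base_code = code,
      atoms = data.frame(name = rows$elety, element = rows$element,
                         x = rows$x, y = rows$y, z = rows$z,
                         occupancy = rows$o, altloc = rows$alt,
                         stringsAsFactors = FALSE)
    )
  }
  if (length(bases) == 0L) {
    stop("no RNA bases found in input (and none recognised in the base library)",
         call. = FALSE)
  }
  structure(list(source_id = source_id, model_number = as.integer(model),
                 bases = bases),
            class = "basenet_structure")
}

#' Remove hydrogen (and deuterium) atoms from a structure
#'
#' Idempotent; parsing already strips hydrogens, this re-applies the policy
#' to structures modified or assembled by hand.
#'
#' @param structure a `basenet_structure`.
#' @return the structure with no H/D atoms.
#' @export
strip_hydrogens <- function(structure) {
  stopifnot(inherits(structure, "basenet_structure"))
  structure$bases <- lapply(structure$bases, function(b) {
    b$atoms <- b$atoms[!(b$atoms$element %in% c("H", "D")), , drop = FALSE]
    rownames(b$atoms) <- NULL
    b
  })
  structure
}

.base_label <- function(b) {
  paste0(b$base_code, b$res_seq, if (nzchar(b$icode)) b$icode else "")
}

.base_identity <- function(b) {
  paste(b$chain_id, b$res_seq, b$icode, sep = "\r")
}

#' @export
print.basenet_structure <- function(x, ...) {
  codes <- vapply(x$bases, `[[`, "", "base_code")
  cat("RNA base structure '", x$source_id, "' (model ", x$model_number, ")\n",
      sep = "")
  cat("  ", length(x$bases), " bases: ",
      paste(sprintf("%s=%d", names(table(codes)), as.integer(table(codes))),
            collapse = " "), "\n", sep = "")
  chains <- unique(vapply(x$bases, `[[`, "", "chain_id"))
  cat("  chains: ", paste(ifelse(nzchar(chains), chains, "''"),
                          collapse = " "), "\n", sep = "")
  invisible(x)
}
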