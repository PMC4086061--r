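# Base library: for every recognised residue name, the base-moiety atom set,
# hydrogen-bond donor and acceptor atoms, and the covalent antecedent used by
# the angle tests. Donor/acceptor inventories follow standard base chemistry
# (amino and imino N-H groups donate; ring N lone pairs and carbonyl O
# accept); C-H...O interactions are not treated as hydrogen bonds.

.moiety_A <- c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")
.moiety_G <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
.moiety_C <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
.moiety_U <- c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")

# one covalently bonded ring atom per donor/acceptor, for the approach-angle
# proxy; where an atom has two ring neighbours the lower-numbered one is used
.antecedent_A <- c(N6 = "C6", N1 = "C6", N3 = "C2", N7 = "C5")
.antecedent_G <- c(N1 = "C6", N2 = "C2", O6 = "C6", N3 = "C2", N7 = "C5")
.antecedent_C <- c(N4 = "C4", O2 = "C2", N3 = "C2")
.antecedent_U <- c(N3 = "C2", O2 = "C2", O4 = "C4")
.antecedent_PSU <- c(N1 = "C2", N3 = "C2", O2 = "C2", O4 = "C4")

.base_entry <- function(code, parent, moiety, donors, acceptors, antecedent) {
  list(code = code, parent = parent, moiety = moiety,
       donors = donors, acceptors = acceptors, antecedent = antecedent)
}

.default_library <- function() {
  entries <- list(
    A = .base_entry("A", "A", .moiety_A, "N6", c("N1", "N3", "N7"), .antecedent_A),
    G = .base_entry("G", "G", .moiety_G, c("N1", "N2"), c("O6", "N3", "N7"), .antecedent_G),
    C = .base_entry("C", "C", .moiety_C, "N4", c("O2", "N3"), .antecedent_C),
    U = .base_entry("U", "U", .moiety_U, "N3", c("O2", "O4"), .antecedent_U),
    # pseudouridine: C-glycosidic, so N1 carries a proton and donates
    PSU = .base_entry("PSU", "U", .moiety_U, c("N1", "N3"), c("O2", "O4"), .antecedent_PSU),
    # common modified bases, donor/acceptor sets derived from the parent with
    # the methylated/saturated position removed where it loses H-bond capacity
    `1MA` = .base_entry("1MA", "A", .moiety_A, "N6", c("N3", "N7"), .antecedent_A),
    `5MC` = .base_entry("5MC", "C", .moiety_C, "N4", c("O2", "N3"), .antecedent_C),
    OMC = .base_entry("OMC", "C", .moiety_C, "N4", c("O2", "N3"), .antecedent_C),
    `2MG` = .base_entry("2MG", "G", .moiety_G, c("N1", "N2"), c("O6", "N3", "N7"), .antecedent_G),
    M2G = .base_entry("M2G", "G", .moiety_G, "N1", c("O6", "N3", "N7"), .antecedent_G),
    `7MG` = .base_entry("7MG", "G", .moiety_G, c("N1", "N2"), c("O6", "N3"), .antecedent_G),
    OMG = .base_entry("OMG", "G", .moiety_G, c("N1", "N2"), c("O6", "N3", "N7"), .antecedent_G),
    H2U = .base_entry("H2U", "U", .moiety_U, "N3", c("O2", "O4"), .antecedent_U),
    `5MU` = .base_entry("5MU", "U", .moiety_U, "N3", c("O2", "O4"), .antecedent_U),
    # thymine (DNA, opt-in): uracil chemistry at the H-bonding positions
    T = .base_entry("T", "U", .moiety_U, "N3", c("O2", "O4"), .antecedent_U)
  )
  entries
}

#' Nucleobase donor/acceptor library
#'
#' The library maps residue names to base definitions: the base-moiety heavy
#' atoms retained from a structure, the hydrogen-bond donor and acceptor atom
#' names, and for each such atom the covalently bonded ring atom (antecedent)
#' used in the approach-angle tests. It covers the four standard RNA bases,
#' pseudouridine and a set of common modified nucleotides (1MA, 5MC, 2MG,
#' M2G, 7MG, OMC, OMG, H2U, 5MU), plus thymine for optional DNA handling.
#'
#' @param config optional list (e.g. parsed from YAML) of entries to add or
#'   override. Each element is named by residue code and may supply `parent`,
#'   `moiety`, `donors`, `acceptors` and `antecedent` (a named list/vector);
#'   missing fields are inherited from the parent base entry.
#' @return named list of base entries, one per recognised residue name. Each
#'   entry has fields `code`, `parent`, `moiety`, `donors`, `acceptors`,
#'   `antecedent`.
#' @examples
#' lib <- base_library()
#' lib$A$donors     # "N6"
#' lib$U$acceptors  # "O2" "O4"
#' @export
base_library <- function(config = NULL) {
  lib <- .default_library()
  if (!is.null(config)) {
    for (code in names(config)) {
      spec <- config[[code]]
      parent <- spec$parent %||% lib[[code]]$parent %||% code
      base <- lib[[parent]]
      if (is.null(base) && is.null(lib[[code]])) {
        stop("library config entry '", code,
             "' names no known parent base", call. = FALSE)
      }
      base <- lib[[code]] %||% base
      ant <- spec$antecedent
      if (!is.null(ant)) ant <- unlist(ant)
      lib[[code]] <- .base_entry(
        code, parent,
        moiety = as.character(spec$moiety %||% base$moiety),
        donors = as.character(spec$donors %||% base$donors),
        acceptors = as.character(spec$acceptors %||% base$acceptors),
        antecedent = ant %||% base$antecedent
      )
    }
  }
  lib
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residue-name aliases applied before library lookup
.dna_alias <- c(DA = "A", DC = "C", DG = "G", DT = "T")

.resolve_base_code <- function(res_name, library, include_dna = FALSE) {
  nm <- trimws(res_name)
  if (nm %in% names(.dna_alias)) {
    if (!include_dna) return(NA_character_)
    nm <- .dna_alias[[nm]]
  }
  if (nm %in% names(library)) nm else NA_character_
}
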