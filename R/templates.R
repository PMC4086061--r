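# Idealized planar nucleobase heavy-atom templates, x/y in Angstrom, z = 0.
# Geometry: standard aromatic bond lengths/angles for the kekulized rings,
# projected onto the base plane and centred at the heavy-atom centroid.
# Only base-moiety atoms are present (no ribose, no phosphate, no hydrogens).

.template_A <- local({
  m <- rbind(
    c(-2.1224, 0.0000, 0),
    c(-2.0045, 1.3638, 0),
    c(-0.7453, 1.7492, 0),
    c(-0.0176, 0.5747, 0),
    c(1.3607, 0.3031, 0),
    c(2.3331, 1.2951, 0),
    c(1.7634, -0.9890, 0),
    c(0.8185, -1.9564, 0),
    c(-0.5241, -1.8188, 0),
    c(-0.8619, -0.5217, 0)
  )
  rownames(m) <- c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")
  attr(m, "element") <- c("N", "C", "N", "C", "C", "N", "N", "C", "N", "C")
  m
})

.template_G <- local({
  m <- rbind(
    c(-2.2413, 0.0000, 0),
    c(-2.3139, -1.3698, 0),
    c(-1.1203, -1.9295, 0),
    c(-0.2484, -0.8695, 0),
    c(1.1973, -0.8271, 0),
    c(1.9473, -1.7981, 0),
    c(1.6812, 0.4756, 0),
    c(0.8896, 1.6078, 0),
    c(1.5452, 2.7961, 0),
    c(-0.4168, 1.5845, 0),
    c(-0.9200, 0.3302, 0)
  )
  rownames(m) <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
  attr(m, "element") <- c("N", "C", "N", "C", "C", "O", "N", "C", "N", "N", "C")
  m
})

.template_C <- local({
  m <- rbind(
    c(-1.5232, 0.0000, 0),
    c(-0.6452, 1.0583, 0),
    c(-1.0938, 2.2013, 0),
    c(0.6990, 0.7830, 0),
    c(1.0919, -0.4543, 0),
    c(2.4421, -0.6743, 0),
    c(0.1629, -1.6094, 0),
    c(-1.1337, -1.3045, 0)
  )
  rownames(m) <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
  attr(m, "element") <- c("N", "C", "O", "N", "C", "N", "C", "C")
  m
})

.template_U <- local({
  m <- rbind(
    c(-1.5284, 0.0000, 0),
    c(-0.6813, 1.0763, 0),
    c(-1.0973, 2.2297, 0),
    c(0.6520, 0.7772, 0),
    c(1.1766, -0.4846, 0),
    c(2.3814, -0.7079, 0),
    c(0.1996, -1.5922, 0),
    c(-1.1026, -1.2985, 0)
  )
  rownames(m) <- c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
  attr(m, "element") <- c("N", "C", "O", "N", "C", "O", "C", "C")
  m
})

#' Idealized base template coordinates
#'
#' Returns the idealized planar heavy-atom template for a base code: a
#' numeric matrix with one row per base-moiety atom (rownames are PDB atom
#' names), columns x/y/z in Angstrom (z is 0; the base lies in its plane),
#' and an `"element"` attribute. Modified bases use their parent base
#' template.
#'
#' @param base_code base library key, e.g. `"A"` or `"PSU"`.
#' @param library a base library, see [base_library()].
#' @return numeric matrix of atom coordinates.
#' @export
base_template <- function(base_code, library = base_library()) {
  entry <- library[[base_code]]
  if (is.null(entry)) {
    stop("base code '", base_code, "' is not in the base library", call. = FALSE)
  }
  tpl <- switch(entry$parent,
    A = .template_A, G = .template_G, C = .template_C, U = .template_U,
    stop("no template for parent base '", entry$parent, "'", call. = FALSE)
  )
  keep <- rownames(tpl) %in% entry$moiety
  out <- tpl[keep, , drop = FALSE]
  attr(out, "element") <- attr(tpl, "element")[keep]
  out
}
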