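# Structure I/O (PDB/mmCIF via bio3d, plus a minimal mmCIF atom_site
# writer) and 30-Angstrom coordinate-sphere extraction.

#' Read a structure file
#'
#' PDB and mmCIF are parsed with bio3d.  When alternate conformers are
#' present, the highest-occupancy altloc of each atom is kept (ties:
#' first label), with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return `na_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, resname = trimws(a$resid),
    elety = gsub('"', "", trimws(a$elety)),
    elesy = if (!is.null(a$elesy)) trimws(a$elesy) else guess_element(a$elety),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE
  )
  atoms$elesy[!nzchar(atoms$elesy)] <- guess_element(
    atoms$elety[!nzchar(atoms$elesy)])
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$elety)
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, ]
    dup <- duplicated(paste(atoms$chain, atoms$resno, atoms$elety))
    if (any(dup)) {
      warning(sum(dup), " alternate-conformer atoms dropped ",
              "(highest occupancy kept)")
      atoms <- atoms[!dup, ]
    }
    atoms <- atoms[order(match(paste(atoms$chain, atoms$resno, atoms$elety),
                               unique(key))), ]
  }
  na_structure(atoms)
}

#' Write a structure file
#'
#' @param s `na_structure`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  a <- s$atoms
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      resno = a$resno, resid = a$resname, elety = a$elety,
      chain = a$chain, o = a$o, b = rep(0, nrow(a)), elesy = a$elesy,
      alt = ifelse(nzchar(a$alt), a$alt, NA)
    )
  } else {
    write_min_cif(a, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer (coordinates category only).
#' @noRd
write_min_cif <- function(a, path) {
  hdr <- c(
    "data_structure", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- sprintf(
    paste("ATOM %d %s \"%s\" . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ?",
          "%d %s %s \"%s\" 1"),
    seq_len(nrow(a)), a$elesy, a$elety, a$resname, a$chain, a$resno,
    a$x, a$y, a$z, a$o, a$resno, a$resname, a$chain, a$elety
  )
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Extract a coordinate sphere
#'
#' Retains every residue with at least one atom within `radius` of the
#' center (whole-residue retention keeps chi and P computable for all
#' retained nucleotides).
#'
#' @param s `na_structure`.
#' @param center 3-vector, Angstrom.
#' @param radius sphere radius in Angstrom (default 30).
#' @return `na_structure` of the sphere.
#' @export
extract_sphere <- function(s, center, radius = 30) {
  stopifnot(radius > 0, length(center) == 3)
  a <- s$atoms
  d2 <- (a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2
  hit <- d2 <= radius^2
  keys <- unique(paste(a$chain[hit], a$resno[hit]))
  keep <- paste(a$chain, a$resno) %in% keys
  if (!any(keep)) warning("empty sphere")
  na_structure(a[keep, , drop = FALSE])
}

#' Sphere centers from phosphorus atoms
#'
#' Selects every `every`-th phosphorus atom of the nucleotide part of
#' the structure as a sphere center.
#'
#' @param s `na_structure`.
#' @param every stride (default 5).
#' @return matrix (n x 3) of center coordinates.
#' @export
phosphate_centers <- function(s, every = 5) {
  a <- s$atoms
  p <- a[a$elety == "P" & is_nucleotide_resname(a$resname), , drop = FALSE]
  idx <- seq_len(nrow(p))
  sel <- idx[idx %% every == 0]
  as.matrix(p[sel, c("x", "y", "z"), drop = FALSE])
}
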