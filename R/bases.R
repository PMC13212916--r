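# Idealized planar nucleobases: ring geometry generated from regular
# polygons with aromatic bond lengths, exocyclic substituents placed
# radially.  Templates live in 2D (base plane) with the glycosidic
# nitrogen at the origin and the C1' direction along -x; attachment to
# a sugar solves the in-plane orientation for a requested chi.

GLYCOSIDIC_BOND <- 1.48  # C1'-N9 / C1'-N1, Angstrom

# Idealized planar base coordinates (force-field-optimized heavy-atom
# geometry, projected onto the base plane), in the template frame:
# glycosidic N at the origin, C1' direction along -x.
#' @noRd
BASE_XY <- list(
  A = matrix(c(
    0.0000, 0.0000,   0.8149, 1.0983,   2.0891, 0.7637,
    2.0898, -0.6183,  3.1241, -1.5690,  4.4712, -1.2286,
    2.7958, -2.8813,  1.4858, -3.2142,  0.4118, -2.3982,
    0.7948, -1.1111), ncol = 2, byrow = TRUE,
    dimnames = list(c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2",
                      "N3", "C4"), NULL)),
  G = matrix(c(
    0.0000, 0.0000,   0.8147, -1.1020,  2.0915, -0.7721,
    2.0869, 0.6006,   3.1790, 1.5487,   4.3744, 1.2717,
    2.7310, 2.8633,   1.4026, 3.2392,   1.1592, 4.5744,
    0.4056, 2.3959,   0.8044, 1.1015), ncol = 2, byrow = TRUE,
    dimnames = list(c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2",
                      "N2", "N3", "C4"), NULL)),
  C = matrix(c(
    0.0000, 0.0000,   0.6682, 1.2011,   1.9987, 1.2457,
    2.6838, -0.0613,  4.0509, -0.1076,  2.0590, -1.1959,
    0.6835, -1.2216,  0.0777, -2.2910), ncol = 2, byrow = TRUE,
    dimnames = list(c("N1", "C6", "C5", "C4", "N4", "N3", "C2", "O2"),
                    NULL)),
  T = matrix(c(
    0.0000, 0.0000,   0.6610, 1.2110,   1.9964, 1.3011,
    2.7575, 2.5853,   2.7769, 0.0412,   4.0032, 0.0388,
    2.0485, -1.1126,  0.6822, -1.2095,  0.1433, -2.3138),
    ncol = 2, byrow = TRUE,
    dimnames = list(c("N1", "C6", "C5", "C7", "C4", "O4", "N3", "C2",
                      "O2"), NULL)),
  U = matrix(c(
    0.0000, 0.0000,   0.6615, 1.2106,   1.9936, 1.2873,
    2.7759, 0.0413,   4.0007, 0.0652,   2.0517, -1.1143,
    0.6836, -1.2112,  0.1446, -2.3154), ncol = 2, byrow = TRUE,
    dimnames = list(c("N1", "C6", "C5", "C4", "O4", "N3", "C2", "O2"),
                    NULL))
)

# Base template: 2D atom coordinates plus chemistry annotations used by
# chi measurement, H-bond detection and interaction analysis.
#' @noRd
base_template <- function(nucleoside) {
  key <- sub("^d", "", nucleoside)
  if (key == "T" && nucleoside != "dT") key <- "T"
  xy <- BASE_XY[[key]]
  if (key %in% c("A", "G")) {
    glyc <- "N9"; ref <- "C4"
    ring <- c("N9", "C8", "N7", "C5", "C4", "C6", "N1", "C2", "N3")
    if (key == "A") {
      donors <- "N6"; acceptors <- c("N1", "N3", "N7")
    } else {
      donors <- c("N1", "N2"); acceptors <- c("O6", "N3", "N7")
    }
  } else {
    glyc <- "N1"; ref <- "C2"
    ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
    if (key == "C") {
      donors <- "N4"; acceptors <- c("O2", "N3")
    } else {
      donors <- "N3"; acceptors <- c("O2", "O4")
    }
  }
  list(xy = xy, glyc = glyc, ref = ref, ring = ring,
       donors = donors, acceptors = acceptors,
       atoms = rownames(xy))
}

#' @noRd
base_atom_names <- function(nucleoside) base_template(nucleoside)$atoms

#' Attach an idealized nucleobase to a placed sugar
#'
#' Adds planar base atoms bonded at C1' (glycosidic bond 1.48 Angstrom,
#' base plane through the bond) so that the measured glycosidic torsion
#' equals `chi`.
#'
#' @param sugar `nucleotide_view` containing at least O4', C1', C2'.
#' @param nucleoside one of A, U, G, C, dA, dT, dG, dC.
#' @param chi requested glycosidic torsion, degrees.
#' @return `nucleotide_view` of the full residue (sugar + base), with
#'   resname set from `nucleoside`.
#' @export
attach_base <- function(sugar, nucleoside, chi) {
  if (!nucleoside %in% NUCLEOSIDES) {
    stop("unknown nucleoside: ", nucleoside)
  }
  tpl <- base_template(nucleoside)
  c1 <- atom_xyz(sugar, "C1'")
  o4 <- atom_xyz(sugar, "O4'")
  atom_xyz(sugar, "C2'")  # required for the attachment frame

  e1 <- c1_substituent_dir(sugar)           # C1' -> N direction ("up" face)
  npos <- c1 + GLYCOSIDIC_BOND * e1
  v <- o4 - c1
  b0 <- vunit(v - sum(v * e1) * e1)
  base3d <- t(apply(tpl$xy, 1, function(p) npos + p[1] * e1 + p[2] * b0))

  # rotate the base about the glycosidic axis to realize the requested chi
  chi0 <- wrap360(dihedral_angle(o4, c1, npos, base3d[tpl$ref, ]))
  delta <- chi - chi0
  rot1 <- rotate_about_axis(base3d, npos, e1, delta)
  got1 <- wrap360(dihedral_angle(o4, c1, npos, rot1[tpl$ref, ]))
  if (circular_diff(got1, chi) > 1e-6) {
    rot1 <- rotate_about_axis(base3d, npos, e1, -delta)
    got1 <- wrap360(dihedral_angle(o4, c1, npos, rot1[tpl$ref, ]))
  }
  if (circular_diff(got1, chi) > 0.01) {
    stop("glycosidic placement failed to reach requested chi")
  }

  keep <- sugar$atoms[!sugar$atoms$elety %in% rownames(rot1), , drop = FALSE]
  atoms <- rbind(
    keep,
    data.frame(elety = rownames(rot1), elesy = guess_element(rownames(rot1)),
               x = rot1[, 1], y = rot1[, 2], z = rot1[, 3],
               stringsAsFactors = FALSE)
  )
  out <- nucleotide_view(atoms, resname = NUC_TO_RESNAME[[nucleoside]],
                         chain = sugar$chain, resno = sugar$resno)
  attr(out, "base_atoms") <- tpl$atoms
  out
}
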