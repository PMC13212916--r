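# Nucleotide building on a rigid backbone: classify the position,
# strip to main-chain atoms, superpose idealized sugar templates onto
# C3'/C4'/C5', attach bases at library chi values, and expand the set
# by delta-chi increments and backrub rotations.

# Canonical pseudorotation phases of the template conformers, on the
# 18-degree pseudorotation wheel.
SUGAR_TEMPLATE_P <- c(
  "3T2" = 0, "3E" = 18, "3T4" = 36,          # 3'-endo-like set
  "2T3" = 180, "2E" = 162, "2T1" = 144, "1E" = 126  # 2'-endo-like set
)

#' Strip a nucleotide to its main-chain atoms
#'
#' Retains exactly the phosphate group and the O3', C3', C4', C5'
#' sugar atoms (P, OP1, OP2, O5', C5', C4', C3', O3'), intersected
#' with the atoms actually present; all other atoms are deleted.
#'
#' @param res `nucleotide_view`.
#' @return `nucleotide_view` with only main-chain atoms.
#' @export
strip_to_mainchain <- function(res) {
  keep <- res$atoms$elety %in% NT_MAINCHAIN
  missing <- setdiff(NT_MAINCHAIN, res$atoms$elety)
  if (length(missing)) {
    message(sprintf("residue %s/%s lacks main-chain atoms: %s",
                    res$chain, res$resno, paste(missing, collapse = " ")))
  }
  out <- res
  out$atoms <- res$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' @noRd
.template_cache <- new.env(parent = emptyenv())

#' Idealized sugar templates for a pucker class
#'
#' 3'-endo-like positions receive three conformers (3T2, 3E, 3T4 at
#' canonical P = 0, 18, 36); 2'-endo-like positions receive four (2T3,
#' 2E, 2T1, 1E at P = 180, 162, 144, 126), reflecting the broader P
#' distribution of 2'-endo sugars.  Template amplitudes default to the
#' observed distribution maxima: 37 deg for deoxyribose, 40 for ribose.
#'
#' @param pucker_class `"ENDO2"` or `"ENDO3"`.
#' @param kind `"ribose"` or `"deoxyribose"`.
#' @return list of templates; each is a list with `name`,
#'   `canonical_P`, `tau_m` and `view` (the idealized sugar).
#' @export
sugar_conformers <- function(pucker_class = c("ENDO3", "ENDO2"),
                             kind = c("ribose", "deoxyribose")) {
  pucker_class <- match.arg(pucker_class)
  kind <- match.arg(kind)
  names <- if (pucker_class == "ENDO3") c("3T2", "3E", "3T4")
           else c("2T3", "2E", "2T1", "1E")
  tau <- if (kind == "ribose") 40 else 37
  lapply(names, function(nm) {
    key <- paste(nm, kind)
    if (is.null(.template_cache[[key]])) {
      .template_cache[[key]] <- list(
        name = nm, canonical_P = unname(SUGAR_TEMPLATE_P[nm]), tau_m = tau,
        view = ideal_sugar(SUGAR_TEMPLATE_P[[nm]], tau, kind)
      )
    }
    .template_cache[[key]]
  })
}

#' Superpose a sugar template onto a stripped backbone
#'
#' Rigidly places the template by least-squares superposition of its
#' C3', C4', C5' atoms onto the same atoms of the main chain.  The
#' placed template contributes the ring atoms (C1', C2', C3', C4',
#' O4', and O2' for ribose); the chain's phosphate, O5', C5' and O3'
#' are untouched.
#'
#' @param template one element of [sugar_conformers()].
#' @param mainchain `nucleotide_view` with at least C3', C4', C5'.
#' @return `nucleotide_view` combining main-chain and placed sugar
#'   atoms, with attributes `sugar_name` and `anchor_rmsd`.
#' @export
place_sugar <- function(template, mainchain) {
  anchors <- c("C3'", "C4'", "C5'")
  fix <- t(vapply(anchors, function(a) atom_xyz(mainchain, a), numeric(3)))
  tv <- template$view
  mov <- t(vapply(anchors, function(a) atom_xyz(tv, a), numeric(3)))
  fit <- superpose_points(mov, fix)
  placed <- fit$transform(view_coords(tv))
  contrib <- setdiff(tv$atoms$elety, c("C5'", "O3'"))
  keep_main <- !(mainchain$atoms$elety %in% contrib)
  idx <- match(contrib, tv$atoms$elety)
  atoms <- rbind(
    mainchain$atoms[keep_main, , drop = FALSE],
    data.frame(elety = contrib, elesy = tv$atoms$elesy[idx],
               x = placed[idx, 1], y = placed[idx, 2], z = placed[idx, 3],
               stringsAsFactors = FALSE)
  )
  out <- nucleotide_view(atoms, resname = mainchain$resname,
                         chain = mainchain$chain, resno = mainchain$resno)
  attr(out, "sugar_name") <- template$name
  attr(out, "anchor_rmsd") <- fit$rmsd
  out
}

#' Build configuration for candidate enumeration
#'
#' @param dchi chi increments in degrees (must include 0).
#' @param backrub_angles backrub rotations in degrees (must include 0).
#' @param backrub_axis `"C3C4"` (rotation about the C3'-C4' axis) or
#'   `"PP"` (about the P(i)-P(i+1) axis; requires the next phosphate).
#' @param h_placements number of alternative H placements for H-bond
#'   donor hydrogens (1 = implicit; 3 samples the staggered ribose
#'   2'-OH positions).
#' @param allowed_nucleosides nucleoside identities offered at the
#'   position; NULL = the position's native nucleoside only.
#' @return list of class `build_config`.
#' @export
build_config <- function(dchi = c(-7, 0, 7), backrub_angles = c(-7, 0, 7),
                         backrub_axis = c("C3C4", "PP"), h_placements = 1L,
                         allowed_nucleosides = NULL) {
  backrub_axis <- match.arg(backrub_axis)
  if (!0 %in% dchi) stop("dchi must contain 0")
  if (!0 %in% backrub_angles) stop("backrub_angles must contain 0")
  if (h_placements < 1) stop("h_placements must be >= 1")
  if (!is.null(allowed_nucleosides) &&
      !all(allowed_nucleosides %in% NUCLEOSIDES)) {
    stop("unknown nucleoside in allowed_nucleosides")
  }
  structure(list(dchi = dchi, backrub_angles = backrub_angles,
                 backrub_axis = backrub_axis,
                 h_placements = as.integer(h_placements),
                 allowed_nucleosides = allowed_nucleosides),
            class = "build_config")
}

#' @noRd
new_candidate <- function(view, nucleoside, sugar_name, chi_base,
                          dchi = 0, backrub = 0, h_variant = 1L,
                          probability = NA_real_) {
  structure(list(view = view, nucleoside = nucleoside,
                 sugar_name = sugar_name, chi_base = chi_base,
                 dchi = dchi, backrub = backrub, h_variant = h_variant,
                 probability = probability),
            class = "rotamer_candidate")
}

#' @export
print.rotamer_candidate <- function(x, ...) {
  cat(sprintf(
    "<rotamer_candidate> %s sugar %s chi %g%+g backrub %g (p = %.3g)\n",
    x$nucleoside, x$sugar_name, x$chi_base, x$dchi, x$backrub,
    x$probability))
  invisible(x)
}

#' Rotate a candidate's base about the glycosidic bond
#'
#' Applies each delta-chi increment as a rigid rotation of the base
#' atoms about the C1'-N axis; sugar and backbone are unchanged.
#'
#' @param cand `rotamer_candidate` with a base attached.
#' @param dchi numeric vector of increments, degrees.
#' @return list of candidates, one per increment.
#' @export
expand_chi <- function(cand, dchi) {
  v <- cand$view
  base_atoms <- attr(v, "base_atoms")
  if (is.null(base_atoms)) stop("candidate has no base attached")
  c1 <- atom_xyz(v, "C1'")
  nglyc <- atom_xyz(v, if (is_purine(cand$nucleoside)) "N9" else "N1")
  axis <- nglyc - c1
  lapply(dchi, function(d) {
    out <- cand
    if (d != 0) {
      idx <- v$atoms$elety %in% base_atoms
      xyz <- view_coords(v)
      # rotate in the same sense as the chi measurement
      r1 <- rotate_about_axis(xyz[idx, , drop = FALSE], c1, axis, d)
      vv <- v
      xyz[idx, ] <- r1
      vv <- set_view_coords(vv, xyz)
      if (circular_diff(glycosidic_chi(vv),
                        wrap360(cand$chi_base + d)) > 1e-6) {
        xyz <- view_coords(v)
        xyz[idx, ] <- rotate_about_axis(xyz[idx, , drop = FALSE], c1,
                                        axis, -d)
        vv <- set_view_coords(v, xyz)
      }
      attr(vv, "base_atoms") <- base_atoms
      out$view <- vv
    }
    out$dchi <- d
    out
  })
}

#' Backrub rotation of a whole candidate nucleotide
#'
#' Rotates the candidate rigidly about the C3'-C4' axis (default) or
#' the P(i)-P(i+1) axis.  The atoms defining the axis stay invariant:
#' C3' and C4' for `"C3C4"`; the two phosphorus atoms for `"PP"`.
#'
#' @param cand `rotamer_candidate`.
#' @param angle rotation in degrees.
#' @param axis `"C3C4"` or `"PP"`.
#' @param next_p position of the following residue's P atom (3-vector),
#'   required for the `"PP"` axis.
#' @return rotated `rotamer_candidate`.
#' @export
backrub <- function(cand, angle, axis = c("C3C4", "PP"), next_p = NULL) {
  axis <- match.arg(axis)
  out <- cand
  out$backrub <- angle
  if (angle == 0) return(out)
  v <- cand$view
  xyz <- view_coords(v)
  if (axis == "C3C4") {
    o <- atom_xyz(v, "C3'")
    a <- atom_xyz(v, "C4'") - o
    rot_idx <- !(v$atoms$elety %in% c("C3'", "C4'"))
  } else {
    if (is.null(next_p)) stop("PP axis requires the next residue's P position")
    o <- atom_xyz(v, "P")
    a <- next_p - o
    rot_idx <- v$atoms$elety != "P"
  }
  xyz[rot_idx, ] <- rotate_about_axis(xyz[rot_idx, , drop = FALSE],
                                      o, a, angle)
  vv <- set_view_coords(v, xyz)
  attr(vv, "base_atoms") <- attr(v, "base_atoms")
  out$view <- vv
  out
}

#' @noRd
add_h_variant <- function(cand, h_variant, kind) {
  out <- cand
  out$h_variant <- h_variant
  v <- cand$view
  if (kind == "ribose" && !is.null(atom_xyz(v, "O2'", required = FALSE))) {
    # staggered 2'-OH hydrogen about the C2'-O2' bond
    tor <- c(60, 180, 300)[((h_variant - 1) %% 3) + 1]
    h <- nerf_place(atom_xyz(v, "C1'"), atom_xyz(v, "C2'"),
                    atom_xyz(v, "O2'"), 0.96, 109.5, tor)
    v$atoms <- rbind(v$atoms[v$atoms$elety != "HO2'", , drop = FALSE],
                     data.frame(elety = "HO2'", elesy = "H",
                                x = h[1], y = h[2], z = h[3],
                                stringsAsFactors = FALSE))
    attr(v, "base_atoms") <- attr(cand$view, "base_atoms")
    out$view <- v
  }
  out
}

#' Closest candidate to a reference conformation
#'
#' Structure-supervised selection: among the enumerated candidates,
#' find the one with the lowest RMSD over the non-main-chain atoms
#' shared with the reference residue (identity must match).  This is
#' the per-position quantity underlying rotamer-library validation:
#' how closely can any library-derived conformation approach the
#' experimentally observed one.
#'
#' @param reference `nucleotide_view` of the observed residue.
#' @param candidates list of `rotamer_candidate`.
#' @return list with `index`, `rmsd` (Angstrom) and `delta_chi`
#'   (degrees, circular) of the best candidate.
#' @export
closest_candidate <- function(reference, candidates) {
  ref_chi <- glycosidic_chi(reference)
  ra <- reference$atoms[!reference$atoms$elety %in% NT_MAINCHAIN &
                        reference$atoms$elesy != "H", , drop = FALSE]
  best <- NULL
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    if (cand$nucleoside != reference$nucleoside) next
    ca <- cand$view$atoms
    idx <- match(ra$elety, ca$elety)
    if (anyNA(idx)) next
    d2 <- (ra$x - ca$x[idx])^2 + (ra$y - ca$y[idx])^2 +
      (ra$z - ca$z[idx])^2
    rmsd <- sqrt(mean(d2))
    if (is.null(best) || rmsd < best$rmsd) {
      best <- list(index = k, rmsd = rmsd,
                   delta_chi = circular_diff(glycosidic_chi(cand$view),
                                             ref_chi))
    }
  }
  if (is.null(best)) stop("no candidate matches the reference identity")
  best
}

#' Enumerate rotamer candidates at a position
#'
#' Builds the full candidate set at one backbone position: for each
#' allowed nucleoside, each library rotamer is attached to each sugar
#' conformer of the position's pucker class, then expanded by H
#' placements, delta-chi increments and backrub rotations.  The
#' candidate count equals
#' `sum over nucleosides of n_rotamers x n_sugars x h x |dchi| x |backrub|`.
#'
#' @param res `nucleotide_view` of the position (full or already
#'   stripped; ring atoms are used for classification when present).
#' @param library `rotamer_library`.
#' @param cfg `build_config`.
#' @param pucker_class optional explicit class; inferred from the
#'   residue's ring when omitted.
#' @param next_p next residue's P position (for the PP backrub axis).
#' @return list of `rotamer_candidate` objects.
#' @export
enumerate_candidates <- function(res, library, cfg = build_config(),
                                 pucker_class = NULL, next_p = NULL) {
  if (is.null(pucker_class)) {
    pucker_class <- classify_pucker(pseudorotation_phase(
      endocyclic_torsions(res)))
  }
  nucs <- cfg$allowed_nucleosides %||% res$nucleoside
  if (any(is.na(nucs))) stop("position nucleoside unknown; supply allowed_nucleosides")
  mainchain <- strip_to_mainchain(res)

  out <- list()
  for (nuc in nucs) {
    rot <- library_group(library, nuc, pucker_class)
    if (!nrow(rot)) {
      stop(sprintf("empty library group: %s/%s", nuc,
                   if (library$flavor == "basic") "ANY" else pucker_class))
    }
    kind <- if (is_deoxy(nuc)) "deoxyribose" else "ribose"
    for (tpl in sugar_conformers(pucker_class, kind)) {
      placed <- place_sugar(tpl, mainchain)
      for (r in seq_len(nrow(rot))) {
        built <- attach_base(placed, nuc, rot$chi[r])
        cand <- new_candidate(built, nuc, tpl$name, rot$chi[r],
                              probability = rot$probability[r])
        for (ec in expand_chi(cand, cfg$dchi)) {
          for (h in seq_len(cfg$h_placements)) {
            hc <- add_h_variant(ec, h, kind)
            for (ang in cfg$backrub_angles) {
              out[[length(out) + 1]] <-
                backrub(hc, ang, cfg$backrub_axis, next_p)
            }
          }
        }
      }
    }
  }
  out
}
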