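# Torsion-based descriptors of nucleotide conformation: endocyclic
# torsions nu0-nu4, pseudorotation phase P and amplitude tau_M
# (Altona-Sundaralingam formalism), glycosidic chi, and the
# 2'-endo-like / 3'-endo-like pucker classification.

# Standard furanose quadruples, j = 0..4
NU_QUADS <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'")
)

#' Endocyclic torsions of a furanose ring
#'
#' Computes the five ring torsions nu0..nu4 of the (deoxy)ribose moiety
#' using the standard furanose atom quadruples.
#'
#' @param res `nucleotide_view` exposing O4', C1', C2', C3', C4'.
#' @return named numeric vector `nu0`..`nu4`, degrees in (-180, 180].
#' @export
endocyclic_torsions <- function(res) {
  vapply(NU_QUADS, function(q) {
    p <- lapply(q, function(nm) atom_xyz(res, nm))
    dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  }, numeric(1))
}

#' Pseudorotation phase of a furanose ring
#'
#' Inverts the cosine pseudorotation model via
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' adding 180 degrees when nu2 < 0 so that mirrored twists are
#' distinguished and P covers the full circle.
#'
#' @param torsions named vector `nu0`..`nu4` in degrees
#'   (as from [endocyclic_torsions()]).
#' @return phase P in degrees in \[0, 360).
#' @export
pseudorotation_phase <- function(torsions) {
  t <- as.numeric(torsions[c("nu0", "nu1", "nu2", "nu3", "nu4")])
  if (anyNA(t)) stop("torsion set must contain nu0..nu4")
  if (all(abs(t) < 1e-12)) {
    stop("planar ring: pseudorotation phase undefined (all torsions zero)")
  }
  num <- (t[5] + t[2]) - (t[4] + t[1])
  den <- 2 * t[3] * (sin(36 * DEG) + sin(72 * DEG))
  # atan2 realizes both the principal value and the +180 branch for
  # nu2 < 0 (den < 0), and resolves nu2 == 0 by the sign of the numerator
  wrap360(atan2(num, den) / DEG)
}

#' Pseudorotation amplitude
#'
#' Maximal endocyclic torsion tau_M.  Uses `nu2 / cos(P)` away from the
#' degenerate phases; within 0.1 of `cos(P) = 0` it falls back to a
#' least-squares fit of the amplitude over all five torsions against
#' the cosine model, which is numerically stable near P = 90/270.
#'
#' @param torsions named vector `nu0`..`nu4`, degrees.
#' @param P pseudorotation phase in degrees consistent with `torsions`.
#' @return amplitude tau_M in degrees (>= 0).
#' @export
pucker_amplitude <- function(torsions, P) {
  t <- as.numeric(torsions[c("nu0", "nu1", "nu2", "nu3", "nu4")])
  cp <- cos(P * DEG)
  if (abs(cp) > 0.1) {
    return(abs(t[3] / cp))
  }
  cj <- cos((P + 144 * (0:4 - 2)) * DEG)
  max(sum(t * cj) / sum(cj * cj), 0)
}

#' Glycosidic torsion chi
#'
#' chi is measured over O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2
#' for pyrimidines, and reported in \[0, 360).
#'
#' @param res `nucleotide_view` of a standard nucleotide.
#' @return chi in degrees in \[0, 360).
#' @export
glycosidic_chi <- function(res) {
  nuc <- res$nucleoside
  if (is.na(nuc)) {
    stop(sprintf("residue %s %s/%s is not a standard nucleotide",
                 res$resname, res$chain, res$resno))
  }
  quad <- if (is_purine(nuc)) c("O4'", "C1'", "N9", "C4")
          else c("O4'", "C1'", "N1", "C2")
  p <- lapply(quad, function(nm) atom_xyz(res, nm))
  wrap360(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]))
}

#' Classify the sugar pucker from the pseudorotation phase
#'
#' 2'-endo-like (`"ENDO2"`) for 80 <= P < 260, otherwise 3'-endo-like
#' (`"ENDO3"`).  The boundary points (left-closed at 80, open at 260)
#' make the classification total on \[0, 360).
#'
#' @param P phase in degrees (vectorized), any real value; wrapped to
#'   \[0, 360).
#' @return character vector of `"ENDO2"` / `"ENDO3"`.
#' @export
classify_pucker <- function(P) {
  P <- wrap360(P)
  ifelse(P >= 80 & P < 260, "ENDO2", "ENDO3")
}

#' Full pucker state of one nucleotide
#'
#' @param res `nucleotide_view`.
#' @return list with `torsions`, `P`, `tau_m`, `pucker_class`.
#' @export
pucker_state <- function(res) {
  t <- endocyclic_torsions(res)
  P <- pseudorotation_phase(t)
  list(torsions = t, P = P, tau_m = pucker_amplitude(t, P),
       pucker_class = classify_pucker(P))
}

#' Cosine-model endocyclic torsions
#'
#' Generates `nu_j = tau_m * cos(P + 144 (j - 2))`, the ideal
#' pseudorotation model underlying the phase/amplitude formulas.
#'
#' @param P phase in degrees.
#' @param tau_m amplitude in degrees.
#' @return named vector `nu0`..`nu4`.
#' @export
cosine_model_torsions <- function(P, tau_m) {
  nu <- tau_m * cos((P + 144 * (0:4 - 2)) * DEG)
  stats::setNames(nu, paste0("nu", 0:4))
}

#' Per-residue conformational descriptor table
#'
#' Computes nu0-nu4, P, tau_M, pucker class and chi for every standard
#' nucleotide in a structure.  Non-standard residues are skipped with a
#' warning; residues with missing ring atoms are likewise skipped.
#'
#' @param s `na_structure`.
#' @return data.frame with one row per analysed nucleotide.
#' @export
analyze_structure <- function(s) {
  rt <- residue_table(s)
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(rt))) {
    if (is_amino_resname(rt$resname[i])) next
    if (!is_nucleotide_resname(rt$resname[i])) {
      skipped <- c(skipped, sprintf("%s %s/%s", rt$resname[i],
                                    rt$chain[i], rt$resno[i]))
      next
    }
    res <- residue_view(s, rt$chain[i], rt$resno[i])
    st <- tryCatch(pucker_state(res), error = function(e) NULL)
    chi <- tryCatch(glycosidic_chi(res), error = function(e) NULL)
    if (is.null(st) || is.null(chi)) {
      skipped <- c(skipped, sprintf("%s %s/%s (incomplete)", rt$resname[i],
                                    rt$chain[i], rt$resno[i]))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      chain = rt$chain[i], resno = rt$resno[i],
      nucleoside = res$nucleoside,
      nu0 = st$torsions[["nu0"]], nu1 = st$torsions[["nu1"]],
      nu2 = st$torsions[["nu2"]], nu3 = st$torsions[["nu3"]],
      nu4 = st$torsions[["nu4"]],
      P = st$P, tau_m = st$tau_m, pucker_class = st$pucker_class,
      chi = chi, stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning("skipped non-standard or incomplete residues: ",
            paste(skipped, collapse = "; "))
  }
  if (!length(rows)) {
    return(data.frame(chain = character(), resno = integer(),
                      nucleoside = character(), nu0 = numeric(),
                      nu1 = numeric(), nu2 = numeric(), nu3 = numeric(),
                      nu4 = numeric(), P = numeric(), tau_m = numeric(),
                      pucker_class = character(), chi = numeric()))
  }
  do.call(rbind, rows)
}
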