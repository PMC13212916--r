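# Performance indicators for comparing rebuilt models against reference
# structures: pooled side-chain RMSD with main-chain exclusion, chi
# recovery rate and mean delta-chi, interaction network fidelity,
# per-residue lDDT, and interface F_nat.

#' @noRd
residue_key <- function(df) paste(df$chain, df$resno)

#' Pooled side-chain RMSD between model and reference
#'
#' Single RMSD over the included atoms of all compared residues (no
#' superposition: both structures share the fixed backbone frame).
#' Excluded from the comparison are the main-chain atoms: P, OP1, OP2,
#' O5', C5', C4', C3', O3' for nucleotides; N, CA, C, O, CB for amino
#' acids.  Residues whose included atom sets differ (e.g. identity
#' redesign) are excluded and counted separately.
#'
#' @param model,reference `na_structure` with shared residue numbering.
#' @return list with `rmsd` (Angstrom), `n_atoms`, `n_residues`
#'   compared and `excluded` (data.frame of skipped residues).
#' @export
sidechain_rmsd <- function(model, reference) {
  rt <- residue_table(reference)
  mt <- residue_table(model)
  common <- merge(rt, mt, by = c("chain", "resno"),
                  suffixes = c("_ref", "_mod"))
  sq <- 0
  n_atoms <- 0L
  n_res <- 0L
  excluded <- list()
  for (i in seq_len(nrow(common))) {
    ch <- common$chain[i]; rn <- common$resno[i]
    rr <- residue_view(reference, ch, rn)
    rm <- residue_view(model, ch, rn)
    excl <- if (is_amino_resname(rr$resname)) AA_MAINCHAIN else NT_MAINCHAIN
    ra <- rr$atoms[!rr$atoms$elety %in% excl & rr$atoms$elesy != "H", ]
    ma <- rm$atoms[!rm$atoms$elety %in% excl & rm$atoms$elesy != "H", ]
    if (rr$resname != rm$resname || !setequal(ra$elety, ma$elety)) {
      excluded[[length(excluded) + 1]] <-
        data.frame(chain = ch, resno = rn, resname_ref = rr$resname,
                   resname_mod = rm$resname, stringsAsFactors = FALSE)
      next
    }
    if (!nrow(ra)) next
    idx <- match(ra$elety, ma$elety)
    d2 <- (ra$x - ma$x[idx])^2 + (ra$y - ma$y[idx])^2 + (ra$z - ma$z[idx])^2
    sq <- sq + sum(d2)
    n_atoms <- n_atoms + nrow(ra)
    n_res <- n_res + 1L
  }
  list(
    rmsd = if (n_atoms) sqrt(sq / n_atoms) else NA_real_,
    n_atoms = n_atoms, n_residues = n_res,
    excluded = if (length(excluded)) do.call(rbind, excluded)
               else data.frame(chain = character(), resno = integer(),
                               resname_ref = character(),
                               resname_mod = character())
  )
}

#' Chi-angle recovery rate
#'
#' Percentage of positions whose chi deviates by less than 15 degrees
#' (strict) from the reference, using the minimal circular difference.
#'
#' @param delta_chis numeric vector of chi differences in degrees (raw
#'   differences are folded circularly).
#' @param cutoff match threshold in degrees (default 15).
#' @return percentage in \[0, 100\].
#' @export
recovery_rate <- function(delta_chis, cutoff = 15) {
  if (!length(delta_chis)) stop("empty delta-chi list")
  d <- circular_diff(delta_chis, 0)
  100 * mean(d < cutoff)
}

#' Mean absolute chi deviation
#'
#' @inheritParams recovery_rate
#' @return mean absolute circular difference, degrees.
#' @export
mean_delta_chi <- function(delta_chis) {
  if (!length(delta_chis)) stop("empty delta-chi list")
  mean(circular_diff(delta_chis, 0))
}

#' Per-position chi deviations between two structures
#'
#' Chi is compared for nucleotide residues present in both structures
#' with unchanged identity; redesigned positions (different resname)
#' are skipped, since chi is not comparable across identities.
#'
#' @param model,reference `na_structure`.
#' @return data.frame with `chain`, `resno`, `chi_model`, `chi_ref`,
#'   `delta_chi` (absolute circular difference).
#' @export
chi_deviations <- function(model, reference) {
  rt <- residue_table(reference)
  rows <- list()
  for (i in seq_len(nrow(rt))) {
    if (!is_nucleotide_resname(rt$resname[i])) next
    rm <- tryCatch(residue_view(model, rt$chain[i], rt$resno[i]),
                   error = function(e) NULL)
    if (is.null(rm) || rm$resname != rt$resname[i]) next
    rr <- residue_view(reference, rt$chain[i], rt$resno[i])
    cm <- tryCatch(glycosidic_chi(rm), error = function(e) NULL)
    cr <- tryCatch(glycosidic_chi(rr), error = function(e) NULL)
    if (is.null(cm) || is.null(cr)) next
    rows[[length(rows) + 1]] <- data.frame(
      chain = rt$chain[i], resno = rt$resno[i], chi_model = cm,
      chi_ref = cr, delta_chi = circular_diff(cm, cr),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(chain = character(), resno = integer(),
                      chi_model = numeric(), chi_ref = numeric(),
                      delta_chi = numeric()))
  }
  do.call(rbind, rows)
}

#' Interaction network fidelity from edge counts
#'
#' Geometric mean of precision and recall over base-pair/stack edges:
#' `sqrt(tp/(tp+fp) * tp/(tp+fn))`.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative
#'   edge counts.
#' @return score in \[0, 1\].
#' @export
inf_score <- function(tp, fp, fn) {
  if (tp + fp == 0 || tp + fn == 0) {
    warning("INF undefined (empty denominator); returning 0")
    return(0)
  }
  sqrt((tp / (tp + fp)) * (tp / (tp + fn)))
}

#' Detect base-pair and base-stack interactions geometrically
#'
#' A pair edge is called when at least two donor-acceptor atom pairs
#' between two bases lie within 3.4 Angstrom, with the H-bond vector
#' roughly in-plane, and the base planes within 30 degrees.  A stack
#' edge is called when base-ring centroids are closer than 4.5
#' Angstrom, planes within 30 degrees, and the in-plane centroid
#' offset below 2.5 Angstrom.
#'
#' @param s `na_structure`.
#' @param hbond_max donor-acceptor distance cutoff (Angstrom).
#' @param plane_max maximal angle between base planes (degrees).
#' @param stack_centroid,stack_offset stack geometry cutoffs (Angstrom).
#' @return data.frame of edges: `chain1`, `resno1`, `chain2`, `resno2`,
#'   `type` ("pair"/"stack"), `n_hbonds`.
#' @export
detect_interactions <- function(s, hbond_max = 3.4, plane_max = 30,
                                stack_centroid = 4.5, stack_offset = 2.5) {
  rt <- residue_table(s)
  rt <- rt[is_nucleotide_resname(rt$resname), , drop = FALSE]
  info <- list()
  for (i in seq_len(nrow(rt))) {
    v <- residue_view(s, rt$chain[i], rt$resno[i])
    tpl <- base_template(v$nucleoside)
    if (!all(tpl$ring %in% v$atoms$elety)) next
    ring <- t(vapply(tpl$ring, function(a) atom_xyz(v, a), numeric(3)))
    ctr <- colMeans(ring)
    sv <- svd(sweep(ring, 2, ctr))
    info[[length(info) + 1]] <- list(
      chain = rt$chain[i], resno = rt$resno[i],
      centroid = ctr, normal = sv$v[, 3],
      donors = intersect(tpl$donors, v$atoms$elety),
      acceptors = intersect(tpl$acceptors, v$atoms$elety),
      view = v
    )
  }
  edges <- list()
  np <- length(info)
  if (np >= 2) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      a <- info[[i]]; b <- info[[j]]
      dvec <- b$centroid - a$centroid
      cd <- vnorm(dvec)
      if (cd > 15) next
      ang <- acos(min(1, abs(sum(a$normal * b$normal)))) / DEG
      if (ang > plane_max) next
      nhb <- count_hbond_contacts(a, b, hbond_max)
      if (nhb >= 2) {
        edges[[length(edges) + 1]] <-
          data.frame(chain1 = a$chain, resno1 = a$resno, chain2 = b$chain,
                     resno2 = b$resno, type = "pair", n_hbonds = nhb,
                     stringsAsFactors = FALSE)
        next
      }
      n <- a$normal
      offset <- vnorm(dvec - sum(dvec * n) * n)
      if (cd < stack_centroid && offset < stack_offset) {
        edges[[length(edges) + 1]] <-
          data.frame(chain1 = a$chain, resno1 = a$resno, chain2 = b$chain,
                     resno2 = b$resno, type = "stack", n_hbonds = 0L,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(chain1 = character(), resno1 = integer(),
                      chain2 = character(), resno2 = integer(),
                      type = character(), n_hbonds = integer()))
  }
  do.call(rbind, edges)
}

# donor-acceptor contacts between two bases, requiring the contact
# vector to lie roughly in the base plane (true H bonds, not stacking
# near-contacts)
#' @noRd
count_hbond_contacts <- function(a, b, hbond_max) {
  n <- 0L
  pairs <- rbind(
    expand.grid(d = a$donors, ac = b$acceptors, stringsAsFactors = FALSE),
    expand.grid(d = b$donors, ac = a$acceptors, stringsAsFactors = FALSE)
  )
  half1 <- length(a$donors) * length(b$acceptors)
  for (r in seq_len(nrow(pairs))) {
    from <- if (r <= half1) a$view else b$view
    to <- if (r <= half1) b$view else a$view
    pd <- atom_xyz(from, pairs$d[r], required = FALSE)
    pa <- atom_xyz(to, pairs$ac[r], required = FALSE)
    if (is.null(pd) || is.null(pa)) next
    dd <- pa - pd
    if (vnorm(dd) > hbond_max || vnorm(dd) < 2.2) next
    if (abs(sum(vunit(dd) * a$normal)) > 0.5) next  # > 60 deg off-normal
    n <- n + 1L
  }
  n
}

#' Compare interaction networks of a model against a reference
#'
#' @param model,reference `na_structure`.
#' @param ... passed to [detect_interactions()].
#' @return list with `tp`, `fp`, `fn` and `inf`.
#' @export
compare_interactions <- function(model, reference, ...) {
  lab <- function(e) {
    if (!nrow(e)) return(character())
    paste(e$chain1, e$resno1, e$chain2, e$resno2, e$type)
  }
  em <- lab(detect_interactions(model, ...))
  er <- lab(detect_interactions(reference, ...))
  tp <- length(intersect(em, er))
  list(tp = tp, fp = length(setdiff(em, er)), fn = length(setdiff(er, em)),
       inf = inf_score(tp, length(setdiff(em, er)), length(setdiff(er, em))))
}

#' Local distance difference test (lDDT)
#'
#' Superposition-free per-residue score: the fraction of reference
#' inter-residue atom distances below the inclusion radius that are
#' preserved in the model within each threshold, averaged over the
#' thresholds (0.5, 1, 2, 4 Angstrom) and, for the structure score,
#' over residues.
#'
#' @param model,reference `na_structure` with shared numbering.
#' @param inclusion_radius reference distance cutoff (Angstrom).
#' @param thresholds preservation thresholds (Angstrom).
#' @return list with `per_residue` (data.frame `chain`, `resno`,
#'   `lddt`) and `mean`.
#' @export
lddt_score <- function(model, reference, inclusion_radius = 15,
                       thresholds = c(0.5, 1, 2, 4)) {
  am <- model$atoms
  ar <- reference$atoms
  keym <- paste(am$chain, am$resno, am$elety)
  keyr <- paste(ar$chain, ar$resno, ar$elety)
  common <- intersect(keym, keyr)
  im <- match(common, keym)
  ir <- match(common, keyr)
  xm <- as.matrix(am[im, c("x", "y", "z")])
  xr <- as.matrix(ar[ir, c("x", "y", "z")])
  res <- paste(ar$chain[ir], ar$resno[ir])
  dm <- as.matrix(stats::dist(xm))
  dr <- as.matrix(stats::dist(xr))
  inter <- outer(res, res, "!=")
  sel <- inter & dr < inclusion_radius
  diag(sel) <- FALSE
  ddiff <- abs(dm - dr)
  ures <- unique(res)
  per <- vapply(ures, function(r) {
    rows <- res == r
    use <- sel & rows  # pairs with one atom in residue r (rows side)
    nn <- sum(use)
    if (!nn) return(NA_real_)
    mean(vapply(thresholds, function(th) sum(ddiff[use] < th) / nn,
                numeric(1)))
  }, numeric(1))
  keep <- !is.na(per)
  rt <- do.call(rbind, strsplit(ures, " "))
  list(
    per_residue = data.frame(chain = rt[keep, 1],
                             resno = as.integer(rt[keep, 2]),
                             lddt = unname(per[keep]),
                             stringsAsFactors = FALSE),
    mean = mean(per[keep])
  )
}

#' Fraction of native interface contacts (F_nat)
#'
#' Native contacts are protein-residue/nucleotide pairs with any
#' heavy-atom distance below the cutoff in the reference; F_nat is the
#' fraction preserved in the model.
#'
#' @param model,reference `na_structure` containing both protein and
#'   nucleic-acid residues.
#' @param contact_cutoff heavy-atom distance cutoff (Angstrom).
#' @return fraction in \[0, 1\].
#' @export
fnat_score <- function(model, reference, contact_cutoff = 5) {
  contacts <- function(s) {
    a <- s$atoms[s$atoms$elesy != "H", ]
    prot <- a[is_amino_resname(a$resname), ]
    nuc <- a[is_nucleotide_resname(a$resname), ]
    if (!nrow(prot) || !nrow(nuc)) {
      stop("structure lacks a protein-nucleic acid interface")
    }
    d <- sqrt(outer(rowSums(prot[, c("x", "y", "z")]^2), rep(1, nrow(nuc))) +
              outer(rep(1, nrow(prot)), rowSums(nuc[, c("x", "y", "z")]^2)) -
              2 * as.matrix(prot[, c("x", "y", "z")]) %*%
                t(as.matrix(nuc[, c("x", "y", "z")])))
    hit <- which(d < contact_cutoff, arr.ind = TRUE)
    unique(paste(prot$chain[hit[, 1]], prot$resno[hit[, 1]],
                 nuc$chain[hit[, 2]], nuc$resno[hit[, 2]]))
  }
  native <- contacts(reference)
  if (!length(native)) stop("no interface contacts in reference")
  modelled <- contacts(model)
  length(intersect(native, modelled)) / length(native)
}

#' Full comparison report
#'
#' Convenience wrapper computing all metrics between a rebuilt model
#' and its reference structure.
#'
#' @param model,reference `na_structure`.
#' @param interface also compute F_nat (requires a protein-nucleic
#'   interface).
#' @return list with `rmsd`, `recovery_pct`, `mean_delta_chi`, `inf`,
#'   `mean_lddt`, `fnat` (NA unless `interface`) and `per_residue`
#'   detail tables.
#' @export
comparison_report <- function(model, reference, interface = FALSE) {
  r <- sidechain_rmsd(model, reference)
  dc <- chi_deviations(model, reference)
  ci <- compare_interactions(model, reference)
  ld <- lddt_score(model, reference)
  list(
    rmsd = r$rmsd,
    recovery_pct = if (nrow(dc)) recovery_rate(dc$delta_chi) else NA_real_,
    mean_delta_chi = if (nrow(dc)) mean_delta_chi(dc$delta_chi) else NA_real_,
    inf = ci$inf, tp = ci$tp, fp = ci$fp, fn = ci$fn,
    mean_lddt = ld$mean,
    fnat = if (interface) fnat_score(model, reference) else NA_real_,
    per_residue = list(chi = dc, lddt = ld$per_residue,
                      excluded = r$excluded)
  )
}
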