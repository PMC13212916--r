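# Synthetic fixtures: idealized nucleotides, Watson-Crick paired toy
# duplexes, and chi-angle populations drawn from a rotamer library.
# Everything is generated in code and deterministic under a fixed seed.

# Internal-coordinate atom placement (NeRF): position d bonded to c with
# given bond length, angle b-c-d and torsion a-b-c-d (degrees).
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * DEG
  tor <- torsion * DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
         bond * sin(tor) * sin(ang))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Idealized single nucleotide
#'
#' Composes an ideal sugar at the requested pseudorotation state, a
#' 5'-phosphate backbone stub (O5', P, OP1, OP2 at canonical backbone
#' torsions) and an idealized base at the requested chi.
#'
#' @param nucleoside one of A, U, G, C, dA, dT, dG, dC.
#' @param P pseudorotation phase, degrees.
#' @param tau_m pucker amplitude, degrees.
#' @param chi glycosidic torsion, degrees.
#' @param chain,resno residue identity for the returned view.
#' @return `nucleotide_view` of the complete nucleotide.
#' @export
ideal_nucleotide <- function(nucleoside, P, tau_m, chi,
                             chain = "A", resno = 1L) {
  if (!nucleoside %in% NUCLEOSIDES) stop("unknown nucleoside: ", nucleoside)
  kind <- if (is_deoxy(nucleoside)) "deoxyribose" else "ribose"
  sug <- ideal_sugar(P, tau_m, kind)
  sug$chain <- chain
  sug$resno <- resno

  c3 <- atom_xyz(sug, "C3'")
  c4 <- atom_xyz(sug, "C4'")
  c5 <- atom_xyz(sug, "C5'")
  o5 <- nerf_place(c3, c4, c5, 1.440, 110.0, 54)    # gamma gauche+
  p  <- nerf_place(c4, c5, o5, 1.600, 120.0, 180)   # beta trans
  op1 <- nerf_place(c5, o5, p, 1.485, 108.0, 60)
  op2 <- nerf_place(c5, o5, p, 1.485, 108.0, 300)
  bb <- data.frame(
    elety = c("O5'", "P", "OP1", "OP2"),
    elesy = c("O", "P", "O", "O"),
    x = c(o5[1], p[1], op1[1], op2[1]),
    y = c(o5[2], p[2], op1[2], op2[2]),
    z = c(o5[3], p[3], op1[3], op2[3]),
    stringsAsFactors = FALSE
  )
  sug$atoms <- rbind(sug$atoms, bb)
  out <- attach_base(sug, nucleoside, chi)
  out$chain <- chain
  out$resno <- resno
  out
}

# Unit normal of the base plane from a fixed atom-order formula
# (consistent between a built nucleotide and its planar template).
#' @noRd
base_plane_normal <- function(coords, nucleoside) {
  tri <- if (is_purine(nucleoside)) c("N9", "C4", "C8")
         else c("N1", "C2", "C6")
  vunit(vcross(coords[tri[2], ] - coords[tri[1], ],
               coords[tri[3], ] - coords[tri[1], ]))
}

# Canonical Watson-Crick donor/acceptor atom pairs, keyed purine first.
#' @noRd
wc_hbond_pairs <- function(purine) {
  if (sub("^d", "", purine) == "G") {
    list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2"))
  } else {
    list(c("N6", "O4"), c("N1", "N3"))
  }
}

# Solve the in-plane pose of the complementary base against the purine
# template: least squares on the canonical H-bond distances (2.9 A) and
# the C1'-C1' distance (10.5 A), with a soft steric floor.  Cached.
#' @noRd
.pair_cache <- new.env(parent = emptyenv())

#' @noRd
wc_pair_geometry <- function(nucleoside) {
  partner <- wc_complement(nucleoside)
  pu <- if (is_purine(nucleoside)) nucleoside else partner
  py <- wc_complement(pu)
  key <- paste(pu, py)
  if (is.null(.pair_cache[[key]])) {
    .pair_cache[[key]] <- solve_wc_pose(pu, py)
  }
  g <- .pair_cache[[key]]
  if (is_purine(nucleoside)) {
    list(base1 = g$pu_xy, base2 = g$py_xy, nuc1 = pu, nuc2 = py)
  } else {
    list(base1 = g$py_xy, base2 = g$pu_xy, nuc1 = py, nuc2 = pu)
  }
}

#' @noRd
solve_wc_pose <- function(pu, py) {
  # the antiparallel partner presents its opposite face: one of the two
  # in-plane mirror images of the partner template admits the canonical
  # H-bond topology; solve both and keep the better fit
  a <- solve_wc_pose_one(pu, py, flip = TRUE)
  b <- solve_wc_pose_one(pu, py, flip = FALSE)
  if (a$objective <= b$objective) a else b
}

# In-plane outward bisector of a polar atom in a 2D template.
#' @noRd
bisector_2d <- function(xy, resname, atom) {
  nb <- hb_neighbor_names(resname, atom)
  nb <- intersect(nb, rownames(xy))
  if (!length(nb)) return(NULL)
  u <- colSums(do.call(rbind, lapply(nb, function(n) {
    vunit2(xy[n, ] - xy[atom, ])
  })))
  if (sqrt(sum(u^2)) < 1e-6) return(NULL)
  -vunit2(u)
}

#' @noRd
dev_deg_2d <- function(dir, v) {
  acos(max(-1, min(1, sum(dir * vunit2(v))))) / DEG
}

#' @noRd
solve_wc_pose_one <- function(pu, py, flip) {
  t1 <- base_template(pu)
  t2 <- base_template(py)
  xy1 <- rbind(t1$xy, `C1'` = c(-GLYCOSIDIC_BOND, 0))
  xy2 <- rbind(t2$xy, `C1'` = c(-GLYCOSIDIC_BOND, 0))
  if (flip) xy2[, 2] <- -xy2[, 2]
  hb <- wc_hbond_pairs(pu)
  rn1 <- NUC_TO_RESNAME[[pu]]
  rn2 <- NUC_TO_RESNAME[[py]]
  don1 <- t1$donors

  # angular deviation of a candidate H bond from ideal: the donor H
  # points along the bisector (ring N-H) or +-60 degrees off it
  # (planar amine); carbonyl/ring lone pairs are treated leniently
  hb_dev <- function(xyA, rnA, a, xyB, b) {
    d <- 0
    dir <- bisector_2d(xyA, rnA, a)
    if (!is.null(dir)) {
      ndev <- dev_deg_2d(dir, xyB[b, ] - xyA[a, ])
      single <- length(intersect(hb_neighbor_names(rnA, a),
                                 rownames(xyA))) == 1
      d <- if (single) abs(ndev - 60) * (ndev > 60) else ndev
    }
    d
  }

  obj <- function(par) {
    th <- par[1]
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    p2 <- sweep(xy2 %*% t(rot), 2, par[2:3], "+")
    val <- 0
    for (h in hb) {
      val <- val + (sqrt(sum((xy1[h[1], ] - p2[h[2], ])^2)) - 2.90)^2
      dev1 <- if (h[1] %in% don1) hb_dev(xy1, rn1, h[1], p2, h[2])
              else hb_dev(p2, rn2, h[2], xy1, h[1])
      val <- val + 0.004 * dev1^2
    }
    val <- val + 0.3 * (sqrt(sum((xy1["C1'", ] - p2["C1'", ])^2)) - 10.5)^2
    dall <- sqrt(outer(rowSums(xy1^2), rep(1, nrow(p2))) +
                 outer(rep(1, nrow(xy1)), rowSums(p2^2)) -
                 2 * xy1 %*% t(p2))
    val + 4 * sum(pmax(0, 2.6 - dall)^2)
  }

  best <- NULL
  hbc1 <- colMeans(do.call(rbind, lapply(hb, function(h) xy1[h[1], , drop = FALSE])))
  hbc2 <- colMeans(do.call(rbind, lapply(hb, function(h) xy2[h[2], , drop = FALSE])))
  u <- vunit2(hbc1 - colMeans(t1$xy))
  for (th0 in seq(0, 330, by = 30) * DEG) {
    rot <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2, 2)
    t0 <- hbc1 + 2.9 * u - as.vector(rot %*% hbc2)
    fit <- stats::optim(c(th0, t0), obj,
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- best$par[1]
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p2 <- sweep(xy2 %*% t(rot), 2, best$par[2:3], "+")
  mid <- (xy1["C1'", ] + p2["C1'", ]) / 2
  list(pu_xy = sweep(xy1, 2, mid), py_xy = sweep(p2, 2, mid),
       objective = best$value)
}

# Helical parameters of the idealized duplex forms.
#' @noRd
duplex_params <- function(form) {
  if (form == "B") {
    list(rise = 3.38, twist = 36, P = 162, chi = 250)
  } else {
    list(rise = 2.81, twist = 32.7, P = 18, chi = 200)
  }
}

#' Idealized toy duplex
#'
#' Builds a two-stranded, Watson-Crick paired duplex from idealized
#' helical parameters (B form: rise 3.38 A, twist 36 deg, 2'-endo
#' sugars, chi in the -ac region; A form: rise 2.81 A, twist 32.7 deg,
#' 3'-endo sugars, chi in the -ap region).  Base pairs are placed from
#' the solved Watson-Crick pose, so the H-bond geometry validates
#' against [detect_interactions()].  The construction is deterministic;
#' `seed` is accepted for interface symmetry with stochastic fixtures.
#'
#' @param sequence character string of 4-20 nucleotides over one
#'   alphabet (DNA or RNA); e.g. "GCGC" with `alphabet = "DNA"`.
#' @param form helical form, `"B"` or `"A"`.
#' @param alphabet `"DNA"`, `"RNA"` or `"auto"` (infer from letters,
#'   defaulting to DNA for the B form and RNA for the A form).
#' @param chi optional chi override (degrees) applied to all positions,
#'   or a vector of per-position values for strand 1 (strand 2 reuses
#'   the scalar/default).
#' @param seed unused (deterministic fixture); kept for uniformity.
#' @return `na_structure` with chains A and B (B numbered so the two
#'   strands are exact reverse complements).
#' @export
toy_duplex <- function(sequence, form = c("B", "A"), alphabet = "auto",
                       chi = NULL, seed = NULL) {
  form <- match.arg(form)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters1)
  if (n < 4 || n > 20) stop("sequence must have 4-20 nucleotides")
  if (!all(letters1 %in% c("A", "C", "G", "T", "U"))) {
    stop("invalid sequence letters")
  }
  if (alphabet == "auto") {
    alphabet <- if ("U" %in% letters1) "RNA"
                else if ("T" %in% letters1) "DNA"
                else if (form == "B") "DNA" else "RNA"
  }
  if (alphabet == "DNA" && "U" %in% letters1) stop("U is not a DNA letter")
  if (alphabet == "RNA" && "T" %in% letters1) stop("T is not an RNA letter")
  nucs <- if (alphabet == "DNA") paste0("d", letters1) else letters1

  par <- duplex_params(form)
  tau <- if (alphabet == "DNA") 37 else 40
  chi1 <- if (is.null(chi)) rep(par$chi, n) else rep_len(chi, n)
  chi2 <- rep(par$chi, n)

  v1 <- vector("list", n)
  v2 <- vector("list", n)
  for (i in seq_len(n)) {
    pg <- wc_pair_geometry(nucs[i])
    helix <- function(p3) {
      p3 <- rotate_about_axis(p3, c(0, 0, 0), c(0, 0, 1),
                              par$twist * (i - 1))
      p3[, 3] <- p3[, 3] + par$rise * (i - 1)
      p3
    }
    # `strand_dir` is the strand's 5'->3' direction along the helix
    # axis (+1 for strand 1, -1 for the antiparallel strand 2).  Base
    # atoms are coplanar, so the superposition alone could mirror the
    # sugar onto either face; an out-of-plane pseudo-point, with its
    # sign chosen so the 5'-phosphate stub points 5'-ward, fixes the
    # face and makes the two strands antiparallel.
    place <- function(nuc, chi_i, targets2d, chain, resno, strand_dir) {
      nt <- ideal_nucleotide(nuc, par$P, tau, chi_i, chain, resno)
      tpl_atoms <- base_atom_names(nuc)
      idx <- match(tpl_atoms, nt$atoms$elety)
      mov <- view_coords(nt)[idx, ]
      rownames(mov) <- tpl_atoms
      n_m <- base_plane_normal(mov, nuc)
      glyc <- if (is_purine(nuc)) "N9" else "N1"
      s_model <- sign(sum((atom_xyz(nt, "P") - atom_xyz(nt, glyc)) * n_m))
      t_sign <- -strand_dir * s_model
      tgt <- helix(cbind(targets2d[tpl_atoms, , drop = FALSE], 0))
      pseudo_t <- helix(cbind(targets2d[glyc, 1], targets2d[glyc, 2],
                              t_sign))
      fit <- superpose_points(rbind(mov, mov[glyc, ] + n_m),
                              rbind(tgt, pseudo_t))
      set_view_coords(nt, fit$transform(view_coords(nt)))
    }
    v1[[i]] <- place(nucs[i], chi1[i], pg$base1, "A", i, +1)
    v2[[i]] <- place(wc_complement(nucs[i]), chi2[i], pg$base2, "B",
                     n + 1 - i, -1)
  }
  views_to_structure(c(v1, v2[order(vapply(v2, function(v) as.numeric(v$resno), 0))]))
}

#' Draw a chi-angle population from a rotamer library group
#'
#' Samples `n` chi values from the Gaussian mixture defined by the
#' (chi, sd, probability) entries of one library group, wrapped to
#' \[0, 360).
#'
#' @param library `rotamer_library`.
#' @param nucleoside nucleoside label.
#' @param pucker_class `"ENDO2"`, `"ENDO3"`, or `"ANY"` (basic flavor).
#' @param n sample size.
#' @param seed RNG seed (mandatory: fixtures are deterministic).
#' @return numeric vector of chi values in \[0, 360).
#' @export
sample_chi_population <- function(library, nucleoside, pucker_class, n,
                                  seed) {
  e <- library_group(library, nucleoside, pucker_class)
  if (!nrow(e)) stop("no library entries for this group")
  with_seed(seed, {
    comp <- sample.int(nrow(e), n, replace = TRUE, prob = e$probability)
    wrap360(stats::rnorm(n, mean = e$chi[comp], sd = e$sd[comp]))
  })
}
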