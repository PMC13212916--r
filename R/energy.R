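# Interaction energy model for candidate selection: capped 6-12
# Lennard-Jones on per-element radii, a geometric hydrogen-bond bonus,
# and a rotamer prior proportional to -ln(library probability).  The
# functional form is a package design choice (pluggable through
# `energy_model()`); selection quality is therefore assessed in trend,
# not as absolute energies.

#' Energy model parameters
#'
#' @param lj_radii named per-element van der Waals radii (Angstrom).
#' @param lj_eps well depth (kcal/mol) applied to all pairs.
#' @param clash_cap per-pair repulsion ceiling (kcal/mol).
#' @param hbond_weight bonus magnitude per geometric H bond (kcal/mol).
#' @param hbond_range donor-acceptor distance window (Angstrom).
#' @param hbond_min_angle minimal root-donor-acceptor angle (degrees).
#' @param prior_weight multiplier on `-ln(probability)`.
#' @param cutoff all-atom interaction cutoff (Angstrom).
#' @return list of class `energy_model`.
#' @export
energy_model <- function(lj_radii = c(C = 1.70, N = 1.55, O = 1.52,
                                      P = 1.80, S = 1.80, H = 1.10),
                         lj_eps = 0.1, clash_cap = 10,
                         hbond_weight = 1.5, hbond_range = c(2.6, 3.4),
                         ring_cone = 40, terminal_cone = 85,
                         mismatch_weight = 1.5, prior_weight = 0.5,
                         cutoff = 8) {
  stopifnot(clash_cap > 0, is.finite(clash_cap), hbond_weight >= 0,
            prior_weight >= 0)
  structure(list(lj_radii = lj_radii, lj_eps = lj_eps,
                 clash_cap = clash_cap, hbond_weight = hbond_weight,
                 hbond_range = hbond_range, ring_cone = ring_cone,
                 terminal_cone = terminal_cone,
                 mismatch_weight = mismatch_weight,
                 prior_weight = prior_weight, cutoff = cutoff),
            class = "energy_model")
}

# Annotated atom set: coordinates plus element radii and H-bond roles.
#' @noRd
atom_set <- function(df) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  roles <- hb_roles(df)
  is_base <- vapply(seq_len(nrow(df)), function(i) {
    is_nucleotide_resname(df$resname[i]) &&
      df$elety[i] %in% base_atom_names(RESNAME_TO_NUC[[df$resname[i]]])
  }, logical(1))
  list(xyz = xyz, elety = df$elety, elesy = df$elesy,
       resname = df$resname, chain = df$chain, resno = df$resno,
       donors = roles$donors, acceptors = roles$acceptors,
       dirs = roles$dirs, is_base = is_base)
}

#' @noRd
view_atom_df <- function(view) {
  data.frame(chain = view$chain, resno = view$resno,
             resname = view$resname, elety = view$atoms$elety,
             elesy = view$atoms$elesy, x = view$atoms$x,
             y = view$atoms$y, z = view$atoms$z, stringsAsFactors = FALSE)
}

# Donor/acceptor indices of an atom table together with each polar
# atom's outward direction: the external bisector of its bonded heavy
# neighbours (the proton / lone-pair direction for planar groups).
#' @noRd
hb_roles <- function(df) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  key <- paste(df$chain, df$resno)
  donors <- integer()
  acceptors <- integer()
  dirs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    role <- atom_hb_role(df$resname[i], df$elety[i])
    if (is.null(role)) next
    nb <- hb_neighbor_names(df$resname[i], df$elety[i])
    j <- which(key == key[i] & df$elety %in% nb)
    if (length(j)) {
      u <- rowsum(t(apply(xyz[j, , drop = FALSE], 1,
                          function(p) vunit(p - xyz[i, ]))),
                  rep(1, length(j)))
      if (vnorm(u) > 1e-6) {
        dirs[[i]] <- list(dir = -vunit(as.numeric(u)),
                          terminal = length(j) == 1)
      }
    }
    if ("donor" %in% role) donors <- c(donors, i)
    if ("acceptor" %in% role) acceptors <- c(acceptors, i)
  }
  list(donors = donors, acceptors = acceptors, dirs = dirs)
}

# Bonded heavy neighbours used for the outward direction of each polar
# atom.
#' @noRd
hb_neighbor_names <- function(resname, elety) {
  bb <- list(`O2'` = "C2'", `O3'` = "C3'", `O5'` = c("C5'", "P"),
             `O4'` = c("C1'", "C4'"), OP1 = "P", OP2 = "P")
  if (elety %in% names(bb)) return(bb[[elety]])
  if (is_nucleotide_resname(resname)) {
    base <- list(
      N6 = "C6", N4 = "C4", N2 = "C2", O6 = "C6", O4 = "C4", O2 = "C2",
      N1 = c("C2", "C6"), N3 = c("C2", "C4"), N7 = c("C5", "C8")
    )
    if (elety %in% names(base)) return(base[[elety]])
  }
  aa <- list(N = "CA", O = "C", OG = "CB", OG1 = "CB", OH = "CZ",
             NE2 = "CD", ND1 = "CG", NZ = "CE", NE = "CD", NH1 = "CZ",
             NH2 = "CZ", ND2 = "CG", OD1 = "CG", OD2 = "CG",
             OE1 = "CD", OE2 = "CD")
  if (elety %in% names(aa)) return(aa[[elety]])
  character()
}

#' @noRd
atom_hb_role <- function(resname, elety) {
  if (is_nucleotide_resname(resname)) {
    if (elety %in% c("O3'", "O4'", "O5'", "OP1", "OP2")) return("acceptor")
    if (elety == "O2'") return(c("donor", "acceptor"))
    tpl <- base_template(RESNAME_TO_NUC[[resname]])
    if (elety %in% tpl$donors) return("donor")
    if (elety %in% tpl$acceptors) return("acceptor")
    return(NULL)
  }
  if (is_amino_resname(resname)) {
    if (elety == "N") return("donor")
    if (elety == "O") return("acceptor")
    if (elety %in% c("OG", "OG1", "OH")) return(c("donor", "acceptor"))
    if (elety %in% c("NE2", "ND1", "NZ", "NE", "NH1", "NH2", "ND2"))
      return("donor")
    if (elety %in% c("OD1", "OD2", "OE1", "OE2")) return("acceptor")
  }
  NULL
}

# Pairwise interaction energy between two annotated atom sets.
# `exclude` is an optional logical matrix (nA x nB) of bonded pairs to
# skip (backbone connectivity across residues).
#' @noRd
interaction_energy <- function(A, B, model, exclude = NULL) {
  ra <- model$lj_radii[A$elesy]
  rb <- model$lj_radii[B$elesy]
  ra[is.na(ra)] <- 1.6
  rb[is.na(rb)] <- 1.6
  d2 <- outer(rowSums(A$xyz^2), rep(1, nrow(B$xyz))) +
    outer(rep(1, nrow(A$xyz)), rowSums(B$xyz^2)) -
    2 * A$xyz %*% t(B$xyz)
  d <- sqrt(pmax(d2, 1e-12))
  mask <- d < model$cutoff
  if (!is.null(exclude)) mask <- mask & !exclude
  if (!any(mask)) return(0)
  r0 <- outer(ra, rb, "+")
  sr <- (r0[mask] / d[mask])
  lj <- model$lj_eps * (sr^12 - 2 * sr^6)
  e <- sum(pmin(lj, model$clash_cap))
  e + hbond_energy(A, B, d, model)
}

# Does atom i (in set S) geometrically "face" the target point?  The
# target must lie within the atom's interaction cone: `ring_cone`
# around the outward bisector for two-neighbour (ring) atoms,
# `terminal_cone` for single-neighbour atoms (planar amines and
# carbonyls, whose protons/lone pairs fan out to ~60 degrees).
#' @noRd
cone_ok <- function(S, i, target, model) {
  info <- S$dirs[[i]]
  if (is.null(info)) return(TRUE)
  v <- target - S$xyz[i, ]
  dev <- acos(max(-1, min(1, sum(info$dir * vunit(v))))) / DEG
  dev <= if (info$terminal) model$terminal_cone else model$ring_cone
}

#' @noRd
hbond_energy <- function(A, B, d, model) {
  in_window <- function(x) {
    x >= model$hbond_range[1] & x <= model$hbond_range[2]
  }
  count_hb <- function(from, to, dmat) {
    n <- 0L
    for (don in from$donors) {
      for (ac in to$acceptors[in_window(dmat[don, to$acceptors])]) {
        if (cone_ok(from, don, to$xyz[ac, ], model) &&
            cone_ok(to, ac, from$xyz[don, ], model)) {
          n <- n + 1L
        }
      }
    }
    n
  }
  nh <- count_hb(A, B, d) + count_hb(B, A, t(d))
  # frontal donor-donor / acceptor-acceptor apposition of nucleobase
  # atoms at H-bond distance is electrostatically unfavourable; this is
  # what tells a Watson-Crick partner from a wobble-like mismatch on a
  # rigid frame
  pure <- function(S, kind) {
    i <- if (kind == "don") setdiff(S$donors, S$acceptors)
         else setdiff(S$acceptors, S$donors)
    i[S$is_base[i]]
  }
  count_mm <- function(ia, ib) {
    n <- 0L
    for (i in ia) {
      for (j in ib[in_window(d[i, ib])]) {
        if (cone_ok(A, i, B$xyz[j, ], model) &&
            cone_ok(B, j, A$xyz[i, ], model)) {
          n <- n + 1L
        }
      }
    }
    n
  }
  nmm <- count_mm(pure(A, "don"), pure(B, "don")) +
    count_mm(pure(A, "acc"), pure(B, "acc"))
  -model$hbond_weight * nh + model$mismatch_weight * nmm
}

#' A designable position for packing
#'
#' @param id position label.
#' @param candidates list of `rotamer_candidate` (>= 1).
#' @param chain,resno residue identity in the parent structure.
#' @param designable whether nucleotide identity is variable.
#' @return list of class `pack_position`.
#' @export
pack_position <- function(id, candidates, chain, resno,
                          designable = FALSE) {
  if (!length(candidates)) stop("position needs at least one candidate")
  structure(list(id = id, candidates = candidates, chain = chain,
                 resno = resno, designable = designable),
            class = "pack_position")
}

#' Self and pair energy tables
#'
#' Self energies combine each candidate's interaction with the fixed
#' environment and the rotamer prior `prior_weight * (-ln p)`; pair
#' energies cover candidate pairs at distinct positions (symmetric,
#' zero beyond the cutoff).  Bonded backbone pairs across neighbouring
#' residues (O3'(i)-P(i+1)) are excluded from the clash term.
#'
#' @param positions list of `pack_position`.
#' @param fixed_env `na_structure` of the fixed context, excluding all
#'   atoms of the designable positions.
#' @param model `energy_model`.
#' @return list of class `energy_tables` with `self` (list of numeric
#'   vectors) and `pair` (list-of-lists of matrices or NULL).
#' @export
compute_tables <- function(positions, fixed_env, model = energy_model()) {
  np <- length(positions)
  env <- atom_set(fixed_env$atoms[fixed_env$atoms$elesy != "H", ,
                                  drop = FALSE])
  cand_sets <- lapply(positions, function(p) {
    lapply(p$candidates, function(cand) atom_set(view_atom_df(cand$view)))
  })
  self_e <- vector("list", np)
  for (i in seq_len(np)) {
    p <- positions[[i]]
    self_e[[i]] <- vapply(seq_along(p$candidates), function(a) {
      cs <- cand_sets[[i]][[a]]
      excl <- bonded_exclusion(cs, env)
      prior <- p$candidates[[a]]$probability
      prior_e <- if (is.na(prior)) 0 else model$prior_weight * (-log(prior))
      interaction_energy(cs, env, model, exclude = excl) + prior_e
    }, numeric(1))
  }
  pair_e <- rep(list(vector("list", np)), np)
  if (np >= 2) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      ni <- length(positions[[i]]$candidates)
      nj <- length(positions[[j]]$candidates)
      m <- matrix(0, ni, nj)
      for (a in seq_len(ni)) for (b in seq_len(nj)) {
        ca <- cand_sets[[i]][[a]]
        cb <- cand_sets[[j]][[b]]
        m[a, b] <- interaction_energy(ca, cb, model,
                                      exclude = bonded_exclusion(ca, cb))
      }
      pair_e[[i]][j] <- if (all(m == 0)) list(NULL) else list(m)
    }
  }
  structure(list(self = self_e, pair = pair_e, n = np), class = "energy_tables")
}

# Covalent backbone connectivity across residue boundaries, excluded
# from the clash term: O3'(i) - P(i+1).
#' @noRd
bonded_exclusion <- function(A, B) {
  excl <- NULL
  ia <- which(A$elety == "O3'")
  ib <- which(B$elety == "P" & B$chain == A$chain[ia][1] &
              B$resno == A$resno[ia][1] + 1)
  add <- function(excl, i, j, nA, nB) {
    if (is.null(excl)) excl <- matrix(FALSE, nA, nB)
    excl[i, j] <- TRUE
    excl
  }
  if (length(ia) && length(ib)) {
    excl <- add(excl, ia[1], ib[1], nrow(A$xyz), nrow(B$xyz))
  }
  ja <- which(A$elety == "P")
  jb <- which(B$elety == "O3'" & B$chain == A$chain[ja][1] &
              B$resno == A$resno[ja][1] - 1)
  if (length(ja) && length(jb)) {
    excl <- add(excl, ja[1], jb[1], nrow(A$xyz), nrow(B$xyz))
  }
  excl
}
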