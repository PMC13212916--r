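# Idealized furanose geometry: a five-membered (deoxy)ribose ring whose
# endocyclic torsions realize the cosine pseudorotation model at a
# requested phase/amplitude, closed by least squares under ideal bond
# lengths and angles, plus the exocyclic C5'/O3'(/O2') substituents.

RING_ORDER <- c("O4'", "C1'", "C2'", "C3'", "C4'")

RING_BONDS <- data.frame(
  a = c("O4'", "C1'", "C2'", "C3'", "C4'"),
  b = c("C1'", "C2'", "C3'", "C4'", "O4'"),
  len = c(1.414, 1.528, 1.525, 1.528, 1.446),
  stringsAsFactors = FALSE
)

RING_ANGLES <- data.frame(
  a = c("C4'", "O4'", "C1'", "C2'", "C3'"),
  b = c("O4'", "C1'", "C2'", "C3'", "C4'"),
  c = c("C1'", "C2'", "C3'", "C4'", "O4'"),
  ang = c(109.9, 106.4, 101.5, 102.7, 105.5),
  stringsAsFactors = FALSE
)

#' @noRd
angle_between <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

# Objective for ring closure: weighted squared residuals of bond
# lengths, bond angles and the five target torsions.
#' @noRd
ring_objective <- function(par, nu_target) {
  xyz <- matrix(par, 5, 3)
  rownames(xyz) <- RING_ORDER
  val <- 0
  for (i in seq_len(5)) {
    d <- vnorm(xyz[RING_BONDS$a[i], ] - xyz[RING_BONDS$b[i], ])
    val <- val + 400 * (d - RING_BONDS$len[i])^2
    ang <- angle_between(xyz[RING_ANGLES$a[i], ], xyz[RING_ANGLES$b[i], ],
                         xyz[RING_ANGLES$c[i], ])
    val <- val + 0.002 * (ang - RING_ANGLES$ang[i])^2
    q <- NU_QUADS[[i]]
    nu <- dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ],
                         xyz[q[4], ])
    val <- val + 0.02 * circular_diff(nu, nu_target[i])^2
  }
  val
}

#' @noRd
ring_initial <- function(tau_m, phase_shift) {
  r <- 1.49 / (2 * sin(36 * DEG))
  th <- (90 + 72 * (0:4)) * DEG
  amp <- 0.0065 * tau_m          # rough out-of-plane scale (Angstrom/deg)
  z <- amp * cos(phase_shift * DEG + (4 * pi / 5) * (0:4))
  cbind(r * cos(th), r * sin(th), z)
}

#' Idealized furanose ring at a requested pseudorotation state
#'
#' Builds a (deoxy)ribose whose endocyclic torsions best fit
#' `nu_j = tau_m cos(P + 144 (j - 2))`, with ideal bond lengths/angles
#' enforced by least squares, then adds the exocyclic substituents C5'
#' (on C4', on the base-carrying face), O3' (on C3', opposite face) and,
#' for ribose, O2' (on C2', opposite face).
#'
#' @param P requested pseudorotation phase, degrees.
#' @param tau_m requested amplitude, degrees; must lie in (10, 60).
#' @param kind `"ribose"` or `"deoxyribose"`.
#' @return `nucleotide_view` (resname "SUG") with the sugar atoms; the
#'   measured phase of the result is within 2 degrees of `P`.
#' @export
ideal_sugar <- function(P, tau_m, kind = c("ribose", "deoxyribose")) {
  kind <- match.arg(kind)
  if (tau_m <= 10 || tau_m >= 60) stop("tau_m must be in (10, 60) degrees")
  P <- wrap360(P)
  cache_key <- sprintf("%.6f|%.6f|%s", P, tau_m, kind)
  cached <- .sugar_cache[[cache_key]]
  if (!is.null(cached)) return(cached)
  nu_target <- cosine_model_torsions(P, tau_m)

  best <- NULL
  for (shift in seq(0, 288, by = 72)) {
    fit <- stats::nlminb(
      start = as.vector(ring_initial(tau_m, P + shift)),
      objective = ring_objective, nu_target = as.numeric(nu_target),
      control = list(iter.max = 500, eval.max = 1000)
    )
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  xyz <- matrix(best$par, 5, 3)
  rownames(xyz) <- RING_ORDER

  ring <- nucleotide_view(
    atoms = data.frame(elety = RING_ORDER,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    resname = "SUG"
  )
  Pm <- pseudorotation_phase(endocyclic_torsions(ring))
  if (circular_diff(Pm, P) > 2) {
    stop(sprintf("ring closure failed: requested P = %.1f, achieved %.1f",
                 P, Pm))
  }

  n <- ring_up_normal(xyz)
  ext <- rbind(
    `C5'` = xyz["C4'", ] + 1.510 * subst_dir(xyz, "C4'", "C3'", "O4'", n, up = TRUE),
    `O3'` = xyz["C3'", ] + 1.423 * subst_dir(xyz, "C3'", "C2'", "C4'", n, up = FALSE)
  )
  if (kind == "ribose") {
    ext <- rbind(ext, `O2'` = xyz["C2'", ] +
                   1.413 * subst_dir(xyz, "C2'", "C1'", "C3'", n, up = FALSE))
  }
  atoms <- data.frame(
    elety = c(RING_ORDER, rownames(ext)),
    x = c(xyz[, 1], ext[, 1]), y = c(xyz[, 2], ext[, 2]),
    z = c(xyz[, 3], ext[, 3]), stringsAsFactors = FALSE
  )
  out <- nucleotide_view(atoms, resname = "SUG")
  .sugar_cache[[cache_key]] <- out
  out
}

#' @noRd
.sugar_cache <- new.env(parent = emptyenv())

# Consistent "up" normal of the ring: the face carrying C5' and the
# nucleobase.  Defined from the ring atom cycle so all generated sugars
# share one handedness.
#' @noRd
ring_up_normal <- function(xyz) {
  c1 <- xyz["C1'", ] - xyz["O4'", ]
  c4 <- xyz["C4'", ] - xyz["O4'", ]
  vunit(vcross(c4, c1))
}

# Direction of an exocyclic substituent on ring atom `x` with ring
# neighbours `a` and `b`; `up` selects the face relative to normal `n`.
#' @noRd
subst_dir <- function(xyz, x, a, b, n, up = TRUE) {
  ua <- vunit(xyz[a, ] - xyz[x, ])
  ub <- vunit(xyz[b, ] - xyz[x, ])
  bis <- -vunit(ua + ub)
  t <- vunit(vcross(ua, ub))
  if (sum(t * n) < 0) t <- -t
  if (!up) t <- -t
  alpha <- 54.75 * DEG
  vunit(cos(alpha) * bis + sin(alpha) * t)
}

#' @noRd
c1_substituent_dir <- function(sugar_view) {
  xyz <- view_coords(sugar_view)
  rownames(xyz) <- sugar_view$atoms$elety
  ring <- xyz[RING_ORDER, ]
  subst_dir(ring, "C1'", "O4'", "C2'", ring_up_normal(ring), up = TRUE)
}
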