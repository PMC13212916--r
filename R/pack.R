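# Combinatorial search for the global minimum energy conformation
# (GMEC): Goldstein dead-end elimination, exhaustive enumeration of
# small residual spaces, and Monte Carlo/simulated annealing for large
# ones.

#' @noRd
pair_lookup <- function(tables, i, j) {
  if (i < j) tables$pair[[i]][[j]]
  else if (j < i) {
    m <- tables$pair[[j]][[i]]
    if (is.null(m)) NULL else t(m)
  } else NULL
}

#' Total energy of an assignment
#'
#' @param tables `energy_tables`.
#' @param assignment integer candidate index per position.
#' @return total energy (self + pair sums).
#' @export
assignment_energy <- function(tables, assignment) {
  e <- sum(vapply(seq_len(tables$n),
                  function(i) tables$self[[i]][assignment[i]], numeric(1)))
  if (tables$n >= 2) {
    for (i in 1:(tables$n - 1)) for (j in (i + 1):tables$n) {
      m <- tables$pair[[i]][[j]]
      if (!is.null(m)) e <- e + m[assignment[i], assignment[j]]
    }
  }
  e
}

#' Goldstein singles dead-end elimination
#'
#' Iterates the Goldstein criterion to a fixpoint: candidate `a` at
#' position `i` is eliminated when some competitor `b` satisfies
#' `self(a) - self(b) + sum_j min_c (pair(a,c) - pair(b,c)) > 0`.
#' The criterion is provably sound: no candidate belonging to a GMEC
#' is ever removed.
#'
#' @param tables `energy_tables`.
#' @return list with `alive` (list of surviving candidate index
#'   vectors) and `tables` (unchanged input, for downstream search).
#' @export
dee_goldstein <- function(tables) {
  np <- tables$n
  alive <- lapply(seq_len(np), function(i) seq_along(tables$self[[i]]))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(np)) {
      cur <- alive[[i]]
      if (length(cur) <= 1) next
      keep <- rep(TRUE, length(cur))
      for (ai in seq_along(cur)) {
        a <- cur[ai]
        for (b in cur) {
          if (a == b) next
          gap <- tables$self[[i]][a] - tables$self[[i]][b]
          for (j in seq_len(np)) {
            if (j == i) next
            m <- pair_lookup(tables, i, j)
            if (is.null(m)) next
            gap <- gap + min(m[a, alive[[j]]] - m[b, alive[[j]]])
          }
          if (gap > 0) {
            keep[ai] <- FALSE
            changed <- TRUE
            break
          }
        }
      }
      if (!any(keep)) stop("dead-end elimination emptied a position")
      alive[[i]] <- cur[keep]
    }
  }
  list(alive = alive, tables = tables)
}

#' @noRd
exhaustive_search <- function(tables, alive) {
  np <- tables$n
  # first position most significant so ties resolve to the lowest
  # (position, candidate) lexicographic assignment
  grid <- rev(expand.grid(rev(alive), KEEP.OUT.ATTRS = FALSE))
  e <- numeric(nrow(grid))
  for (i in seq_len(np)) e <- e + tables$self[[i]][grid[[i]]]
  if (np >= 2) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      m <- tables$pair[[i]][[j]]
      if (!is.null(m)) e <- e + m[cbind(grid[[i]], grid[[j]])]
    }
  }
  best <- which.min(e)
  list(assignment = as.integer(grid[best, ]), total_energy = e[best],
       method = "DEE_EXHAUSTIVE")
}

#' Monte Carlo / simulated annealing search
#'
#' Metropolis single-position moves under geometric cooling; the best
#' assignment ever seen is returned.  Deterministic for a fixed seed.
#'
#' @param tables `energy_tables`.
#' @param alive surviving candidates per position (default: all).
#' @param schedule list with `t_start`, `t_end`, `steps`.
#' @param restarts independent annealing runs.
#' @param seed RNG seed.
#' @return list with `assignment`, `total_energy`, `method = "DEE_MCSA"`.
#' @export
mcsa_search <- function(tables, alive = NULL,
                        schedule = list(t_start = 10, t_end = 0.05,
                                        steps = 4000),
                        restarts = 3, seed = 1) {
  np <- tables$n
  if (is.null(alive)) {
    alive <- lapply(seq_len(np), function(i) seq_along(tables$self[[i]]))
  }
  delta_e <- function(assign, i, new) {
    d <- tables$self[[i]][new] - tables$self[[i]][assign[i]]
    for (j in seq_len(np)) {
      if (j == i) next
      m <- pair_lookup(tables, i, j)
      if (!is.null(m)) d <- d + m[new, assign[j]] - m[assign[i], assign[j]]
    }
    d
  }
  with_seed(seed, {
    best <- NULL
    cool <- (schedule$t_end / schedule$t_start)^(1 / schedule$steps)
    for (r in seq_len(restarts)) {
      assign <- vapply(alive, function(a) a[sample.int(length(a), 1)],
                       integer(1))
      e <- assignment_energy(tables, assign)
      if (is.null(best) || e < best$total_energy) {
        best <- list(assignment = assign, total_energy = e)
      }
      temp <- schedule$t_start
      for (s in seq_len(schedule$steps)) {
        i <- sample.int(np, 1)
        opts <- alive[[i]]
        if (length(opts) == 1) {
          temp <- temp * cool
          next
        }
        new <- opts[sample.int(length(opts), 1)]
        if (new == assign[i]) {
          temp <- temp * cool
          next
        }
        d <- delta_e(assign, i, new)
        if (d < 0 || stats::runif(1) < exp(-d / temp)) {
          assign[i] <- new
          e <- e + d
          if (e < best$total_energy - 1e-12) {
            best <- list(assignment = assign, total_energy = e)
          }
        }
        temp <- temp * cool
      }
    }
    best$total_energy <- assignment_energy(tables, best$assignment)
    c(best, method = "DEE_MCSA")
  })
}

#' Select the minimum-energy assignment
#'
#' Runs dead-end elimination, then exhaustive enumeration when the
#' residual space has at most `exhaustive_limit` combinations,
#' otherwise Monte Carlo/simulated annealing on the reduced space.
#'
#' @param tables `energy_tables`.
#' @param seed RNG seed (annealing path only).
#' @param exhaustive_limit enumeration threshold (default 1e6).
#' @return list with `assignment` (one candidate index per position),
#'   `total_energy` and `method`.
#' @export
solve_gmec <- function(tables, seed = 1, exhaustive_limit = 1e6) {
  dee <- dee_goldstein(tables)
  space <- prod(vapply(dee$alive, length, numeric(1)))
  if (space <= exhaustive_limit) {
    exhaustive_search(tables, dee$alive)
  } else {
    mcsa_search(tables, dee$alive, seed = seed)
  }
}

#' Rebuild or redesign positions of a structure
#'
#' End-to-end packing: enumerate rotamer candidates at each requested
#' position, build energy tables against the fixed environment, search
#' for the minimum-energy assignment, and splice the selected
#' candidates back onto the rigid backbone.
#'
#' @param s `na_structure`.
#' @param positions data.frame with columns `chain`, `resno` and
#'   optionally `designable` (logical; designable positions are offered
#'   all four nucleotides of their alphabet).
#' @param library `rotamer_library`.
#' @param cfg `build_config`; its `allowed_nucleosides` (when set)
#'   overrides the per-position identity sets.
#' @param model `energy_model`.
#' @param seed RNG seed for the annealing path.
#' @return list with `structure` (rebuilt `na_structure`), `solution`
#'   (assignment/energy/method) and `report` (per-position data.frame:
#'   selected nucleoside, sugar, chi, probability).
#' @export
pack_structure <- function(s, positions, library, cfg = build_config(),
                           model = energy_model(), seed = 1) {
  if (is.null(positions$designable)) positions$designable <- FALSE
  pos_objs <- list()
  for (k in seq_len(nrow(positions))) {
    res <- residue_view(s, positions$chain[k], positions$resno[k])
    allowed <- cfg$allowed_nucleosides
    if (is.null(allowed)) {
      allowed <- if (positions$designable[k]) {
        if (is_deoxy(res$nucleoside)) DNA_NUCLEOSIDES else RNA_NUCLEOSIDES
      } else res$nucleoside
    }
    cfg_k <- cfg
    cfg_k$allowed_nucleosides <- allowed
    next_p <- NULL
    if (cfg$backrub_axis == "PP") {
      nxt <- tryCatch(residue_view(s, positions$chain[k],
                                   positions$resno[k] + 1),
                      error = function(e) NULL)
      if (!is.null(nxt)) next_p <- atom_xyz(nxt, "P", required = FALSE)
      if (is.null(next_p)) {
        stop("PP backrub axis requires the next residue's phosphate")
      }
    }
    cands <- enumerate_candidates(res, library, cfg_k, next_p = next_p)
    pos_objs[[k]] <- pack_position(
      id = sprintf("%s/%s", positions$chain[k], positions$resno[k]),
      candidates = cands, chain = positions$chain[k],
      resno = positions$resno[k], designable = positions$designable[k]
    )
  }
  keep <- !(paste(s$atoms$chain, s$atoms$resno) %in%
            paste(positions$chain, positions$resno))
  fixed_env <- na_structure(s$atoms[keep, , drop = FALSE])
  tables <- compute_tables(pos_objs, fixed_env, model)
  sol <- solve_gmec(tables, seed = seed)

  out <- s
  rows <- list()
  for (k in seq_along(pos_objs)) {
    cand <- pos_objs[[k]]$candidates[[sol$assignment[k]]]
    out <- replace_residue(out, cand$view)
    rows[[k]] <- data.frame(
      id = pos_objs[[k]]$id, chain = pos_objs[[k]]$chain,
      resno = pos_objs[[k]]$resno, nucleoside = cand$nucleoside,
      sugar = cand$sugar_name, chi = wrap360(cand$chi_base + cand$dchi),
      backrub = cand$backrub, probability = cand$probability,
      self_energy = tables$self[[k]][sol$assignment[k]],
      stringsAsFactors = FALSE)
  }
  list(structure = out, solution = sol, report = do.call(rbind, rows))
}
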