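# Atomic-structure container and per-residue views.
#
# A `na_structure` wraps a flat atom table (one row per atom); residues
# are addressed by (chain, resno).  A `nucleotide_view` is the
# per-residue working unit used by all geometry operations.

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `elety` (atom name, PDB convention), `elesy` (element symbol),
#'   `x`, `y`, `z` and optionally `o` (occupancy) and `alt` (altloc).
#' @return object of class `na_structure`.
#' @export
na_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "na_structure")
}

#' @noRd
guess_element <- function(elety) {
  e <- sub("[^A-Za-z].*$", "", elety)
  e <- sub("'.*$", "", e)
  substr(toupper(e), 1, 1)
}

#' @export
print.na_structure <- function(x, ...) {
  a <- x$atoms
  res <- unique(a[, c("chain", "resno")])
  cat(sprintf("<na_structure> %d atoms, %d residues, chains: %s\n",
              nrow(a), nrow(res),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Residue identifiers of a structure
#'
#' @param s `na_structure`.
#' @return data.frame with `chain`, `resno`, `resname`, one row per residue,
#'   in file order.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno)
  a[!duplicated(key), c("chain", "resno", "resname")]
}

#' Extract one residue as a nucleotide view
#'
#' @param s `na_structure`.
#' @param chain chain identifier.
#' @param resno residue number.
#' @return object of class `nucleotide_view`: list with `nucleoside`
#'   (NA for non-nucleotide residues), `resname`, `chain`, `resno` and
#'   `atoms` (data.frame `elety`, `elesy`, `x`, `y`, `z`).
#' @export
residue_view <- function(s, chain, resno) {
  a <- s$atoms[s$atoms$chain == chain & s$atoms$resno == resno, , drop = FALSE]
  if (!nrow(a)) stop(sprintf("no residue %s/%s in structure", chain, resno))
  nucleotide_view(
    atoms = a[, c("elety", "elesy", "x", "y", "z")],
    resname = a$resname[1], chain = chain, resno = resno
  )
}

#' Construct a nucleotide (or generic residue) view
#'
#' @param atoms data.frame with `elety`, `x`, `y`, `z` (and optionally
#'   `elesy`).
#' @param resname residue name (PDB style, e.g. "DG", "U", "ALA").
#' @param chain,resno residue identity; default "A"/1.
#' @return `nucleotide_view` object.
#' @export
nucleotide_view <- function(atoms, resname, chain = "A", resno = 1L) {
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  if (anyDuplicated(atoms$elety)) stop("duplicate atom names in residue")
  if (any(!nzchar(atoms$elety))) stop("empty atom name")
  nuc <- unname(RESNAME_TO_NUC[resname])
  structure(
    list(nucleoside = if (is.null(nuc)) NA_character_ else nuc,
         resname = resname, chain = chain, resno = resno,
         atoms = atoms[, c("elety", "elesy", "x", "y", "z")]),
    class = "nucleotide_view"
  )
}

#' @export
print.nucleotide_view <- function(x, ...) {
  cat(sprintf("<nucleotide_view> %s %s/%s (%d atoms)\n",
              x$resname, x$chain, x$resno, nrow(x$atoms)))
  invisible(x)
}

#' Coordinates of a named atom in a residue view
#'
#' @param res `nucleotide_view`.
#' @param name atom name (e.g. "C1'").
#' @param required error (TRUE) or return NULL (FALSE) when absent.
#' @return numeric 3-vector or NULL.
#' @export
atom_xyz <- function(res, name, required = TRUE) {
  i <- match(name, res$atoms$elety)
  if (is.na(i)) {
    if (required) {
      stop(sprintf("residue %s %s/%s lacks atom %s",
                   res$resname, res$chain, res$resno, name))
    }
    return(NULL)
  }
  as.numeric(res$atoms[i, c("x", "y", "z")])
}

#' @noRd
view_coords <- function(res) as.matrix(res$atoms[, c("x", "y", "z")])

#' @noRd
set_view_coords <- function(res, xyz) {
  res$atoms$x <- xyz[, 1]
  res$atoms$y <- xyz[, 2]
  res$atoms$z <- xyz[, 3]
  res
}

#' Assemble residue views into a structure
#'
#' @param views list of `nucleotide_view` objects.
#' @return `na_structure` with atoms in the given residue order.
#' @export
views_to_structure <- function(views) {
  rows <- lapply(views, function(v) {
    data.frame(chain = v$chain, resno = v$resno, resname = v$resname,
               elety = v$atoms$elety, elesy = v$atoms$elesy,
               x = v$atoms$x, y = v$atoms$y, z = v$atoms$z,
               o = 1, alt = "", stringsAsFactors = FALSE)
  })
  na_structure(do.call(rbind, rows))
}

#' Replace one residue of a structure
#'
#' @param s `na_structure`.
#' @param view replacement `nucleotide_view` (keyed by its chain/resno).
#' @return modified `na_structure`.
#' @export
replace_residue <- function(s, view) {
  a <- s$atoms
  sel <- a$chain == view$chain & a$resno == view$resno
  if (!any(sel)) stop("residue to replace not found")
  first <- which(sel)[1]
  new <- data.frame(chain = view$chain, resno = view$resno,
                    resname = view$resname,
                    elety = view$atoms$elety, elesy = view$atoms$elesy,
                    x = view$atoms$x, y = view$atoms$y, z = view$atoms$z,
                    o = 1, alt = "", stringsAsFactors = FALSE)
  before <- a[seq_len(nrow(a)) < first & !sel, , drop = FALSE]
  after <- a[seq_len(nrow(a)) >= first & !sel, , drop = FALSE]
  na_structure(rbind(before, new, after))
}

#' @noRd
is_nucleotide_resname <- function(resname) resname %in% names(RESNAME_TO_NUC)

#' @noRd
is_amino_resname <- function(resname) resname %in% AMINO3
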