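# Internal helpers shared across modules.

DEG <- pi / 180

#' @noRd
wrap360 <- function(x) ((x %% 360) + 360) %% 360

#' @noRd
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  # convention is (-180, 180]: the -180 representative maps to +180
  y[y <= -180 + 1e-12] <- 180
  y
}

#' Minimal circular difference between two angles
#'
#' Returns the absolute angular separation in degrees, always in
#' \[0, 180\].  Used by both the chi-recovery rule and the mean
#' delta-chi statistic so that a single convention applies everywhere.
#'
#' @param a,b angles in degrees (any range; vectors recycle).
#' @return absolute circular difference in degrees.
#' @export
#' @examples
#' circular_diff(350, 10)   # 20
#' circular_diff(200, 200)  # 0
circular_diff <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

# Run code with a temporary RNG seed, restoring global state afterwards.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

NUCLEOSIDES <- c("A", "U", "G", "C", "dA", "dT", "dG", "dC")
PURINES <- c("A", "G", "dA", "dG")
RNA_NUCLEOSIDES <- c("A", "U", "G", "C")
DNA_NUCLEOSIDES <- c("dA", "dT", "dG", "dC")

#' @noRd
is_purine <- function(nucleoside) nucleoside %in% PURINES

#' @noRd
is_deoxy <- function(nucleoside) nucleoside %in% DNA_NUCLEOSIDES

# PDB residue names <-> nucleoside labels
RESNAME_TO_NUC <- c(
  A = "A", U = "U", G = "G", C = "C",
  DA = "dA", DT = "dT", DG = "dG", DC = "dC"
)
NUC_TO_RESNAME <- stats::setNames(names(RESNAME_TO_NUC), RESNAME_TO_NUC)

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

# Atoms excluded from side-chain RMSD (the "main-chain" definitions)
NT_MAINCHAIN <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")
AA_MAINCHAIN <- c("N", "CA", "C", "O", "CB")

#' @noRd
wc_complement <- function(nucleoside) {
  comp <- c(A = "U", U = "A", G = "C", C = "G",
            dA = "dT", dT = "dA", dG = "dC", dC = "dG")
  unname(comp[nucleoside])
}
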