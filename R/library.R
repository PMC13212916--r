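# Rotamer libraries: container, TSV serialization, derivation from chi
# samples (pucker-dependent and basic flavors), and a synthetic example
# library used by tests and demonstrations.

#' Construct a rotamer library
#'
#' @param entries data.frame with columns `nucleoside`, `pucker_class`
#'   (`"ENDO2"`/`"ENDO3"` for the pucker flavor, `"ANY"` for basic),
#'   `chi` (integer degrees), `sd` (degrees) and `probability`.
#' @param flavor `"pucker"` (pucker-class-dependent chi sets) or
#'   `"basic"` (pucker-independent).
#' @param provenance free-text origin note.
#' @return object of class `rotamer_library`.
#' @export
rotamer_library <- function(entries, flavor = c("pucker", "basic"),
                            provenance = "") {
  flavor <- match.arg(flavor)
  need <- c("nucleoside", "pucker_class", "chi", "sd", "probability")
  stopifnot(all(need %in% names(entries)))
  if (flavor == "pucker" &&
      !all(entries$pucker_class %in% c("ENDO2", "ENDO3"))) {
    stop("pucker flavor requires pucker_class ENDO2/ENDO3")
  }
  if (flavor == "basic" && !all(entries$pucker_class == "ANY")) {
    stop("basic flavor requires pucker_class ANY")
  }
  grp <- split(entries$probability,
               paste(entries$nucleoside, entries$pucker_class))
  sums <- vapply(grp, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-6)) {
    stop("group probabilities must sum to 1")
  }
  if (any(vapply(grp, length, 0L) > 8)) stop("more than 8 entries in a group")
  rownames(entries) <- NULL
  structure(list(entries = entries, flavor = flavor,
                 provenance = provenance),
            class = "rotamer_library")
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat(sprintf("<rotamer_library> flavor '%s', %d entries, %d groups\n",
              x$flavor, nrow(x$entries),
              length(unique(paste(x$entries$nucleoside,
                                  x$entries$pucker_class)))))
  invisible(x)
}

#' Entries of one library group
#'
#' @param library `rotamer_library`.
#' @param nucleoside nucleoside label.
#' @param pucker_class pucker class of the position; ignored (mapped to
#'   `"ANY"`) for basic-flavor libraries.
#' @return data.frame of entries (possibly empty).
#' @export
library_group <- function(library, nucleoside, pucker_class = "ANY") {
  cls <- if (library$flavor == "basic") "ANY" else pucker_class
  e <- library$entries
  e[e$nucleoside == nucleoside & e$pucker_class == cls, , drop = FALSE]
}

#' Write / read a rotamer library as TSV
#'
#' Plain tab-separated table with header
#' `nucleoside  pucker_class  chi  sd  probability`; rewritable
#' bit-exactly.
#'
#' @param library `rotamer_library`.
#' @param path file path.
#' @export
write_rotamer_library <- function(library, path) {
  utils::write.table(library$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_rotamer_library
#' @param flavor flavor of the library being read; `"auto"` infers it
#'   from the pucker_class column.
#' @export
read_rotamer_library <- function(path, flavor = "auto") {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (flavor == "auto") {
    flavor <- if (all(e$pucker_class == "ANY")) "basic" else "pucker"
  }
  rotamer_library(e, flavor = flavor,
                  provenance = paste("read from", path))
}

#' Derive the pucker-dependent rotamer library from chi samples
#'
#' For every (nucleoside, pucker class) group: scan component counts
#' with [scan_gmm_components()], curate the selected model with
#' [curate_gmm()] (falling back to the largest smaller component count
#' whose model passes the 10-degree separation rule), round component
#' means to integer chi and take weights as rotamer probabilities.
#'
#' @param samples data.frame with columns `nucleoside`, `pucker_class`,
#'   `chi` (degrees in \[0, 360)).
#' @param seed RNG seed for the EM restart streams.
#' @param k_max largest component count scanned.
#' @return `rotamer_library` of flavor `"pucker"`.
#' @export
build_pucker_library <- function(samples, seed = 1, k_max = 20) {
  stopifnot(all(c("nucleoside", "pucker_class", "chi") %in% names(samples)))
  groups <- split(samples$chi,
                  list(samples$nucleoside, samples$pucker_class),
                  drop = TRUE, sep = "|")
  rows <- lapply(names(groups), function(g) {
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    model <- tryCatch(
      fit_group_model(groups[[g]], seed = seed, k_max = k_max),
      error = function(e) stop("group ", g, ": ", conditionMessage(e))
    )
    data.frame(nucleoside = parts[1], pucker_class = parts[2],
               chi = as.integer(round(model$components$mean) %% 360),
               sd = model$components$sd,
               probability = model$components$weight,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  ord <- order(match(entries$nucleoside, NUCLEOSIDES), entries$pucker_class,
               entries$chi)
  rotamer_library(entries[ord, ], flavor = "pucker",
                  provenance = sprintf("GMM fit, seed %d", seed))
}

# Scan, select by first local BIC minimum, curate; on a 10-degree
# separation rejection retry with the next-smaller component count.
#' @noRd
fit_group_model <- function(chi, seed, k_max = 20) {
  sc <- scan_gmm_components(chi, k_min = 1, k_max = k_max, seed = seed)
  for (k in seq(sc$selected, 1)) {
    m <- sc$models[[as.character(k)]]
    if (is.null(m)) m <- fit_chi_gmm(chi, k, seed = seed + k)
    cur <- tryCatch(curate_gmm(m), gmm_rejected = function(e) NULL)
    if (!is.null(cur)) return(cur)
  }
  stop("no component count passes the separation rule")
}

#' Derive the basic (pucker-independent) rotamer library
#'
#' One Gaussian per user-specified chi window, fitted by the moments of
#' the in-window samples; rotamer probability is the window's share of
#' the total fitted mass (area ratio).
#'
#' @param samples data.frame with columns `nucleoside`, `chi`.
#' @param peak_windows named list: for each nucleoside a list of
#'   `c(lo, hi)` degree intervals (non-overlapping, within \[0, 360)).
#' @return `rotamer_library` of flavor `"basic"`.
#' @export
build_basic_library <- function(samples, peak_windows) {
  stopifnot(all(c("nucleoside", "chi") %in% names(samples)))
  rows <- list()
  for (nuc in names(peak_windows)) {
    chi <- samples$chi[samples$nucleoside == nuc]
    wins <- peak_windows[[nuc]]
    check_windows(wins)
    fits <- list()
    for (w in wins) {
      inw <- chi[chi >= w[1] & chi < w[2]]
      if (length(inw) < 2) {
        warning(sprintf("window [%g, %g) for %s is empty; skipped",
                        w[1], w[2], nuc))
        next
      }
      fits[[length(fits) + 1]] <-
        data.frame(mean = mean(inw), sd = stats::sd(inw),
                   mass = length(inw))
    }
    if (!length(fits)) next
    f <- do.call(rbind, fits)
    rows[[length(rows) + 1]] <- data.frame(
      nucleoside = nuc, pucker_class = "ANY",
      chi = as.integer(round(f$mean) %% 360), sd = f$sd,
      probability = f$mass / sum(f$mass), stringsAsFactors = FALSE
    )
  }
  entries <- do.call(rbind, rows)
  rotamer_library(entries, flavor = "basic",
                  provenance = "single-Gaussian window fits")
}

#' @noRd
check_windows <- function(wins) {
  b <- do.call(rbind, lapply(wins, function(w) sort(w)))
  if (any(b < 0 | b > 360)) stop("windows must lie within [0, 360)")
  if (nrow(b) > 1) {
    b <- b[order(b[, 1]), , drop = FALSE]
    if (any(b[-1, 1] < b[-nrow(b), 2])) stop("windows overlap")
  }
  invisible(TRUE)
}

#' Synthetic example rotamer library
#'
#' A small, fully synthetic pucker-dependent library (and its basic
#' counterpart) with well-separated chi modes in the syn (+sc, ~65),
#' -ap (~200) and -ac (~250) regions.  It is used as the generating
#' reference in round-trip tests and demonstrations; it is not a
#' statistical survey of experimental structures.
#'
#' @param flavor `"pucker"` or `"basic"`.
#' @return `rotamer_library`.
#' @export
example_library <- function(flavor = c("pucker", "basic")) {
  flavor <- match.arg(flavor)
  mk <- function(nuc, cls, chi, sd, p) {
    data.frame(nucleoside = nuc, pucker_class = cls, chi = chi, sd = sd,
               probability = p, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (nuc in NUCLEOSIDES) {
    if (flavor == "basic") {
      if (is_purine(nuc)) {
        rows[[nuc]] <- mk(nuc, "ANY", c(65L, 200L, 250L), c(10, 12, 14),
                          c(0.10, 0.45, 0.45))
      } else {
        rows[[nuc]] <- mk(nuc, "ANY", c(200L, 250L), c(11, 13),
                          c(0.55, 0.45))
      }
      next
    }
    if (is_purine(nuc)) {
      rows[[paste0(nuc, 2)]] <- mk(nuc, "ENDO2", c(65L, 200L, 250L),
                                   c(10, 14, 15), c(0.15, 0.25, 0.60))
      rows[[paste0(nuc, 3)]] <- mk(nuc, "ENDO3", c(65L, 200L, 250L),
                                   c(10, 10, 12), c(0.10, 0.75, 0.15))
    } else {
      rows[[paste0(nuc, 2)]] <- mk(nuc, "ENDO2", c(205L, 250L),
                                   c(12, 13), c(0.35, 0.65))
      rows[[paste0(nuc, 3)]] <- mk(nuc, "ENDO3", c(200L, 245L),
                                   c(9, 12), c(0.80, 0.20))
    }
  }
  rotamer_library(do.call(rbind, rows), flavor = flavor,
                  provenance = "synthetic example library")
}
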