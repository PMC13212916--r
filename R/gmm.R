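# Univariate Gaussian mixture fitting for chi-angle distributions:
# seeded multi-restart EM, BIC model selection at the first local
# minimum, and the library curation rules.

#' @noRd
logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' @noRd
kmeanspp_means <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(x, function(xi) min((xi - centers[1:(j - 1)])^2),
                   numeric(1))
      if (sum(d2) <= 0) {
        centers[j] <- x[sample.int(length(x), 1)]
      } else {
        centers[j] <- x[sample.int(length(x), 1, prob = d2)]
      }
    }
  }
  centers
}

#' @noRd
em_once <- function(x, k, tol, max_iter) {
  n <- length(x)
  mu <- kmeanspp_means(x, k)
  sigma <- rep(max(stats::sd(x) / k, 1), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ld <- vapply(seq_len(k), function(j) {
      log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE)
    }, numeric(n))
    lse <- logsumexp_rows(ld)
    ll <- sum(lse)
    resp <- exp(ld - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, 1e-6))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * n) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll_old,
       converged = converged)
}

#' @noRd
new_gmm_model <- function(mu, sigma, w, loglik, n, converged = TRUE,
                          data = NULL) {
  ord <- order(mu)
  k_par <- 3 * length(mu) - 1
  structure(
    list(
      components = data.frame(mean = mu[ord], sd = sigma[ord],
                              weight = w[ord]),
      loglik = loglik, k = k_par, n = n,
      bic = -2 * loglik + k_par * log(n),
      converged = converged, data = data
    ),
    class = "gmm_model"
  )
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> %d component(s), loglik %.2f, BIC %.2f\n",
              nrow(x$components), x$loglik, x$bic))
  print(x$components, digits = 4)
  invisible(x)
}

#' @noRd
gmm_loglik <- function(x, comp) {
  ld <- vapply(seq_len(nrow(comp)), function(j) {
    log(comp$weight[j]) + stats::dnorm(x, comp$mean[j], comp$sd[j],
                                       log = TRUE)
  }, numeric(length(x)))
  if (is.null(dim(ld))) ld <- matrix(ld, nrow = 1)
  sum(logsumexp_rows(ld))
}

#' Fit a Gaussian mixture to chi samples
#'
#' Multi-restart EM (k-means++ initialization, best log-likelihood
#' kept) on angular samples in \[0, 360).  The domain is treated as
#' linear: chi distributions have no mass at the 0/360 boundary, so no
#' circular correction is required.  Components are returned sorted by
#' mean; the free-parameter count for BIC is `3k - 1` (means, variances
#' and the weight simplex).
#'
#' @param samples numeric chi values in \[0, 360).
#' @param n_components number of Gaussian components.
#' @param seed RNG seed for the restart stream.
#' @param tol convergence tolerance on the per-observation
#'   log-likelihood gain between EM steps.
#' @param max_iter maximum EM iterations per restart.
#' @param restarts number of random restarts (>= 5 by default).
#' @return object of class `gmm_model` with fields `components`
#'   (mean/sd/weight), `loglik`, `k`, `n`, `bic`, `converged`.
#' @export
fit_chi_gmm <- function(samples, n_components, seed = 1, tol = 1e-4,
                        max_iter = 400, restarts = 5) {
  x <- as.numeric(samples)
  if (length(x) < 10 * n_components) {
    stop("too few samples: need at least 10 per component")
  }
  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(restarts)) {
      fit <- em_once(x, n_components, tol, max_iter)
      if (is.null(b) || fit$loglik > b$loglik) b <- fit
    }
    b
  })
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best-so-far")
  }
  new_gmm_model(best$mu, best$sigma, best$w, best$loglik, length(x),
                best$converged, data = x)
}

#' Scan component counts and select by first local BIC minimum
#'
#' Fits mixtures with `k_min..k_max` components and selects the first
#' local minimum of the BIC curve (`BIC[k] < BIC[k-1]` and
#' `BIC[k] <= BIC[k+1]`).  Scanning stops once the minimum is
#' confirmed; if the BIC decreases monotonically to `k_max`, `k_max`
#' is selected with a warning.
#'
#' @inheritParams fit_chi_gmm
#' @param k_min,k_max component-count range (1..20 by default).
#' @return list with `models` (fitted `gmm_model`s, indexed by
#'   component count from `k_min`), `selected` (component count of the
#'   first local BIC minimum) and `bic` (numeric vector).
#' @export
scan_gmm_components <- function(samples, k_min = 1, k_max = 20, seed = 1,
                                tol = 1e-4, restarts = 5) {
  stopifnot(k_min >= 1, k_max >= k_min)
  models <- list()
  bic <- numeric(0)
  selected <- NA_integer_
  for (k in k_min:k_max) {
    models[[as.character(k)]] <-
      fit_chi_gmm(samples, k, seed = seed + k, tol = tol,
                  restarts = restarts)
    bic[as.character(k)] <- models[[as.character(k)]]$bic
    i <- k - k_min + 1
    if (i >= 2) {
      # is position i-1 a (first) local minimum of the BIC curve?
      left_ok <- (i - 1 == 1) || (bic[i - 1] < bic[i - 2])
      if (left_ok && bic[i - 1] <= bic[i]) {
        selected <- k - 1
        break
      }
    }
  }
  if (is.na(selected)) {
    selected <- k_max
    if ((k_max - k_min) >= 1) {
      warning("BIC decreased monotonically to k_max; selecting k_max")
    }
  }
  list(models = models, selected = selected, bic = bic)
}

#' Apply the library curation rules to a fitted mixture
#'
#' Two rules: (a) a model containing two neighbouring components whose
#' means are separated by less than 10 degrees is rejected (a classed
#' error of condition `gmm_rejected`, signalling the caller to fall
#' back to a smaller component count); (b) components with weight
#' below 1% or standard deviation above 50 degrees are removed and the
#' remaining weights renormalized to sum to one.  Log-likelihood and
#' BIC are recomputed from the stored samples after removal.
#'
#' @param model `gmm_model` (with stored sample data).
#' @return curated `gmm_model`.
#' @export
curate_gmm <- function(model) {
  comp <- model$components
  if (nrow(comp) >= 2 && any(diff(comp$mean) < 10)) {
    stop(structure(
      class = c("gmm_rejected", "error", "condition"),
      list(message = "model rejected: neighbouring means separated by < 10 degrees",
           call = sys.call())
    ))
  }
  keep <- comp$weight >= 0.01 & comp$sd <= 50
  if (!any(keep)) stop("curation removed all components")
  comp <- comp[keep, , drop = FALSE]
  comp$weight <- comp$weight / sum(comp$weight)
  rownames(comp) <- NULL
  ll <- if (!is.null(model$data)) gmm_loglik(model$data, comp) else model$loglik
  new_gmm_model(comp$mean, comp$sd, comp$weight, ll, model$n,
                model$converged, data = model$data)
}
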