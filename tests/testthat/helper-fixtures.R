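# Shared fixtures and independent oracles for the test suite.

# duplexes are reused across test files; build each once per session
.fixture_env <- new.env()

cached_duplex <- function(sequence, form = "B") {
  key <- paste(sequence, form)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- toy_duplex(sequence, form)
  }
  .fixture_env[[key]]
}

# brute-force dihedral via explicit rotation-matrix construction:
# rotate p1 into the frame where b2 is the z axis and measure the polar
# angle of the two projections (independent of the analytic formula)
oracle_dihedral <- function(p1, p2, p3, p4) {
  ez <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  any_v <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- any_v - sum(any_v * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  ang <- function(p, o) {
    v <- p - o
    atan2(sum(v * ey), sum(v * ex))
  }
  d <- (ang(p4, p3) - ang(p1, p2)) * 180 / pi
  d <- ((d + 180) %% 360) - 180
  if (d <= -180 + 1e-12) d <- 180
  d
}

# random pairwise-decomposable energy instances for GMEC oracles
random_tables <- function(seed, np = 4, max_cand = 5) {
  set.seed(seed)
  nc <- sample(2:max_cand, np, replace = TRUE)
  self <- lapply(nc, function(k) rnorm(k, 0, 2))
  pair <- rep(list(vector("list", np)), np)
  for (i in 1:(np - 1)) for (j in (i + 1):np) {
    m <- if (runif(1) < 0.2) NULL
         else matrix(rnorm(nc[i] * nc[j], 0, 1.5), nc[i], nc[j])
    pair[[i]][j] <- list(m)
  }
  structure(list(self = self, pair = pair, n = np),
            class = "energy_tables")
}

# exhaustive enumeration, independent of the package's search code
brute_force_min <- function(tables) {
  grid <- expand.grid(lapply(tables$self, seq_along))
  min(apply(grid, 1, function(a) {
    assignment_energy(tables, as.integer(a))
  }))
}

# mixture sampler independent of sample_chi_population
draw_mixture <- function(n, means, sds, weights, seed) {
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  ((rnorm(n, means[comp], sds[comp])) %% 360 + 360) %% 360
}
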