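test_that("library construction enforces its invariants", {
  lib <- example_library()
  expect_s3_class(lib, "rotamer_library")
  sums <- tapply(lib$entries$probability,
                 paste(lib$entries$nucleoside, lib$entries$pucker_class),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(lib$entries$chi == round(lib$entries$chi)))
  counts <- table(paste(lib$entries$nucleoside, lib$entries$pucker_class))
  expect_true(all(counts >= 1 & counts <= 8))

  bad <- lib$entries
  bad$probability[1] <- bad$probability[1] + 0.5
  expect_error(rotamer_library(bad, "pucker"), "sum to 1")
})

test_that("library group lookup honours the flavor", {
  lib <- example_library("pucker")
  g <- library_group(lib, "dA", "ENDO2")
  expect_true(all(g$pucker_class == "ENDO2"))
  basic <- example_library("basic")
  # basic flavor ignores the position's pucker class
  expect_equal(library_group(basic, "dA", "ENDO2"),
               library_group(basic, "dA", "ANY"))
})

test_that("library TSV serialization round-trips bit-exactly", {
  lib <- example_library()
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_rotamer_library(lib, p1)
  back <- read_rotamer_library(p1)
  expect_equal(back$entries, lib$entries)
  expect_equal(back$flavor, lib$flavor)
  write_rotamer_library(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("pucker-dependent library building recovers a known generator", {
  # two groups at moderate n keep this fast; the full 16-group round
  # trip runs in the acceptance suite
  ref <- example_library()
  s1 <- sample_chi_population(ref, "dG", "ENDO2", 4000, seed = 301)
  s2 <- sample_chi_population(ref, "U", "ENDO3", 4000, seed = 302)
  samples <- rbind(
    data.frame(nucleoside = "dG", pucker_class = "ENDO2", chi = s1),
    data.frame(nucleoside = "U", pucker_class = "ENDO3", chi = s2)
  )
  lib <- build_pucker_library(samples, seed = 9)
  g1 <- library_group(lib, "dG", "ENDO2")
  r1 <- library_group(ref, "dG", "ENDO2")
  expect_equal(nrow(g1), nrow(r1))
  expect_lt(max(abs(sort(g1$chi) - sort(r1$chi))), 2)
  expect_lt(max(abs(g1$probability[order(g1$chi)] -
                    r1$probability[order(r1$chi)])), 0.03)
  g2 <- library_group(lib, "U", "ENDO3")
  expect_lt(max(abs(sort(g2$chi) -
                    sort(library_group(ref, "U", "ENDO3")$chi))), 2)
})

test_that("a single tight mode yields one entry with probability 1", {
  set.seed(77)
  chi <- (rnorm(2500, 210, 9)) %% 360
  lib <- build_pucker_library(
    data.frame(nucleoside = "A", pucker_class = "ENDO3", chi = chi),
    seed = 5)
  g <- library_group(lib, "A", "ENDO3")
  expect_equal(nrow(g), 1)
  expect_equal(g$probability, 1)
  expect_equal(g$chi, 210, tolerance = 2)
})

test_that("sub-percent components are excluded from the built library", {
  x <- draw_mixture(8000, c(65, 200, 250), c(6, 10, 10),
                    c(0.005, 0.595, 0.400), seed = 55)
  lib <- build_pucker_library(
    data.frame(nucleoside = "dC", pucker_class = "ENDO2", chi = x),
    seed = 3)
  g <- library_group(lib, "dC", "ENDO2")
  # the +sc-like 0.5% component must not appear
  expect_false(any(g$chi < 150))
  expect_equal(sum(g$probability), 1, tolerance = 1e-9)
})

test_that("basic library probabilities equal in-window area ratios", {
  x <- draw_mixture(10000, c(200, 250), c(9, 8), c(0.7, 0.3), seed = 12)
  lib <- build_basic_library(
    data.frame(nucleoside = "dA", chi = x),
    peak_windows = list(dA = list(c(150, 225), c(225, 300)))
  )
  g <- library_group(lib, "dA", "ANY")
  expect_equal(nrow(g), 2)
  expect_equal(g$probability[order(g$chi)], c(0.7, 0.3), tolerance = 0.02)
  expect_true(all(g$pucker_class == "ANY"))

  # single window covering everything -> probability 1
  lib1 <- build_basic_library(data.frame(nucleoside = "dA", chi = x),
                              peak_windows = list(dA = list(c(0, 360))))
  expect_equal(library_group(lib1, "dA", "ANY")$probability, 1)

  # symmetric equal-mass modes -> 0.5/0.5
  xs <- draw_mixture(10000, c(200, 250), c(8, 8), c(0.5, 0.5), seed = 13)
  libs <- build_basic_library(data.frame(nucleoside = "dA", chi = xs),
                              peak_windows = list(dA = list(c(150, 225),
                                                            c(225, 300))))
  expect_equal(library_group(libs, "dA", "ANY")$probability, c(0.5, 0.5),
               tolerance = 0.02)

  # empty window skipped with a warning; overlap rejected
  expect_warning(
    build_basic_library(data.frame(nucleoside = "dA", chi = x),
                        peak_windows = list(dA = list(c(150, 300),
                                                      c(0, 10)))),
    "empty")
  expect_error(
    build_basic_library(data.frame(nucleoside = "dA", chi = x),
                        peak_windows = list(dA = list(c(150, 260),
                                                      c(250, 300)))),
    "overlap")
})

test_that("chi population sampling matches the generating group", {
  lib <- example_library()
  x <- sample_chi_population(lib, "dT", "ENDO3", 1e5, seed = 21)
  g <- library_group(lib, "dT", "ENDO3")
  # component proportions within a binomial bound of the probabilities
  near1 <- mean(circular_diff(x, g$chi[1]) <
                circular_diff(x, g$chi[2]))
  expect_equal(near1, g$probability[1], tolerance = 0.012)
  expect_true(all(x >= 0 & x < 360))
  # deterministic under a fixed seed
  expect_identical(x, sample_chi_population(lib, "dT", "ENDO3", 1e5,
                                            seed = 21))
})
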