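test_that("pooled side-chain RMSD follows its closed form", {
  d <- cached_duplex("GATC", "B")
  self <- sidechain_rmsd(d, d)
  expect_equal(self$rmsd, 0)
  expect_equal(nrow(self$excluded), 0)

  # displace one included atom by 1 A among N-1 perfect atoms
  mod <- d
  i <- which(mod$atoms$elety == "N9")[1]
  mod$atoms$x[i] <- mod$atoms$x[i] + 1
  r <- sidechain_rmsd(mod, d)
  expect_equal(r$rmsd, 1 / sqrt(r$n_atoms), tolerance = 1e-9)

  # main-chain displacement is excluded from the comparison
  mod2 <- d
  j <- which(mod2$atoms$elety == "P")[1]
  mod2$atoms$x[j] <- mod2$atoms$x[j] + 3
  expect_equal(sidechain_rmsd(mod2, d)$rmsd, 0)

  # identity change excludes the residue and counts it separately
  nt <- ideal_nucleotide("dA", 162, 37, 250, chain = "A", resno = 1)
  mod3 <- replace_residue(d, nt)
  r3 <- sidechain_rmsd(mod3, d)
  expect_equal(nrow(r3$excluded), 1)
  expect_equal(r3$n_residues, 7)
})

test_that("recovery rate applies the strict 15-degree rule circularly", {
  expect_equal(recovery_rate(c(14.9, 15.1)), 50)
  expect_equal(recovery_rate(rep(0, 10)), 100)
  # a raw difference of 350 is a circular distance of 10: a match
  expect_equal(recovery_rate(350), 100)
  expect_equal(recovery_rate(15), 0)   # exactly 15 is not a match
  expect_error(recovery_rate(numeric()), "empty")
})

test_that("mean delta-chi averages absolute circular differences", {
  expect_equal(mean_delta_chi(c(0, 0)), 0)
  expect_equal(mean_delta_chi(c(4, -6)), 5)
  expect_equal(mean_delta_chi(rep(180, 5)), 180)
  expect_equal(mean_delta_chi(c(355, 10)), 7.5)  # circular folding
})

test_that("chi deviation tables and recovery share one circular primitive", {
  d <- cached_duplex("GATC", "B")
  dc <- chi_deviations(d, d)
  expect_equal(nrow(dc), 8)
  expect_true(all(dc$delta_chi < 1e-9))
  expect_equal(recovery_rate(dc$delta_chi), 100)
})

test_that("INF equals the geometric mean of precision and recall", {
  expect_equal(inf_score(9, 1, 1), 0.9)
  expect_equal(inf_score(5, 0, 0), 1)
  expect_warning(expect_equal(inf_score(0, 3, 0), 0))
  expect_equal(inf_score(6, 2, 3), sqrt((6 / 8) * (6 / 9)))
})

test_that("geometric interaction detection finds pairs and stacks", {
  d <- cached_duplex("GCGC", "B")
  e <- detect_interactions(d)
  pairs <- e[e$type == "pair", ]
  expect_equal(nrow(pairs), 4)
  # each strand-1 position pairs its reverse-complement partner
  expect_setequal(paste(pairs$resno1, pairs$resno2),
                  c("1 4", "2 3", "3 2", "4 1"))
  expect_true(all(pairs$n_hbonds >= 2))

  # two isolated distant bases: no edges
  nt1 <- ideal_nucleotide("dG", 162, 37, 250, chain = "A", resno = 1)
  nt2 <- ideal_nucleotide("dC", 162, 37, 250, chain = "B", resno = 1)
  nt2$atoms[, c("x")] <- nt2$atoms[, c("x")] + 20
  expect_equal(nrow(detect_interactions(views_to_structure(
    list(nt1, nt2)))), 0)

  # ideal stacked dimer (rise 3.4, twist 36): one stack edge
  ntb <- ideal_nucleotide("dG", 162, 37, 250, chain = "A", resno = 2)
  xyz <- as.matrix(ntb$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz[ntb$atoms$elety %in% c("N9", "C4", "N3"), ])
  sv <- svd(sweep(xyz[ntb$atoms$elety %in%
                        c("N9", "C8", "N7", "C5", "C4", "C6", "N1",
                          "C2", "N3"), ], 2, ctr))
  normal <- sv$v[, 3]
  stacked <- sweep(rotate_about_axis(xyz, ctr, normal, 36), 2,
                   3.4 * normal, "+")
  ntb$atoms$x <- stacked[, 1]; ntb$atoms$y <- stacked[, 2]
  ntb$atoms$z <- stacked[, 3]
  es <- detect_interactions(views_to_structure(list(
    ideal_nucleotide("dG", 162, 37, 250, chain = "A", resno = 1), ntb)))
  expect_equal(nrow(es), 1)
  expect_equal(es$type, "stack")
})

test_that("interaction comparison yields exact INF on perturbed fixtures", {
  d <- cached_duplex("GCGC", "B")
  ci <- compare_interactions(d, d)
  expect_equal(ci$inf, 1)
  expect_equal(ci$fp + ci$fn, 0)
  # breaking one pair loses edges relative to the reference
  mod <- d
  sel <- mod$atoms$chain == "A" & mod$atoms$resno == 1
  mod$atoms$z[sel] <- mod$atoms$z[sel] + 25
  ci2 <- compare_interactions(mod, d)
  expect_lt(ci2$inf, 1)
  expect_gt(ci2$fn, 0)
})

test_that("lDDT is local, bounded and monotone under noise", {
  d <- cached_duplex("GATCGA", "B")
  ld <- lddt_score(d, d)
  expect_true(all(ld$per_residue$lddt == 1))
  expect_equal(ld$mean, 1)

  # moving one residue rigidly ruins its score, not remote ones
  mod <- d
  sel <- mod$atoms$chain == "A" & mod$atoms$resno == 1
  mod$atoms$x[sel] <- mod$atoms$x[sel] + 10
  ld2 <- lddt_score(mod, d)
  moved <- ld2$per_residue$lddt[ld2$per_residue$chain == "A" &
                                ld2$per_residue$resno == 1]
  far <- ld2$per_residue$lddt[ld2$per_residue$chain == "B" &
                              ld2$per_residue$resno == 1]
  expect_lt(moved, 0.5)
  expect_gt(far, 0.9)

  # scores never increase when more noise is added
  set.seed(5)
  n <- nrow(d$atoms)
  noise <- matrix(rnorm(3 * n, sd = 0.2), n, 3)
  m1 <- d; m2 <- d
  m1$atoms[, c("x", "y", "z")] <- d$atoms[, c("x", "y", "z")] + noise
  m2$atoms[, c("x", "y", "z")] <- d$atoms[, c("x", "y", "z")] + 3 * noise
  expect_lt(lddt_score(m2, d)$mean, lddt_score(m1, d)$mean)
  expect_lt(lddt_score(m1, d)$mean, 1)
})

test_that("F_nat counts preserved protein-nucleotide contacts", {
  d <- cached_duplex("GATC", "B")
  # a synthetic two-residue peptide flanking the duplex: one residue in
  # contact, one far away
  near_atom <- atom_xyz(residue_view(d, "A", 2), "N7")
  pep <- data.frame(
    chain = "P", resno = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2),
    resname = "ALA",
    elety = rep(c("N", "CA", "C", "O", "CB"), 2),
    elesy = rep(c("N", "C", "C", "O", "C"), 2),
    x = c(near_atom[1] + c(4, 4.5, 5, 5.5, 4.2), rep(50, 5)),
    y = c(near_atom[2] + c(0, 0.5, 1, 0, 1.2), 51:55),
    z = c(near_atom[3] + c(0, 1, 0, 1, 0.5), rep(50, 5)),
    o = 1, alt = "", stringsAsFactors = FALSE
  )
  complex <- na_structure(rbind(d$atoms, pep))
  expect_equal(fnat_score(complex, complex), 1)

  # disrupting the contact residue loses all native contacts
  broken <- complex
  sel <- broken$atoms$chain == "P" & broken$atoms$resno == 1
  broken$atoms$x[sel] <- broken$atoms$x[sel] + 40
  expect_equal(fnat_score(broken, complex), 0)

  # disrupting one of two contact residues loses exactly its counted
  # share of the native contacts (independent contact count below)
  pep2 <- pep
  pep2$resno <- c(rep(1, 5), rep(2, 5))
  pep2[6:10, c("x", "y", "z")] <-
    data.frame(x = near_atom[1] + c(4, 4.5, 5, 5.5, 4.2),
               y = near_atom[2] + c(2, 2.5, 3, 2, 3.2),
               z = near_atom[3] + c(0, 1, 0, 1, 0.5))
  complex2 <- na_structure(rbind(d$atoms, pep2))
  half <- complex2
  sel2 <- half$atoms$chain == "P" & half$atoms$resno == 2
  half$atoms$x[sel2] <- half$atoms$x[sel2] + 40
  count_contacts <- function(s) {
    a <- s$atoms
    prot <- a[a$resname == "ALA", ]
    nuc <- a[a$resname != "ALA", ]
    pairs <- character()
    for (i in seq_len(nrow(prot))) {
      dd <- sqrt((prot$x[i] - nuc$x)^2 + (prot$y[i] - nuc$y)^2 +
                 (prot$z[i] - nuc$z)^2)
      hit <- dd < 5
      pairs <- c(pairs, paste(prot$resno[i], nuc$chain[hit],
                              nuc$resno[hit]))
    }
    unique(pairs)
  }
  nat <- count_contacts(complex2)
  pres <- count_contacts(half)
  expect_equal(fnat_score(half, complex2),
               length(intersect(nat, pres)) / length(nat))
  expect_lt(fnat_score(half, complex2), 1)

  expect_error(fnat_score(d, d), "interface")
})

test_that("metrics are invariant under atom reordering within residues", {
  d <- cached_duplex("GATC", "B")
  set.seed(2)
  resh <- d$atoms[order(paste(d$atoms$chain, d$atoms$resno),
                        sample(nrow(d$atoms))), ]
  dm <- na_structure(resh)
  expect_equal(sidechain_rmsd(dm, d)$rmsd, 0)
  expect_equal(lddt_score(dm, d)$mean, 1)
  expect_equal(compare_interactions(dm, d)$inf, 1)
})
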