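test_that("stripping retains exactly the nucleotide main-chain atoms", {
  nt <- ideal_nucleotide("dG", 162, 37, 250)
  mc <- strip_to_mainchain(nt)
  expect_setequal(mc$atoms$elety,
                  c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'"))
  expect_equal(nrow(mc$atoms), 8)
  # idempotent
  expect_equal(strip_to_mainchain(mc)$atoms, mc$atoms)
  # 5'-terminal residue lacking the phosphate keeps what it has
  term <- nt
  term$atoms <- term$atoms[!term$atoms$elety %in% c("P", "OP1", "OP2"), ]
  expect_message(mc5 <- strip_to_mainchain(term), "lacks")
  expect_equal(nrow(mc5$atoms), 5)
})

test_that("sugar conformer sets follow the pseudorotation wheel", {
  e3 <- sugar_conformers("ENDO3", "ribose")
  e2 <- sugar_conformers("ENDO2", "deoxyribose")
  expect_length(e3, 3)
  expect_length(e2, 4)
  expect_equal(vapply(e3, `[[`, 0, "canonical_P"), c(0, 18, 36))
  expect_equal(vapply(e2, `[[`, 0, "canonical_P"), c(180, 162, 144, 126))
  expect_equal(e3[[2]]$name, "3E")
  expect_equal(e3[[2]]$canonical_P, 18)
  expect_equal(e3[[1]]$tau_m, 40)
  expect_equal(e2[[1]]$tau_m, 37)
  # every template's measured phase is close to its canonical phase
  for (tpl in c(e3, e2)) {
    p <- pseudorotation_phase(endocyclic_torsions(tpl$view))
    expect_lt(circular_diff(p, tpl$canonical_P), 2)
  }
})

test_that("sugar placement anchors on C3'/C4'/C5'", {
  nt <- ideal_nucleotide("A", 18, 40, 200)
  mc <- strip_to_mainchain(nt)
  tpl <- sugar_conformers("ENDO3", "ribose")[[2]]  # 3E, same as source
  placed <- place_sugar(tpl, mc)
  expect_lt(attr(placed, "anchor_rmsd"), 0.05)
  expect_true(all(c("C1'", "C2'", "O4'", "O2'") %in% placed$atoms$elety))

  # equivariance under a rigid transform of the input
  xyz <- as.matrix(mc$atoms[, c("x", "y", "z")])
  moved <- sweep(rotate_about_axis(xyz, c(0, 0, 0), c(1, 1, 1), 40), 2,
                 c(3, 2, 1), "+")
  mc2 <- mc
  mc2$atoms$x <- moved[, 1]; mc2$atoms$y <- moved[, 2]
  mc2$atoms$z <- moved[, 3]
  placed2 <- place_sugar(tpl, mc2)
  p1 <- as.matrix(placed$atoms[, c("x", "y", "z")])
  p1m <- sweep(rotate_about_axis(p1, c(0, 0, 0), c(1, 1, 1), 40), 2,
               c(3, 2, 1), "+")
  expect_equal(as.matrix(placed2$atoms[, c("x", "y", "z")]), p1m,
               tolerance = 1e-6, ignore_attr = TRUE)

  # an ENDO2 position receives four sugars with distinct phases
  nt2 <- ideal_nucleotide("dT", 162, 37, 250)
  mc3 <- strip_to_mainchain(nt2)
  phases <- vapply(sugar_conformers("ENDO2", "deoxyribose"),
                   function(t) {
                     pl <- place_sugar(t, mc3)
                     pseudorotation_phase(endocyclic_torsions(pl))
                   }, numeric(1))
  expect_equal(length(unique(round(phases))), 4)
  expect_true(all(circular_diff(phases, c(180, 162, 144, 126)) < 5))
})

test_that("base attachment realizes the requested chi exactly", {
  nt <- ideal_nucleotide("dA", 162, 37, 250)
  expect_equal(glycosidic_chi(nt), 250, tolerance = 0.01)
  mc <- strip_to_mainchain(nt)
  tpl <- sugar_conformers("ENDO2", "deoxyribose")[[2]]
  placed <- place_sugar(tpl, mc)
  for (chi in c(65, 200, 250)) {
    built <- attach_base(placed, "dA", chi)
    expect_equal(glycosidic_chi(built), chi, tolerance = 0.01)
  }
  # purine vs pyrimidine frames
  bpy <- attach_base(placed, "dC", 240)
  expect_true(all(c("N1", "C2", "N3", "N4", "O2") %in% bpy$atoms$elety))
  expect_equal(glycosidic_chi(bpy), 240, tolerance = 0.01)

  # two attachments differing only in chi share the sugar coordinates
  b1 <- attach_base(placed, "dA", 200)
  b2 <- attach_base(placed, "dA", 260)
  sug1 <- b1$atoms[b1$atoms$elety %in% c("C1'", "C2'", "O4'"), ]
  sug2 <- b2$atoms[b2$atoms$elety %in% c("C1'", "C2'", "O4'"), ]
  expect_equal(sug1, sug2)

  expect_error(attach_base(placed, "dX", 200), "unknown nucleoside")
})

test_that("chi expansion rotates the base only, by the stated increments", {
  nt <- ideal_nucleotide("dG", 162, 37, 250)
  cand <- structure(list(view = nt, nucleoside = "dG", sugar_name = "2E",
                         chi_base = 250, dchi = 0, backrub = 0,
                         h_variant = 1L, probability = 0.5),
                    class = "rotamer_candidate")
  ex <- expand_chi(cand, c(-7, 0, 7))
  expect_length(ex, 3)
  chis <- vapply(ex, function(cc) glycosidic_chi(cc$view), numeric(1))
  expect_equal(chis, c(243, 250, 257), tolerance = 1e-6)
  # dchi = 0 is an identity copy
  expect_equal(ex[[2]]$view$atoms, nt$atoms)
  # sugar untouched, base rigidly rotated (distances to axis preserved)
  for (cc in ex) {
    sug <- cc$view$atoms[cc$view$atoms$elety == "C2'", ]
    expect_equal(sug, nt$atoms[nt$atoms$elety == "C2'", ],
                 ignore_attr = TRUE)
    ringd <- dist(as.matrix(
      cc$view$atoms[cc$view$atoms$elety %in% c("N9", "C4", "C8", "N1"),
                    c("x", "y", "z")]))
    ringd0 <- dist(as.matrix(
      nt$atoms[nt$atoms$elety %in% c("N9", "C4", "C8", "N1"),
               c("x", "y", "z")]))
    expect_equal(as.numeric(ringd), as.numeric(ringd0), tolerance = 1e-9)
  }
})

test_that("backrub rotations preserve the defining axis", {
  nt <- ideal_nucleotide("dG", 162, 37, 250)
  cand <- structure(list(view = nt, nucleoside = "dG", sugar_name = "2E",
                         chi_base = 250, dchi = 0, backrub = 0,
                         h_variant = 1L, probability = 0.5),
                    class = "rotamer_candidate")
  # zero angle is the identity
  expect_equal(backrub(cand, 0)$view$atoms, nt$atoms)
  b7 <- backrub(cand, 7)
  for (a in c("C3'", "C4'")) {
    expect_equal(atom_xyz(b7$view, a), atom_xyz(nt, a), tolerance = 1e-9)
  }
  expect_false(isTRUE(all.equal(atom_xyz(b7$view, "N9"),
                                atom_xyz(nt, "N9"))))
  # +7 then -7 is the identity
  back <- backrub(b7, -7)
  expect_equal(as.matrix(back$view$atoms[, c("x", "y", "z")]),
               as.matrix(nt$atoms[, c("x", "y", "z")]), tolerance = 1e-9)
  # PP axis needs the next phosphate
  expect_error(backrub(cand, 7, axis = "PP"), "next")
  bpp <- backrub(cand, 7, axis = "PP", next_p = c(10, 0, 0))
  expect_equal(atom_xyz(bpp$view, "P"), atom_xyz(nt, "P"),
               tolerance = 1e-9)
})

test_that("candidate counts obey the multiplicative law", {
  lib <- example_library()
  d <- cached_duplex("GATC", "B")
  res <- residue_view(d, "A", 1)  # dG, ENDO2 -> 3 rotamers, 4 sugars

  grid <- expand.grid(dchi = c(1, 3), br = c(1, 3), h = c(1, 3))
  for (r in seq_len(nrow(grid))) {
    cfg <- build_config(
      dchi = if (grid$dchi[r] == 1) 0 else c(-7, 0, 7),
      backrub_angles = if (grid$br[r] == 1) 0 else c(-7, 0, 7),
      h_placements = grid$h[r]
    )
    cands <- enumerate_candidates(res, lib, cfg)
    expect_length(cands, 3 * 4 * grid$h[r] * grid$dchi[r] * grid$br[r])
  }

  # an ENDO3 position with 2 rotamers and both expansions on gives
  # 2 x 3 x 1 x 3 x 3 = 54
  dA <- toy_duplex("ACGU", "A")
  resU <- residue_view(dA, "A", 4)  # U, ENDO3 -> 2 rotamers, 3 sugars
  cands54 <- enumerate_candidates(resU, lib, build_config())
  expect_length(cands54, 2 * 3 * 1 * 3 * 3)

  # identity design sums the per-nucleoside counts
  cfg_design <- build_config(dchi = 0, backrub_angles = 0,
                             allowed_nucleosides = c("dA", "dT", "dG",
                                                     "dC"))
  cands_d <- enumerate_candidates(res, lib, cfg_design)
  expect_length(cands_d, (3 + 2 + 3 + 2) * 4)
  # provenance carried on every candidate
  expect_true(all(vapply(cands_d, function(cc) {
    cc$nucleoside %in% c("dA", "dT", "dG", "dC") && !is.na(cc$probability)
  }, logical(1))))
})

test_that("candidate chi equals chi_base + dchi before backrub", {
  lib <- example_library()
  d <- cached_duplex("GATC", "B")
  res <- residue_view(d, "A", 2)
  cands <- enumerate_candidates(res, lib,
                                build_config(backrub_angles = 0))
  for (cc in cands) {
    expect_lt(circular_diff(glycosidic_chi(cc$view),
                            cc$chi_base + cc$dchi), 0.5)
  }
})

test_that("a reference on a library chi is recovered with zero delta-chi", {
  lib <- example_library()
  d <- cached_duplex("GATC", "B")
  cfg <- build_config(dchi = 0, backrub_angles = 0)
  for (i in 1:4) {
    res <- residue_view(d, "A", i)
    cc <- closest_candidate(res, enumerate_candidates(res, lib, cfg))
    expect_lt(cc$delta_chi, 1e-6)
    expect_lt(cc$rmsd, 0.05)
  }
})
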