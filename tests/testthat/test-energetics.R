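test_that("bond potential is the harmonic sum over topology bonds", {
  topo <- shared_topology("hyaluronan", 2)
  db <- shared_db("hyaluronan")
  set.seed(4)
  conf <- build_chain(topo, db)
  b0 <- gagchain:::.topology_b0(topo)
  ## chain with every bond at its equilibrium length has zero energy:
  ## rescale each bond is impossible globally, so check the arithmetic on
  ## a controlled perturbation instead
  e0 <- bond_potential(conf)
  expect_gte(e0, 0)
  ## stretching one terminal bond by 0.1 A adds k_b * 0.01 = 3 kcal/mol
  r <- which(topo$atoms$name == "O6A")[1]
  partner <- topo$bonds[topo$bonds[, 1] == r | topo$bonds[, 2] == r, ]
  j <- setdiff(as.integer(partner), r)[1]
  u <- (conf$coords[r, ] - conf$coords[j, ])
  bl <- sqrt(sum(u^2))
  conf2 <- conf
  conf2$coords[r, ] <- conf$coords[j, ] + u / bl * (bl + 0.1)
  conf3 <- conf
  conf3$coords[r, ] <- conf$coords[j, ] + u / bl * (bl - 0.1)
  brow <- which((topo$bonds[, 1] == r & topo$bonds[, 2] == j) |
                  (topo$bonds[, 1] == j & topo$bonds[, 2] == r))
  k_b <- energy_params()$k_bond
  base <- k_b * (bl - b0[brow])^2
  expect_equal(bond_potential(conf2) - e0,
               k_b * (bl + 0.1 - b0[brow])^2 - base, tolerance = 1e-9)
  ## symmetric +/- displacement about b0 gives equal energies
  conf2$coords[r, ] <- conf$coords[j, ] + u / bl * (b0[brow] + 0.07)
  conf3$coords[r, ] <- conf$coords[j, ] + u / bl * (b0[brow] - 0.07)
  expect_equal(bond_potential(conf2), bond_potential(conf3),
               tolerance = 1e-9)
})

test_that("nonphysical detection flags overlaps and piercings, not clean chains", {
  ## clean extended chain
  ext <- build_fixed(polymer_spec("hyaluronan", 10),
                     reference_dihedrals$hyaluronan)
  det <- detect_nonphysical(ext)
  expect_false(det$nonphysical)
  ## two parallel bonds 0.3 A apart (synthetic 4-atom system)
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 0.3, 0), c(1.5, 0.3, 0))
  bonds <- rbind(c(1L, 2L), c(3L, 4L))
  out <- gagchain:::.detect_nonphysical(co, bonds,
                                        matrix(integer(0), 0, 6),
                                        c(1L, 1L, 2L, 2L), 0.5)
  expect_equal(nrow(out$overlap_bonds), 1)
  ## a bond threaded through a ring center
  ring <- ring_from_pucker(0.57, 0, 0)
  co <- rbind(ring, c(0, 0, -2), c(0, 0, 2))
  bonds <- rbind(cbind(1:6, c(2:6, 1)), c(7L, 8L))
  out <- gagchain:::.detect_nonphysical(co, bonds,
                                        matrix(1:6, 1), rep(c(1L, 2L),
                                                            c(6, 2)), 0.5)
  expect_gte(length(out$pierce_bond), 1)
  expect_equal(out$pierce_residue[1], 1L)
})

test_that("restrained minimization relaxes defect-free chains and keeps dihedrals", {
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  set.seed(12)
  conf <- build_chain(topo, db)
  mr <- minimize_restrained(conf)
  expect_lt(mr$post_bond_pe, 10)
  expect_lte(mr$post_bond_pe, mr$pre_bond_pe)
  expect_lt(mr$max_dihedral_drift, 5)
  expect_true(mr$converged)
  ## an already-minimal input barely moves
  mr2 <- minimize_restrained(mr$conf)
  expect_lt(abs(mr2$post_bond_pe - mr$post_bond_pe), 0.5)
  expect_lt(superpose_rmsd(mr2$conf$coords, mr$conf$coords), 0.05)
})

test_that("a planted ring piercing raises the screened energy far above baseline", {
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  fx <- find_pierced_chain(topo, db)
  expect_true(detect_nonphysical(fx$pierced)$nonphysical)
  base <- minimize_restrained(fx$base)
  bad <- minimize_restrained(fx$pierced)
  expect_gte(bad$post_bond_pe - base$post_bond_pe, 132)
})

test_that("the cutoff anchors at the extended reference plus a 100 kcal/mol buffer", {
  db <- shared_db("hyaluronan")
  cut20 <- compute_cutoff(polymer_spec("hyaluronan", 20), db)
  expect_equal(cut20$buffer, 100)
  expect_equal(cut20$cutoff, cut20$reference + 100)
  ## near-template extended reference carries little strain
  expect_lt(cut20$reference, 20)
  cut10 <- compute_cutoff(polymer_spec("hyaluronan", 10), db)
  expect_gte(cut20$cutoff, cut10$cutoff)
})

test_that("ensembles are screened, deterministic and feature-complete", {
  db <- shared_db("hyaluronan")
  sp <- polymer_spec("hyaluronan", 10)
  cut <- compute_cutoff(sp, db)
  e1 <- generate_ensemble(sp, db, N = 25, seed = 17, cutoff = cut)
  e2 <- generate_ensemble(sp, db, N = 25, seed = 17, cutoff = cut)
  expect_identical(e1$members, e2$members)
  expect_true(all(e1$members$post_pe <= cut$cutoff))
  expect_equal(dim(e1$phi), c(25, 9))
  expect_equal(dim(e1$pucker_label), c(25, 10))
  expect_true(all(e1$pucker_label %in% c("4C1", "1C4", "3,OB", "3S1", "B1,4",
                                         "5S1", "2,5B", "2SO", "B3,O", "1S3",
                                         "1,4B", "1S5", "B2,5", "OS2")))
  ## sub-ensemble selection
  all_chair <- subset_ensemble(e1, function(f) all(f$pucker_label == "4C1"))
  none <- subset_ensemble(e1, function(f) any(f$pucker_label == "9X9"))
  expect_equal(nrow(none$members), 0)
  taut <- subset_ensemble(e1, function(f) TRUE)
  expect_identical(taut$members, e1$members)
  expect_equal(nrow(all_chair$members) +
                 nrow(subset_ensemble(e1, function(f) {
                   any(f$pucker_label != "4C1")
                 })$members), 25)
})

test_that("geometric defects are caught by the energy screen", {
  ## the filter-soundness property: every conformation the geometric
  ## detector flags must end above the cutoff after minimization
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  cut <- compute_cutoff(topo, db)
  flagged <- list()
  for (k in 1:150) {
    set.seed(7000 + k)
    conf <- build_chain(topo, db)
    if (detect_nonphysical(conf)$nonphysical) {
      flagged[[length(flagged) + 1]] <- conf
    }
  }
  ## planted defects guarantee coverage even when natural ones are rare
  flagged[[length(flagged) + 1]] <- find_pierced_chain(topo, db)$pierced
  for (conf in flagged) {
    mr <- minimize_restrained(conf)
    expect_gt(mr$post_bond_pe, cut$cutoff)
  }
})
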