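test_that("homogeneous-dihedral 20-mers reproduce the reference end-to-end distances", {
  for (gag in names(reference_dihedrals)) {
    conf <- build_fixed(polymer_spec(gag, 20), reference_dihedrals[[gag]])
    e <- end_to_end(conf)
    expect_lt(abs(e - reference_e2e[[gag]]) / reference_e2e[[gag]], 0.03)
  }
})

test_that("built chains carry exactly the requested dihedrals", {
  sp <- polymer_spec("hyaluronan", 20)
  conf <- build_fixed(sp, reference_dihedrals$hyaluronan)
  d <- linkage_dihedrals(conf)
  for (type in unique(d$type)) {
    expect_equal(d$phi[d$type == type],
                 rep(reference_dihedrals$hyaluronan[[type]][1],
                     sum(d$type == type)), tolerance = 1e-9)
    expect_equal(d$psi[d$type == type],
                 rep(reference_dihedrals$hyaluronan[[type]][2],
                     sum(d$type == type)), tolerance = 1e-9)
  }
  expect_equal(nrow(d), 19)
  expect_error(build_fixed(sp, reference_dihedrals$dermatan), "no dihedrals")
  ## bit-for-bit determinism
  conf2 <- build_fixed(sp, reference_dihedrals$hyaluronan)
  expect_identical(conf$coords, conf2$coords)
})

test_that("sampled builds measure back the drawn conformer values", {
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  set.seed(21)
  conf <- build_chain(topo, db)
  d <- linkage_dihedrals(conf)
  for (j in c(1, 2, 10, 19)) {
    type <- topo$linkages$type[j]
    lrow <- db$linkages[[type]][conf$provenance$link_rows[j], ]
    expect_equal(d$phi[j], lrow$phi, tolerance = 1e-6)
    expect_equal(d$psi[j], lrow$psi, tolerance = 1e-6)
  }
  ## every placement-plan internal coordinate is realized exactly
  co <- conf$coords
  pl <- conf$plan
  tor_rows <- which(!is.na(pl$torsion))
  errs <- vapply(tor_rows, function(r) {
    abs(gagchain:::.wrap180(
      dihedral(co[pl$a[r], ], co[pl$b[r], ], co[pl$c[r], ], co[pl$idx[r], ]) -
        pl$torsion[r]))
  }, numeric(1))
  expect_lt(max(errs), 1e-8)
  ## same seed, same chain
  set.seed(21)
  conf2 <- build_chain(topo, db)
  expect_identical(conf$coords, conf2$coords)
})

test_that("adjacent linkages are uncorrelated by construction", {
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  nrep <- 400
  phis <- matrix(NA_real_, nrep, 19)
  for (k in seq_len(nrep)) {
    set.seed(3000 + k)
    phis[k, ] <- linkage_dihedrals(build_chain(topo, db))$phi
  }
  ## compare same-type junctions two apart (adjacent junctions alternate
  ## linkage type, so their phi distributions differ by construction)
  for (j in c(1, 4, 9)) {
    r <- stats::cor(phis[, j], phis[, j + 2])
    expect_lt(abs(r), 3 / sqrt(nrep))
  }
})

test_that("end-to-end distance respects the backbone contour bound", {
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  set.seed(8)
  conf <- build_chain(topo, db)
  ## walk the chain through its junction oxygens: e2e cannot exceed the
  ## summed span lengths (triangle inequality over the backbone path)
  sp <- topo$spec
  path <- c(topo$residues[[1]][match(paste0("O", sp$nonreducing_pos),
                                     topo$atoms$name[topo$residues[[1]]])],
            topo$linkages$o,
            topo$residues[[20]][match("O1",
                                      topo$atoms$name[topo$residues[[20]]])])
  spans <- vapply(seq_len(length(path) - 1), function(k) {
    atom_distance(conf$coords[path[k], ], conf$coords[path[k + 1], ])
  }, numeric(1))
  expect_lte(end_to_end(conf), sum(spans) + 1e-9)
})

test_that("the extended reference dominates sampled chains and grows with length", {
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  ext <- build_extended_reference(topo, db)
  e_ext <- end_to_end(ext)
  e_rand <- vapply(seq_len(400), function(k) {
    set.seed(5000 + k)
    end_to_end(build_chain(topo, db))
  }, numeric(1))
  expect_true(all(e_rand <= e_ext))
  ext10 <- build_extended_reference(polymer_spec("hyaluronan", 10), db)
  expect_gt(e_ext, end_to_end(ext10))
  ## deterministic given the database
  ext2 <- build_extended_reference(topo, db)
  expect_identical(ext$coords, ext2$coords)
})
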