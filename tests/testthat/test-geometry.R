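test_that("distances, angles and dihedrals reproduce hand-computed cases", {
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  p <- c(1.3, -2.2, 0.7)
  expect_equal(atom_distance(p, p), 0)
  sh <- c(4, -1, 2)
  expect_equal(atom_distance(p + sh, c(3, 4, 0) + sh),
               atom_distance(p, c(3, 4, 0)))

  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(bond_angle(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 180)
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(bond_angle(eq[2, ], eq[1, ], eq[3, ]), 60)
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "coincident")

  ## hand-derived sign convention case
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral sign flips under mirror reflection, invariant to rigid moves", {
  set.seed(3)
  for (k in 1:50) {
    pts <- matrix(rnorm(12, sd = 2), 4)
    d0 <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                   error = function(e) NULL)
    if (is.null(d0)) next
    mir <- pts %*% diag(c(1, 1, -1))
    expect_equal(dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ]), -d0,
                 tolerance = 1e-9)
    tr <- random_rigid(k)
    rp <- apply_rigid(pts, tr)
    expect_equal(dihedral(rp[1, ], rp[2, ], rp[3, ], rp[4, ]), d0,
                 tolerance = 1e-8)
    expect_equal(bond_angle(rp[1, ], rp[2, ], rp[3, ]),
                 bond_angle(pts[1, ], pts[2, ], pts[3, ]), tolerance = 1e-8)
  }
})

test_that("place_atom solves the frame equations and inverts measurement", {
  expect_equal(place_atom(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), 1, 90, 180),
               c(2, 1, 0), tolerance = 1e-12)
  expect_error(place_atom(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 1, 90, 0),
               "collinear")
  ## round trip on random valid internal coordinates
  set.seed(11)
  n_draws <- 10000
  worst <- 0
  for (k in seq_len(n_draws)) {
    a <- rnorm(3); b <- a + rnorm(3); cc <- b + rnorm(3)
    bond <- runif(1, 0.8, 2.5)
    ang <- runif(1, 15, 165)
    tor <- runif(1, -179.9, 180)
    d <- tryCatch(place_atom(a, b, cc, bond, ang, tor),
                  error = function(e) NULL)
    if (is.null(d)) next
    worst <- max(worst,
                 abs(atom_distance(cc, d) - bond) / bond,
                 abs(bond_angle(b, cc, d) - ang) / 180,
                 abs(dihedral(a, b, cc, d) - tor) / 360)
  }
  expect_lt(worst, 1e-9)
})

test_that("plan measurement and realization are inverse up to a rigid move", {
  tpl <- residue_template("GlcNAcb")
  plan_idx <- data.frame(idx = match(tpl$plan$atom, tpl$atoms),
                         a = match(tpl$plan$a, tpl$atoms),
                         b = match(tpl$plan$b, tpl$atoms),
                         c = match(tpl$plan$c, tpl$atoms),
                         bond = NA_real_, angle = NA_real_,
                         torsion = NA_real_)
  tr <- random_rigid(5)
  moved <- apply_rigid(tpl$coords, tr)
  m1 <- gagchain:::measure_plan(tpl$coords, plan_idx)
  m2 <- gagchain:::measure_plan(moved, plan_idx)
  ## internals are invariant under the rigid transform
  expect_equal(m1$bond, m2$bond, tolerance = 1e-8)
  expect_equal(m1$torsion, m2$torsion, tolerance = 1e-7)
  rebuilt <- gagchain:::realize_plan(m1, length(tpl$atoms))
  expect_lt(superpose_rmsd(rebuilt, tpl$coords), 1e-6)
})

test_that("a planar zig-zag measures all-trans torsions", {
  n <- 8
  co <- cbind(seq_len(n) * 0.8, rep(c(0, 0.6), length.out = n), 0)
  plan <- data.frame(idx = 1:n, a = c(NA, NA, NA, 1:(n - 3)),
                     b = c(NA, NA, NA, 2:(n - 2)),
                     c = c(NA, NA, NA, 3:(n - 1)),
                     bond = NA_real_, angle = NA_real_, torsion = NA_real_)
  m <- gagchain:::measure_plan(co, plan)
  expect_true(all(abs(abs(m$torsion[4:n]) - 180) < 1e-9))
})
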