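## Calibration helpers: idealized displacement patterns built from the
## label definitions (superscript atoms above the plane, subscripts below),
## independent of the classifier's internal vertex table.
ring_atom_index <- c("O" = 1, "1" = 2, "2" = 3, "3" = 4, "4" = 5, "5" = 6)

pattern_ring <- function(z, mean_bond = 1.49) {
  hex <- ring_from_pucker(0, 0, 0, mean_bond)
  hex[, 3] <- z - mean(z)
  hex
}

boat_ring <- function(up1, up2, h = 0.25) {
  a <- ring_atom_index[[up1]]
  z <- h * cos(2 * pi * ((1:6) - a) / 3)
  pattern_ring(z)
}

skew_ring <- function(up, down, h = 0.35) {
  z <- numeric(6)
  z[ring_atom_index[[up]]] <- h
  z[ring_atom_index[[down]]] <- -h
  pattern_ring(z)
}

test_that("planar and pure-chair displacement patterns give the textbook parameters", {
  expect_equal(cremer_pople(ring_from_pucker(0, 0, 0))$Q, 0, tolerance = 1e-9)
  z <- (-1)^(0:5) * 0.25
  cp <- cremer_pople(pattern_ring(z))
  expect_equal(cp$Q, sqrt(6) * 0.25, tolerance = 1e-9)
  expect_equal(cp$theta, 0, tolerance = 1e-9)
})

test_that("puckering parameters are invariant under rigid transforms", {
  r0 <- ring_from_pucker(0.57, 78, 204)
  cp0 <- cremer_pople(r0)
  for (k in 1:20) {
    r1 <- apply_rigid(r0, random_rigid(k))
    cp1 <- cremer_pople(r1)
    expect_equal(cp1$Q, cp0$Q, tolerance = 1e-9)
    expect_equal(cp1$theta, cp0$theta, tolerance = 1e-7)
    expect_equal(cp1$phi, cp0$phi, tolerance = 1e-6)
  }
})

test_that("index cycling follows the Cremer-Pople phase relations", {
  r0 <- ring_from_pucker(0.57, 78, 204)
  cp0 <- cremer_pople(r0)
  ## shift by 2: parity preserved, phase advances by 240 degrees
  r2 <- r0[c(3:6, 1:2), ]
  cp2 <- cremer_pople(r2)
  expect_equal(cp2$Q, cp0$Q, tolerance = 1e-9)
  expect_equal(cp2$theta, cp0$theta, tolerance = 1e-7)
  expect_equal(cp2$phi, (cp0$phi + 240) %% 360, tolerance = 1e-6)
  ## shift by 1: alternation parity flips, theta reflects
  r1 <- r0[c(2:6, 1), ]
  cp1 <- cremer_pople(r1)
  expect_equal(cp1$Q, cp0$Q, tolerance = 1e-9)
  expect_equal(cp1$theta, 180 - cp0$theta, tolerance = 1e-7)
})

test_that("inverse construction round-trips over a parameter grid", {
  for (Q in c(0.3, 0.57, 0.8)) {
    for (th in c(0, 30, 60, 90, 120, 150, 180)) {
      for (ph in c(0, 45, 150, 290)) {
        cp <- cremer_pople(ring_from_pucker(Q, th, ph))
        expect_equal(cp$Q, Q, tolerance = 1e-3)
        expect_equal(cp$theta, th, tolerance = 0.5)
        if (th > 1 && th < 179) {
          dphi <- abs(((cp$phi - ph + 180) %% 360) - 180)
          expect_lt(dphi, 0.5)
        }
      }
    }
  }
  expect_error(ring_from_pucker(1.5, 90, 0), "feasibility")
})

test_that("chair classification is calibrated by constructed templates", {
  chair <- ring_from_pucker(0.57, 0, 0)
  expect_lt(cremer_pople(chair)$theta, 30)
  expect_equal(classify_pucker(chair)$label, "4C1")
  expect_equal(classify_pucker(ring_from_pucker(0.57, 180, 0))$label, "1C4")
  expect_equal(classify_pucker(list(theta = 5, phi = 111))$label, "4C1")
  expect_equal(classify_pucker(list(theta = 178, phi = 30))$label, "1C4")
})

test_that("the equator wheel is calibrated by idealized boat and skew geometries", {
  ## boats with named atoms up
  for (b in list(c("3,OB", "3", "O"), c("1,4B", "1", "4"),
                 c("2,5B", "2", "5"))) {
    cls <- classify_pucker(boat_ring(b[2], b[3]))
    expect_equal(cls$label, b[1])
    expect_equal(cls$family, "boat")
  }
  ## inverted boats: same atoms down
  for (b in list(c("B3,O", "3"), c("B1,4", "1"), c("B2,5", "2"))) {
    ring <- boat_ring(b[2], c("3" = "O", "1" = "4", "2" = "5")[[b[2]]])
    ring[, 3] <- -ring[, 3]
    expect_equal(classify_pucker(ring)$label, b[1])
  }
  ## skew-boats: superscript up, subscript down
  skews <- list(c("1S3", "1", "3"), c("3S1", "3", "1"), c("1S5", "1", "5"),
                c("5S1", "5", "1"), c("2SO", "2", "O"), c("OS2", "O", "2"))
  for (s in skews) {
    cls <- classify_pucker(skew_ring(s[2], s[3]))
    expect_equal(cls$label, s[1])
    expect_equal(cls$family, "skew-boat")
  }
  expect_equal(pucker_vertex("2SO")$theta, 90)
  expect_error(pucker_vertex("9X9"), "unknown")
})

test_that("classification partitions the sphere", {
  labs <- c("4C1", "1C4", "3,OB", "3S1", "B1,4", "5S1", "2,5B", "2SO",
            "B3,O", "1S3", "1,4B", "1S5", "B2,5", "OS2")
  for (th in seq(0, 180, by = 15)) {
    for (ph in seq(0, 355, by = 12.5)) {
      cls <- classify_pucker(list(theta = th, phi = ph))
      expect_true(cls$label %in% labs)
    }
  }
  ## tie between adjacent vertices resolves toward the lower phi vertex
  expect_equal(classify_pucker(list(theta = 90, phi = 15))$label, "3,OB")
})
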