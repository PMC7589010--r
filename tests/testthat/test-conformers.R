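test_that("extraction pools scale as snapshots x residues and concatenate", {
  topo <- shared_topology("hyaluronan", 6)
  db <- shared_db("hyaluronan")
  confs <- lapply(1:3, function(s) {
    set.seed(100 + s)
    build_chain(topo, db)
  })
  ex <- extract_conformers(confs, topo)
  ## 3 snapshots x 3 residues of each type; junctions 2x b1-3 + 3x... n=6:
  ## 5 junctions alternate b1-3, b1-4, b1-3, b1-4, b1-3
  expect_equal(nrow(ex$rings$GlcA), 3 * 3)
  expect_equal(nrow(ex$rings$GlcNAcb), 3 * 3)
  expect_equal(nrow(ex$linkages[["GlcAb1-3GlcNAc"]]), 3 * 3)
  expect_equal(nrow(ex$linkages[["GlcNAcb1-4GlcA"]]), 3 * 2)
  ## extraction is linear: extract(A u B) = extract(A) pool-concat extract(B)
  exA <- extract_conformers(confs[1:2], topo)
  exB <- extract_conformers(confs[3], topo)
  expect_equal(rbind(exA$rings$GlcA[, 1:10], exB$rings$GlcA[, 1:10]),
               ex$rings$GlcA[, 1:10], ignore_attr = TRUE)
  expect_error(extract_conformers(list(), topo), "empty")
})

test_that("extraction from a built chain recovers the sampled conformers", {
  topo <- shared_topology("hyaluronan", 20)
  db <- shared_db("hyaluronan")
  set.seed(77)
  conf <- build_chain(topo, db)
  ex <- extract_conformers(list(conf), topo)
  ## linkage conformers: all eight parameters recovered exactly
  for (type in names(ex$linkages)) {
    jj <- which(topo$linkages$type == type)
    for (k in seq_along(jj)) {
      sampled <- db$linkages[[type]][conf$provenance$link_rows[jj[k]], 1:8]
      got <- ex$linkages[[type]][k, 1:8]
      expect_equal(as.numeric(got), as.numeric(sampled), tolerance = 1e-6)
    }
  }
  ## ring conformers: all internals recovered except the anomeric-O (O1,
  ## absent on donors, refilled from the template) and the acceptor-slot
  ## O bond/angle, which the junction overrides with the linkage
  ## conformer's values
  pn <- gagchain:::.ring_param_names("GlcA")
  free <- !grepl("O1$|^b_O4$|^a_O4$", pn)
  for (i in c(3, 5, 9)) {  # interior GlcA residues
    sampled <- as.numeric(db$rings$GlcA[conf$provenance$ring_rows[i], pn])
    got <- as.numeric(ex$rings$GlcA[(i + 1) / 2, pn])
    expect_equal(got[free], sampled[free], tolerance = 1e-6)
  }
  ## cached pucker equals recomputation from the realized ring
  row <- ex$rings$GlcA[2, ]
  loc <- realize_ring_conformer("GlcA", as.numeric(row[, pn]))
  cp <- cremer_pople(loc[1:6, ])
  expect_equal(row$Q, cp$Q, tolerance = 1e-9)
  expect_equal(row$theta, cp$theta, tolerance = 1e-6)
  expect_equal(classify_pucker(cp)$label, row$label)
})

test_that("uniform sampling is reproducible and unbiased", {
  db <- shared_db("hyaluronan")
  small <- conformer_db(list(GlcA = db$rings$GlcA[1:10, ]),
                        list("GlcAb1-3GlcNAc" =
                               db$linkages[["GlcAb1-3GlcNAc"]][1:5, ]))
  set.seed(9)
  d1 <- replicate(20, sample_conformer(small, "ring", "GlcA")$source)
  set.seed(9)
  d2 <- replicate(20, sample_conformer(small, "ring", "GlcA")$source)
  expect_identical(d1, d2)
  expect_error(sample_conformer(small, "ring", "Gal"), "unknown")
  ## frequency uniformity over a 10-element pool
  set.seed(31)
  n <- 30000
  draws <- vapply(seq_len(n), function(k) {
    sample_conformer(small, "ring", "GlcA")$source
  }, character(1))
  counts <- table(factor(draws, levels = unique(small$rings$GlcA$source)))
  expect_gt(stats::chisq.test(as.integer(counts))$p.value, 0.001)
  expect_true(all(abs(counts - n / 10) < 3 * sqrt(n * 0.1 * 0.9)))
})

test_that("database serialization round-trips losslessly", {
  db <- shared_db("dermatan", n = 60)
  f1 <- tempfile(fileext = ".jsonl")
  f2 <- tempfile(fileext = ".jsonl")
  save_db(db, f1)
  db2 <- load_db(f1)
  save_db(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
  for (type in names(db$rings)) {
    a <- db$rings[[type]]; b <- db2$rings[[type]]
    num <- vapply(a, is.numeric, logical(1))
    expect_equal(as.matrix(a[, num]), as.matrix(b[, num]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  ## truncated file errors with a position
  lines <- readLines(f1)
  f3 <- tempfile(fileext = ".jsonl")
  writeLines(c(lines[1:5], substr(lines[6], 1, 40)), f3)
  expect_error(load_db(f3), "line 6")
  ## header is mandatory; empty databases are rejected at construction
  f4 <- tempfile(fileext = ".jsonl")
  writeLines(lines[-1], f4)
  expect_error(load_db(f4), "header")
  expect_error(conformer_db(list(), list()))
  expect_error(conformer_db(list(GlcA = db$rings$IdoA[0, ]),
                            db$linkages), "empty")
})
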