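test_that("PDB output round-trips through an independent reader", {
  skip_if_not_installed("bio3d")
  db <- shared_db("hyaluronan")
  topo <- shared_topology("hyaluronan", 20)
  set.seed(13)
  confs <- lapply(1:3, function(k) build_chain(topo, db))
  f <- tempfile(fileext = ".pdb")
  write_pdb(confs, f, multi_model = TRUE)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  expect_equal(sum(grepl("^ENDMDL", txt)), 3)
  expect_equal(sum(grepl("^CONECT", txt)), 19)
  ## residue codes alternate in sequence order
  het <- grep("^HETATM", txt, value = TRUE)
  resnames <- unique(substr(het[1:40], 18, 20))
  expect_equal(resnames, c("BDP", "NAG"))
  rd <- read_pdb_ensemble(f)
  expect_equal(length(rd$conformations), 3)
  for (k in 1:3) {
    expect_lt(max(abs(rd$conformations[[k]]$coords - confs[[k]]$coords)),
              0.001)
  }
  ## statistics computed from the file match the originals
  expect_equal(end_to_end(rd$conformations[[2]]), end_to_end(confs[[2]]),
               tolerance = 1e-3)
})

test_that("PDB reading validates residue codes and model consistency", {
  skip_if_not_installed("bio3d")
  db <- shared_db("dermatan", n = 60)
  conf <- build_chain(build_topology(polymer_spec("dermatan", 4)), db)
  f <- tempfile(fileext = ".pdb")
  write_pdb(conf, f)
  ## corrupt a residue code
  txt <- readLines(f)
  bad <- sub("IDR", "XXX", txt)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(read_pdb_ensemble(f2), "XXX")
  ## model with missing atoms
  f3 <- tempfile(fileext = ".pdb")
  writeLines(txt[-5], f3)
  expect_error(read_pdb_ensemble(f3), "missing|atoms")
})

test_that("the command-line interface is deterministic end to end", {
  wd <- tempfile(); dir.create(wd)
  old <- setwd(wd); on.exit(setwd(old))
  code <- gag_cli(c("gen-db", "--gag", "hyaluronan", "--n-per-pool", "80",
                    "--seed", "3", "--out", "db.jsonl"))
  expect_equal(code, 0L)
  expect_true(file.exists("db.jsonl"))
  expect_true(file.exists("db.jsonl.manifest.json"))
  for (run in 1:2) {
    code <- gag_cli(c("build", "--gag", "hyaluronan", "--length", "10",
                      "--n", "8", "--seed", "5", "--db", "db.jsonl",
                      "--out-prefix", paste0("run", run)))
    expect_equal(code, 0L)
  }
  expect_identical(readLines("run1_members.csv"),
                   readLines("run2_members.csv"))
  code <- gag_cli(c("analyze", "--csv", "run1_members.csv", "--bin", "0.25",
                    "--out", "summary.json"))
  expect_equal(code, 0L)
  sm <- jsonlite::fromJSON("summary.json")
  mem <- read.csv("run1_members.csv")
  expect_equal(sm$most_probable_e2e,
               histogram_mode(mem$e2e, 0.25)$most_probable)
  ## analyze straight from a multi-model PDB
  skip_if_not_installed("bio3d")
  code <- gag_cli(c("build", "--gag", "hyaluronan", "--length", "10",
                    "--n", "8", "--seed", "5", "--db", "db.jsonl",
                    "--out-prefix", "run3", "--pdb"))
  expect_equal(code, 0L)
  code <- gag_cli(c("analyze", "--pdb", "run3_models.pdb", "--bin", "0.25",
                    "--out", "pdbsum.json"))
  expect_equal(code, 0L)
  ps <- jsonlite::fromJSON("pdbsum.json")
  expect_equal(ps$mean_e2e, sm$mean_e2e, tolerance = 1e-3)
  expect_true(file.exists("pdbsum_e2e_hist.csv"))
  expect_true(file.exists("pdbsum_dG_GlcAb13GlcNAc.tsv"))
  grid <- utils::read.table("pdbsum_dG_GlcAb13GlcNAc.tsv", sep = "\t",
                            header = TRUE, row.names = 1, check.names = FALSE)
  expect_equal(dim(grid), c(144, 144))
  expect_equal(min(grid, na.rm = TRUE), 0)

  ## usage errors exit 2
  expect_equal(gag_cli(c("build", "--gag", "hyaluronan")), 2L)
  expect_equal(gag_cli(character(0)), 2L)
  expect_equal(gag_cli("frobnicate"), 2L)
  expect_equal(gag_cli(c("analyze", "--out", "x.json")), 2L)
})
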