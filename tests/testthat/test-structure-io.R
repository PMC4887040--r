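# PDB reading/writing, hydrogen building and site-set derivation.

test_that("a minimal PDB text parses with author numbering preserved", {
  s <- read_structure(TINY_PDB)
  expect_s3_class(s, "protein_structure")
  expect_equal(residue_ids(s), c("A:10", "A:11", "A:12"))
  expect_equal(residue_name(s, "A:11"), "SER")
  expect_equal(residue_atoms(s, "A:10")$resno[1], 10)
})

test_that("altlocs resolve to the highest-occupancy conformer", {
  s <- read_structure(TINY_PDB)
  ser <- residue_atoms(s, "A:11")
  expect_equal(sum(ser$atom == "OG"), 1L)
  # altloc A (occ 0.60) wins: its x coordinate is 14.966
  expect_equal(ser$x[ser$atom == "OG"], 14.966)
})

test_that("write -> read round-trips coordinates to PDB precision", {
  s <- read_structure(TINY_PDB)
  tf <- tempfile(fileext = ".pdb")
  write_structure(s, tf)
  s2 <- read_structure(tf)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(s2$atoms$atom, s$atoms$atom)
})

test_that("malformed ATOM records are reported with their line number", {
  bad <- sub("11.104", "xx.xxx", TINY_PDB)
  expect_error(read_structure(bad), "line 1")
  expect_error(read_structure("REMARK nothing here"), "no ATOM record")
})

test_that("hydrogen building adds the canonical hydrogens at table geometry", {
  s <- build_hydrogens(read_structure(TINY_PDB))
  ala <- residue_atoms(s, "A:10")
  # N-terminal residue: no HN (no preceding carbonyl), but HA + 3 HB
  expect_true(all(c("HA", "HB1", "HB2", "HB3") %in% ala$atom))
  ser <- residue_atoms(s, "A:11")
  expect_true(all(c("HN", "HA", "HB2", "HB3", "HG1") %in% ser$atom))
  # amide N-H bond length equals the ideal value to 1e-6
  n <- as.numeric(ser[ser$atom == "N", c("x", "y", "z")])
  hn <- as.numeric(ser[ser$atom == "HN", c("x", "y", "z")])
  expect_equal(measure("distance", n, hn), 0.997, tolerance = 1e-6)
  # serine gains exactly one (rotatable) hydroxyl hydrogen
  expect_equal(sum(ser$atom == "HG1"), 1L)
  og <- as.numeric(ser[ser$atom == "OG", c("x", "y", "z")])
  hg <- as.numeric(ser[ser$atom == "HG1", c("x", "y", "z")])
  expect_equal(measure("distance", og, hg), 0.960, tolerance = 1e-6)
})

test_that("hydrogen building is idempotent", {
  s1 <- build_hydrogens(read_structure(TINY_PDB))
  s2 <- build_hydrogens(s1)
  expect_equal(nrow(s2$atoms), nrow(s1$atoms))
  expect_equal(s2$atoms$x, s1$atoms$x)
})

test_that("candidate sites agree with a brute-force distance computation", {
  fx <- get_fixture(2)
  s <- fx$scaffold
  refs <- unname(fx$truth$assignment[c("SER1", "HIS2", "ASP3")])
  for (radius in c(6, 10, 15)) {
    got <- candidate_sites(s, refs, radius = radius)
    # brute force
    ca <- s$atoms[s$atoms$atom == "CA", ]
    ids <- sitematch:::.residue_key(ca$chain, ca$resno, ca$icode)
    cen <- colMeans(as.matrix(ca[match(refs, ids), c("x", "y", "z")]))
    d <- sqrt(rowSums(sweep(as.matrix(ca[, c("x", "y", "z")]), 2, cen)^2))
    expect_setequal(got, ids[d <= radius])
  }
  # the reference residues themselves are always within a sane radius
  expect_true(all(refs %in% candidate_sites(s, refs, radius = 15)))
  expect_error(candidate_sites(s, "Z:999"), "not found")
})

test_that("design sites agree with brute force and exclude prolines", {
  fx <- get_fixture(2)
  s <- fx$scaffold
  ts <- fx$truth$ts_pose
  got <- design_sites(s, ts, 7.0)
  at <- s$atoms[!s$atoms$is_hydrogen, ]
  keys <- sitematch:::.residue_key(at$chain, at$resno, at$icode)
  dmin <- sitematch:::row_min_dist_cpp(as.matrix(at[, c("x", "y", "z")]), ts)
  expected <- unique(keys[dmin <= 7.0])
  expect_setequal(got, expected)
  # a TS far away selects nothing
  expect_length(design_sites(s, ts + 500, 7.0), 0L)
  # boundary behaviour: single atoms just inside/outside the shell
  one <- s
  expect_error(design_sites(one, ts[0, , drop = FALSE]), "empty")
})
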