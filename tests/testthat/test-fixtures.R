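# Planted-fixture generator: determinism, validity, perturbation.

test_that("regeneration from the same seed is byte-identical", {
  fa <- generate_fixture(6)
  fb <- generate_fixture(6)
  expect_identical(fa$scaffold$atoms, fb$scaffold$atoms)
  expect_identical(fa$truth$main_dof, fb$truth$main_dof)
  expect_identical(fa$truth$ts_pose, fb$truth$ts_pose)
})

test_that("the generated truth satisfies every constraint exactly and passes pruning", {
  fx <- get_fixture(2)
  chk <- fx$truth$constraint_check
  expect_true(chk$all_satisfied)
  expect_equal(chk$rms_deviation, 0)
  # candidate set holds every planted site plus decoys
  expect_true(all(fx$truth$assignment %in% fx$sites))
  expect_gt(length(fx$decoys), 0)
})

test_that("fixtures round-trip through PDB I/O", {
  fx <- get_fixture(2)
  tf <- tempfile(fileext = ".pdb")
  write_structure(fx$scaffold, tf)
  back <- read_structure(tf)
  expect_equal(residue_ids(back), residue_ids(fx$scaffold))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(fx$scaffold$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("perturbation flags validity according to noise size", {
  fx <- get_fixture(2)
  p0 <- perturb_fixture(fx, 0, seed = 1)
  expect_true(p0$perturbed$valid)
  expect_equal(unname(p0$perturbed$main_dof), unname(fx$truth$main_dof))
  p_big <- perturb_fixture(fx, 60, seed = 1)
  expect_false(p_big$perturbed$valid)
  expect_gt(p_big$perturbed$closure_deviation, 0.1)
})

test_that("fixture export writes a scaffold PDB and machine-readable truth", {
  fx <- get_fixture(2)
  dir <- tempfile("fxout")
  write_fixture(fx, dir)
  expect_true(file.exists(file.path(dir, "scaffold.pdb")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$assignment$SER1, fx$truth$assignment[["SER1"]])
  expect_equal(truth$seed, fx$seed)
})
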