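# Kinematic loop building and closure.

test_that("build_loops yields one main loop plus a side loop per extra side-chain role", {
  fx <- get_fixture(2)
  loops <- build_loops(fx$motif, fx$truth$assignment, fx$scaffold)
  expect_s3_class(loops$main, "kinematic_loop")
  side_roles <- setdiff(
    fx$motif$residues$role[fx$motif$residues$via == "side_chain"],
    main_loop_roles(fx$motif))
  expect_named(loops$sides, side_roles)
  expect_setequal(loops$backbone_roles,
                  fx$motif$residues$role[fx$motif$residues$via == "backbone"])
})

test_that("main-loop DOFs decompose into chis, TS torsions, orientation spins and bounded constraints", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  dof <- loop$dof
  n_chi1 <- n_chi(m$residues$aa[m$residues$role == mains[1]])
  n_chi2 <- n_chi(m$residues$aa[m$residues$role == mains[2]])
  n_rot_ts <- length(m$ts$rotatable)
  # forward chis appear as .c<j> labels, reversed chis as .rchi<j>
  expect_equal(sum(grepl("\\.c[0-9]\\.", dof$label)), n_chi1)
  expect_equal(sum(grepl("\\.rchi[0-9]", dof$label)), n_chi2)
  expect_equal(sum(grepl("^ts\\.[A-Z]", dof$label)), n_rot_ts)
  # every bounded DOF corresponds to an enforced motif constraint
  expect_gte(length(loop$enforced), sum(dof$kind == "bounded"))
  # bond lengths in the chain are never DOFs
  expect_true(all(dof$par %in% c(2L, 3L)))
})

test_that("the planted torsions are an exactly closed fixed point", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  cl <- close_loop(loop, fx$truth$main_dof)
  expect_true(cl$converged)
  expect_lt(cl$closure_deviation, 1e-6)
  cl_ccd <- ccd_close_loop(loop, fx$truth$main_dof)
  expect_true(cl_ccd$converged)
})

test_that("perturbed planted loops re-close under both algorithms", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  n_ok <- 0
  for (k in 1:15) {
    fp <- perturb_fixture(fx, torsion_noise = 20, seed = k)
    cl <- close_loop(loop, fp$perturbed$main_dof)
    if (cl$converged) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 14)
})

test_that("closure never alters bond lengths or bond angles", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  fp <- perturb_fixture(fx, torsion_noise = 25, seed = 3)
  cl <- close_loop(loop, fp$perturbed$main_dof)
  co <- cl$coords
  zm <- loop$zmat
  nf <- nrow(loop$fixed)
  for (i in seq_len(nrow(zm))) {
    d <- co[nf + i, ]
    expect_equal(measure("distance", co[zm[i, "r3"], ], d),
                 unname(zm[i, "len"]), tolerance = 1e-9)
    ang <- measure("angle", co[zm[i, "r2"], ], co[zm[i, "r3"], ], d)
    k <- which(loop$dof$row == i & loop$dof$par == 2L)
    expected_ang <- if (length(k)) unname(cl$torsions[k]) else unname(zm[i, "ang"])
    expect_equal(ang, expected_ang, tolerance = 1e-9)
  }
})

test_that("accepted closures keep bounded torsions inside their ranges", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  sols <- multistart_close(loop, max_samples = 40, seed = 5)
  expect_gt(length(sols), 0)
  bd <- loop$dof$kind == "bounded"
  for (cl in sols) {
    v <- unname(cl$torsions)[bd]
    expect_true(all(v >= loop$dof$lo[bd] - 1e-6 &
                      v <= loop$dof$hi[bd] + 1e-6))
  }
})

test_that("initial-loop sampling enumerates the free grid deterministically", {
  fx <- get_fixture(2)
  loops <- build_loops(fx$motif, fx$truth$assignment, fx$scaffold)
  loop <- loops$sides[[1]]
  n_grid <- prod(vapply(seq_len(nrow(loop$dof)), function(k)
    if (loop$dof$kind[k] == "free" && loop$dof$par[k] == 3L)
      length(loop$grids[[k]]) else 1L, numeric(1)))
  st <- sample_initial_loops(loop, max_samples = 10000, seed = 1)
  expect_length(st, n_grid)
  # capped subsampling is reproducible and distinct
  s1 <- sample_initial_loops(loop, max_samples = 5, seed = 7)
  s2 <- sample_initial_loops(loop, max_samples = 5, seed = 7)
  expect_identical(s1, s2)
  expect_length(unique(lapply(s1, paste, collapse = ",")), 5L)
  s3 <- sample_initial_loops(loop, max_samples = 5, seed = 8)
  expect_false(identical(s1, s3))
})

test_that("max reach bounds every sampled conformation (Monte-Carlo soundness)", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  mx <- max_loop_length(loop, seed = 1)
  term <- loop$targets$row[1]
  set.seed(41)
  for (i in 1:300) {
    lo2 <- pmax(loop$dof$lo, -180)
    hi2 <- pmin(loop$dof$hi, 180)
    v <- lo2 + runif(length(lo2)) * (hi2 - lo2)
    co <- sitematch:::.loop_eval(loop, v)
    reach <- sqrt(sum((co[term, ] - loop$start_ca)^2))
    expect_lte(reach, mx + 1e-6)
  }
  # the anchors of the planted pair are within reach
  expect_lte(sqrt(sum((loop$end_ca - loop$start_ca)^2)), mx)
})
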