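# Matching engine: assignment enumeration, ranking, TS comparison and the
# full per-scaffold pipeline.

test_that("assignment enumeration counts permutations and respects exclusions", {
  m <- toy_triad_motif()
  mm <- minimal_motif(m)            # 3 roles
  sites <- paste0("A:", 1:5)
  out <- enumerate_assignments(mm, sites)
  expect_length(out, 5 * 4 * 3)
  expect_true(all(vapply(out, function(a) !anyDuplicated(a), logical(1))))
  # pigeonhole: too few sites
  expect_length(enumerate_assignments(mm, sites[1:2]), 0L)
  # excluding one main-pair combination removes exactly the assignments that
  # use it (brute-force recount)
  mains <- main_loop_roles(mm)
  excl <- data.frame(site1 = "A:1", site2 = "A:2")
  out2 <- enumerate_assignments(mm, sites, exclude_pairs = excl)
  brute <- Filter(function(a)
    !(a[[mains[1]]] == "A:1" && a[[mains[2]]] == "A:2"), out)
  expect_length(out2, length(brute))
})

test_that("ranking is stable, idempotent and agrees with a sort oracle", {
  mk <- function(score_dev, rep_t, rep_b, sites) {
    rep_df <- data.frame(kind = "distance", a1 = "X:1", a2 = "Y:1", a3 = NA,
                         a4 = NA, optimal = 1, tolerance = 0,
                         measured = 1 + score_dev, deviation = 0)
    structure(list(scaffold_id = "t", site_assignment = sites,
                   ts_pose = matrix(0, 1, 3),
                   constraint_report = list(report = rep_df,
                                            all_satisfied = TRUE,
                                            rms_deviation = 0),
                   repulsion = list(match_vs_template = rep_t,
                                    match_vs_backbone = rep_b),
                   rank_score = NA_real_), class = "site_match")
  }
  set.seed(5)
  ms <- lapply(1:12, function(i)
    mk(runif(1, 0, 2), runif(1, 0, 50), runif(1, 0, 20),
       c(R1 = paste0("A:", i))))
  ranked <- rank_matches(ms)
  scores <- vapply(ranked, `[[`, numeric(1), "rank_score")
  expect_true(!is.unsorted(scores))
  # oracle: recompute the score formula independently
  oracle <- vapply(ms, function(m)
    abs(m$constraint_report$report$measured - 1) +
      (m$repulsion$match_vs_template + m$repulsion$match_vs_backbone) / 100,
    numeric(1))
  expect_equal(sort(oracle), scores, tolerance = 1e-12)
  # permutation invariance and idempotence
  ranked2 <- rank_matches(ms[sample(12)])
  expect_equal(vapply(ranked2, function(m) m$site_assignment[["R1"]],
                      character(1)),
               vapply(ranked, function(m) m$site_assignment[["R1"]],
                      character(1)))
  expect_equal(rank_matches(ranked), ranked)
  # a perfect zero-deviation zero-repulsion match ranks first
  perfect <- mk(0, 0, 0, c(R1 = "A:99"))
  expect_equal(rank_matches(c(ms, list(perfect)))[[1]]$site_assignment[["R1"]],
               "A:99")
})

test_that("TS comparison is a plain no-fit RMSD keyed by atom name", {
  fx <- get_fixture(2)
  fake <- structure(list(ts_pose = fx$truth$ts_pose), class = "site_match")
  expect_equal(ts_rmsd_vs_reference(fake, fx$truth$ts_pose), 0)
  shifted <- fx$truth$ts_pose + matrix(rep(c(1, 0, 0), each = nrow(fx$truth$ts_pose)),
                                       ncol = 3)
  expect_equal(ts_rmsd_vs_reference(fake, shifted), 1, tolerance = 1e-12)
  set.seed(9)
  pert <- fx$truth$ts_pose + matrix(rnorm(length(fx$truth$ts_pose), sd = 0.3),
                                    ncol = 3)
  expect_equal(ts_rmsd_vs_reference(fake, pert),
               sqrt(mean(rowSums((fx$truth$ts_pose - pert)^2))),
               tolerance = 1e-12)
  bad <- fx$truth$ts_pose
  rownames(bad)[1] <- "ZZ"
  expect_error(ts_rmsd_vs_reference(fake, bad), "mismatch")
})

test_that("match_scaffold recovers the planted site at rank one", {
  fx <- get_fixture(2)
  ms <- match_scaffold(fx$scaffold, fx$motif, match_config(seed = 1),
                       sites = fx$sites)
  expect_gt(length(ms), 0)
  top <- ms[[1]]
  expect_equal(sort(unname(top$site_assignment)),
               sort(unname(fx$truth$assignment)))
  expect_equal(top$site_assignment[["SER1"]], fx$truth$assignment[["SER1"]])
  expect_lt(ts_rmsd_vs_reference(top, fx$truth$ts_pose), 0.5)
  # every emitted match satisfies every constraint and every threshold
  p <- pruning_params()
  for (m in ms) {
    expect_true(m$constraint_report$all_satisfied)
    expect_lte(m$repulsion$match_vs_template, p$match_template_max)
    expect_lte(m$repulsion$match_vs_backbone, p$match_backbone_max)
    expect_false(anyDuplicated(m$site_assignment) > 0)
  }
})

test_that("shifting the constraint optima far from the planted geometry yields no match", {
  fx <- get_fixture(2)
  m <- fx$motif
  dists <- m$constraints$kind == "distance"
  m$constraints$optimal[dists] <- m$constraints$optimal[dists] +
    5 * m$constraints$tolerance[dists]
  ms <- match_scaffold(fx$scaffold, m, match_config(seed = 1),
                       sites = fx$sites)
  expect_length(ms, 0L)
})

test_that("a complex motif never yields more matches than its minimal restriction", {
  fx <- get_fixture(4)
  cfg <- match_config(seed = 1, max_samples = 60)
  n_complex <- length(match_scaffold(fx$scaffold, fx$motif, cfg,
                                     sites = fx$sites))
  n_minimal <- length(match_scaffold(fx$scaffold, minimal_motif(fx$motif),
                                     cfg, sites = fx$sites))
  expect_lte(n_complex, n_minimal)
})

test_that("matching is deterministic under a fixed seed", {
  fx <- get_fixture(2)
  cfg <- match_config(seed = 3, max_samples = 40)
  m1 <- match_scaffold(fx$scaffold, fx$motif, cfg, sites = fx$sites)
  m2 <- match_scaffold(fx$scaffold, fx$motif, cfg, sites = fx$sites)
  expect_equal(length(m1), length(m2))
  if (length(m1)) {
    expect_equal(m1[[1]]$site_assignment, m2[[1]]$site_assignment)
    expect_equal(m1[[1]]$ts_pose, m2[[1]]$ts_pose, tolerance = 1e-12)
  }
})
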