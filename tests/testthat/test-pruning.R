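# Pruning strategies: reach, duplicate elimination, repulsion thresholds.

test_that("repulsion thresholds implement the four stage cut-offs", {
  p <- pruning_params()
  expect_equal(prune_by_repulsion("main_loop", 149, p), "keep")
  expect_equal(prune_by_repulsion("main_loop", 151, p), "prune")
  expect_equal(prune_by_repulsion("side_loop", 31, p), "prune")
  expect_equal(prune_by_repulsion("match_vs_template", 199, p), "keep")
  expect_equal(prune_by_repulsion("match_vs_backbone", 51, p), "prune")
  expect_equal(prune_by_repulsion("main_loop", 0, p), "keep")
})

test_that("the linear repulsion model is zero outside onset, k at contact, monotone", {
  p <- pruning_params()
  a <- matrix(c(0, 0, 0), 1)
  b <- matrix(c(10, 0, 0), 1)
  expect_equal(repulsion_energy(a, b, p, radii_a = 1.7, radii_b = 1.7), 0)
  # fully collapsed pair costs exactly k
  expect_equal(repulsion_energy(a, a, p, radii_a = 1.7, radii_b = 1.7),
               p$clash_scale)
  # energy is non-increasing as the groups separate
  prev <- Inf
  for (r in seq(0.5, 3.5, by = 0.25)) {
    e <- repulsion_energy(a, matrix(c(r, 0, 0), 1), p,
                          radii_a = 1.7, radii_b = 1.7)
    expect_lte(e, prev + 1e-12)
    prev <- e
  }
  expect_error(
    repulsion_energy(data.frame(x = 0, y = 0, z = 0, radius = NA, atom = "X"),
                     data.frame(x = 1, y = 0, z = 0, radius = 1.7, atom = "Y")),
    "radius")
})

test_that("greedy loop deduplication matches an independent oracle", {
  set.seed(17)
  mk <- function(base) {
    co <- base + matrix(rnorm(30, sd = 0.02), 10)
    structure(list(coords = co, torsions = numeric(0)), class = "closed_loop")
  }
  base1 <- matrix(rnorm(30), 10)
  base2 <- base1 + 2
  loops <- c(lapply(1:4, function(i) mk(base1)),
             lapply(1:3, function(i) mk(base2)))
  loops <- loops[sample(seq_along(loops))]
  kept <- dedup_loops(loops, threshold = 0.5)
  # oracle: greedy streaming recomputed independently
  oracle <- list()
  for (l in loops) {
    dup <- any(vapply(oracle, function(k)
      sqrt(mean(rowSums((l$coords - k$coords)^2))) <= 0.5, logical(1)))
    if (!dup) oracle[[length(oracle) + 1L]] <- l
  }
  expect_equal(length(kept), length(oracle))
  expect_identical(kept, oracle)
  # every discarded loop is within threshold of some kept loop
  for (l in loops) {
    expect_true(any(vapply(kept, function(k)
      rmsd_nofit(l$coords, k$coords) <= 0.5 + 1e-12, logical(1))))
  }
  # loops separated by twice the threshold are all kept
  far <- lapply(1:3, function(i) {
    structure(list(coords = base1 + 3 * i, torsions = numeric(0)),
              class = "closed_loop")
  })
  expect_length(dedup_loops(far, 0.5), 3L)
})

test_that("reach pruning discards unreachable pairs and keeps the planted pair", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  mx <- max_loop_length(loop, seed = 1)
  expect_equal(prune_by_reach(loop, pruning_params(), mx), "keep")
  far <- loop
  far$end_ca <- far$start_ca + c(50, 0, 0)
  expect_equal(prune_by_reach(far, pruning_params(), mx), "prune")
})

test_that("no planted ground truth is pruned at any repulsion stage", {
  fx <- get_fixture(2)
  m <- fx$motif
  mains <- main_loop_roles(m)
  loop <- build_main_loop(m, mains[1], mains[2], fx$truth$assignment[[mains[1]]],
                          fx$truth$assignment[[mains[2]]], fx$scaffold)
  cl <- close_loop(loop, fx$truth$main_dof)
  params <- pruning_params()
  rsets <- sitematch:::.repulsion_sets(fx$scaffold, fx$sites)
  grp <- sitematch:::.loop_heavy_atoms(loop, cl)
  e_main <- sitematch:::.rep_energy_vs(
    grp, rsets$backbone, unname(fx$truth$assignment[mains]),
    rsets$backbone_key, params)
  expect_equal(prune_by_repulsion("main_loop", e_main, params), "keep")
  # whole planted site (all side chains + TS) against template and backbone
  co <- fx$truth$coords
  labs <- names(co)
  side <- !grepl(":(N|CA|C|O|HN|HA)$", labs) &
    !sitematch:::element_of(sub("^.*:", "", labs)) == "H"
  xyz <- do.call(rbind, co[side])
  g <- list(xyz = xyz,
            radii = vdw_radius(sitematch:::element_of(sub("^.*:", "", labs[side]))))
  e_tpl <- sitematch:::.rep_energy_vs(g, rsets$template, character(0), NULL,
                                      params)
  e_bb <- sitematch:::.rep_energy_vs(g, rsets$backbone,
                                     unname(fx$truth$assignment),
                                     rsets$backbone_key, params)
  expect_equal(prune_by_repulsion("match_vs_template", e_tpl, params), "keep")
  expect_equal(prune_by_repulsion("match_vs_backbone", e_bb, params), "keep")
})
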