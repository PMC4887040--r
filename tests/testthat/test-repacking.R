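# Side-chain repacking: rotamer library, energy tables, DEE/GMEC,
# hydrogen-bond detection and binding energy.

test_that("hydroxyl expansion multiplies Ser/Thr/Tyr and leaves others alone", {
  lib <- default_rotamer_library()
  ex <- expand_hydroxyl_rotamers(lib, step = 120)
  expect_equal(nrow(ex$SER), nrow(lib$SER) * 3)
  expect_equal(nrow(ex$TYR), nrow(lib$TYR) * 3)
  expect_identical(ex$ALA, lib$ALA)
  expect_identical(ex$HIS, lib$HIS)
  expect_error(expand_hydroxyl_rotamers(lib, step = 100), "divide")
  # heavy atoms are identical across the expansions of one rotamer
  bb <- sitematch:::template_xyz(sitematch:::residue_template("SER"),
                                 c("N", "CA", "C"))
  rownames(bb) <- c("N", "CA", "C")
  r1 <- sitematch:::rotamer_coords("SER", bb, c(chi1 = -60, hchi = 60))
  r2 <- sitematch:::rotamer_coords("SER", bb, c(chi1 = -60, hchi = 180))
  h1 <- r1[!r1$is_hydrogen, c("atom", "x", "y", "z")]
  h2 <- r2[!r2$is_hydrogen, c("atom", "x", "y", "z")]
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r1[r1$atom == "HG1", c("x", "y", "z")],
                                r2[r2$atom == "HG1", c("x", "y", "z")],
                                tolerance = 1e-6)))
})

test_that("DEE plus branch-and-bound equals exhaustive enumeration", {
  for (seed in 1:30) {
    tab <- random_tables(n_sites = 4, n_rot = 6, seed = seed)
    red <- dee_reduce(tab)
    sol <- solve_gmec(red)
    ref <- exhaustive_gmec(tab)
    expect_equal(sol$total_energy, ref$energy, tolerance = 1e-9)
  }
})

test_that("Goldstein elimination removes a uniformly dominated rotamer", {
  tab <- random_tables(3, 4, seed = 99)
  # make rotamer 1 at site 1 dominated by rotamer 2 everywhere
  tab$singleton[[1]][1] <- tab$singleton[[1]][2] + 50
  tab$pairwise[[1]][[2]][1, ] <- tab$pairwise[[1]][[2]][2, ] + 1
  tab$pairwise[[1]][[3]][1, ] <- tab$pairwise[[1]][[3]][2, ] + 1
  red <- dee_reduce(tab)
  expect_lt(length(red$singleton[[1]]), length(tab$singleton[[1]]))
  expect_gte(attr(red, "eliminated"), 1L)
  # one-rotamer-per-site tables pass through unchanged
  tab1 <- random_tables(3, 1, seed = 7)
  expect_equal(dee_reduce(tab1)$singleton, tab1$singleton)
})

test_that("GMEC is gauge invariant under constant singleton shifts", {
  tab <- random_tables(3, 5, seed = 13)
  sol <- solve_gmec(tab)
  tab2 <- tab
  tab2$singleton[[2]] <- tab2$singleton[[2]] + 7.5
  sol2 <- solve_gmec(tab2)
  expect_equal(sol2$assignment, sol$assignment)
  expect_equal(sol2$total_energy, sol$total_energy + 7.5, tolerance = 1e-9)
})

test_that("energy tables are symmetric and zero for distant site pairs", {
  fx <- get_fixture(2)
  ts <- ts_atom_table(fx$motif$ts, fx$truth$ts_pose)
  ds <- design_sites(fx$scaffold, fx$truth$ts_pose, 7.0)[1:4]
  lib <- expand_hydroxyl_rotamers(default_rotamer_library())
  tab <- build_energy_tables(fx$scaffold, ts, ds, lib)
  for (i in seq_along(ds)) for (j in seq_along(ds)) if (j > i) {
    pw <- tab$pairwise[[i]][[j]]
    expect_true(all(is.finite(pw)))
    for (ri in seq_len(min(3, nrow(pw)))) for (rj in seq_len(min(3, ncol(pw))))
      expect_equal(sitematch:::.pair_e(tab, i, j, ri, rj),
                   sitematch:::.pair_e(tab, j, i, rj, ri))
  }
  # a clashing rotamer scores worse than a clash-free one at the same site
  s_ser <- fx$truth$assignment[["SER1"]]
  i <- match(s_ser, tab$sites)
  if (!is.na(i)) expect_gt(diff(range(tab$singleton[[i]])), 0)
})

test_that("hydrogen-bond detection applies the distance/angle criterion", {
  mk_atoms <- function(da, ang) {
    # donor N with H aimed at acceptor O; place O at distance `da` from N
    # with the D-H...A angle equal to `ang`
    n <- c(0, 0, 0)
    h <- c(1.0, 0, 0)
    th <- (180 - ang) * pi / 180
    o <- h + (da - 1) * c(cos(th), sin(th), 0)
    data.frame(chain = c("A", "A", "B"), resno = c(1, 1, 2), icode = "",
               atom = c("N", "HN", "O"), element = c("N", "H", "O"),
               x = c(n[1], h[1], o[1]), y = c(n[2], h[2], o[2]),
               z = c(n[3], h[3], o[3]),
               is_hydrogen = c(FALSE, TRUE, FALSE),
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(detect_hydrogen_bonds(mk_atoms(2.9, 165))), 1L)
  expect_equal(nrow(detect_hydrogen_bonds(mk_atoms(4.0, 165))), 0L)
  expect_equal(nrow(detect_hydrogen_bonds(mk_atoms(2.9, 100))), 0L)
  # boundary: exactly 3.3 A is inside the (closed) interval
  b <- detect_hydrogen_bonds(mk_atoms(3.3, 170))
  expect_equal(nrow(b), 1L)
  expect_equal(b$distance, 3.3, tolerance = 0.05)
})

test_that("hydrogen-bond recovery is the matched fraction of the reference", {
  ref <- data.frame(donor_res = c("A:1", "A:2"), donor_atom = "N",
                    hydrogen = "HN", acceptor_res = "B:9",
                    acceptor_atom = "O1", distance = 2.9, angle = 160,
                    stringsAsFactors = FALSE)
  expect_equal(hbond_recovery(ref, ref)$fraction, 1)
  other <- ref; other$donor_res <- c("C:5", "C:6")
  expect_equal(hbond_recovery(other, ref)$fraction, 0)
  # 80 of 88, as a fraction
  big <- ref[rep(1, 88), ]; big$donor_res <- paste0("A:", 1:88)
  pred <- big[1:80, ]
  expect_equal(hbond_recovery(pred, big)$fraction, 80 / 88, tolerance = 1e-12)
  expect_error(hbond_recovery(ref, ref[0, ]), "empty reference")
})

test_that("binding energy vanishes at separation, is rigid-invariant, rewards H-bonds", {
  fx <- get_fixture(2)
  ts <- ts_atom_table(fx$motif$ts, fx$truth$ts_pose)
  be0 <- binding_energy(fx$scaffold, ts)
  far <- ts; far$x <- far$x + 100
  expect_equal(binding_energy(fx$scaffold, far), 0, tolerance = 1e-6)
  # rigid motion of the whole complex leaves the binding energy unchanged
  sc2 <- fx$scaffold
  sc2$atoms$x <- sc2$atoms$x + 5
  ts2 <- ts; ts2$x <- ts2$x + 5
  expect_equal(binding_energy(sc2, ts2), be0, tolerance = 1e-9)
  # the planted complex binds favourably (it is built around the TS)
  expect_lt(be0, 0)
})

test_that("repacking with the TS at its planted pose recovers the planted bonds", {
  fx <- get_fixture(2)
  ts <- ts_atom_table(fx$motif$ts, fx$truth$ts_pose)
  ds <- design_sites(fx$scaffold, fx$truth$ts_pose, 7.0)
  rp <- repack_sites(fx$scaffold, ts, ds)
  expect_s3_class(rp, "repack_result")
  expect_true(all(ds %in% names(rp$assignment)))
  rec <- hbond_recovery(rp$hydrogen_bonds, fx$truth$hydrogen_bonds)
  expect_gte(rec$fraction, 0.75)
  expect_lt(rp$binding_energy, 0)
})
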