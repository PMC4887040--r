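# Geometric kernel: measurements, internal->Cartesian placement, Kabsch
# superposition.

test_that("distance, angle and dihedral measurements match hand values", {
  expect_equal(measure("distance", c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(measure("angle", c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # sign convention fixed by a documented test vector (standard convention:
  # Biopython/MDAnalysis give +90 here)
  expect_equal(measure("dihedral", c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                       c(1, 1, 1)), 90)
  expect_error(measure("dihedral", c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                       c(3, 1, 0)), "degenerate")
  expect_error(measure("angle", c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
})

test_that("internal_to_cartesian is the exact inverse of measure", {
  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(3); b <- a + rnorm(3); c_ <- b + rnorm(3)
    if (sum(sitematch:::.cross3(b - a, c_ - b)^2) < 1e-4) next
    len <- runif(1, 0.8, 2.5)
    ang <- runif(1, 20, 160)
    tor <- runif(1, -179, 179)
    d <- internal_to_cartesian(a, b, c_, len, ang, tor)
    expect_equal(measure("distance", c_, d), len, tolerance = 1e-9)
    expect_equal(measure("angle", b, c_, d), ang, tolerance = 1e-9)
    expect_equal(measure("dihedral", a, b, c_, d), tor, tolerance = 1e-9)
  }
})

test_that("degenerate placement requests are rejected", {
  a <- c(0, 0, 0); b <- c(1, 0, 0); c_ <- c(1, 1, 0)
  expect_error(internal_to_cartesian(a, b, c_, 1.5, 180, 0), "open interval")
  expect_error(internal_to_cartesian(a, b, c(2, 0, 0), 1.5, 109, 0),
               "collinear")
  expect_error(internal_to_cartesian(a, b, c_, -1, 109, 0), "> 0")
})

test_that("chained ideal peptide geometry gives the canonical CA-CA distance", {
  # N-CA-C of residue 1, then C-N-CA of residue 2 at ideal values
  n1 <- c(1.458, 0, 0); ca1 <- c(0, 0, 0)
  c1 <- internal_to_cartesian(c(0, 0, 1), n1, ca1, 1.525, 111.0, 47)
  n2 <- internal_to_cartesian(n1, ca1, c1, 1.329, 117.2, -45)
  ca2 <- internal_to_cartesian(ca1, c1, n2, 1.458, 121.7, 180)
  expect_equal(measure("distance", ca1, ca2), 3.80, tolerance = 0.05 / 3.8)
})

test_that("superposition recovers rigid transforms and matches an independent oracle", {
  set.seed(21)
  X <- matrix(rnorm(30), 10)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  Y <- X %*% t(R) + matrix(rep(c(1, -2, 3), each = 10), 10)
  fit <- superpose(Y, X)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_transform(Y, fit), X, tolerance = 1e-8,
               ignore_attr = TRUE)
  # independent oracle: bio3d's Kabsch fit on random non-congruent sets
  for (i in 1:5) {
    A <- matrix(rnorm(30), 10)
    B <- matrix(rnorm(30), 10)
    ours <- superpose(A, B)$rmsd
    ref <- bio3d::rmsd(as.numeric(t(B)), as.numeric(t(A)), fit = TRUE)
    expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds to 3 decimals
    # fitted RMSD never exceeds the no-fit RMSD
    expect_lte(ours, rmsd_nofit(A, B) + 1e-12)
  }
})

test_that("measurements are invariant under rigid motion", {
  set.seed(31)
  pts <- matrix(rnorm(12), 4)
  th <- runif(3, -pi, pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  shift <- rnorm(3)
  moved <- sweep(pts %*% t(Rz), 2, shift, "+")
  expect_equal(measure("distance", pts[1, ], pts[2, ]),
               measure("distance", moved[1, ], moved[2, ]), tolerance = 1e-9)
  expect_equal(measure("angle", pts[1, ], pts[2, ], pts[3, ]),
               measure("angle", moved[1, ], moved[2, ], moved[3, ]),
               tolerance = 1e-9)
  expect_equal(measure("dihedral", pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
               measure("dihedral", moved[1, ], moved[2, ], moved[3, ],
                       moved[4, ]), tolerance = 1e-9)
  # reflection flips the dihedral sign
  refl <- pts; refl[, 3] <- -refl[, 3]
  expect_equal(measure("dihedral", refl[1, ], refl[2, ], refl[3, ], refl[4, ]),
               -measure("dihedral", pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
               tolerance = 1e-9)
})

test_that("wrap_angle maps onto (-180, 180] with shortest-arc semantics", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(-181), 179)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(c(360, -360, 540)), c(0, 0, 180))
})
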