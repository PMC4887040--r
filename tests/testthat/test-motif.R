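# Catalytic motifs: parsing, serialization, constraint evaluation.

motif_dir <- system.file("extdata", "motifs", package = "sitematch")

test_that("the shipped triad motifs carry the expected role compositions", {
  pnpa <- parse_motif(file.path(motif_dir, "pnpa_triad.yaml"))
  expect_equal(pnpa$residues$role,
               c("SER1", "HIS2", "ASP3", "ALA4", "ALA5", "ALA6"))
  expect_equal(sum(pnpa$residues$class == "catalytic"), 3L)
  expect_equal(sum(pnpa$residues$via == "backbone"), 3L)
  ceph1 <- parse_motif(file.path(motif_dir, "cephalexin_classic.yaml"))
  expect_equal(nrow(ceph1$residues), 7L)
  expect_true("ASP7" %in% ceph1$residues$role)
  ceph2 <- parse_motif(file.path(motif_dir, "cephalexin_flexible.yaml"))
  expect_true(all(c("TYR5", "SER6", "GLU7") %in% ceph2$residues$role))
  expect_equal(nrow(ceph2$residues), 7L)
})

test_that("serialize -> parse is the identity on motif content", {
  m <- toy_triad_motif()
  tf <- tempfile(fileext = ".yaml")
  write_motif(m, tf)
  m2 <- parse_motif(tf)
  expect_equal(m2$residues, m$residues)
  expect_equal(m2$constraints, m$constraints)
  expect_equal(m2$ts$atoms, m$ts$atoms)
  expect_equal(m2$ts$xyz, m$ts$xyz, tolerance = 1e-9)
})

test_that("TS internal coordinates reconstruct the local geometry", {
  ts <- toy_triad_motif()$ts
  xyz <- ts_local_coords(ts)
  zm <- ts$zmatrix
  nm <- ts$atoms$name
  for (i in seq_along(zm)) {
    r <- zm[[i]]
    if (i >= 2L) {
      bonded <- utils::tail(unlist(r$ref), 1L)
      expect_equal(measure("distance", xyz[match(bonded, nm), ], xyz[i, ]),
                   as.numeric(r$length), tolerance = 1e-6)
    }
    if (i >= 4L) {
      refs <- match(unlist(r$ref), nm)
      expect_equal(measure("dihedral", xyz[refs[1], ], xyz[refs[2], ],
                           xyz[refs[3], ], xyz[i, ]),
                   as.numeric(r$torsion), tolerance = 1e-6)
    }
  }
})

test_that("malformed motifs fail with named errors", {
  m <- yaml::yaml.load(paste(readLines(file.path(motif_dir, "toy_triad.yaml")),
                             collapse = "\n"))
  m$ts <- read_ts_model(file.path(motif_dir, "toy_ts.yaml"))
  bad <- m
  bad$constraints[[1]]$atoms[[1]] <- "GHOST9:OG"
  expect_error(parse_motif(bad), "GHOST9")
  bad2 <- m
  bad2$constraints[[1]]$kind <- "hyperbola"
  expect_error(parse_motif(bad2), "unknown constraint kind")
})

test_that("constraint deviation wraps dihedrals and subtracts tolerance", {
  mk <- function(kind, atoms, optimal, tol)
    data.frame(kind = kind, a1 = atoms[1], a2 = atoms[2],
               a3 = if (length(atoms) >= 3) atoms[3] else NA,
               a4 = if (length(atoms) >= 4) atoms[4] else NA,
               optimal = optimal, tolerance = tol, stringsAsFactors = FALSE)
  co <- list("A:X" = c(0, 0, 0), "B:Y" = c(3.3, 0, 0))
  d <- constraint_deviation(mk("distance", c("A:X", "B:Y"), 2.8, 0.3), co)
  expect_equal(d$measured, 3.3)
  expect_equal(d$deviation, 0.2, tolerance = 1e-12)
  # wrapped dihedral: optimal 179, measured -179, tolerance 5 -> satisfied
  co2 <- list(a = c(0, 0, 0), b = c(1, 0, 0), c = c(1, 1, 0))
  co2$d <- internal_to_cartesian(co2$a, co2$b, co2$c, 1, 109, -179)
  names(co2) <- c("A:a", "A:b", "A:c", "A:d")
  dd <- constraint_deviation(
    mk("improper_dihedral", c("A:a", "A:b", "A:c", "A:d"), 179, 5), co2)
  expect_equal(dd$deviation, 0)
  expect_error(constraint_deviation(mk("distance", c("A:X", "Q:Z"), 2, 0.1),
                                    co), "unresolved")
})

test_that("the planted fixture satisfies every constraint with zero deviation", {
  fx <- get_fixture(2)
  chk <- check_match_constraints(fx$motif, fx$truth$coords)
  expect_true(chk$all_satisfied)
  expect_equal(chk$rms_deviation, 0)
  # perturbing one side-chain atom beyond tolerance breaks exactly the
  # constraints that reference it
  co <- fx$truth$coords
  co[["ASP3:OD2"]] <- co[["ASP3:OD2"]] + c(1.5, 0, 0)
  chk2 <- check_match_constraints(fx$motif, co)
  expect_false(chk2$all_satisfied)
  viol <- chk2$report[chk2$report$deviation > 0, ]
  expect_true(all(grepl("OD2", paste(viol$a1, viol$a2, viol$a3, viol$a4))))
})

test_that("empty constraint sets are trivially satisfied", {
  m <- toy_triad_motif()
  m$constraints <- m$constraints[0, ]
  chk <- check_match_constraints(m, list())
  expect_true(chk$all_satisfied)
  expect_equal(chk$rms_deviation, 0)
})

test_that("the minimal motif view is a role and constraint subset", {
  m <- toy_triad_motif()
  mm <- minimal_motif(m)
  expect_true(all(mm$residues$class == "catalytic"))
  expect_true(all(mm$residues$role %in% m$residues$role))
  key <- function(cs) paste(cs$kind, cs$a1, cs$a2, cs$a3, cs$a4)
  expect_true(all(key(mm$constraints) %in% key(m$constraints)))
  # coordinates satisfying the complex motif satisfy the minimal one
  fx <- get_fixture(2)
  expect_true(check_match_constraints(mm, fx$truth$coords)$all_satisfied)
})
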