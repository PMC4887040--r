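# Surrogate free-energy model in protein-design energy units (PEU): Lennard-Jones
# van der Waals with a linearized short-range repulsion, a directional
# 10-12 hydrogen-bond term and Coulomb electrostatics with a
# distance-dependent dielectric.  The functional forms and constants are this
# package's own calibration; PEU is defined as the unit of this model.

.LJ_EPS <- c(C = 0.10, N = 0.20, O = 0.16, S = 0.45, H = 0.03, P = 0.30)
.HB_EPS <- 2.5      # well depth of the 10-12 H-bond term, PEU
.HB_R0 <- 1.90      # optimal H...acceptor distance, Angstrom
.ELEC_K <- 83.0     # 332 / 4: Coulomb constant over eps(r) = 4r
.CUTOFF <- 10.0     # pair interaction cutoff, Angstrom

# annotate an atom table with donor-hydrogen parents and acceptor flags
# (expects columns element, is_hydrogen, x, y, z and a residue key)
.annotate_hbond_roles <- function(at) {
  key <- if (!is.null(at$chain)) .residue_key(at$chain, at$resno, at$icode)
         else rep("LIG", nrow(at))
  at$.reskey <- key
  at$.donor_parent <- NA_integer_
  at$.acceptor <- FALSE
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (k in unique(key)) {
    idx <- which(key == k)
    sub <- at[idx, , drop = FALSE]
    heavyNO <- idx[sub$element %in% c("N", "O")]
    hs <- idx[sub$is_hydrogen]
    n_h <- integer(length(heavyNO))
    for (h in hs) {
      if (length(heavyNO) == 0L) next
      d <- sqrt(colSums((t(xyz[heavyNO, , drop = FALSE]) - xyz[h, ])^2))
      j <- which.min(d)
      if (d[j] < 1.25) {
        at$.donor_parent[h] <- heavyNO[j]
        n_h[j] <- n_h[j] + 1L
      }
    }
    # acceptors: all oxygens; nitrogens with no bound hydrogen
    for (i in seq_along(heavyNO)) {
      el <- at$element[heavyNO[i]]
      at$.acceptor[heavyNO[i]] <- el == "O" || (el == "N" && n_h[i] == 0L)
    }
  }
  at
}

# pairwise interaction energy between two annotated atom tables (PEU);
# same-residue pairs are excluded when tables share residues
.pair_energy <- function(a, b, cutoff = .CUTOFF) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  d2[d2 < 1e-12] <- 1e-12
  r <- sqrt(d2)
  within <- r < cutoff & outer(a$.reskey, b$.reskey, `!=`)
  if (!any(within)) return(0)
  # Lennard-Jones, repulsion linearized below 0.8 rmin
  rmin <- outer(a$radius, b$radius, `+`)
  eps <- sqrt(outer(.LJ_EPS[a$element], .LJ_EPS[b$element]))
  q <- (rmin / r)
  lj <- eps * (q^12 - 2 * q^6)
  lin_at <- 0.8
  sl <- r < lin_at * rmin
  if (any(sl & within)) {
    # linear continuation with the slope at 0.8 rmin
    f0 <- eps * (lin_at^-12 - 2 * lin_at^-6)
    df <- eps * (-12 * lin_at^-13 + 12 * lin_at^-7) / rmin
    lj[sl] <- (f0 + df * (r - lin_at * rmin))[sl]
  }
  e <- sum(lj[within])
  # electrostatics with distance-dependent dielectric eps(r) = 4r
  qa <- a$charge; qa[is.na(qa)] <- 0
  qb <- b$charge; qb[is.na(qb)] <- 0
  if (any(qa != 0) && any(qb != 0))
    e <- e + sum((.ELEC_K * outer(qa, qb) / d2)[within])
  # directional 10-12 hydrogen-bond term (both donor/acceptor directions)
  e <- e + .hbond_energy(a, b, r, within) +
    .hbond_energy(b, a, t(r), t(within))
  unname(e)
}

.hbond_energy <- function(don, acc, r, within) {
  hs <- which(!is.na(don$.donor_parent))
  as_ <- which(acc$.acceptor)
  if (length(hs) == 0L || length(as_) == 0L) return(0)
  e <- 0
  for (h in hs) {
    d_at <- don$.donor_parent[h]
    hx <- as.numeric(don[h, c("x", "y", "z")])
    dx <- as.numeric(don[d_at, c("x", "y", "z")])
    for (ac in as_) {
      if (!within[h, ac]) next
      dist <- r[h, ac]
      if (dist > 3.5) next
      ax <- as.numeric(acc[ac, c("x", "y", "z")])
      ang <- measure("angle", dx, hx, ax)
      if (ang < 90) next
      q <- .HB_R0 / dist
      # 10-12 form: -eps at the optimum distance, scaled by directionality
      e <- e + .HB_EPS * (5 * q^12 - 6 * q^10) *
        cos(pi * (180 - ang) / 180)^2
    }
  }
  e
}

# interaction energy between two raw atom tables (annotates both)
energy_between <- function(atoms_a, atoms_b, cutoff = .CUTOFF) {
  .pair_energy(.annotate_hbond_roles(atoms_a), .annotate_hbond_roles(atoms_b),
               cutoff)
}

#' Detect hydrogen bonds in an atom set
#'
#' Criterion: donor-acceptor heavy-atom distance <= 3.3 Angstrom (closed
#' interval) and donor-H...acceptor angle >= 120 degrees, between different
#' residues.  Donors are N/O atoms with a bound hydrogen; acceptors are
#' oxygens and hydrogen-free nitrogens.
#'
#' @param atoms atom table with columns `atom`, `element`, `is_hydrogen`,
#'   `x`, `y`, `z` and residue identity (`chain`, `resno`, `icode`) --
#'   e.g. `protein_structure$atoms`, optionally with TS rows appended.
#' @param max_da donor-acceptor distance cutoff (default 3.3).
#' @param min_angle minimum D-H...A angle in degrees (default 120).
#' @return data.frame with donor/acceptor residue keys and atom names,
#'   distances and angles; zero rows when none.
#' @export
detect_hydrogen_bonds <- function(atoms, max_da = 3.3, min_angle = 120) {
  at <- .annotate_hbond_roles(atoms)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  hs <- which(!is.na(at$.donor_parent))
  as_ <- which(at$.acceptor)
  out <- list()
  for (h in hs) {
    d_at <- at$.donor_parent[h]
    for (ac in as_) {
      if (at$.reskey[ac] == at$.reskey[d_at]) next
      dda <- sqrt(sum((xyz[d_at, ] - xyz[ac, ])^2))
      if (dda > max_da) next
      ang <- measure("angle", xyz[d_at, ], xyz[h, ], xyz[ac, ])
      if (ang < min_angle) next
      out[[length(out) + 1L]] <- data.frame(
        donor_res = at$.reskey[d_at], donor_atom = at$atom[d_at],
        hydrogen = at$atom[h],
        acceptor_res = at$.reskey[ac], acceptor_atom = at$atom[ac],
        distance = dda, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(donor_res = character(0), donor_atom = character(0),
                      hydrogen = character(0), acceptor_res = character(0),
                      acceptor_atom = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  # one bond per donor-H/acceptor pair; drop duplicates from multiple H
  key <- paste(res$donor_res, res$donor_atom, res$acceptor_res,
               res$acceptor_atom)
  res <- res[order(key, res$distance), , drop = FALSE]
  res <- res[!duplicated(paste(res$donor_res, res$donor_atom,
                               res$acceptor_res, res$acceptor_atom)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond recovery against a reference list
#'
#' Bonds are identified by donor atom id and acceptor atom id
#' (`residue|atom` on both sides); recovery is the fraction of reference
#' bonds present among the predictions.
#'
#' @param predicted,reference data.frames as from [detect_hydrogen_bonds()].
#' @return list with `fraction`, `matched`, `missed`, `extra`.
#' @export
hbond_recovery <- function(predicted, reference) {
  if (is.null(reference) || nrow(reference) == 0L)
    stop("empty reference hydrogen-bond list: recovery undefined",
         call. = FALSE)
  id <- function(df) paste0(df$donor_res, "|", df$donor_atom, ">",
                            df$acceptor_res, "|", df$acceptor_atom)
  pid <- id(predicted); rid <- id(reference)
  matched <- reference[rid %in% pid, , drop = FALSE]
  missed <- reference[!(rid %in% pid), , drop = FALSE]
  extra <- predicted[!(pid %in% rid), , drop = FALSE]
  list(fraction = nrow(matched) / nrow(reference),
       matched = matched, missed = missed, extra = extra)
}
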