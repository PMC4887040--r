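# Rotamer-based side-chain repacking around a fixed transition-state pose:
# backbone-independent rotamer library, energy tables, dead-end elimination
# (Goldstein) and an exact branch-and-bound GMEC search, hydrogen-bond
# recovery and binding energy.

.SP3 <- c(-60, 60, 180)

# chi sets per residue; adjacent gauche+/gauche- combinations (syn-pentane
# clashes) are removed for aliphatic chains
.chi_sets <- function(res) {
  switch(res,
    SER = , CYS = , THR = , VAL = list(.SP3),
    LEU = , ILE = list(.SP3, .SP3),
    ASP = list(.SP3, c(0, 90)),
    ASN = list(.SP3, c(-90, 0, 90, 180)),
    GLU = list(.SP3, .SP3, c(0, 90)),
    GLN = list(.SP3, .SP3, c(-90, 0, 90, 180)),
    MET = list(.SP3, .SP3, .SP3),
    LYS = list(.SP3, .SP3, .SP3, .SP3),
    ARG = list(.SP3, .SP3, .SP3, c(-90, 90, 180)),
    HIS = list(.SP3, c(-90, 60, 90, 180)),
    PHE = , TYR = list(.SP3, c(-60, 60, 90)),
    TRP = list(.SP3, c(-90, 90, 180)),
    NULL)
}

.syn_pentane <- function(chis) {
  n <- length(chis)
  if (n < 2L) return(FALSE)
  any(vapply(seq_len(n - 1L), function(i)
    (chis[i] == 60 && chis[i + 1L] == -60) ||
      (chis[i] == -60 && chis[i + 1L] == 60), logical(1)))
}

#' Backbone-independent rotamer library
#'
#' A compact library generated from standard staggered chi statistics
#' (sp3 bonds at -60/60/180, planar groups at their common orientations),
#' with adjacent gauche+/gauche- combinations removed for aliphatic chains.
#' Layout-compatible loaders can substitute an external library.
#'
#' @return a `rotamer_library`: named list of chi matrices (one row per
#'   rotamer), plus a `provenance` attribute.
#' @export
default_rotamer_library <- function() {
  res <- c("SER", "CYS", "THR", "VAL", "LEU", "ILE", "ASP", "ASN", "GLU",
           "GLN", "MET", "LYS", "ARG", "HIS", "PHE", "TYR", "TRP")
  lib <- lapply(res, function(rn) {
    sets <- .chi_sets(rn)
    g <- as.matrix(do.call(expand.grid, sets))
    colnames(g) <- paste0("chi", seq_along(sets))
    aliphatic <- rn %in% c("LEU", "ILE", "MET", "LYS", "ARG", "GLU", "GLN")
    if (aliphatic && ncol(g) >= 2L)
      g <- g[!apply(g, 1, .syn_pentane), , drop = FALSE]
    g
  })
  names(lib) <- res
  lib <- c(lib, list(ALA = matrix(numeric(0), 1, 0), GLY = matrix(numeric(0), 1, 0)))
  structure(lib, class = "rotamer_library",
            provenance = "sitematch built-in staggered-chi library")
}

#' Read a rotamer library from a chi-list text file
#'
#' Plain-text format: one rotamer per line, `RES chi1 [chi2 chi3 chi4]`;
#' lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a `rotamer_library`.
#' @export
read_rotamer_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  res <- vapply(parts, `[[`, character(1), 1L)
  lib <- lapply(split(parts, res), function(ps) {
    chis <- lapply(ps, function(p) as.numeric(p[-1L]))
    n <- max(lengths(chis))
    m <- do.call(rbind, lapply(chis, function(x) c(x, rep(NA, n - length(x)))))
    colnames(m) <- paste0("chi", seq_len(max(1, n)))[seq_len(ncol(m))]
    m
  })
  structure(lib, class = "rotamer_library", provenance = path)
}

#' Expand Ser/Thr/Tyr rotamers over hydroxyl-hydrogen torsions
#'
#' Each rotamer of the hydroxyl-bearing residues is replicated with the
#' hydroxyl hydrogen placed at every grid value (`360 / step` positions);
#' heavy atoms are untouched and other residues are unchanged.
#'
#' @param library a `rotamer_library`.
#' @param step grid step in degrees (must divide 360).
#' @return the expanded library; expanded matrices gain an `hchi` column.
#' @export
expand_hydroxyl_rotamers <- function(library, step = 120) {
  if (360 %% step != 0) stop("step must divide 360", call. = FALSE)
  hvals <- seq(-180 + step, 180, by = step)
  for (rn in intersect(c("SER", "THR", "TYR"), names(library))) {
    m <- library[[rn]]
    out <- do.call(rbind, lapply(hvals, function(h)
      cbind(m, hchi = rep(h, nrow(m)))))
    library[[rn]] <- out
  }
  library
}

# full-atom coordinates of one rotamer placed on a site's backbone: side
# chain heavy atoms + side-chain hydrogens, tagged with the site's residue
# identity so same-residue exclusions work
rotamer_coords <- function(resname, bb, chi, site_chain = "A", site_resno = 1,
                           site_icode = "") {
  chi <- chi[!is.na(chi)]
  hchi <- NULL
  if (length(chi) && !is.null(names(chi)) && "hchi" %in% names(chi)) {
    hchi <- chi[["hchi"]]
    chi <- chi[names(chi) != "hchi"]
  }
  heavy <- build_residue_atoms(resname, bb, chi = if (length(chi)) chi else NULL)
  rows <- hydrogen_topology()
  rows <- rows[rows$res == resname, , drop = FALSE]
  coords <- as.matrix(heavy[, c("x", "y", "z")])
  rownames(coords) <- heavy$atom
  hl <- list()
  for (i in seq_len(nrow(rows))) {
    refs <- match(c(rows$r1[i], rows$r2[i], rows$r3[i]), rownames(coords))
    if (anyNA(refs)) next
    tor <- rows$tor[i]
    if (rows$rot[i] == "r" && !is.null(hchi)) tor <- hchi
    p <- internal_to_cartesian(coords[refs[1L], ], coords[refs[2L], ],
                               coords[refs[3L], ], rows$len[i], rows$ang[i],
                               tor)
    hl[[length(hl) + 1L]] <- data.frame(atom = rows$atom[i], x = p[1],
                                        y = p[2], z = p[3],
                                        charge = rows$charge[i],
                                        stringsAsFactors = FALSE)
  }
  all_at <- rbind(heavy, if (length(hl)) do.call(rbind, hl))
  # side chain only: the backbone is part of the fixed environment
  all_at <- all_at[!(all_at$atom %in% c("N", "CA", "C", "O", "HN", "HA")), ,
                   drop = FALSE]
  if (nrow(all_at) == 0L) return(NULL)
  all_at$element <- element_of(all_at$atom)
  all_at$is_hydrogen <- all_at$element == "H"
  all_at$radius <- vdw_radius(all_at$element)
  all_at$chain <- site_chain
  all_at$resno <- site_resno
  all_at$icode <- site_icode
  all_at$resname <- resname
  all_at
}

#' Build singleton and pairwise rotamer energy tables
#'
#' Singleton energies are the interaction of each rotamer with the fixed
#' environment (scaffold backbone, non-design side chains and the fixed TS
#' pose); pairwise energies are rotamer-rotamer interactions between design
#' sites.  All entries are finite (the short-range repulsion is linearized).
#'
#' @param scaffold a `protein_structure` with hydrogens built.
#' @param ts_atoms TS atom table (columns `atom`, `element`, `x`, `y`, `z`,
#'   `charge`, `radius`, `is_hydrogen`) in the scaffold frame, or `NULL`.
#' @param design_sites residue ids to repack (see [design_sites()]).
#' @param library a `rotamer_library`.
#' @param identities optional named vector overriding the amino-acid type
#'   modelled at each site (defaults to the scaffold residue types).
#' @return an `energy_tables` object.
#' @export
build_energy_tables <- function(scaffold, ts_atoms, design_sites, library,
                                identities = NULL) {
  at <- scaffold$atoms
  key <- .residue_key(at$chain, at$resno, at$icode)
  sidechain_names <- function(rn) {
    c(.topo_rows(rn)$atom,
      hydrogen_topology()$atom[hydrogen_topology()$res == rn])
  }
  # fixed environment: everything except the design sites' side chains
  env_drop <- rep(FALSE, nrow(at))
  for (s in design_sites) {
    rn <- residue_name(scaffold, s)
    env_drop <- env_drop | (key == s & at$atom %in% sidechain_names(rn))
  }
  cols <- c("chain", "resno", "icode", "atom", "element", "x", "y", "z",
            "charge", "radius", "is_hydrogen")
  env <- at[!env_drop, cols, drop = FALSE]
  if (!is.null(ts_atoms) && nrow(ts_atoms)) {
    ts_atoms$chain <- "zTS"; ts_atoms$resno <- 9999L; ts_atoms$icode <- ""
    env <- rbind(env, ts_atoms[, cols])
  }
  env_ann <- .annotate_hbond_roles(env)
  rot_sets <- list()
  singleton <- list()
  for (s in design_sites) {
    rn <- identities[[s]] %||% residue_name(scaffold, s)
    m <- library[[rn]]
    if (is.null(m))
      stop("rotamer library has no entries for ", rn, call. = FALSE)
    bb <- backbone_frame(scaffold, s)
    parts <- strsplit(s, ":")[[1L]]
    rots <- list()
    for (r in seq_len(nrow(m))) {
      chi <- m[r, ]
      names(chi) <- colnames(m)
      rc <- tryCatch(rotamer_coords(rn, bb, chi, site_chain = parts[1L],
                                    site_resno = residue_atoms(scaffold, s)$resno[1L],
                                    site_icode = residue_atoms(scaffold, s)$icode[1L]),
                     error = function(e) NULL)
      if (is.null(rc)) next
      rots[[length(rots) + 1L]] <- list(chi = chi, atoms = rc,
                                        ann = .annotate_hbond_roles(rc))
    }
    if (length(rots) == 0L)
      stop("no placeable rotamer at site ", s, call. = FALSE)
    rot_sets[[s]] <- rots
    singleton[[s]] <- vapply(rots, function(rr)
      .pair_energy(rr$ann, env_ann), numeric(1))
  }
  n <- length(design_sites)
  pairwise <- vector("list", n)
  for (i in seq_len(n)) pairwise[[i]] <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    si <- design_sites[i]; sj <- design_sites[j]
    m <- matrix(0, length(rot_sets[[si]]), length(rot_sets[[sj]]))
    for (ri in seq_along(rot_sets[[si]]))
      for (rj in seq_along(rot_sets[[sj]]))
        m[ri, rj] <- .pair_energy(rot_sets[[si]][[ri]]$ann,
                                  rot_sets[[sj]][[rj]]$ann)
    pairwise[[i]][[j]] <- m
  }
  structure(list(sites = design_sites, rotamers = rot_sets,
                 singleton = singleton, pairwise = pairwise),
            class = "energy_tables")
}

#' @export
print.energy_tables <- function(x, ...) {
  cat(sprintf("<energy_tables> %d sites, rotamers: %s\n", length(x$sites),
              paste(vapply(x$singleton, length, numeric(1)), collapse = "/")))
  invisible(x)
}

.pair_e <- function(tables, i, j, ri, rj) {
  if (i < j) tables$pairwise[[i]][[j]][ri, rj]
  else if (i > j) tables$pairwise[[j]][[i]][rj, ri]
  else 0
}

#' Dead-end elimination (Goldstein criterion)
#'
#' Iterates single-rotamer Goldstein elimination to a fixpoint: rotamer `r`
#' at a site is removed when some alternative `r'` satisfies
#' `E(r) - E(r') + sum_j min_s [E(r,s) - E(r',s)] > 0`; every eliminated
#' rotamer is provably absent from the global minimum-energy conformation.
#'
#' @param tables an `energy_tables` object.
#' @return the reduced `energy_tables` (with an `eliminated` attribute
#'   counting removals).
#' @export
dee_reduce <- function(tables) {
  n <- length(tables$sites)
  alive <- lapply(tables$singleton, function(v) seq_along(v))
  changed <- TRUE
  n_elim <- 0L
  while (changed) {
    changed <- FALSE
    for (i in seq_len(n)) {
      ai <- alive[[i]]
      if (length(ai) <= 1L) next
      drop <- logical(length(ai))
      for (ri_idx in seq_along(ai)) {
        ri <- ai[ri_idx]
        for (rj in ai) {
          if (rj == ri) next
          gap <- tables$singleton[[i]][ri] - tables$singleton[[i]][rj]
          for (k in seq_len(n)) {
            if (k == i) next
            diffs <- vapply(alive[[k]], function(s)
              .pair_e(tables, i, k, ri, s) - .pair_e(tables, i, k, rj, s),
              numeric(1))
            gap <- gap + min(diffs)
          }
          if (gap > 1e-9) { drop[ri_idx] <- TRUE; break }
        }
      }
      if (any(drop)) {
        alive[[i]] <- ai[!drop]
        n_elim <- n_elim + sum(drop)
        changed <- TRUE
        if (length(alive[[i]]) == 0L)
          stop("dead-end elimination removed every rotamer at site ",
               tables$sites[i], " (inconsistent model)", call. = FALSE)
      }
    }
  }
  out <- tables
  for (i in seq_len(n)) {
    keep <- alive[[i]]
    out$rotamers[[i]] <- tables$rotamers[[i]][keep]
    out$singleton[[i]] <- tables$singleton[[i]][keep]
    for (j in seq_len(n)) {
      if (j <= i) next
      out$pairwise[[i]][[j]] <-
        tables$pairwise[[i]][[j]][keep, alive[[j]], drop = FALSE]
    }
    for (j in seq_len(i - 1L)) {
      out$pairwise[[j]][[i]] <-
        tables$pairwise[[j]][[i]][alive[[j]], keep, drop = FALSE]
    }
  }
  attr(out, "eliminated") <- n_elim
  out
}

#' Exact global minimum-energy rotamer assignment
#'
#' Branch-and-bound depth-first search with an admissible lower bound
#' (current cost + per-site minima of singleton and pair terms); exact, and
#' equivalent to exhaustive enumeration.  Sites are expanded in order of
#' increasing rotamer count.
#'
#' @param tables an `energy_tables` object (typically after [dee_reduce()]).
#' @return list with `assignment` (named rotamer indices), `chi` (per-site
#'   chi vectors), `total_energy`.
#' @export
solve_gmec <- function(tables) {
  n <- length(tables$sites)
  if (n == 0L) stop("empty energy tables", call. = FALSE)
  ord <- order(vapply(tables$singleton, length, numeric(1)))
  best <- list(energy = Inf, pick = NULL)
  pick <- integer(n)
  # minimum entry of every pairwise block (for the admissible bound below)
  pair_min <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    m <- tables$pairwise[[i]][[j]]
    pair_min[i, j] <- pair_min[j, i] <- if (length(m)) min(m) else 0
  }
  # admissible bound: per future site, the minimum of singleton plus pairs
  # to the already assigned sites; plus the minimum possible entry of every
  # pair among the still-unassigned sites (those terms can be negative and
  # must not be dropped)
  lower_tail <- function(k, pick) {
    lb <- 0
    for (pos in k:n) {
      i <- ord[pos]
      cand <- tables$singleton[[i]]
      add <- vapply(seq_along(cand), function(ri) {
        v <- cand[ri]
        for (ppos in seq_len(k - 1L)) {
          j <- ord[ppos]
          v <- v + .pair_e(tables, i, j, ri, pick[j])
        }
        v
      }, numeric(1))
      lb <- lb + min(add)
    }
    if (k < n) {
      for (pa in k:(n - 1L)) for (pb in (pa + 1L):n)
        lb <- lb + pair_min[ord[pa], ord[pb]]
    }
    lb
  }
  recurse <- function(k, cost) {
    if (k > n) {
      if (cost < best$energy) best <<- list(energy = cost, pick = pick)
      return()
    }
    i <- ord[k]
    cand <- seq_along(tables$singleton[[i]])
    costs <- vapply(cand, function(ri) {
      v <- tables$singleton[[i]][ri]
      for (ppos in seq_len(k - 1L)) {
        j <- ord[ppos]
        v <- v + .pair_e(tables, i, j, ri, pick[j])
      }
      v
    }, numeric(1))
    for (ri in cand[order(costs)]) {
      new_cost <- cost + costs[match(ri, cand)]
      pick[i] <<- ri
      # prune only on the admissible lower bound: remaining contributions
      # can be negative, so the partial cost alone proves nothing
      if (k < n && new_cost + lower_tail(k + 1L, pick) >= best$energy) next
      recurse(k + 1L, new_cost)
    }
  }
  recurse(1L, 0)
  assignment <- stats::setNames(best$pick, tables$sites)
  chi <- lapply(seq_len(n), function(i)
    tables$rotamers[[i]][[best$pick[i]]]$chi)
  names(chi) <- tables$sites
  list(assignment = assignment, chi = chi, total_energy = best$energy)
}

#' Repack design-site side chains around a fixed TS pose
#'
#' Convenience pipeline: energy tables, dead-end elimination, exact GMEC
#' search, then assembly of the repacked structure, hydrogen-bond detection
#' and binding energy.
#'
#' @inheritParams build_energy_tables
#' @param hbond_max_da,hbond_min_angle hydrogen-bond criterion.
#' @return a `repack_result`: `assignment`, `chi`, `total_energy`,
#'   `structure` (repacked), `hydrogen_bonds`, `binding_energy`.
#' @export
repack_sites <- function(scaffold, ts_atoms, design_sites,
                         library = expand_hydroxyl_rotamers(default_rotamer_library()),
                         identities = NULL, hbond_max_da = 3.3,
                         hbond_min_angle = 120) {
  tables <- build_energy_tables(scaffold, ts_atoms, design_sites, library,
                                identities)
  reduced <- dee_reduce(tables)
  sol <- solve_gmec(reduced)
  # assemble: replace design-site side chains with the selected rotamers
  at <- scaffold$atoms
  key <- .residue_key(at$chain, at$resno, at$icode)
  out_at <- at
  for (i in seq_along(design_sites)) {
    s <- design_sites[i]
    rot <- reduced$rotamers[[i]][[sol$assignment[[s]]]]
    rn <- rot$atoms$resname[1L]
    drop <- key == s & !(at$atom %in% c("N", "CA", "C", "O", "HN", "HA"))
    keep_rows <- out_at[!( .residue_key(out_at$chain, out_at$resno, out_at$icode) == s &
                             !(out_at$atom %in% c("N", "CA", "C", "O", "HN", "HA"))), ,
                        drop = FALSE]
    newsc <- rot$atoms
    add <- data.frame(chain = newsc$chain, resno = newsc$resno,
                      icode = newsc$icode, resname = rn, atom = newsc$atom,
                      element = newsc$element, x = newsc$x, y = newsc$y,
                      z = newsc$z, occ = 1, het = FALSE,
                      is_hydrogen = newsc$is_hydrogen, charge = newsc$charge,
                      radius = newsc$radius, stringsAsFactors = FALSE)
    out_at <- rbind(keep_rows, add)
  }
  ids <- residue_ids(scaffold)
  k2 <- .residue_key(out_at$chain, out_at$resno, out_at$icode)
  out_at <- out_at[order(match(k2, ids)), , drop = FALSE]
  rownames(out_at) <- NULL
  repacked <- scaffold
  repacked$atoms <- out_at
  region <- out_at
  if (!is.null(ts_atoms) && nrow(ts_atoms)) {
    ts2 <- ts_atoms
    ts2$chain <- "zTS"; ts2$resno <- 9999L; ts2$icode <- ""
    ts2$resname <- "TS"; ts2$occ <- 1; ts2$het <- TRUE
    region <- rbind(out_at, ts2[, colnames(out_at)])
  }
  hb <- detect_hydrogen_bonds(region, max_da = hbond_max_da,
                              min_angle = hbond_min_angle)
  be <- if (!is.null(ts_atoms) && nrow(ts_atoms))
    binding_energy(repacked, ts_atoms) else NA_real_
  structure(list(assignment = sol$assignment, chi = sol$chi,
                 total_energy = sol$total_energy, structure = repacked,
                 hydrogen_bonds = hb, binding_energy = be,
                 tables = reduced),
            class = "repack_result")
}

#' @export
print.repack_result <- function(x, ...) {
  cat(sprintf("<repack_result> %d sites, total energy %.2f PEU, %d hydrogen bonds, binding %.2f PEU\n",
              length(x$assignment), x$total_energy, nrow(x$hydrogen_bonds),
              x$binding_energy))
  invisible(x)
}

#' Binding energy between a protein conformation and a TS pose
#'
#' The energy difference between the bound and the rigidly separated
#' enzyme-TS system at the repacked conformation, with no re-minimization.
#' Because the conformations are held fixed, the internal energies of both
#' parts cancel and the difference equals the protein-TS interaction energy
#' under the same model (computed with the model's cutoff).
#'
#' @param scaffold a `protein_structure` (repacked).
#' @param ts_atoms TS atom table in the scaffold frame.
#' @return binding energy in PEU (negative = favourable).
#' @export
binding_energy <- function(scaffold, ts_atoms) {
  ts2 <- ts_atoms
  ts2$chain <- "zTS"; ts2$resno <- 9999L; ts2$icode <- ""
  cols <- c("chain", "resno", "icode", "atom", "element", "x", "y", "z",
            "charge", "radius", "is_hydrogen")
  energy_between(scaffold$atoms[, cols], ts2[, cols])
}
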