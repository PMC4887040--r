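# Synthetic planted fixtures: compact toy scaffolds with an active site that
# satisfies every motif constraint exactly, plus decoy residues, so the full
# matching/repacking pipeline is testable without downloads.
#
# Construction is forward-kinematic: the motif's own loop parameterization is
# evaluated at chosen torsions (side-chain chis drawn from the rotamer
# library, orientation spins drawn uniformly), and the scaffold is then built
# AROUND the resulting solution, so the planted match is exactly closed and
# all bounded parameters sit at their optima (deviation zero).

.unit <- function(v) v / sqrt(sum(v^2))

.rand_unit <- function() {
  repeat {
    v <- stats::runif(3, -1, 1)
    n <- sqrt(sum(v^2))
    if (n > 1e-3 && n <= 1) return(v / n)
  }
}

# any vector perpendicular to u, spun by a random angle
.rand_perp <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- .unit(.cross3(u, a))
  p2 <- .cross3(u, p1)
  th <- stats::runif(1, -pi, pi)
  .unit(cos(th) * p1 + sin(th) * p2)
}

#' The toy catalytic-triad motif shipped with the package
#' @return a `catalytic_motif`.
#' @export
toy_triad_motif <- function() {
  parse_motif(system.file("extdata", "motifs", "toy_triad.yaml",
                          package = "sitematch", mustWork = TRUE))
}

# choose planted DOF values for a builder chain; chis come from the rotamer
# library so repacking can reproduce the planted side chains exactly
.plant_dof_values <- function(loop, lib, roles_aa) {
  chis <- lapply(roles_aa, function(aa) {
    m <- lib[[aa]]
    chi_cols <- grep("^chi", colnames(m))
    if (length(chi_cols) == 0L) return(numeric(0))
    as.numeric(m[sample.int(nrow(m), 1L), chi_cols])
  })
  vals <- numeric(nrow(loop$dof))
  for (k in seq_len(nrow(loop$dof))) {
    d <- loop$dof[k, ]
    lab <- d$label
    role <- sub("\\..*$", "", lab)
    if (d$kind == "bounded" || d$par == 2L) {
      vals[k] <- d$init
    } else if (grepl("\\.c[0-9]\\.torsion$", lab)) {
      j <- as.integer(sub("^.*\\.c([0-9])\\.torsion$", "\\1", lab))
      vals[k] <- chis[[role]][j]
    } else if (grepl("\\.rchi[0-9]", lab)) {
      j <- as.integer(sub("^.*\\.rchi([0-9]).*$", "\\1", lab))
      vals[k] <- wrap_angle(chis[[role]][j] + d$init - 180)
    } else {
      vals[k] <- stats::runif(1, -180, 180)
    }
  }
  list(values = vals, chis = chis)
}

# build the full-atom data frame of one residue from its backbone frame,
# optional placed side-chain coordinates and the position of the next
# residue's N (to orient the carbonyl O)
.residue_df <- function(resname, bb, resno, placed = NULL, next_n = NULL,
                        chain = "A") {
  base <- build_residue_atoms(resname, bb)
  if (!is.null(placed)) {
    for (nm in names(placed)) {
      i <- match(nm, base$atom)
      if (!is.na(i)) base[i, c("x", "y", "z")] <- as.list(placed[[nm]])
    }
  }
  if (!is.null(next_n)) {
    o <- internal_to_cartesian(next_n, bb["CA", ], bb["C", ], 1.231, 121.0, 180)
    base[base$atom == "O", c("x", "y", "z")] <- as.list(o)
  }
  data.frame(chain = chain, resno = resno, icode = "", resname = resname,
             atom = base$atom, element = element_of(base$atom),
             x = base$x, y = base$y, z = base$z, occ = 1, het = FALSE,
             is_hydrogen = FALSE, charge = base$charge,
             radius = vdw_radius(element_of(base$atom)),
             stringsAsFactors = FALSE)
}

# extend a residue backbone into a 3-residue segment (prev, site, next) with
# idealized helix-like dihedrals; returns the atom table
.segment_atoms <- function(bb, resname, base_resno, placed = NULL,
                           phi = -60, psi = -45, c_prev = NULL,
                           with_next = TRUE) {
  n <- bb["N", ]; ca <- bb["CA", ]; cc <- bb["C", ]
  if (is.null(c_prev))
    c_prev <- internal_to_cartesian(cc, ca, n, 1.329, 121.7, phi)
  ca_p <- internal_to_cartesian(ca, n, c_prev, 1.525, 117.2, 180)
  n_p <- internal_to_cartesian(n, c_prev, ca_p, 1.458, 111.0, psi)
  bb_p <- rbind(N = n_p, CA = ca_p, C = c_prev)
  if (!with_next)
    return(rbind(.residue_df("ALA", bb_p, base_resno - 1L, next_n = n),
                 .residue_df(resname, bb, base_resno, placed = placed)))
  n_n <- internal_to_cartesian(n, ca, cc, 1.329, 117.2, psi)
  ca_n <- internal_to_cartesian(ca, cc, n_n, 1.458, 121.7, 180)
  c_n <- internal_to_cartesian(cc, n_n, ca_n, 1.525, 111.0, phi)
  bb_n <- rbind(N = n_n, CA = ca_n, C = c_n)
  rbind(.residue_df("ALA", bb_p, base_resno - 1L, next_n = n),
        .residue_df(resname, bb, base_resno, placed = placed, next_n = n_n),
        .residue_df("ALA", bb_n, base_resno + 1L))
}

# backbone-donor segment aimed so that the amide H of the site residue
# points at acceptor `a_xyz` with the donor-acceptor distance `d`
.donor_segment <- function(a_xyz, d, base_resno, existing_xyz,
                           max_tries = 200, avoid = NULL) {
  # the candidate segment shape is the same for every aim direction and
  # spin; build it once in a canonical frame (acceptor at origin, approach
  # along +x, CA tilt toward +y) and rigidly transform per trial
  u0 <- c(1, 0, 0); p0 <- c(0, 1, 0)
  n0 <- d * u0
  hn0 <- n0 - 0.997 * u0
  ca0 <- n0 + 1.458 * (cos(119 * pi / 180) * -u0 +
                         sin(119 * pi / 180) * p0)
  c_prev0 <- internal_to_cartesian(hn0, ca0, n0, 1.329, 121.7, 180)
  cc0 <- internal_to_cartesian(c_prev0, n0, ca0, 1.525, 111.0, -60)
  bb0 <- rbind(N = n0, CA = ca0, C = cc0)
  core0 <- .segment_atoms(bb0, "ALA", base_resno, c_prev = c_prev0,
                          with_next = FALSE)
  full0 <- .segment_atoms(bb0, "ALA", base_resno, c_prev = c_prev0)
  m_core <- as.matrix(core0[, c("x", "y", "z")])
  m_full <- as.matrix(full0[, c("x", "y", "z")])
  place <- function(seg, m, R) {
    seg[, c("x", "y", "z")] <- sweep(m %*% t(R), 2, a_xyz, "+")
    seg
  }
  for (try in seq_len(max_tries)) {
    if (is.null(avoid)) {
      u <- .rand_unit()                    # acceptor -> N direction
    } else {
      # approach at exactly the optimal donor angle (120 deg from the
      # acceptor's bond to its neighbour), with a free azimuth: planted
      # truths sit at the constraint optima
      av <- .unit(avoid - a_xyz)
      pp <- .rand_perp(av)
      u <- .unit(cos(120 * pi / 180) * av + sin(120 * pi / 180) * pp)
    }
    for (spin in seq_len(8L)) {
      p <- .rand_perp(u)
      R <- cbind(u, p, .cross3(u, p))
      hc <- sweep(m_core %*% t(R), 2, a_xyz, "+")
      if (nrow(existing_xyz) &&
          min(row_min_dist_cpp(hc, existing_xyz)) <= 2.85)
        next
      hf <- sweep(m_full %*% t(R), 2, a_xyz, "+")
      if (nrow(existing_xyz) == 0L ||
          min(row_min_dist_cpp(hf, existing_xyz)) > 2.85)
        return(place(full0, m_full, R))
      return(place(core0, m_core, R))
    }
  }
  NULL
}

# free-floating decoy segment with its central CA near `center` at radius
# range `rr`
.decoy_segment <- function(center, rr, base_resno, existing_xyz,
                           max_tries = 80, clash = 2.9) {
  tpl <- residue_template("ALA")
  bb0 <- template_xyz(tpl, c("N", "CA", "C"))
  rownames(bb0) <- c("N", "CA", "C")
  # canonical segment built once; trials are rigid copies
  seg0 <- .segment_atoms(bb0, "ALA", base_resno)
  m0 <- as.matrix(seg0[, c("x", "y", "z")])
  ca0 <- as.numeric(bb0["CA", ])
  for (try in seq_len(max_tries)) {
    u <- .rand_unit()
    pos <- center + stats::runif(1, rr[1], rr[2]) * u
    # random rotation from three uniform angles
    th <- stats::runif(3, -pi, pi)
    cz <- cos(th[1]); sz <- sin(th[1]); cy <- cos(th[2]); sy <- sin(th[2])
    cx <- cos(th[3]); sx <- sin(th[3])
    R <- matrix(c(cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
                  sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
                  -sy, cy * sx, cy * cx), 3, 3, byrow = TRUE)
    shift <- pos - as.numeric(ca0 %*% t(R))
    m <- sweep(m0 %*% t(R), 2, shift, "+")
    if (nrow(existing_xyz) == 0L ||
        min(row_min_dist_cpp(m, existing_xyz)) > clash) {
      seg <- seg0
      seg[, c("x", "y", "z")] <- m
      return(seg)
    }
  }
  NULL
}

#' Generate a planted synthetic fixture
#'
#' Builds a compact poly-alanine scaffold whose active site satisfies every
#' constraint of `motif` exactly: the motif's own kinematic parameterization
#' is evaluated at planted torsions (side-chain chis from the rotamer
#' library, bounded parameters at their optima), the anchor residues are
#' materialized around the solution, backbone-donor roles are aimed at their
#' acceptors, and decoy residues are added within the candidate shell.
#' Fully deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param motif a `catalytic_motif` (default: [toy_triad_motif()]).
#' @param n_residues approximate total residue count (filled up with distant
#'   filler segments).
#' @param decoy_sites number of decoy candidate residues in the active-site
#'   shell.
#' @param library rotamer library supplying planted chi values.
#' @return a `planted_fixture`: `scaffold` (with hydrogens), `motif`,
#'   `truth` (assignment, ts_pose, coords, chis, planted main-loop DOFs,
#'   hydrogen bonds), `sites` (candidate ids), `seed`.
#' @export
generate_fixture <- function(seed, motif = toy_triad_motif(),
                             n_residues = 30, decoy_sites = 4,
                             library = default_rotamer_library()) {
  roles <- motif$residues$role
  if (n_residues < length(roles) + decoy_sites)
    stop("n_residues must be at least motif size + decoys", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  mains <- main_loop_roles(motif)
  aa <- stats::setNames(motif$residues$aa, roles)
  side_roles <- setdiff(roles[motif$residues$via == "side_chain"], mains)
  bb_roles <- roles[motif$residues$via == "backbone"]

  # stub scaffold: site1 at the template frame, site2 anywhere (only the
  # site1 anchor feeds the chain; site2 enters through the targets)
  tpl1 <- residue_template(aa[[mains[1L]]])
  bb1 <- template_xyz(tpl1, c("N", "CA", "C"))
  rownames(bb1) <- c("N", "CA", "C")
  stub_at <- rbind(
    .residue_df(aa[[mains[1L]]], bb1, 11L),
    .residue_df(aa[[mains[2L]]], sweep(bb1, 2, c(8, 0, 0), "+"), 21L))
  stub <- structure(list(atoms = stub_at,
                         het = stub_at[0, ], source_id = "stub",
                         resolution = NA_real_),
                    class = "protein_structure")
  main <- build_main_loop(motif, mains[1L], mains[2L], "A:11", "A:21", stub)

  ts_names <- paste0("TS:", motif$ts$atoms$name)
  dcs <- motif$constraints[motif$constraints$kind == "distance", , drop = FALSE]
  cpair_ex <- c(paste(dcs$a1, dcs$a2, sep = "~"),
                paste(dcs$a2, dcs$a1, sep = "~"))
  # placement failures inside one attempt trigger a full re-draw
  retry <- function(msg)
    stop(structure(class = c("fixture_retry", "error", "condition"),
                   list(message = msg, call = NULL)))
  last_msg <- "no attempt"
  for (attempt in seq_len(20L)) {
    fx <- tryCatch(.fixture_attempt(motif, main, roles, mains, side_roles,
                                    bb_roles, aa, library, ts_names,
                                    cpair_ex, n_residues, decoy_sites,
                                    seed, retry),
                   fixture_retry = function(e) {
                     last_msg <<- conditionMessage(e)
                     NULL
                   })
    if (!is.null(fx)) return(fx)
  }
  stop("infeasible constraint set: ", last_msg, call. = FALSE)
}

# one construction attempt; `retry` signals a placement failure
.fixture_attempt <- function(motif, main, roles, mains, side_roles, bb_roles,
                             aa, library, ts_names, cpair_ex, n_residues,
                             decoy_sites, seed, retry) {
  # draw planted main-loop torsions until the placed atoms are clash-free
  placed <- NULL
  for (try in seq_len(40)) {
    pv <- .plant_dof_values(main, library,
                            stats::setNames(main$aas, main$roles))
    coords <- .loop_eval(main, pv$values)
    rownames(coords) <- main$labels
    labs <- rownames(coords)
    grp <- ifelse(startsWith(labs, "TS:"), "TS", sub(":.*$", "", labs))
    d2 <- as.matrix(stats::dist(coords))
    mask <- outer(grp, grp, `!=`)                 # inter-group pairs only
    pairlab <- outer(labs, labs, paste, sep = "~")
    mask[pairlab %in% cpair_ex] <- FALSE          # constrained contacts OK
    ok <- !any(mask & d2 < 2.9)
    if (ok) { placed <- list(coords = coords, pv = pv); break }
  }
  if (is.null(placed))
    retry("no clash-free planted main loop found")
  coords <- placed$coords
  chis <- placed$pv$chis

  cmap <- lapply(seq_len(nrow(coords)), function(i) coords[i, ])
  names(cmap) <- rownames(coords)
  ts_pose <- do.call(rbind, cmap[ts_names])
  rownames(ts_pose) <- motif$ts$atoms$name
  ts_centroid <- colMeans(ts_pose)

  get_bb <- function(role) {
    m <- rbind(N = cmap[[paste0(role, ":N")]],
               CA = cmap[[paste0(role, ":CA")]],
               C = cmap[[paste0(role, ":C")]])
    m
  }
  role_sidechain <- function(role) {
    nm <- grep(paste0("^", role, ":"), names(cmap), value = TRUE)
    nm <- nm[!(nm %in% paste0(role, ":", c("N", "CA", "C")))]
    out <- cmap[nm]
    names(out) <- sub("^.*:", "", names(out))
    out
  }

  # side-chain stabilizer roles (e.g. the triad Asp): reverse-built from the
  # hydrogen-bond direction of their (already placed) partner
  for (role in side_roles) {
    links <- .role_dist_constraints(motif, role)
    link <- NULL
    for (l in links) if (l$other %in% names(cmap)) { link <- l; break }
    if (is.null(link))
      stop("cannot plant ", role, ": no link to placed atoms", call. = FALSE)
    pxyz <- cmap[[link$other]]
    prole <- .parse_atom_ref(link$other)$role
    patom <- .parse_atom_ref(link$other)$atom
    d_opt <- motif$constraints$optimal[link$i]
    # direction: along the partner's donor hydrogen when it has one
    # (His ND1-H), otherwise a sampled direction
    dirv <- NULL
    if (prole == "HIS2" && patom == "ND1") {
      hd1 <- internal_to_cartesian(cmap[["HIS2:CE1"]], cmap[["HIS2:CG"]],
                                   cmap[["HIS2:ND1"]], 1.0, 126.0, 180.0)
      dirv <- .unit(hd1 - pxyz)
    }
    done <- FALSE
    for (try in seq_len(80)) {
      u <- if (is.null(dirv)) .rand_unit()
           else if (try == 1L) dirv
           else {
             # jitter within a narrow cone around the aimed direction
             p <- .rand_perp(dirv)
             th <- stats::runif(1, 0, 10) * pi / 180
             .unit(cos(th) * dirv + sin(th) * p)
           }
      fxyz <- pxyz + d_opt * u
      env <- .new_builder()
      # reference atoms for the approach frame: the partner's neighbours
      pre_lab <- paste0(prole, ":", if (prole == "TS") motif$ts$atoms$name[1L]
                        else .bond_parent(aa[[prole]], patom))
      if (is.null(cmap[[pre_lab]])) pre_lab <- names(cmap)[1L]
      .b_add_fixed(env, "GEN:pre", cmap[[pre_lab]])
      .b_add_fixed(env, link$other, pxyz)
      .b_add_fixed(env, paste0(role, ":", link$self_atom), fxyz)
      term <- .b_reverse_sidechain(env, motif, role, aa[[role]],
                                   link$self_atom, link$other, "GEN:pre")
      gen <- .b_finish(env, "gen",
                       data.frame(row = 1, x = 0, y = 0, z = 0, w = 1,
                                  label = "none"),
                       meta = list(roles = role, aas = aa[[role]],
                                   start_ca = c(0, 0, 0)))
      pv2 <- .plant_dof_values(gen, library, stats::setNames(aa[[role]], role))
      cc <- .loop_eval(gen, pv2$values)
      rownames(cc) <- gen$labels
      new_idx <- which(startsWith(rownames(cc), paste0(role, ":")))
      newxyz <- cc[new_idx, , drop = FALSE]
      other_lab <- setdiff(names(cmap), c(rownames(cc), link$other))
      other_xyz <- do.call(rbind, cmap[other_lab])
      mind <- min(row_min_dist_cpp(newxyz, other_xyz))
      # every constraint touching this role that is evaluable now must hold
      trial <- cmap
      for (i in new_idx) trial[[rownames(cc)[i]]] <- cc[i, ]
      cons_ok <- TRUE
      csm <- motif$constraints
      for (i in seq_len(nrow(csm))) {
        at <- c(csm$a1[i], csm$a2[i], csm$a3[i], csm$a4[i])
        at <- at[!is.na(at)]
        if (!any(grepl(paste0("^", role, ":"), at))) next
        if (!all(at %in% names(trial))) next
        dv <- constraint_deviation(csm[i, , drop = FALSE], trial)
        if (dv$deviation > 0) { cons_ok <- FALSE; break }
      }
      if (cons_ok && (mind > 2.85 || !is.finite(mind))) {
        for (i in new_idx) cmap[[rownames(cc)[i]]] <- cc[i, ]
        chis[[role]] <- pv2$chis[[role]]
        done <- TRUE
        break
      }
      # keep the aimed direction (it is constraint-determined); retries
      # redraw the chi/spin values only
    }
    if (!done) retry(paste("cannot place side role", role))
  }

  # assemble segments around the placed active site
  seg_list <- list()
  existing <- function() {
    if (length(seg_list) == 0L)
      do.call(rbind, cmap)
    else rbind(do.call(rbind, cmap),
               as.matrix(do.call(rbind, seg_list)[, c("x", "y", "z")]))
  }
  res_counter <- 0L
  site_ids <- character(0)
  # placed atoms excluding one role (for flank clash checks)
  existing_excl <- function(role) {
    keep <- !startsWith(names(cmap), paste0(role, ":"))
    base_xyz <- do.call(rbind, cmap[keep])
    if (length(seg_list) == 0L) base_xyz
    else rbind(base_xyz,
               as.matrix(do.call(rbind, seg_list)[, c("x", "y", "z")]))
  }
  for (role in c(mains, side_roles)) {
    res_counter <- res_counter + 1L
    base <- res_counter * 10L + 1L
    sc_atoms <- role_sidechain(role)
    sc_far <- do.call(rbind, sc_atoms[!(names(sc_atoms) %in% c("CB", "O"))])
    other <- existing_excl(role)
    seg <- NULL
    for (tryk in seq_len(40L)) {
      phi <- if (tryk == 1L) -60 else stats::runif(1, -150, -45)
      psi <- if (tryk == 1L) -45 else stats::runif(1, -60, 150)
      cand <- .segment_atoms(get_bb(role), aa[[role]], base,
                             placed = sc_atoms, phi = phi, psi = psi,
                             with_next = tryk <= 30L)
      flank <- cand[cand$resno != base, , drop = FALSE]
      fh <- as.matrix(flank[, c("x", "y", "z")])
      ok1 <- is.null(sc_far) ||
        min(row_min_dist_cpp(fh, sc_far)) > 2.9
      # only the flank residues are new; the site residue was validated
      # during planting (and carries intentional constraint contacts)
      ok2 <- nrow(other) == 0L || nrow(fh) == 0L ||
        min(row_min_dist_cpp(fh, other)) > 2.85
      if (ok1 && ok2) { seg <- cand; break }
    }
    if (is.null(seg)) retry(paste("cannot place flanks for", role))
    seg_list[[length(seg_list) + 1L]] <- seg
    site_ids[role] <- paste0("A:", base)
  }
  # backbone-donor roles aimed at their acceptor atoms
  for (role in bb_roles) {
    links <- .role_dist_constraints(motif, role)
    link <- NULL
    for (l in links) if (l$other %in% names(cmap)) { link <- l; break }
    if (is.null(link))
      stop("backbone role ", role, " has no distance constraint", call. = FALSE)
    res_counter <- res_counter + 1L
    base <- res_counter * 10L + 1L
    oref <- .parse_atom_ref(link$other)
    avoid <- if (oref$role == "TS") {
      zrow <- motif$ts$zmatrix[[match(oref$atom, motif$ts$atoms$name)]]
      nb <- if (length(zrow$ref)) utils::tail(unlist(zrow$ref), 1L) else NULL
      if (!is.null(nb)) cmap[[paste0("TS:", nb)]] else NULL
    } else {
      nb <- .bond_parent(aa[[oref$role]], oref$atom)
      cmap[[paste0(oref$role, ":", nb)]]
    }
    seg <- .donor_segment(cmap[[link$other]],
                          motif$constraints$optimal[link$i], base,
                          existing(), avoid = avoid)
    if (is.null(seg)) retry(paste("cannot place donor role", role))
    seg_list[[length(seg_list) + 1L]] <- seg
    site_ids[role] <- paste0("A:", base)
  }
  # decoys in the active-site shell, fillers farther out
  decoy_ids <- character(0)
  for (k in seq_len(decoy_sites)) {
    res_counter <- res_counter + 1L
    base <- res_counter * 10L + 1L
    seg <- .decoy_segment(ts_centroid, c(7.5, 11), base, existing())
    if (is.null(seg)) next
    seg_list[[length(seg_list) + 1L]] <- seg
    decoy_ids <- c(decoy_ids, paste0("A:", base))
  }
  while (3L * (res_counter) < n_residues - 2L) {
    res_counter <- res_counter + 1L
    base <- res_counter * 10L + 1L
    seg <- .decoy_segment(ts_centroid, c(11, 15), base, existing(),
                          max_tries = 40)
    if (is.null(seg)) break
    seg_list[[length(seg_list) + 1L]] <- seg
  }

  atoms <- do.call(rbind, seg_list)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  scaffold <- structure(list(atoms = atoms, het = atoms[0, ],
                             source_id = sprintf("fixture_seed%d",
                                                 as.integer(seed)),
                             resolution = NA_real_),
                        class = "protein_structure")
  scaffold <- suppressWarnings(build_hydrogens(scaffold))

  # aim the nucleophile's hydroxyl hydrogen at its acceptor, snapped to the
  # hydroxyl-expansion grid
  hchi <- NULL
  if (aa[[mains[1L]]] %in% c("SER", "THR", "TYR")) {
    s1 <- site_ids[[mains[1L]]]
    acc <- cmap[[paste0(mains[2L], ":NE2")]]
    if (!is.null(acc)) {
      f_nm <- switch(aa[[mains[1L]]], SER = "OG", THR = "OG1", TYR = "OH")
      ref <- switch(aa[[mains[1L]]], SER = c("CA", "CB"), THR = c("CA", "CB"),
                    TYR = c("CE1", "CZ"))
      rx <- residue_xyz(scaffold, s1, c(ref, f_nm))
      ideal <- measure("dihedral", rx[1, ], rx[2, ], rx[3, ], acc)
      grid <- c(-60, 60, 180)
      hchi <- grid[which.min(abs(wrap_angle(grid - ideal)))]
      hrow <- hydrogen_topology()
      hrow <- hrow[hrow$res == aa[[mains[1L]]] & hrow$rot == "r", ][1L, ]
      hxyz <- internal_to_cartesian(rx[1, ], rx[2, ], rx[3, ], hrow$len,
                                    hrow$ang, hchi)
      sel <- with(scaffold$atoms,
                  .residue_key(chain, resno, icode) == s1 & atom == hrow$atom)
      scaffold$atoms[sel, c("x", "y", "z")] <- as.list(hxyz)
    }
  }

  # final truth coordinate map: scaffold atoms for every role + the TS
  truth_coords <- list()
  for (role in roles) {
    a <- residue_atoms(scaffold, site_ids[[role]])
    for (i in seq_len(nrow(a)))
      truth_coords[[paste0(role, ":", a$atom[i])]] <-
        as.numeric(a[i, c("x", "y", "z")])
  }
  for (nm in ts_names) truth_coords[[nm]] <- cmap[[nm]]
  chk <- check_match_constraints(motif, truth_coords)
  if (!chk$all_satisfied)
    stop("internal error: planted fixture violates its own constraints",
         call. = FALSE)

  # planted hydrogen bonds in the active site (motif residues + TS)
  cols <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z", "occ", "het", "is_hydrogen", "charge", "radius")
  tsdf <- ts_atom_table(motif$ts, ts_pose)
  tsdf$chain <- "zTS"; tsdf$resno <- 9999L; tsdf$icode <- ""
  tsdf$resname <- "TS"; tsdf$occ <- 1; tsdf$het <- TRUE
  region <- rbind(scaffold$atoms[, cols], tsdf[, cols])
  hb <- detect_hydrogen_bonds(region)
  active <- c(unname(site_ids), "zTS:9999")
  hb <- hb[hb$donor_res %in% active & hb$acceptor_res %in% active, ,
           drop = FALSE]

  structure(list(
    scaffold = scaffold, motif = motif,
    truth = list(assignment = stats::setNames(unname(site_ids), roles),
                 ts_pose = ts_pose, coords = truth_coords, chis = chis,
                 hchi = hchi, main_dof = stats::setNames(placed$pv$values,
                                                         main$dof$label),
                 constraint_check = chk, hydrogen_bonds = hb, valid = TRUE),
    sites = c(unname(site_ids), decoy_ids),
    decoys = decoy_ids, seed = as.integer(seed)),
    class = "planted_fixture")
}

#' @export
print.planted_fixture <- function(x, ...) {
  cat(sprintf("<planted_fixture> seed %d: %d residues, %d candidate sites (%d decoys), motif %s\n",
              x$seed, length(residue_ids(x$scaffold)), length(x$sites),
              length(x$decoys), x$motif$name))
  invisible(x)
}

#' Perturb a fixture's planted torsions
#'
#' Adds uniform noise to the free torsions of the planted main-loop solution
#' and re-evaluates the chain.  The perturbed truth is kept when the motif
#' constraints still hold and the loop still closes; otherwise it is flagged
#' invalid.  The perturbed torsion vector is the standard starting point for
#' closure-recovery tests.
#'
#' @param fixture a `planted_fixture`.
#' @param torsion_noise noise half-width in degrees (>= 0).
#' @param seed integer seed.
#' @return the fixture with `$perturbed` (`main_dof`, `closure_deviation`,
#'   `valid`).
#' @export
perturb_fixture <- function(fixture, torsion_noise, seed = 1) {
  stopifnot(torsion_noise >= 0)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  motif <- fixture$motif
  mains <- main_loop_roles(motif)
  loop <- build_main_loop(motif, mains[1L], mains[2L],
                          fixture$truth$assignment[[mains[1L]]],
                          fixture$truth$assignment[[mains[2L]]],
                          fixture$scaffold)
  vals <- fixture$truth$main_dof
  free <- loop$dof$kind == "free" & loop$dof$par == 3L
  vals[free] <- vals[free] + stats::runif(sum(free), -torsion_noise,
                                          torsion_noise)
  vals <- pmin(pmax(vals, loop$dof$lo), loop$dof$hi)
  coords <- .loop_eval(loop, vals)
  rownames(coords) <- loop$labels
  trial <- fixture$truth$coords
  for (i in seq_len(nrow(coords)))
    if (grepl(":", rownames(coords)[i]))
      trial[[rownames(coords)[i]]] <- coords[i, ]
  dev <- sqrt(sum((coords[loop$targets$row[1L], ] -
                     as.numeric(loop$targets[1L, c("x", "y", "z")]))^2))
  chk <- tryCatch(check_match_constraints(motif, trial),
                  error = function(e) list(all_satisfied = FALSE))
  fixture$perturbed <- list(main_dof = vals, closure_deviation = dev,
                            valid = chk$all_satisfied && dev <= 0.1)
  if (torsion_noise == 0) fixture$perturbed$valid <- TRUE
  fixture
}

#' Write a fixture to disk (PDB scaffold + truth JSON)
#'
#' @param fixture a `planted_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(fixture$scaffold, file.path(dir, "scaffold.pdb"))
  truth <- list(assignment = as.list(fixture$truth$assignment),
                sites = fixture$sites,
                ts_pose = cbind(atom = rownames(fixture$truth$ts_pose),
                                as.data.frame(fixture$truth$ts_pose)),
                seed = fixture$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
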