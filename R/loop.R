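# Kinematic loops: chains of fixed bond lengths/angles and free or bounded
# torsions spanning scaffold backbone anchors, side chains, constraint
# pseudo-bonds and the transition-state model; closed by continuous
# optimization (quasi-Newton via L-BFGS-B on a compiled objective, or an
# extended CCD baseline).
#
# Main loop: start-anchor backbone -> residue-1 side chain -> pseudo-bond
# into the TS (a distance constraint frozen at its optimum) -> rigid TS
# (plus rotatable TS torsions) -> pseudo-bond out to residue-2's functional
# atom -> residue-2 side chain reversed -> end-anchor backbone.  Each further
# side-chain role contributes a side loop from its own anchor to an already
# placed atom.  Backbone-interaction roles have no torsional freedom and are
# checked directly against the constraints.

.topo_rows <- function(aa) {
  sc <- sidechain_topology()
  sc[sc$res == aa, , drop = FALSE]
}

.bond_parent <- function(aa, atom) {
  if (atom %in% c("N", "C", "CB")) return("CA")
  if (atom == "CA") return(NA_character_)
  rows <- .topo_rows(aa)
  i <- match(atom, rows$atom)
  if (is.na(i)) stop("unknown atom ", atom, " for ", aa, call. = FALSE)
  rows$r3[i]
}

# chain of atoms CA -> ... -> functional atom following bond parents
.path_to <- function(aa, fatom) {
  path <- fatom
  while (path[1L] != "CA") {
    p <- .bond_parent(aa, path[1L])
    if (is.na(p)) break
    path <- c(p, path)
  }
  if (path[1L] != "CA")
    stop("no bond path from CA to ", fatom, " in ", aa, call. = FALSE)
  path
}

# chi-axis bonds as unordered atom-name pairs
.chi_bonds <- function(aa) {
  lapply(chi_definitions(aa), function(d) sort(d[2:3]))
}

.is_chi_bond <- function(aa, a, b) {
  key <- sort(c(a, b))
  any(vapply(.chi_bonds(aa), function(x) identical(x, key), logical(1)))
}

.chi_bond_index <- function(aa, a, b) {
  key <- sort(c(a, b))
  hit <- which(vapply(.chi_bonds(aa), function(x) identical(x, key),
                      logical(1)))
  if (length(hit)) hit[1L] else NA_integer_
}

# --- builder state ---------------------------------------------------------

.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$fixed <- matrix(numeric(0), 0, 3)
  env$labels <- character(0)      # labels for all coords (fixed then placed)
  env$rows <- list()              # zmat rows
  env$dof <- list()
  env$enforced <- integer(0)      # indices of constraints enforced in-chain
  env
}

.b_index <- function(env, label) {
  i <- match(label, env$labels)
  if (is.na(i)) stop("builder: unplaced reference '", label, "'", call. = FALSE)
  i
}

.b_add_fixed <- function(env, label, xyz) {
  env$fixed <- rbind(env$fixed, as.numeric(xyz))
  env$labels <- c(env$labels, label)
}

.b_add_row <- function(env, label, a, b, c, len, ang, tor,
                       ang_kind = "fixed", tor_kind = "fixed",
                       ang_lo = NA, ang_hi = NA, tor_lo = NA, tor_hi = NA,
                       grid = NULL, dof_label = NULL) {
  ia <- .b_index(env, a); ib <- .b_index(env, b); ic <- .b_index(env, c)
  env$rows[[length(env$rows) + 1L]] <-
    c(ia, ib, ic, len, ang, tor)
  env$labels <- c(env$labels, label)
  row_idx <- length(env$rows)
  if (ang_kind != "fixed")
    env$dof[[length(env$dof) + 1L]] <- list(
      row = row_idx, par = 2L, kind = ang_kind,
      lo = if (is.na(ang_lo)) 15 else max(5, ang_lo),
      hi = if (is.na(ang_hi)) 165 else min(175, ang_hi),
      init = ang, grid = ang,
      label = paste0(dof_label %||% label, ".angle"))
  if (tor_kind != "fixed")
    env$dof[[length(env$dof) + 1L]] <- list(
      row = row_idx, par = 3L, kind = tor_kind,
      lo = if (is.na(tor_lo)) -Inf else tor_lo,
      hi = if (is.na(tor_hi)) Inf else tor_hi,
      init = tor, grid = grid %||% tor,
      label = paste0(dof_label %||% label, ".torsion"))
  invisible(row_idx)
}

.b_finish <- function(env, kind, targets, meta = list()) {
  zmat <- do.call(rbind, env$rows)
  colnames(zmat) <- c("r1", "r2", "r3", "len", "ang", "tor")
  dof <- if (length(env$dof)) data.frame(
    row = vapply(env$dof, `[[`, numeric(1), "row"),
    par = vapply(env$dof, `[[`, numeric(1), "par"),
    kind = vapply(env$dof, `[[`, character(1), "kind"),
    lo = vapply(env$dof, `[[`, numeric(1), "lo"),
    hi = vapply(env$dof, `[[`, numeric(1), "hi"),
    init = vapply(env$dof, `[[`, numeric(1), "init"),
    label = vapply(env$dof, `[[`, character(1), "label"),
    stringsAsFactors = FALSE) else
    data.frame(row = numeric(0), par = numeric(0), kind = character(0),
               lo = numeric(0), hi = numeric(0), init = numeric(0),
               label = character(0))
  grids <- lapply(env$dof, `[[`, "grid")
  structure(c(list(kind = kind, fixed = env$fixed, zmat = zmat,
                   labels = env$labels, dof = dof, grids = grids,
                   targets = targets, enforced = env$enforced), meta),
            class = "kinematic_loop")
}

#' @export
print.kinematic_loop <- function(x, ...) {
  nfree <- sum(x$dof$kind == "free")
  nbound <- sum(x$dof$kind == "bounded")
  cat(sprintf("<kinematic_loop> %s: %d placed atoms, %d free + %d bounded DOFs, %d targets\n",
              x$kind, nrow(x$zmat), nfree, nbound, nrow(x$targets)))
  invisible(x)
}

# --- constraint -> DOF mapping helpers -------------------------------------

.find_constraint <- function(motif, kind, atoms) {
  cs <- motif$constraints
  n <- length(atoms)
  for (i in seq_len(nrow(cs))) {
    if (cs$kind[i] != kind) next
    ca <- c(cs$a1[i], cs$a2[i], cs$a3[i], cs$a4[i])[seq_len(n)]
    if (identical(ca, atoms) || identical(ca, rev(atoms))) return(i)
  }
  NA_integer_
}

# angle/torsion kinds and bounds for a row placing `d` from (a, b, c), given
# the motif constraints; marks mapped constraints as enforced
.row_kinds <- function(env, motif, a, b, c, d, default_ang, default_tor,
                       ang_free = TRUE, tor_free = TRUE, grid = NULL) {
  out <- list(ang = default_ang, ang_kind = if (ang_free) "free" else "fixed",
              ang_lo = NA, ang_hi = NA,
              tor = default_tor, tor_kind = if (tor_free) "free" else "fixed",
              tor_lo = NA, tor_hi = NA, grid = grid)
  i <- .find_constraint(motif, "angle", c(b, c, d))
  if (!is.na(i)) {
    cs <- motif$constraints[i, ]
    out$ang <- cs$optimal
    out$ang_kind <- "bounded"
    out$ang_lo <- cs$optimal - cs$tolerance
    out$ang_hi <- cs$optimal + cs$tolerance
    env$enforced <- union(env$enforced, i)
  }
  i <- .find_constraint(motif, "improper_dihedral", c(a, b, c, d))
  if (!is.na(i)) {
    cs <- motif$constraints[i, ]
    out$tor <- cs$optimal
    out$tor_kind <- "bounded"
    out$tor_lo <- cs$optimal - cs$tolerance
    out$tor_hi <- cs$optimal + cs$tolerance
    env$enforced <- union(env$enforced, i)
  }
  out
}

.GRID_SP3 <- c(-60, 60, 180)
.GRID_SP2 <- c(90, -90)

# forward placement of a whole side chain (all heavy atoms) for `role` of
# amino-acid type `aa`, anchored at fixed backbone labels ROLE:N/CA/C
.b_forward_sidechain <- function(env, role, aa) {
  rows <- .topo_rows(aa)
  lab <- function(atom) paste0(role, ":", atom)
  for (i in seq_len(nrow(rows))) {
    chi <- grepl("^c", rows$type[i])
    .b_add_row(env, lab(rows$atom[i]), lab(rows$r1[i]), lab(rows$r2[i]),
               lab(rows$r3[i]), rows$len[i], rows$ang[i],
               if (chi) 180 else rows$tor[i],
               tor_kind = if (chi) "free" else "fixed",
               grid = if (chi) .GRID_SP3 else NULL,
               dof_label = paste0(role, ".", rows$type[i]))
  }
}

# embed the TS via a pseudo-bond from functional atom `flabel` whose last
# two path atoms are `alabel`, `blabel`; dist constraint row index `ci`
.b_embed_ts <- function(env, motif, alabel, blabel, flabel, ci) {
  ts <- motif$ts
  cs <- motif$constraints[ci, ]
  env$enforced <- union(env$enforced, ci)
  nm <- ts$atoms$name
  tslab <- function(a) paste0("TS:", a)
  root <- nm[1L]
  # the constraint names (F, TS:root) in some order; root atom of embedding
  # is whichever TS atom the pseudo-bond touches
  ref_atoms <- c(cs$a1, cs$a2)
  ts_ref <- ref_atoms[startsWith(ref_atoms, "TS:")]
  root <- sub("^TS:", "", ts_ref)
  if (!identical(root, nm[1L]))
    stop("TS attachment must use the zmatrix root atom (", nm[1L], ")",
         call. = FALSE)
  rot_atoms <- unlist(ts$rotatable)
  # row 1: root via pseudo-bond (length frozen at the constraint optimum)
  k <- .row_kinds(env, motif, alabel, blabel, flabel, tslab(root),
                  default_ang = 109.5, default_tor = 0, grid = .GRID_SP2)
  .b_add_row(env, tslab(root), alabel, blabel, flabel, cs$optimal,
             k$ang, k$tor, ang_kind = k$ang_kind, tor_kind = k$tor_kind,
             ang_lo = k$ang_lo, ang_hi = k$ang_hi, tor_lo = k$tor_lo,
             tor_hi = k$tor_hi, grid = k$grid, dof_label = "ts.entry")
  if (length(nm) >= 2L) {
    r <- ts$zmatrix[[2L]]
    k <- .row_kinds(env, motif, blabel, flabel, tslab(root), tslab(nm[2L]),
                    default_ang = 109.5, default_tor = 90, grid = .GRID_SP2)
    .b_add_row(env, tslab(nm[2L]), blabel, flabel, tslab(root),
               as.numeric(r$length), k$ang, k$tor, ang_kind = k$ang_kind,
               tor_kind = k$tor_kind, ang_lo = k$ang_lo, ang_hi = k$ang_hi,
               tor_lo = k$tor_lo, tor_hi = k$tor_hi, grid = k$grid,
               dof_label = "ts.orient1")
  }
  if (length(nm) >= 3L) {
    r <- ts$zmatrix[[3L]]
    # internal angle fixed; the torsion about the two placed TS atoms is the
    # remaining rigid-body orientation DOF
    bonded <- r$ref[[2L]]
    other <- r$ref[[1L]]
    k <- .row_kinds(env, motif, flabel, tslab(other), tslab(bonded),
                    tslab(nm[3L]), default_ang = as.numeric(r$angle),
                    default_tor = 90, ang_free = FALSE, grid = .GRID_SP2)
    .b_add_row(env, tslab(nm[3L]), flabel, tslab(other), tslab(bonded),
               as.numeric(r$length), as.numeric(r$angle), k$tor,
               tor_kind = k$tor_kind, tor_lo = k$tor_lo, tor_hi = k$tor_hi,
               grid = k$grid, dof_label = "ts.orient2")
  }
  if (length(nm) > 3L) {
    for (i in 4:length(nm)) {
      r <- ts$zmatrix[[i]]
      rot <- nm[i] %in% rot_atoms
      .b_add_row(env, tslab(nm[i]), tslab(r$ref[[1L]]), tslab(r$ref[[2L]]),
                 tslab(r$ref[[3L]]), as.numeric(r$length), as.numeric(r$angle),
                 as.numeric(r$torsion),
                 tor_kind = if (rot) "free" else "fixed",
                 grid = if (rot) .GRID_SP3 else NULL,
                 dof_label = paste0("ts.", nm[i]))
    }
  }
}

# reversed side chain for the second main-loop role: from its functional
# atom (placed by an exit pseudo-bond) back down to CA, N, C, then branch
# completion.  Returns labels of the terminal CA/N/C rows.
.b_reverse_sidechain <- function(env, motif, role, aa, fatom, partner_label,
                                 pre_label) {
  tpl <- residue_template(aa)
  lab <- function(atom) paste0(role, ":", atom)
  path <- .path_to(aa, fatom)           # CA ... F
  rpath <- rev(path)                    # F ... CA
  seqs <- c(rpath, "N", "C")
  # reference sequence: r0 = pre (partner's own reference), r1 = partner
  refs <- c(pre_label, partner_label, lab(rpath))
  m <- length(rpath)
  for (k in 2:length(seqs)) {
    atom <- seqs[k]
    a <- refs[k - 1L]; b <- refs[k]; c_ <- refs[k + 1L]
    if (atom == "C") {
      # improper: C placed about the N-CA axis at the template value
      ic <- template_ic(tpl, "CB", "N", "CA", "C")
      .b_add_row(env, lab("C"), lab("CB"), lab("N"), lab("CA"),
                 ic$len, ic$ang, ic$tor)
      next
    }
    prev1 <- seqs[k - 1L]               # bonded parent in reversed chain
    dxy <- template_xyz(tpl, c(prev1, atom))
    ic_len <- measure("distance", dxy[1L, ], dxy[2L, ])
    if (k == 2L) {
      # angle at the functional atom involves the external partner: a DOF
      kk <- .row_kinds(env, motif, a, b, c_, lab(atom),
                       default_ang = 120, default_tor = 0, grid = .GRID_SP2)
      .b_add_row(env, lab(atom), a, b, c_, ic_len, kk$ang, kk$tor,
                 ang_kind = kk$ang_kind, tor_kind = kk$tor_kind,
                 ang_lo = kk$ang_lo, ang_hi = kk$ang_hi,
                 tor_lo = kk$tor_lo, tor_hi = kk$tor_hi, grid = kk$grid,
                 dof_label = paste0(role, ".approach"))
      next
    }
    prev2 <- seqs[k - 2L]
    ang <- template_ic(tpl, prev2, prev1, atom)$ang
    chi_j <- if (k >= 4L) .chi_bond_index(aa, prev2, prev1) else NA_integer_
    free <- (k == 3L) || !is.na(chi_j)
    tor_val <- if (k == 3L) 180 else
      template_ic(tpl, seqs[k - 3L], prev2, prev1, atom)$tor
    dof_lab <- if (!is.na(chi_j)) paste0(role, ".rchi", chi_j)
               else paste0(role, ".rev.", atom)
    # an improper-dihedral constraint on this row's atoms bounds the torsion
    ci <- .find_constraint(motif, "improper_dihedral", c(a, b, c_, lab(atom)))
    if (free && !is.na(ci)) {
      cc <- motif$constraints[ci, ]
      env$enforced <- union(env$enforced, ci)
      .b_add_row(env, lab(atom), a, b, c_, ic_len, ang, cc$optimal,
                 tor_kind = "bounded", tor_lo = cc$optimal - cc$tolerance,
                 tor_hi = cc$optimal + cc$tolerance, dof_label = dof_lab)
    } else {
      .b_add_row(env, lab(atom), a, b, c_, ic_len, ang, tor_val,
                 tor_kind = if (free) "free" else "fixed",
                 grid = if (free) .GRID_SP3 else NULL,
                 dof_label = dof_lab)
    }
  }
  # branch completion: heavy atoms not on the path, placed rigidly
  rows <- .topo_rows(aa)
  for (i in seq_len(nrow(rows))) {
    atom <- rows$atom[i]
    if (atom %in% path) next
    if (grepl("^c", rows$type[i])) {
      # chi-typed branch: re-reference against the placed path sibling
      sib <- path[match(rows$r3[i], path) + 1L]
      ict <- template_ic(tpl, sib, rows$r2[i], rows$r3[i], atom)
      .b_add_row(env, lab(atom), lab(sib), lab(rows$r2[i]), lab(rows$r3[i]),
                 ict$len, ict$ang, ict$tor)
    } else {
      .b_add_row(env, lab(atom), lab(rows$r1[i]), lab(rows$r2[i]),
                 lab(rows$r3[i]), rows$len[i], rows$ang[i], rows$tor[i])
    }
  }
  lab(c("CA", "N", "C"))
}

# --- loop construction ------------------------------------------------------

.role_info <- function(motif, role) {
  i <- match(role, motif$residues$role)
  if (is.na(i)) stop("unknown role ", role, call. = FALSE)
  as.list(motif$residues[i, ])
}

# distance constraints touching a role's side chain, as (index, self atom,
# other label) records
.role_dist_constraints <- function(motif, role) {
  cs <- motif$constraints
  out <- list()
  for (i in seq_len(nrow(cs))) {
    if (cs$kind[i] != "distance") next
    ends <- c(cs$a1[i], cs$a2[i])
    roles <- vapply(ends, function(a) .parse_atom_ref(a)$role, character(1))
    if (role %in% roles) {
      self <- ends[roles == role][1L]
      other <- ends[roles != role]
      if (length(other) == 0L) next  # intra-role constraint: not a link
      out[[length(out) + 1L]] <- list(i = i,
                                      self_atom = .parse_atom_ref(self)$atom,
                                      other = other[1L])
    }
  }
  out
}

#' Select the two main-loop roles of a motif
#'
#' The two side-chain catalytic roles with the strongest constraint
#' connectivity to the TS: the first must carry a distance constraint to the
#' TS root; the second a distance constraint to the TS or to the first role.
#' Ties resolve in motif order.
#'
#' @param motif a `catalytic_motif`.
#' @return character vector of two role ids.
#' @export
main_loop_roles <- function(motif) {
  rs <- motif$residues
  sc <- rs$role[rs$via == "side_chain" & rs$class == "catalytic"]
  if (length(sc) < 2L)
    sc <- rs$role[rs$via == "side_chain"]
  if (length(sc) < 2L)
    stop("motif needs at least two side-chain roles for a main loop",
         call. = FALSE)
  n_ts <- vapply(sc, function(r) {
    links <- .role_dist_constraints(motif, r)
    sum(vapply(links, function(l) startsWith(l$other, "TS:"), logical(1)))
  }, numeric(1))
  if (!any(n_ts > 0))
    stop("no side-chain role has a distance constraint to the TS", call. = FALSE)
  role1 <- sc[which.max(n_ts)]
  rest <- setdiff(sc, role1)
  ok <- vapply(rest, function(r) {
    links <- .role_dist_constraints(motif, r)
    any(vapply(links, function(l)
      startsWith(l$other, "TS:") || startsWith(l$other, paste0(role1, ":")),
      logical(1)))
  }, logical(1))
  if (!any(ok))
    stop("no second role is linked to the TS or to ", role1, call. = FALSE)
  c(role1, rest[ok][1L])
}

#' Build the kinematic loops for one site assignment
#'
#' @param motif a `catalytic_motif`.
#' @param assignment named character vector mapping every role id to a
#'   distinct residue id of the scaffold.
#' @param scaffold a `protein_structure`.
#' @return list with `main` (a `kinematic_loop`), `sides` (list of side
#'   `kinematic_loop`s, one per remaining side-chain role in motif order) and
#'   `backbone_roles` (roles checked directly against the scaffold backbone).
#' @export
build_loops <- function(motif, assignment, scaffold) {
  roles <- motif$residues$role
  if (!all(roles %in% names(assignment)))
    stop("assignment must cover every motif role", call. = FALSE)
  if (anyDuplicated(assignment[roles]))
    stop("assignment must map roles to distinct residues", call. = FALSE)
  mains <- main_loop_roles(motif)
  for (r in mains)
    if (.role_info(motif, r)$via != "side_chain")
      stop("main-loop role ", r, " must interact via its side chain",
           call. = FALSE)
  main <- build_main_loop(motif, mains[1L], mains[2L],
                          assignment[[mains[1L]]], assignment[[mains[2L]]],
                          scaffold)
  side_roles <- setdiff(roles[motif$residues$via == "side_chain"], mains)
  # side loops anchor on already placed atoms; for the standalone builder we
  # evaluate the main loop at its initial torsions to get provisional
  # coordinates (the engine re-anchors per closed main-loop solution)
  co <- chain_place_cpp(main$fixed, main$zmat, main$dof$row, main$dof$par,
                        main$dof$init)
  rownames(co) <- main$labels
  placed <- lapply(seq_len(nrow(co)), function(i) co[i, ])
  names(placed) <- main$labels
  sides <- list()
  for (r in side_roles) {
    sides[[r]] <- build_side_loop(motif, r, assignment[[r]], scaffold, placed)
    for (i in seq_along(sides[[r]]$labels))
      placed[[sides[[r]]$labels[i]]] <- c(0, 0, 0)
  }
  backbone_roles <- roles[motif$residues$via == "backbone"]
  list(main = main, sides = sides, backbone_roles = backbone_roles)
}

#' @rdname build_loops
#' @param role1,role2 the two main-loop role ids.
#' @param site1,site2 residue ids of their assigned sites.
#' @export
build_main_loop <- function(motif, role1, role2, site1, site2, scaffold) {
  aa1 <- .role_info(motif, role1)$aa
  aa2 <- .role_info(motif, role2)$aa
  env <- .new_builder()
  bb1 <- backbone_frame(scaffold, site1)
  for (nm in c("N", "CA", "C"))
    .b_add_fixed(env, paste0(role1, ":", nm), bb1[nm, ])
  .b_forward_sidechain(env, role1, aa1)
  # pseudo-bond into the TS from role1's functional atom
  links1 <- .role_dist_constraints(motif, role1)
  ts_link <- NULL
  for (l in links1) if (startsWith(l$other, "TS:")) { ts_link <- l; break }
  if (is.null(ts_link))
    stop(role1, " has no distance constraint to the TS", call. = FALSE)
  f1 <- ts_link$self_atom
  path1 <- .path_to(aa1, f1)
  p1 <- path1[length(path1) - 1L]
  p2 <- if (length(path1) >= 3L) path1[length(path1) - 2L] else "N"
  .b_embed_ts(env, motif, paste0(role1, ":", p2), paste0(role1, ":", p1),
              paste0(role1, ":", f1), ts_link$i)
  # exit pseudo-bond to role2's functional atom
  links2 <- .role_dist_constraints(motif, role2)
  exit_link <- NULL
  for (l in links2) {
    tgt_role <- .parse_atom_ref(l$other)$role
    if (tgt_role %in% c("TS", role1)) { exit_link <- l; break }
  }
  if (is.null(exit_link))
    stop(role2, " has no distance constraint to the TS or ", role1,
         call. = FALSE)
  partner <- exit_link$other
  f2 <- exit_link$self_atom
  # reference pair for the exit row: the partner's own placement references
  pi <- .b_index(env, partner)
  nf <- nrow(env$fixed)
  if (pi <= nf) stop("exit partner must be a placed chain atom", call. = FALSE)
  prow <- env$rows[[pi - nf]]
  b_lab <- env$labels[prow[3L]]
  a_lab <- env$labels[prow[2L]]
  cs <- motif$constraints[exit_link$i, ]
  env$enforced <- union(env$enforced, exit_link$i)
  kk <- .row_kinds(env, motif, a_lab, b_lab, partner, paste0(role2, ":", f2),
                   default_ang = 109.5, default_tor = 0, grid = .GRID_SP2)
  .b_add_row(env, paste0(role2, ":", f2), a_lab, b_lab, partner, cs$optimal,
             kk$ang, kk$tor, ang_kind = kk$ang_kind, tor_kind = kk$tor_kind,
             ang_lo = kk$ang_lo, ang_hi = kk$ang_hi, tor_lo = kk$tor_lo,
             tor_hi = kk$tor_hi, grid = kk$grid,
             dof_label = paste0(role2, ".exit"))
  term <- .b_reverse_sidechain(env, motif, role2, aa2, f2, partner, b_lab)
  bb2 <- backbone_frame(scaffold, site2)
  t_idx <- vapply(term, function(l) .b_index(env, l), numeric(1))
  targets <- data.frame(row = t_idx,
                        x = bb2[c("CA", "N", "C"), 1],
                        y = bb2[c("CA", "N", "C"), 2],
                        z = bb2[c("CA", "N", "C"), 3],
                        w = c(1, 1, 1),
                        label = c("CA", "N", "C"),
                        stringsAsFactors = FALSE)
  .b_finish(env, "main", targets,
            meta = list(roles = c(role1, role2), sites = c(site1, site2),
                        aas = c(aa1, aa2), includes_ts = TRUE,
                        start_ca = bb1["CA", ], end_ca = bb2["CA", ],
                        terminal_ca_label = term[1L]))
}

#' @rdname build_loops
#' @param role a side-loop role id.
#' @param site its assigned residue id.
#' @param placed_coords named list (label -> 3-vector) of already placed
#'   atoms (TS and earlier roles), or a character vector of available labels
#'   when only the topology is needed.
#' @export
build_side_loop <- function(motif, role, site, scaffold, placed_coords) {
  info <- .role_info(motif, role)
  if (info$via != "side_chain")
    stop("side loops are built for side-chain roles only", call. = FALSE)
  aa <- info$aa
  if (is.character(placed_coords))
    stop("side loops need concrete coordinates for the placed atoms",
         call. = FALSE)
  placed_labels <- names(placed_coords)
  links <- .role_dist_constraints(motif, role)
  link <- NULL
  for (l in links) if (l$other %in% placed_labels) { link <- l; break }
  if (is.null(link))
    stop(role, " has no distance constraint to an already placed atom",
         call. = FALSE)
  # reversed construction, exactly like the main loop's second residue: the
  # chain starts at the placed partner atom, places the functional atom via
  # the frozen pseudo-bond, walks the side chain down to CA, and must land
  # on the site's backbone frame.  Constraint angles/impropers at the
  # hydrogen bond map onto bounded DOFs of the first rows.
  f <- link$self_atom
  cs <- motif$constraints[link$i, ]
  pref <- .parse_atom_ref(link$other)
  # reference pair (a, b) for the exit row: prefer atoms named by an
  # improper constraint (X, Y, partner, F), then an angle constraint
  # (Y, partner, F), then the partner's own bond parents
  a_lab <- b_lab <- NULL
  ci <- NA_integer_
  csall <- motif$constraints
  for (i in seq_len(nrow(csall))) {
    if (csall$kind[i] == "improper_dihedral" &&
        ((csall$a3[i] == link$other && csall$a4[i] == paste0(role, ":", f)) ||
         (csall$a2[i] == link$other && csall$a1[i] == paste0(role, ":", f)))) {
      if (csall$a3[i] == link$other) {
        a_lab <- csall$a1[i]; b_lab <- csall$a2[i]
      } else {
        a_lab <- csall$a4[i]; b_lab <- csall$a3[i]
      }
      break
    }
  }
  if (is.null(b_lab)) {
    for (i in seq_len(nrow(csall))) {
      if (csall$kind[i] == "angle" &&
          ((csall$a2[i] == link$other && csall$a3[i] == paste0(role, ":", f)) ||
           (csall$a2[i] == link$other && csall$a1[i] == paste0(role, ":", f))))
        b_lab <- if (csall$a3[i] == paste0(role, ":", f)) csall$a1[i]
                 else csall$a3[i]
    }
  }
  if (is.null(b_lab) && pref$role != "TS") {
    paa <- .role_info(motif, pref$role)$aa
    bp <- tryCatch(.bond_parent(paa, pref$atom), error = function(e) NA)
    if (!is.na(bp)) b_lab <- paste0(pref$role, ":", bp)
  }
  if (is.null(b_lab)) {
    # fall back to any placed atom near the partner
    cands <- setdiff(placed_labels, link$other)
    d <- vapply(cands, function(l)
      sqrt(sum((placed_coords[[l]] - placed_coords[[link$other]])^2)),
      numeric(1))
    b_lab <- cands[which.min(d)]
  }
  if (is.null(a_lab)) {
    cands <- setdiff(placed_labels, c(link$other, b_lab))
    d <- vapply(cands, function(l)
      sqrt(sum((placed_coords[[l]] - placed_coords[[b_lab]])^2)), numeric(1))
    a_lab <- cands[which.min(d)]
  }
  env <- .new_builder()
  .b_add_fixed(env, a_lab, placed_coords[[a_lab]])
  .b_add_fixed(env, b_lab, placed_coords[[b_lab]])
  .b_add_fixed(env, link$other, placed_coords[[link$other]])
  env$enforced <- union(env$enforced, link$i)
  kk <- .row_kinds(env, motif, a_lab, b_lab, link$other, paste0(role, ":", f),
                   default_ang = 120, default_tor = 0, grid = .GRID_SP2)
  .b_add_row(env, paste0(role, ":", f), a_lab, b_lab, link$other, cs$optimal,
             kk$ang, kk$tor, ang_kind = kk$ang_kind, tor_kind = kk$tor_kind,
             ang_lo = kk$ang_lo, ang_hi = kk$ang_hi, tor_lo = kk$tor_lo,
             tor_hi = kk$tor_hi, grid = kk$grid,
             dof_label = paste0(role, ".exit"))
  term <- .b_reverse_sidechain(env, motif, role, aa, f, link$other, b_lab)
  bb <- backbone_frame(scaffold, site)
  t_idx <- vapply(term, function(l) .b_index(env, l), numeric(1))
  targets <- data.frame(row = t_idx,
                        x = bb[c("CA", "N", "C"), 1],
                        y = bb[c("CA", "N", "C"), 2],
                        z = bb[c("CA", "N", "C"), 3],
                        w = c(1, 1, 1), label = c("CA", "N", "C"),
                        stringsAsFactors = FALSE)
  .b_finish(env, "side", targets,
            meta = list(roles = role, sites = site, aas = aa,
                        includes_ts = FALSE,
                        start_ca = as.numeric(placed_coords[[link$other]]),
                        partner = link$other, self_atom = f,
                        link_tolerance = cs$tolerance,
                        terminal_ca_label = term[1L]))
}

# --- closure ----------------------------------------------------------------

.loop_eval <- function(loop, par) {
  chain_place_cpp(loop$fixed, loop$zmat, loop$dof$row, loop$dof$par, par)
}

.loop_obj <- function(loop, par, targets = loop$targets) {
  chain_obj_cpp(loop$fixed, loop$zmat, loop$dof$row, loop$dof$par, par,
                targets$row, as.matrix(targets[, c("x", "y", "z")]),
                targets$w)
}

.closure_result <- function(loop, par, tolerance, method, value,
                            targets = loop$targets) {
  coords <- .loop_eval(loop, par)
  rownames(coords) <- loop$labels
  devs <- sqrt(rowSums((coords[targets$row, , drop = FALSE] -
                          as.matrix(targets[, c("x", "y", "z")]))^2))
  ca_dev <- devs[targets$label %in% c("CA")][1]
  if (is.na(ca_dev)) ca_dev <- devs[1]
  orient_ok <- all(devs <= 2 * tolerance)
  conv <- ca_dev <= tolerance && orient_ok
  # wrap only the unconstrained torsions: bounded torsions live in their
  # constraint box, whose limits may extend beyond +-180
  par <- ifelse(loop$dof$par == 3L & loop$dof$kind == "free",
                wrap_angle(par), par)
  structure(list(torsions = stats::setNames(par, loop$dof$label),
                 closure_deviation = unname(ca_dev),
                 target_deviations = stats::setNames(devs, targets$label),
                 coords = coords, converged = conv, objective = value,
                 method = method, loop_kind = loop$kind),
            class = "closed_loop")
}

#' @export
print.closed_loop <- function(x, ...) {
  cat(sprintf("<closed_loop> %s: %s, closure deviation %.4f A (%s)\n",
              x$loop_kind, if (x$converged) "converged" else "not converged",
              x$closure_deviation, x$method))
  invisible(x)
}

#' Close a kinematic loop by quasi-Newton optimization
#'
#' Minimizes the squared deviation of the terminal anchor atoms (terminal CA
#' plus an orientation penalty on the flanking N and C; a single virtual atom
#' for side loops) over the free and bounded torsions/angles, using
#' L-BFGS-B with box bounds on the bounded degrees of freedom.  Bond lengths
#' and bond angles of the chain are never altered.
#'
#' @param loop a `kinematic_loop`.
#' @param initial_torsions numeric vector of initial DOF values (defaults to
#'   the loop's built-in initials).
#' @param tolerance closure tolerance in Angstrom (default 0.1); the terminal
#'   CA must land within `tolerance` and the orientation atoms within
#'   `2 * tolerance` for the result to count as converged.
#' @param maxit maximum optimizer iterations.
#' @param bounded_penalty weight of a weak quadratic pull of the bounded
#'   (constraint-ranged) DOFs toward their optima.  The closure manifold
#'   usually has residual dimensions; the penalty selects the manifold point
#'   whose constraint parameters sit nearest their optimal values without
#'   trading off the anchor targets.
#' @return a `closed_loop` (with `converged = FALSE` when closure failed;
#'   non-convergence is an outcome, not an error).
#' @export
close_loop <- function(loop, initial_torsions = NULL, tolerance = 0.1,
                       maxit = 200, bounded_penalty = 1e-3) {
  par0 <- initial_torsions %||% loop$dof$init
  stopifnot(length(par0) == nrow(loop$dof))
  if (nrow(loop$dof) == 0L)
    return(.closure_result(loop, numeric(0), tolerance, "quasi-newton",
                           .loop_obj(loop, numeric(0))))
  tg <- loop$targets
  txyz <- as.matrix(tg[, c("x", "y", "z")])
  pen_w <- ifelse(loop$dof$kind == "bounded", bounded_penalty, 0)
  opt_v <- loop$dof$init
  fn <- function(p) chain_obj_cpp(loop$fixed, loop$zmat, loop$dof$row,
                                  loop$dof$par, p, tg$row, txyz, tg$w) +
    sum(pen_w * (p - opt_v)^2)
  gr <- function(p) chain_grad_cpp(loop$fixed, loop$zmat, loop$dof$row,
                                   loop$dof$par, p, tg$row, txyz, tg$w) +
    2 * pen_w * (p - opt_v)
  lo <- loop$dof$lo; hi <- loop$dof$hi
  par0 <- pmin(pmax(par0, lo), hi)
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lo,
                      upper = hi,
                      control = list(maxit = maxit, factr = 1e4))
  value <- .loop_obj(loop, opt$par)
  .closure_result(loop, opt$par, tolerance, "quasi-newton", value)
}

#' Close a kinematic loop by extended cyclic coordinate descent
#'
#' The baseline closure algorithm: analytic one-torsion-at-a-time updates
#' (multi-target CCD), with bounded angle DOFs relaxed by a bounded scan.
#' Shares [close_loop()]'s convergence contract.
#'
#' @inheritParams close_loop
#' @param max_sweeps maximum CCD sweeps.
#' @return a `closed_loop`.
#' @export
ccd_close_loop <- function(loop, initial_torsions = NULL, tolerance = 0.1,
                           max_sweeps = 200) {
  par0 <- initial_torsions %||% loop$dof$init
  stopifnot(length(par0) == nrow(loop$dof))
  if (nrow(loop$dof) == 0L)
    return(.closure_result(loop, numeric(0), tolerance, "ccd",
                           .loop_obj(loop, numeric(0))))
  tg <- loop$targets
  lo <- pmax(loop$dof$lo, -360); hi <- pmin(loop$dof$hi, 360)
  par0 <- pmin(pmax(par0, lo), hi)
  res <- ccd_close_cpp(loop$fixed, loop$zmat, loop$dof$row, loop$dof$par,
                       par0, lo, hi, tg$row,
                       as.matrix(tg[, c("x", "y", "z")]), tg$w,
                       max_sweeps = max_sweeps)
  .closure_result(loop, res$par, tolerance, "ccd", res$value)
}

#' Deterministic multistart initial torsion vectors
#'
#' Free torsions are enumerated on a per-DOF grid (staggered values for
#' sp3-like chi bonds, perpendicular values for sp2-like orientation bonds);
#' bounded DOFs are seeded at their constraint optimum.  When the full grid
#' exceeds `max_samples` a deterministic subsample (seeded permutation) is
#' taken.
#'
#' @param loop a `kinematic_loop`.
#' @param max_samples cap on the number of starts.
#' @param seed integer seed controlling subsampling.
#' @return list of numeric DOF vectors.
#' @export
sample_initial_loops <- function(loop, max_samples = 100, seed = 1) {
  nd <- nrow(loop$dof)
  if (nd == 0L) return(list(numeric(0)))
  vals <- lapply(seq_len(nd), function(k) {
    if (loop$dof$kind[k] == "free" && loop$dof$par[k] == 3L)
      loop$grids[[k]]
    else loop$dof$init[k]
  })
  grid <- as.matrix(do.call(expand.grid, vals))
  colnames(grid) <- loop$dof$label
  if (nrow(grid) > max_samples) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed %% .Machine$integer.max)
    grid <- grid[sample.int(nrow(grid), max_samples), , drop = FALSE]
  }
  lapply(seq_len(nrow(grid)), function(i) unname(grid[i, ]))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Theoretical maximum reach of a loop
#'
#' Runs the closure optimizer against a dummy target placed 1,000 Angstrom
#' from the start anchor along the start-to-end direction, from several
#' extended starts, and returns the largest achieved distance between the
#' start CA and the computed terminal atom.  Used by reach pruning: a site
#' pair whose true anchor separation exceeds this bound cannot be spanned by
#' the loop.
#'
#' @param loop a `kinematic_loop`.
#' @param n_starts number of multistart initializations.
#' @param seed subsampling seed.
#' @return maximum reach in Angstrom.
#' @export
max_loop_length <- function(loop, n_starts = 12, seed = 1) {
  dir <- loop$targets[1L, c("x", "y", "z")]
  dir <- as.numeric(dir) - loop$start_ca
  if (!all(is.finite(dir)) || sum(dir^2) < 1e-12) dir <- c(1, 0, 0)
  dir <- dir / sqrt(sum(dir^2))
  dummy <- loop$start_ca + 1000 * dir
  tg <- loop$targets[1L, , drop = FALSE]
  tg$x <- dummy[1]; tg$y <- dummy[2]; tg$z <- dummy[3]; tg$w <- 1
  term_row <- tg$row
  if (nrow(loop$dof) == 0L) {
    coords <- .loop_eval(loop, numeric(0))
    return(sqrt(sum((coords[term_row, ] - loop$start_ca)^2)))
  }
  # candidate starts: the fully extended configuration, corners of the
  # box-bounded DOFs, and a seeded Monte-Carlo sweep of the whole DOF space
  # (the best samples are then polished by the optimizer, so the returned
  # bound dominates everything the sampler saw and its local neighbourhood)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed((seed + 7919L) %% .Machine$integer.max)
  lo <- pmax(loop$dof$lo, -180)
  hi <- pmin(loop$dof$hi, 180)
  ext <- ifelse(loop$dof$kind == "free" & loop$dof$par == 3L, 180,
                loop$dof$init)
  reach_of <- function(par) {
    coords <- .loop_eval(loop, par)
    sqrt(sum((coords[term_row, ] - loop$start_ca)^2))
  }
  cands <- list(ext)
  boxed <- which(loop$dof$kind == "bounded" | loop$dof$par == 2L)
  n_corner <- min(64L, 2^length(boxed))
  for (r in seq_len(n_corner)) {
    v <- ext
    pickhi <- if (r <= 2L) rep(r == 2L, length(boxed))
              else stats::runif(length(boxed)) > 0.5
    v[boxed] <- ifelse(pickhi, hi[boxed], lo[boxed])
    cands[[length(cands) + 1L]] <- v
  }
  n_mc <- 3000L
  mc_reach <- numeric(n_mc)
  mc_par <- vector("list", n_mc)
  for (i in seq_len(n_mc)) {
    v <- lo + stats::runif(length(lo)) * (hi - lo)
    mc_par[[i]] <- v
    mc_reach[i] <- reach_of(v)
  }
  cands <- c(cands, mc_par[order(-mc_reach)[seq_len(20L)]])
  best <- max(mc_reach)
  txyz <- as.matrix(tg[, c("x", "y", "z")])
  fn <- function(p) chain_obj_cpp(loop$fixed, loop$zmat, loop$dof$row,
                                  loop$dof$par, p, tg$row, txyz, tg$w)
  gr <- function(p) chain_grad_cpp(loop$fixed, loop$zmat, loop$dof$row,
                                   loop$dof$par, p, tg$row, txyz, tg$w)
  best_par <- mc_par[[which.max(mc_reach)]]
  for (s in cands) {
    s <- pmin(pmax(s, loop$dof$lo), loop$dof$hi)
    opt <- stats::optim(s, fn, gr, method = "L-BFGS-B", lower = loop$dof$lo,
                        upper = loop$dof$hi,
                        control = list(maxit = 150, factr = 1e7))
    r <- reach_of(opt$par)
    if (r > best) { best <- r; best_par <- opt$par }
  }
  # final coordinate-ascent sweeps from the best point: the maximum often
  # sits on box faces that gradient steps approach slowly
  v <- best_par
  for (sweep in 1:3) {
    for (k in seq_along(v)) {
      grid <- seq(lo[k], hi[k], length.out = 25L)
      vals <- vapply(grid, function(g) { v2 <- v; v2[k] <- g; reach_of(v2) },
                     numeric(1))
      j <- which.max(vals)
      if (vals[j] > best) { best <- vals[j]; v[k] <- grid[j] }
    }
  }
  best
}

#' Multistart closure with deduplication
#'
#' Closes a loop from every sampled start, keeps converged solutions and
#' removes duplicates by greedy streaming no-fit RMSD over the placed atoms.
#'
#' @inheritParams close_loop
#' @param max_samples,seed passed to [sample_initial_loops()].
#' @param dedup_rmsd RMSD threshold in Angstrom for duplicate elimination.
#' @param method `"hybrid"` (default: cheap CCD warm start, quasi-Newton
#'   polish of promising starts), `"qn"` or `"ccd"`.
#' @param prefilter hybrid mode only: squared-deviation level below which a
#'   CCD-warmed start is polished by the quasi-Newton closer.
#' @return list of distinct converged `closed_loop`s (possibly empty).
#' @export
multistart_close <- function(loop, tolerance = 0.1, max_samples = 100,
                             seed = 1, dedup_rmsd = 0.5, method = "hybrid",
                             prefilter = 9) {
  starts <- sample_initial_loops(loop, max_samples = max_samples, seed = seed)
  sols <- list()
  if (method == "hybrid" && nrow(loop$dof) > 0L) {
    tg <- loop$targets
    txyz <- as.matrix(tg[, c("x", "y", "z")])
    lo <- pmax(loop$dof$lo, -360); hi <- pmin(loop$dof$hi, 360)
    warm1 <- function(s) {
      s <- pmin(pmax(s, lo), hi)
      ccd_close_cpp(loop$fixed, loop$zmat, loop$dof$row, loop$dof$par, s,
                    lo, hi, tg$row, txyz, tg$w, max_sweeps = 15,
                    angle_every = 5)
    }
    # phase 1: cheap probe of a subset; abandon hopeless loops early
    probe_n <- min(24L, length(starts))
    probe <- lapply(starts[seq_len(probe_n)], warm1)
    if (!any(vapply(probe, `[[`, numeric(1), "value") < prefilter * 3))
      return(list())
    warms <- c(probe, lapply(starts[-seq_len(probe_n)], warm1))
    vals <- vapply(warms, `[[`, numeric(1), "value")
    cand <- order(vals)
    cand <- cand[vals[cand] < prefilter][seq_len(min(40L, sum(vals < prefilter)))]
    for (i in cand) {
      cl <- close_loop(loop, warms[[i]]$par, tolerance = tolerance)
      if (cl$converged) sols[[length(sols) + 1L]] <- cl
    }
  } else {
    closer <- if (method == "ccd") ccd_close_loop else close_loop
    for (s in starts) {
      cl <- closer(loop, s, tolerance = tolerance)
      if (cl$converged) sols[[length(sols) + 1L]] <- cl
    }
  }
  if (length(sols) <= 1L) return(sols)
  dedup_loops(sols, dedup_rmsd)
}

#' Re-close a loop with additional point targets
#'
#' Constraint-guided refinement: the loop is re-optimized from a converged
#' solution with extra target points appended (typically ideal
#' hydrogen-bond positions for backbone-donor constraints), so the closure
#' picks the point of the solution manifold that also satisfies constraints
#' against fixed scaffold atoms.
#'
#' @param loop a `kinematic_loop`.
#' @param closed a converged `closed_loop` providing the starting torsions.
#' @param extra data.frame with columns `row` (index into the loop's
#'   combined coordinates), `x`, `y`, `z`, `w`.
#' @param tolerance closure tolerance for the original targets.
#' @return a `closed_loop` judged against the loop's original targets.
#' @export
refine_loop <- function(loop, closed, extra, tolerance = 0.1,
                        bounded_penalty = 1e-3) {
  tg <- rbind(loop$targets[, c("row", "x", "y", "z", "w")],
              extra[, c("row", "x", "y", "z", "w")])
  tg$label <- c(loop$targets$label, rep("extra", nrow(extra)))
  par0 <- unname(closed$torsions)
  txyz <- as.matrix(tg[, c("x", "y", "z")])
  pen_w <- ifelse(loop$dof$kind == "bounded", bounded_penalty, 0)
  opt_v <- loop$dof$init
  fn <- function(p) chain_obj_cpp(loop$fixed, loop$zmat, loop$dof$row,
                                  loop$dof$par, p, tg$row, txyz, tg$w) +
    sum(pen_w * (p - opt_v)^2)
  gr <- function(p) chain_grad_cpp(loop$fixed, loop$zmat, loop$dof$row,
                                   loop$dof$par, p, tg$row, txyz, tg$w) +
    2 * pen_w * (p - opt_v)
  par0 <- pmin(pmax(par0, loop$dof$lo), loop$dof$hi)
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = loop$dof$lo,
                      upper = loop$dof$hi,
                      control = list(maxit = 200, factr = 1e4))
  .closure_result(loop, opt$par, tolerance, "quasi-newton", opt$value)
}

#' Patch a side loop's target onto freshly placed coordinates
#'
#' Side loops are built before the main loop is closed; once the TS and the
#' earlier roles are placed, the virtual-atom target is filled in from the
#' actual partner coordinates.
#'
#' @param loop a side `kinematic_loop`.
#' @param coords named list (label -> 3-vector) containing the loop's
#'   partner atom.
#' @return the loop with a concrete target.
#' @export
set_side_target <- function(loop, coords) {
  p <- coords[[loop$partner]]
  if (is.null(p)) stop("coordinates lack partner atom ", loop$partner,
                       call. = FALSE)
  loop$targets$x <- p[1]; loop$targets$y <- p[2]; loop$targets$z <- p[3]
  loop
}
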