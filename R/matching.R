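# Matching engine: enumerate site assignments, drive loop building, closure
# and pruning, assemble matches and rank them.

#' Matching run configuration
#'
#' @param candidate_radius candidate-site selection radius around the
#'   catalytic-residue centroid, in Angstrom (screening only).
#' @param closure_tolerance loop-closure tolerance in Angstrom.
#' @param max_samples multistart cap for main loops.
#' @param side_samples multistart cap for side loops.
#' @param seed integer seed controlling deterministic subsampling.
#' @param pruning a [pruning_params()] list.
#' @param max_matches cap on matches returned per scaffold.
#' @param side_branch maximum alternative placements explored per side role.
#' @param w_constraint,w_repulsion ranking weights (see [rank_matches()]).
#' @param method closure strategy for multistart (see [multistart_close()]).
#' @return a `match_config` list.
#' @export
match_config <- function(candidate_radius = 15, closure_tolerance = 0.1,
                         max_samples = 72, side_samples = 24, seed = 1,
                         pruning = pruning_params(), max_matches = 1000,
                         side_branch = 3, w_constraint = 1, w_repulsion = 1,
                         method = "hybrid") {
  stopifnot(candidate_radius > 0, closure_tolerance > 0, max_samples >= 1)
  structure(list(candidate_radius = candidate_radius,
                 closure_tolerance = closure_tolerance,
                 max_samples = max_samples, side_samples = side_samples,
                 seed = as.integer(seed), pruning = pruning,
                 max_matches = max_matches, side_branch = side_branch,
                 w_constraint = w_constraint, w_repulsion = w_repulsion,
                 method = method),
            class = "match_config")
}

# residues usable as side-chain hosts: complete backbone, not proline, not
# flagged incomplete
.usable_sites <- function(scaffold, sites) {
  ok <- vapply(sites, function(s) {
    a <- residue_atoms(scaffold, s)
    all(c("N", "CA", "C") %in% a$atom) && a$resname[1L] != "PRO" &&
      !(s %in% (scaffold$skip_sites %||% character(0)))
  }, logical(1))
  sites[ok]
}

#' Enumerate injective role-to-site assignments
#'
#' Lazily ordered depth-first enumeration (motif-role order crossed with
#' site order), yielding every injective map from roles to usable sites.
#' Site pairs listed in `exclude_pairs` are excluded for the two main-loop
#' roles before yielding (reach pruning).
#'
#' @param motif a `catalytic_motif`.
#' @param sites character vector of candidate residue ids.
#' @param scaffold a `protein_structure` (for backbone usability checks); if
#'   `NULL`, all sites are assumed usable.
#' @param exclude_pairs optional data.frame with columns `site1`, `site2` of
#'   ordered pairs excluded for the main-loop roles.
#' @param max_assignments cap on the number returned.
#' @return list of named character vectors (role -> site).
#' @export
enumerate_assignments <- function(motif, sites, scaffold = NULL,
                                  exclude_pairs = NULL,
                                  max_assignments = 100000) {
  if (length(sites) == 0L) return(list())
  if (!is.null(scaffold)) sites <- .usable_sites(scaffold, sites)
  roles <- motif$residues$role
  if (length(sites) < length(roles)) return(list())
  mains <- tryCatch(main_loop_roles(motif), error = function(e) character(0))
  excluded <- function(assign) {
    if (is.null(exclude_pairs) || length(mains) < 2L) return(FALSE)
    s1 <- assign[[mains[1L]]]; s2 <- assign[[mains[2L]]]
    if (is.null(s1) || is.null(s2)) return(FALSE)
    any(exclude_pairs$site1 == s1 & exclude_pairs$site2 == s2)
  }
  out <- list()
  recurse <- function(assign, remaining_roles, remaining_sites) {
    if (length(out) >= max_assignments) return()
    if (length(remaining_roles) == 0L) {
      out[[length(out) + 1L]] <<- unlist(assign)
      return()
    }
    r <- remaining_roles[1L]
    for (s in remaining_sites) {
      assign[[r]] <- s
      if (excluded(assign)) next
      recurse(assign, remaining_roles[-1L], setdiff(remaining_sites, s))
      if (length(out) >= max_assignments) return()
    }
  }
  recurse(list(), roles, sites)
  out
}

# --- coordinate bookkeeping -------------------------------------------------

# named list label -> xyz for a residue's backbone (and existing atoms),
# prefixed with a role id
.role_scaffold_coords <- function(scaffold, role, site) {
  a <- residue_atoms(scaffold, site)
  out <- lapply(seq_len(nrow(a)), function(i) as.numeric(a[i, c("x", "y", "z")]))
  names(out) <- paste0(role, ":", a$atom)
  out
}

# merge placed chain coordinates (rows labelled) into a coords map
.merge_placed <- function(coords, cl, n_fixed) {
  m <- cl$coords
  labs <- rownames(m)
  for (i in seq_len(nrow(m))) {
    if (startsWith(labs[i], "VIRTUAL:")) next
    coords[[labs[i]]] <- m[i, ]
  }
  coords
}

# constraints fully resolvable in a coords map
.resolvable_constraints <- function(motif, coords) {
  cs <- motif$constraints
  if (nrow(cs) == 0L) return(integer(0))
  nm <- names(coords)
  which(vapply(seq_len(nrow(cs)), function(i) {
    atoms <- c(cs$a1[i], cs$a2[i], cs$a3[i], cs$a4[i])
    all(atoms[!is.na(atoms)] %in% nm)
  }, logical(1)))
}

.constraints_ok <- function(motif, coords, subset = NULL) {
  cs <- motif$constraints
  idx <- subset %||% seq_len(nrow(cs))
  for (i in idx) {
    d <- constraint_deviation(cs[i, , drop = FALSE], coords)
    if (d$deviation > 0) return(FALSE)
  }
  TRUE
}

# heavy placed atoms of a closed loop (drops anchors, virtual atoms and the
# terminal backbone copies)
.loop_heavy_atoms <- function(loop, cl) {
  n_fixed <- nrow(loop$fixed)
  labs <- rownames(cl$coords)
  keep <- seq_len(nrow(cl$coords)) > n_fixed &
    !startsWith(labs, "VIRTUAL:") &
    !(labs %in% paste0(loop$roles[length(loop$roles)], ":",
                       c("CA", "N", "C")))
  xyz <- cl$coords[keep, , drop = FALSE]
  els <- element_of(sub("^.*:", "", rownames(xyz)))
  list(xyz = xyz, radii = vdw_radius(els))
}

# scaffold atom groups for repulsion stages
.repulsion_sets <- function(scaffold, candidate_sites) {
  at <- scaffold$atoms[!scaffold$atoms$is_hydrogen, , drop = FALSE]
  key <- .residue_key(at$chain, at$resno, at$icode)
  is_cand <- key %in% candidate_sites
  bb_names <- c("N", "CA", "C", "O")
  backbone <- at[is_cand & at$atom %in% bb_names, , drop = FALSE]
  template <- at[!is_cand, , drop = FALSE]
  list(backbone = backbone, backbone_key = key[is_cand & at$atom %in% bb_names],
       template = template)
}

.rep_energy_vs <- function(group, set, exclude_sites, set_key, params) {
  if (length(exclude_sites) && length(set_key)) {
    keep <- !(set_key %in% exclude_sites)
    set <- set[keep, , drop = FALSE]
  }
  if (nrow(set) == 0L || nrow(group$xyz) == 0L) return(0)
  repulsion_cpp(group$xyz, group$radii,
                as.matrix(set[, c("x", "y", "z")]), set$radius,
                params$clash_onset, params$clash_scale)
}

# --- match object -----------------------------------------------------------

.new_match <- function(scaffold, motif, assignment, coords, report,
                       repulsion, closure) {
  ts_names <- motif$ts$atoms$name
  ts_pose <- do.call(rbind, lapply(ts_names, function(a)
    coords[[paste0("TS:", a)]]))
  rownames(ts_pose) <- ts_names
  structure(list(scaffold_id = scaffold$source_id,
                 site_assignment = assignment,
                 ts_pose = ts_pose,
                 coords = coords,
                 constraint_report = report,
                 repulsion = repulsion,
                 closure = closure,
                 rank_score = NA_real_),
            class = "site_match")
}

#' @export
print.site_match <- function(x, ...) {
  cat(sprintf("<site_match> %s: %s | rms dev %.3f, repulsion %.1f PEU, score %.3f\n",
              x$scaffold_id,
              paste(names(x$site_assignment), x$site_assignment,
                    sep = "=", collapse = " "),
              x$constraint_report$rms_deviation,
              sum(unlist(x$repulsion)), x$rank_score))
  invisible(x)
}

#' Rank matches
#'
#' Ascending by `w_constraint * rms_from_optimum + w_repulsion *
#' repulsion/100`.  `rms_from_optimum` is the unit-normalized RMS of the
#' full deviations of every constraint from its optimal value (Angstrom
#' terms / 1 A, degree terms / 10 deg) -- not merely the part beyond
#' tolerance, which is zero for every admitted match and therefore cannot
#' rank them.  `repulsion` is the whole-match repulsion (template + backbone
#' stages) in PEU.  Ties break by lower total repulsion, then by
#' lexicographic site ids.  Stable and idempotent.
#'
#' @param matches list of `site_match` objects.
#' @param w_constraint,w_repulsion ranking weights.
#' @return the list sorted by rank, with `rank_score` filled in.
#' @export
rank_matches <- function(matches, w_constraint = 1, w_repulsion = 1) {
  if (length(matches) == 0L) return(matches)
  rms_opt <- function(m) {
    rep <- m$constraint_report$report
    if (is.null(rep) || nrow(rep) == 0L) return(0)
    diff <- ifelse(rep$kind == "distance", rep$measured - rep$optimal,
                   wrap_angle(rep$measured - rep$optimal))
    norm <- ifelse(rep$kind == "distance", 1, 10)
    sqrt(mean((diff / norm)^2))
  }
  score <- vapply(matches, function(m) {
    rep_tot <- (m$repulsion$match_vs_template %||% 0) +
      (m$repulsion$match_vs_backbone %||% 0)
    w_constraint * rms_opt(m) + w_repulsion * rep_tot / 100
  }, numeric(1))
  rep_all <- vapply(matches, function(m) sum(unlist(m$repulsion)), numeric(1))
  sites <- vapply(matches, function(m)
    paste(m$site_assignment, collapse = "|"), character(1))
  ord <- order(score, rep_all, sites)
  out <- matches[ord]
  for (i in seq_along(out)) out[[i]]$rank_score <- score[ord][i]
  out
}

#' No-fit TS RMSD of a match against a reference pose
#'
#' Heavy-atom RMSD in the scaffold frame (no superposition), with atom
#' correspondence by TS atom name.
#'
#' @param match a `site_match`.
#' @param reference_ts n x 3 matrix with row names giving TS atom names.
#' @return RMSD in Angstrom.
#' @export
ts_rmsd_vs_reference <- function(match, reference_ts) {
  ref <- as.matrix(reference_ts)
  idx <- match(rownames(ref), rownames(match$ts_pose))
  if (anyNA(idx))
    stop("TS atom name mismatch: ",
         paste(rownames(ref)[is.na(idx)], collapse = ", "), call. = FALSE)
  rmsd_nofit(match$ts_pose[idx, , drop = FALSE], ref)
}

# --- the full matching pipeline for one scaffold ---------------------------

#' Match a motif onto one scaffold
#'
#' For every surviving role-to-site assignment: build the kinematic loops,
#' close the main loop from multiple starts, deduplicate, check the
#' constraints evaluable at each stage, prune by repulsion, close side loops,
#' place backbone roles, and assemble ranked matches.  The result is fully
#' deterministic given the scaffold, motif, config and seed.  An empty list
#' is a valid outcome (the scaffold is discarded).
#'
#' @param scaffold a `protein_structure` (hydrogens recommended for
#'   backbone-role constraints that reference amide hydrogens).
#' @param motif a `catalytic_motif`.
#' @param config a [match_config()].
#' @param sites candidate residue ids; default: every usable residue.
#' @return list of `site_match` objects, ranked.
#' @export
match_scaffold <- function(scaffold, motif, config = match_config(),
                           sites = NULL) {
  sites <- .usable_sites(scaffold, sites %||% residue_ids(scaffold))
  roles <- motif$residues$role
  if (length(sites) < length(roles)) return(list())
  mains <- main_loop_roles(motif)
  side_roles <- setdiff(roles[motif$residues$via == "side_chain"], mains)
  bb_roles <- roles[motif$residues$via == "backbone"]
  # "anchor" backbone roles constrain only TS atoms (plus their own
  # backbone); they are used to guide main-loop refinement
  anchor_specs <- lapply(stats::setNames(bb_roles, bb_roles), function(r)
    .anchor_spec(motif, r))
  is_anchor <- vapply(bb_roles, function(r) {
    if (is.null(anchor_specs[[r]])) return(FALSE)
    cs <- motif$constraints
    for (i in seq_len(nrow(cs))) {
      at <- c(cs$a1[i], cs$a2[i], cs$a3[i], cs$a4[i])
      at <- at[!is.na(at)]
      rr <- vapply(at, function(a) .parse_atom_ref(a)$role, character(1))
      if (r %in% rr && !all(rr %in% c(r, "TS"))) return(FALSE)
    }
    TRUE
  }, logical(1))
  anchor_roles <- bb_roles[is_anchor]
  other_bb_roles <- bb_roles[!is_anchor]
  params <- config$pruning
  rsets <- .repulsion_sets(scaffold, sites)
  reach_cache <- new.env(parent = emptyenv())
  side_loop_cache <- new.env(parent = emptyenv())
  matches <- list()

  add_backbone_roles <- function(coords, used, rem) {
    # assign the remaining backbone roles injectively; every constraint
    # mentioning a role must be checkable and satisfied at its site
    if (length(rem) == 0L)
      return(list(list(coords = coords, ext = character(0))))
    role <- rem[1L]
    found <- list()
    for (s in setdiff(sites, used)) {
      cand <- tryCatch(.role_scaffold_coords(scaffold, role, s),
                       error = function(e) NULL)
      if (is.null(cand)) next
      if (residue_name(scaffold, s) == "PRO") next
      trial <- utils::modifyList(coords, cand)
      cs <- motif$constraints
      touches <- vapply(seq_len(nrow(cs)), function(i)
        any(grepl(paste0("^", role, ":"),
                  c(cs$a1[i], cs$a2[i], cs$a3[i], cs$a4[i]))), logical(1))
      idx <- which(touches)
      if (length(idx) == 0L) next   # role takes part in no constraint
      if (!all(idx %in% .resolvable_constraints(motif, trial))) next
      if (!.constraints_ok(motif, trial, idx)) next
      .dbg("    bb role %s -> %s ok", role, s)
      deeper <- add_backbone_roles(trial, c(used, s), rem[-1L])
      for (d in deeper) {
        d$ext <- c(stats::setNames(s, role), d$ext)
        found[[length(found) + 1L]] <- d
      }
      if (length(found) >= config$side_branch) break
    }
    found
  }

  # backbone roles that hang off a given side role via a distance constraint
  .dep_bb_roles <- function(role) {
    out <- list()
    for (r in other_bb_roles) {
      links <- .role_dist_constraints(motif, r)
      for (l in links) {
        pr <- .parse_atom_ref(l$other)
        if (pr$role == role) {
          out[[r]] <- list(self_atom = l$self_atom, other_atom = pr$atom,
                           d = motif$constraints$optimal[l$i])
          break
        }
      }
    }
    out
  }

  place_side_roles <- function(coords, used, k, done_bb, energies) {
    if (k > length(side_roles)) {
      res <- add_backbone_roles(coords, used,
                                setdiff(other_bb_roles, done_bb))
      return(lapply(res, function(r)
        list(coords = r$coords, ext = r$ext, used = used,
             energies = energies)))
    }
    role <- side_roles[k]
    deps <- .dep_bb_roles(role)
    opts <- list()
    for (s in setdiff(sites, used)) {
      loop <- tryCatch(build_side_loop(motif, role, s, scaffold, coords),
                       error = function(e) NULL)
      if (is.null(loop)) next
      # cheap reach check: partner-to-anchor distance vs chain extent
      span <- sqrt(sum((as.numeric(loop$targets[1, c("x", "y", "z")]) -
                          loop$start_ca)^2))
      rkey <- paste("side", role, loop$aas)
      if (is.null(reach_cache[[rkey]]))
        reach_cache[[rkey]] <- max_loop_length(loop, n_starts = 6,
                                               seed = config$seed)
      if (reach_cache[[rkey]] + params$reach_margin < span) next
      tol_side <- config$closure_tolerance
      sols <- multistart_close(loop, tolerance = tol_side,
                               max_samples = config$side_samples,
                               seed = config$seed,
                               dedup_rmsd = params$dedup_rmsd,
                               method = config$method)
      # when the partner atom is a donor with a known hydrogen, also close
      # against the acceptor's ideal position on the donor-H axis (this puts
      # the hydrogen-bond geometry inside the closure objective)
      ftgt <- .partner_h_target(motif, loop, coords)
      if (!is.null(ftgt)) {
        loopf <- loop
        loopf$targets <- rbind(loopf$targets, ftgt)
        sols <- c(sols, multistart_close(loopf, tolerance = tol_side,
                                         max_samples = config$side_samples,
                                         seed = config$seed,
                                         dedup_rmsd = params$dedup_rmsd,
                                         method = config$method))
      }
      accept <- function(cl, bb_ext) {
        trial <- .merge_placed(coords, cl, nrow(loop$fixed))
        for (r in names(bb_ext))
          trial <- utils::modifyList(trial,
            .role_scaffold_coords(scaffold, r, bb_ext[[r]]))
        idx <- setdiff(.resolvable_constraints(motif, trial),
                       .resolvable_constraints(motif, coords))
        if (isTRUE(getOption("sitematch.debug"))) {
          for (i in idx) {
            dv <- constraint_deviation(motif$constraints[i, , drop = FALSE],
                                       trial)
            if (dv$deviation > 0)
              .dbg("      viol c%d %s %s-%s meas %.2f dev %.2f", i,
                   motif$constraints$kind[i], motif$constraints$a1[i],
                   motif$constraints$a2[i], dv$measured, dv$deviation)
          }
        }
        if (!.constraints_ok(motif, trial, idx)) return(NULL)
        grp <- .loop_heavy_atoms(loop, cl)
        e_bb <- .rep_energy_vs(grp, rsets$backbone,
                               c(used, s, unname(bb_ext)),
                               rsets$backbone_key, params)
        if (prune_by_repulsion("side_loop", e_bb, params) == "prune")
          return(NULL)
        list(site = s, cl = cl, trial = trial, e = e_bb, bb_ext = bb_ext)
      }
      for (cl in sols) {
        if (length(deps) == 0L) {
          o <- accept(cl, character(0))
          if (!is.null(o)) opts[[length(opts) + 1L]] <- o
          next
        }
        # the plain solution may satisfy a donor directly
        o <- accept(cl, character(0))
        if (!is.null(o)) opts[[length(opts) + 1L]] <- o
      }
      if (length(deps) > 0L) {
        # donor-guided closure: for each candidate donor site of the first
        # dependent backbone role, close the side loop jointly against the
        # partner atom and the donor's ideal hydrogen-bond point
        r <- names(deps)[1L]
        sp <- deps[[r]]
        xrow <- match(paste0(role, ":", sp$other_atom), loop$labels)
        ppos <- as.numeric(loop$targets[1L, c("x", "y", "z")])
        if (!is.na(xrow)) {
          for (sd in setdiff(sites, c(used, s))) {
            sx <- tryCatch(residue_xyz(scaffold, sd, c("N", "HN")),
                           error = function(e) NULL)
            if (is.null(sx)) next
            tgt <- sx[1, ] + sp$d * .unit(sx[2, ] - sx[1, ])
            if (sqrt(sum((tgt - ppos)^2)) > 6.5) next
            loop2 <- loop
            loop2$targets <- rbind(loop2$targets,
              data.frame(row = xrow, x = tgt[1], y = tgt[2], z = tgt[3],
                         w = 1, label = "donor"))
            sols2 <- multistart_close(loop2, tolerance = tol_side,
                                      max_samples = config$side_samples,
                                      seed = config$seed,
                                      dedup_rmsd = params$dedup_rmsd,
                                      method = config$method)
            for (cl2 in sols2) {
              o <- accept(cl2, stats::setNames(sd, r))
              if (!is.null(o)) opts[[length(opts) + 1L]] <- o
            }
          }
        }
      }
    }
    .dbg("  side role %s: %d feasible placements (%d donor-guided)", role,
         length(opts),
         sum(vapply(opts, function(o) length(o$bb_ext) > 0, logical(1))))
    if (length(opts) == 0L) return(list())
    escore <- vapply(opts, `[[`, numeric(1), "e")
    guided <- vapply(opts, function(o) length(o$bb_ext) > 0, logical(1))
    opts <- opts[order(escore)]
    guided <- guided[order(escore)]
    # keep the best few of each kind: donor-guided options already satisfy a
    # dependent backbone role and must not be crowded out
    keep <- c(which(guided)[seq_len(min(sum(guided), config$side_branch))],
              which(!guided)[seq_len(min(sum(!guided), config$side_branch))])
    opts <- opts[sort(keep)]
    found <- list()
    for (o in opts) {
      en <- energies
      en[[paste0("side_", role)]] <- o$e
      deeper <- place_side_roles(o$trial, c(used, o$site, unname(o$bb_ext)),
                                 k + 1L, c(done_bb, names(o$bb_ext)), en)
      for (d in deeper) {
        d$ext <- c(stats::setNames(o$site, role), o$bb_ext, d$ext)
        found[[length(found) + 1L]] <- d
      }
    }
    found
  }

  for (s1 in sites) for (s2 in setdiff(sites, s1)) {
    main <- tryCatch(build_main_loop(motif, mains[1L], mains[2L], s1, s2,
                                     scaffold),
                     error = function(e) NULL)
    if (is.null(main)) next
    rkey <- paste("main", paste(main$aas, collapse = "-"))
    if (is.null(reach_cache[[rkey]]))
      reach_cache[[rkey]] <- max_loop_length(main, seed = config$seed)
    if (prune_by_reach(main, params, reach_cache[[rkey]]) == "prune") next
    sols <- multistart_close(main, tolerance = config$closure_tolerance,
                             max_samples = config$max_samples,
                             seed = config$seed,
                             dedup_rmsd = params$dedup_rmsd,
                             method = config$method)
    if (length(sols) == 0L) next
    .dbg("pair %s-%s: %d closed main solutions", s1, s2, length(sols))
    base_coords <- c(.role_scaffold_coords(scaffold, mains[1L], s1),
                     .role_scaffold_coords(scaffold, mains[2L], s2))
    # keep only the least-clashing distinct solutions per pair
    surv <- list()
    for (cl in sols) {
      coords <- .merge_placed(base_coords, cl, nrow(main$fixed))
      idx <- .resolvable_constraints(motif, coords)
      if (!.constraints_ok(motif, coords, idx)) next
      grp <- .loop_heavy_atoms(main, cl)
      e_main <- .rep_energy_vs(grp, rsets$backbone, c(s1, s2),
                               rsets$backbone_key, params)
      if (prune_by_repulsion("main_loop", e_main, params) == "prune") next
      surv[[length(surv) + 1L]] <- list(cl = cl, coords = coords,
                                        e_main = e_main)
    }
    if (length(surv) > 32L) {
      e <- vapply(surv, `[[`, numeric(1), "e_main")
      surv <- surv[order(e)][seq_len(32L)]
    }
    .dbg("pair %s-%s: %d survive early checks", s1, s2, length(surv))
    # anchor-role refinement: choose donor sites for the TS-anchoring
    # backbone roles and re-close the main loop toward their ideal
    # hydrogen-bond points; solutions that then violate any resolvable
    # constraint are dropped (pruning iii)
    refined <- list()
    for (sv in surv) {
      if (length(anchor_roles) == 0L) {
        refined[[length(refined) + 1L]] <- c(sv, list(ext = character(0)))
        next
      }
      combos <- list(list(ext = character(0), extra = NULL))
      ok_combo <- TRUE
      for (role in anchor_roles) {
        spec <- anchor_specs[[role]]
        arow <- match(paste0("TS:", spec$ts_atom), main$labels)
        a_cur <- sv$cl$coords[arow, ]
        nxt <- list()
        for (combo in combos) {
          for (s in setdiff(sites, c(s1, s2, combo$ext))) {
            atoms_need <- c(spec$x_atom,
                            if (!is.na(spec$h_atom)) spec$h_atom)
            sx <- tryCatch(residue_xyz(scaffold, s, atoms_need),
                           error = function(e) NULL)
            if (is.null(sx)) next
            tgt <- if (!is.na(spec$h_atom))
              sx[1, ] + spec$d * .unit(sx[2, ] - sx[1, ])
            else a_cur + (sx[1, ] - a_cur) *
              (1 - spec$d / max(1e-6, sqrt(sum((sx[1, ] - a_cur)^2))))
            if (sqrt(sum((a_cur - tgt)^2)) > 4) next
            donors <- combo$donors %||% list()
            donors[[paste0(role, ":", spec$x_atom)]] <- sx[1, ]
            nxt[[length(nxt) + 1L]] <- list(
              ext = c(combo$ext, stats::setNames(s, role)),
              donors = donors,
              extra = rbind(combo$extra,
                            data.frame(row = arow, x = tgt[1], y = tgt[2],
                                       z = tgt[3], w = 1)))
            if (length(nxt) >= 12L) break
          }
          if (length(nxt) >= 12L) break
        }
        combos <- nxt
        if (length(combos) == 0L) { ok_combo <- FALSE; break }
      }
      if (!ok_combo) next
      for (combo in combos) {
        # one refinement per neighbour-direction variant (cone
        # intersections are two-fold degenerate)
        variants <- list(combo$extra)
        for (ar in unique(combo$extra$row)) {
          rows <- combo$extra[combo$extra$row == ar, , drop = FALSE]
          a_tgt <- c(mean(rows$x), mean(rows$y), mean(rows$z))
          a_atom <- sub("^TS:", "", main$labels[ar])
          nts <- .neighbour_target(motif, main, sv$cl, a_atom, a_tgt,
                                   combo$donors %||% list())
          if (!is.null(nts))
            variants <- unlist(lapply(variants, function(v)
              lapply(nts, function(nt) rbind(v, nt))), recursive = FALSE)
        }
        for (extra in variants) {
          rf <- refine_loop(main, sv$cl, extra,
                            tolerance = config$closure_tolerance)
          if (!rf$converged) next
          coords2 <- .merge_placed(base_coords, rf, nrow(main$fixed))
          for (role in names(combo$ext))
            coords2 <- utils::modifyList(coords2,
              .role_scaffold_coords(scaffold, role, combo$ext[[role]]))
          idx <- .resolvable_constraints(motif, coords2)
          if (!.constraints_ok(motif, coords2, idx)) next
          grp2 <- .loop_heavy_atoms(main, rf)
          e2 <- .rep_energy_vs(grp2, rsets$backbone,
                               c(s1, s2, unname(combo$ext)),
                               rsets$backbone_key, params)
          if (prune_by_repulsion("main_loop", e2, params) == "prune") next
          refined[[length(refined) + 1L]] <-
            list(cl = rf, coords = coords2, e_main = e2, ext = combo$ext)
        }
      }
    }
    # deduplicate refined solutions by TS pose and keep the ones closest
    # to the constraint optima
    if (length(refined) > 1L) {
      tsrows <- which(startsWith(main$labels, "TS:"))
      rms_opt_of <- function(sv) {
        idx <- .resolvable_constraints(motif, sv$coords)
        if (length(idx) == 0L) return(0)
        devs <- vapply(idx, function(i) {
          cc <- motif$constraints[i, , drop = FALSE]
          dv <- constraint_deviation(cc, sv$coords)
          diff <- if (cc$kind == "distance") dv$measured - cc$optimal
                  else wrap_angle(dv$measured - cc$optimal)
          diff / if (cc$kind == "distance") 1 else 10
        }, numeric(1))
        sqrt(mean(devs^2))
      }
      sc <- vapply(refined, rms_opt_of, numeric(1))
      refined <- refined[order(sc)]
      kept <- list()
      for (sv in refined) {
        ts_xyz <- sv$cl$coords[tsrows, , drop = FALSE]
        dup <- FALSE
        for (k in kept)
          if (rmsd_nofit(ts_xyz, k$cl$coords[tsrows, , drop = FALSE]) < 0.3 &&
              identical(sort(unname(k$ext)), sort(unname(sv$ext)))) {
            dup <- TRUE
            break
          }
        if (!dup) kept[[length(kept) + 1L]] <- sv
        if (length(kept) >= 8L) break
      }
      refined <- kept
    }
    .dbg("pair %s-%s: %d refined solutions", s1, s2, length(refined))
    ridx <- 0L
    for (sv in refined) {
      ridx <- ridx + 1L
      cl <- sv$cl
      coords <- sv$coords
      e_main <- sv$e_main
      full <- place_side_roles(coords, c(s1, s2, unname(sv$ext)), 1L,
                               character(0), list(main = e_main))
      .dbg("  refined #%d: %d full assemblies", ridx, length(full))
      for (f in full) {
        assignment <- c(stats::setNames(c(s1, s2), mains), sv$ext, f$ext)
        assignment <- assignment[roles]
        report <- tryCatch(check_match_constraints(motif, f$coords),
                           error = function(e) NULL)
        if (is.null(report) || !report$all_satisfied) {
          .dbg("  final constraint check failed (%s)",
               if (is.null(report)) "unresolved" else "violation")
          next
        }
        # whole-match repulsion: all placed side-chain + TS heavy atoms
        placed_labs <- names(f$coords)
        is_placed <- startsWith(placed_labs, "TS:") |
          vapply(placed_labs, function(l) {
            pr <- .parse_atom_ref(l)
            pr$role %in% c(mains, side_roles) &&
              !(pr$atom %in% c("N", "CA", "C", "O", "HN", "HA")) &&
              element_of(pr$atom) != "H"
          }, logical(1))
        xyz <- do.call(rbind, f$coords[is_placed])
        grp_all <- list(xyz = xyz,
                        radii = vdw_radius(element_of(
                          sub("^.*:", "", placed_labs[is_placed]))))
        own_sites <- unname(assignment[c(mains, side_roles)])
        e_tpl <- .rep_energy_vs(grp_all, rsets$template, character(0),
                                NULL, params)
        e_bb <- .rep_energy_vs(grp_all, rsets$backbone, own_sites,
                               rsets$backbone_key, params)
        if (prune_by_repulsion("match_vs_template", e_tpl, params) == "prune") {
          .dbg("  pruned: match-vs-template %.1f PEU", e_tpl)
          next
        }
        if (prune_by_repulsion("match_vs_backbone", e_bb, params) == "prune") {
          .dbg("  pruned: match-vs-backbone %.1f PEU", e_bb)
          next
        }
        rep <- f$energies
        rep$match_vs_template <- e_tpl
        rep$match_vs_backbone <- e_bb
        matches[[length(matches) + 1L]] <-
          .new_match(scaffold, motif, assignment, f$coords, report, rep,
                     list(main_deviation = cl$closure_deviation))
        if (length(matches) >= config$max_matches) break
      }
      if (length(matches) >= config$max_matches) break
    }
    if (length(matches) >= config$max_matches) break
  }
  rank_matches(matches, config$w_constraint, config$w_repulsion)
}

# additional refinement targets derived from donor-approach angle
# constraints (X, A, B) with A, B TS atoms: given the anchored position of
# the acceptor A, find the direction of its TS neighbour B that best meets
# every angle optimum (projected-gradient on the unit sphere, warm-started
# from the current direction) and emit a point target for B
.neighbour_target <- function(motif, main, cl, a_atom, a_tgt, donor_xyz_list) {
  cs <- motif$constraints
  specs <- list()
  for (i in seq_len(nrow(cs))) {
    if (cs$kind[i] != "angle") next
    pr <- lapply(c(cs$a1[i], cs$a2[i], cs$a3[i]), .parse_atom_ref)
    if (pr[[2L]]$role == "TS" && pr[[2L]]$atom == a_atom &&
        pr[[3L]]$role == "TS") {
      x <- donor_xyz_list[[paste0(pr[[1L]]$role, ":", pr[[1L]]$atom)]]
      if (is.null(x)) next
      specs[[length(specs) + 1L]] <- list(u = .unit(x - a_tgt),
                                          cth = cos(cs$optimal[i] * pi / 180),
                                          b_atom = pr[[3L]]$atom)
    }
  }
  if (length(specs) == 0L) return(NULL)
  b_atom <- specs[[1L]]$b_atom
  specs <- Filter(function(s) s$b_atom == b_atom, specs)
  brow <- match(paste0("TS:", b_atom), main$labels)
  arow <- match(paste0("TS:", a_atom), main$labels)
  if (is.na(brow) || is.na(arow)) return(NULL)
  r <- sqrt(sum((cl$coords[brow, ] - cl$coords[arow, ])^2))
  mk <- function(d) data.frame(row = brow, x = a_tgt[1] + r * d[1],
                               y = a_tgt[2] + r * d[2],
                               z = a_tgt[3] + r * d[3], w = 1)
  if (length(specs) >= 2L) {
    # two angle cones intersect in (at most) two directions: return both
    uA <- specs[[1L]]$u; uB <- specs[[2L]]$u
    g <- sum(uA * uB)
    det <- 1 - g^2
    if (det > 1e-6) {
      al <- (specs[[1L]]$cth - g * specs[[2L]]$cth) / det
      be <- (specs[[2L]]$cth - g * specs[[1L]]$cth) / det
      nrm2 <- 1 - (al^2 + be^2 + 2 * al * be * g)
      base <- al * uA + be * uB
      if (nrm2 > 0) {
        n <- .cross3(uA, uB) / sqrt(det)
        return(list(mk(.unit(base + sqrt(nrm2) * n)),
                    mk(.unit(base - sqrt(nrm2) * n))))
      }
      return(list(mk(.unit(base))))
    }
  }
  # single cone: projected-gradient from the current direction
  d <- .unit(cl$coords[brow, ] - cl$coords[arow, ])
  for (it in seq_len(25L)) {
    g <- c(0, 0, 0)
    for (s in specs) g <- g + 2 * (sum(d * s$u) - s$cth) * s$u
    d <- .unit(d - 0.3 * g)
  }
  list(mk(d))
}

# ideal-point target for a side loop's functional atom: when the partner
# atom carries a donor hydrogen (per the hydrogen topology of its amino
# acid), the acceptor belongs on the extension of that D-H bond at the
# link-constraint distance
.partner_h_target <- function(motif, loop, coords) {
  pr <- .parse_atom_ref(loop$partner)
  if (pr$role == "TS") return(NULL)
  i <- match(pr$role, motif$residues$role)
  if (is.na(i)) return(NULL)
  aa <- motif$residues$aa[i]
  hy <- hydrogen_topology()
  hrow <- hy[hy$res == aa & hy$r3 == pr$atom, , drop = FALSE]
  if (nrow(hrow) == 0L) return(NULL)
  refs <- lapply(c(hrow$r1[1L], hrow$r2[1L], hrow$r3[1L]), function(a)
    coords[[paste0(pr$role, ":", a)]])
  if (any(vapply(refs, is.null, logical(1)))) return(NULL)
  h <- internal_to_cartesian(refs[[1L]], refs[[2L]], refs[[3L]],
                             hrow$len[1L], hrow$ang[1L], hrow$tor[1L])
  p <- coords[[loop$partner]]
  f_idx <- match(paste0(loop$roles, ":", loop$self_atom), loop$labels)
  if (is.na(f_idx)) return(NULL)
  # the frozen pseudo-bond length is the link constraint's optimal distance
  d <- loop$zmat[f_idx - nrow(loop$fixed), "len"]
  tgt <- p + d * .unit(h - p)
  data.frame(row = f_idx, x = tgt[1], y = tgt[2], z = tgt[3], w = 1,
             label = "fpoint", stringsAsFactors = FALSE)
}

# distance-to-TS specification of a backbone role: the constrained backbone
# atom, the TS atom, the optimal distance and (when an angle constraint
# names it) the donor hydrogen defining the ideal approach direction
.anchor_spec <- function(motif, role) {
  cs <- motif$constraints
  for (i in seq_len(nrow(cs))) {
    if (cs$kind[i] != "distance") next
    ends <- c(cs$a1[i], cs$a2[i])
    rr <- vapply(ends, function(a) .parse_atom_ref(a)$role, character(1))
    if (!(role %in% rr && "TS" %in% rr)) next
    x_atom <- .parse_atom_ref(ends[rr == role][1L])$atom
    ts_atom <- .parse_atom_ref(ends[rr == "TS"][1L])$atom
    h_atom <- NA_character_
    for (j in seq_len(nrow(cs))) {
      if (cs$kind[j] != "angle") next
      pr <- lapply(c(cs$a1[j], cs$a2[j], cs$a3[j]), .parse_atom_ref)
      if (pr[[1L]]$role == role && pr[[2L]]$role == role &&
          pr[[3L]]$role == "TS" && pr[[3L]]$atom == ts_atom &&
          pr[[1L]]$atom == x_atom) {
        h_atom <- pr[[2L]]$atom
        break
      }
    }
    return(list(i = i, x_atom = x_atom, ts_atom = ts_atom,
                d = cs$optimal[i], h_atom = h_atom))
  }
  NULL
}

.dbg <- function(fmt, ...) {
  if (isTRUE(getOption("sitematch.debug")))
    message(sprintf(fmt, ...))
  invisible(NULL)
}
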