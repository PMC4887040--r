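# Catalytic motifs: residue roles (catalytic / stabilizing / TS-binding),
# the transition-state model, and the geometric constraint set with optima
# and tolerances.  File format is YAML; bit-exact examples ship under
# inst/extdata/motifs.

.CONSTRAINT_KINDS <- c("distance", "angle", "improper_dihedral")
.ROLE_CLASSES <- c("catalytic", "stabilizes_catalytic", "stabilizes_TS")

#' Read a transition-state model
#'
#' A TS model is a set of atoms with partial charges plus a Z-matrix of
#' internal coordinates that reconstructs the geometry, and a list of
#' rotatable torsions.  Z-matrix rows after the third must reference TS atoms
#' only, so the tail of the molecule is rigid relative to its first three
#' atoms unless a torsion is declared rotatable.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return a `ts_model` with `atoms` (name, element, charge tables for both
#'   charge sets), `zmatrix`, `rotatable`, `xyz` (local-frame coordinates).
#' @export
read_ts_model <- function(path) {
  spec <- if (is.character(path)) yaml::read_yaml(path) else path
  atoms <- do.call(rbind, lapply(spec$atoms, function(a)
    data.frame(name = a$name, element = a$element,
               charge_charmm = as.numeric(a$charge %||% 0),
               charge_parse = as.numeric(a$charge_parse %||% a$charge %||% 0),
               stringsAsFactors = FALSE)))
  zm <- spec$zmatrix
  if (length(zm) != nrow(atoms))
    stop("TS zmatrix must have one row per atom", call. = FALSE)
  nm <- atoms$name
  for (i in seq_along(zm)) {
    refs <- unlist(zm[[i]]$ref)
    if (i == 1L && length(refs) != 0L)
      stop("TS zmatrix root row must have no refs", call. = FALSE)
    if (i == 2L && length(refs) != 1L)
      stop("TS zmatrix row 2 must have one ref", call. = FALSE)
    if (i == 3L && length(refs) != 2L)
      stop("TS zmatrix row 3 must have two refs", call. = FALSE)
    if (i > 3L && length(refs) != 3L)
      stop("TS zmatrix rows beyond 3 must have three refs", call. = FALSE)
    bad <- setdiff(refs, nm[seq_len(i - 1L)])
    if (length(bad))
      stop("TS zmatrix row ", i, " references unplaced atom(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  ts <- structure(list(name = spec$name %||% "ts", atoms = atoms,
                       zmatrix = zm,
                       rotatable = spec$rotatable %||% list(),
                       charge_set = spec$charge_set %||% "charmm"),
                  class = "ts_model")
  for (rt in ts$rotatable)
    if (!all(unlist(rt) %in% nm))
      stop("rotatable torsion references unknown TS atom(s)", call. = FALSE)
  ts$xyz <- ts_local_coords(ts)
  ts
}

#' Local-frame Cartesian coordinates of a TS model
#' @param ts a `ts_model`.
#' @return n x 3 matrix, rows named by atom.
#' @export
ts_local_coords <- function(ts) {
  zm <- ts$zmatrix
  nm <- ts$atoms$name
  xyz <- matrix(NA_real_, length(zm), 3, dimnames = list(nm, NULL))
  xyz[1L, ] <- c(0, 0, 0)
  if (length(zm) >= 2L) {
    r <- zm[[2L]]
    xyz[2L, ] <- c(as.numeric(r$length), 0, 0) + xyz[match(r$ref[[1L]], nm), ]
  }
  if (length(zm) >= 3L) {
    r <- zm[[3L]]
    b <- xyz[match(r$ref[[1L]], nm), ]  # angle vertex neighbour
    c_ <- xyz[match(r$ref[[2L]], nm), ] # bonded atom
    # place in the xy-plane: synthesize a dummy out-of-plane reference
    dummy <- b + c(0, 0, 1)
    xyz[3L, ] <- internal_to_cartesian(dummy, b, c_, as.numeric(r$length),
                                       as.numeric(r$angle), 90)
  }
  if (length(zm) > 3L) {
    for (i in 4:length(zm)) {
      r <- zm[[i]]
      idx <- match(unlist(r$ref), nm)
      xyz[i, ] <- internal_to_cartesian(xyz[idx[1L], ], xyz[idx[2L], ],
                                        xyz[idx[3L], ], as.numeric(r$length),
                                        as.numeric(r$angle), as.numeric(r$torsion))
    }
  }
  xyz
}

#' TS atom table in a given pose
#'
#' Expands a `ts_model` plus a pose (coordinates for its atoms) into the
#' atom-table layout used by the energy model and repacking.
#'
#' @param ts a `ts_model`.
#' @param pose n x 3 matrix with row names matching the TS atom names
#'   (default: the local-frame coordinates).
#' @param charge_set `"charmm"` or `"parse"`.
#' @return data.frame with columns `atom`, `element`, `x`, `y`, `z`,
#'   `charge`, `radius`, `is_hydrogen`.
#' @export
ts_atom_table <- function(ts, pose = NULL, charge_set = ts$charge_set) {
  pose <- pose %||% ts$xyz
  idx <- match(ts$atoms$name, rownames(pose))
  if (anyNA(idx)) stop("pose lacks TS atom(s): ",
                       paste(ts$atoms$name[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  q <- if (identical(charge_set, "parse")) ts$atoms$charge_parse
       else ts$atoms$charge_charmm
  data.frame(atom = ts$atoms$name, element = ts$atoms$element,
             x = pose[idx, 1], y = pose[idx, 2], z = pose[idx, 3],
             charge = q, radius = vdw_radius(ts$atoms$element),
             is_hydrogen = ts$atoms$element == "H",
             stringsAsFactors = FALSE)
}

.parse_atom_ref <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("atom reference must be 'ROLE:ATOM' or 'TS:ATOM': ", s, call. = FALSE)
  list(role = parts[1L], atom = parts[2L])
}

#' Parse a catalytic motif file
#'
#' @param path YAML motif file path, or parsed list.  A relative `ts:` entry
#'   is resolved against the motif file's directory.
#' @return a `catalytic_motif`: `residues` (role, aa, class, via),
#'   `constraints` (kind, atoms, optimal, tolerance), `ts`, `name`.
#' @export
parse_motif <- function(path) {
  dir <- "."
  if (is.character(path)) {
    dir <- dirname(path)
    spec <- yaml::read_yaml(path)
  } else spec <- path
  residues <- do.call(rbind, lapply(spec$residues, function(r) {
    cls <- r$class
    if (!cls %in% .ROLE_CLASSES)
      stop("unknown role class '", cls, "' for role ", r$role, call. = FALSE)
    via <- r$via %||% "side_chain"
    if (!via %in% c("side_chain", "backbone"))
      stop("unknown interaction mode '", via, "'", call. = FALSE)
    data.frame(role = r$role, aa = toupper(r$aa %||% "ANY"), class = cls,
               via = via, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(residues$role))
    stop("duplicate role ids in motif", call. = FALSE)
  ts <- spec$ts
  if (is.character(ts)) {
    tsp <- if (file.exists(ts)) ts else file.path(dir, ts)
    ts <- read_ts_model(tsp)
  } else if (!inherits(ts, "ts_model")) ts <- read_ts_model(ts)
  known <- c(residues$role, "TS")
  constraints <- do.call(rbind, lapply(spec$constraints, function(cc) {
    if (!cc$kind %in% .CONSTRAINT_KINDS)
      stop("unknown constraint kind: ", cc$kind, call. = FALSE)
    atoms <- unlist(cc$atoms)
    need <- c(distance = 2L, angle = 3L, improper_dihedral = 4L)[[cc$kind]]
    if (length(atoms) != need)
      stop(cc$kind, " constraint needs ", need, " atom refs", call. = FALSE)
    for (a in atoms) {
      ref <- .parse_atom_ref(a)
      if (!ref$role %in% known)
        stop("constraint references undeclared role '", ref$role, "'",
             call. = FALSE)
      if (ref$role == "TS" && !ref$atom %in% ts$atoms$name)
        stop("constraint references unknown TS atom '", ref$atom, "'",
             call. = FALSE)
    }
    tol <- as.numeric(cc$tolerance)
    if (is.na(tol) || tol < 0) stop("tolerance must be >= 0", call. = FALSE)
    data.frame(kind = cc$kind,
               a1 = atoms[1L], a2 = atoms[2L],
               a3 = if (need >= 3L) atoms[3L] else NA_character_,
               a4 = if (need >= 4L) atoms[4L] else NA_character_,
               optimal = as.numeric(cc$optimal), tolerance = tol,
               stringsAsFactors = FALSE)
  }))
  structure(list(name = spec$name %||% "motif", residues = residues,
                 ts = ts, constraints = constraints),
            class = "catalytic_motif")
}

#' @export
print.catalytic_motif <- function(x, ...) {
  cat(sprintf("<catalytic_motif> %s: %d roles (%s), %d constraints, TS '%s' (%d atoms)\n",
              x$name, nrow(x$residues),
              paste(x$residues$role, collapse = ", "),
              nrow(x$constraints), x$ts$name, nrow(x$ts$atoms)))
  invisible(x)
}

#' Serialize a motif back to YAML
#' @param motif a `catalytic_motif`.
#' @param file output path.
#' @param ts_file optional path to write the TS model separately; by default
#'   the TS is embedded inline.
#' @return `file`, invisibly.
#' @export
write_motif <- function(motif, file, ts_file = NULL) {
  ts_spec <- list(name = motif$ts$name, charge_set = motif$ts$charge_set,
                  atoms = lapply(seq_len(nrow(motif$ts$atoms)), function(i)
                    list(name = motif$ts$atoms$name[i],
                         element = motif$ts$atoms$element[i],
                         charge = motif$ts$atoms$charge_charmm[i],
                         charge_parse = motif$ts$atoms$charge_parse[i])),
                  zmatrix = motif$ts$zmatrix,
                  rotatable = motif$ts$rotatable)
  if (!is.null(ts_file)) {
    yaml::write_yaml(ts_spec, ts_file)
    ts_entry <- basename(ts_file)
  } else ts_entry <- ts_spec
  cs <- motif$constraints
  spec <- list(
    name = motif$name,
    ts = ts_entry,
    residues = lapply(seq_len(nrow(motif$residues)), function(i)
      list(role = motif$residues$role[i], aa = motif$residues$aa[i],
           class = motif$residues$class[i], via = motif$residues$via[i])),
    constraints = lapply(seq_len(nrow(cs)), function(i) {
      atoms <- c(cs$a1[i], cs$a2[i], cs$a3[i], cs$a4[i])
      list(kind = cs$kind[i], atoms = as.list(atoms[!is.na(atoms)]),
           optimal = cs$optimal[i], tolerance = cs$tolerance[i])
    }))
  yaml::write_yaml(spec, file)
  invisible(file)
}

#' Restrict a complex motif to its catalytic roles
#'
#' The minimal active-site view: only roles of class `catalytic` are kept,
#' together with the constraints that reference only those roles and the TS.
#'
#' @param motif a `catalytic_motif`.
#' @return a `catalytic_motif`.
#' @export
minimal_motif <- function(motif) {
  keep <- motif$residues$class == "catalytic"
  roles <- motif$residues$role[keep]
  ok_ref <- function(a) is.na(a) || .parse_atom_ref(a)$role %in% c(roles, "TS")
  cs <- motif$constraints
  ck <- vapply(seq_len(nrow(cs)), function(i)
    all(vapply(c(cs$a1[i], cs$a2[i], cs$a3[i], cs$a4[i]), ok_ref, logical(1))),
    logical(1))
  out <- motif
  out$residues <- motif$residues[keep, , drop = FALSE]
  out$constraints <- cs[ck, , drop = FALSE]
  out$name <- paste0(motif$name, "_minimal")
  out
}

#' Deviation of one geometric constraint
#'
#' Measures the constrained quantity in a coordinate resolution and returns
#' the deviation beyond tolerance,
#' `max(0, |wrap(measured - optimal)| - tolerance)`, with shortest-arc
#' wrapping for dihedrals.
#'
#' @param constraint one row of a motif's `constraints` table (as a list or
#'   single-row data.frame).
#' @param coords named list mapping `"ROLE:ATOM"` / `"TS:ATOM"` to coordinate
#'   3-vectors.
#' @return list with `measured` and `deviation`.
#' @export
constraint_deviation <- function(constraint, coords) {
  cc <- as.list(constraint)
  atoms <- unlist(cc[c("a1", "a2", "a3", "a4")], use.names = FALSE)
  atoms <- atoms[!is.na(atoms)]
  pts <- lapply(atoms, function(a) {
    p <- coords[[a]]
    if (is.null(p)) stop("unresolved atom reference: ", a, call. = FALSE)
    p
  })
  kind <- if (cc$kind == "improper_dihedral") "dihedral" else cc$kind
  measured <- do.call(measure, c(list(kind), pts))
  diff <- if (kind == "dihedral") wrap_angle(measured - cc$optimal)
          else measured - cc$optimal
  list(measured = measured,
       deviation = max(0, abs(diff) - cc$tolerance))
}

#' Check all motif constraints on a coordinate resolution
#'
#' @param motif a `catalytic_motif`.
#' @param coords named list mapping atom references to coordinates (see
#'   [constraint_deviation()]).
#' @param norm_length,norm_angle normalization used to mix units in
#'   `rms_deviation`: deviations are divided by 1 Angstrom and 10 degrees by
#'   default.
#' @return list with `report` (per-constraint measured/deviation),
#'   `all_satisfied`, `rms_deviation`.
#' @export
check_match_constraints <- function(motif, coords, norm_length = 1,
                                    norm_angle = 10) {
  cs <- motif$constraints
  if (is.null(cs) || nrow(cs) == 0L)
    return(list(report = data.frame(), all_satisfied = TRUE, rms_deviation = 0))
  res <- lapply(seq_len(nrow(cs)), function(i)
    constraint_deviation(cs[i, , drop = FALSE], coords))
  measured <- vapply(res, `[[`, numeric(1), "measured")
  deviation <- vapply(res, `[[`, numeric(1), "deviation")
  norm <- ifelse(cs$kind == "distance", norm_length, norm_angle)
  report <- cbind(cs, measured = measured, deviation = deviation)
  list(report = report,
       all_satisfied = all(deviation == 0),
       rms_deviation = sqrt(mean((deviation / norm)^2)))
}
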