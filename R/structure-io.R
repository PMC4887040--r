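# Macromolecular structure I/O and site-set derivation.  PDB records are read
# and written through bio3d; this module adds altloc resolution, water
# removal, polymer/ligand separation, explicit-hydrogen building and the
# candidate/design-site rules used by matching and repacking.

.residue_key <- function(chain, resno, icode) {
  icode <- ifelse(is.na(icode) | icode == "" | icode == " ", "", icode)
  chain <- ifelse(is.na(chain) | chain == "", "_", chain)
  paste0(chain, ":", resno, icode)
}

#' Read a protein structure from PDB text or file
#'
#' Parses standard ATOM/HETATM records (first model only).  Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken in
#' favour of altloc `A`, then alphabetically), waters are dropped, and HETATM
#' ligand atoms are kept separately from the polymer.
#'
#' @param pdb a file path, or a character scalar/vector of PDB record text.
#' @param source_id identifier stored on the structure (defaults to the file
#'   base name or `"pdb_text"`).
#' @param keep_waters keep water molecules (default `FALSE`).
#' @return a `protein_structure`: list with `atoms` (polymer atom table),
#'   `het` (ligand atom table), `source_id`, `resolution`.
#' @export
read_structure <- function(pdb, source_id = NULL, keep_waters = FALSE) {
  is_path <- length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)
  if (is_path) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(source_id))
      source_id <- sub("\\.(pdb|ent)$", "", basename(pdb))
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    if (is.null(source_id)) source_id <- "pdb_text"
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM record found in PDB input", call. = FALSE)
  # validate coordinate fields early so we can report the offending line
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("malformed ATOM record at line %d: %s", i, lines[i]),
           call. = FALSE)
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb3d <- bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)
  at <- pdb3d$atom
  resolution <- NA_real_
  remark2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(remark2)) {
    v <- suppressWarnings(as.numeric(regmatches(
      remark2[1], regexpr("[0-9]+\\.[0-9]+", remark2[1]))))
    if (length(v)) resolution <- v
  }
  if (!keep_waters) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model after water removal", call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution: within each (residue, atom name) group keep highest
  # occupancy; ties -> 'A', then alphabetical
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
  pref <- order(-at$o, at$alt != "A", at$alt)      # preference within a key
  first <- pref[!duplicated(key[pref])]            # winning row per key
  at <- at[sort(first), , drop = FALSE]            # restore file order
  elem <- ifelse(!is.na(at$elesy) & at$elesy != "", at$elesy,
                 element_of(at$elety))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "_", at$chain),
    resno = at$resno,
    icode = at$insert,
    resname = at$resid,
    atom = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occ = at$o,
    het = at$type == "HETATM",
    is_hydrogen = elem == "H",
    charge = NA_real_,
    radius = vdw_radius(elem),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms[!atoms$het, , drop = FALSE],
                 het = atoms[atoms$het, , drop = FALSE],
                 source_id = source_id,
                 resolution = resolution),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues, %d polymer atoms (%d H), %d ligand atoms\n",
              x$source_id, length(residue_ids(x)), nrow(x$atoms),
              sum(x$atoms$is_hydrogen), nrow(x$het)))
  invisible(x)
}

#' Write a structure to PDB format
#'
#' @param structure a `protein_structure`.
#' @param file output path.
#' @param include_het write ligand atoms as HETATM records (default `TRUE`).
#' @return `file`, invisibly.
#' @export
write_structure <- function(structure, file, include_het = TRUE) {
  at <- structure$atoms
  if (include_het && nrow(structure$het)) at <- rbind(at, structure$het)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resname, chain = at$chain,
                   insert = ifelse(at$icode == "", NA, at$icode),
                   elety = at$atom, o = at$occ, b = rep(0, nrow(at)),
                   elesy = at$element)
  invisible(file)
}

#' Residue identifiers of a structure
#'
#' Identifiers are author chain + number + insertion code, e.g. `"A:105"`,
#' in chain/number order.
#'
#' @param structure a `protein_structure`.
#' @return character vector of residue ids.
#' @export
residue_ids <- function(structure) {
  at <- structure$atoms
  key <- .residue_key(at$chain, at$resno, at$icode)
  unique(key[order(at$chain, at$resno, at$icode)])
}

#' Atom table of one residue
#' @param structure a `protein_structure`.
#' @param id residue id as in [residue_ids()].
#' @return data.frame of the residue's atoms.
#' @export
residue_atoms <- function(structure, id) {
  at <- structure$atoms
  at[.residue_key(at$chain, at$resno, at$icode) == id, , drop = FALSE]
}

#' Residue name for a residue id
#' @inheritParams residue_atoms
#' @return three-letter code.
#' @export
residue_name <- function(structure, id) {
  a <- residue_atoms(structure, id)
  if (nrow(a) == 0L) stop("no such residue: ", id, call. = FALSE)
  a$resname[1L]
}

#' Backbone frame (N, CA, C) of a residue
#' @inheritParams residue_atoms
#' @return 3 x 3 matrix with rows N, CA, C.
#' @export
backbone_frame <- function(structure, id) {
  a <- residue_atoms(structure, id)
  idx <- match(c("N", "CA", "C"), a$atom)
  if (anyNA(idx))
    stop("residue ", id, " lacks a complete N/CA/C backbone frame", call. = FALSE)
  m <- as.matrix(a[idx, c("x", "y", "z")])
  rownames(m) <- c("N", "CA", "C")
  m
}

# coordinates of named atoms of a residue (error when missing)
residue_xyz <- function(structure, id, atoms) {
  a <- residue_atoms(structure, id)
  idx <- match(atoms, a$atom)
  if (anyNA(idx))
    stop("residue ", id, " lacks atom(s): ",
         paste(atoms[is.na(idx)], collapse = ", "), call. = FALSE)
  m <- as.matrix(a[idx, c("x", "y", "z")])
  rownames(m) <- atoms
  m
}

#' Build explicit hydrogens at ideal geometry
#'
#' Places polar and nonpolar hydrogens for standard residues from the ideal
#' internal-coordinate table.  Existing hydrogens are preserved; hydroxyl
#' hydrogens of Ser/Thr/Tyr are placed at their default torsion and flagged
#' as rotatable.  The backbone amide hydrogen needs the preceding residue's
#' carbonyl carbon; N-terminal residues get no HN.  Residues with missing
#' parent heavy atoms are skipped with a warning and recorded in
#' `$skip_sites`.
#'
#' @param structure a `protein_structure`.
#' @return the structure with hydrogens added; idempotent.
#' @export
build_hydrogens <- function(structure) {
  at <- structure$atoms
  hy <- hydrogen_topology()
  ids <- residue_ids(structure)
  skip <- character(0)
  new_rows <- list()
  # map residue id -> C coordinates for peptide-bond lookup
  ckey <- .residue_key(at$chain, at$resno, at$icode)
  c_at <- at[at$atom == "C", , drop = FALSE]
  c_xyz <- as.matrix(c_at[, c("x", "y", "z")])
  c_ids <- .residue_key(c_at$chain, c_at$resno, c_at$icode)
  for (id in ids) {
    res <- at[ckey == id, , drop = FALSE]
    rn <- res$resname[1L]
    have <- res$atom
    getxyz <- function(nm) {
      i <- match(nm, have)
      if (is.na(i)) return(NULL)
      as.numeric(res[i, c("x", "y", "z")])
    }
    if (anyNA(match(c("N", "CA", "C"), have))) {
      skip <- c(skip, id)
      next
    }
    add <- function(name, xyz, charge, rot) {
      new_rows[[length(new_rows) + 1L]] <<- data.frame(
        chain = res$chain[1L], resno = res$resno[1L], icode = res$icode[1L],
        resname = rn, atom = name, element = "H",
        x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, het = FALSE,
        is_hydrogen = TRUE, charge = charge, radius = vdw_radius("H"),
        stringsAsFactors = FALSE)
    }
    # backbone amide H: needs preceding residue C within peptide-bond range
    if (!("HN" %in% have) && rn != "PRO" && nrow(c_at)) {
      nxyz <- getxyz("N")
      d <- sqrt(rowSums(sweep(c_xyz, 2, nxyz)^2))
      j <- which(c_ids != id & d < 1.8)
      if (length(j)) {
        j <- j[which.min(d[j])]
        hn <- internal_to_cartesian(c_xyz[j, ], getxyz("CA"), nxyz,
                                    .BB$len_n_h, .BB$ang_ca_n_h, 180)
        add("HN", hn, .BB$q_hn, FALSE)
      }
    }
    # alpha hydrogen(s) for non-GLY handled generically; GLY in the table
    if (rn != "GLY" && !("HA" %in% have)) {
      ha <- internal_to_cartesian(getxyz("N"), getxyz("C"), getxyz("CA"),
                                  .BB$len_ca_ha, 109.0, -118.0)
      add("HA", ha, .BB$q_ha, FALSE)
    }
    rows <- hy[hy$res == rn, , drop = FALSE]
    missing_parent <- FALSE
    for (i in seq_len(nrow(rows))) {
      if (rows$atom[i] %in% have) next
      refs <- lapply(c(rows$r1[i], rows$r2[i], rows$r3[i]), getxyz)
      if (any(vapply(refs, is.null, logical(1)))) {
        missing_parent <- TRUE
        next
      }
      p <- internal_to_cartesian(refs[[1]], refs[[2]], refs[[3]],
                                 rows$len[i], rows$ang[i], rows$tor[i])
      add(rows$atom[i], p, rows$charge[i], rows$rot[i] == "r")
    }
    if (missing_parent) {
      warning("residue ", id, " (", rn,
              ") has missing side-chain heavy atoms; skipped as a site",
              call. = FALSE)
      skip <- c(skip, id)
    }
  }
  if (length(new_rows)) {
    newdf <- do.call(rbind, new_rows)
    # insert hydrogens after their residue's existing atoms to keep residue
    # blocks contiguous
    all_at <- rbind(at, newdf)
    k <- .residue_key(all_at$chain, all_at$resno, all_at$icode)
    all_at <- all_at[order(match(k, ids)), , drop = FALSE]
    rownames(all_at) <- NULL
    structure$atoms <- all_at
  }
  structure$skip_sites <- union(structure$skip_sites, skip)
  structure$hydrogens_built <- TRUE
  structure
}

#' Candidate sites for matching
#'
#' Selects the residues whose CA atom lies within `radius` of the centroid of
#' the CA atoms of a set of reference residues (in screening these are the
#' native catalytic residues annotated for the scaffold).  Prolines are
#' included here; role-specific exclusion happens later.
#'
#' @param structure a `protein_structure`.
#' @param reference_residues character vector of residue ids.
#' @param radius selection radius in Angstrom (default 15).
#' @return character vector of residue ids in deterministic (chain, number)
#'   order.
#' @export
candidate_sites <- function(structure, reference_residues, radius = 15) {
  stopifnot(radius >= 0)
  ids <- residue_ids(structure)
  missing <- setdiff(reference_residues, ids)
  if (length(missing))
    stop("reference residue(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ca <- structure$atoms[structure$atoms$atom == "CA", , drop = FALSE]
  ca_ids <- .residue_key(ca$chain, ca$resno, ca$icode)
  ref_idx <- match(reference_residues, ca_ids)
  if (anyNA(ref_idx))
    stop("reference residue(s) lack CA atoms: ",
         paste(reference_residues[is.na(ref_idx)], collapse = ", "),
         call. = FALSE)
  centroid <- colMeans(as.matrix(ca[ref_idx, c("x", "y", "z")]))
  d <- sqrt(rowSums(sweep(as.matrix(ca[, c("x", "y", "z")]), 2, centroid)^2))
  sel <- ca_ids[d <= radius]
  ids[ids %in% sel]
}

#' Design sites for side-chain repacking
#'
#' Residues with any heavy atom within `radius` of any heavy atom of the
#' transition-state model, excluding prolines.
#'
#' @param structure a `protein_structure`.
#' @param ts_xyz n x 3 matrix of TS heavy-atom coordinates.
#' @param radius shell radius in Angstrom (default 7.0).
#' @return character vector of residue ids.
#' @export
design_sites <- function(structure, ts_xyz, radius = 7.0) {
  ts_xyz <- as.matrix(ts_xyz)
  if (nrow(ts_xyz) == 0L) stop("empty TS coordinates", call. = FALSE)
  at <- structure$atoms[!structure$atoms$is_hydrogen, , drop = FALSE]
  d <- row_min_dist_cpp(as.matrix(at[, c("x", "y", "z")]), ts_xyz)
  keys <- .residue_key(at$chain, at$resno, at$icode)
  sel <- unique(keys[d <= radius])
  sel <- sel[!vapply(sel, function(id) residue_name(structure, id) == "PRO",
                     logical(1))]
  ids <- residue_ids(structure)
  ids[ids %in% sel]
}
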