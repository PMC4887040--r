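# Scaffold-library filtering and multi-scaffold screening: the workflow that
# scans a library of enzyme structures for scaffolds able to host a
# catalytic motif.

#' Scaffold-library filter criteria
#'
#' Defaults mirror common practice for design-scaffold libraries: X-ray
#' structures below 3.0 Angstrom resolution (strict), 300-800 residues,
#' pairwise sequence identity below 95% (first member of each cluster kept),
#' membership in a catalytic-site annotation set and prior E. coli
#' expression.
#'
#' @param require_xray require `method == "xray"`.
#' @param max_resolution strict upper bound on resolution (Angstrom).
#' @param min_residues,max_residues size window.
#' @param max_identity identity threshold in percent (cluster-based).
#' @param require_csa require the catalytic-site-annotation flag.
#' @param require_ecoli_expression require the expression flag.
#' @return a `library_criteria` list.
#' @export
library_criteria <- function(require_xray = TRUE, max_resolution = 3.0,
                             min_residues = 300, max_residues = 800,
                             max_identity = 95, require_csa = TRUE,
                             require_ecoli_expression = TRUE) {
  stopifnot(min_residues <= max_residues, max_resolution > 0)
  structure(list(require_xray = require_xray,
                 max_resolution = max_resolution,
                 min_residues = min_residues, max_residues = max_residues,
                 max_identity = max_identity, require_csa = require_csa,
                 require_ecoli_expression = require_ecoli_expression),
            class = "library_criteria")
}

#' Filter a scaffold-metadata table
#'
#' @param metadata data.frame with columns `id`, `method`, `resolution`,
#'   `n_residues`, `identity_cluster` (precomputed >= `max_identity`
#'   clusters), `csa`, `expression`.
#' @param criteria a [library_criteria()] list.
#' @return the surviving rows (same order); a `drops` attribute records the
#'   reason for each removal.  Idempotent and order-stable.
#' @export
filter_library <- function(metadata, criteria = library_criteria()) {
  need <- c("id", "method", "resolution", "n_residues", "identity_cluster",
            "csa", "expression")
  missing <- setdiff(need, colnames(metadata))
  if (length(missing))
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(metadata) == 0L) {
    attr(metadata, "drops") <- data.frame(id = character(0),
                                          reason = character(0))
    return(metadata)
  }
  reason <- rep(NA_character_, nrow(metadata))
  flag <- function(cond, why) {
    hit <- which(cond & is.na(reason))
    reason[hit] <<- why
  }
  if (criteria$require_xray)
    flag(tolower(metadata$method) != "xray", "not X-ray")
  flag(!(metadata$resolution < criteria$max_resolution), "resolution")
  flag(metadata$n_residues < criteria$min_residues, "too small")
  flag(metadata$n_residues > criteria$max_residues, "too large")
  if (criteria$require_csa) flag(!metadata$csa, "not in CSA set")
  if (criteria$require_ecoli_expression)
    flag(!metadata$expression, "no expression record")
  # identity clusters: keep the first surviving member (by id order)
  ok <- is.na(reason)
  surv <- metadata[ok, , drop = FALSE]
  first <- !duplicated(surv$identity_cluster[order(surv$id)])[
    order(order(surv$id))]
  dup_ids <- surv$id[!first]
  flag(metadata$id %in% dup_ids, "sequence identity")
  out <- metadata[is.na(reason), , drop = FALSE]
  attr(out, "drops") <- data.frame(id = metadata$id[!is.na(reason)],
                                   reason = reason[!is.na(reason)],
                                   stringsAsFactors = FALSE)
  out
}

#' Burial proxy for the transition-state pose
#'
#' Automated surrogate for visual pocket inspection: the match passes when at
#' least `min_fraction` of TS heavy atoms have at least `min_neighbors`
#' protein heavy atoms within `radius`.
#'
#' @param match a `site_match`.
#' @param scaffold a `protein_structure`.
#' @param min_fraction fraction of buried TS atoms required (default 0.6).
#' @param min_neighbors neighbour count defining "buried" (default 8).
#' @param radius neighbour radius in Angstrom (default 6).
#' @return `"pass"` or `"fail"`.
#' @export
pocket_check <- function(match, scaffold, min_fraction = 0.6,
                         min_neighbors = 8, radius = 6) {
  ts <- match$ts_pose
  at <- scaffold$atoms[!scaffold$atoms$is_hydrogen, , drop = FALSE]
  axyz <- as.matrix(at[, c("x", "y", "z")])
  buried <- vapply(seq_len(nrow(ts)), function(i) {
    d <- sqrt(colSums((t(axyz) - ts[i, ])^2))
    sum(d <= radius) >= min_neighbors
  }, logical(1))
  if (mean(buried) >= min_fraction) "pass" else "fail"
}

#' Read a catalytic-residue sidecar annotation
#'
#' Plain-text sidecar (CSA-style): one catalytic residue per line,
#' `chain resno [resname]`; `#` comments allowed.
#'
#' @param path file path.
#' @return character vector of residue ids (`chain:resno`).
#' @export
read_catalytic_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  vapply(parts, function(p) paste0(p[1L], ":", p[2L]), character(1))
}

#' Screen a scaffold library for a motif
#'
#' For each scaffold (a PDB file with a `.cat` sidecar listing its native
#' catalytic residues): select candidate sites within the configured radius
#' of the catalytic-residue CA centroid, run [match_scaffold()], apply the
#' pocket burial check, and report.  Scaffolds with no surviving match are
#' marked discarded; unreadable scaffolds are logged and skipped.
#'
#' @param library_dir directory of `<id>.pdb` + `<id>.cat` files.
#' @param motif a `catalytic_motif`.
#' @param config a [match_config()].
#' @param pocket_min_fraction passed to [pocket_check()].
#' @return a `screen_report`: `per_scaffold` data.frame, `matches` (named
#'   list of ranked match lists), `summary` counts.
#' @export
screen_library <- function(library_dir, motif, config = match_config(),
                           pocket_min_fraction = 0.6) {
  pdbs <- sort(list.files(library_dir, pattern = "\\.pdb$",
                          full.names = TRUE))
  rows <- list()
  all_matches <- list()
  for (p in pdbs) {
    id <- sub("\\.pdb$", "", basename(p))
    row <- data.frame(id = id, n_sites = 0L, n_matches = 0L,
                      n_after_pocket = 0L, discard_reason = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      scaf <- build_hydrogens(read_structure(p))
      catf <- sub("\\.pdb$", ".cat", p)
      refs <- if (file.exists(catf)) read_catalytic_annotation(catf)
              else residue_ids(scaf)[1L]
      sites <- candidate_sites(scaf, refs, radius = config$candidate_radius)
      row$n_sites <- length(sites)
      ms <- match_scaffold(scaf, motif, config, sites = sites)
      row$n_matches <- length(ms)
      keep <- Filter(function(m)
        pocket_check(m, scaf, min_fraction = pocket_min_fraction) == "pass",
        ms)
      row$n_after_pocket <- length(keep)
      if (length(keep) == 0L)
        row$discard_reason <- if (length(ms)) "pocket-check-fail" else "no-match"
      list(row = row, matches = keep)
    }, error = function(e) {
      row$discard_reason <- paste0("error: ", conditionMessage(e))
      list(row = row, matches = list())
    })
    rows[[length(rows) + 1L]] <- res$row
    all_matches[[id]] <- res$matches
  }
  per <- do.call(rbind, rows)
  selected <- per$id[per$n_after_pocket > 0]
  structure(list(per_scaffold = per, matches = all_matches,
                 summary = list(n_scaffolds = nrow(per),
                                n_selected = length(selected),
                                selected = selected,
                                total_matches = sum(per$n_after_pocket))),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d scaffolds screened, %d selected (%d matches)\n",
              x$summary$n_scaffolds, x$summary$n_selected,
              x$summary$total_matches))
  invisible(x)
}

#' Serialize a screen report to JSON
#' @param report a `screen_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  out <- list(summary = report$summary,
              per_scaffold = report$per_scaffold,
              matches = lapply(report$matches, function(ms)
                lapply(ms, function(m)
                  list(assignment = as.list(m$site_assignment),
                       rank_score = m$rank_score,
                       rms_deviation = m$constraint_report$rms_deviation,
                       repulsion = m$repulsion))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
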