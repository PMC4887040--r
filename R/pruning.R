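# Pruning strategies that keep the matching enumeration tractable:
#  (i)  reach pruning: site pairs whose anchors are farther apart than the
#       loop's theoretical maximum length are discarded before closure;
#  (ii) duplicate elimination of converged loops by RMSD;
#  (iii) immediate constraint checks after closure (in matching_engine);
#  (iv) van der Waals repulsion thresholds between closed loops / matches
#       and the scaffold backbone or template.
#
# "Backbone" means the main-chain atoms of candidate-site residues;
# "template" means all atoms of residues not at candidate sites.

#' Pruning parameters
#'
#' Repulsion thresholds are in protein-design energy units (PEU), the unit of this
#' package's linear repulsion model: 150 between a closed main loop and the
#' backbone, 30 between a closed side loop and the backbone, 200 between the
#' whole match and the template and 50 between the whole match and the
#' backbone.
#'
#' @param main_loop_backbone_max,side_loop_backbone_max,match_template_max,match_backbone_max
#'   stage thresholds in PEU.
#' @param dedup_rmsd duplicate-loop RMSD threshold in Angstrom.
#' @param reach_margin slack added to the maximum loop length in reach
#'   pruning, in Angstrom.
#' @param clash_onset fraction `c` of the summed van der Waals radii below
#'   which the linear repulsion turns on.
#' @param clash_scale energy `k` in PEU of one fully collapsed pair (r = 0).
#' @return a `pruning_params` list.
#' @export
pruning_params <- function(main_loop_backbone_max = 150,
                           side_loop_backbone_max = 30,
                           match_template_max = 200,
                           match_backbone_max = 50,
                           dedup_rmsd = 0.5,
                           reach_margin = 0.5,
                           clash_onset = 0.85,
                           clash_scale = 10) {
  stopifnot(main_loop_backbone_max >= 0, side_loop_backbone_max >= 0,
            match_template_max >= 0, match_backbone_max >= 0,
            dedup_rmsd >= 0, reach_margin >= 0, clash_onset > 0,
            clash_scale >= 0)
  structure(list(main_loop_backbone_max = main_loop_backbone_max,
                 side_loop_backbone_max = side_loop_backbone_max,
                 match_template_max = match_template_max,
                 match_backbone_max = match_backbone_max,
                 dedup_rmsd = dedup_rmsd, reach_margin = reach_margin,
                 clash_onset = clash_onset, clash_scale = clash_scale),
            class = "pruning_params")
}

#' Reach pruning of a site pair
#'
#' A pair is pruned when the loop's theoretical maximum length (plus the
#' configured margin) is shorter than the true distance between the two
#' anchor CA atoms.
#'
#' @param loop a main `kinematic_loop` built for the pair.
#' @param params a [pruning_params()] list.
#' @param max_length optional precomputed [max_loop_length()] (it depends
#'   only on the chain topology, so it can be memoized across pairs).
#' @return `"keep"` or `"prune"`.
#' @export
prune_by_reach <- function(loop, params = pruning_params(),
                           max_length = NULL) {
  if (is.null(max_length)) max_length <- max_loop_length(loop)
  span <- sqrt(sum((loop$end_ca - loop$start_ca)^2))
  if (max_length + params$reach_margin < span) "prune" else "keep"
}

#' Eliminate duplicate converged loops
#'
#' Greedy streaming deduplication in input order: a loop is kept iff its
#' no-fit RMSD (over the placed atoms) to every already kept loop exceeds
#' `threshold`.  Output order is stable.
#'
#' @param closed list of `closed_loop`s sharing one atom correspondence.
#' @param threshold RMSD threshold in Angstrom.
#' @return the kept sublist.
#' @export
dedup_loops <- function(closed, threshold = 0.5) {
  if (length(closed) <= 1L) return(closed)
  kept <- list(closed[[1L]])
  for (i in seq_along(closed)[-1L]) {
    ci <- closed[[i]]$coords
    dup <- FALSE
    for (k in kept) {
      if (rmsd_nofit(ci, k$coords) <= threshold) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- closed[[i]]
  }
  kept
}

#' Linear repulsive clash energy between two atom groups
#'
#' `e(r) = k * max(0, c*(Ri+Rj) - r) / (c*(Ri+Rj))` summed over all pairs:
#' zero outside the clash onset, `k` PEU for a fully collapsed pair, linear
#' in between.  Heavy atoms only; groups must be disjoint (bonded and 1-3
#' pairs are excluded by construction of the groups).
#'
#' @param atoms_a,atoms_b data.frames with columns `x`, `y`, `z`, `radius`
#'   (as in `protein_structure$atoms`), or n x 3 matrices together with
#'   `radii_a`/`radii_b`.
#' @param params a [pruning_params()] (supplies `clash_onset`, `clash_scale`).
#' @param radii_a,radii_b radii vectors when matrices are passed.
#' @return repulsion energy in PEU (>= 0).
#' @export
repulsion_energy <- function(atoms_a, atoms_b, params = pruning_params(),
                             radii_a = NULL, radii_b = NULL) {
  get_parts <- function(a, radii) {
    if (is.data.frame(a)) {
      if (is.null(a$radius) || anyNA(a$radius))
        stop("missing van der Waals radius on atom(s): ",
             paste(utils::head(a$atom[is.na(a$radius)], 3), collapse = ", "),
             call. = FALSE)
      list(xyz = as.matrix(a[, c("x", "y", "z")]), r = a$radius)
    } else {
      if (is.null(radii)) stop("radii required with matrix input", call. = FALSE)
      list(xyz = as.matrix(a), r = radii)
    }
  }
  pa <- get_parts(atoms_a, radii_a)
  pb <- get_parts(atoms_b, radii_b)
  if (nrow(pa$xyz) == 0L || nrow(pb$xyz) == 0L) return(0)
  repulsion_cpp(pa$xyz, pa$r, pb$xyz, pb$r, params$clash_onset,
                params$clash_scale)
}

#' Repulsion-threshold pruning
#'
#' @param stage one of `"main_loop"`, `"side_loop"`, `"match_vs_template"`,
#'   `"match_vs_backbone"`.
#' @param energy repulsion energy in PEU.
#' @param params a [pruning_params()] list.
#' @return `"keep"` or `"prune"`.
#' @export
prune_by_repulsion <- function(stage = c("main_loop", "side_loop",
                                         "match_vs_template",
                                         "match_vs_backbone"),
                               energy, params = pruning_params()) {
  stage <- match.arg(stage)
  thr <- switch(stage,
                main_loop = params$main_loop_backbone_max,
                side_loop = params$side_loop_backbone_max,
                match_vs_template = params$match_template_max,
                match_vs_backbone = params$match_backbone_max)
  if (energy > thr) "prune" else "keep"
}
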