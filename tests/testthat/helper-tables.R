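# synthetic rotamer-energy tables and the exhaustive GMEC oracle, shared by
# the repacking unit tests and the acceptance suite

# build a synthetic random energy-table object (the module's core oracle
# input): n_sites x n_rot random singletons and symmetric pairwise tables
random_tables <- function(n_sites, n_rot, seed) {
  set.seed(seed)
  sites <- paste0("S", seq_len(n_sites))
  singleton <- lapply(seq_len(n_sites), function(i) rnorm(n_rot, sd = 3))
  names(singleton) <- sites
  pairwise <- vector("list", n_sites)
  for (i in seq_len(n_sites)) pairwise[[i]] <- vector("list", n_sites)
  for (i in seq_len(n_sites)) for (j in seq_len(n_sites)) if (j > i)
    pairwise[[i]][[j]] <- matrix(rnorm(n_rot * n_rot, sd = 2), n_rot)
  rot <- lapply(seq_len(n_sites), function(i)
    lapply(seq_len(n_rot), function(r) list(chi = r)))
  names(rot) <- sites
  structure(list(sites = sites, rotamers = rot, singleton = singleton,
                 pairwise = pairwise), class = "energy_tables")
}

exhaustive_gmec <- function(tab) {
  n <- length(tab$sites)
  sizes <- vapply(tab$singleton, length, numeric(1))
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  best <- Inf; pick <- NULL
  for (g in seq_len(nrow(grid))) {
    idx <- as.integer(grid[g, ])
    e <- sum(vapply(seq_len(n), function(i) tab$singleton[[i]][idx[i]],
                    numeric(1)))
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
      e <- e + tab$pairwise[[i]][[j]][idx[i], idx[j]]
    if (e < best) { best <- e; pick <- idx }
  }
  list(energy = best, pick = pick)
}

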