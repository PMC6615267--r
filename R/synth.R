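# Synthetic scRNA-seq counts with planted gene modules.
#
# The generator emulates the statistical structure the autoencoder is
# designed for: nonnegative integer counts, heavy zero inflation,
# correlated gene modules shared across cells, and discrete cell groups
# whose module activity differs.  Rates follow an additive program
# model,
#   rate(cell, gene) = baseline + sum_m activity(cell, m) * scale * member(m, gene),
# with per-cell module activities drawn from a Gamma distribution
# (over-dispersed, nonnegative) and multiplied by the cell's group
# shift; counts are Poisson draws thinned by Bernoulli dropout.

#' Simulation configuration for planted-module count data
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_modules Number of planted gene modules.
#' @param genes_per_module Genes in each module.
#' @param module_overlap_fraction Fraction of each module's genes shared
#'   with the previous module, in `[0, 1)`.  Default 0 (disjoint).
#' @param baseline_rate Background Poisson mean for every gene.
#' @param activity_scale Multiplier translating module activity into
#'   added Poisson rate on member genes.
#' @param n_groups Number of discrete cell groups (cells split evenly).
#' @param group_activity_shifts `n_groups x n_modules` matrix of
#'   multiplicative activity factors; defaults to all ones.
#' @param dropout_prob Probability that any count is zeroed after
#'   sampling (technical dropout), in `[0, 1]`.
#' @param gamma_shape,gamma_scale Parameters of the Gamma distribution
#'   of per-cell module activities.
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 500L, n_genes = 600L, n_modules = 5L,
                       genes_per_module = 60L, module_overlap_fraction = 0,
                       baseline_rate = 0.1, activity_scale = 1,
                       n_groups = 2L, group_activity_shifts = NULL,
                       dropout_prob = 0.3, gamma_shape = 2, gamma_scale = 1,
                       seed = 1L) {
  if (n_cells < 1 || n_genes < 1 || n_modules < 1 || genes_per_module < 1)
    stop_oae("oae_config_error", "dimensions must be positive")
  if (module_overlap_fraction < 0 || module_overlap_fraction >= 1)
    stop_oae("oae_config_error", "module_overlap_fraction must be in [0, 1)")
  if (baseline_rate <= 0)
    stop_oae("oae_config_error", "baseline_rate must be > 0")
  if (activity_scale < 0)
    stop_oae("oae_config_error", "activity_scale must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop_oae("oae_config_error", "dropout_prob must be in [0, 1]")
  need <- n_modules * genes_per_module -
    (n_modules - 1) * floor(module_overlap_fraction * genes_per_module)
  if (need > n_genes)
    stop_oae("oae_config_error", "module layout needs ", need,
             " genes but n_genes = ", n_genes)
  if (is.null(group_activity_shifts))
    group_activity_shifts <- matrix(1, n_groups, n_modules)
  group_activity_shifts <- as.matrix(group_activity_shifts)
  if (!all(dim(group_activity_shifts) == c(n_groups, n_modules)))
    stop_oae("oae_config_error",
             "group_activity_shifts must be n_groups x n_modules")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 module_overlap_fraction = module_overlap_fraction,
                 baseline_rate = baseline_rate, activity_scale = activity_scale,
                 n_groups = as.integer(n_groups),
                 group_activity_shifts = group_activity_shifts,
                 dropout_prob = dropout_prob, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate counts with planted gene modules
#'
#' @param config A [sim_config()].
#' @return `list(counts, truth)`: `counts` is a cells-by-genes integer
#'   matrix (cells `cell_0001`..., genes `g0001`...); `truth` holds the
#'   planted `modules` (a [gene_sets()] collection), the
#'   `cell_activities` matrix (cells x modules, after group shifts), the
#'   `grouping` ([cell_grouping()]) and the pre-dropout `rates`.
#' @examples
#' sim <- simulate_counts(sim_config(n_cells = 50, n_genes = 80,
#'                                   n_modules = 2, genes_per_module = 10))
#' dim(sim$counts)
#' names(sim$truth$modules)
#' @export
simulate_counts <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  gene_names <- sprintf("g%04d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("cell_%04d", seq_len(cfg$n_cells))
  with_seed(cfg$seed, {
    # plant modules over a random gene permutation; consecutive modules
    # share `overlap * genes_per_module` genes when overlap > 0
    perm <- sample(cfg$n_genes)
    ov <- floor(cfg$module_overlap_fraction * cfg$genes_per_module)
    M <- matrix(0, cfg$n_modules, cfg$n_genes,
                dimnames = list(sprintf("module_%d", seq_len(cfg$n_modules)),
                                gene_names))
    pos <- 1L
    prev <- integer(0)
    for (m in seq_len(cfg$n_modules)) {
      fresh <- cfg$genes_per_module - if (m > 1) ov else 0L
      idx <- c(if (m > 1 && ov > 0) tail(prev, ov), perm[pos:(pos + fresh - 1L)])
      pos <- pos + fresh
      M[m, idx] <- 1
      prev <- idx
    }
    groups <- rep_len(LETTERS[seq_len(cfg$n_groups)], cfg$n_cells)
    A <- matrix(rgamma(cfg$n_cells * cfg$n_modules, shape = cfg$gamma_shape,
                       scale = cfg$gamma_scale),
                cfg$n_cells, cfg$n_modules)
    A <- A * cfg$group_activity_shifts[match(groups, LETTERS), , drop = FALSE]
    rates <- cfg$baseline_rate + cfg$activity_scale * (A %*% M)
    counts <- matrix(rpois(length(rates), rates), cfg$n_cells, cfg$n_genes)
    if (cfg$dropout_prob > 0) {
      keep <- matrix(rbinom(length(counts), 1L, 1 - cfg$dropout_prob),
                     cfg$n_cells, cfg$n_genes)
      counts <- counts * keep
    }
    dimnames(counts) <- list(cell_ids, gene_names)
    dimnames(A) <- list(cell_ids, rownames(M))
    dimnames(rates) <- dimnames(counts)
    modules <- gene_sets(apply(M, 1, function(r) gene_names[r > 0],
                               simplify = FALSE),
                         provenance = "planted synthetic modules")
    truth <- list(modules = modules, cell_activities = A,
                  grouping = cell_grouping(stats::setNames(groups, cell_ids)),
                  rates = rates, config = cfg)
    storage.mode(counts) <- "double"
    list(counts = counts, truth = truth)
  })
}

#' Canonical planted-module benchmark
#'
#' The package's standard validation fixture: 500 cells, 600 genes,
#' 5 disjoint planted modules of 60 genes, two equal cell groups where
#' group B doubles module-1 activity and halves module-2 activity,
#' 30% dropout.  Returned signatures are the 5 planted sets plus 5
#' decoy sets of 60 random non-module genes, so recovery can be judged
#' against both truth and noise.
#'
#' @param seed Integer seed (fixed default, so the fixture is stable).
#' @param n_cells,n_genes,n_modules,genes_per_module Overridable sizes
#'   for quick small-scale runs; defaults are the canonical fixture.
#' @param dropout_prob Dropout probability (default 0.3).
#' @return `list(counts, truth, signatures)` where `signatures` is a
#'   [gene_sets()] collection of planted plus decoy sets.
#' @export
default_benchmark <- function(seed = 1L, n_cells = 500L, n_genes = 600L,
                              n_modules = 5L, genes_per_module = 60L,
                              dropout_prob = 0.3) {
  shifts <- matrix(1, 2, n_modules)
  shifts[2, 1] <- 2
  if (n_modules >= 2) shifts[2, 2] <- 0.5
  cfg <- sim_config(n_cells = n_cells, n_genes = n_genes,
                    n_modules = n_modules,
                    genes_per_module = genes_per_module,
                    n_groups = 2L, group_activity_shifts = shifts,
                    dropout_prob = dropout_prob, seed = seed)
  sim <- simulate_counts(cfg)
  module_genes <- unique(unlist(sim$truth$modules))
  free <- setdiff(colnames(sim$counts), module_genes)
  decoys <- with_seed(derive_seed(seed, 99L), {
    lapply(seq_len(n_modules), function(i)
      sample(free, min(genes_per_module, length(free))))
  })
  names(decoys) <- sprintf("decoy_%d", seq_len(n_modules))
  sigs <- gene_sets(c(unclass(sim$truth$modules), decoys),
                    provenance = "planted modules + decoys")
  list(counts = sim$counts, truth = sim$truth, signatures = sigs)
}
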