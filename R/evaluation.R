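# Evaluation utilities: clustering agreement, module-unit matching,
# FACS-style quantile gating and UMAP embedding of the representation.

#' k-means clustering with seeded restarts
#'
#' Runs `stats::kmeans` `n_restarts` times from seeded random starts
#' and keeps the solution with the lowest total within-cluster sum of
#' squares.
#'
#' @param x Numeric matrix, cells as rows (raw input or an [encode()]
#'   representation).
#' @param k Number of clusters, `1 <= k <= n_cells`.
#' @param n_restarts Number of random restarts (default 20).
#' @param seed Integer seed; results are reproducible.
#' @return `list(labels, k, inertia)`; `labels` is an integer vector in
#'   `1..k` named by rownames of `x`.
#' @export
kmeans_cluster <- function(x, k, n_restarts = 20L, seed = 1L) {
  if (k < 1) stop_oae("oae_parameter_error", "k must be >= 1")
  if (k > nrow(x)) stop_oae("oae_parameter_error", "k exceeds the number of cells")
  if (k == nrow(x)) {  # every cell its own cluster; kmeans itself balks here
    labels <- seq_len(k)
    names(labels) <- rownames(x)
    return(list(labels = labels, k = as.integer(k), inertia = 0))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- with_seed(derive_seed(seed, r),
                    suppressWarnings(kmeans(x, centers = k, iter.max = 100L)))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- as.integer(best$cluster)
  names(labels) <- rownames(x)
  list(labels = labels, k = as.integer(k), inertia = best$tot.withinss)
}

#' Normalized mutual information between two clusterings
#'
#' `I(A; B)` divided by a normalizer derived from the two label
#' entropies; the default arithmetic normalization `(H(A) + H(B)) / 2`
#' keeps the score in `[0, 1]`, symmetric, and invariant to label
#' permutations.  When both labelings are constant (zero entropy) the
#' score is defined as 1.
#'
#' @param labels_a,labels_b Equal-length label vectors (any type).
#' @param normalization `"arithmetic"` (default), `"geometric"`,
#'   `"min"`, or `"max"`.
#' @return A scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b,
                normalization = c("arithmetic", "geometric", "min", "max")) {
  normalization <- match.arg(normalization)
  if (length(labels_a) != length(labels_b) || !length(labels_a))
    stop_oae("oae_dimension_error", "label vectors must have equal, positive length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pi_); hb <- ent(p_j)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  geometric = sqrt(ha * hb),
                  min = min(ha, hb),
                  max = max(ha, hb))
  if (denom <= 0) return(1)
  max(0, min(1, mi / denom))
}

#' Match gene sets to hidden units by maximum total impact
#'
#' Solves the linear assignment problem (Hungarian algorithm, via
#' `clue::solve_LSAP`) assigning each gene set to a distinct hidden
#' unit so that the summed impact of matched pairs is maximal.
#'
#' @param impact An `impact_matrix` (sets x units) from
#'   [pathway_impact()], or any numeric matrix with at least as many
#'   columns as rows.
#' @return `list(assignment, scores, total)`: `assignment` is a named
#'   integer vector mapping each set to a unit column index, `scores`
#'   the matched impact values.
#' @export
match_modules_to_units <- function(impact) {
  m <- unclass(impact)
  if (nrow(m) > ncol(m))
    stop_oae("oae_infeasible_matching", "more gene sets (", nrow(m),
             ") than retained units (", ncol(m), ")")
  sol <- clue::solve_LSAP(m - min(0, min(m)), maximum = TRUE)
  assignment <- as.integer(sol)
  names(assignment) <- rownames(m)
  scores <- m[cbind(seq_len(nrow(m)), assignment)]
  names(scores) <- rownames(m)
  list(assignment = assignment, scores = scores, total = sum(scores))
}

#' Hard quantile gating of cells from marker intensities
#'
#' Assigns cell-type labels from per-marker intensity quantiles with
#' hard gates: *high* = above the marker's median, *low* = at or below
#' the median, *mid* = strictly between the 25th and 75th percentiles
#' (linear-interpolation quantiles).  A cell receives a type label only
#' if it satisfies every stated marker requirement; cells matching no
#' type are `"unassigned"`, cells matching several are `"ambiguous"`.
#'
#' @param intensities Numeric matrix, cells x markers, with dimnames.
#' @param gates A data frame or matrix, cell types as rows and markers
#'   as columns, entries in `{"high", "mid", "low", "", NA}`.
#' @return A [cell_grouping()] over the cells.
#' @export
facs_gate <- function(intensities, gates) {
  gates <- as.matrix(gates)
  markers <- colnames(gates)
  missing <- setdiff(markers[apply(gates != "" & !is.na(gates), 2, any)],
                     colnames(intensities))
  if (length(missing))
    stop_oae("oae_missing_marker", "marker(s) absent from intensity table: ",
             paste(missing, collapse = ", "))
  pass <- list()
  for (mk in colnames(intensities)) {
    v <- intensities[, mk]
    med <- median(v)
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    pass[[mk]] <- list(high = v > med, low = v <= med,
                       mid = v > q[1] & v < q[2])
  }
  types <- rownames(gates)
  ok <- matrix(TRUE, nrow(intensities), length(types),
               dimnames = list(rownames(intensities), types))
  for (t in types) for (mk in markers) {
    lvl <- gates[t, mk]
    if (!is.na(lvl) && nzchar(lvl))
      ok[, t] <- ok[, t] & pass[[mk]][[lvl]]
  }
  hits <- rowSums(ok)
  label <- rep("unassigned", nrow(intensities))
  label[hits == 1] <- types[apply(ok[hits == 1, , drop = FALSE], 1, which)]
  label[hits > 1] <- "ambiguous"
  cell_grouping(stats::setNames(label, rownames(intensities)))
}

#' UMAP embedding of a representation
#'
#' Two-dimensional UMAP (via the \pkg{uwot} package) of the cells'
#' representation, seeded for reproducibility.
#'
#' @param rep Numeric matrix, cells x dimensions (e.g. from
#'   [encode()]); at least 3 cells.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (clamped to `n_cells - 1`).
#' @return Matrix `n_cells x 2` with columns `UMAP1`, `UMAP2`.
#' @export
embed_umap <- function(rep, seed = 1L, n_neighbors = 15L) {
  if (nrow(rep) < 3)
    stop_oae("oae_parameter_error", "UMAP needs at least 3 cells")
  nn <- max(2L, min(n_neighbors, nrow(rep) - 1L))
  emb <- with_seed(seed,
                   uwot::umap(rep, n_neighbors = nn, n_components = 2,
                              n_threads = 1, n_sgd_threads = 0))
  dimnames(emb) <- list(rownames(rep), c("UMAP1", "UMAP2"))
  emb
}
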