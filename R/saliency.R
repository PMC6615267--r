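# Saliency maps and gene-set impact scores.
#
# A saliency map asks: holding one representation unit out as the
# quantity of interest, how does it respond to an infinitesimal change
# in each input gene of each cell?  Vanilla saliency is the exact
# encoder Jacobian row; guided backpropagation additionally clips
# negative gradients at every nonlinearity on the way back, which
# empirically sharpens attributions.  Averaging absolute saliencies
# over cells and then over the genes of a signature yields per-unit
# pathway impact scores.

ZERO_IMPACT_TOL <- 1e-12

#' Saliency map of one representation unit
#'
#' Gradient of a single representation unit with respect to every input
#' gene, for every cell, computed by backpropagation through the
#' encoder only.  The backward pass starts from a gradient of one at
#' the chosen unit and zero elsewhere.
#'
#' @param object A fitted `oae` model.
#' @param counts Cells-by-genes matrix in the model's gene order.
#' @param unit Representation-unit index (1-based).
#' @param method `"guided"` (default): negative gradients are set to
#'   zero at each nonlinearity during the backward pass.  `"vanilla"`:
#'   the exact gradient.  Output entries can still be negative under
#'   guided backpropagation, through negative first-layer weights; only
#'   gradients at nonlinearities are clipped.
#' @return Numeric matrix `n_cells x n_genes`.
#' @export
saliency <- function(object, counts, unit, method = c("guided", "vanilla")) {
  method <- match.arg(method)
  check_gene_order(object, counts)
  k <- rep_dim(object)
  if (length(unit) != 1 || unit < 1 || unit > k)
    stop_oae("oae_index_error", "unit must be a single index in 1..", k)
  ne <- n_encode(object)
  fw <- oae_forward(object, counts, n_layers = ne)
  dact <- act_grad(object$config$activation)
  guided <- method == "guided"
  # gradient wrt the unit's pre-activation
  G <- dact(fw$Z[[ne]][, unit, drop = FALSE])
  if (guided) G[G < 0] <- 0
  G <- G %*% object$W[[ne]][unit, , drop = FALSE]
  if (ne > 1) for (l in (ne - 1):1) {
    if (guided) G[G < 0] <- 0
    G <- (G * dact(fw$Z[[l]])) %*% object$W[[l]]
  }
  dimnames(G) <- list(rownames(counts), object$gene_names)
  G
}

#' Per-gene impact of every representation unit
#'
#' For each unit, the mean over cells of the absolute guided saliency of
#' each gene: a nonnegative `representation_dim x n_genes` matrix whose
#' row `u` summarizes which genes drive unit `u` across the supplied
#' cells.
#'
#' @inheritParams saliency
#' @param method Saliency variant, as in [saliency()].
#' @return An object of class `gene_impact_matrix` (a matrix with
#'   attribute `n_cells_used`).
#' @export
gene_impact <- function(object, counts, method = c("guided", "vanilla")) {
  method <- match.arg(method)
  if (!nrow(counts)) stop_oae("oae_dimension_error", "need at least one cell")
  k <- rep_dim(object)
  imp <- matrix(0, k, length(object$gene_names),
                dimnames = list(paste0("U", seq_len(k)), object$gene_names))
  for (u in seq_len(k))
    imp[u, ] <- colMeans(abs(saliency(object, counts, u, method = method)))
  structure(imp, n_cells_used = nrow(counts), class = "gene_impact_matrix")
}

# Raw (pre-scaling) set x unit scores: mean gene impact over the genes
# of each set that are present in the model's gene space.  Sets with no
# present gene are dropped with a warning.
raw_set_scores <- function(gimp, signatures) {
  gn <- colnames(gimp)
  present <- lapply(signatures, function(s) intersect(s, gn))
  empty <- lengths(present) == 0
  if (any(empty)) {
    warning("dropping gene set(s) with no gene in the model: ",
            paste(names(signatures)[empty], collapse = ", "))
    present <- present[!empty]
  }
  if (!length(present))
    stop_oae("oae_empty_signature",
             "no gene set shares any gene with the model")
  S <- t(vapply(present, function(s)
    rowMeans(gimp[, s, drop = FALSE]), numeric(nrow(gimp))))
  dimnames(S) <- list(names(present), rownames(gimp))
  S
}

new_impact_matrix <- function(values, scale, n_cells_used) {
  structure(values, scale = scale, n_cells_used = n_cells_used,
            class = "impact_matrix")
}

#' Pathway impact of gene sets on the representation units
#'
#' Scores each gene set against each representation unit as the
#' arithmetic mean of the per-gene impacts ([gene_impact()]) of the
#' set's genes present in the model.  Units with (numerically) zero
#' impact for every set are omitted, then the remaining matrix is
#' min-max scaled jointly to `[0, 1]`.
#'
#' @param object A fitted `oae` model.
#' @param counts Cells over which impact is averaged.
#' @param signatures A [gene_sets()] collection.
#' @param gimp Optionally, a precomputed [gene_impact()] matrix (skips
#'   the saliency pass).
#' @return An `impact_matrix` (sets x kept units) with attribute
#'   `scale = "unit_interval"`.  In the degenerate case where every
#'   entry is equal, all entries map to 0 with a warning.
#' @export
pathway_impact <- function(object, counts = NULL, signatures, gimp = NULL) {
  if (is.null(gimp)) gimp <- gene_impact(object, counts)
  S <- raw_set_scores(gimp, signatures)
  keep <- apply(S, 2, function(col) any(col > ZERO_IMPACT_TOL))
  if (!any(keep))
    stop_oae("oae_empty_signature", "every unit has zero impact for every set")
  S <- S[, keep, drop = FALSE]
  rng <- range(S)
  if (rng[2] - rng[1] <= 0) {
    warning("degenerate min-max scaling (all scores equal); returning zeros")
    S[] <- 0
  } else S <- (S - rng[1]) / (rng[2] - rng[1])
  new_impact_matrix(S, "unit_interval", attr(gimp, "n_cells_used"))
}

#' Contrast pathway impact between two groups of cells
#'
#' Computes unscaled set-by-unit impact scores separately for the two
#' groups (over the union of units retained in either group), subtracts
#' them (`a - b`) and divides by the maximum absolute difference, so
#' scores fall in `[-1, 1]`: positive where a pathway drives a unit
#' more in group `a`, negative where more in group `b`.
#'
#' @param object A fitted `oae` model.
#' @param cells_a,cells_b Count matrices for the two groups (model gene
#'   order).
#' @param signatures A [gene_sets()] collection.
#' @return An `impact_matrix` with attribute
#'   `scale = "signed_unit_interval"`.  Identical groups yield an
#'   all-zero matrix.
#' @export
compare_groups <- function(object, cells_a, cells_b, signatures) {
  if (!nrow(cells_a) || !nrow(cells_b))
    stop_oae("oae_dimension_error", "both groups need at least one cell")
  Sa <- raw_set_scores(gene_impact(object, cells_a), signatures)
  Sb <- raw_set_scores(gene_impact(object, cells_b), signatures)
  common_sets <- intersect(rownames(Sa), rownames(Sb))
  Sa <- Sa[common_sets, , drop = FALSE]; Sb <- Sb[common_sets, , drop = FALSE]
  keep <- apply(Sa, 2, function(c) any(c > ZERO_IMPACT_TOL)) |
          apply(Sb, 2, function(c) any(c > ZERO_IMPACT_TOL))
  D <- (Sa - Sb)[, keep, drop = FALSE]
  if (length(D)) {  # no retained unit in either group: empty contrast
    m <- max(abs(D))
    if (m > 0) D <- D / m
  }
  new_impact_matrix(D, "signed_unit_interval",
                    nrow(cells_a) + nrow(cells_b))
}

#' Pathway impact per cell group
#'
#' Runs [pathway_impact()] on the full matrix and on each group's cells
#' separately (unit filtering and scaling applied independently per
#' heatmap), mirroring per-population impact summaries.
#'
#' @param object A fitted `oae` model.
#' @param counts Cells-by-genes matrix.
#' @param grouping A [cell_grouping()] covering the cells of `counts`.
#' @param signatures A [gene_sets()] collection.
#' @return Named list of `impact_matrix` objects: `all` first, then one
#'   per group.
#' @export
per_group_impacts <- function(object, counts, grouping, signatures) {
  labs <- as.character(grouping[rownames(counts)])
  out <- list(all = pathway_impact(object, counts, signatures))
  for (g in levels(grouping)) {
    ix <- which(!is.na(labs) & labs == g)
    if (!length(ix))
      stop_oae("oae_missing_group", "group '", g, "' has no cells in counts")
    out[[g]] <- pathway_impact(object, counts[ix, , drop = FALSE], signatures)
  }
  out
}

#' @export
print.impact_matrix <- function(x, ...) {
  cat("Impact matrix (", attr(x, "scale"), "): ", nrow(x), " sets x ",
      ncol(x), " units, from ", attr(x, "n_cells_used"), " cells\n", sep = "")
  print(round(unclass(x)[seq_len(min(6, nrow(x))),
                         seq_len(min(8, ncol(x))), drop = FALSE], 3))
  if (nrow(x) > 6 || ncol(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Heatmap of an impact matrix
#'
#' Signatures as rows, hidden units as columns.  Rows whose maximum
#' absolute entry falls below `threshold` can be hidden to show only
#' high-impact pathways.
#'
#' @param x An `impact_matrix`.
#' @param threshold Hide rows with `max(|entry|) <` this value; `0`
#'   shows everything.  Default 0.5.
#' @param ... Unused.
#' @return The plotted submatrix, invisibly.
#' @export
plot.impact_matrix <- function(x, threshold = 0.5, ...) {
  keep <- apply(abs(unclass(x)), 1, max) >= threshold
  if (!any(keep)) keep[] <- TRUE
  m <- unclass(x)[keep, , drop = FALSE]
  signed <- identical(attr(x, "scale"), "signed_unit_interval")
  pal <- if (signed) hcl.colors(51, "Blue-Red 2") else hcl.colors(51, "YlOrRd", rev = TRUE)
  zlim <- if (signed) c(-1, 1) else c(0, 1)
  old <- par(mar = c(4, 10, 2, 1)); on.exit(par(old))
  image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
        col = pal, zlim = zlim, axes = FALSE, xlab = "hidden unit", ylab = "")
  axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2, cex.axis = 0.7)
  axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2, cex.axis = 0.7)
  box()
  invisible(m)
}

#' Write / read an impact matrix as TSV
#'
#' The TSV has set names as the first column and unit ids as the
#' remaining column names; metadata (scale, number of cells used) goes
#' to a `#`-prefixed header block.
#'
#' @param x An `impact_matrix`.
#' @param path Output path.
#' @return `path` (write) or an `impact_matrix` (read).
#' @export
write_impact <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# scale: ", attr(x, "scale")),
               paste0("# n_cells_used: ", attr(x, "n_cells_used"))), con)
  df <- data.frame(set = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_impact
#' @export
read_impact <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  getm <- function(key) sub(paste0("# ", key, ": "), "",
                            grep(paste0("^# ", key, ":"), meta, value = TRUE))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_impact_matrix(m, getm("scale"), as.integer(getm("n_cells_used")))
}
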