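# The orthogonality-constrained Poisson autoencoder.
#
# Architecture: n_genes -> layer_dims -> n_genes, SoftPlus after every
# layer (including the output, so reconstructions stay strictly positive
# and the Poisson log is always defined).  The middle entry of
# layer_dims is the representation layer; the weight matrix of the final
# encoding layer (rows = representation units) carries the soft
# orthogonality penalty lambda * ||I - W W'||_F.

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
sigmoid  <- function(z) 1 / (1 + exp(-z))

act_fun <- function(activation) {
  if (activation == "softplus") softplus else identity
}
act_grad <- function(activation) {
  if (activation == "softplus") sigmoid else function(z) array(1, dim(z))
}

#' Configuration for an orthogonality-constrained Poisson autoencoder
#'
#' @param layer_dims Integer vector of hidden-layer sizes; must have odd
#'   length, the middle entry being the representation dimension.
#'   Default `c(128, 64, 128)`.
#' @param lambda Nonnegative weight of the soft orthogonality penalty
#'   `lambda * ||I - W W'||_F` on the final encoder weight matrix.
#' @param epsilon Small positive constant inside the Poisson
#'   log-likelihood log term.
#' @param learning_rate Positive step size for stochastic gradient
#'   descent (one update per cell; no mini-batches).
#' @param momentum Nesterov momentum coefficient in `[0, 1)`.
#' @param patience Early stopping: halt when the test loss has not
#'   improved for this many consecutive epochs.
#' @param max_epochs Hard cap on training epochs.
#' @param test_fraction Fraction of cells held out to monitor the test
#'   loss, in `(0, 1)`.
#' @param seed Integer master seed governing initialization, the
#'   train/test split and per-epoch shuffling.
#' @param activation `"softplus"` (default) or `"linear"`; the linear
#'   variant removes all nonlinearities and exists for analytic checks
#'   of gradients and saliency maps.
#' @return A validated list of class `oae_config`.
#' @export
oae_config <- function(layer_dims = c(128L, 64L, 128L), lambda = 0.1,
                       epsilon = 1e-8, learning_rate = 1e-3,
                       momentum = 0.9, patience = 10L, max_epochs = 100L,
                       test_fraction = 0.1, seed = 1L,
                       activation = c("softplus", "linear")) {
  activation <- match.arg(activation)
  num <- function(x, what) {
    x <- suppressWarnings(as.numeric(x))
    if (length(x) != 1 || is.na(x))
      stop_oae("oae_config_error", what, " must be a single number")
    x
  }
  lambda <- num(lambda, "lambda"); epsilon <- num(epsilon, "epsilon")
  learning_rate <- num(learning_rate, "learning_rate")
  momentum <- num(momentum, "momentum")
  test_fraction <- num(test_fraction, "test_fraction")
  patience <- num(patience, "patience"); max_epochs <- num(max_epochs, "max_epochs")
  seed <- num(seed, "seed")
  layer_dims <- as.integer(layer_dims)
  if (!length(layer_dims) || anyNA(layer_dims))
    stop_oae("oae_config_error", "layer_dims must be integers")
  if (length(layer_dims) %% 2 == 0 || any(layer_dims < 1))
    stop_oae("oae_config_error",
             "layer_dims must have odd length and positive entries ",
             "(the middle entry is the representation size)")
  if (lambda < 0) stop_oae("oae_config_error", "lambda must be >= 0")
  if (epsilon <= 0) stop_oae("oae_config_error", "epsilon must be > 0")
  if (learning_rate < 0) stop_oae("oae_config_error", "learning_rate must be >= 0")
  if (momentum < 0 || momentum >= 1)
    stop_oae("oae_config_error", "momentum must be in [0, 1)")
  if (patience < 1 || max_epochs < 1)
    stop_oae("oae_config_error", "patience and max_epochs must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_oae("oae_config_error", "test_fraction must be in (0, 1)")
  structure(list(layer_dims = layer_dims, lambda = lambda, epsilon = epsilon,
                 learning_rate = learning_rate, momentum = momentum,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 activation = activation),
            class = "oae_config")
}

#' Read a training configuration from a file
#'
#' Loads a key-value configuration file (JSON, or YAML when the
#' \pkg{yaml} package is available) whose keys mirror the arguments of
#' [oae_config()].  Values given in `...` override file values, which
#' in turn override the package defaults — the precedence used by the
#' command-line interface, where flags beat the `--config` file.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param ... Named [oae_config()] arguments overriding the file.
#' @return A validated [oae_config()].
#' @export
read_oae_config <- function(path, ...) {
  if (!file.exists(path)) stop_oae("oae_config_error", "file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_oae("oae_config_error", "reading YAML configs needs the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(vals), names(formals(oae_config)))
  if (length(bad))
    stop_oae("oae_config_error", "unknown configuration key(s): ",
             paste(bad, collapse = ", "))
  over <- list(...)
  vals[names(over)] <- over
  do.call(oae_config, vals)
}

rep_dim  <- function(object) object$config$layer_dims[(length(object$config$layer_dims) + 1) / 2]
n_encode <- function(object) (length(object$config$layer_dims) + 1) / 2

#' Initialize an untrained autoencoder
#'
#' Builds the network topology `n_genes -> layer_dims -> n_genes` with
#' Xavier (Glorot uniform) weight initialization and all biases set to
#' the small constant 0.01, reproducibly from the configuration seed.
#'
#' @param config An [oae_config()].
#' @param gene_names Character vector of input feature names; its length
#'   fixes the input (and output) dimension.
#' @return An object of class `oae` with empty training history.
#' @export
oae_init <- function(config, gene_names) {
  if (!inherits(config, "oae_config")) config <- do.call(oae_config, config)
  gene_names <- as.character(gene_names)
  n_genes <- length(gene_names)
  if (n_genes < 1) stop_oae("oae_config_error", "need at least one gene")
  dims <- c(n_genes, config$layer_dims, n_genes)
  k <- dims[1 + (length(config$layer_dims) + 1) / 2]
  if (n_genes < k)
    warning("fewer genes (", n_genes, ") than representation units (", k, ")")
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  with_seed(derive_seed(config$seed, 0L), {
    for (l in seq_along(W)) {
      fan_in <- dims[l]; fan_out <- dims[l + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_out, fan_in)
      b[[l]] <- rep(0.01, fan_out)
    }
  })
  structure(list(W = W, b = b, gene_names = gene_names, config = config,
                 history = NULL, best_epoch = NA_integer_, trained = FALSE),
            class = "oae")
}

# Full forward pass; returns activations A (list, one per layer) and
# pre-activations Z.  X is cells x genes.
oae_forward <- function(object, X, n_layers = length(object$W)) {
  f <- act_fun(object$config$activation)
  A <- vector("list", n_layers); Z <- vector("list", n_layers)
  cur <- X
  for (l in seq_len(n_layers)) {
    Z[[l]] <- sweep(tcrossprod(cur, object$W[[l]]), 2, object$b[[l]], "+")
    A[[l]] <- f(Z[[l]])
    cur <- A[[l]]
  }
  list(A = A, Z = Z)
}

#' Poisson negative log-likelihood reconstruction loss
#'
#' `mean(yhat - x * log(yhat + epsilon))` over all matrix entries: the
#' Poisson negative log-likelihood of the observed counts `x` under
#' reconstructed rates `yhat`, omitting the model-independent `log(x!)`
#' term.  Appropriate for raw, unnormalized count data.
#'
#' @param x Observed counts (matrix or vector).
#' @param yhat Strictly positive reconstructions, same shape as `x`.
#' @param epsilon Small positive stabilizer inside the log.
#' @return A scalar; finite for all valid inputs (may be negative, as
#'   the constant term is omitted).
#' @export
poisson_nll <- function(x, yhat, epsilon = 1e-8) {
  if (length(x) != length(yhat))
    stop_oae("oae_dimension_error", "x and yhat must have the same shape")
  mean(yhat - x * log(yhat + epsilon))
}

#' Soft orthogonality penalty on the final encoder weights
#'
#' `lambda * ||I - W W'||_F`, the Frobenius norm of the deviation of the
#' representation-unit weight rows from orthonormality.  Zero exactly
#' when the rows of `W` are orthonormal.
#'
#' @param W Final encoder weight matrix, rows = representation units.
#' @param lambda Nonnegative penalty weight.
#' @return A nonnegative scalar.
#' @export
orthogonality_penalty <- function(W, lambda = 1) {
  D <- diag(nrow(W)) - tcrossprod(W)
  lambda * sqrt(sum(D^2))
}

#' Total training loss
#'
#' The scalar minimized during training: [poisson_nll()] plus
#' [orthogonality_penalty()].
#'
#' @inheritParams poisson_nll
#' @inheritParams orthogonality_penalty
#' @return A scalar.
#' @export
total_loss <- function(x, yhat, W, lambda = 0.1, epsilon = 1e-8) {
  poisson_nll(x, yhat, epsilon) + orthogonality_penalty(W, lambda)
}

#' Analytic gradient of the total loss
#'
#' Backpropagates [total_loss()] through the network for a batch of
#' cells, returning the gradient with respect to every weight matrix and
#' bias vector.  This is the exact gradient the trainer follows; it can
#' be checked against finite differences.
#'
#' @param object An `oae` model.
#' @param X Cells-by-genes count matrix (rows are cells).
#' @return `list(W =, b =, loss =)` with gradients shaped like the
#'   parameters.
#' @export
loss_gradient <- function(object, X) {
  cfg <- object$config
  L <- length(object$W)
  fw <- oae_forward(object, X)
  Y <- fw$A[[L]]
  dact <- act_grad(cfg$activation)
  nll <- poisson_nll(X, Y, cfg$epsilon)
  gW <- vector("list", L); gb <- vector("list", L)
  dZ <- (1 - X / (Y + cfg$epsilon)) / length(X) * dact(fw$Z[[L]])
  for (l in L:1) {
    A_prev <- if (l == 1) X else fw$A[[l - 1]]
    gW[[l]] <- crossprod(dZ, A_prev)
    dimnames(gW[[l]]) <- NULL
    gb[[l]] <- unname(colSums(dZ))
    if (l > 1) dZ <- (dZ %*% object$W[[l]]) * dact(fw$Z[[l - 1]])
  }
  pen <- 0
  if (cfg$lambda > 0) {
    le <- n_encode(object)
    W <- object$W[[le]]
    D <- diag(nrow(W)) - tcrossprod(W)
    f <- sqrt(sum(D^2))
    pen <- cfg$lambda * f
    if (f > 0) gW[[le]] <- gW[[le]] - (2 * cfg$lambda / f) * (D %*% W)
  }
  list(W = gW, b = gb, loss = nll + pen)
}

#' Train an initialized autoencoder
#'
#' Stochastic gradient descent with Nesterov momentum, one update per
#' cell (batch size 1, no mini-batches) in a freshly shuffled order each
#' epoch.  A seeded fraction of cells is held out; after every epoch the
#' held-out loss is recorded and training stops once it has failed to
#' improve for `patience` consecutive epochs (or at `max_epochs`),
#' restoring the weights of the best epoch.
#'
#' @param object An `oae` model from [oae_init()].
#' @param counts Cells-by-genes count matrix whose column order matches
#'   `object$gene_names`.
#' @param grouping Optional [cell_grouping()]; when supplied the
#'   train/test split is stratified by group.
#' @param verbose Print per-epoch losses.
#' @return The trained `oae` object with populated `history` (a data
#'   frame with columns `epoch`, `train_loss`, `test_loss`, `penalty`,
#'   `ortho_norm`) and `best_epoch`.
#' @export
oae_train <- function(object, counts, grouping = NULL, verbose = FALSE) {
  cfg <- object$config
  validate_counts(counts)
  check_gene_order(object, counts)
  n <- nrow(counts)
  test_idx <- with_seed(derive_seed(cfg$seed, 1L), {
    if (!is.null(grouping)) {
      g <- as.character(grouping[rownames(counts)])
      unlist(lapply(split(seq_len(n), g), function(ix)
        sample(ix, max(1L, round(cfg$test_fraction * length(ix))))),
        use.names = FALSE)
    } else sample(n, max(1L, round(cfg$test_fraction * n)))
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  if (!length(train_idx)) stop_oae("oae_config_error", "no training cells left")
  Xtr <- counts[train_idx, , drop = FALSE]
  Xte <- counts[test_idx, , drop = FALSE]
  le <- n_encode(object)
  vW <- lapply(object$W, function(w) array(0, dim(w)))
  vb <- lapply(object$b, function(v) numeric(length(v)))
  mu <- cfg$momentum; lr <- cfg$learning_rate
  hist <- list()
  best <- Inf; best_W <- object$W; best_b <- object$b
  best_epoch <- 0L; bad <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100L + epoch),
                     sample(nrow(Xtr)))
    for (i in ord) {
      g <- loss_gradient(object, Xtr[i, , drop = FALSE])
      if (!is.finite(g$loss))
        stop_oae("oae_divergence_error", "non-finite loss at epoch ", epoch,
                 " (learning_rate = ", lr, "); lower the learning rate")
      # Nesterov momentum in the standard deep-learning parameterization:
      # v <- mu v + g ; theta <- theta - lr (g + mu v)
      for (l in seq_along(object$W)) {
        vW[[l]] <- mu * vW[[l]] + g$W[[l]]
        vb[[l]] <- mu * vb[[l]] + g$b[[l]]
        object$W[[l]] <- object$W[[l]] - lr * (g$W[[l]] + mu * vW[[l]])
        object$b[[l]] <- object$b[[l]] - lr * (g$b[[l]] + mu * vb[[l]])
      }
    }
    W <- object$W[[le]]
    onorm <- sqrt(sum((diag(nrow(W)) - tcrossprod(W))^2))
    pen <- cfg$lambda * onorm
    tr_loss <- poisson_nll(Xtr, oae_forward(object, Xtr)$A[[length(object$W)]],
                           cfg$epsilon) + pen
    te_loss <- poisson_nll(Xte, oae_forward(object, Xte)$A[[length(object$W)]],
                           cfg$epsilon) + pen
    if (!is.finite(tr_loss) || !is.finite(te_loss))
      stop_oae("oae_divergence_error", "non-finite loss at epoch ", epoch,
               " (learning_rate = ", lr, "); lower the learning rate")
    hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss,
                       test_loss = te_loss, penalty = pen, ortho_norm = onorm)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  test %.5f  penalty %.5f",
                      epoch, tr_loss, te_loss, pen))
    if (te_loss < best) {
      best <- te_loss; best_W <- object$W; best_b <- object$b
      best_epoch <- epoch; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  object$W <- best_W; object$b <- best_b
  object$history <- as.data.frame(do.call(rbind, hist))
  rownames(object$history) <- NULL
  object$best_epoch <- best_epoch
  object$test_cells <- rownames(counts)[test_idx]
  object$trained <- TRUE
  object
}

check_gene_order <- function(object, counts) {
  gn <- colnames(counts)
  if (length(gn) != length(object$gene_names) || any(gn != object$gene_names)) {
    d <- which(gn[seq_len(min(length(gn), length(object$gene_names)))] !=
                 object$gene_names[seq_len(min(length(gn), length(object$gene_names)))])
    where <- if (length(d)) paste0("first mismatch at column ", d[1], ": '",
                                   gn[d[1]], "' vs model '",
                                   object$gene_names[d[1]], "'")
             else paste0("matrix has ", length(gn), " genes, model expects ",
                         length(object$gene_names))
    stop_oae("oae_feature_mismatch",
             "gene order does not match the trained model; ", where)
  }
  invisible(TRUE)
}

#' Fit an orthogonality-constrained Poisson autoencoder
#'
#' The main entry point: optionally restricts the count matrix to
#' signature genes, initializes the network ([oae_init()]) and trains it
#' ([oae_train()]).
#'
#' @param counts Cells-by-genes raw count matrix (no normalization or
#'   log transform; the Poisson loss consumes counts directly).
#' @param signatures Optional [gene_sets()]; when supplied the input is
#'   restricted to the union of signature genes before training.
#' @param grouping Optional [cell_grouping()] used to stratify the
#'   train/test split.
#' @param keep_data Store the (restricted) training counts in the fitted
#'   object, enabling [residuals()] and [simulate()] without re-supplying
#'   data.
#' @param verbose Print per-epoch losses.
#' @param config A ready-made [oae_config()] (e.g. from
#'   [read_oae_config()] or [oae_grid()]); when supplied, `...` must be
#'   empty.
#' @param ... Configuration values passed to [oae_config()]
#'   (`layer_dims`, `lambda`, `learning_rate`, `seed`, ...).
#' @return A fitted object of class `oae`.
#' @examples
#' bench <- default_benchmark(n_cells = 60, n_genes = 40, n_modules = 2,
#'                            genes_per_module = 10)
#' fit <- oae(bench$counts, layer_dims = c(16, 8, 16), max_epochs = 3,
#'            seed = 1)
#' fit
#' dim(predict(fit, type = "representation"))
#' @export
oae <- function(counts, signatures = NULL, grouping = NULL,
                keep_data = TRUE, verbose = FALSE, config = NULL, ...) {
  validate_counts(counts)
  if (!is.null(signatures))
    counts <- restrict_to_signature_genes(counts, signatures)
  cfg <- if (is.null(config)) oae_config(...) else {
    if (...length())
      stop_oae("oae_config_error",
               "give either a ready-made config or ... arguments, not both")
    if (!inherits(config, "oae_config")) config <- do.call(oae_config, config)
    config
  }
  fit <- oae_init(cfg, colnames(counts))
  fit <- oae_train(fit, counts, grouping = grouping, verbose = verbose)
  if (keep_data) fit$data <- counts
  fit$call <- match.call()
  fit
}

#' Encode cells into the representation layer
#'
#' Applies only the encoding half of the network; the returned matrix
#' has one nonnegative row per cell and one column per representation
#' unit.
#'
#' @param object A fitted `oae` model.
#' @param counts Cells-by-genes matrix in the model's gene order.
#' @return Numeric matrix `n_cells x representation_dim` (columns named
#'   `U1`, `U2`, ...).
#' @export
encode <- function(object, counts) {
  check_gene_order(object, counts)
  R <- oae_forward(object, counts, n_layers = n_encode(object))$A[[n_encode(object)]]
  dimnames(R) <- list(rownames(counts), paste0("U", seq_len(ncol(R))))
  R
}

#' @rdname predict.oae
#' @export
reconstruct <- function(object, counts) {
  check_gene_order(object, counts)
  Y <- oae_forward(object, counts)$A[[length(object$W)]]
  dimnames(Y) <- dimnames(counts)
  Y
}

#' Predict method for fitted autoencoders
#'
#' @param object A fitted `oae` model.
#' @param newdata Cells-by-genes count matrix; defaults to the stored
#'   training data.
#' @param type `"representation"` (encoder output) or
#'   `"reconstruction"` (full autoencoder output, strictly positive
#'   Poisson rates).
#' @param ... Unused.
#' @return A numeric matrix.
#' @export
predict.oae <- function(object, newdata = NULL,
                        type = c("representation", "reconstruction"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- stored_data(object)
  if (type == "representation") encode(object, newdata)
  else reconstruct(object, newdata)
}

stored_data <- function(object) {
  if (is.null(object$data))
    stop_oae("oae_config_error",
             "no stored training data (fit with keep_data = TRUE) ",
             "and no newdata supplied")
  object$data
}

#' @export
coef.oae <- function(object, ...) {
  W <- object$W[[n_encode(object)]]
  rownames(W) <- paste0("U", seq_len(nrow(W)))
  W
}

#' @export
residuals.oae <- function(object, newdata = NULL,
                          type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- stored_data(object)
  mu <- reconstruct(object, newdata)
  r <- newdata - mu
  if (type == "pearson") r <- r / sqrt(mu)
  r
}

#' @export
simulate.oae <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- stored_data(object)
  mu <- reconstruct(object, newdata)
  draw <- function() {
    s <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu), dimnames = dimnames(mu))
    s
  }
  if (!is.null(seed)) with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

#' @export
print.oae <- function(x, ...) {
  cfg <- x$config
  cat("Orthogonality-constrained Poisson autoencoder\n")
  cat("  architecture:", paste(c(length(x$gene_names), cfg$layer_dims,
                                 length(x$gene_names)), collapse = " -> "),
      paste0("(", cfg$activation, ")\n"))
  cat("  lambda:", cfg$lambda, "  learning rate:", cfg$learning_rate,
      "  momentum:", cfg$momentum, "\n")
  if (isTRUE(x$trained)) {
    h <- x$history
    cat("  trained: ", nrow(h), " epochs (best epoch ", x$best_epoch, ")\n",
        sep = "")
    cat(sprintf("  best test loss: %.5f   ||I - WW'||_F: %.4f\n",
                min(h$test_loss), h$ortho_norm[x$best_epoch]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.oae <- function(object, ...) {
  structure(list(fit = object), class = "summary.oae")
}

#' @export
print.summary.oae <- function(x, ...) {
  print(x$fit)
  h <- x$fit$history
  if (!is.null(h)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(tail(h, 5), row.names = FALSE, digits = 5)
  }
  W <- coef(x$fit)
  cat("\nFinal encoder weight W:", nrow(W), "x", ncol(W),
      " row-norm range [", sprintf("%.3f", min(sqrt(rowSums(W^2)))), ", ",
      sprintf("%.3f", max(sqrt(rowSums(W^2)))), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.oae <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop_oae("oae_config_error", "model is untrained")
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Poisson loss", ylim = range(c(h$train_loss, h$test_loss)))
  lines(h$epoch, h$test_loss, lty = 2)
  legend("topright", c("train", "test"), lty = 1:2, bty = "n")
  plot(h$epoch, h$ortho_norm, type = "l", xlab = "epoch",
       ylab = "||I - WW'||_F", main = "orthogonality")
  invisible(x)
}

#' Euclidean norm of the singular values of a representation
#'
#' Computed from the singular value decomposition of the representation
#' matrix; numerically this equals its Frobenius norm.  Used to quantify
#' the effect of the orthogonality penalty on the learned representation.
#'
#' @param rep Representation matrix (cells x units), e.g. from
#'   [encode()].
#' @return A nonnegative scalar.
#' @export
representation_singular_norm <- function(rep) {
  if (!nrow(rep)) stop_oae("oae_dimension_error", "need at least one cell")
  sqrt(sum(svd(rep, nu = 0, nv = 0)$d^2))
}

#' Grid search over training hyperparameters
#'
#' Trains one model per (`lambda`, `learning_rate`) pair with a shared
#' seed and returns the configuration with the smallest best test loss.
#' Ties are broken toward smaller `lambda`, then smaller
#' `learning_rate`; configurations that diverge are dropped.
#'
#' @param counts Cells-by-genes count matrix.
#' @param lambdas,learning_rates Numeric vectors defining the grid.
#' @param grouping Optional [cell_grouping()] for split stratification.
#' @param ... Further arguments to [oae_config()], shared by all grid
#'   points.
#' @return `list(best_config, results, best_fit)`: `results` is a data
#'   frame with one row per grid point and its best test loss (`NA` for
#'   diverged runs).
#' @export
oae_grid <- function(counts, lambdas = c(0, 0.01, 0.1, 1),
                     learning_rates = c(1e-5, 1e-4, 1e-3),
                     grouping = NULL, ...) {
  grid <- expand.grid(lambda = lambdas, learning_rate = learning_rates,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop_oae("oae_config_error", "empty hyperparameter grid")
  res <- rep(NA_real_, nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- oae_config(lambda = grid$lambda[i],
                      learning_rate = grid$learning_rate[i], ...)
    fit <- tryCatch(
      oae_train(oae_init(cfg, colnames(counts)), counts, grouping = grouping),
      oae_divergence_error = function(e) NULL)
    if (!is.null(fit)) {
      res[i] <- min(fit$history$test_loss)
      fits[[i]] <- fit
    }
  }
  if (all(is.na(res)))
    stop_oae("oae_no_viable_config",
             "every configuration in the grid diverged")
  ord <- order(res, grid$lambda, grid$learning_rate, na.last = TRUE)
  best <- ord[1]
  list(best_config = fits[[best]]$config,
       results = cbind(grid, test_loss = res),
       best_fit = fits[[best]])
}
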