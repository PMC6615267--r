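# Shared fixtures and independent oracles used across the test files.

# A tiny valid count matrix with names.
tiny_counts <- function(n_cells = 4, n_genes = 6, seed = 42, max_count = 5) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * n_genes, 1.5), n_cells, n_genes)
    m[m > max_count] <- max_count
    dimnames(m) <- list(paste0("c", seq_len(n_cells)),
                        paste0("G", seq_len(n_genes)))
    storage.mode(m) <- "double"
    m
  })
}

# A small (optionally linear) model over n_genes features.
tiny_model <- function(n_genes = 6, layer_dims = c(4, 2, 4), seed = 1,
                       activation = "softplus", lambda = 0.1, ...) {
  oae_init(oae_config(layer_dims = layer_dims, seed = seed,
                      activation = activation, lambda = lambda, ...),
           paste0("G", seq_len(n_genes)))
}

# Central finite-difference gradient of f at x (scalar-valued f).
fd_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Independent total-loss evaluator used as the finite-difference oracle:
# recomputes the forward pass from a flat parameter vector without any
# of the package's gradient machinery.
flat_params <- function(model) {
  unlist(c(lapply(model$W, as.vector), model$b))
}

unflatten_into <- function(model, theta) {
  pos <- 1L
  for (l in seq_along(model$W)) {
    n <- length(model$W[[l]])
    model$W[[l]][] <- theta[pos:(pos + n - 1)]; pos <- pos + n
  }
  for (l in seq_along(model$b)) {
    n <- length(model$b[[l]])
    model$b[[l]][] <- theta[pos:(pos + n - 1)]; pos <- pos + n
  }
  model
}

loss_at <- function(model, X, theta) {
  m <- unflatten_into(model, theta)
  sp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
  act <- if (m$config$activation == "softplus") sp else identity
  cur <- X
  for (l in seq_along(m$W))
    cur <- act(sweep(tcrossprod(cur, m$W[[l]]), 2, m$b[[l]], "+"))
  le <- (length(m$config$layer_dims) + 1) / 2
  W <- m$W[[le]]
  mean(cur - X * log(cur + m$config$epsilon)) +
    m$config$lambda * sqrt(sum((diag(nrow(W)) - tcrossprod(W))^2))
}

# Brute-force maximum-assignment oracle (all permutations; n <= 6).
brute_force_assignment <- function(m) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_total <- -Inf
  for (cols in combn(ncol(m), nrow(m), simplify = FALSE))
    for (p in perms(cols)) {
      tot <- sum(m[cbind(seq_len(nrow(m)), p)])
      if (tot > best_total) { best_total <- tot; best <- p }
    }
  list(assignment = best, total = best_total)
}

# Small planted-module benchmark for fast end-to-end tests.
small_benchmark <- function(seed = 1) {
  default_benchmark(seed = seed, n_cells = 80, n_genes = 60, n_modules = 3,
                    genes_per_module = 10)
}
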