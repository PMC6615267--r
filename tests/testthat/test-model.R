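# Network construction, losses, gradients, training and fitted-model
# methods.

test_that("configuration invariants are enforced", {
  expect_error(oae_config(layer_dims = c(8, 4)), class = "oae_config_error")
  expect_error(oae_config(lambda = -1), class = "oae_config_error")
  expect_error(oae_config(momentum = 1), class = "oae_config_error")
  expect_error(oae_config(test_fraction = 0), class = "oae_config_error")
  cfg <- oae_config(layer_dims = c(4, 2, 4))
  expect_s3_class(cfg, "oae_config")
})

test_that("initialization gives the declared topology, deterministically", {
  m <- tiny_model(n_genes = 6, layer_dims = c(4, 2, 4), seed = 7)
  expect_length(m$W, 4)
  expect_identical(dim(m$W[[1]]), c(4L, 6L))
  expect_identical(dim(m$W[[2]]), c(2L, 4L))  # final encoder: rep x penultimate
  expect_identical(dim(coef(m)), c(2L, 4L))
  expect_identical(dim(m$W[[4]]), c(6L, 4L))
  expect_true(all(vapply(m$b, function(b) all(b == 0.01), TRUE)))
  m2 <- tiny_model(n_genes = 6, layer_dims = c(4, 2, 4), seed = 7)
  expect_identical(m$W, m2$W)
  expect_warning(tiny_model(n_genes = 2, layer_dims = c(4, 3, 4)),
                 "representation units")
})

test_that("poisson_nll matches hand-computed values and the Poisson MLE", {
  # zero-count limit: loss at x = 0 is just yhat
  expect_equal(poisson_nll(matrix(0), matrix(1e-4)), 1e-4)
  # hand evaluation of the formula at x = 1, yhat = 1
  expect_equal(poisson_nll(matrix(1), matrix(1)), 1 - log(1 + 1e-8))
  # brute-force scan: for x = 3 the minimizer over integer yhat is 3
  losses <- vapply(1:5, function(y) poisson_nll(matrix(3), matrix(y)), 0)
  expect_identical(which.min(losses), 3L)
  # equals the true Poisson NLL up to the x-dependent log(x!) constant
  for (x in 0:3) {
    y <- 2.37
    expect_equal(poisson_nll(x, y, epsilon = 1e-300) + lfactorial(x),
                 -dpois(x, y, log = TRUE), tolerance = 1e-12)
  }
  expect_error(poisson_nll(matrix(1), matrix(1, 2, 1)),
               class = "oae_dimension_error")
})

test_that("orthogonality penalty matches hand computations", {
  expect_equal(orthogonality_penalty(diag(2), lambda = 5), 0)
  # W = diag(2, 1): I - WW' = diag(-3, 0), Frobenius norm 3, times 0.1
  expect_equal(orthogonality_penalty(diag(c(2, 1)), lambda = 0.1), 0.3)
  # all-zero 2x3: ||I_2||_F = sqrt(2)
  expect_equal(orthogonality_penalty(matrix(0, 2, 3), lambda = 1), sqrt(2))
})

test_that("total loss composes additively and linearly in lambda", {
  x <- matrix(1); y <- matrix(1); W <- matrix(1, 1, 1)
  expect_equal(total_loss(x, y, W, lambda = 0), poisson_nll(x, y))
  expect_equal(total_loss(x, y, W, lambda = 0.5), 1 - log(1 + 1e-8),
               tolerance = 1e-12)  # penalty is 0 for orthonormal 1x1 W
  W2 <- diag(c(2, 1))
  p1 <- total_loss(x, y, W2, lambda = 0.1) - poisson_nll(x, y)
  p2 <- total_loss(x, y, W2, lambda = 0.2) - poisson_nll(x, y)
  expect_equal(p2, 2 * p1)
})

test_that("analytic gradients agree with central finite differences", {
  # the SoftPlus output keeps reconstructions positive, so the loss (and
  # its finite-difference probe) is well defined everywhere
  for (lambda in c(0, 0.2)) {
    m <- tiny_model(n_genes = 6, layer_dims = c(4, 2, 4), seed = 3,
                    lambda = lambda)
    X <- tiny_counts(n_cells = 4, n_genes = 6)
    g <- loss_gradient(m, X)
    analytic <- unlist(c(lapply(g$W, as.vector), g$b))
    theta <- flat_params(m)
    numeric_g <- fd_grad(function(th) loss_at(m, X, th), theta, h = 1e-5)
    denom <- pmax(abs(numeric_g), 1e-6)
    expect_lt(max(abs(analytic - numeric_g) / denom), 1e-4)
  }
})

test_that("training descends, is deterministic, and records history", {
  sim <- simulate_counts(sim_config(n_cells = 60, n_genes = 40, n_modules = 2,
                                    genes_per_module = 10, seed = 5))
  fit1 <- oae(sim$counts, layer_dims = c(8, 4, 8), max_epochs = 15, seed = 9)
  expect_s3_class(fit1, "oae")
  h <- fit1$history
  expect_named(h, c("epoch", "train_loss", "test_loss", "penalty", "ortho_norm"))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  fit2 <- oae(sim$counts, layer_dims = c(8, 4, 8), max_epochs = 15, seed = 9)
  expect_identical(fit1$W, fit2$W)
  fit3 <- oae(sim$counts, layer_dims = c(8, 4, 8), max_epochs = 1, seed = 9)
  expect_identical(nrow(fit3$history), 1L)
})

test_that("a plateau triggers early stopping after exactly patience epochs", {
  x <- tiny_counts(n_cells = 10, n_genes = 6)
  fit <- oae(x, layer_dims = c(4, 2, 4), learning_rate = 0, patience = 4,
             max_epochs = 50, seed = 2)
  expect_identical(nrow(fit$history), 5L)  # 1 improving + patience flat
  expect_identical(fit$best_epoch, 1L)
  init <- oae_init(fit$config, colnames(x))
  expect_identical(fit$W, init$W)  # zero learning rate: epoch-1 weights = init
})

test_that("divergence raises a dedicated error naming epoch and rate", {
  x <- tiny_counts(n_cells = 10, n_genes = 6, max_count = 9)
  err <- expect_error(
    oae(x, layer_dims = c(4, 2, 4), learning_rate = 1e9, max_epochs = 5,
        seed = 1),
    class = "oae_divergence_error")
  expect_match(conditionMessage(err), "epoch")
})

test_that("encode maps rows independently into a nonnegative representation", {
  x <- tiny_counts(n_cells = 5, n_genes = 6)
  fit <- oae(x, layer_dims = c(4, 2, 4), max_epochs = 2, seed = 1)
  R <- encode(fit, x)
  expect_identical(dim(R), c(5L, 2L))
  expect_true(all(R >= 0))
  # a zero-count cell still encodes strictly positive (bias + SoftPlus)
  z <- x; z[1, ] <- 0
  expect_true(all(encode(fit, z)[1, ] > 0))
  # row-wise map: stacking duplicates duplicates rows
  dup <- x[c(1, 1), , drop = FALSE]
  rownames(dup) <- c("a", "b")
  Rd <- encode(fit, dup)
  expect_equal(unname(Rd[1, ]), unname(Rd[2, ]))
  # feature mismatch names the first discrepancy
  bad <- x; colnames(bad)[2] <- "WRONG"
  err <- expect_error(encode(fit, bad), class = "oae_feature_mismatch")
  expect_match(conditionMessage(err), "WRONG")
  # reconstructions are strictly positive
  expect_true(all(reconstruct(fit, x) > 0))
})

test_that("predict, residuals and simulate operate on the stored data", {
  x <- tiny_counts(n_cells = 5, n_genes = 6)
  fit <- oae(x, layer_dims = c(4, 2, 4), max_epochs = 2, seed = 1)
  expect_identical(predict(fit), encode(fit, x))
  expect_identical(dim(predict(fit, type = "reconstruction")), dim(x))
  r <- residuals(fit)
  expect_identical(dim(r), dim(x))
  s <- simulate(fit, nsim = 2, seed = 4)
  expect_length(s, 2)
  expect_true(all(s[[1]] >= 0) && all(s[[1]] == round(s[[1]])))
  expect_identical(simulate(fit, seed = 4)[[1]], s[[1]])
})

test_that("the singular-value norm equals the Frobenius norm", {
  expect_equal(representation_singular_norm(diag(2)), sqrt(2))
  expect_equal(representation_singular_norm(diag(c(3, 4))), 5)
  m <- matrix(rnorm(12), 3, 4)
  expect_equal(representation_singular_norm(3 * m),
               3 * representation_singular_norm(m))
  expect_equal(representation_singular_norm(m), sqrt(sum(m^2)))
})

test_that("grid search selects by test loss with deterministic tie-breaks", {
  x <- tiny_counts(n_cells = 12, n_genes = 6)
  g1 <- oae_grid(x, lambdas = 0.1, learning_rates = 1e-3,
                 layer_dims = c(4, 2, 4), max_epochs = 3, seed = 1)
  expect_equal(g1$best_config$lambda, 0.1)
  expect_identical(nrow(g1$results), 1L)
  # a diverging rate is skipped in favour of the converging one
  g2 <- oae_grid(x, lambdas = 0.1, learning_rates = c(1e9, 1e-3),
                 layer_dims = c(4, 2, 4), max_epochs = 3, seed = 1)
  expect_equal(g2$best_config$learning_rate, 1e-3)
  expect_true(is.na(g2$results$test_loss[g2$results$learning_rate == 1e9]))
  # duplicate configurations: the first occurrence wins
  g3 <- oae_grid(x, lambdas = c(0.1, 0.1), learning_rates = 1e-3,
                 layer_dims = c(4, 2, 4), max_epochs = 3, seed = 1)
  expect_equal(g3$best_config$lambda, 0.1)
  expect_error(oae_grid(x, lambdas = 0.1, learning_rates = 1e9,
                        layer_dims = c(4, 2, 4), max_epochs = 3, seed = 1),
               class = "oae_no_viable_config")
})

test_that("configuration files load with flag-style overrides", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(layer_dims = c(6, 3, 6), lambda = 0.25,
                            max_epochs = 7),
                       f, auto_unbox = TRUE)
  cfg <- read_oae_config(f)
  expect_identical(cfg$layer_dims, c(6L, 3L, 6L))
  expect_equal(cfg$lambda, 0.25)
  expect_identical(cfg$max_epochs, 7L)
  # explicit arguments override the file
  cfg2 <- read_oae_config(f, lambda = 0.5, seed = 9)
  expect_equal(cfg2$lambda, 0.5)
  expect_identical(cfg2$seed, 9L)
  expect_identical(cfg2$max_epochs, 7L)
  # unknown keys are rejected
  fbad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(lamda = 0.1), fbad, auto_unbox = TRUE)
  expect_error(read_oae_config(fbad), class = "oae_config_error")
  # YAML dialect
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("lambda: 0.05", "learning_rate: 1e-4"), fy)
  cfgy <- read_oae_config(fy)
  expect_equal(cfgy$lambda, 0.05)
  expect_equal(cfgy$learning_rate, 1e-4)
  # a fit accepts a ready-made config but not a config plus overrides
  x <- tiny_counts(n_cells = 8, n_genes = 6)
  fit <- oae(x, config = oae_config(layer_dims = c(4, 2, 4), max_epochs = 2))
  expect_identical(nrow(fit$history), 2L)
  expect_error(oae(x, config = cfg, lambda = 1), class = "oae_config_error")
})

test_that("checkpoints round-trip the model exactly", {
  x <- tiny_counts(n_cells = 8, n_genes = 6)
  fit <- oae(x, layer_dims = c(4, 2, 4), max_epochs = 3, seed = 1,
             keep_data = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  write_oae(fit, f)
  back <- read_oae(f)
  expect_equal(back$W, fit$W)
  expect_equal(back$b, fit$b)
  expect_identical(back$gene_names, fit$gene_names)
  expect_equal(back$history, fit$history)
  expect_identical(back$best_epoch, fit$best_epoch)
  expect_equal(encode(back, x), encode(fit, x))
  expect_error(read_oae(withr::local_tempfile(lines = "{}", fileext = ".json")),
               class = "oae_malformed_input")
})

test_that("print and summary report architecture and training state", {
  x <- tiny_counts(n_cells = 8, n_genes = 6)
  fit <- oae(x, layer_dims = c(4, 2, 4), max_epochs = 2, seed = 1)
  expect_output(print(fit), "6 -> 4 -> 2 -> 4 -> 6")
  expect_output(print(summary(fit)), "Training history")
})
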