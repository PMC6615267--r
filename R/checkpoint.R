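# Versioned plain-text (JSON) model checkpoints.

CHECKPOINT_FORMAT <- "oae-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save / load a fitted autoencoder
#'
#' Checkpoints are a single versioned JSON file holding every weight
#' array and bias vector at full double precision, the gene order, the
#' configuration and the training history; `read_oae(write_oae(fit))`
#' round-trips the model exactly.
#'
#' @param object A (possibly untrained) `oae` model.
#' @param path Checkpoint file path.
#' @return `write_oae` returns `path` invisibly; `read_oae` returns the
#'   restored `oae` object.
#' @export
write_oae <- function(object, path) {
  payload <- list(
    format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
    package_version = as.character(packageVersion("oae")),
    config = unclass(object$config),
    gene_names = object$gene_names,
    W = lapply(object$W, function(w) list(dim = dim(w), data = as.vector(w))),
    b = object$b,
    history = object$history,
    best_epoch = object$best_epoch,
    trained = isTRUE(object$trained),
    test_cells = object$test_cells)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_oae
#' @export
read_oae <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, CHECKPOINT_FORMAT))
    stop_oae("oae_malformed_input", path, " is not an oae checkpoint")
  if (unlist(p$version) > CHECKPOINT_VERSION)
    stop_oae("oae_malformed_input", "checkpoint version ", unlist(p$version),
             " is newer than this package supports")
  cfgl <- lapply(p$config, unlist)
  cfg <- oae_config(layer_dims = cfgl$layer_dims, lambda = cfgl$lambda,
                    epsilon = cfgl$epsilon, learning_rate = cfgl$learning_rate,
                    momentum = cfgl$momentum, patience = cfgl$patience,
                    max_epochs = cfgl$max_epochs,
                    test_fraction = cfgl$test_fraction, seed = cfgl$seed,
                    activation = cfgl$activation)
  W <- lapply(p$W, function(w) {
    d <- unlist(w$dim)
    matrix(as.numeric(unlist(w$data)), d[1], d[2])
  })
  b <- lapply(p$b, function(v) as.numeric(unlist(v)))
  hist <- if (!is.null(p$history) && length(p$history)) {
    h <- do.call(rbind, lapply(p$history, function(r) as.data.frame(lapply(r, unlist))))
    rownames(h) <- NULL
    h
  } else NULL
  structure(list(W = W, b = b, gene_names = as.character(unlist(p$gene_names)),
                 config = cfg, history = hist,
                 best_epoch = if (is.null(p$best_epoch)) NA_integer_
                              else as.integer(unlist(p$best_epoch)),
                 trained = isTRUE(unlist(p$trained)),
                 test_cells = as.character(unlist(p$test_cells))),
            class = "oae")
}
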