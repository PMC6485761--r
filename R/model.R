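#' Model configuration for the bimodal multi-sized-filter CNN
#'
#' Collects every architectural and training hyperparameter. The defaults are
#' the full-scale architecture: parallel convolution filters of lengths 8, 16
#' and 32 in every multi-sized convolution module (MCM); 16 filters per size
#' in the first-layer sequence and structure MCMs; three combined MCMs with
#' 32 filters per size, each halving the position axis by max pooling
#' (200 -> 100 -> 50 -> 25); a 64-unit dense layer; sigmoid output trained
#' with binary cross-entropy. Dropout is parameterized as keep-probabilities
#' (0.75 after the first-layer convolutions, 0.5 before the dense layer) and
#' converted to drop rates internally. The optimizer is Adadelta with
#' learning rate 1.0, rho 0.95 and no decay.
#'
#' Position-axis padding is "same" in every convolution so that the
#' multi-size outputs align for stacking; the height axis is fully collapsed
#' ("valid"). The first-layer MCMs do not pool along the position axis; each
#' combined MCM pools by 2, giving exactly one factor-2 reduction between the
#' raw inputs and the first combined response, which the motif-extraction
#' arithmetic relies on.
#'
#' @param filter_sizes Even filter lengths along the position axis.
#' @param filters_per_size Filters per size in the first-layer MCMs.
#' @param combined_filters Filters per size in the combined MCMs.
#' @param n_combined_layers Number of combined MCMs (each pools by 2).
#' @param dense_units Units in the fully connected layer.
#' @param dropout_keep_conv,dropout_keep_dense Keep-probabilities.
#' @param length Input window length; must be divisible by
#'   `2^n_combined_layers`.
#' @param epochs,batch_size,patience Training schedule; early stopping
#'   monitors validation loss and restores the best weights.
#' @param optimizer `"adadelta"` (the default; learning rate 1.0, rho 0.95)
#'   or `"adam"` (with `rho` as the second-moment decay).
#' @param learning_rate,rho,epsilon Optimizer parameters.
#' @param init Weight initializer: `"glorot"` (Glorot-uniform weights, zero
#'   biases) or `"small_uniform"` (convolution weights uniform in
#'   (0.0001, 0.01), a variant that helps on small datasets).
#' @return An object of class `mmcnn_config`.
#' @export
mmcnn_config <- function(filter_sizes = c(8L, 16L, 32L),
                         filters_per_size = 16L,
                         combined_filters = 32L,
                         n_combined_layers = 3L,
                         dense_units = 64L,
                         dropout_keep_conv = 0.75,
                         dropout_keep_dense = 0.5,
                         length = 200L,
                         epochs = 30L,
                         batch_size = 32L,
                         patience = 5L,
                         optimizer = c("adadelta", "adam"),
                         learning_rate = NULL,
                         rho = NULL,
                         epsilon = 1e-6,
                         init = c("glorot", "small_uniform")) {
  filter_sizes <- as.integer(sort(filter_sizes))
  if (length(filter_sizes) == 0L) stop("filter_sizes must be non-empty")
  if (any(filter_sizes %% 2L != 0L)) stop("filter_sizes must be even")
  length <- as.integer(length)
  n_combined_layers <- as.integer(n_combined_layers)
  if (n_combined_layers < 1L) stop("need at least one combined layer")
  if (length %% (2L^n_combined_layers) != 0L)
    stop("length must be divisible by 2^n_combined_layers")
  if (dropout_keep_conv <= 0 || dropout_keep_conv > 1 ||
      dropout_keep_dense <= 0 || dropout_keep_dense > 1)
    stop("dropout keep-probabilities must be in (0, 1]")
  if (filters_per_size < 1L || combined_filters < 1L || dense_units < 1L)
    stop("filter and unit counts must be positive")
  optimizer <- match.arg(optimizer)
  if (is.null(learning_rate)) learning_rate <- if (optimizer == "adadelta") 1.0 else 0.002
  if (is.null(rho)) rho <- if (optimizer == "adadelta") 0.95 else 0.999
  structure(list(
    filter_sizes = filter_sizes,
    filters_per_size = as.integer(filters_per_size),
    combined_filters = as.integer(combined_filters),
    n_combined_layers = n_combined_layers,
    dense_units = as.integer(dense_units),
    dropout_keep_conv = dropout_keep_conv,
    dropout_keep_dense = dropout_keep_dense,
    length = length,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    patience = as.integer(patience),
    optimizer = optimizer,
    learning_rate = learning_rate,
    rho = rho,
    epsilon = epsilon,
    init = match.arg(init)
  ), class = "mmcnn_config")
}

# Shape bookkeeping shared by initialization and the flat<->nested converters.
config_shapes <- function(cfg) {
  S <- length(cfg$filter_sizes)
  C0 <- 2L * S * cfg$filters_per_size
  Cc <- S * cfg$combined_filters
  flat_dim <- (cfg$length %/% 2L^cfg$n_combined_layers) * Cc
  list(S = S, C0 = C0, Cc = Cc, flat_dim = flat_dim,
       type_names = as.vector(rbind(paste0("seq", cfg$filter_sizes),
                                    paste0("shape", cfg$filter_sizes))))
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize untrained network weights
#'
#' Builds the flat weight list for a configuration: Glorot-uniform weights
#' with zero biases, or the small-uniform convolution variant.
#'
#' @param cfg An [mmcnn_config()].
#' @param seed Integer seed for reproducible initialization.
#' @return Flat list of weight matrices (see [weights_nested()] for the
#'   named view).
#' @export
mmcnn_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  sh <- config_shapes(cfg)
  K1 <- cfg$filters_per_size; K2 <- cfg$combined_filters
  conv_init <- function(nr, nc, f, cin) {
    if (cfg$init == "small_uniform")
      matrix(stats::runif(nr * nc, 1e-4, 0.01), nr, nc)
    else glorot(nr, nc, f * cin, f * nc)
  }
  w <- list()
  for (f in cfg$filter_sizes) w <- c(w, list(conv_init(f * 4L, K1, f, 4L)))
  for (f in cfg$filter_sizes) w <- c(w, list(matrix(0, K1, 1L)))
  for (f in cfg$filter_sizes) w <- c(w, list(conv_init(f * f, K1, f, f)))
  for (f in cfg$filter_sizes) w <- c(w, list(matrix(0, K1, 1L)))
  Cin <- sh$C0
  for (l in seq_len(cfg$n_combined_layers)) {
    for (f in cfg$filter_sizes) w <- c(w, list(conv_init(f * Cin, K2, f, Cin)))
    for (f in cfg$filter_sizes) w <- c(w, list(matrix(0, K2, 1L)))
    Cin <- sh$Cc
  }
  w <- c(w, list(glorot(sh$flat_dim, cfg$dense_units, sh$flat_dim, cfg$dense_units),
                 matrix(0, cfg$dense_units, 1L),
                 glorot(cfg$dense_units, 1L, cfg$dense_units, 1L),
                 matrix(0, 1L, 1L)))
  w
}

#' Named view of a flat weight list
#'
#' Converts between the flat weight list consumed by the compiled network and
#' a named nested structure: `seq_w`/`seq_b` (sequence filters, one
#' `(f*4) x K1` matrix per size), `str_w`/`str_b` (structure filters,
#' `(f*f) x K1`), `comb_w`/`comb_b` (combined filters per layer and size,
#' `(f*C) x K2`), and the dense-layer parameters.
#'
#' @param w Flat weight list.
#' @param cfg The matching [mmcnn_config()].
#' @return Named nested list.
#' @export
weights_nested <- function(w, cfg) {
  S <- length(cfg$filter_sizes)
  nm <- paste0("f", cfg$filter_sizes)
  idx <- 0L
  take <- function(n) {
    out <- w[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  out <- list(
    seq_w = stats::setNames(take(S), nm), seq_b = stats::setNames(take(S), nm),
    str_w = stats::setNames(take(S), nm), str_b = stats::setNames(take(S), nm),
    comb_w = list(), comb_b = list())
  for (l in seq_len(cfg$n_combined_layers)) {
    out$comb_w[[l]] <- stats::setNames(take(S), nm)
    out$comb_b[[l]] <- stats::setNames(take(S), nm)
  }
  out$dense1_w <- take(1L)[[1L]]
  out$dense1_b <- take(1L)[[1L]]
  out$dense2_w <- take(1L)[[1L]]
  out$dense2_b <- take(1L)[[1L]]
  out
}

#' @rdname weights_nested
#' @param nested Named nested weight list from [weights_nested()].
#' @export
weights_flatten <- function(nested, cfg) {
  w <- c(nested$seq_w, nested$seq_b, nested$str_w, nested$str_b)
  for (l in seq_len(cfg$n_combined_layers))
    w <- c(w, nested$comb_w[[l]], nested$comb_b[[l]])
  unname(c(w, list(nested$dense1_w, nested$dense1_b,
                   nested$dense2_w, nested$dense2_b)))
}

cfg_for_cpp <- function(cfg) {
  list(length = cfg$length, filter_sizes = as.integer(cfg$filter_sizes),
       filters_per_size = cfg$filters_per_size,
       combined_filters = cfg$combined_filters,
       n_combined_layers = cfg$n_combined_layers,
       dense_units = cfg$dense_units,
       dropout_keep_conv = cfg$dropout_keep_conv,
       dropout_keep_dense = cfg$dropout_keep_dense)
}

check_encoded <- function(data, cfg) {
  stopifnot(is.list(data), !is.null(data$seq), !is.null(data$str))
  d <- dim(data$seq)
  if (d[1L] != cfg$length || d[2L] != 4L)
    stop("encoded data length ", d[1L], " does not match config length ", cfg$length)
  if (length(data$str) != d[3L]) stop("sequence/structure sample counts differ")
  invisible(data)
}

#' Area under the ROC curve
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return AUROC as a plain number.
#' @export
auroc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Fit the bimodal multi-sized-filter CNN
#'
#' Trains the RBP binding-site classifier by stratified k-fold cross
#' validation: the labeled dataset is split into `folds` equal parts, one
#' network is trained per fold (the held-out part serving as the validation
#' set for early stopping), and the fitted object predicts with the
#' arithmetic mean of the fold scores. With `folds = 1` a single network is
#' trained on a stratified `1 - valid_fraction` subset.
#'
#' @param data Encoded dataset from [encode_dataset()] (fields `seq`, `str`,
#'   `labels`); both classes must be present.
#' @param config An [mmcnn_config()].
#' @param folds Number of cross-validation folds (default 10).
#' @param valid_fraction Validation fraction when `folds = 1`.
#' @param seed Integer seed controlling fold assignment, weight
#'   initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses?
#' @return An object of class `mmcnn` with elements `fold_models` (flat
#'   weight lists), `config`, `history`, `fold_auc` (validation AUROC per
#'   fold), `folds`, `seed`.
#' @seealso [predict.mmcnn()], [response_enrichment()], [extract_responses()]
#' @export
mmcnn <- function(data, config = mmcnn_config(), folds = 10L,
                  valid_fraction = 0.1, seed = 1L, verbose = FALSE) {
  check_encoded(data, config)
  labels <- data$labels
  if (is.null(labels)) stop("data has no labels")
  if (length(unique(labels)) < 2L) stop("training data contains a single class")
  folds <- as.integer(folds)
  n <- length(labels)
  if (folds > 1L) {
    fold_id <- stratified_folds(labels, folds, seed)
  } else {
    fold_id <- stratified_folds(labels, max(2L, round(1 / valid_fraction)), seed)
    fold_id <- ifelse(fold_id == 1L, 1L, 2L)  # 1 = validation, rest train
  }
  n_models <- if (folds > 1L) folds else 1L
  fold_models <- vector("list", n_models)
  history <- vector("list", n_models)
  fold_auc <- numeric(n_models)
  opt <- list(epochs = config$epochs, batch_size = config$batch_size,
              optimizer = config$optimizer,
              learning_rate = config$learning_rate, rho = config$rho,
              epsilon = config$epsilon, patience = config$patience,
              seed = 0, verbose = isTRUE(verbose))
  for (f in seq_len(n_models)) {
    vidx <- which(fold_id == f)
    tidx <- setdiff(seq_len(n), vidx)
    if (length(unique(labels[vidx])) < 2L || length(unique(labels[tidx])) < 2L)
      stop("fold ", f, " contains a single class; use fewer folds")
    w0 <- mmcnn_init(config, seed = seed + f)
    opt$seed <- seed * 1000 + f
    fit <- cpp_train(w0, data$seq, data$str, labels,
                     as.integer(tidx - 1L), as.integer(vidx - 1L),
                     cfg_for_cpp(config), opt)
    fold_models[[f]] <- fit$weights
    history[[f]] <- list(train_loss = fit$train_loss,
                         valid_loss = fit$valid_loss,
                         best_epoch = fit$best_epoch)
    vs <- cpp_forward(fit$weights, data$seq[, , vidx, drop = FALSE],
                      data$str[vidx], cfg_for_cpp(config))$scores
    fold_auc[f] <- auroc(vs, labels[vidx])
    if (verbose) message(sprintf("fold %d: validation AUROC %.4f", f, fold_auc[f]))
  }
  structure(list(fold_models = fold_models, config = config,
                 history = history, fold_auc = fold_auc,
                 folds = n_models, seed = seed, call = match.call()),
            class = "mmcnn")
}

#' Predict binding scores
#'
#' The ensemble score of a sequence is the arithmetic mean of the scores of
#' the fold models.
#'
#' @param object Fitted `mmcnn` object.
#' @param newdata Encoded dataset from [encode_dataset()].
#' @param per_fold Return the n x folds matrix of per-fold scores instead of
#'   their mean?
#' @param ... Unused.
#' @return Numeric vector of scores in `[0, 1]` (or a matrix when
#'   `per_fold = TRUE`), named by sequence ids when available.
#' @export
predict.mmcnn <- function(object, newdata, per_fold = FALSE, ...) {
  check_encoded(newdata, object$config)
  cfg <- cfg_for_cpp(object$config)
  m <- vapply(object$fold_models,
              function(w) as.numeric(cpp_forward(w, newdata$seq, newdata$str, cfg)$scores),
              numeric(dim(newdata$seq)[3L]))
  m <- matrix(m, nrow = dim(newdata$seq)[3L])
  rownames(m) <- newdata$ids
  if (per_fold) m else rowMeans(m)
}

#' @export
print.mmcnn <- function(x, ...) {
  cfg <- x$config
  cat("Bimodal multi-sized-filter CNN (mmCNN)\n")
  cat(sprintf("  input: %d nt window; sequence (%d x 4) + structure (%d x %d)\n",
              cfg$length, cfg$length, cfg$length, cfg$length))
  cat(sprintf("  filter sizes: %s; %d first-layer + %d combined filters per size\n",
              paste(cfg$filter_sizes, collapse = ", "),
              cfg$filters_per_size, cfg$combined_filters))
  cat(sprintf("  %d combined MCM layers, dense %d\n",
              cfg$n_combined_layers, cfg$dense_units))
  cat(sprintf("  ensemble of %d fold model(s); mean validation AUROC %.4f\n",
              x$folds, mean(x$fold_auc)))
  invisible(x)
}

#' @export
summary.mmcnn <- function(object, ...) {
  print(object)
  cat("\nPer-fold validation AUROC:\n")
  print(round(object$fold_auc, 4))
  ep <- vapply(object$history, function(h) h$best_epoch, numeric(1))
  cat("Best epoch per fold:", paste(ep, collapse = ", "), "\n")
  invisible(object)
}

#' Filter weights of a fitted model
#'
#' @param object Fitted `mmcnn` object.
#' @param fold Which fold model to inspect.
#' @param ... Unused.
#' @return Named nested weight list (see [weights_nested()]): `W` combined
#'   filters (`comb_w`), `w` sequence filters (`seq_w`), `ws` structure
#'   filters (`str_w`), and biases.
#' @export
coef.mmcnn <- function(object, fold = 1L, ...) {
  weights_nested(object$fold_models[[fold]], object$config)
}

#' Plot training history
#'
#' @param x Fitted `mmcnn` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mmcnn <- function(x, ...) {
  tl <- lapply(x$history, `[[`, "train_loss")
  vl <- lapply(x$history, `[[`, "valid_loss")
  ne <- max(vapply(tl, length, integer(1)))
  pad <- function(v) c(v, rep(NA, ne - length(v)))
  m <- cbind(vapply(tl, pad, numeric(ne)), vapply(vl, pad, numeric(ne)))
  graphics::matplot(m, type = "l", lty = c(rep(1, x$folds), rep(2, x$folds)),
                    xlab = "epoch", ylab = "binary cross-entropy",
                    main = "training (solid) / validation (dashed) loss", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' Writes the configuration as JSON and the fold weights as RDS files into a
#' directory; `load_mmcnn()` restores an identical predictor.
#'
#' @param object Fitted `mmcnn` object.
#' @param dir Checkpoint directory (created if missing).
#' @return `save_mmcnn`: `dir` invisibly; `load_mmcnn`: the `mmcnn` object.
#' @export
save_mmcnn <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(object$config)
  meta <- list(config = cfg, folds = object$folds, seed = object$seed,
               fold_auc = object$fold_auc)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in seq_len(object$folds))
    saveRDS(object$fold_models[[f]], file.path(dir, sprintf("fold_%02d.rds", f)))
  saveRDS(object$history, file.path(dir, "history.rds"))
  invisible(dir)
}

#' @rdname save_mmcnn
#' @export
load_mmcnn <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- do.call(mmcnn_config, meta$config[setdiff(names(meta$config), NULL)])
  folds <- meta$folds
  fold_models <- lapply(seq_len(folds), function(f)
    readRDS(file.path(dir, sprintf("fold_%02d.rds", f))))
  history <- readRDS(file.path(dir, "history.rds"))
  structure(list(fold_models = fold_models, config = cfg, history = history,
                 fold_auc = meta$fold_auc, folds = folds, seed = meta$seed,
                 call = NULL),
            class = "mmcnn")
}

#' Extract internal responses of a fold model
#'
#' Runs a forward pass in inference mode and returns the intermediate
#' activations the motif-extraction procedure consumes: per-size sequence
#' and structure first-layer responses (length x K1, after ReLU), the
#' stacked combined input (length x 2*S*K1, pre-dropout), and the per-size
#' combined response of the first combined MCM (length/2 x K2, after ReLU
#' and pooling), plus the corresponding filter weights.
#'
#' @param object Fitted `mmcnn` object (or a flat weight list).
#' @param data Encoded dataset from [encode_dataset()].
#' @param fold Fold model to use.
#' @param samples Optional integer subset of samples.
#' @return List with `scores`, `responses` (one bundle per sample) and
#'   `weights` (named nested list).
#' @export
extract_responses <- function(object, data, fold = 1L, samples = NULL) {
  cfg <- if (inherits(object, "mmcnn")) object$config else attr(object, "config")
  w <- if (inherits(object, "mmcnn")) object$fold_models[[fold]] else object
  check_encoded(data, cfg)
  if (is.null(samples)) samples <- seq_len(dim(data$seq)[3L])
  out <- cpp_forward(w, data$seq[, , samples, drop = FALSE], data$str[samples],
                     cfg_for_cpp(cfg), responses = TRUE)
  list(scores = as.numeric(out$scores), responses = out$responses,
       weights = weights_nested(w, cfg))
}
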