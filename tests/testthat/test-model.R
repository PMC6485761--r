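test_that("configuration is validated", {
  expect_error(mmcnn_config(filter_sizes = c(3, 8)), "even")
  expect_error(mmcnn_config(filter_sizes = integer(0)), "non-empty")
  expect_error(mmcnn_config(length = 100, n_combined_layers = 3), "divisible")
  expect_error(mmcnn_config(dropout_keep_conv = 0), "keep")
  expect_error(mmcnn_config(filters_per_size = 0), "positive")
  cfg <- mmcnn_config()
  expect_equal(cfg$filter_sizes, c(8L, 16L, 32L))
  expect_equal(cfg$dense_units, 64L)
})

test_that("weight lists round-trip through the nested view", {
  cfg <- toy_config()
  w <- mmcnn_init(cfg, seed = 1)
  nw <- weights_nested(w, cfg)
  expect_equal(dim(nw$seq_w$f4), c(16, 2))
  expect_equal(dim(nw$str_w$f8), c(64, 2))
  expect_equal(dim(nw$comb_w[[1]]$f4), c(4 * 8, 2))
  expect_identical(weights_flatten(nw, cfg), w)
})

test_that("forward pass yields probabilities and exact zero-input behavior", {
  cfg <- toy_config()
  w <- toy_weights(cfg)
  d <- toy_inputs(cfg, 4)
  out <- mmcnn:::cpp_forward(w, d$seq, d$str, mmcnn:::cfg_for_cpp(cfg))
  expect_true(all(out$scores > 0 & out$scores < 1))

  # zero input through zero-bias Glorot net: every response is exactly the
  # propagated bias constant (zero), and the sigmoid output is exactly 1/2
  w0 <- mmcnn_init(cfg, seed = 2)
  zs <- array(0, c(cfg$length, 4, 1))
  ze <- list(matrix(numeric(0), ncol = 3))
  out0 <- mmcnn:::cpp_forward(w0, zs, ze, mmcnn:::cfg_for_cpp(cfg), TRUE)
  expect_identical(as.numeric(out0$scores), 0.5)
  r <- out0$responses[[1]]
  expect_true(all(vapply(r$sequence, function(m) all(m == 0), logical(1))))
  expect_true(all(vapply(r$structure, function(m) all(m == 0), logical(1))))
})

test_that("responses match the brute-force forward oracle", {
  cfg <- toy_config()
  w <- toy_weights(cfg, seed = 5)
  d <- toy_inputs(cfg, 3, seed = 9)
  er <- extract_responses(structure(list(fold_models = list(w), config = cfg,
                                         folds = 1), class = "mmcnn"), d)
  for (i in 1:3) {
    o <- oracle_forward(w, cfg, d$seq[, , i], dense_structure(d$str[[i]], cfg$length))
    expect_equal(er$scores[i], o$score, tolerance = 1e-10)
    for (s in 1:2) {
      expect_equal(er$responses[[i]]$sequence[[s]], o$seq[[s]], tolerance = 1e-10)
      expect_equal(er$responses[[i]]$structure[[s]], o$str[[s]], tolerance = 1e-10)
      expect_equal(er$responses[[i]]$combined_response[[s]],
                   o$combined_response[[s]], tolerance = 1e-10)
    }
    expect_equal(er$responses[[i]]$combined_input, o$combined_input,
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- toy_config()
  w <- toy_weights(cfg, seed = 3)
  d <- toy_inputs(cfg, 4, seed = 4)
  g <- mmcnn:::cpp_grads(w, d$seq, d$str, d$labels, mmcnn:::cfg_for_cpp(cfg))
  eps <- 1e-6
  set.seed(6)
  for (t in sample(seq_along(w), 8)) {
    i <- sample(nrow(w[[t]]), 1); j <- sample(ncol(w[[t]]), 1)
    wp <- w; wp[[t]][i, j] <- wp[[t]][i, j] + eps
    wm <- w; wm[[t]][i, j] <- wm[[t]][i, j] - eps
    fd <- (mmcnn:::cpp_grads(wp, d$seq, d$str, d$labels, mmcnn:::cfg_for_cpp(cfg))$loss -
           mmcnn:::cpp_grads(wm, d$seq, d$str, d$labels, mmcnn:::cfg_for_cpp(cfg))$loss) /
      (2 * eps)
    expect_equal(g$grads[[t]][i, j], fd, tolerance = 1e-5)
  }
})

test_that("forward pass is translation-covariant along the position axis", {
  cfg <- toy_config()
  w <- toy_weights(cfg, seed = 8)
  L <- cfg$length
  set.seed(10)
  base <- sample(4, L, TRUE)
  x1 <- array(0, c(L, 4, 1)); x1[cbind(1:L, base, 1)] <- 1
  x2 <- array(0, c(L, 4, 1))  # same content shifted by +2 positions
  x2[cbind(3:L, base[1:(L - 2)], 1)] <- 1
  es <- list(matrix(numeric(0), ncol = 3))
  r1 <- mmcnn:::cpp_forward(w, x1, es, mmcnn:::cfg_for_cpp(cfg), TRUE)$responses[[1]]
  r2 <- mmcnn:::cpp_forward(w, x2, es, mmcnn:::cfg_for_cpp(cfg), TRUE)$responses[[1]]
  for (s in 1:2) {
    # interior rows, away from both boundaries and the filter footprint
    f <- cfg$filter_sizes[s]
    rows <- (f + 2):(L - f - 2)
    expect_equal(r2$sequence[[s]][rows + 2, ], r1$sequence[[s]][rows, ],
                 tolerance = 1e-10)
    # pooled combined response shifts by 1 when the input shifts by 2
    prows <- (f %/% 2 + 2):(L / 2 - f %/% 2 - 2)
    expect_equal(r2$combined_response[[s]][prows + 1, ],
                 r1$combined_response[[s]][prows, ], tolerance = 1e-10)
  }
})

test_that("training separates planted toy data and is seed-deterministic", {
  cfg <- toy_config(epochs = 20L, patience = 99L, filters_per_size = 4L,
                    batch_size = 16L)
  set.seed(20)
  L <- 32; n <- 400
  seqs <- array(0, c(L, 4, n)); labels <- rep_len(c(1, 0), n)
  for (i in 1:n) {
    s <- sample(4, L, TRUE)
    if (labels[i] == 1) s[13:16] <- c(2, 3, 2, 1)
    seqs[cbind(1:L, s, i)] <- 1
  }
  d <- list(seq = seqs, str = rep(list(matrix(numeric(0), ncol = 3)), n),
            labels = labels, ids = as.character(1:n), length = L)
  fit <- mmcnn(d, cfg, folds = 1, seed = 5)
  p <- predict(fit, d)
  expect_gt(auroc(p, labels), 0.99)

  fit2 <- mmcnn(d, cfg, folds = 1, seed = 5)
  expect_identical(predict(fit2, d), p)     # bitwise deterministic

  # label shuffle destroys the signal
  d0 <- d; set.seed(30); d0$labels <- sample(d0$labels)
  fit0 <- mmcnn(d0, toy_config(epochs = 5L), folds = 1, seed = 5)
  expect_lt(abs(fit0$fold_auc - 0.5), 0.15)
})

test_that("cross-validation produces per-fold models averaged at prediction", {
  cfg <- toy_config(epochs = 2L)
  d <- toy_inputs(cfg, 60, seed = 12)
  fit <- mmcnn(d, cfg, folds = 3, seed = 2)
  expect_equal(fit$folds, 3)
  pf <- predict(fit, d, per_fold = TRUE)
  expect_equal(dim(pf), c(60, 3))
  expect_identical(unname(predict(fit, d)), unname(rowMeans(pf)))
  expect_error(mmcnn(list(seq = d$seq, str = d$str,
                          labels = rep(1, 60), ids = d$ids, length = 32),
                     cfg, folds = 3), "single class")
})

test_that("checkpoints restore identical predictors", {
  cfg <- toy_config(epochs = 2L)
  d <- toy_inputs(cfg, 30, seed = 13)
  fit <- mmcnn(d, cfg, folds = 2, seed = 9)
  dir <- tempfile()
  save_mmcnn(fit, dir)
  fit2 <- load_mmcnn(dir)
  expect_identical(predict(fit2, d), predict(fit, d))
  expect_equal(fit2$fold_auc, fit$fold_auc)
})
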