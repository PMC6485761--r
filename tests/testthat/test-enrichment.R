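toy_model <- function(cfg = toy_config(), seed = 5) {
  structure(list(fold_models = list(toy_weights(cfg, seed = seed)),
                 config = cfg, folds = 1, fold_auc = NA_real_),
            class = "mmcnn")
}

test_that("maximal combined responses agree with an exhaustive scan", {
  cfg <- toy_config()
  fit <- toy_model(cfg)
  d <- toy_inputs(cfg, 6, seed = 21)
  idx <- max_combined_response(fit, d, fold = 1)
  er <- extract_responses(fit, d)
  for (i in 1:6) for (s in 1:2) {
    m <- er$responses[[i]]$combined_response[[s]]
    best <- max(m)
    cand <- which(m == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    expect_equal(c(idx$x[i, s], idx$k[i, s]), unname(cand[1, ]))
  }
  expect_error(max_combined_response(fit, subset_encoded(d, integer(0))),
               "at least one")
})

test_that("tie-breaking picks the lowest position, then filter index", {
  expect_equal(mmcnn:::argmax2(matrix(0, 5, 3)), c(1, 1))
  m <- matrix(0, 5, 3); m[4, 2] <- 7
  expect_equal(mmcnn:::argmax2(m), c(4, 2))
  m2 <- matrix(0, 5, 3); m2[2, 3] <- 7; m2[2, 1] <- 7; m2[4, 1] <- 7
  expect_equal(mmcnn:::argmax2(m2), c(2, 1))
})

test_that("combined enrichment: delta filter, linearity and additivity", {
  cfg <- toy_config()
  w <- mmcnn_init(cfg, 1)
  for (t in seq_along(w)) w[[t]] <- w[[t]] * 0
  nw <- weights_nested(w, cfg)
  C0 <- 2 * 2 * 2
  # delta combined filter for size 4: weight 1 at (X=2, channel 1, k=1);
  # channel 1 is the seq4 k'=1 response, given signal via its filter
  W1 <- nw$comb_w[[1]]$f4
  W1[(2 - 1) * C0 + 1, 1] <- 1
  nw$comb_w[[1]]$f4 <- W1
  nw$seq_w$f4[1, 1] <- 0.5
  w <- weights_flatten(nw, cfg)
  fit <- structure(list(fold_models = list(w), config = cfg, folds = 1),
                   class = "mmcnn")
  d <- toy_inputs(cfg, 4, seed = 3)
  idx <- max_combined_response(fit, d, fold = 1)
  ce <- combined_enrichment(fit, d, idx, fold = 1)
  er <- extract_responses(fit, d)
  # delta filter: enrichment cell (2, ch 3) equals the sum over samples of the
  # combined-input value at that window cell; all other cells are zero
  expected <- 0
  for (i in 1:4) {
    rows0 <- 2 * (idx$x[i, 1] - 1) - 2 + 0:3
    if (rows0[1] < 0 || rows0[4] >= cfg$length) next
    expected <- expected + er$responses[[i]]$combined_input[rows0[2] + 1, 1]
  }
  expect_equal(ce$E[[1]][2, 1], expected, tolerance = 1e-10)
  expect_equal(sum(ce$E[[1]] != 0), sum(ce$E[[1]][2, 1] != 0))

  # additivity over disjoint sample sets (before the max over k')
  dA <- subset_encoded(d, 1:2); dB <- subset_encoded(d, 3:4)
  iA <- max_combined_response(fit, dA, fold = 1)
  iB <- max_combined_response(fit, dB, fold = 1)
  eA <- combined_enrichment(fit, dA, iA, fold = 1)
  eB <- combined_enrichment(fit, dB, iB, fold = 1)
  for (s in 1:2)
    expect_equal(eA$E[[s]] + eB$E[[s]], ce$E[[s]], tolerance = 1e-10)

  # N identical samples scale the enrichment N-fold
  d1 <- subset_encoded(d, 1)
  dN <- subset_encoded(d, c(1, 1, 1))
  i1 <- max_combined_response(fit, d1, fold = 1)
  iN <- max_combined_response(fit, dN, fold = 1)
  e1 <- combined_enrichment(fit, d1, i1, fold = 1)
  eN <- combined_enrichment(fit, dN, iN, fold = 1)
  expect_equal(eN$E[[1]], 3 * e1$E[[1]], tolerance = 1e-10)
})

test_that("selection maximizes response score with documented tie rules", {
  mk <- function(scores, enr) {
    structure(list(enrichment = enr, response_score = scores,
                   filter_sizes = c(4L, 8L),
                   type_names = c("seq4", "shape4", "seq8", "shape8"),
                   fold = 1L),
              class = "mmcnn_combined_enrichment")
  }
  e4 <- matrix(0, 4, 4); e4[2, 1] <- 5; e4[3, 2] <- 1
  e8 <- matrix(0, 8, 4)
  sel <- select_enrichment(mk(c(5, 3), list(e4, e8)))
  expect_equal(sel$filter_size, 4)
  expect_equal(sel$t_seq_name, "seq4")
  expect_equal(sel$d_seq, 2 - 1 - 2)   # z = 2 (1-based), center 2
  expect_equal(sel$t_struct_name, "shape4")

  # equal scores -> the smaller size wins; all-equal enrichment -> first types
  sel2 <- select_enrichment(mk(c(3, 3), list(matrix(1, 4, 4), matrix(1, 8, 4))))
  expect_equal(sel2$filter_size, 4)
  expect_equal(sel2$t_seq_name, "seq4")
  expect_equal(sel2$z_seq, 1)
})

test_that("every enrichment quantity matches the explicit-loop oracle", {
  cfg <- toy_config()
  fit <- toy_model(cfg, seed = 17)
  d <- toy_inputs(cfg, 5, seed = 23)
  o <- oracle_enrichment(fit$fold_models[[1]], cfg, d)

  idx <- max_combined_response(fit, d, fold = 1)
  expect_equal(unname(idx$x), unname(o$x))
  expect_equal(unname(idx$k), unname(o$k))

  ce <- combined_enrichment(fit, d, idx, fold = 1)
  for (s in 1:2) {
    expect_equal(ce$E[[s]], o$E[[s]], tolerance = 1e-6)
    expect_equal(unname(ce$enrichment[[s]]), o$enrichment[[s]], tolerance = 1e-6)
  }
  expect_equal(ce$response_score, o$response_score, tolerance = 1e-6)

  sel <- select_enrichment(ce)
  expect_equal(sel$size_index, o$size_index)
  expect_equal(sel$t_seq, o$t_seq)
  expect_equal(sel$t_struct, o$t_struct)
  expect_equal(sel$d_seq, o$d_seq)
  expect_equal(sel$d_struct, o$d_struct)

  se <- sequence_enrichment(fit, d, idx, sel, fold = 1)
  expect_equal(unname(se$matrix), o$sequence$matrix, tolerance = 1e-6)
  expect_equal(se$n_used, o$sequence$n_used)

  st <- structure_enrichment(fit, d, idx, sel, fold = 1)
  expect_equal(st$matrix, o$structure$matrix, tolerance = 1e-6)
  expect_equal(st$profile, o$profile, tolerance = 1e-6)

  expect_equal(unname(to_pwm(se)$pwm), o$pwm, tolerance = 1e-6)
  al <- align_motifs(se, st, sel)
  expect_equal(attr(al, "offset"), o$offset)
})

test_that("softmax PWM conversion and 12-window selection", {
  expect_equal(unname(to_pwm(matrix(0, 3, 4))$pwm),
               matrix(0.25, 3, 4))
  big <- matrix(0, 2, 4); big[1, 2] <- 50
  expect_gt(to_pwm(big)$pwm[1, 2], 0.999)

  set.seed(2)
  m <- matrix(rnorm(20 * 4), 20, 4)
  pw <- to_pwm(m, window = 12)
  expect_equal(rowSums(pw$pwm), rep(1, 20), tolerance = 1e-12)
  sc <- rowSums(m)
  best <- which.max(vapply(1:9, function(s) sum(sc[s:(s + 11)]), numeric(1)))
  expect_equal(pw$window_start, best)
  expect_equal(pw$window_pwm, pw$pwm[best:(best + 11), ])
})

test_that("motif alignment merges PWM and structure profile on one axis", {
  cfg <- toy_config()
  fit <- toy_model(cfg, seed = 31)
  d <- toy_inputs(cfg, 4, seed = 32)
  idx <- max_combined_response(fit, d, fold = 1)
  ce <- combined_enrichment(fit, d, idx, fold = 1)
  sel <- select_enrichment(ce)
  se <- sequence_enrichment(fit, d, idx, sel, fold = 1)
  st <- structure_enrichment(fit, d, idx, sel, fold = 1)
  al <- align_motifs(se, st, sel)
  expect_s3_class(al, "mmcnn_aligned_motif")
  expect_identical(attr(al, "offset"), sel$d_seq - sel$d_struct)
  expect_equal(sum(!is.na(al$p_A)), se$filter_size)
  expect_equal(sum(!is.na(al$structure_score)), st$filter_size)
  expect_equal(diff(al$position), rep(1, nrow(al) - 1))

  sel0 <- sel; sel0$d_struct <- sel0$d_seq
  expect_identical(attr(align_motifs(se, st, sel0), "offset"), 0L)
  tf <- tempfile()
  write_motif_table(al, tf)
  back <- utils::read.delim(tf)
  expect_equal(back$position, al$position)
})

test_that("boundary windows are dropped and counted", {
  cfg <- toy_config()
  fit <- toy_model(cfg, seed = 41)
  d <- toy_inputs(cfg, 3, seed = 42)
  idx <- max_combined_response(fit, d, fold = 1)
  idx$x[, 2] <- 1L   # force windows across the left boundary for size 8
  ce <- combined_enrichment(fit, d, idx, fold = 1)
  expect_equal(ce$n_dropped[2], 3L)
  idx$x[, 1] <- 1L
  sel <- structure(list(size_index = 1L, filter_size = 4L, t_seq = 1L,
                        t_seq_name = "seq4", t_struct = 2L,
                        t_struct_name = "shape4", z_seq = 1L, z_struct = 1L,
                        d_seq = -10L, d_struct = -10L,
                        response_score = 1, fold = 1L),
                   class = "mmcnn_selection")
  expect_error(sequence_enrichment(fit, d, idx, sel, fold = 1), "dropped")
})

test_that("MEME minimal format round-trips RNA PWMs", {
  set.seed(9)
  p1 <- matrix(runif(32), 8, 4); p1 <- p1 / rowSums(p1)
  colnames(p1) <- c("A", "U", "G", "C")
  p2 <- matrix(runif(16), 4, 4); p2 <- p2 / rowSums(p2)
  colnames(p2) <- c("A", "U", "G", "C")
  tf <- tempfile(fileext = ".meme")
  write_meme(list(alpha = p1, beta = p2), tf, nsites = 50)
  txt <- readLines(tf)
  expect_true(any(grepl("^MEME version", txt)))
  expect_true(any(grepl("ALPHABET= ACGU", txt)))
  back <- read_meme(tf)
  expect_equal(names(back), c("alpha", "beta"))
  expect_equal(back$alpha, p1, tolerance = 1e-5)
  expect_equal(back$beta, p2, tolerance = 1e-5)
  expect_equal(pwm_consensus(p1),
               paste(c("A", "U", "G", "C")[apply(p1, 1, which.max)], collapse = ""))
})
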