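test_that("positives carry the planted consensus at the drawn positions", {
  spec <- synthetic_spec(n_pos = 10, n_neg = 0, motif = "UGUAAAUA",
                         motif_positions = 96, seed = 4)
  gs <- generate_sequences(spec)
  expect_equal(nrow(gs$records), 10)
  expect_true(all(substr(gs$records$sequence, 96, 103) == "UGUAAAUA"))
  expect_equal(gs$truth$motif_starts, rep(96L, 10))

  spec2 <- synthetic_spec(n_pos = 30, n_neg = 0, motif_positions = c(50, 150),
                          seed = 5)
  gs2 <- generate_sequences(spec2)
  st <- gs2$truth$motif_starts
  expect_true(all(st >= 50 & st <= 150))
  expect_true(all(mapply(function(s, p) substr(s, p, p + 7) == "UGUAAAUA",
                         gs2$records$sequence, st)))
})

test_that("generation is reproducible from the seed", {
  spec <- synthetic_spec(n_pos = 15, n_neg = 15, seed = 7,
                         stem = list(start = 95, length = 6, loop = 4, target = 0.9))
  a <- generate_sequences(spec); b <- generate_sequences(spec)
  expect_identical(a, b)
  ea <- generate_ensembles(a$records, spec)
  eb <- generate_ensembles(b$records, spec)
  expect_identical(ea, eb)
})

test_that("dinucleotide shuffling preserves exact dinucleotide counts", {
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  spec <- synthetic_spec(n_pos = 5, n_neg = 5, seed = 9)
  gs <- generate_sequences(spec)
  for (i in 1:5) {
    pos <- gs$records$sequence[i]
    neg <- gs$records$sequence[5 + i]
    expect_identical(dinucs(neg), dinucs(pos))
    expect_false(identical(neg, pos))
  }
})

test_that("background negatives match the background composition", {
  spec <- synthetic_spec(n_pos = 1, n_neg = 40, motif = NULL,
                         negatives = "background", seed = 10)
  gs <- generate_sequences(spec)
  counts <- table(factor(unlist(strsplit(
    gs$records$sequence[gs$records$label == 0], "")), c("A", "U", "G", "C")))
  n <- sum(counts)
  # 3 sigma of a multinomial with p = 1/4
  expect_true(all(abs(counts - n / 4) < 3 * sqrt(n * 0.25 * 0.75)))
})

test_that("planted ensembles hit the pair-probability target analytically", {
  stem <- list(start = 50, length = 5, loop = 4, target = 0.8)
  spec <- synthetic_spec(n_pos = 6, n_neg = 6, length = 120,
                         motif_positions = 30, stem = stem,
                         ensemble_size = 20, seed = 12)
  gs <- generate_sequences(spec)
  ens <- generate_ensembles(gs$records, spec)
  planted <- cbind(50:54, 63:59)  # pairs (start+k, end3-k), end3 = 63
  for (i in 1:6) {
    m <- stem_probability_matrix(ens[[paste0("pos_", sprintf("%04d", i))]],
                                 length = 120)
    expect_equal(unname(m[planted]), rep(0.8, 5), tolerance = 0.02)
    mn <- stem_probability_matrix(ens[[paste0("neg_", sprintf("%04d", i))]],
                                  length = 120)
    expect_true(all(mn[planted] < 1e-9))
  }
  # target 1 with a single dominant structure: entries exactly 1
  spec1 <- synthetic_spec(n_pos = 2, n_neg = 0, length = 120,
                          motif_positions = 30,
                          stem = list(start = 50, length = 5, loop = 4, target = 1),
                          ensemble_size = 10, n_dominant = 1, seed = 13)
  gs1 <- generate_sequences(spec1)
  e1 <- generate_ensembles(gs1$records, spec1)
  m1 <- stem_probability_matrix(e1$pos_0001, length = 120)
  expect_equal(unname(m1[planted]), rep(1, 5), tolerance = 1e-6)
})

test_that("generated data passes the package's own validators end to end", {
  spec <- synthetic_spec(n_pos = 4, n_neg = 4, seed = 14,
                         stem = list(start = 95, length = 6, loop = 4, target = 0.9))
  dir <- tempfile()
  out <- generate_dataset(spec, dir)
  expect_setequal(list.files(dir), c("positives.fa", "negatives.fa",
                                     "ensembles.txt", "truth.json"))
  pos <- read_labeled_fasta(file.path(dir, "positives.fa"), 1)
  neg <- read_labeled_fasta(file.path(dir, "negatives.fa"), 0)
  ens <- parse_ensemble_file(file.path(dir, "ensembles.txt"))
  expect_equal(nrow(pos), 4); expect_equal(nrow(neg), 4)
  expect_setequal(names(ens), c(pos$id, neg$id))
  d <- encode_dataset(rbind(pos, neg), ens, require_ensembles = TRUE)
  expect_equal(dim(d$seq), c(200, 4, 8))
  for (tr in d$str) {
    expect_true(all(tr[, 3] >= 0 & tr[, 3] <= 1))
    expect_true(all(tr[, 1] >= 0 & tr[, 1] < 200))
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$consensus, "UGUAAAUA")
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(motif = strrep("A", 300)), "longer")
  expect_error(synthetic_spec(stem = list(start = 95, length = 6, loop = 2)),
               "loop")
  expect_error(synthetic_spec(stem = list(start = 190, length = 6, loop = 4)),
               "fit")
  expect_error(synthetic_spec(motif = "UGUX"), "A,C,G,U")
})

test_that("stronger planted motifs are easier to classify", {
  aucs <- vapply(c(0.45, 0.75, 1), function(pr) {
    spec <- synthetic_spec(n_pos = 150, n_neg = 150, length = 64,
                           motif = "UGUAAA", motif_prob = pr,
                           motif_positions = c(20, 40),
                           negatives = "background", seed = 21)
    gs <- generate_sequences(spec)
    d <- encode_dataset(gs$records, NULL, length = 64)
    cfg <- mmcnn_config(filter_sizes = c(4, 8), filters_per_size = 4,
                        combined_filters = 4, length = 64, epochs = 12,
                        batch_size = 16, patience = 99)
    fit <- mmcnn(d, cfg, folds = 1, valid_fraction = 0.25, seed = 2)
    fit$fold_auc
  }, numeric(1))
  expect_true(aucs[3] >= aucs[2] - 0.05 && aucs[2] >= aucs[1] - 0.05)
  expect_gt(aucs[3], aucs[1])
})
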