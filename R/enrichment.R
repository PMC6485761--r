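# Motif extraction by filter response enrichment.
#
# Positive samples are pushed through a trained fold model; for every filter
# size the position/filter pair maximizing the combined response is located,
# windows of the stacked combined representation (and later of the raw
# inputs) are multiplied elementwise by the maximally-responding filters'
# weights and summed over samples. Internally all positional arithmetic is
# 0-based to match the mapping P(x_n, d_t) = 2(x_n + d_t) between the pooled
# combined-response axis and raw sequence coordinates; the reported positions
# are 1-based.

argmax2 <- function(m) {
  idx <- which(m == max(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  unname(c(idx[1L, 1L], idx[1L, 2L]))
}

# Apply fun(responses, sample_indices) over chunks of forward passes.
for_each_response_chunk <- function(object, data, fold, chunk, fun) {
  n <- dim(data$seq)[3L]
  for (st in seq.int(1L, n, by = chunk)) {
    ids <- seq.int(st, min(n, st + chunk - 1L))
    er <- extract_responses(object, data, fold = fold, samples = ids)
    fun(er$responses, ids)
  }
  invisible(NULL)
}

#' Locate maximal combined responses of positive samples
#'
#' For each positive sample and each filter size, finds the position `x_n`
#' (on the pooled combined-response axis of length `length/2`) and combined
#' filter index `k_n` of the global maximum of the first combined MCM
#' response. Ties are broken towards the lowest position, then the lowest
#' filter index.
#'
#' @param object Fitted `mmcnn` object.
#' @param data Encoded positive samples from [encode_dataset()].
#' @param fold Fold model to analyze.
#' @param chunk Samples per forward-pass chunk.
#' @return Object of class `mmcnn_maxresponse`: list with integer matrices
#'   `x` and `k` (samples x filter sizes, 1-based) and the config.
#' @export
max_combined_response <- function(object, data, fold = 1L, chunk = 256L) {
  cfg <- object$config
  n <- dim(data$seq)[3L]
  if (n < 1L) stop("need at least one positive sample")
  S <- length(cfg$filter_sizes)
  x <- matrix(0L, n, S); k <- matrix(0L, n, S)
  for_each_response_chunk(object, data, fold, chunk, function(resp, ids) {
    for (u in seq_along(ids)) {
      for (s in seq_len(S)) {
        a <- argmax2(resp[[u]]$combined_response[[s]])
        x[ids[u], s] <<- a[1L]; k[ids[u], s] <<- a[2L]
      }
    }
  })
  structure(list(x = x, k = k, fold = fold, config = cfg),
            class = "mmcnn_maxresponse")
}

#' Combined response enrichment
#'
#' For each filter size, extracts per sample the window of the stacked
#' combined representation of width `filter_size` centered over the maximal
#' combined response (the pooled position `x_n` is mapped back to the
#' unpooled axis as `2 x_n` before windowing), multiplies it elementwise by
#' the responding combined filter `k_n`'s weights, sums over samples, and
#' takes the maximum over the first-layer filter index to suppress noise.
#' Samples whose window crosses the array boundary are dropped and counted.
#'
#' @param object Fitted `mmcnn` object.
#' @param data Encoded positives (same ones used for `indices`).
#' @param indices [max_combined_response()] result.
#' @param fold,chunk As in [max_combined_response()].
#' @return Object of class `mmcnn_combined_enrichment`: per filter size the
#'   raw enrichment `E` (filter_size x 2S*K1), the type-level `enrichment`
#'   matrix (filter_size x 2S, after max over first-layer filters), the
#'   `response_score`, and dropped-sample counts.
#' @export
combined_enrichment <- function(object, data, indices, fold = indices$fold,
                                chunk = 256L) {
  cfg <- object$config
  sh <- config_shapes(cfg)
  S <- sh$S; K1 <- cfg$filters_per_size; C0 <- sh$C0; L <- cfg$length
  W1 <- weights_nested(object$fold_models[[fold]], cfg)$comb_w[[1L]]
  E <- lapply(cfg$filter_sizes, function(f) matrix(0, f, C0))
  used <- integer(S); dropped <- integer(S)
  for_each_response_chunk(object, data, fold, chunk, function(resp, ids) {
    for (u in seq_along(ids)) {
      ci <- resp[[u]]$combined_input
      for (s in seq_len(S)) {
        f <- cfg$filter_sizes[s]
        x0 <- indices$x[ids[u], s] - 1L
        rows0 <- 2L * x0 - f %/% 2L + seq_len(f) - 1L
        if (rows0[1L] < 0L || rows0[f] >= L) {
          dropped[s] <<- dropped[s] + 1L
          next
        }
        kn <- indices$k[ids[u], s]
        Wk <- t(matrix(W1[[s]][, kn], nrow = C0))   # f x C0
        E[[s]] <<- E[[s]] + ci[rows0 + 1L, , drop = FALSE] * Wk
        used[s] <<- used[s] + 1L
      }
    }
  })
  if (all(used == 0L))
    stop("all ", dim(data$seq)[3L], " samples dropped at the array boundary")
  enr <- vector("list", S)
  score <- numeric(S)
  for (s in seq_len(S)) {
    # max over first-layer filter index k' within each type block
    m <- sapply(seq_len(2L * S), function(t)
      apply(E[[s]][, (t - 1L) * K1 + seq_len(K1), drop = FALSE], 1L, max))
    m <- matrix(m, nrow = cfg$filter_sizes[s],
                dimnames = list(NULL, sh$type_names))
    enr[[s]] <- m
    score[s] <- sum(apply(m, 2L, max))
  }
  structure(list(E = E, enrichment = enr, response_score = score,
                 filter_sizes = cfg$filter_sizes, type_names = sh$type_names,
                 n_used = used, n_dropped = dropped, fold = fold,
                 config = cfg),
            class = "mmcnn_combined_enrichment")
}

#' Select the best enrichment
#'
#' Chooses the filter size with the maximal response score and, within it,
#' the best sequence filter type and best structure filter type (maximum
#' over positions of the type's enrichment). For each selected type the
#' shifting constant `d_t` is the difference between the maximally enriched
#' position and the window center `filter_size/2`. Ties resolve to the
#' smaller filter size and the lower type index.
#'
#' @param ce A [combined_enrichment()] result.
#' @return Object of class `mmcnn_selection` with the selected size, types,
#'   argmax positions `z` (1-based) and shifting constants `d_seq`,
#'   `d_struct` (in raw-sequence coordinates).
#' @export
select_enrichment <- function(ce) {
  si <- which.max(ce$response_score)   # first max -> smaller size (sizes sorted)
  m <- ce$enrichment[[si]]
  f <- ce$filter_sizes[si]
  S <- length(ce$filter_sizes)
  seq_types <- seq.int(1L, 2L * S, by = 2L)
  str_types <- seq.int(2L, 2L * S, by = 2L)
  pick <- function(types) {
    mx <- apply(m[, types, drop = FALSE], 2L, max)
    types[which.max(mx)]
  }
  t_seq <- pick(seq_types)
  t_struct <- pick(str_types)
  z_seq <- which.max(m[, t_seq])
  z_struct <- which.max(m[, t_struct])
  structure(list(
    size_index = si, filter_size = f,
    t_seq = t_seq, t_seq_name = ce$type_names[t_seq],
    t_struct = t_struct, t_struct_name = ce$type_names[t_struct],
    z_seq = z_seq, z_struct = z_struct,
    d_seq = (z_seq - 1L) - f %/% 2L,
    d_struct = (z_struct - 1L) - f %/% 2L,
    response_score = ce$response_score[si],
    fold = ce$fold),
    class = "mmcnn_selection")
}

# Shared per-sample mapping from the pooled argmax x_n to raw coordinates:
# candidate positions 2(x_n + d_t) and 2(x_n + d_t) + 1, the one with the
# higher first-layer response of the selected type wins (tie -> the even
# position); returns NULL when the window crosses the boundary.
map_sample_position <- function(x0, d, f_t, L, resp) {
  p0 <- 2L * (x0 + d)
  if (p0 < 0L || p0 + 1L >= L) return(NULL)
  r0 <- max(resp[p0 + 1L, ]); r1 <- max(resp[p0 + 2L, ])
  P0 <- if (r1 > r0) p0 + 1L else p0
  win0 <- P0 - f_t %/% 2L + seq_len(f_t) - 1L
  if (win0[1L] < 0L || win0[f_t] >= L) return(NULL)
  kprime <- which.max(resp[P0 + 1L, ])
  list(P0 = P0, win0 = win0, kprime = kprime)
}

# Combined-filter weighting factor W[z, t, k', k_n] for the selected size.
combined_weight_factor <- function(W1s, z, t, kprime, kn, K1, C0) {
  W1s[(z - 1L) * C0 + (t - 1L) * K1 + kprime, kn]
}

#' Sequence response enrichment
#'
#' Maps each positive's maximal combined-response position back to raw
#' sequence coordinates via `P(x_n, d_t) = 2(x_n + d_t)` (choosing between
#' the two pooled-away positions by the higher sequence response), windows
#' the one-hot sequence with the selected sequence filter's length, and
#' accumulates the elementwise product with that filter's weights, scaled by
#' the combined-filter weighting factor `W[z, t_seq, k'_n, k_n]`. Windowed
#' positions falling outside the array are dropped.
#'
#' @param object,data,indices,fold,chunk As in [combined_enrichment()].
#' @param selection A [select_enrichment()] result.
#' @return Object of class `mmcnn_sequence_enrichment`: `matrix`
#'   (filter length x 4, columns A,U,G,C of weighted nucleotide
#'   propensities), the sequence filter size, and sample counts.
#' @export
sequence_enrichment <- function(object, data, indices, selection,
                                fold = selection$fold, chunk = 256L) {
  cfg <- object$config
  sh <- config_shapes(cfg)
  K1 <- cfg$filters_per_size
  s_seq <- (selection$t_seq + 1L) %/% 2L
  f_t <- cfg$filter_sizes[s_seq]
  nw <- weights_nested(object$fold_models[[fold]], cfg)
  W1s <- nw$comb_w[[1L]][[selection$size_index]]
  acc <- matrix(0, f_t, 4L, dimnames = list(NULL, .NUC))
  used <- 0L; dropped <- 0L
  si <- selection$size_index
  for_each_response_chunk(object, data, fold, chunk, function(resp, ids) {
    for (u in seq_along(ids)) {
      x0 <- indices$x[ids[u], si] - 1L
      kn <- indices$k[ids[u], si]
      mp <- map_sample_position(x0, selection$d_seq, f_t, cfg$length,
                                resp[[u]]$sequence[[s_seq]])
      if (is.null(mp)) { dropped <<- dropped + 1L; next }
      wf <- combined_weight_factor(W1s, selection$z_seq, selection$t_seq,
                                   mp$kprime, kn, K1, sh$C0)
      wseq <- t(matrix(nw$seq_w[[s_seq]][, mp$kprime], nrow = 4L))  # f_t x 4
      acc <<- acc + wf * (data$seq[mp$win0 + 1L, , ids[u]] * wseq)
      used <<- used + 1L
    }
  })
  if (used == 0L)
    stop("all ", dim(data$seq)[3L], " samples dropped at the array boundary")
  structure(list(matrix = acc, filter_size = f_t, s_seq = s_seq,
                 n_used = used, n_dropped = dropped, selection = selection),
            class = "mmcnn_sequence_enrichment")
}

#' Structure response enrichment
#'
#' Same procedure as [sequence_enrichment()] for the selected structure
#' filter type: a `filter_size x filter_size` block of the stem-pair
#' probability matrix, centered at `P(x_n, d_t)` on both axes, is multiplied
#' elementwise by the responding structure filter's weights and accumulated.
#' The 2-D enrichment is reduced to a 1-D profile by a maximum over the
#' pairing-partner axis.
#'
#' @inheritParams sequence_enrichment
#' @return Object of class `mmcnn_structure_enrichment`: `matrix`
#'   (filter_size x filter_size), `profile` (length filter_size), counts.
#' @export
structure_enrichment <- function(object, data, indices, selection,
                                 fold = selection$fold, chunk = 256L) {
  cfg <- object$config
  sh <- config_shapes(cfg)
  K1 <- cfg$filters_per_size
  s_str <- selection$t_struct %/% 2L
  f_t <- cfg$filter_sizes[s_str]
  nw <- weights_nested(object$fold_models[[fold]], cfg)
  W1s <- nw$comb_w[[1L]][[selection$size_index]]
  acc <- matrix(0, f_t, f_t)
  used <- 0L; dropped <- 0L
  si <- selection$size_index
  for_each_response_chunk(object, data, fold, chunk, function(resp, ids) {
    for (u in seq_along(ids)) {
      x0 <- indices$x[ids[u], si] - 1L
      kn <- indices$k[ids[u], si]
      mp <- map_sample_position(x0, selection$d_struct, f_t, cfg$length,
                                resp[[u]]$structure[[s_str]])
      if (is.null(mp)) { dropped <<- dropped + 1L; next }
      wf <- combined_weight_factor(W1s, selection$z_struct, selection$t_struct,
                                   mp$kprime, kn, K1, sh$C0)
      ws <- t(matrix(nw$str_w[[s_str]][, mp$kprime], nrow = f_t))  # (a,b) layout
      tr <- data$str[[ids[u]]]
      Mwin <- matrix(0, f_t, f_t)
      if (nrow(tr) > 0L) {
        keep <- tr[, 1L] %in% mp$win0 & tr[, 2L] %in% mp$win0
        if (any(keep)) {
          sel <- tr[keep, , drop = FALSE]
          Mwin[cbind(sel[, 1L] - mp$win0[1L] + 1L,
                     sel[, 2L] - mp$win0[1L] + 1L)] <- sel[, 3L]
        }
      }
      acc <<- acc + wf * (Mwin * ws)
      used <<- used + 1L
    }
  })
  if (used == 0L)
    stop("all ", dim(data$seq)[3L], " samples dropped at the array boundary")
  structure(list(matrix = acc, profile = apply(acc, 1L, max),
                 filter_size = f_t, s_str = s_str,
                 n_used = used, n_dropped = dropped, selection = selection),
            class = "mmcnn_structure_enrichment")
}

#' Convert a sequence enrichment to a probability PWM
#'
#' Applies a position-wise softmax over the four nucleotides to turn the
#' weighted propensities into a position weight matrix. For long filters
#' (`filter_size > window`) the `window`-wide sub-window with the maximal
#' summed enrichment is reported alongside the full PWM.
#'
#' @param enrichment A [sequence_enrichment()] result (or a plain
#'   positions x 4 matrix).
#' @param window Logo window width (default 12).
#' @return List with `pwm` (rows sum to 1), and when the filter is longer
#'   than `window`: `window_start` (1-based) and `window_pwm`.
#' @export
to_pwm <- function(enrichment, window = 12L) {
  m <- if (is.matrix(enrichment)) enrichment else enrichment$matrix
  pwm <- t(apply(m, 1L, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  colnames(pwm) <- .NUC
  out <- list(pwm = pwm)
  if (nrow(m) > window) {
    sc <- rowSums(m)
    tot <- vapply(seq_len(nrow(m) - window + 1L),
                  function(s) sum(sc[s + seq_len(window) - 1L]), numeric(1L))
    out$window_start <- which.max(tot)
    out$window_pwm <- pwm[out$window_start + seq_len(window) - 1L, , drop = FALSE]
  }
  out
}

#' Align the extracted sequence and structure motifs
#'
#' The positional relationship between the sequence and structure motifs is
#' the difference of their shifting constants, `d_seq - d_struct`, in raw
#' sequence coordinates. The result is a merged per-position table of
#' nucleotide probabilities and structure scores on a common coordinate axis
#' (0 = the combined-response anchor position).
#'
#' @param seq_enrichment A [sequence_enrichment()] result.
#' @param struct_enrichment A [structure_enrichment()] result.
#' @param selection The shared [select_enrichment()] result.
#' @return Object of class `mmcnn_aligned_motif`: a data.frame with columns
#'   `position`, `p_A`, `p_U`, `p_G`, `p_C`, `structure_score` and an
#'   `offset` attribute.
#' @export
align_motifs <- function(seq_enrichment, struct_enrichment, selection) {
  offset <- selection$d_seq - selection$d_struct
  pwm <- to_pwm(seq_enrichment)$pwm
  prof <- struct_enrichment$profile
  fs <- seq_enrichment$filter_size; ft <- struct_enrichment$filter_size
  seq_pos <- selection$d_seq - fs %/% 2L + seq_len(fs) - 1L
  str_pos <- selection$d_struct - ft %/% 2L + seq_len(ft) - 1L
  pos <- seq.int(min(seq_pos, str_pos), max(seq_pos, str_pos))
  tab <- data.frame(position = pos,
                    p_A = NA_real_, p_U = NA_real_, p_G = NA_real_,
                    p_C = NA_real_, structure_score = NA_real_)
  tab[match(seq_pos, pos), c("p_A", "p_U", "p_G", "p_C")] <- pwm
  tab$structure_score[match(str_pos, pos)] <- prof
  structure(tab, offset = offset, class = c("mmcnn_aligned_motif", "data.frame"))
}

#' Full response-enrichment motif extraction
#'
#' Runs the complete pipeline on a set of positive samples: maximal combined
#' responses, combined enrichment per filter size, selection of the best
#' filter size and filter types, sequence and structure enrichment, PWM
#' conversion and motif alignment. With `fold = "best"` the enrichment is
#' run on every fold model and the fold with the highest selected response
#' score is reported.
#'
#' @param object Fitted `mmcnn` object.
#' @param data Encoded positive samples (label 1) from [encode_dataset()].
#' @param fold Integer fold to analyze, or `"best"`.
#' @param chunk Samples per forward-pass chunk.
#' @param window Logo window width passed to [to_pwm()].
#' @return Object of class `mmcnn_enrichment` bundling `indices`,
#'   `combined`, `selection`, `sequence`, `structure`, `pwm`, `aligned`,
#'   and the analyzed `fold`.
#' @export
response_enrichment <- function(object, data, fold = "best", chunk = 256L,
                                window = 12L) {
  folds <- if (identical(fold, "best")) seq_len(object$folds) else as.integer(fold)
  best <- NULL
  for (f in folds) {
    idx <- max_combined_response(object, data, fold = f, chunk = chunk)
    ce <- combined_enrichment(object, data, idx, fold = f, chunk = chunk)
    sel <- select_enrichment(ce)
    if (is.null(best) || sel$response_score > best$selection$response_score)
      best <- list(fold = f, indices = idx, combined = ce, selection = sel)
  }
  se <- sequence_enrichment(object, data, best$indices, best$selection,
                            fold = best$fold, chunk = chunk)
  st <- structure_enrichment(object, data, best$indices, best$selection,
                             fold = best$fold, chunk = chunk)
  structure(list(fold = best$fold, indices = best$indices,
                 combined = best$combined, selection = best$selection,
                 sequence = se, structure = st,
                 pwm = to_pwm(se, window = window),
                 aligned = align_motifs(se, st, best$selection)),
            class = "mmcnn_enrichment")
}

#' @export
print.mmcnn_enrichment <- function(x, ...) {
  s <- x$selection
  cat("Response-enrichment motif extraction\n")
  cat(sprintf("  fold %d; selected filter size %d (response score %.4g)\n",
              x$fold, s$filter_size, s$response_score))
  cat(sprintf("  sequence type %s (d_t = %+d), structure type %s (d_t = %+d)\n",
              s$t_seq_name, s$d_seq, s$t_struct_name, s$d_struct))
  cat(sprintf("  sequence-structure offset: %+d nt\n",
              attr(x$aligned, "offset")))
  cat(sprintf("  samples used: %d sequence / %d structure (dropped %d / %d at boundary)\n",
              x$sequence$n_used, x$structure$n_used,
              x$sequence$n_dropped, x$structure$n_dropped))
  cons <- paste(colnames(x$pwm$pwm)[apply(x$pwm$pwm, 1L, which.max)],
                collapse = "")
  cat("  PWM consensus:", cons, "\n")
  invisible(x)
}

#' Consensus string of a PWM
#'
#' @param pwm Positions x 4 probability matrix with columns A,U,G,C.
#' @return Character consensus (argmax letter per position).
#' @export
pwm_consensus <- function(pwm) {
  paste(.NUC[apply(pwm, 1L, which.max)], collapse = "")
}

#' Write / read PWMs in MEME minimal motif format
#'
#' Writes position weight matrices with the RNA alphabet `ACGU` in MEME
#' minimal format; `read_meme()` parses such files back (letter order is
#' converted between MEME's A,C,G,U and the package-internal A,U,G,C).
#'
#' @param pwms A single PWM matrix (columns A,U,G,C) or named list of them.
#' @param path Output (input) file.
#' @param nsites Number of contributing sites recorded per motif.
#' @param background Background letter frequencies (A,C,G,U order).
#' @return `write_meme`: `path` invisibly. `read_meme`: named list of PWM
#'   matrices with columns A,U,G,C.
#' @export
write_meme <- function(pwms, path, nsites = 20L,
                       background = c(0.25, 0.25, 0.25, 0.25)) {
  if (is.matrix(pwms)) pwms <- list(motif_1 = pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "", "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f U %.5f", background[1L],
                       background[2L], background[3L], background[4L]), ""),
             con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]][, c("A", "C", "G", "U"), drop = FALSE]
    writeLines(c(paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         nrow(p), as.integer(nsites))), con)
    writeLines(apply(p, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) stop("not a MEME file: ", path)
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    nm <- sub("^MOTIF\\s+", "", lines[s])
    nm <- sub("\\s.*$", "", nm)
    hdr <- s + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[hdr + seq_len(w)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "[[:space:]]+"), as.numeric))
    colnames(m) <- c("A", "C", "G", "U")
    out[[nm]] <- m[, c("A", "U", "G", "C")]
  }
  out
}

#' Write an aligned motif table as TSV
#'
#' @param aligned An [align_motifs()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(aligned, path) {
  utils::write.table(as.data.frame(aligned), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
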