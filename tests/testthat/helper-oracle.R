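# Independent brute-force oracles: straightforward nested-loop
# re-implementations of the forward pass and of the response-enrichment
# equations, kept deliberately separate from the package's compiled path.

toy_config <- function(...) {
  defaults <- list(filter_sizes = c(4L, 8L), filters_per_size = 2L,
                   combined_filters = 2L, length = 32L, dense_units = 5L,
                   epochs = 2L, batch_size = 8L)
  do.call(mmcnn_config, utils::modifyList(defaults, list(...)))
}

# Random weights pushed away from the ReLU kink so gradients are exact.
toy_weights <- function(cfg, seed = 42L) {
  w <- mmcnn_init(cfg, seed = seed)
  set.seed(seed + 1L)
  lapply(w, function(m) m + matrix(stats::rnorm(length(m), 0, 0.05), nrow(m)))
}

# n random one-hot sequences and sparse structure matrices.
toy_inputs <- function(cfg, n, seed = 7L, n_pairs = 3L) {
  set.seed(seed)
  L <- cfg$length
  seqs <- array(0, c(L, 4L, n))
  str <- vector("list", n)
  for (i in seq_len(n)) {
    seqs[cbind(seq_len(L), sample(4L, L, TRUE), i)] <- 1
    ii <- sample(0:(L - 6L), n_pairs)
    jj <- pmin(L - 1L, ii + sample(4:5, n_pairs, TRUE))
    v <- round(stats::runif(n_pairs, 0.3, 1), 3)
    tr <- cbind(c(ii, jj), c(jj, ii), c(v, v))
    colnames(tr) <- c("i", "j", "p")
    str[[i]] <- tr
  }
  list(seq = seqs, str = str, labels = rep_len(c(1, 0), n),
       ids = as.character(seq_len(n)), length = L)
}

relu <- function(x) pmax(x, 0)

dense_structure <- function(tr, L) {
  M <- matrix(0, L, L)
  if (nrow(tr) > 0L) M[tr[, 1:2, drop = FALSE] + 1L] <- tr[, 3L]
  M
}

# position-axis "same" convolution, patch [i - f/2, i + f/2), 0-based math
oracle_conv1d <- function(A, W, b, f) {
  L <- nrow(A); C <- ncol(A); K <- ncol(W)
  O <- matrix(0, L, K)
  for (i in 0:(L - 1L)) for (k in seq_len(K)) {
    acc <- b[k]
    for (a in 0:(f - 1L)) {
      p <- i - f %/% 2L + a
      if (p < 0L || p >= L) next
      for (ch in 0:(C - 1L))
        acc <- acc + A[p + 1L, ch + 1L] * W[a * C + ch + 1L, k]
    }
    O[i + 1L, k] <- acc
  }
  O
}

oracle_struct_conv <- function(M, W, b, f) {
  L <- nrow(M); K <- ncol(W)
  O <- matrix(0, L, K)
  for (i in 0:(L - 1L)) for (k in seq_len(K)) {
    best <- -Inf
    for (j in 0:(L - 1L)) {
      acc <- 0
      for (a in 0:(f - 1L)) for (bb in 0:(f - 1L)) {
        p <- i - f %/% 2L + a; q <- j - f %/% 2L + bb
        if (p < 0L || p >= L || q < 0L || q >= L) next
        acc <- acc + M[p + 1L, q + 1L] * W[a * f + bb + 1L, k]
      }
      if (acc > best) best <- acc
    }
    O[i + 1L, k] <- relu(best + b[k])
  }
  O
}

pool2 <- function(O) {
  L2 <- nrow(O) %/% 2L
  out <- matrix(0, L2, ncol(O))
  for (i in seq_len(L2))
    for (k in seq_len(ncol(O)))
      out[i, k] <- max(O[2L * i - 1L, k], O[2L * i, k])
  out
}

# Full inference-mode forward pass; returns all intermediate responses.
oracle_forward <- function(w, cfg, X, M) {
  nw <- weights_nested(w, cfg)
  S <- length(cfg$filter_sizes)
  seqO <- strO <- vector("list", S)
  for (s in seq_len(S)) {
    f <- cfg$filter_sizes[s]
    seqO[[s]] <- relu(oracle_conv1d(X, nw$seq_w[[s]], nw$seq_b[[s]][, 1L], f))
    strO[[s]] <- oracle_struct_conv(M, nw$str_w[[s]], nw$str_b[[s]][, 1L], f)
  }
  Z <- do.call(cbind, unlist(lapply(seq_len(S), function(s)
    list(seqO[[s]], strO[[s]])), recursive = FALSE))
  comb1 <- vector("list", S)
  A <- Z
  for (l in seq_len(cfg$n_combined_layers)) {
    outs <- vector("list", S)
    for (s in seq_len(S)) {
      f <- cfg$filter_sizes[s]
      O <- relu(oracle_conv1d(A, nw$comb_w[[l]][[s]], nw$comb_b[[l]][[s]][, 1L], f))
      outs[[s]] <- pool2(O)
      if (l == 1L) comb1[[s]] <- outs[[s]]
    }
    A <- do.call(cbind, outs)
  }
  flat <- as.vector(A)
  h1 <- relu(drop(t(nw$dense1_w) %*% flat) + nw$dense1_b[, 1L])
  spre <- sum(nw$dense2_w[, 1L] * h1) + nw$dense2_b[1L, 1L]
  list(seq = seqO, str = strO, combined_input = Z, combined_response = comb1,
       score = 1 / (1 + exp(-spre)))
}

# 1-based argmax of a matrix with ties to the lowest row, then column.
oracle_argmax2 <- function(m) {
  best <- -Inf; bi <- 1L; bj <- 1L
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m)))
    if (m[i, j] > best) { best <- m[i, j]; bi <- i; bj <- j }
  # column-major scan finds lowest column first; rescan rows-first
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (m[i, j] == best) return(c(i, j))
}

# Explicit-loop implementation of the full enrichment chain (Eqs 3-10
# analogues) on top of oracle_forward; returns the same quantities the
# package computes.
oracle_enrichment <- function(w, cfg, data) {
  n <- dim(data$seq)[3L]
  S <- length(cfg$filter_sizes)
  K1 <- cfg$filters_per_size
  C0 <- 2L * S * K1
  L <- cfg$length
  nw <- weights_nested(w, cfg)
  fw <- lapply(seq_len(n), function(i)
    oracle_forward(w, cfg, data$seq[, , i], dense_structure(data$str[[i]], L)))
  xs <- ks <- matrix(0L, n, S)
  for (i in seq_len(n)) for (s in seq_len(S)) {
    a <- oracle_argmax2(fw[[i]]$combined_response[[s]])
    xs[i, s] <- a[1L]; ks[i, s] <- a[2L]
  }
  E <- lapply(cfg$filter_sizes, function(f) matrix(0, f, C0))
  for (s in seq_len(S)) {
    f <- cfg$filter_sizes[s]
    for (i in seq_len(n)) {
      cen <- 2L * (xs[i, s] - 1L)
      rows0 <- cen - f %/% 2L + 0:(f - 1L)
      if (rows0[1L] < 0L || rows0[f] >= L) next
      for (X in seq_len(f)) for (ch in seq_len(C0))
        E[[s]][X, ch] <- E[[s]][X, ch] +
          fw[[i]]$combined_input[rows0[X] + 1L, ch] *
          nw$comb_w[[1L]][[s]][(X - 1L) * C0 + ch, ks[i, s]]
    }
  }
  enr <- score <- vector("list", S)
  for (s in seq_len(S)) {
    f <- cfg$filter_sizes[s]
    m <- matrix(0, f, 2L * S)
    for (tt in seq_len(2L * S)) for (X in seq_len(f))
      m[X, tt] <- max(E[[s]][X, (tt - 1L) * K1 + seq_len(K1)])
    enr[[s]] <- m
    score[[s]] <- sum(apply(m, 2L, max))
  }
  score <- unlist(score)
  si <- which.max(score)
  m <- enr[[si]]; f <- cfg$filter_sizes[si]
  seq_types <- seq.int(1L, 2L * S, 2L); str_types <- seq.int(2L, 2L * S, 2L)
  t_seq <- seq_types[which.max(apply(m[, seq_types, drop = FALSE], 2L, max))]
  t_struct <- str_types[which.max(apply(m[, str_types, drop = FALSE], 2L, max))]
  z_seq <- which.max(m[, t_seq]); z_struct <- which.max(m[, t_struct])
  d_seq <- z_seq - 1L - f %/% 2L; d_struct <- z_struct - 1L - f %/% 2L

  enrich_one <- function(t_sel, z_sel, d_sel, structural) {
    s_sel <- (t_sel + 1L) %/% 2L
    f_t <- cfg$filter_sizes[s_sel]
    acc <- if (structural) matrix(0, f_t, f_t) else matrix(0, f_t, 4L)
    used <- 0L
    for (i in seq_len(n)) {
      x0 <- xs[i, si] - 1L
      p0 <- 2L * (x0 + d_sel)
      if (p0 < 0L || p0 + 1L >= L) next
      resp <- if (structural) fw[[i]]$str[[s_sel]] else fw[[i]]$seq[[s_sel]]
      P0 <- if (max(resp[p0 + 2L, ]) > max(resp[p0 + 1L, ])) p0 + 1L else p0
      win0 <- P0 - f_t %/% 2L + 0:(f_t - 1L)
      if (win0[1L] < 0L || win0[f_t] >= L) next
      kp <- which.max(resp[P0 + 1L, ])
      wf <- nw$comb_w[[1L]][[si]][(z_sel - 1L) * C0 + (t_sel - 1L) * K1 + kp,
                                  ks[i, si]]
      if (structural) {
        M <- dense_structure(data$str[[i]], L)
        for (X in seq_len(f_t)) for (Y in seq_len(f_t))
          acc[X, Y] <- acc[X, Y] + wf * M[win0[X] + 1L, win0[Y] + 1L] *
            nw$str_w[[s_sel]][(X - 1L) * f_t + Y, kp]
      } else {
        for (X in seq_len(f_t)) for (y in 1:4)
          acc[X, y] <- acc[X, y] + wf * data$seq[win0[X] + 1L, y, i] *
            nw$seq_w[[s_sel]][(X - 1L) * 4L + y, kp]
      }
      used <- used + 1L
    }
    list(matrix = acc, n_used = used)
  }
  se <- enrich_one(t_seq, z_seq, d_seq, FALSE)
  st <- enrich_one(t_struct, z_struct, d_struct, TRUE)
  pwm <- t(apply(se$matrix, 1L, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  list(x = xs, k = ks, E = E, enrichment = enr, response_score = score,
       size_index = si, t_seq = t_seq, t_struct = t_struct,
       z_seq = z_seq, z_struct = z_struct, d_seq = d_seq, d_struct = d_struct,
       sequence = se, structure = st, profile = apply(st$matrix, 1L, max),
       pwm = pwm, offset = d_seq - d_struct)
}

# Brute-force stem probability matrix: dense accumulation per structure.
oracle_spm <- function(ensemble, length) {
  p <- boltzmann_probabilities(ensemble)
  M <- matrix(0, length, length)
  off <- (length - nchar(ensemble$structures[1L])) %/% 2L
  for (l in seq_along(ensemble$structures)) {
    pt <- pair_table(ensemble$structures[l])
    if (nrow(pt) == 0L) next
    for (r in seq_len(nrow(pt))) {
      i <- pt[r, 1L] + off; j <- pt[r, 2L] + off
      M[i, j] <- M[i, j] + p[l]
      M[j, i] <- M[j, i] + p[l]
    }
  }
  M
}

# Random valid nested dot-bracket over a given length.
random_structure <- function(L, max_pairs = 6L) {
  s <- rep(".", L)
  n_try <- sample.int(max_pairs, 1L)
  for (k in seq_len(n_try)) {
    i <- sample.int(L - 4L, 1L)
    j <- i + sample(4:min(12L, L - i), 1L)
    if (j > L) next
    if (all(s[i:j] == ".")) { s[i] <- "("; s[j] <- ")" }
  }
  paste(s, collapse = "")
}

random_ensemble <- function(L, n_members, energy_span = 10, id = "e1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    sequence_id = id,
    energies = sort(stats::runif(n_members, -energy_span, 0)),
    structures = vapply(seq_len(n_members), function(i) random_structure(L),
                        character(1L))),
    class = "structure_ensemble")
}
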