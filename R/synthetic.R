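# Synthetic planted-motif datasets with full ground truth.
#
# Positives carry one instance of a sequence motif (drawn from a PWM) at a
# controlled position, and optionally a hairpin stem whose Boltzmann-dominant
# ensemble members all contain the planted base pairs. Negatives are
# dinucleotide-shuffled positives (composition-matched) or pure background,
# with decoy-only structure ensembles. Everything is reproducible from the
# spec seed, and the emitted files (FASTA + ensemble dialect + truth JSON)
# exercise the real readers end to end.

#' Specification of a synthetic planted-motif dataset
#'
#' @param n_pos,n_neg Numbers of positive and negative sequences.
#' @param length Sequence length (default 200).
#' @param background Background nucleotide probabilities (A,U,G,C).
#' @param motif Planted sequence motif: a consensus string (converted to a
#'   PWM via `motif_prob`) or a positions x 4 probability matrix
#'   (columns A,U,G,C), or `NULL` for no sequence motif.
#' @param motif_prob Probability of the consensus letter at each motif
#'   position when `motif` is a string (remainder split evenly). The default
#'   1 plants the exact consensus.
#' @param motif_positions Planting positions (1-based motif start):
#'   a single fixed position, or `c(min, max)` for a uniform draw.
#' @param stem Optional planted hairpin: `list(start, length, loop,
#'   target)` with `start` the 1-based first position of the 5' arm,
#'   `length` the stem length in base pairs, `loop` the hairpin loop length
#'   (>= 3), and `target` the stem-pair probability mass in (0, 1] that the
#'   Boltzmann-dominant members must carry.
#' @param ensemble_size Structures per sequence ensemble (<= 100).
#' @param n_dominant Number of low-energy members carrying the planted stem.
#' @param energy_gap Energy separation (kcal/mol) between dominant and decoy
#'   members; derived analytically from `target` when `NULL` so that the
#'   Boltzmann mass of the dominant members equals `target` exactly.
#' @param negatives `"dinucleotide"` (shuffled positives, composition
#'   matched) or `"background"`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 100L, n_neg = 100L, length = 200L,
                           background = c(0.25, 0.25, 0.25, 0.25),
                           motif = "UGUAAAUA", motif_prob = 1,
                           motif_positions = c(50L, 150L),
                           stem = NULL, ensemble_size = 20L, n_dominant = 5L,
                           energy_gap = NULL,
                           negatives = c("dinucleotide", "background"),
                           seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 0L, length >= 20L)
  background <- background / sum(background)
  if (is.character(motif)) {
    ch <- strsplit(toupper(gsub("T", "U", motif)), "")[[1L]]
    if (any(!(ch %in% .NUC))) stop("motif consensus must be over A,C,G,U")
    pwm <- matrix((1 - motif_prob) / 3, length(ch), 4L,
                  dimnames = list(NULL, .NUC))
    pwm[cbind(seq_along(ch), match(ch, .NUC))] <- motif_prob
    motif <- pwm
  }
  if (!is.null(motif)) {
    if (nrow(motif) > length) stop("motif longer than sequence length")
    if (any(abs(rowSums(motif) - 1) > 1e-9)) stop("motif PWM rows must sum to 1")
    if (length(motif_positions) == 1L)
      motif_positions <- rep(motif_positions, 2L)
    if (motif_positions[2L] + nrow(motif) - 1L > length)
      stop("motif does not fit at the stated positions")
  }
  if (!is.null(stem)) {
    stopifnot(all(c("start", "length", "loop") %in% names(stem)))
    if (is.null(stem$target)) stem$target <- 0.9
    if (stem$loop < 3L) stop("hairpin loop must be at least 3 nt")
    if (stem$target <= 0 || stem$target > 1)
      stop("stem pair-probability target must be in (0, 1]")
    stem$end3 <- stem$start + 2L * stem$length + stem$loop - 1L
    if (stem$start < 1L || stem$end3 > length)
      stop("planted stem does not fit in the sequence window")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), background = background,
                 motif = motif, motif_positions = as.integer(motif_positions),
                 stem = stem, ensemble_size = as.integer(ensemble_size),
                 n_dominant = as.integer(n_dominant), energy_gap = energy_gap,
                 negatives = match.arg(negatives), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Altschul-Erickson dinucleotide shuffle: a random Eulerian walk over the
# dinucleotide multigraph, preserving exact dinucleotide counts.
dinucleotide_shuffle <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 3L) return(sequence)
  letters_ <- unique(ch)
  edges <- split(ch[-1L], factor(ch[-n], levels = letters_))
  last <- ch[n]
  repeat {
    # choose a random terminal edge per non-final vertex, check connectivity
    last_edge <- vapply(letters_, function(v) {
      e <- edges[[v]]
      if (v == last || length(e) == 0L) NA_character_
      else e[sample.int(length(e), 1L)]
    }, character(1L))
    ok <- TRUE
    for (v in letters_) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  shuffled <- lapply(letters_, function(v) {
    e <- edges[[v]]
    if (is.na(last_edge[[v]])) return(sample(e))
    i <- match(last_edge[[v]], e)
    rest <- e[-i]
    c(if (length(rest)) sample(rest) else character(0), last_edge[[v]])
  })
  names(shuffled) <- letters_
  ptr <- stats::setNames(rep(1L, length(letters_)), letters_)
  out <- character(n)
  out[1L] <- ch[1L]
  for (i in 2L:n) {
    v <- out[i - 1L]
    out[i] <- shuffled[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
  }
  paste(out, collapse = "")
}

#' Generate labeled synthetic sequences
#'
#' Positives are background draws with one motif instance sampled from the
#' planted PWM inserted at a drawn position; negatives are dinucleotide
#' shuffles of the positives (default) or pure background draws.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (data.frame `id`, `sequence`, `label`) and
#'   `truth` (per-positive motif starts, the planted PWM/stem, and the
#'   planted sequence-structure offset in nucleotides, when both exist).
#' @export
generate_sequences <- function(spec) {
  set.seed(spec$seed)
  L <- spec$length
  draw_bg <- function() paste(sample(.NUC, L, TRUE, prob = spec$background),
                              collapse = "")
  motif_starts <- integer(0)
  pos_seqs <- character(spec$n_pos)
  for (i in seq_len(spec$n_pos)) {
    s <- strsplit(draw_bg(), "")[[1L]]
    if (!is.null(spec$motif)) {
      w <- nrow(spec$motif)
      st <- if (spec$motif_positions[1L] == spec$motif_positions[2L])
        spec$motif_positions[1L]
      else sample(spec$motif_positions[1L]:spec$motif_positions[2L], 1L)
      ins <- vapply(seq_len(w), function(p)
        sample(.NUC, 1L, prob = spec$motif[p, ]), character(1L))
      s[st + seq_len(w) - 1L] <- ins
      motif_starts <- c(motif_starts, st)
    }
    pos_seqs[i] <- paste(s, collapse = "")
  }
  neg_seqs <- character(spec$n_neg)
  if (spec$n_neg > 0L) {
    if (spec$negatives == "dinucleotide") {
      src <- rep_len(seq_len(spec$n_pos), spec$n_neg)
      neg_seqs <- vapply(src, function(i) dinucleotide_shuffle(pos_seqs[i]),
                         character(1L))
    } else {
      neg_seqs <- vapply(seq_len(spec$n_neg), function(i) draw_bg(), character(1L))
    }
  }
  records <- data.frame(
    id = c(sprintf("pos_%04d", seq_len(spec$n_pos)),
           sprintf("neg_%04d", seq_len(spec$n_neg))),
    sequence = c(pos_seqs, neg_seqs),
    label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)),
    stringsAsFactors = FALSE)
  offset <- NULL
  if (!is.null(spec$motif) && !is.null(spec$stem) &&
      spec$motif_positions[1L] == spec$motif_positions[2L]) {
    motif_center <- spec$motif_positions[1L] + nrow(spec$motif) / 2
    arm5_center <- spec$stem$start + spec$stem$length / 2
    offset <- motif_center - arm5_center
  }
  truth <- list(motif_starts = motif_starts, pwm = spec$motif,
                consensus = if (!is.null(spec$motif)) pwm_consensus(spec$motif),
                stem = spec$stem, offset = offset, spec = spec)
  list(records = records, truth = truth)
}

# Dot-bracket string with a hairpin: arms [start, start+len) and the
# matching 3' arm, loop in between. 1-based start.
hairpin_db <- function(L, start, len, loop) {
  s <- rep(".", L)
  s[start + seq_len(len) - 1L] <- "("
  s[start + len + loop + seq_len(len) - 1L] <- ")"
  paste(s, collapse = "")
}

# Random decoy hairpin avoiding a forbidden position range (1-based span).
random_decoy_db <- function(L, avoid = NULL) {
  repeat {
    len <- sample(4:8, 1L)
    loop <- sample(3:8, 1L)
    span <- 2L * len + loop
    start <- sample.int(L - span + 1L, 1L)
    if (is.null(avoid) ||
        start + span - 1L < avoid[1L] || start > avoid[2L])
      return(hairpin_db(L, start, len, loop))
  }
}

#' Generate structure ensembles with a planted stem
#'
#' For each positive, builds an ensemble whose low-energy members all
#' contain the planted hairpin pairs and whose Boltzmann mass equals the
#' spec's pair-probability `target`; higher-energy decoy hairpins at random
#' non-overlapping positions make up the rest. Negatives (and positives of
#' stem-free specs) receive decoy-only ensembles. The dominant/decoy energy
#' gap `g` is solved from the Boltzmann distribution:
#' `target = n_dom * exp(g/kT) / (n_dom * exp(g/kT) + n_decoy)`, so the
#' realized stem-pair probabilities equal the target exactly.
#'
#' @param records Data.frame from [generate_sequences()].
#' @param spec The same [synthetic_spec()].
#' @return Named list of `structure_ensemble` objects keyed by record id.
#' @export
generate_ensembles <- function(records, spec) {
  set.seed(spec$seed + 1L)
  L <- spec$length
  kT <- 0.001987 * 310.15
  m <- spec$ensemble_size
  ndom <- min(spec$n_dominant, m)
  stem <- spec$stem
  out <- vector("list", nrow(records))
  names(out) <- records$id
  avoid <- if (!is.null(stem)) c(stem$start, stem$end3)
  for (i in seq_len(nrow(records))) {
    planted <- records$label[i] == 1L && !is.null(stem)
    if (planted) {
      ndec <- m - ndom
      g <- if (!is.null(spec$energy_gap)) spec$energy_gap
      else if (stem$target >= 1 || ndec == 0L) 50
      else kT * log(stem$target / (1 - stem$target) * ndec / ndom)
      base_db <- hairpin_db(L, stem$start, stem$length, stem$loop)
      dom <- c(base_db,
               vapply(seq_len(max(0L, ndom - 1L)), function(j) {
                 extra <- random_decoy_db(L, avoid)
                 merged <- strsplit(base_db, "")[[1L]]
                 ech <- strsplit(extra, "")[[1L]]
                 merged[ech != "."] <- ech[ech != "."]
                 paste(merged, collapse = "")
               }, character(1L)))
      dec <- vapply(seq_len(ndec), function(j) random_decoy_db(L, avoid),
                    character(1L))
      energies <- c(rep(-20 - g, ndom), rep(-20, ndec))
      structures <- c(dom, dec)
    } else {
      structures <- vapply(seq_len(m), function(j) random_decoy_db(L, avoid),
                           character(1L))
      energies <- -20 + sort(stats::runif(m, 0, 5))
    }
    out[[records$id[i]]] <- structure(
      list(sequence_id = records$id[i], energies = energies,
           structures = structures),
      class = "structure_ensemble")
  }
  out
}

#' Generate and write a complete synthetic dataset
#'
#' Emits `positives.fa`, `negatives.fa`, `ensembles.txt` and `truth.json`
#' into a directory, exercising the package's own writers so that the files
#' round-trip through [read_labeled_fasta()] and [parse_ensemble_file()].
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `records`, `truth`, `ensembles`, `dir`.
#' @export
generate_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- generate_sequences(spec)
  ens <- generate_ensembles(gs$records, spec)
  write_fasta(gs$records[gs$records$label == 1L, ], file.path(dir, "positives.fa"))
  write_fasta(gs$records[gs$records$label == 0L, ], file.path(dir, "negatives.fa"))
  write_ensemble_file(ens, file.path(dir, "ensembles.txt"))
  truth <- gs$truth
  truth$spec <- NULL
  truth$pwm <- if (!is.null(truth$pwm)) unclass(truth$pwm)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(records = gs$records, truth = gs$truth, ensembles = ens,
                 dir = dir))
}
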