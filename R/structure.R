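#' Boltzmann weights of a suboptimal structure ensemble
#'
#' Converts free energies of ranked suboptimal structures into ensemble
#' probabilities `p_l = exp(-e_l/kT) / sum_m exp(-e_m/kT)`. The exponentials
#' are shifted by the minimum energy before normalization, so energy spreads
#' of 100 kcal/mol and more are handled without overflow; the result is
#' invariant under adding a constant to all energies.
#'
#' @param x A `structure_ensemble` or a numeric vector of free energies
#'   (kcal/mol).
#' @param kB Boltzmann constant, kcal mol^-1 K^-1 (default 0.001987).
#' @param temperature Temperature in Kelvin (default 310.15, i.e. 37 C).
#' @return Numeric vector of probabilities summing to 1.
#' @export
boltzmann_probabilities <- function(x, kB = 0.001987, temperature = 310.15) {
  en <- if (inherits(x, "structure_ensemble")) x$energies else x
  if (length(en) == 0L) stop("empty ensemble")
  if (anyNA(en)) stop("NA energy in ensemble")
  w <- exp(-(en - min(en)) / (kB * temperature))
  w / sum(w)
}

#' Base-pair table of a dot-bracket structure
#'
#' Standard stack-based matching of nested parentheses.
#'
#' @param dot_bracket Dot-bracket string over `.`, `(`, `)`.
#' @return Two-column integer matrix of pairs `(i, j)`, 1-based with `i < j`,
#'   ordered by `i`; zero rows for an unpaired structure.
#' @export
pair_table <- function(dot_bracket) {
  chk <- validate_dot_bracket(dot_bracket)
  if (!is.null(chk)) stop(chk)
  ch <- strsplit(dot_bracket, "", fixed = TRUE)[[1L]]
  bracket_pos <- which(ch != ".")
  n_pairs <- length(bracket_pos) %/% 2L
  pairs <- matrix(0L, nrow = n_pairs, ncol = 2L)
  stack <- integer(n_pairs)
  depth <- 0L; k <- 0L
  for (pos in bracket_pos) {
    if (ch[pos] == "(") {
      depth <- depth + 1L
      stack[depth] <- pos
    } else {
      k <- k + 1L
      pairs[k, ] <- c(stack[depth], pos)
      depth <- depth - 1L
    }
  }
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

# Left padding offset used when placing a structure of length n0 into a
# centered window of length `length` (matches center_sequences).
structure_offset <- function(n0, length) {
  if (n0 > length)
    stop("structure length ", n0, " exceeds window length ", length)
  (length - n0) %/% 2L
}

#' Stem-pair probability matrix of a structure ensemble
#'
#' The structure feature of the model: entry `(i, j)` is the
#' Boltzmann-weighted probability, over the ensemble of suboptimal
#' structures, that residues `i` and `j` form a stem pair,
#' `p(i,j) = sum_l p_l * [i,j paired in structure l]`. Matrices are
#' accumulated structure by structure in ensemble (ascending energy) order.
#' Structures shorter than `length` are centered in the window the same way
#' sequences are, so matrix coordinates align with the one-hot encoding.
#'
#' @param ensemble A `structure_ensemble`.
#' @param length Window length (default 200).
#' @param weights Optional probabilities from [boltzmann_probabilities()];
#'   computed from the ensemble energies when `NULL`.
#' @return Symmetric `length` x `length` matrix with zero diagonal, entries
#'   in `[0, 1]`, and row sums at most 1 (each residue pairs with at most one
#'   partner per structure).
#' @export
stem_probability_matrix <- function(ensemble, length = 200L, weights = NULL) {
  tr <- spm_triplets(ensemble, length, weights)
  m <- matrix(0, length, length)
  if (nrow(tr) > 0L) m[tr[, 1:2, drop = FALSE] + 1L] <- tr[, 3L]
  m
}

# Sparse triplet form of the stem probability matrix: columns i, j, p with
# 0-based indices, both (i,j) and (j,i) present. Shared by encode_dataset
# and the C++ structure convolution.
spm_triplets <- function(ensemble, length = 200L, weights = NULL) {
  if (is.null(weights)) weights <- boltzmann_probabilities(ensemble)
  if (length(weights) != length(ensemble$structures))
    stop("weights do not correspond to ensemble members")
  n0 <- unique(nchar(ensemble$structures))
  if (length(n0) != 1L)
    stop("inconsistent structure lengths in ensemble '", ensemble$sequence_id, "'")
  off <- structure_offset(n0, length)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (l in seq_along(ensemble$structures)) {
    pt <- pair_table(ensemble$structures[l])
    if (nrow(pt) == 0L) next
    ii <- c(ii, pt[, 1L]); jj <- c(jj, pt[, 2L])
    ww <- c(ww, rep.int(weights[l], nrow(pt)))
  }
  if (length(ii) == 0L) return(matrix(numeric(0), ncol = 3L))
  key <- (ii - 1L) * n0 + (jj - 1L)
  p <- rowsum(ww, key, reorder = TRUE)[, 1L]
  uk <- sort(unique(key))
  i <- uk %/% n0 + off
  j <- uk %% n0 + off
  tr <- rbind(cbind(i, j, p), cbind(j, i, p))
  colnames(tr) <- c("i", "j", "p")
  tr[order(tr[, 1L], tr[, 2L]), , drop = FALSE]
}

#' Annotate loop types of a secondary structure
#'
#' Classifies every position of a dot-bracket structure into the six
#' canonical secondary-structure element classes: `S` stem (paired), `H`
#' hairpin loop, `I` internal loop, `B` bulge, `M` multiloop, `E` external
#' region. Unpaired positions are classified by the loop closed by their
#' innermost enclosing pair: no inner helix gives `H`; one inner helix gives
#' `I` when both strands carry unpaired bases and `B` when only one does;
#' two or more inner helices give `M`.
#'
#' @param dot_bracket Dot-bracket string.
#' @return String of the same length over `S,M,H,I,B,E`.
#' @export
annotate_loop_types <- function(dot_bracket) {
  chk <- validate_dot_bracket(dot_bracket)
  if (!is.null(chk)) stop(chk)
  ch <- strsplit(dot_bracket, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  partner <- integer(n)
  pt <- pair_table(dot_bracket)
  if (nrow(pt) > 0L) {
    partner[pt[, 1L]] <- pt[, 2L]
    partner[pt[, 2L]] <- pt[, 1L]
  }
  ann <- rep("E", n)
  ann[partner > 0L] <- "S"

  classify_loop <- function(i, j) {
    # positions strictly inside enclosing pair (i,j); i=0, j=n+1 for exterior
    children <- integer(0)
    unpaired <- integer(0)
    pos <- i + 1L
    while (pos < j) {
      if (partner[pos] > pos) {
        children <- c(children, pos)
        pos <- partner[pos] + 1L
      } else if (partner[pos] == 0L) {
        unpaired <- c(unpaired, pos)
        pos <- pos + 1L
      } else pos <- pos + 1L  # closing bracket: defensive, not reachable
    }
    if (length(unpaired) == 0L) return(invisible(NULL))
    type <- if (i == 0L) {
      "E"
    } else if (length(children) == 0L) {
      "H"
    } else if (length(children) == 1L) {
      a <- children[1L]; b <- partner[a]
      left <- any(unpaired < a); right <- any(unpaired > b)
      if (left && right) "I" else "B"
    } else "M"
    ann[unpaired] <<- type
    invisible(NULL)
  }

  classify_loop(0L, n + 1L)
  if (nrow(pt) > 0L)
    for (r in seq_len(nrow(pt))) classify_loop(pt[r, 1L], pt[r, 2L])
  paste(ann, collapse = "")
}

.LOOP_TYPES <- c("S", "M", "H", "I", "B", "E")

#' One-hot encode a loop-type annotation
#'
#' Alternative 6-letter structure representation (channel order
#' `S,M,H,I,B,E`). Annotations shorter than `length` are centered with `N`
#' padding, which maps to all-zero rows; every non-padding row has exactly
#' one 1.
#'
#' @param annotation String over `S,M,H,I,B,E` (and `N` for padding), e.g.
#'   from [annotate_loop_types()].
#' @param length Window length (default 200).
#' @return `length` x 6 binary matrix.
#' @export
one_hot_structure <- function(annotation, length = 200L) {
  n0 <- nchar(annotation)
  if (n0 < length) {
    off <- structure_offset(n0, length)
    annotation <- paste0(strrep("N", off), annotation,
                         strrep("N", length - n0 - off))
  } else if (n0 > length) {
    stop("annotation length ", n0, " exceeds window length ", length)
  }
  ch <- strsplit(annotation, "", fixed = TRUE)[[1L]]
  bad <- !(ch %in% c(.LOOP_TYPES, "N"))
  if (any(bad)) stop("invalid loop-type character '", ch[which(bad)[1L]], "'")
  m <- matrix(0, nrow = length, ncol = 6L, dimnames = list(NULL, .LOOP_TYPES))
  idx <- match(ch, .LOOP_TYPES)
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Write / read a stem probability matrix as sparse text
#'
#' Cache format for structure features: a header line `#spm <n>` followed by
#' one `i j p` triplet per nonzero upper-triangle entry (1-based indices).
#' Round-trips exactly.
#'
#' @param m Symmetric matrix from [stem_probability_matrix()].
#' @param path Output (input) path.
#' @return `write_spm`: `path` invisibly; `read_spm`: the dense matrix.
#' @export
write_spm <- function(m, path) {
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#spm ", nrow(m)), con)
  if (nrow(idx) > 0L)
    writeLines(sprintf("%d %d %.17g", idx[, 1L], idx[, 2L], m[idx]), con)
  invisible(path)
}

#' @rdname write_spm
#' @export
read_spm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#spm ")) stop("not a spm file: ", path)
  n <- as.integer(sub("^#spm ", "", lines[1L]))
  m <- matrix(0, n, n)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) > 0L) {
    f <- do.call(rbind, lapply(strsplit(body, " ", fixed = TRUE), as.numeric))
    m[f[, 1:2, drop = FALSE]] <- f[, 3L]
    m[f[, 2:1, drop = FALSE]] <- f[, 3L]
  }
  m
}
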