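#' Read a labeled FASTA file of RNA sequences
#'
#' Reads candidate binding-site sequences and attaches a binary class label
#' (1 = bound by the RBP, 0 = unbound). DNA-style input is accepted: `T` is
#' mapped to `U` and case is folded, so GraphProt-style lowercase "viewpoint"
#' annotation is ignored. Characters outside `A,C,G,U,N` are rejected.
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @param label Binary class label attached to every record (0 or 1).
#' @return A data.frame with columns `id`, `sequence`, `label`, one row per
#'   FASTA entry, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT"), tf)
#' read_labeled_fasta(tf, label = 1)
#' @export
read_labeled_fasta <- function(path, label) {
  stopifnot(length(label) == 1L, label %in% c(0L, 1L))
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  ids <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("invalid characters in record '", ids[which(bad)[1L]],
         "' (allowed: A,C,G,U,N and T on input)")
  }
  if (any(!nzchar(seqs))) stop("empty sequence in record '", ids[which(!nzchar(seqs))[1L]], "'")
  data.frame(id = ids, sequence = unname(seqs), label = as.integer(label),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records Data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", records$id, "\n", records$sequence), con)
  invisible(path)
}

#' Trim or pad sequences to a fixed window centered on the binding site
#'
#' Binding sites are assumed to sit in the middle of each input sequence, so
#' longer sequences are trimmed symmetrically about their center and shorter
#' ones padded symmetrically with `N`. An odd overhang is resolved towards the
#' 3' end: one extra base is trimmed from (or one extra `N` appended to) the
#' 3' side.
#'
#' @param x Character vector of sequences (or a data.frame from
#'   [read_labeled_fasta()], in which case the `sequence` column is replaced).
#' @param length Target length in nucleotides (default 200).
#' @return Object of the same shape as `x` with all sequences of length
#'   `length`. Idempotent.
#' @export
center_sequences <- function(x, length = 200L) {
  if (is.data.frame(x)) {
    x$sequence <- center_sequences(x$sequence, length)
    return(x)
  }
  length <- as.integer(length)
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == length) return(s)
    if (n > length) {
      left <- (n - length) %/% 2L
      substr(s, left + 1L, left + length)
    } else {
      d <- length - n
      left <- d %/% 2L
      paste0(strrep("N", left), s, strrep("N", d - left))
    }
  }, character(1L), USE.NAMES = FALSE)
}

.NUC <- c("A", "U", "G", "C")

#' One-hot encode a fixed-length RNA sequence
#'
#' Channel order is `A,U,G,C`; `N` (padding or ambiguity) maps to an all-zero
#' row. The attribute `valid_span` records the 1-based inclusive range of
#' non-`N` positions (`c(1, 0)` when the sequence is all `N`).
#'
#' @param sequence A single RNA string over `A,C,G,U,N`.
#' @param length Required sequence length (default 200).
#' @return A `length` x 4 binary matrix with columns `A,U,G,C`.
#' @export
one_hot_encode <- function(sequence, length = 200L) {
  if (nchar(sequence) != length)
    stop("sequence length ", nchar(sequence), " != required length ", length)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !(ch %in% c(.NUC, "N"))
  if (any(bad)) stop("invalid character '", ch[which(bad)[1L]], "' in sequence")
  m <- matrix(0, nrow = length, ncol = 4L, dimnames = list(NULL, .NUC))
  idx <- match(ch, .NUC)
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  attr(m, "valid_span") <- if (any(keep)) as.integer(range(which(keep)))
                           else c(1L, 0L)
  m
}

#' Decode a one-hot matrix back to an RNA string
#'
#' Inverse of [one_hot_encode()]: all-zero rows decode to `N`.
#'
#' @param m One-hot matrix with 4 columns in `A,U,G,C` order.
#' @return RNA string.
#' @export
one_hot_decode <- function(m) {
  idx <- apply(m, 1L, function(r) {
    w <- which(r == 1)
    if (length(w) == 0L) 0L else w[1L]
  })
  paste(c("N", .NUC)[idx + 1L], collapse = "")
}

#' Parse a suboptimal secondary-structure ensemble file
#'
#' Reads the plain-text dialect produced by suboptimal folding tools such as
#' RNAshapes: blocks start with `>` + sequence id, followed by one line per
#' structure holding the free energy (kcal/mol) and a dot-bracket string;
#' trailing columns (e.g. abstract shape strings) are ignored. Structures are
#' sorted by ascending free energy and truncated to the `top` lowest-energy
#' members, because the Boltzmann weight of higher-energy structures is
#' negligible.
#'
#' @param path Path to an ensemble file.
#' @param top Keep at most this many lowest-energy structures (default 100).
#' @return Named list of `structure_ensemble` objects, each a list with
#'   `sequence_id`, `energies` (ascending, kcal/mol) and `structures`
#'   (dot-bracket strings).
#' @examples
#' f <- system.file("extdata", "example_ensembles.txt", package = "mmcnn")
#' ens <- parse_ensemble_file(f)
#' ens$hairpin_example$energies
#' @export
parse_ensemble_file <- function(path, top = 100L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ensemble file: ", path)
  if (!startsWith(lines[1L], ">")) stop("ensemble file must start with a '>' header: ", path)
  heads <- which(startsWith(lines, ">"))
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    id <- trimws(sub("^>", "", lines[heads[h]]))
    body <- lines[seq.int(heads[h] + 1L, bounds[h + 1L] - 1L)]
    if (heads[h] + 1L > bounds[h + 1L] - 1L)
      stop("record '", id, "' has no structures")
    fields <- strsplit(trimws(body), "[[:space:]]+")
    en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    if (anyNA(en)) {
      ln <- heads[h] + which(is.na(en))[1L]
      stop("record '", id, "', line ", ln, ": energy not a number")
    }
    db <- vapply(fields, `[`, "", 2L)
    for (k in seq_along(db)) {
      chk <- validate_dot_bracket(db[k])
      if (!is.null(chk))
        stop("record '", id, "', line ", heads[h] + k, ": ", chk)
    }
    ord <- order(en)
    ord <- ord[seq_len(min(length(ord), top))]
    out[[id]] <- structure(
      list(sequence_id = id, energies = en[ord], structures = unname(db[ord])),
      class = "structure_ensemble")
  }
  out
}

#' Write structure ensembles in the ensemble file dialect
#'
#' Inverse of [parse_ensemble_file()]; round-trips exactly for valid
#' ensembles (energies are written with full precision).
#'
#' @param ensembles Named list of `structure_ensemble` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_file <- function(ensembles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in ensembles) {
    writeLines(paste0(">", e$sequence_id), con)
    writeLines(sprintf("%.17g\t%s", e$energies, e$structures), con)
  }
  invisible(path)
}

# NULL when balanced and pseudoknot-free, else an error message.
validate_dot_bracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  if (any(!(ch %in% c(".", "(", ")"))))
    return("invalid structure character (only '.', '(', ')' allowed; pseudoknot notation rejected)")
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0L) || depth[length(depth)] != 0L)
    return("unbalanced brackets")
  NULL
}

#' Encode a dataset for the network
#'
#' Runs the full input pipeline: centers sequences to the model length,
#' one-hot encodes them, and converts each record's structure ensemble into a
#' sparse stem-pair probability matrix aligned with the centered window.
#' Records without an ensemble in `ensembles` get an all-zero structure input
#' when `require_ensembles = FALSE`, otherwise an error names the sequence.
#'
#' @param records Data.frame from [read_labeled_fasta()] (columns `id`,
#'   `sequence`, and optionally `label`).
#' @param ensembles Named list from [parse_ensemble_file()], or `NULL` for
#'   sequence-only encoding.
#' @param length Model input length (default 200).
#' @param require_ensembles Error on records lacking an ensemble?
#' @return List with `seq` (length x 4 x n array), `str` (list of n sparse
#'   triplet matrices, 0-based `i,j,v` including both symmetric orientations),
#'   `labels`, `ids`, `length`.
#' @export
encode_dataset <- function(records, ensembles = NULL, length = 200L,
                           require_ensembles = FALSE) {
  records <- center_sequences(records, length)
  n <- nrow(records)
  seq_arr <- array(0, dim = c(length, 4L, n))
  str_list <- vector("list", n)
  empty <- matrix(numeric(0), ncol = 3L)
  for (i in seq_len(n)) {
    seq_arr[, , i] <- one_hot_encode(records$sequence[i], length)
    e <- ensembles[[records$id[i]]]
    if (is.null(e)) {
      if (require_ensembles)
        stop("no structure ensemble for sequence '", records$id[i], "'")
      str_list[[i]] <- empty
    } else {
      str_list[[i]] <- spm_triplets(e, length)
    }
  }
  labels <- if ("label" %in% names(records)) as.numeric(records$label) else NULL
  list(seq = seq_arr, str = str_list, labels = labels, ids = records$id,
       length = as.integer(length))
}
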