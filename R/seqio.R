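#' Amino-acid vocabulary
#'
#' The 20 canonical amino acids plus one padding symbol (`-`), giving a
#' vocabulary of size V = 21. Indices are 0-based and gap-free; the padding
#' symbol always has index 0 so that an all-zero argmax decodes to padding.
#' Non-canonical residue codes (B, J, O, U, X, Z) are not part of the
#' vocabulary; [encode_batch()] maps them to padding by default or errors in
#' strict mode.
#'
#' @param pad_symbol single character used for padding (default `"-"`).
#' @return An object of class `aa_vocabulary`: list with `symbols` (ordered
#'   character vector, padding first), `index` (named integer vector of
#'   0-based indices) and `size`.
#' @examples
#' v <- aa_vocabulary()
#' v$size           # 21
#' v$index[["A"]]   # 1
#' @export
aa_vocabulary <- function(pad_symbol = "-") {
  stopifnot(is.character(pad_symbol), nchar(pad_symbol) == 1L)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  symbols <- c(pad_symbol, aa)
  idx <- seq_along(symbols) - 1L
  names(idx) <- symbols
  structure(list(symbols = symbols, index = idx, size = length(symbols),
                 pad_symbol = pad_symbol, pad_index = 0L),
            class = "aa_vocabulary")
}

new_protein_record <- function(accession, sequence) {
  list(accession = accession, sequence = sequence, length = nchar(sequence))
}

#' Read protein sequences from a FASTA file
#'
#' The accession is the first whitespace-delimited token of each header;
#' sequences are uppercased and terminal stop characters (`*`) stripped.
#'
#' @param path path to a FASTA file.
#' @return List of protein records, each a list with `accession`,
#'   `sequence` and `length`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKV", ">P2", "acde"), f)
#' recs <- read_fasta(f)
#' recs[[2]]$sequence  # "ACDE"
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  xs <- Biostrings::readAAStringSet(path)
  if (length(xs) == 0L) return(list())
  headers <- names(xs)
  seqs <- toupper(as.character(xs))
  seqs <- sub("\\*+$", "", seqs)
  accs <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  bad <- which(is.na(accs) | accs == "")
  if (length(bad)) {
    stop("FASTA record ", bad[1L], ": malformed (empty) header")
  }
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop("FASTA record ", empty[1L], " ('", accs[empty[1L]],
         "'): empty sequence")
  }
  mapply(new_protein_record, accs, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records (or plain sequences) to FASTA
#'
#' @param records list of protein records, or a character vector of
#'   sequences (then headers are `gen_<index>`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- mapply(new_protein_record,
                      paste0("gen_", seq_along(records)), records,
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  seqs <- vapply(records, `[[`, character(1), "sequence")
  accs <- vapply(records, `[[`, character(1), "accession")
  xs <- Biostrings::AAStringSet(seqs)
  names(xs) <- accs
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}

#' Drop sequences longer than a residue cap
#'
#' Dataset-level length filter: records with more than `max_len` residues
#' are removed (the boundary is inclusive: length equal to `max_len` is
#' kept). Input order is preserved.
#'
#' @param records list of protein records.
#' @param max_len maximum residue length retained (default 2000).
#' @param verbose report the number of records removed.
#' @return Filtered list; the number removed is attached as
#'   `attr(, "n_removed")`.
#' @export
filter_by_length <- function(records, max_len = 2000L, verbose = FALSE) {
  stopifnot(max_len >= 1L)
  keep <- vapply(records, function(r) r$length <= max_len, logical(1))
  out <- records[keep]
  n_removed <- sum(!keep)
  if (verbose) {
    message("filter_by_length: removed ", n_removed, " of ",
            length(records), " records (> ", max_len, " residues)")
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Read a protein-to-GO annotation table
#'
#' Two-column tab-separated input, one `(accession, GO id)` pair per line.
#' Pairs are deduplicated; per-class counts are the number of distinct
#' accessions annotated with each class.
#'
#' @param path path to the TSV file.
#' @param known_accessions optional character vector; annotations whose
#'   accession is not in it trigger a warning (they are kept).
#' @return An `annotation_table`: list with `pairs` (data.frame `accession`,
#'   `go_id`) and `counts` (named integer vector, one entry per class).
#' @export
read_annotations <- function(path, known_accessions = NULL) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) {
    return(annotation_table(data.frame(accession = character(),
                                       go_id = character())))
  }
  parts <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    i <- which(nf != 2L)[1L]
    stop("annotation line ", lines_keep[i], ": expected 2 tab-separated ",
         "fields, found ", nf[i])
  }
  acc <- vapply(parts, `[`, character(1), 1L)
  go <- vapply(parts, `[`, character(1), 2L)
  bad <- which(!grepl("^GO:[0-9]{7}$", go))
  if (length(bad)) {
    stop("annotation line ", lines_keep[bad[1L]], ": malformed GO id '",
         go[bad[1L]], "'")
  }
  if (!is.null(known_accessions)) {
    unknown <- setdiff(unique(acc), known_accessions)
    if (length(unknown)) {
      warning(length(unknown), " annotated accession(s) absent from the ",
              "sequence set, e.g. '", unknown[1L], "'")
    }
  }
  annotation_table(data.frame(accession = acc, go_id = go,
                              stringsAsFactors = FALSE))
}

#' Build an annotation table from an accession/GO-id data frame
#'
#' @param pairs data.frame with columns `accession` and `go_id`; duplicate
#'   pairs are dropped.
#' @return An `annotation_table` (see [read_annotations()]).
#' @export
annotation_table <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("accession", "go_id") %in% names(pairs)))
  pairs <- unique(pairs[, c("accession", "go_id")])
  rownames(pairs) <- NULL
  counts <- integer(0)
  if (nrow(pairs)) {
    tab <- table(pairs$go_id)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(list(pairs = pairs, counts = counts),
            class = "annotation_table")
}

#' One-hot encode protein sequences into a fixed-length batch
#'
#' Sequences are truncated to `seq_len` or right-padded with the padding
#' symbol; each position carries a one-hot vector over the vocabulary, so
#' per-position sums are exactly 1.
#'
#' @param records list of protein records (or a character vector of
#'   sequences).
#' @param vocab an [aa_vocabulary()].
#' @param seq_len encoded length L (default 160).
#' @param strict if `TRUE`, a residue outside the vocabulary is an error
#'   naming the residue and its 1-based position; if `FALSE` (default) such
#'   residues are mapped to the padding symbol.
#' @return An `encoded_batch`: numeric array of dim `(n, seq_len, V)` with
#'   the accessions attached as `attr(, "accessions")`.
#' @export
encode_batch <- function(records, vocab = aa_vocabulary(), seq_len = 160L,
                         strict = FALSE) {
  stopifnot(seq_len >= 1L)
  if (is.character(records)) {
    records <- mapply(new_protein_record,
                      paste0("seq_", seq_along(records)), records,
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  if (!length(records)) stop("encode_batch: no records supplied")
  n <- length(records)
  V <- vocab$size
  # index matrix (n x L) of 1-based vocabulary positions, padding = 1
  im <- matrix(1L, n, seq_len)
  for (i in seq_len(n)) {
    s <- records[[i]]$sequence
    chars <- strsplit(substr(s, 1L, seq_len), "")[[1]]
    if (length(chars)) {
      pos <- match(chars, vocab$symbols)
      bad <- which(is.na(pos))
      if (length(bad)) {
        if (strict) {
          stop("record '", records[[i]]$accession, "': residue '",
               chars[bad[1L]], "' at position ", bad[1L],
               " is outside the vocabulary")
        }
        pos[bad] <- 1L
      }
      im[i, seq_along(chars)] <- pos
    }
  }
  arr <- array(0, dim = c(n, seq_len, V))
  ii <- rep(seq_len(n), times = seq_len)
  ll <- rep(seq_len(seq_len), each = n)
  arr[cbind(ii, ll, as.vector(im))] <- 1
  structure(arr,
            accessions = vapply(records, `[[`, character(1), "accession"),
            class = "encoded_batch")
}

#' Decode an encoded batch back to sequences
#'
#' Per position the argmax symbol is taken (ties broken by lowest
#' vocabulary index); the sequence ends at the first padding symbol, so the
#' decoded strings are always over the amino-acid alphabet. For one-hot
#' encodings of real sequences (where padding occurs only as a suffix) this
#' coincides with stripping trailing padding.
#'
#' @param batch an `encoded_batch` array `(n, L, V)` of values in `[0, 1]`
#'   (one-hot or probability simplex rows).
#' @param vocab the [aa_vocabulary()] used for encoding.
#' @return Character vector of decoded sequences.
#' @export
decode_batch <- function(batch, vocab = aa_vocabulary()) {
  stopifnot(length(dim(batch)) == 3L, dim(batch)[3] == vocab$size)
  n <- dim(batch)[1]
  L <- dim(batch)[2]
  out <- character(n)
  for (i in seq_len(n)) {
    m <- matrix(batch[i, , ], L, vocab$size)
    idx <- max.col(m, ties.method = "first")
    stop_at <- which(idx == 1L)
    keep <- if (length(stop_at)) seq_len(stop_at[1L] - 1L) else seq_len(L)
    out[i] <- paste0(vocab$symbols[idx[keep]], collapse = "")
  }
  out
}

# encoded_batch array (n, L, V) <-> tape matrix (n*L, V); rows are ordered
# batch-fastest (row = b + (l-1)*n), which is a plain dim change in
# column-major storage.
batch_to_mat <- function(batch) {
  d <- dim(batch)
  m <- as.numeric(batch)
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

mat_to_batch <- function(m, n, L) {
  arr <- as.numeric(m)
  dim(arr) <- c(n, L, ncol(m))
  structure(arr, class = "encoded_batch")
}
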