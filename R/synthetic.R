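#' Design of a synthetic motif-planted proteome
#'
#' Describes a desk-scale corpus standing in for a real annotated proteome:
#' background sequences drawn i.i.d. from residue frequencies, with one
#' distinct k-mer motif per functional class planted into the sequences of
#' annotated proteins, so class membership is statistically detectable from
#' sequence content. The default design (8 classes, 320 proteins, lengths
#' 80-160, 1-3 labels per protein, balanced class weights) trains in
#' minutes on one CPU; long-tailed class-frequency structure is available
#' through `class_weights` (e.g. `1/rank`) or exact designed
#' `class_counts`.
#'
#' @param n_classes number of GO classes.
#' @param n_proteins number of proteins.
#' @param len_range integer range of sequence lengths (inclusive).
#' @param labels_per_protein integer range of labels per protein; a
#'   minimum of 0 permits unannotated proteins.
#' @param motif_len motif length (4-8).
#' @param background `"uniform"` over the 20 residues, or `"uniprot-like"`
#'   (realistic amino-acid frequencies).
#' @param class_weights optional sampling weight per class (default
#'   balanced). Ignored when `class_counts` is given.
#' @param class_counts optional vector of exact per-class protein counts
#'   (designed counts); overrides weight-based assignment.
#' @param go_offset first GO numeric id (classes are `GO:<7 digits>`).
#' @param seed RNG seed.
#' @return A `synthetic_design` list (includes the per-class `motifs` and
#'   `classes` ids).
#' @export
synthetic_design <- function(n_classes = 8L, n_proteins = 320L,
                             len_range = c(80L, 160L),
                             labels_per_protein = c(1L, 3L),
                             motif_len = 6L,
                             background = c("uniform", "uniprot-like"),
                             class_weights = NULL, class_counts = NULL,
                             go_offset = 1000001L, seed = 1L) {
  background <- match.arg(background)
  stopifnot(n_classes >= 1L, n_proteins >= 1L,
            motif_len >= 4L, motif_len <= 8L,
            length(len_range) == 2L, len_range[1] <= len_range[2],
            len_range[1] >= 3L * motif_len,
            length(labels_per_protein) == 2L,
            labels_per_protein[1] >= 0L,
            labels_per_protein[2] >= labels_per_protein[1],
            labels_per_protein[2] <= n_classes)
  if (!is.null(class_counts)) {
    stopifnot(length(class_counts) == n_classes,
              all(class_counts >= 0), all(class_counts <= n_proteins))
  }
  aa <- aa_vocabulary()$symbols[-1]
  freqs <- if (background == "uniform") {
    stats::setNames(rep(1 / 20, 20), aa)
  } else {
    # approximate UniProt/SwissProt amino-acid composition
    stats::setNames(c(8.3, 1.4, 5.5, 6.7, 3.9, 7.1, 2.3, 5.9, 5.8, 9.7,
                      2.4, 4.1, 4.7, 3.9, 5.5, 6.6, 5.4, 6.9, 1.1, 2.9) / 100,
                    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))[aa]
  }
  set.seed(seed)
  # distinct equal-length motifs (equal length rules out substring nesting)
  motifs <- character(0)
  while (length(motifs) < n_classes) {
    cand <- paste0(sample(aa, motif_len, replace = TRUE), collapse = "")
    if (!cand %in% motifs) motifs <- c(motifs, cand)
  }
  if (is.null(class_weights)) {
    class_weights <- rep(1, n_classes)   # balanced default design
  }
  classes <- sprintf("GO:%07d", go_offset + seq_len(n_classes) - 1L)
  structure(list(n_classes = as.integer(n_classes),
                 n_proteins = as.integer(n_proteins),
                 len_range = as.integer(len_range),
                 labels_per_protein = as.integer(labels_per_protein),
                 motif_len = as.integer(motif_len),
                 background = background, freqs = freqs,
                 motifs = stats::setNames(motifs, classes),
                 classes = classes,
                 class_weights = class_weights / sum(class_weights),
                 class_counts = class_counts, seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Generate a synthetic annotated protein corpus
#'
#' Draws background sequences from the design's residue frequencies,
#' assigns classes (by long-tailed weights, or exactly by designed
#' `class_counts`), and plants each assigned class's motif at a
#' uniform-random position without overlapping previously planted motifs.
#' A sequence too short for its motifs is lengthened to fit and flagged in
#' the manifest. Deterministic given `seed`.
#'
#' @param design a [synthetic_design()].
#' @param out_dir optional directory; when given, writes `corpus.fasta`,
#'   `annotations.tsv` (accession TAB GO-id) and `manifest.json`.
#' @param seed RNG seed (default: the design's).
#' @return A `synthetic_corpus`: list with `records`, `annotations`
#'   (data.frame accession/go_id), and `manifest` (per-protein planted
#'   classes and motif positions; per-class counts; the design).
#' @export
generate_corpus <- function(design, out_dir = NULL, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)
  n <- design$n_proteins
  accs <- sprintf("SYN%05d", seq_len(n))
  # class assignment: protein -> character vector of class ids
  assigned <- vector("list", n)
  if (!is.null(design$class_counts)) {
    for (ci in seq_len(design$n_classes)) {
      members <- sample.int(n, design$class_counts[ci])
      for (i in members) {
        assigned[[i]] <- c(assigned[[i]], design$classes[ci])
      }
    }
  } else {
    lp <- design$labels_per_protein
    for (i in seq_len(n)) {
      n_lab <- if (lp[1] == lp[2]) lp[1] else sample(lp[1]:lp[2], 1L)
      if (n_lab > 0L) {
        assigned[[i]] <- design$classes[
          sample.int(design$n_classes, n_lab, prob = design$class_weights)]
      }
    }
  }
  aa <- names(design$freqs)
  records <- vector("list", n)
  manifest_prot <- vector("list", n)
  ml <- design$motif_len
  for (i in seq_len(n)) {
    len <- sample(design$len_range[1]:design$len_range[2], 1L)
    cls <- assigned[[i]]
    lengthened <- FALSE
    if (length(cls) * ml > len) {          # infeasible: lengthen to fit
      len <- length(cls) * (ml + 2L)
      lengthened <- TRUE
    }
    chars <- sample(aa, len, replace = TRUE, prob = design$freqs)
    # plant motifs at non-overlapping uniform-random positions
    occupied <- integer(0)
    positions <- integer(0)
    for (cl in cls) {
      placed <- FALSE
      for (try in 1:200) {
        pos <- sample.int(len - ml + 1L, 1L)
        span <- pos:(pos + ml - 1L)
        if (!any(span %in% occupied)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {       # dense packing: first free window, left to right
        for (pos in seq_len(len - ml + 1L)) {
          span <- pos:(pos + ml - 1L)
          if (!any(span %in% occupied)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {     # still no room: append at the end
          pos <- len + 1L
          len <- len + ml
          span <- pos:(pos + ml - 1L)
          chars <- c(chars, sample(aa, ml, replace = TRUE,
                                   prob = design$freqs))
          lengthened <- TRUE
        }
      }
      occupied <- c(occupied, span)
      positions <- c(positions, pos)
      chars[span] <- strsplit(design$motifs[[cl]], "")[[1]]
    }
    records[[i]] <- new_protein_record(accs[i], paste0(chars, collapse = ""))
    manifest_prot[[i]] <- list(accession = accs[i],
                               classes = as.list(cls),
                               motif_positions = as.list(positions),
                               lengthened = lengthened)
  }
  ann <- data.frame(
    accession = rep(accs, lengths(assigned)),
    go_id = unlist(assigned, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(ann)) ann <- data.frame(accession = character(),
                                    go_id = character())
  counts <- integer(design$n_classes)
  names(counts) <- design$classes
  if (nrow(ann)) {
    tab <- table(unique(ann)$go_id)
    counts[names(tab)] <- as.integer(tab)
  }
  manifest <- list(seed = seed, n_proteins = n,
                   per_class_counts = as.list(counts),
                   proteins = manifest_prot,
                   motifs = as.list(design$motifs),
                   design = design[c("n_classes", "n_proteins", "len_range",
                                     "labels_per_protein", "motif_len",
                                     "background")])
  corpus <- structure(list(records = records, annotations = ann,
                           manifest = manifest),
                      class = "synthetic_corpus")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(records, file.path(out_dir, "corpus.fasta"))
    utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  corpus
}

#' Permute annotation labels (negative control)
#'
#' Randomly permutes the accession column of an annotation table, breaking
#' any sequence-to-function association while preserving per-class counts
#' exactly. Permutations creating duplicate pairs are rejected and redrawn
#' (duplicates would collapse under deduplication and change counts).
#'
#' @param annotations data.frame with columns `accession` and `go_id`, an
#'   `annotation_table`, or a path to a two-column TSV.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling bound.
#' @return Data.frame of the same shape with accessions permuted.
#' @export
permute_labels <- function(annotations, seed = 1L, max_tries = 1000L) {
  if (is.character(annotations)) {
    annotations <- read_annotations(annotations)$pairs
  } else if (inherits(annotations, "annotation_table")) {
    annotations <- annotations$pairs
  }
  stopifnot(is.data.frame(annotations),
            all(c("accession", "go_id") %in% names(annotations)))
  n <- nrow(annotations)
  if (n <= 1L) return(annotations)
  set.seed(seed)
  out <- annotations
  out$accession <- annotations$accession[sample.int(n)]
  # repair duplicate (accession, class) pairs by swapping accessions
  # between rows; each swap keeps the per-class row counts, so the
  # deduplicated per-class counts match the input exactly
  key <- function(a, g) paste(a, g, sep = "\r")
  for (iter in seq_len(max_tries)) {
    keys <- key(out$accession, out$go_id)
    dup <- which(duplicated(keys))
    if (!length(dup)) {
      rownames(out) <- NULL
      return(out)
    }
    tab <- keys
    for (i in dup) {
      for (try in 1:200) {
        j <- sample.int(n, 1L)
        if (j == i) next
        ai <- out$accession[i]
        aj <- out$accession[j]
        if (ai == aj) next
        new_i <- key(aj, out$go_id[i])
        new_j <- key(ai, out$go_id[j])
        if (!(new_i %in% tab) && !(new_j %in% tab)) {
          out$accession[i] <- aj
          out$accession[j] <- ai
          tab <- key(out$accession, out$go_id)
          break
        }
      }
    }
  }
  keys <- key(out$accession, out$go_id)
  if (any(duplicated(keys))) {
    stop("permute_labels: could not repair duplicate pairs in ",
         max_tries, " passes")
  }
  rownames(out) <- NULL
  out
}
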