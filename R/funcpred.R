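#' Extract transfer-learning features from the critic
#'
#' Runs the discriminator forward with its final linear layer removed and
#' returns, per sequence, the input to that deleted layer: the capsule
#' length-layer outputs (`tap = "lengths"`, the default; feature dimension
#' equals the number of output capsules). For ablation, `tap = "residual"`
#' instead returns the pre-capsule residual features mean-pooled over
#' positions (dimension `d`).
#'
#' @param disc a discriminator from [build_discriminator()] (trained or
#'   untrained).
#' @param batch an `encoded_batch` array `(N, L, V)` of real sequences.
#' @param tap `"lengths"` (default) or `"residual"`.
#' @param chunk_size sequences per forward pass (memory control).
#' @return Numeric feature matrix `(N, F)`; row order matches the batch,
#'   with accessions carried over as rownames when present.
#' @export
extract_features <- function(disc, batch, tap = c("lengths", "residual"),
                             chunk_size = 64L) {
  tap <- match.arg(tap)
  stopifnot(inherits(disc, "gocapgan_discriminator"),
            length(dim(batch)) == 3L)
  cfg <- disc$config
  if (dim(batch)[2] != cfg$seq_len || dim(batch)[3] != cfg$vocab_size) {
    stop("extract_features: batch is (", dim(batch)[2], ", ",
         dim(batch)[3], ") per sequence but the discriminator expects (",
         cfg$seq_len, ", ", cfg$vocab_size, ")")
  }
  N <- dim(batch)[1]
  disc_n <- with_par_nodes(disc, leaf = FALSE)
  out <- NULL
  for (start in seq(1L, N, by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1L, N)
    xb <- batch[rows, , , drop = FALSE]
    fwd <- disc_forward(disc_n, nn_const(batch_to_mat(xb)), length(rows))
    feats <- if (tap == "lengths") {
      nn_value(fwd$lengths)
    } else {
      # mean-pool residual features over positions: rows are b-fastest
      res <- nn_value(fwd$residual)
      b_ids <- rep(seq_along(rows), cfg$seq_len)
      rowsum(res, b_ids) / cfg$seq_len
    }
    out <- rbind(out, feats)
  }
  accs <- attr(batch, "accessions")
  if (!is.null(accs)) rownames(out) <- accs
  out
}

#' Select frequent, eligible GO classes
#'
#' Keeps classes annotated to at least `min_count` distinct proteins, sorts
#' them by descending count (ties broken lexicographically by GO id) and
#' truncates to the `top_k` most frequent — the published eligibility rule
#' (at least 16 sequences per class) followed by top-25 selection.
#'
#' @param table an `annotation_table`.
#' @param min_count eligibility threshold (default 16).
#' @param top_k classes retained (default 25).
#' @return Character vector of selected GO ids, most frequent first, with
#'   `attr(, "n_eligible")` giving the eligible-class total. If fewer than
#'   `top_k` classes are eligible, all are returned with a warning.
#' @export
select_classes <- function(table, min_count = 16L, top_k = 25L) {
  stopifnot(inherits(table, "annotation_table"),
            min_count >= 1L, top_k >= 1L)
  counts <- table$counts
  elig <- counts[counts >= min_count]
  n_eligible <- length(elig)
  if (n_eligible == 0L) {
    out <- character(0)
    attr(out, "n_eligible") <- 0L
    return(out)
  }
  ord <- order(-elig, names(elig))
  sel <- names(elig)[ord]
  if (n_eligible < top_k) {
    warning("select_classes: only ", n_eligible,
            " classes eligible (requested top ", top_k, ")")
  }
  out <- utils::head(sel, top_k)
  attr(out, "n_eligible") <- n_eligible
  out
}

#' Binary multi-label target matrix
#'
#' `Y[i, l] = 1` iff protein `i` is annotated with class `l`.
#'
#' @param records list of protein records (order defines rows), or a
#'   character vector of accessions.
#' @param table an `annotation_table`.
#' @param classes character vector of class ids (order defines columns).
#' @return Binary matrix `(N, length(classes))` with accession rownames and
#'   class colnames.
#' @export
build_label_matrix <- function(records, table, classes) {
  stopifnot(length(classes) >= 1L)
  accs <- if (is.character(records)) {
    records
  } else {
    vapply(records, `[[`, character(1), "accession")
  }
  Y <- matrix(0L, length(accs), length(classes),
              dimnames = list(accs, classes))
  pairs <- table$pairs
  keep <- pairs$go_id %in% classes & pairs$accession %in% accs
  if (any(keep)) {
    Y[cbind(match(pairs$accession[keep], accs),
            match(pairs$go_id[keep], classes))] <- 1L
  }
  Y
}

#' Binary cross-entropy loss
#'
#' Mean over all label slots of `-[y log(h) + (1 - y) log(1 - h)]`;
#' probabilities are clamped to `[eps, 1 - eps]`.
#'
#' @param y binary matrix (or vector) of targets.
#' @param h matching matrix (or vector) of predicted probabilities.
#' @param eps clamping constant (default 1e-7).
#' @return Scalar nonnegative loss.
#' @export
bce_loss <- function(y, h, eps = 1e-7) {
  y <- as.numeric(y)
  h <- as.numeric(h)
  if (length(y) != length(h)) stop("bce_loss: shape mismatch")
  h <- pmin(pmax(h, eps), 1 - eps)
  -mean(y * log(h) + (1 - y) * log(1 - h))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train the multi-label classifier
#'
#' A single dense layer with sigmoid activation trained on binary
#' cross-entropy with Adam (defaults lr 0.001, beta1 0.9, beta2 0.999) for
#' the configured epochs (default 40), in shuffled minibatches.
#' Deterministic given `seed`.
#'
#' @param features numeric matrix `(N, F)`.
#' @param labels binary matrix `(N, L)`.
#' @param epochs training epochs (default 40).
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param batch_size minibatch size (default 32; capped at N).
#' @param seed RNG seed for minibatch shuffling.
#' @return A `classifier_model`: list with `W` `(F, L)`, `b` `(1, L)`,
#'   `classes`, `threshold` and the training `loss` history (one entry per
#'   epoch, mean minibatch loss).
#' @export
train_classifier <- function(features, labels, epochs = 40L, lr = 1e-3,
                             beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                             batch_size = 32L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  N <- nrow(features)
  stopifnot(N >= 2L, nrow(labels) == N)
  if (all(labels == 0)) {
    warning("train_classifier: all-zero label matrix; training proceeds")
  }
  Fdim <- ncol(features)
  Ldim <- ncol(labels)
  W <- matrix(0, Fdim, Ldim)
  b <- matrix(0, 1, Ldim)
  mW <- vW <- matrix(0, Fdim, Ldim)
  mb <- vb <- matrix(0, 1, Ldim)
  bs <- min(batch_size, N)
  set.seed(seed)
  t_step <- 0
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    ep_losses <- numeric(0)
    for (start in seq(1L, N, by = bs)) {
      rows <- perm[start:min(start + bs - 1L, N)]
      X <- features[rows, , drop = FALSE]
      Y <- labels[rows, , drop = FALSE]
      H <- sigmoid(sweep(X %*% W, 2, b, "+"))
      ep_losses <- c(ep_losses, bce_loss(Y, H))
      m <- nrow(X) * Ldim
      gW <- crossprod(X, H - Y) / m
      gb <- matrix(colSums(H - Y) / m, 1, Ldim)
      t_step <- t_step + 1
      mW <- beta1 * mW + (1 - beta1) * gW
      vW <- beta2 * vW + (1 - beta2) * gW^2
      mb <- beta1 * mb + (1 - beta1) * gb
      vb <- beta2 * vb + (1 - beta2) * gb^2
      mhW <- mW / (1 - beta1^t_step)
      vhW <- vW / (1 - beta2^t_step)
      mhb <- mb / (1 - beta1^t_step)
      vhb <- vb / (1 - beta2^t_step)
      W <- W - lr * mhW / (sqrt(vhW) + adam_eps)
      b <- b - lr * mhb / (sqrt(vhb) + adam_eps)
    }
    loss_hist[ep] <- mean(ep_losses)
  }
  structure(list(W = W, b = b, classes = colnames(labels),
                 threshold = 0.5, loss = loss_hist),
            class = "classifier_model")
}

#' Predicted class probabilities
#'
#' @param model a `classifier_model`.
#' @param features numeric matrix `(N, F)`.
#' @return Matrix of sigmoid probabilities in `(0, 1)`.
#' @export
predict_proba <- function(model, features) {
  features <- as.matrix(features)
  H <- sigmoid(sweep(features %*% model$W, 2, model$b, "+"))
  colnames(H) <- model$classes
  rownames(H) <- rownames(features)
  H
}

#' Threshold probabilities into binary labels
#'
#' `Y[i, l] = 1` iff the predicted probability is `>= threshold` (ties at
#' the threshold count as positive). Lowering the threshold never turns a
#' positive into a negative.
#'
#' @param model a `classifier_model`.
#' @param features numeric matrix `(N, F)`.
#' @param threshold decision threshold in `(0, 1)` (default `model$threshold`).
#' @return Binary label matrix.
#' @export
predict_labels <- function(model, features, threshold = model$threshold) {
  stopifnot(threshold > 0, threshold < 1)
  H <- predict_proba(model, features)
  Y <- (H >= threshold) + 0L
  Y
}
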