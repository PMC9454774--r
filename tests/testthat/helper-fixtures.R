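# shared fixtures: tiny configurations and reference (oracle) implementations

ns <- asNamespace("gocapgan")

tiny_config <- function(...) {
  defaults <- list(batch_size = 4L, seq_len = 16L, noise_dim = 8L,
                   epochs = 1L, d = 8L, kernel = 5L, n_critic = 2L,
                   caps_stride = 4L, primary_dim = 8L, out_caps = 3L,
                   out_dim = 4L, seed = 11L)
  do.call(gan_config, utils::modifyList(defaults, list(...)))
}

random_seqs <- function(n, len_range = c(6L, 14L), seed = 1L) {
  set.seed(seed)
  aa <- aa_vocabulary()$symbols[-1]
  vapply(seq_len(n), function(i) {
    paste0(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
           collapse = "")
  }, character(1))
}

# scalar-loop reference for capsule votes: x_hat[k|j] = W[j,k] x_j + B[j,k]
oracle_votes <- function(inputs, params) {
  J <- params$j_in; K <- params$k_out
  out <- array(0, dim = c(J, K, params$d_out))
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      for (t in seq_len(params$d_out)) {
        acc <- params$B[j, k, t]
        for (u in seq_len(params$d_in)) {
          acc <- acc + params$W[j, k, t, u] * inputs[j, u]
        }
        out[j, k, t] <- acc
      }
    }
  }
  out
}

# scalar-loop reference for dynamic routing (mirrors the published
# procedure step by step, no vectorization)
oracle_route <- function(votes, iterations = 3L) {
  J <- dim(votes)[1]; K <- dim(votes)[2]; d <- dim(votes)[3]
  b <- matrix(0, J, K)
  v <- matrix(0, K, d)
  cc <- matrix(0, J, K)
  for (it in seq_len(iterations)) {
    for (j in seq_len(J)) {
      e <- exp(b[j, ] - max(b[j, ]))
      cc[j, ] <- e / sum(e)
    }
    for (k in seq_len(K)) {
      s <- numeric(d)
      for (j in seq_len(J)) s <- s + cc[j, k] * votes[j, k, ]
      n2 <- sum(s * s)
      v[k, ] <- if (n2 == 0) s * 0 else (n2 / (1 + n2)) * s / sqrt(n2 + 1e-8)
    }
    if (it < iterations) {
      for (j in seq_len(J)) {
        for (k in seq_len(K)) {
          b[j, k] <- b[j, k] + sum(votes[j, k, ] * v[k, ])
        }
      }
    }
  }
  list(coupling = cc, v = v)
}

# tiny synthetic corpus + encoded batch for network-level tests
tiny_corpus <- function(n_proteins = 24L, n_classes = 3L, seed = 5L) {
  design <- synthetic_design(n_classes = n_classes, n_proteins = n_proteins,
                             len_range = c(20L, 30L),
                             labels_per_protein = c(1L, 2L),
                             motif_len = 5L, seed = seed)
  generate_corpus(design)
}
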