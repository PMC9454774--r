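#' Capsule squash nonlinearity
#'
#' Maps a vector `s` to `(|s|^2 / (1 + |s|^2)) * s / |s|`: the output is a
#' nonnegative scalar multiple of the input (orientation preserved) whose
#' norm lies in `[0, 1)` and increases monotonically with `|s|`. The zero
#' vector maps exactly to the zero vector; an epsilon guards the internal
#' division only.
#'
#' @param s numeric vector (or matrix: each row squashed independently).
#' @param eps internal guard for the norm division (default 1e-8).
#' @return Squashed vector (or matrix) of the same shape.
#' @examples
#' squash(c(3, 4))          # norm 25/26 * 1 = 0.9615...
#' sqrt(sum(squash(c(3, 4))^2))
#' @export
squash <- function(s, eps = 1e-8) {
  if (is.matrix(s)) {
    return(squash_rows_num(s, eps = eps))
  }
  stopifnot(is.numeric(s), all(is.finite(s)))
  n2 <- sum(s * s)
  if (n2 == 0) return(s * 0)
  (n2 / (1 + n2)) * s / sqrt(n2 + eps)
}

#' Parameters of a capsule layer
#'
#' Holds the affine vote transformation: weight blocks `W[j, k, , ]`
#' (`d_out` x `d_in`) and biases `B[j, k, ]` mapping input capsule `j` to
#' its vote for output capsule `k`. Biases are per `(j, k)` pair by default
#' (`bias_mode = "per_pair"`); `"per_output"` ties them across `j`.
#'
#' @param j_in,k_out number of input / output capsules.
#' @param d_in,d_out input / output capsule dimensionality.
#' @param bias_mode `"per_pair"` (default) or `"per_output"`.
#' @param init_sd standard deviation of the normal weight initialization.
#' @param seed optional seed for reproducible initialization.
#' @return A `capsule_params` object: list with arrays `W`
#'   `(j_in, k_out, d_out, d_in)` and `B` `(j_in, k_out, d_out)` plus the
#'   dimensions.
#' @export
capsule_params <- function(j_in, k_out, d_in, d_out,
                           bias_mode = c("per_pair", "per_output"),
                           init_sd = 0.1, seed = NULL) {
  bias_mode <- match.arg(bias_mode)
  stopifnot(j_in >= 1, k_out >= 1, d_in >= 1, d_out >= 1)
  if (!is.null(seed)) set.seed(seed)
  W <- array(stats::rnorm(j_in * k_out * d_out * d_in, sd = init_sd),
             dim = c(j_in, k_out, d_out, d_in))
  B <- array(stats::rnorm(j_in * k_out * d_out, sd = init_sd),
             dim = c(j_in, k_out, d_out))
  if (bias_mode == "per_output") {
    for (j in seq_len(j_in)) B[j, , ] <- B[1, , ]
  }
  structure(list(W = W, B = B, j_in = j_in, k_out = k_out,
                 d_in = d_in, d_out = d_out, bias_mode = bias_mode),
            class = "capsule_params")
}

#' Affine capsule votes
#'
#' Vote of input capsule `j` for output capsule `k`:
#' `x_hat[k|j] = W[j,k] %*% x[j] + B[j,k]`.
#'
#' @param inputs matrix `(j_in, d_in)` of input capsule vectors (rows), or
#'   a list of `j_in` vectors.
#' @param params a [capsule_params()] object.
#' @return Vote array `(j_in, k_out, d_out)`.
#' @export
compute_votes <- function(inputs, params) {
  if (is.list(inputs)) inputs <- do.call(rbind, inputs)
  if (!is.matrix(inputs)) inputs <- matrix(inputs, nrow = 1)
  if (nrow(inputs) != params$j_in) {
    stop("compute_votes: got ", nrow(inputs), " input capsules, expected ",
         "j_in = ", params$j_in)
  }
  if (ncol(inputs) != params$d_in) {
    stop("compute_votes: input capsule dimension ", ncol(inputs),
         " does not match d_in = ", params$d_in)
  }
  votes <- array(0, dim = c(params$j_in, params$k_out, params$d_out))
  for (j in seq_len(params$j_in)) {
    for (k in seq_len(params$k_out)) {
      votes[j, k, ] <- params$W[j, k, , , drop = TRUE] %*% inputs[j, ] +
        params$B[j, k, ]
    }
  }
  votes
}

#' Dynamic routing by agreement
#'
#' Routing logits `b[j,k]` start at zero. Each round computes coupling
#' coefficients `c = softmax(b)` over the output-capsule axis `k`, the
#' weighted vote sum `s[k] = sum_j c[j,k] * x_hat[k|j]`, the squashed
#' outputs `v[k] = squash(s[k])`, and then (except after the final round)
#' the agreement update `b[j,k] <- b[j,k] + x_hat[k|j] . v[k]`. Logits are
#' re-initialized every call: routing is not stateful across batches.
#'
#' @param votes vote array `(j_in, k_out, d_out)` from [compute_votes()].
#' @param iterations number of routing rounds (default 3).
#' @return A `routing_state`: list with `b`, `coupling` (rows sum to 1),
#'   `s` `(k_out, d_out)`, `v` `(k_out, d_out)` and `iterations`.
#' @export
dynamic_route <- function(votes, iterations = 3L) {
  stopifnot(length(dim(votes)) == 3L)
  if (iterations < 1L) stop("dynamic_route: iterations must be >= 1")
  J <- dim(votes)[1]
  K <- dim(votes)[2]
  d <- dim(votes)[3]
  vm <- matrix(votes, J, K * d)    # columns ordered k-fastest: col = k + (t-1)*K
  b <- matrix(0, J, K)
  cc <- NULL
  v <- NULL
  s <- NULL
  for (it in seq_len(iterations)) {
    e <- exp(b - apply(b, 1, max))
    cc <- e / rowSums(e)
    w <- vm * cc[, rep(seq_len(K), times = d), drop = FALSE]
    s <- matrix(colSums(w), K, d)
    v <- squash_rows_num(s)
    if (it < iterations) {
      agree <- vm * rep(as.vector(v), each = J)
      b <- b + vapply(seq_len(K), function(k) {
        rowSums(agree[, seq.int(k, K * d, by = K), drop = FALSE])
      }, numeric(J))
    }
  }
  structure(list(b = b, coupling = cc, s = s, v = v,
                 iterations = iterations),
            class = "routing_state")
}

# numeric (non-tape) row-wise squash; zero rows map to zero exactly
squash_rows_num <- function(m, eps = 1e-8) {
  n2 <- rowSums(m * m)
  scale <- ifelse(n2 == 0, 0, (n2 / (1 + n2)) / sqrt(n2 + eps))
  m * scale
}

#' Capsule lengths (existence probabilities)
#'
#' @param state a `routing_state` from [dynamic_route()], or a matrix of
#'   output capsule vectors (one per row).
#' @return Numeric vector of `|v[k]|`, each in `[0, 1)`.
#' @export
capsule_lengths <- function(state) {
  v <- if (inherits(state, "routing_state")) state$v else state
  stopifnot(is.matrix(v))
  sqrt(rowSums(v * v))
}
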