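#' GAN configuration
#'
#' All hyperparameters of the sequence WGAN. Defaults follow the published
#' training setup (batch size 32, sequence length 160, 12 epochs, gradient
#' penalty weight lambda = 10, noise dimension 128, RMSprop with learning
#' rate 1e-4, alpha 0.99, eps 1e-8, Wasserstein loss) with desk-scale
#' choices where the publication is silent: model width `d = 64`, kernel
#' size 5, 6 residual blocks in both networks, 5 critic updates per
#' generator update, Gumbel-softmax temperature 1, primary capsule
#' dimension 8 (capsule conv stride 4), 10 output capsules of dimension 16.
#'
#' @param batch_size minibatch size Psi.
#' @param seq_len encoded sequence length L.
#' @param noise_dim generator input (latent) dimension.
#' @param epochs training epochs; one epoch is `floor(N / batch_size)` full
#'   minibatches, drop-last.
#' @param lambda gradient-penalty weight (>= 0).
#' @param lr RMSprop learning rate.
#' @param rms_alpha,rms_eps RMSprop smoothing constant and stabilizer.
#' @param n_res_blocks residual blocks in each network.
#' @param d channel width of the convolutional stacks.
#' @param kernel 1-D convolution kernel size (odd).
#' @param n_critic critic updates per generator update.
#' @param tau Gumbel-softmax temperature (> 0).
#' @param lrelu_slope LeakyReLU negative slope.
#' @param skip_scale residual skip scaling.
#' @param caps_stride stride of the capsule conv sub-layer.
#' @param primary_dim primary capsule dimension (also the capsule conv
#'   channel count: one primary capsule per retained position).
#' @param out_caps,out_dim output capsule count and dimension.
#' @param routing_iters dynamic-routing rounds.
#' @param straight_through use the straight-through Gumbel estimator
#'   (default `TRUE`): the generator emits hard one-hot samples while
#'   gradients flow through the underlying softmax. Keeps the critic from
#'   separating real and generated batches by simplex softness instead of
#'   sequence content.
#' @param bias_mode capsule vote bias: `"per_pair"` or `"per_output"`.
#' @param lipschitz `"gp"` (gradient penalty, default) or `"clip"` (weight
#'   clipping with bound `clip_value`).
#' @param clip_value weight-clipping bound when `lipschitz = "clip"`.
#' @param vocab_size vocabulary size V (21: 20 residues + padding).
#' @param seed RNG seed for construction and training.
#' @return A `gan_config` list.
#' @export
gan_config <- function(batch_size = 32L, seq_len = 160L, noise_dim = 128L,
                       epochs = 12L, lambda = 10, lr = 1e-4,
                       rms_alpha = 0.99, rms_eps = 1e-8,
                       n_res_blocks = 6L, d = 64L, kernel = 5L,
                       n_critic = 5L, tau = 1.0, lrelu_slope = 0.2,
                       skip_scale = 0.3, caps_stride = 4L,
                       primary_dim = 8L, out_caps = 10L, out_dim = 16L,
                       routing_iters = 3L, straight_through = TRUE,
                       bias_mode = c("per_pair", "per_output"),
                       lipschitz = c("gp", "clip"), clip_value = 0.01,
                       vocab_size = 21L, seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size),
              seq_len = as.integer(seq_len),
              noise_dim = as.integer(noise_dim),
              epochs = as.integer(epochs), lambda = lambda, lr = lr,
              rms_alpha = rms_alpha, rms_eps = rms_eps,
              n_res_blocks = as.integer(n_res_blocks), d = as.integer(d),
              kernel = as.integer(kernel), n_critic = as.integer(n_critic),
              tau = tau, lrelu_slope = lrelu_slope,
              skip_scale = skip_scale,
              caps_stride = as.integer(caps_stride),
              primary_dim = as.integer(primary_dim),
              out_caps = as.integer(out_caps),
              out_dim = as.integer(out_dim),
              routing_iters = as.integer(routing_iters),
              straight_through = isTRUE(straight_through),
              bias_mode = match.arg(bias_mode),
              lipschitz = match.arg(lipschitz), clip_value = clip_value,
              vocab_size = as.integer(vocab_size),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(batch_size >= 1, seq_len >= 1, noise_dim >= 1, epochs >= 0,
              lambda >= 0, lr > 0, tau > 0, n_res_blocks >= 1, d >= 1,
              kernel >= 1, kernel %% 2 == 1, n_critic >= 1,
              caps_stride >= 1, primary_dim >= 1, out_caps >= 1,
              out_dim >= 1, routing_iters >= 1)
  })
  if (cfg$seq_len %% cfg$caps_stride != 0) {
    stop("gan_config: seq_len (", cfg$seq_len, ") is not divisible by ",
         "caps_stride (", cfg$caps_stride, "); the capsule reshape ",
         "cannot tile the conv output")
  }
  structure(cfg, class = "gan_config")
}

glorot_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Build the sequence generator
#'
#' Linear map from the latent vector to `L x d` position features, six
#' residual blocks (each two 1-D convolutions with LeakyReLU, additive skip
#' scaled by `skip_scale`), then a per-position projection to vocabulary
#' channels with Gumbel-softmax activation, so every output position lies
#' on the probability simplex. Construction is deterministic given
#' `config$seed`.
#'
#' @param config a [gan_config()].
#' @return A `gocapgan_generator`: list with `config`, `params` (named list
#'   of weight matrices) and `n_params`.
#' @export
build_generator <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  set.seed(config$seed)
  L <- config$seq_len
  d <- config$d
  V <- config$vocab_size
  ker <- config$kernel
  p <- list(
    fc_W = glorot_mat(config$noise_dim, L * d),
    fc_b = matrix(0, 1, L * d)
  )
  for (i in seq_len(config$n_res_blocks)) {
    p[[paste0("res", i, "_W1")]] <- glorot_mat(ker * d, d)
    p[[paste0("res", i, "_b1")]] <- matrix(0, 1, d)
    p[[paste0("res", i, "_W2")]] <- glorot_mat(ker * d, d)
    p[[paste0("res", i, "_b2")]] <- matrix(0, 1, d)
  }
  p$out_W <- glorot_mat(d, V)
  p$out_b <- matrix(0, 1, V)
  g <- structure(list(config = config, params = p), class = "gocapgan_generator")
  g$n_params <- count_params(g)
  g
}

#' Build the capsule critic (discriminator)
#'
#' Initial 1-D convolution over vocabulary channels, six residual blocks, a
#' capsule stage (strided conv sub-layer to `primary_dim` channels, reshape
#' into one primary capsule per retained position, squash, dynamic routing
#' over `routing_iters` rounds, capsule length layer) and a final linear
#' layer producing one unbounded critic score per sequence.
#'
#' @param config a [gan_config()].
#' @return A `gocapgan_discriminator`: list with `config`, `params`,
#'   `n_caps` (primary capsule count J), `n_features` (length-layer width,
#'   the transfer-learning feature dimension) and `n_params`.
#' @export
build_discriminator <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  set.seed(config$seed + 1L)
  L <- config$seq_len
  d <- config$d
  V <- config$vocab_size
  ker <- config$kernel
  J <- L %/% config$caps_stride          # primary capsules = L' * d' / d'
  pd <- config$primary_dim
  K <- config$out_caps
  od <- config$out_dim
  p <- list(
    in_W = glorot_mat(ker * V, d),
    in_b = matrix(0, 1, d)
  )
  for (i in seq_len(config$n_res_blocks)) {
    p[[paste0("res", i, "_W1")]] <- glorot_mat(ker * d, d)
    p[[paste0("res", i, "_b1")]] <- matrix(0, 1, d)
    p[[paste0("res", i, "_W2")]] <- glorot_mat(ker * d, d)
    p[[paste0("res", i, "_b2")]] <- matrix(0, 1, d)
  }
  p$caps_W <- glorot_mat(ker * d, pd)
  p$caps_b <- matrix(0, 1, pd)
  for (j in seq_len(J)) {
    p[[paste0("vote_W", j)]] <- glorot_mat(pd, K * od)
  }
  if (config$bias_mode == "per_pair") {
    for (j in seq_len(J)) p[[paste0("vote_b", j)]] <- matrix(0, 1, K * od)
  } else {
    p$vote_b_shared <- matrix(0, 1, K * od)
  }
  p$head_W <- glorot_mat(K, 1)
  p$head_b <- matrix(0, 1, 1)
  disc <- structure(list(config = config, params = p, n_caps = J,
                         n_features = K),
                    class = "gocapgan_discriminator")
  disc$n_params <- count_params(disc)
  disc
}

#' Total trainable parameter count
#'
#' @param model a generator, discriminator, or plain parameter list.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  p <- if (is.list(model) && !is.null(model$params)) model$params else model
  sum(vapply(p, length, integer(1)))
}

## ---- tape forward passes --------------------------------------------------

# im2col gather indices for a same-padded strided 1-D conv over a batch
# stored as (n*L, C) with rows batch-fastest (row = b + (l-1)*n).
# Returns list(idx, n_out_rows): idx has length n*L_out*kernel; out-of-range
# taps point to the appended zero row (n*L + 1).
conv_indices <- function(n, L, kernel, stride = 1L) {
  L_out <- L %/% stride
  centers <- (seq_len(L_out) - 1L) * stride + 1L + (stride %/% 2L)
  centers <- pmin(centers, L)
  half <- (kernel - 1L) %/% 2L
  zero_row <- n * L + 1L
  idx <- integer(n * L_out * kernel)
  pos <- 1L
  for (t in seq_len(kernel)) {
    src <- centers + (t - 1L) - half           # length L_out
    ok <- src >= 1L & src <= L
    block <- rep(zero_row, n * L_out)
    bb <- rep(seq_len(n), times = L_out)
    ll <- rep(src, each = n)
    okr <- rep(ok, each = n)
    block[okr] <- bb[okr] + (ll[okr] - 1L) * n
    idx[pos:(pos + n * L_out - 1L)] <- block
    pos <- pos + n * L_out
  }
  list(idx = idx, rows = n * L_out, L_out = L_out)
}

# same-padded 1-D convolution on the tape; x is (n*L, C_in)
nn_conv1d <- function(x, W, b, n, L, kernel, stride = 1L) {
  ci <- conv_indices(n, L, kernel, stride)
  n_in <- n * L
  xp <- nn_scatter_rows(x, seq_len(n_in), n_in + 1L)   # append zero row
  g <- nn_gather_rows(xp, ci$idx)                      # (rows*kernel, C_in)
  m <- nn_reshape(g, ci$rows, kernel * ncol(x$value))  # (rows, kernel*C_in)
  nn_add(nn_matmul(m, W), nn_reprow(b, ci$rows))
}

nn_res_block <- function(x, W1, b1, W2, b2, n, L, kernel, slope, skip) {
  h <- nn_lrelu(nn_conv1d(x, W1, b1, n, L, kernel), slope)
  h <- nn_lrelu(nn_conv1d(h, W2, b2, n, L, kernel), slope)
  nn_add(x, nn_smul(h, skip))
}

# generator forward: z (B x noise_dim) node -> list(out = (B*L, V) simplex
# rows, logits node). gumbel_u: uniform draws (B*L x V) or NULL for plain
# softmax output.
gen_forward <- function(gen, z, gumbel_u = NULL) {
  cfg <- gen$config
  p <- gen$par_nodes
  B <- nrow(z$value)
  L <- cfg$seq_len
  d <- cfg$d
  # fc output columns ordered position-fastest so the reshape to the
  # batch-fastest (B*L, d) conv layout is a plain dim change
  h <- nn_add(nn_matmul(z, p$fc_W), nn_reprow(p$fc_b, B))
  x <- nn_reshape(h, B * L, d)
  for (i in seq_len(cfg$n_res_blocks)) {
    x <- nn_res_block(x, p[[paste0("res", i, "_W1")]],
                      p[[paste0("res", i, "_b1")]],
                      p[[paste0("res", i, "_W2")]],
                      p[[paste0("res", i, "_b2")]],
                      B, L, cfg$kernel, cfg$lrelu_slope, cfg$skip_scale)
  }
  logits <- nn_add(nn_matmul(x, p$out_W), nn_reprow(p$out_b, B * L))
  if (!is.null(gumbel_u)) {
    gnoise <- -log(-log(pmax(gumbel_u, 1e-12)))
    logits <- nn_add(logits, nn_const(gnoise))
  }
  out <- nn_softmax_rows(nn_smul(logits, 1 / cfg$tau))
  if (isTRUE(cfg$straight_through)) {
    # hard one-hot forward (the argmax of the gumbel-softmax is an exact
    # categorical sample), soft gradient through the underlying softmax
    soft <- out$value
    hard <- matrix(0, nrow(soft), ncol(soft))
    hard[cbind(seq_len(nrow(soft)), max.col(soft, ties.method = "first"))] <- 1
    out <- nn_add(out, nn_const(hard - soft))
  }
  list(out = out, logits = logits, B = B)
}

# discriminator forward: x (B*L, V) node -> list(score (B,1) node,
# lengths (B,K) node, coupling value matrix, pooled residual features)
disc_forward <- function(disc, x, B) {
  cfg <- disc$config
  p <- disc$par_nodes
  L <- cfg$seq_len
  d <- cfg$d
  ker <- cfg$kernel
  h <- nn_lrelu(nn_conv1d(x, p$in_W, p$in_b, B, L, ker), cfg$lrelu_slope)
  for (i in seq_len(cfg$n_res_blocks)) {
    h <- nn_res_block(h, p[[paste0("res", i, "_W1")]],
                      p[[paste0("res", i, "_b1")]],
                      p[[paste0("res", i, "_W2")]],
                      p[[paste0("res", i, "_b2")]],
                      B, L, ker, cfg$lrelu_slope, cfg$skip_scale)
  }
  # capsule conv sub-layer: strided conv to primary_dim channels; each
  # retained position is one primary capsule of dimension primary_dim
  pc <- nn_conv1d(h, p$caps_W, p$caps_b, B, L, ker, cfg$caps_stride)
  J <- disc$n_caps
  K <- cfg$out_caps
  od <- cfg$out_dim
  prim <- nn_squash_rows(pc)                  # (B*J, pd), rows b-fastest
  # votes: per input capsule j an affine map pd -> K*od
  vote_blocks <- vector("list", J)
  for (j in seq_len(J)) {
    rows_j <- (j - 1L) * B + seq_len(B)
    pj <- nn_gather_rows(prim, rows_j)
    bj <- if (cfg$bias_mode == "per_pair") {
      p[[paste0("vote_b", j)]]
    } else {
      p$vote_b_shared
    }
    vote_blocks[[j]] <- nn_add(nn_matmul(pj, p[[paste0("vote_W", j)]]),
                               nn_reprow(bj, B))
  }
  votes <- nn_vstack(vote_blocks)             # (B*J, K*od), rows b-fastest
  rt <- route_tape(votes, B, J, K, od, cfg$routing_iters)
  score <- nn_add(nn_matmul(rt$lengths, p$head_W),
                  nn_reprow(p$head_b, B))
  list(score = score, lengths = rt$lengths, coupling = rt$coupling,
       primary = prim, residual = h)
}

# vectorized dynamic routing on the tape. votes: (B*J, K*od) node, rows
# batch-fastest (row = b + (j-1)*B), columns dim-fastest within capsule
# (col = (k-1)*od + t). Returns lengths (B, K) node and the final coupling
# value matrix (B*J, K).
route_tape <- function(votes, B, J, K, od, iterations) {
  batch_of_row <- rep(seq_len(B), times = J)
  col_caps <- rep(seq_len(K), each = od)
  b_log <- nn_const(matrix(0, B * J, K))
  v2 <- NULL
  cc <- NULL
  for (it in seq_len(iterations)) {
    cc <- nn_softmax_rows(b_log)
    cexp <- nn_gather_cols(cc, col_caps)                 # (B*J, K*od)
    w <- nn_mul(votes, cexp)
    s <- nn_scatter_rows(w, batch_of_row, B)             # (B, K*od)
    # regroup to one row per (b, k): (B, K*od) -> (K*B, od)
    s2 <- nn_t(nn_reshape(nn_t(s), od, K * B))           # rows k-fastest
    v2 <- nn_squash_rows(s2)                             # (K*B, od)
    if (it < iterations) {
      vflat <- nn_t(nn_reshape(nn_t(v2), K * od, B))     # (B, K*od)
      vexp <- nn_gather_rows(vflat, batch_of_row)        # (B*J, K*od)
      agree <- nn_scatter_cols(nn_mul(votes, vexp), col_caps, K)
      b_log <- nn_add(b_log, agree)
    }
  }
  len2 <- nn_pow(nn_sadd(nn_rowsum(nn_mul(v2, v2)), 1e-16), 0.5) # (K*B, 1)
  lengths <- nn_t(nn_reshape(len2, K, B))                # (B, K)
  list(lengths = lengths, coupling = cc$value, v = v2$value)
}

## ---- losses ---------------------------------------------------------------

#' Wasserstein critic loss
#'
#' `mean(scores_fake) - mean(scores_real)`: the negation of the critic's
#' objective, so that minimizing it maximizes the score gap between real
#' and generated batches.
#'
#' @param scores_real,scores_fake equal-length numeric score vectors.
#' @return Scalar loss.
#' @export
critic_loss <- function(scores_real, scores_fake) {
  if (!length(scores_real) || !length(scores_fake)) {
    stop("critic_loss: empty score vector")
  }
  if (length(scores_real) != length(scores_fake)) {
    stop("critic_loss: score vectors differ in length")
  }
  mean(scores_fake) - mean(scores_real)
}

#' Wasserstein generator loss
#'
#' `-mean(scores_fake)`: minimized when the critic scores generated
#' sequences highly.
#'
#' @param scores_fake numeric score vector for generated sequences.
#' @return Scalar loss.
#' @export
generator_loss <- function(scores_fake) {
  if (!length(scores_fake)) stop("generator_loss: empty score vector")
  -mean(scores_fake)
}

## ---- gradient penalty -----------------------------------------------------

#' Linear critic (for penalty identities and tests)
#'
#' A fixed critic `D(x) = sum(w * x)` over the flattened `(L, V)` input.
#' With `normalize = TRUE` the weight tensor is scaled to unit L2 norm, so
#' the input-gradient norm is exactly 1 everywhere and the gradient penalty
#' vanishes.
#'
#' @param w numeric array/matrix of shape `(L, V)`.
#' @param normalize scale `w` to unit norm (default `TRUE`).
#' @return A `linear_critic` object usable with [gradient_penalty()].
#' @export
linear_critic <- function(w, normalize = TRUE) {
  w <- as.matrix(w)
  if (normalize) w <- w / sqrt(sum(w^2))
  structure(list(w = w), class = "linear_critic")
}

#' Constant critic (for penalty identities and tests)
#'
#' `D(x) = c` for every input; its input gradient is zero, so the gradient
#' penalty equals `lambda` exactly.
#'
#' @param value the constant score.
#' @return A `constant_critic` object usable with [gradient_penalty()].
#' @export
constant_critic <- function(value = 0) {
  structure(list(value = value), class = "constant_critic")
}

# dispatch a critic forward pass on the tape: x node is (B*L, V)
critic_score_node <- function(critic, x, B) {
  if (inherits(critic, "gocapgan_discriminator")) {
    if (is.null(critic$par_nodes)) critic <- with_par_nodes(critic, leaf = FALSE)
    return(disc_forward(critic, x, B)$score)
  }
  if (inherits(critic, "linear_critic")) {
    L <- nrow(critic$w)
    wmat <- matrix(0, B * L, ncol(critic$w))
    for (l in seq_len(L)) wmat[(l - 1L) * B + seq_len(B), ] <-
        matrix(critic$w[l, ], B, ncol(critic$w), byrow = TRUE)
    per_row <- nn_rowsum(nn_mul(x, nn_const(wmat)))      # (B*L, 1)
    return(nn_scatter_rows(per_row, rep(seq_len(B), L), B))
  }
  if (inherits(critic, "constant_critic")) {
    # constant head on top of a zero multiple of x keeps x in the graph
    per_row <- nn_rowsum(nn_smul(x, 0))
    zs <- nn_scatter_rows(per_row, rep(seq_len(B), nrow(x$value) %/% B), B)
    return(nn_sadd(zs, critic$value))
  }
  if (is.function(critic)) return(critic(x, B))
  stop("unsupported critic object of class ", paste(class(critic), collapse = "/"))
}

# attach parameter nodes (leaf = trainable, const = frozen) to a model
with_par_nodes <- function(model, leaf = TRUE) {
  mk <- if (leaf) nn_leaf else nn_const
  model$par_nodes <- lapply(model$params, mk)
  model
}

# gradient-penalty node: lambda * mean((|grad_x D(x_tilde)| - 1)^2).
# x_tilde is a leaf; the input gradient is obtained by backprop and the
# penalty stays differentiable w.r.t. the critic parameters.
gp_node <- function(critic, xt, B, lambda) {
  score <- critic_score_node(critic, xt, B)
  total <- nn_sum(score)
  gx <- nn_grad(total, list(xt))[[1]]
  L <- nrow(xt$value) %/% B
  per_row <- nn_rowsum(nn_mul(gx, gx))                   # (B*L, 1)
  per_sample <- nn_scatter_rows(per_row, rep(seq_len(B), L), B)
  norms <- nn_pow(nn_sadd(per_sample, 1e-16), 0.5)
  nn_smul(nn_mean(nn_pow(nn_sadd(norms, -1), 2)), lambda)
}

#' Gradient penalty at interpolated inputs
#'
#' Draws one epsilon ~ Uniform(0,1) per batch element, forms the
#' interpolate `x_tilde = eps * real + (1 - eps) * fake`, and returns
#' `lambda * mean((|grad_x D(x_tilde)|_2 - 1)^2)` (the soft Lipschitz
#' penalty). Always nonnegative; exactly 0 for a unit-norm linear critic
#' and exactly `lambda` for a constant critic.
#'
#' @param critic a discriminator from [build_discriminator()], a
#'   [linear_critic()] / [constant_critic()], or a function
#'   `(x_node, B) -> score_node`.
#' @param real,fake `encoded_batch` arrays of identical shape `(B, L, V)`.
#' @param lambda penalty weight (>= 0).
#' @param eps optional numeric vector of per-sample interpolation weights
#'   (drawn from the current RNG when `NULL`).
#' @return Scalar penalty value.
#' @export
gradient_penalty <- function(critic, real, fake, lambda = 10, eps = NULL) {
  if (lambda < 0) stop("gradient_penalty: lambda must be >= 0")
  stopifnot(identical(dim(real), dim(fake)))
  if (lambda == 0) return(0)
  B <- dim(real)[1]
  if (is.null(eps)) eps <- stats::runif(B)
  xt_val <- batch_to_mat(interp_batches(real, fake, eps))
  xt <- nn_leaf(xt_val)
  nn_value(gp_node(critic, xt, B, lambda))[1, 1]
}

interp_batches <- function(real, fake, eps) {
  e <- array(rep(eps, times = prod(dim(real)[-1])), dim = dim(real))
  e * real + (1 - e) * fake
}

## ---- optimizer ------------------------------------------------------------

rmsprop_state <- function(params) {
  lapply(params, function(p) array(0, dim = dim(p)))
}

rmsprop_update <- function(params, grads, state, lr, alpha, eps) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]] <- alpha * state[[nm]] + (1 - alpha) * g * g
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

## ---- training loop --------------------------------------------------------

#' Train the sequence WGAN
#'
#' Alternates `n_critic` critic updates (Wasserstein critic loss plus
#' gradient penalty, or weight clipping when `lipschitz = "clip"`) with one
#' generator update per cycle; one epoch is `floor(N / batch_size)` cycles
#' over shuffled data (drop-last), and the cycle's real minibatch is shared
#' by its critic updates (fresh generator noise every update). Both
#' networks use RMSprop. Fully reproducible given `config$seed`; training
#' aborts on a non-finite loss with a reference to the last checkpoint.
#'
#' @param gen,disc networks from [build_generator()] /
#'   [build_discriminator()].
#' @param data an `encoded_batch` array `(N, L, V)` of real sequences.
#' @param config the [gan_config()] (must match the networks).
#' @param checkpoint_dir directory for per-epoch checkpoints and the JSON
#'   manifest; `NULL` disables checkpointing.
#' @param verbose print per-epoch progress.
#' @return A `train_state`: list with the trained `gen` and `disc`, loss
#'   histories (`critic_loss`, `gen_loss`, `gp`), `steps`, `checkpoints`
#'   and `seed`.
#' @export
train_gan <- function(gen, disc, data, config = gen$config,
                      checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "gan_config"))
  N <- dim(data)[1]
  B <- config$batch_size
  n_batches <- N %/% B
  if (config$epochs > 0 && n_batches < 1) {
    stop("train_gan: need at least one full batch of data (N = ", N,
         ", batch_size = ", B, ")")
  }
  set.seed(config$seed)
  hist_c <- numeric(0)
  hist_g <- numeric(0)
  hist_gp <- numeric(0)
  checkpoints <- character(0)
  opt_d <- rmsprop_state(disc$params)
  opt_g <- rmsprop_state(gen$params)
  save_ckpt <- function(tag) {
    if (is.null(checkpoint_dir)) return(invisible(NULL))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(checkpoint_dir, paste0("ckpt_", tag, ".rds"))
    saveRDS(list(gen_params = gen$params, disc_params = disc$params,
                 config = unclass(config)), path)
    manifest <- list(tag = tag, step = length(hist_c) + length(hist_g),
                     critic_loss = if (length(hist_c)) utils::tail(hist_c, 1) else NA,
                     gen_loss = if (length(hist_g)) utils::tail(hist_g, 1) else NA,
                     seed = config$seed, config = unclass(config))
    jsonlite::write_json(manifest,
                         file.path(checkpoint_dir, paste0("ckpt_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    checkpoints <<- c(checkpoints, path)
    invisible(path)
  }
  save_ckpt("init")
  L <- config$seq_len
  V <- config$vocab_size
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(N)
    t0 <- Sys.time()
    for (bi in seq_len(n_batches)) {
      rows <- perm[(bi - 1L) * B + seq_len(B)]
      real <- data[rows, , , drop = FALSE]
      real_mat <- batch_to_mat(real)
      ## ---- critic updates
      for (ci in seq_len(config$n_critic)) {
        z <- matrix(stats::rnorm(B * config$noise_dim), B)
        gu <- matrix(stats::runif(B * L * V), B * L, V)
        gen_n <- with_par_nodes(gen, leaf = FALSE)
        fake_mat <- nn_value(gen_forward(gen_n, nn_const(z), gu)$out)
        disc_n <- with_par_nodes(disc, leaf = TRUE)
        sr <- disc_forward(disc_n, nn_const(real_mat), B)$score
        sf <- disc_forward(disc_n, nn_const(fake_mat), B)$score
        loss_n <- nn_sub(nn_mean(sf), nn_mean(sr))
        gp_val <- 0
        if (config$lipschitz == "gp" && config$lambda > 0) {
          eps <- stats::runif(B)
          fake_arr <- mat_to_batch(fake_mat, B, L)
          xt <- nn_leaf(batch_to_mat(interp_batches(real, fake_arr, eps)))
          gp_n <- gp_node(disc_n, xt, B, config$lambda)
          gp_val <- nn_value(gp_n)[1, 1]
          loss_n <- nn_add(loss_n, gp_n)
        }
        c_loss <- nn_value(loss_n)[1, 1] - gp_val
        if (!is.finite(c_loss) || !is.finite(gp_val)) {
          stop("train_gan: non-finite critic loss at epoch ", epoch,
               "; last checkpoint: ",
               if (length(checkpoints)) utils::tail(checkpoints, 1) else "<none>")
        }
        grads <- lapply(nn_grad(loss_n, disc_n$par_nodes), nn_value)
        names(grads) <- names(disc$params)
        upd <- rmsprop_update(disc$params, grads, opt_d,
                              config$lr, config$rms_alpha, config$rms_eps)
        disc$params <- upd$params
        opt_d <- upd$state
        if (config$lipschitz == "clip") {
          disc$params <- lapply(disc$params, function(pm) {
            pmin(pmax(pm, -config$clip_value), config$clip_value)
          })
        }
        hist_c <- c(hist_c, c_loss)
        hist_gp <- c(hist_gp, gp_val)
      }
      ## ---- generator update
      z <- matrix(stats::rnorm(B * config$noise_dim), B)
      gu <- matrix(stats::runif(B * L * V), B * L, V)
      gen_n <- with_par_nodes(gen, leaf = TRUE)
      fake_n <- gen_forward(gen_n, nn_const(z), gu)$out
      disc_n <- with_par_nodes(disc, leaf = FALSE)
      sf <- disc_forward(disc_n, fake_n, B)$score
      loss_n <- nn_smul(nn_mean(sf), -1)
      g_loss <- nn_value(loss_n)[1, 1]
      if (!is.finite(g_loss)) {
        stop("train_gan: non-finite generator loss at epoch ", epoch,
             "; last checkpoint: ",
             if (length(checkpoints)) utils::tail(checkpoints, 1) else "<none>")
      }
      grads <- lapply(nn_grad(loss_n, gen_n$par_nodes), nn_value)
      names(grads) <- names(gen$params)
      upd <- rmsprop_update(gen$params, grads, opt_g,
                            config$lr, config$rms_alpha, config$rms_eps)
      gen$params <- upd$params
      opt_g <- upd$state
      hist_g <- c(hist_g, g_loss)
    }
    save_ckpt(paste0("epoch", epoch))
    if (verbose) {
      message(sprintf("epoch %d/%d: critic %.4f, gen %.4f, gp %.4f (%.1fs)",
                      epoch, config$epochs, utils::tail(hist_c, 1),
                      utils::tail(hist_g, 1), utils::tail(hist_gp, 1),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  structure(list(gen = gen, disc = disc, critic_loss = hist_c,
                 gen_loss = hist_g, gp = hist_gp,
                 steps = length(hist_c) + length(hist_g),
                 checkpoints = checkpoints, seed = config$seed),
            class = "train_state")
}

#' Generate sequences from the generator
#'
#' Draws latent vectors and Gumbel noise from `seed`, runs the generator,
#' and decodes the simplex outputs to amino-acid strings (argmax per
#' position, padding terminates the sequence).
#'
#' @param gen a generator (trained or untrained).
#' @param n number of sequences (>= 1).
#' @param seed RNG seed.
#' @param vocab the [aa_vocabulary()] matching the generator's
#'   `vocab_size`.
#' @return Character vector of `n` sequences (length <= `seq_len`).
#' @export
generate_sequences <- function(gen, n, seed = 1L, vocab = aa_vocabulary()) {
  if (n < 1) stop("generate_sequences: n must be >= 1")
  cfg <- gen$config
  stopifnot(vocab$size == cfg$vocab_size)
  set.seed(seed)
  z <- matrix(stats::rnorm(n * cfg$noise_dim), n)
  gu <- matrix(stats::runif(n * cfg$seq_len * cfg$vocab_size),
               n * cfg$seq_len, cfg$vocab_size)
  gen_n <- with_par_nodes(gen, leaf = FALSE)
  out <- nn_value(gen_forward(gen_n, nn_const(z), gu)$out)
  decode_batch(mat_to_batch(out, n, cfg$seq_len), vocab)
}
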