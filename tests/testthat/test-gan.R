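test_that("generator parameter count equals the analytic layer-by-layer sum", {
  cfg <- tiny_config()
  gen <- build_generator(cfg)
  L <- cfg$seq_len; d <- cfg$d; V <- cfg$vocab_size; ker <- cfg$kernel
  analytic <- (cfg$noise_dim * L * d + L * d) +              # input linear
    cfg$n_res_blocks * 2 * (ker * d * d + d) +               # residual convs
    (d * V + V)                                              # output proj
  expect_equal(gen$n_params, analytic)
  expect_equal(count_params(gen$params), analytic)
})

test_that("discriminator parameter count equals the analytic sum", {
  cfg <- tiny_config()
  disc <- build_discriminator(cfg)
  L <- cfg$seq_len; d <- cfg$d; V <- cfg$vocab_size; ker <- cfg$kernel
  J <- L %/% cfg$caps_stride; pd <- cfg$primary_dim
  K <- cfg$out_caps; od <- cfg$out_dim
  analytic <- (ker * V * d + d) +                            # input conv
    cfg$n_res_blocks * 2 * (ker * d * d + d) +               # residual convs
    (ker * d * pd + pd) +                                    # capsule conv
    J * (pd * K * od) + J * (K * od) +                       # votes W + B
    (K + 1)                                                  # linear head
  expect_equal(disc$n_params, analytic)
  expect_equal(disc$n_caps, J)
  expect_equal(disc$n_features, K)
})

test_that("two builds with the same seed give identical initial weights", {
  cfg <- tiny_config()
  g1 <- build_generator(cfg)
  g2 <- build_generator(cfg)
  expect_identical(g1$params, g2$params)
  d1 <- build_discriminator(cfg)
  d2 <- build_discriminator(cfg)
  expect_identical(d1$params, d2$params)
})

test_that("untileable capsule reshape is a construction error", {
  expect_error(gan_config(seq_len = 15L, caps_stride = 4L),
               "not divisible")
})

test_that("generator forward emits simplex rows of the right shape", {
  cfg <- tiny_config()
  gen <- ns$with_par_nodes(build_generator(cfg), leaf = FALSE)
  set.seed(2)
  z <- matrix(rnorm(4 * cfg$noise_dim), 4)
  gu <- matrix(runif(4 * cfg$seq_len * cfg$vocab_size),
               4 * cfg$seq_len, cfg$vocab_size)
  out <- ns$nn_value(ns$gen_forward(gen, ns$nn_const(z), gu)$out)
  expect_equal(dim(out), c(4L * cfg$seq_len, cfg$vocab_size))
  expect_equal(rowSums(out), rep(1, 4 * cfg$seq_len), tolerance = 1e-9)
  expect_true(all(out >= 0))
})

test_that("discriminator forward gives finite scalars and unit coupling rows", {
  cfg <- tiny_config()
  disc <- ns$with_par_nodes(build_discriminator(cfg), leaf = FALSE)
  enc <- encode_batch(random_seqs(4L, c(8L, 16L), seed = 3L),
                      seq_len = cfg$seq_len)
  fwd <- ns$disc_forward(disc, ns$nn_const(ns$batch_to_mat(enc)), 4L)
  sc <- ns$nn_value(fwd$score)
  expect_equal(dim(sc), c(4L, 1L))
  expect_true(all(is.finite(sc)))
  expect_equal(rowSums(fwd$coupling),
               rep(1, nrow(fwd$coupling)), tolerance = 1e-9)
  lens <- ns$nn_value(fwd$lengths)
  expect_true(all(lens >= 0 & lens < 1))
})

test_that("critic and generator losses match their arithmetic oracles", {
  expect_equal(critic_loss(c(1, 1), c(0, 0)), -1)
  expect_equal(critic_loss(c(2, 4), c(2, 4)), 0)
  expect_equal(generator_loss(c(0, 0)), 0)
  expect_equal(generator_loss(c(2, 4)), -3)
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(critic_loss(a, b), mean(b) - mean(a), tolerance = 1e-12)
    expect_equal(generator_loss(b), -mean(b), tolerance = 1e-12)
    # antisymmetry
    expect_equal(critic_loss(a, b), -critic_loss(b, a), tolerance = 1e-12)
  }
  expect_error(critic_loss(numeric(0), numeric(0)), "empty")
  expect_error(generator_loss(numeric(0)), "empty")
})

test_that("gradient penalty identities hold", {
  set.seed(6)
  real <- encode_batch(random_seqs(3L, c(4L, 8L), seed = 1L), seq_len = 8L)
  fake <- encode_batch(random_seqs(3L, c(4L, 8L), seed = 2L), seq_len = 8L)
  # lambda = 0: penalty 0 regardless
  expect_equal(gradient_penalty(constant_critic(2), real, fake, 0), 0)
  # unit-norm linear critic: gradient norm exactly 1 -> penalty 0
  lc <- linear_critic(matrix(rnorm(8 * 21), 8, 21))
  expect_equal(gradient_penalty(lc, real, fake, 10), 0, tolerance = 1e-12)
  # constant critic: zero gradient -> penalty lambda
  expect_equal(gradient_penalty(constant_critic(5), real, fake, 10), 10,
               tolerance = 1e-6)
  expect_equal(gradient_penalty(constant_critic(5), real, fake, 2.5), 2.5,
               tolerance = 1e-6)
  expect_error(gradient_penalty(lc, real, fake, -1), "lambda")
  # nonnegative for a real discriminator
  cfg <- tiny_config()
  disc <- build_discriminator(cfg)
  r2 <- encode_batch(random_seqs(4L, c(8L, 16L), seed = 4L),
                     seq_len = cfg$seq_len)
  f2 <- encode_batch(random_seqs(4L, c(8L, 16L), seed = 5L),
                     seq_len = cfg$seq_len)
  expect_gte(gradient_penalty(disc, r2, f2, 10), 0)
})

test_that("zero-epoch training returns empty histories and an init checkpoint", {
  cfg <- tiny_config(epochs = 0L)
  gen <- build_generator(cfg)
  disc <- build_discriminator(cfg)
  enc <- encode_batch(random_seqs(8L, c(8L, 16L), seed = 6L),
                      seq_len = cfg$seq_len)
  dir <- withr::local_tempdir()
  st <- train_gan(gen, disc, enc, cfg, checkpoint_dir = dir)
  expect_length(st$critic_loss, 0L)
  expect_length(st$gen_loss, 0L)
  expect_equal(st$steps, 0L)
  expect_true(file.exists(file.path(dir, "ckpt_init.rds")))
  expect_true(file.exists(file.path(dir, "ckpt_init.json")))
})

test_that("training histories have the exact step-count arithmetic", {
  cfg <- tiny_config(epochs = 2L, n_critic = 2L, batch_size = 4L)
  gen <- build_generator(cfg)
  disc <- build_discriminator(cfg)
  # N = 11 -> 2 full batches per epoch, drop-last
  enc <- encode_batch(random_seqs(11L, c(8L, 16L), seed = 7L),
                      seq_len = cfg$seq_len)
  st <- train_gan(gen, disc, enc, cfg)
  n_cycles <- 2L * (11L %/% 4L)
  expect_length(st$critic_loss, n_cycles * cfg$n_critic)
  expect_length(st$gp, n_cycles * cfg$n_critic)
  expect_length(st$gen_loss, n_cycles)
  expect_equal(st$steps, n_cycles * (cfg$n_critic + 1L))
  expect_true(all(is.finite(st$critic_loss)))
  expect_true(all(st$gp >= 0))
})

test_that("training is bit-reproducible under a fixed seed", {
  cfg <- tiny_config(epochs = 1L, n_critic = 2L)
  enc <- encode_batch(random_seqs(8L, c(8L, 16L), seed = 8L),
                      seq_len = cfg$seq_len)
  st1 <- train_gan(build_generator(cfg), build_discriminator(cfg), enc, cfg)
  st2 <- train_gan(build_generator(cfg), build_discriminator(cfg), enc, cfg)
  expect_identical(st1$critic_loss, st2$critic_loss)
  expect_identical(st1$gen_loss, st2$gen_loss)
  expect_identical(st1$gen$params, st2$gen$params)
  expect_identical(st1$disc$params, st2$disc$params)
})

test_that("weight clipping mode bounds the critic weights", {
  cfg <- tiny_config(epochs = 1L, n_critic = 2L, lipschitz = "clip",
                     clip_value = 0.01)
  enc <- encode_batch(random_seqs(8L, c(8L, 16L), seed = 9L),
                      seq_len = cfg$seq_len)
  st <- train_gan(build_generator(cfg), build_discriminator(cfg), enc, cfg)
  expect_true(all(vapply(st$disc$params,
                         function(p) all(abs(p) <= 0.01 + 1e-12),
                         logical(1))))
})

test_that("generated sequences are deterministic, in-alphabet, length-bounded", {
  cfg <- tiny_config()
  gen <- build_generator(cfg)
  s1 <- generate_sequences(gen, 1L, seed = 42L)
  s2 <- generate_sequences(gen, 1L, seed = 42L)
  expect_identical(s1, s2)
  many <- generate_sequences(gen, 32L, seed = 7L)
  expect_length(many, 32L)
  expect_true(all(nchar(many) <= cfg$seq_len))
  chars <- unique(strsplit(paste0(many, collapse = ""), "")[[1]])
  expect_true(all(chars %in% aa_vocabulary()$symbols[-1]))
  expect_error(generate_sequences(gen, 0L), "n must be")
})

test_that("critic-only updates on separated point masses reduce critic loss", {
  # lambda = 0, unconstrained critic, constant real/fake batches: the
  # Wasserstein gap must widen (loss decrease) over the first updates
  cfg <- tiny_config(epochs = 1L, n_critic = 10L, lambda = 0, lr = 5e-3,
                     batch_size = 4L)
  gen <- build_generator(cfg)
  disc <- build_discriminator(cfg)
  enc <- encode_batch(rep("MMMMMMMMMMMMMMMM", 4L), seq_len = cfg$seq_len)
  st <- train_gan(gen, disc, enc, cfg)
  first <- st$critic_loss[1]
  last <- utils::tail(st$critic_loss, 1)
  expect_lt(last, first)
})

test_that("a generator trained on a single-letter corpus shifts its output", {
  # frequency-shift check: training on all-A sequences must raise the
  # fraction of 'A' emitted relative to the untrained generator
  cfg <- gan_config(batch_size = 4L, seq_len = 12L, noise_dim = 6L,
                    epochs = 30L, d = 6L, kernel = 3L, n_critic = 5L,
                    caps_stride = 3L, primary_dim = 6L, out_caps = 2L,
                    out_dim = 3L, lr = 2e-3, seed = 11L)
  gen0 <- build_generator(cfg)
  disc0 <- build_discriminator(cfg)
  enc <- encode_batch(rep(strrep("A", 12L), 8L), seq_len = cfg$seq_len)
  st <- train_gan(gen0, disc0, enc, cfg)
  freq_a <- function(g) {
    seqs <- generate_sequences(g, 200L, seed = 123L)
    chars <- strsplit(paste0(seqs, collapse = ""), "")[[1]]
    if (!length(chars)) return(0)
    mean(chars == "A")
  }
  expect_gt(freq_a(st$gen), freq_a(gen0) + 0.1)
})
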