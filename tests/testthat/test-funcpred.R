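test_that("extract_features is deterministic with the declared dimension", {
  cfg <- tiny_config()
  disc <- build_discriminator(cfg)
  enc <- encode_batch(rep(random_seqs(3L, c(8L, 16L), seed = 1L), 2L),
                      seq_len = cfg$seq_len)
  feats <- extract_features(disc, enc)
  expect_equal(ncol(feats), disc$n_features)
  expect_equal(nrow(feats), 6L)
  expect_true(all(is.finite(feats)))
  # the same protein encoded twice yields identical rows
  expect_equal(unname(feats[1, ]), unname(feats[4, ]), tolerance = 1e-12)
  # chunked and unchunked extraction agree (row order preserved)
  expect_equal(extract_features(disc, enc, chunk_size = 2L), feats,
               tolerance = 1e-12)
  # residual tap has width d
  expect_equal(ncol(extract_features(disc, enc, tap = "residual")), cfg$d)
  # shape mismatch names the expected geometry
  bad <- encode_batch("MKV", seq_len = 8L)
  expect_error(extract_features(disc, bad), "expects")
})

test_that("features of two motif classes beat chance for a held-out probe", {
  design <- synthetic_design(n_classes = 2L, n_proteins = 50L,
                             len_range = c(24L, 32L),
                             labels_per_protein = c(1L, 1L),
                             motif_len = 6L, seed = 31L)
  corpus <- generate_corpus(design)
  cfg <- tiny_config(seq_len = 32L, d = 12L, seed = 31L)
  disc <- build_discriminator(cfg)
  enc <- encode_batch(corpus$records, seq_len = 32L)
  feats <- extract_features(disc, enc)
  y <- as.integer(vapply(corpus$manifest$proteins,
                         function(p) p$classes[[1]], "") ==
                    design$classes[1])
  set.seed(31)
  idx <- sample(50L)
  tr <- idx[1:35]
  te <- idx[36:50]
  fit <- stats::glm.fit(cbind(1, scale(feats[tr, ])), y[tr],
                        family = stats::binomial())
  scores <- cbind(1, scale(feats[te, ])) %*% fit$coefficients
  # held-out AUC above 0.5 (better than chance)
  auc <- mean(outer(scores[y[te] == 1], scores[y[te] == 0], ">") +
                0.5 * outer(scores[y[te] == 1], scores[y[te] == 0], "=="))
  expect_gt(auc, 0.5)
})

test_that("select_classes applies threshold, ordering and truncation", {
  tab <- annotation_table(data.frame(
    accession = c(paste0("P", 1:20), paste0("Q", 1:16), paste0("R", 1:15)),
    go_id = c(rep("GO:0000002", 20), rep("GO:0000001", 16),
              rep("GO:0000003", 15))))
  expect_warning(select_classes(tab, min_count = 16L, top_k = 25L),
                 "only 2 classes eligible")
  sel <- suppressWarnings(select_classes(tab, min_count = 16L, top_k = 25L))
  expect_equal(as.character(sel), c("GO:0000002", "GO:0000001"))
  expect_equal(attr(sel, "n_eligible"), 2L)
  # all below threshold -> empty
  sel0 <- select_classes(tab, min_count = 100L, top_k = 5L)
  expect_length(sel0, 0L)
  expect_equal(attr(sel0, "n_eligible"), 0L)
  # ties broken lexicographically by GO id
  tab2 <- annotation_table(data.frame(
    accession = rep(paste0("P", 1:16), 2L),
    go_id = rep(c("GO:0000009", "GO:0000001"), each = 16)))
  sel2 <- suppressWarnings(select_classes(tab2, 16L, 25L))
  expect_equal(as.character(sel2), c("GO:0000001", "GO:0000009"))
})

test_that("select_classes matches the generator manifest on designed counts", {
  counts <- c(60L, 55L, 50L, 45L, 40L, 35L, 30L, 25L, 20L, 16L,
              15L, 12L, 8L, 4L, 2L)
  design <- synthetic_design(n_classes = 15L, n_proteins = 80L,
                             len_range = c(40L, 60L), motif_len = 4L,
                             class_counts = counts, seed = 13L)
  corpus <- generate_corpus(design)
  tab <- annotation_table(corpus$annotations)
  sel <- select_classes(tab, min_count = 16L, top_k = 10L)
  manifest_counts <- unlist(corpus$manifest$per_class_counts)
  expect_equal(unname(manifest_counts), counts)   # designed counts realized
  eligible <- names(manifest_counts)[manifest_counts >= 16L]
  expected <- eligible[order(-manifest_counts[eligible], eligible)]
  expect_equal(as.character(sel), expected)
  expect_equal(attr(sel, "n_eligible"), 10L)
  # order-invariance: shuffling annotation rows changes nothing
  shuffled <- corpus$annotations[sample(nrow(corpus$annotations)), ]
  expect_equal(as.character(select_classes(annotation_table(shuffled),
                                           16L, 10L)),
               as.character(sel))
})

test_that("build_label_matrix plants exactly the annotated pairs", {
  corpus <- tiny_corpus()
  tab <- annotation_table(corpus$annotations)
  classes <- sort(unique(corpus$annotations$go_id))
  Y <- build_label_matrix(corpus$records, tab, classes)
  expect_equal(dim(Y), c(length(corpus$records), length(classes)))
  expect_true(all(Y %in% c(0L, 1L)))
  # column sums equal per-class counts restricted to the record set
  expect_equal(unname(colSums(Y)), unname(tab$counts[classes]))
  # matrix equals the manifest's planted labels
  for (i in seq_along(corpus$manifest$proteins)) {
    planted <- unlist(corpus$manifest$proteins[[i]]$classes)
    expect_equal(which(Y[i, ] == 1), match(sort(planted), classes),
                 ignore_attr = TRUE)
  }
  # a protein with no selected-class annotation gets an all-zero row
  Y2 <- build_label_matrix(corpus$records, tab, "GO:9999999")
  expect_true(all(Y2 == 0L))
})

test_that("bce_loss matches hand values and a scalar-loop oracle", {
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0, 1), c(1 - 1e-9, 1e-9, 1 - 1e-9)), 1e-5)
  set.seed(55)
  for (i in 1:10) {
    y <- matrix(rbinom(12, 1, 0.5), 3)
    h <- matrix(runif(12, 0.01, 0.99), 3)
    loop <- 0
    for (a in 1:3) for (b in 1:4) {
      loop <- loop - (y[a, b] * log(h[a, b]) +
                        (1 - y[a, b]) * log(1 - h[a, b]))
    }
    expect_equal(bce_loss(y, h), loop / 12, tolerance = 1e-9)
    # symmetry under joint permutation of label slots
    p <- sample(12)
    expect_equal(bce_loss(as.numeric(y)[p], as.numeric(h)[p]),
                 bce_loss(y, h), tolerance = 1e-12)
  }
})

test_that("classifier training reduces loss on separable data, reproducibly", {
  set.seed(70)
  X <- rbind(matrix(rnorm(40 * 3, mean = 2), 40),
             matrix(rnorm(40 * 3, mean = -2), 40))
  Y <- cbind(rep(c(1, 0), each = 40), rep(c(0, 1), each = 40))
  fit <- train_classifier(X, Y, epochs = 40L, lr = 0.01, seed = 3L)
  expect_lt(utils::tail(fit$loss, 1), 0.5 * fit$loss[1])
  fit2 <- train_classifier(X, Y, epochs = 40L, lr = 0.01, seed = 3L)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$b, fit2$b)
})

test_that("constant features drive predictions toward label prevalence", {
  # with uninformative input the optimum of the cross-entropy is the
  # per-class base rate
  X <- matrix(1, 200, 2)
  Y <- cbind(rbinom(200, 1, 0.8) * 0 + c(rep(1, 160), rep(0, 40)),
             c(rep(1, 40), rep(0, 160)))
  fit <- train_classifier(X, Y, epochs = 600L, lr = 0.05, seed = 2L)
  H <- predict_proba(fit, X)
  expect_equal(mean(H[, 1]), 0.8, tolerance = 0.05)
  expect_equal(mean(H[, 2]), 0.2, tolerance = 0.05)
})

test_that("all-zero labels warn but train", {
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(0, 10, 2)
  expect_warning(train_classifier(X, Y, epochs = 2L), "all-zero")
})

test_that("predict_labels applies the >= threshold rule monotonically", {
  model <- structure(list(W = matrix(0, 2, 2), b = matrix(0, 1, 2),
                          classes = c("a", "b"), threshold = 0.5),
                     class = "classifier_model")
  X <- matrix(rnorm(10), 5, 2)
  # zero weights: all probabilities exactly 0.5 -> all ones at 0.5
  expect_true(all(predict_labels(model, X, threshold = 0.5) == 1L))
  # probabilities all below threshold -> all-zero matrix
  model$b <- matrix(log(0.49 / 0.51), 1, 2)   # sigmoid = 0.49
  expect_true(all(predict_labels(model, X, threshold = 0.5) == 0L))
  # lowering the threshold never decreases an entry
  set.seed(20)
  model$W <- matrix(rnorm(4), 2, 2)
  for (i in 1:10) {
    t1 <- runif(1, 0.05, 0.9)
    t2 <- runif(1, 0.05, 0.9)
    lo <- min(t1, t2); hi <- max(t1, t2)
    Xr <- matrix(rnorm(10), 5, 2)
    expect_true(all(predict_labels(model, Xr, lo) >=
                      predict_labels(model, Xr, hi)))
  }
})
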