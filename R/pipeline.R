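#' Resolved pipeline configuration
#'
#' Merges the GAN hyperparameters, classifier settings, evaluation settings
#' and synthetic-design settings into one serializable list. Values can be
#' loaded from a YAML file and overridden by arguments. The default is the
#' desk-scale study configuration: the default synthetic design (8 classes,
#' 320 proteins, planted motifs), a small WGAN (width 16, 2 epochs), the
#' published classifier settings (binary cross-entropy, Adam, 40 epochs)
#' and 3-fold / 5-repeat evaluation.
#'
#' @param config_file optional YAML file of settings (same names as the
#'   arguments of [gan_config()], [synthetic_design()], plus
#'   `min_count`, `top_k`, `cls_epochs`, `cls_lr`, `cls_batch_size`,
#'   `threshold`, `k`, `repeats`, `mode`).
#' @param ... overrides applied on top of the file values.
#' @param seed master seed; every stage derives its RNG stream from it.
#' @return A `run_config` list with elements `gan` (a [gan_config()]),
#'   `design` (a [synthetic_design()]), `select`, `classifier`, `evaluate`
#'   and `seed`.
#' @export
run_config <- function(config_file = NULL, ..., seed = 1L) {
  vals <- list()
  if (!is.null(config_file)) {
    vals <- yaml::read_yaml(config_file)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  take <- function(names_wanted) vals[intersect(names(vals), names_wanted)]
  gan_args <- take(names(formals(gan_config)))
  # desk-scale GAN defaults unless overridden: width 16, 2 epochs, a
  # learning rate scaled up from the full-scale schedule (about 200x fewer
  # updates), and a wider capsule stage for transfer-feature capacity
  if (is.null(gan_args$d)) gan_args$d <- 16L
  if (is.null(gan_args$epochs)) gan_args$epochs <- 2L
  if (is.null(gan_args$lr)) gan_args$lr <- 1e-3
  if (is.null(gan_args$primary_dim)) gan_args$primary_dim <- 32L
  if (is.null(gan_args$out_caps)) gan_args$out_caps <- 32L
  if (is.null(gan_args$out_dim)) gan_args$out_dim <- 8L
  gan_args$seed <- as.integer(seed)
  design_args <- take(setdiff(names(formals(synthetic_design)), "seed"))
  design_args$seed <- as.integer(seed) + 101L
  num_or <- function(nm, default) if (is.null(vals[[nm]])) default else vals[[nm]]
  cfg <- list(
    gan = do.call(gan_config, gan_args),
    design = do.call(synthetic_design, design_args),
    select = list(min_count = as.integer(num_or("min_count", 16L)),
                  top_k = as.integer(num_or("top_k", 25L))),
    classifier = list(epochs = as.integer(num_or("cls_epochs", 40L)),
                      lr = num_or("cls_lr", 1e-3),
                      batch_size = as.integer(num_or("cls_batch_size", 32L)),
                      threshold = num_or("threshold", 0.5)),
    evaluate = list(k = as.integer(num_or("k", 3L)),
                    repeats = as.integer(num_or("repeats", 5L)),
                    mode = num_or("mode", "micro")),
    fasta = vals$fasta, annotations = vals$annotations,
    max_len = as.integer(num_or("max_len", 2000L)),
    seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(run_dir, stage, t0, verbose) {
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  line <- sprintf("[%s] %-18s done in %.1fs", format(Sys.time(), "%H:%M:%S"),
                  stage, elapsed)
  cat(line, "\n", file = file.path(run_dir, "pipeline.log"), append = TRUE)
  if (verbose) message(line)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, GAN training, feature extraction, class
#' selection, classifier training and repeated k-fold evaluation, writing
#' each stage's artifacts plus the resolved configuration and seed into
#' `out_dir`. With `resume = TRUE`, stages whose artifacts already exist in
#' `out_dir` are loaded instead of recomputed, so a run is resumable from
#' any completed stage (and `skip_gan = TRUE` with a `checkpoint` reuses a
#' previously trained critic).
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param resume load existing stage artifacts instead of recomputing.
#' @param skip_gan skip GAN training and load `checkpoint` instead.
#' @param checkpoint path to a checkpoint `.rds` (from [train_gan()]) used
#'   when `skip_gan = TRUE`.
#' @param verbose log stage timing to the console as well as the log file.
#' @return Invisibly, a list with `metrics` (the [evaluate_cv()] report),
#'   `control_metrics` (same evaluation under label-permuted annotations),
#'   `classes`, `features`, `labels`, `train_state` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, skip_gan = FALSE,
                         checkpoint = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(serialize_config(config), file.path(out_dir, "config.yaml"))
  writeLines(as.character(config$seed), file.path(out_dir, "seed.txt"))
  gcfg <- config$gan

  ## stage 1: simulate or ingest
  t0 <- Sys.time()
  fasta_path <- file.path(out_dir, "corpus.fasta")
  ann_path <- file.path(out_dir, "annotations.tsv")
  if (!is.null(config$fasta)) {
    file.copy(config$fasta, fasta_path, overwrite = !resume)
    file.copy(config$annotations, ann_path, overwrite = !resume)
  } else if (!(resume && file.exists(fasta_path) && file.exists(ann_path))) {
    generate_corpus(config$design, out_dir = out_dir,
                    seed = config$design$seed)
  }
  records <- read_fasta(fasta_path)
  records <- filter_by_length(records, config$max_len)
  table <- read_annotations(ann_path,
                            known_accessions = vapply(records, `[[`,
                                                      character(1), "accession"))
  encoded <- encode_batch(records, seq_len = gcfg$seq_len,
                          vocab = aa_vocabulary())
  stage_log(out_dir, "simulate/ingest", t0, verbose)

  ## stage 2: GAN training
  t0 <- Sys.time()
  ckpt_dir <- file.path(out_dir, "checkpoints")
  final_ckpt <- file.path(ckpt_dir, paste0("ckpt_epoch", gcfg$epochs, ".rds"))
  train_state <- NULL
  if (skip_gan || (resume && file.exists(final_ckpt))) {
    ckpt_path <- if (skip_gan && !is.null(checkpoint)) checkpoint else final_ckpt
    ck <- readRDS(ckpt_path)
    gen <- build_generator(gcfg)
    disc <- build_discriminator(gcfg)
    gen$params <- ck$gen_params
    disc$params <- ck$disc_params
  } else {
    gen <- build_generator(gcfg)
    disc <- build_discriminator(gcfg)
    train_state <- train_gan(gen, disc, encoded, gcfg,
                             checkpoint_dir = ckpt_dir, verbose = verbose)
    gen <- train_state$gen
    disc <- train_state$disc
    utils::write.table(
      data.frame(step = seq_along(train_state$critic_loss),
                 critic_loss = train_state$critic_loss,
                 gp = train_state$gp),
      file.path(out_dir, "critic_losses.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage_log(out_dir, "train-gan", t0, verbose)

  ## stage 3: feature extraction
  t0 <- Sys.time()
  feat_path <- file.path(out_dir, "features.tsv")
  if (resume && file.exists(feat_path)) {
    fm <- utils::read.table(feat_path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE)
    features <- as.matrix(fm)
  } else {
    features <- extract_features(disc, encoded)
    utils::write.table(
      data.frame(accession = rownames(features), features,
                 check.names = FALSE),
      feat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage_log(out_dir, "extract-features", t0, verbose)

  ## stage 4: class selection + label matrix
  t0 <- Sys.time()
  classes <- select_classes(table, min_count = config$select$min_count,
                            top_k = config$select$top_k)
  if (!length(classes)) {
    stop("run_pipeline: no class meets the eligibility threshold (min_count = ",
         config$select$min_count, ")")
  }
  writeLines(classes, file.path(out_dir, "classes.txt"))
  labels <- build_label_matrix(records, table, classes)
  utils::write.table(
    data.frame(accession = rownames(labels), labels, check.names = FALSE),
    file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  stage_log(out_dir, "select-classes", t0, verbose)

  ## stage 5: final classifier on all data
  t0 <- Sys.time()
  feat_z <- features
  sdv <- apply(feat_z, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  feat_z <- sweep(sweep(feat_z, 2, colMeans(feat_z)), 2, sdv, "/")
  fit <- train_classifier(feat_z,
                          labels, epochs = config$classifier$epochs,
                          lr = config$classifier$lr,
                          batch_size = config$classifier$batch_size,
                          seed = config$seed + 7L)
  saveRDS(fit, file.path(out_dir, "classifier.rds"))
  stage_log(out_dir, "train-classifier", t0, verbose)

  ## stage 6: repeated k-fold evaluation + permuted control
  t0 <- Sys.time()
  plan <- plan_repeated_kfold(nrow(features), k = config$evaluate$k,
                              repeats = config$evaluate$repeats,
                              seed = config$seed + 11L)
  metrics <- evaluate_cv(features, labels, plan,
                         epochs = config$classifier$epochs,
                         lr = config$classifier$lr,
                         batch_size = config$classifier$batch_size,
                         threshold = config$classifier$threshold,
                         mode = config$evaluate$mode,
                         seed = config$seed + 13L)
  perm_ann <- permute_labels(table, seed = config$seed + 17L)
  perm_labels <- build_label_matrix(records, annotation_table(perm_ann),
                                    classes)
  control <- evaluate_cv(features, perm_labels, plan,
                         epochs = config$classifier$epochs,
                         lr = config$classifier$lr,
                         batch_size = config$classifier$batch_size,
                         threshold = config$classifier$threshold,
                         mode = config$evaluate$mode,
                         seed = config$seed + 13L)
  utils::write.table(metrics$per_fold, file.path(out_dir, "per_fold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    metrics = as.list(metrics$mean), metrics_sd = as.list(metrics$sd),
    control = as.list(control$mean),
    n_proteins = nrow(features), n_classes = length(classes),
    n_eligible = attr(classes, "n_eligible"),
    averaging = metrics$mode, seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_log(out_dir, "evaluate", t0, verbose)

  invisible(list(metrics = metrics, control_metrics = control,
                 classes = classes, features = features, labels = labels,
                 train_state = train_state, out_dir = out_dir))
}

serialize_config <- function(config) {
  list(gan = unclass(config$gan),
       design = unclass(config$design)[c("n_classes", "n_proteins",
                                         "len_range", "labels_per_protein",
                                         "motif_len", "background", "seed")],
       select = config$select, classifier = config$classifier,
       evaluate = config$evaluate, max_len = config$max_len,
       seed = config$seed)
}
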