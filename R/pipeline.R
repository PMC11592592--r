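# End-to-end orchestration: simulate -> encode -> train -> tree ->
# describe -> evaluate, driven by a single YAML/list configuration, with
# a reproducibility manifest (seeds, stage hashes) and a qualitative
# latent-space visualization helper.

#' Default pipeline configuration
#'
#' @param out_dir output directory
#' @param seed master seed (stages derive their own fixed offsets)
#' @param n number of synthetic records
#' @param dataset `"planted"` (rule-labeled, see
#'   [generate_planted_rule_dataset()]) or `"mixture"` (mechanism
#'   negatives, see [generate_dataset()])
#' @param train_fraction fraction of records used for training
#' @param epochs training epochs
#' @param scale model scale preset
#' @return Nested configuration list.
#' @export
pipeline_config <- function(out_dir = "mirdiva_run", seed = 1L, n = 1000L,
                            dataset = c("planted", "mixture"),
                            train_fraction = 0.75, epochs = 60L,
                            scale = "desk") {
  list(out_dir = out_dir, seed = as.integer(seed), n = as.integer(n),
       dataset = match.arg(dataset), train_fraction = train_fraction,
       model = list(scale = scale, epochs = as.integer(epochs)),
       tree = list(max_depth = 5L, min_samples = 10L, min_acc = 0.8))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipeline_config()
  utils::modifyList(base, config)
}

#' Run the full description-generation pipeline
#'
#' Simulates a labeled hairpin dataset, trains the DIVA model, fits the
#' latent decision tree on the training split, extracts the pre-miRNA
#' descriptions and evaluates reconstruction and classification on the
#' held-out split. All artifacts (dataset files, loss history, tree JSON,
#' DOT graph, report and manifest) are written under `out_dir`.
#'
#' @param config a [pipeline_config()] list or path to a YAML file
#' @param verbose print stage progress
#' @return The manifest list, invisibly; the report is at
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_files <- character(0)
  t_start <- proc.time()[["elapsed"]]

  say("[simulate] %d %s records (seed %d)", cfg$n, cfg$dataset, cfg$seed)
  records <- if (cfg$dataset == "planted") {
    generate_planted_rule_dataset(cfg$n, seed = cfg$seed)
  } else {
    generate_dataset(generator_config(n_samples = cfg$n, seed = cfg$seed))
  }
  set.seed(cfg$seed)
  records <- records[sample.int(length(records))]  # classes mixed before splitting
  data_dir <- file.path(cfg$out_dir, "data")
  write_dataset(records, data_dir)
  stage_files <- c(stage_files, file.path(data_dir, "structures.dbn"),
                   file.path(data_dir, "labels.tsv"))

  say("[encode] images and bond vectors")
  tensors <- dataset_tensors(records)
  utils::write.table(tensors$M, file.path(cfg$out_dir, "bond_vectors.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  stage_files <- c(stage_files, file.path(cfg$out_dir, "bond_vectors.tsv"))

  say("[train] %s-scale DIVA, %d epochs", cfg$model$scale, cfg$model$epochs)
  mcfg <- diva_config(scale = cfg$model$scale, epochs = cfg$model$epochs)
  model <- diva_train(tensors, mcfg, seed = cfg$seed + 1L, verbose = verbose)
  utils::write.csv(model$history, file.path(cfg$out_dir, "loss_history.csv"),
                   row.names = FALSE)
  stage_files <- c(stage_files, file.path(cfg$out_dir, "loss_history.csv"))

  say("[tree] latent decision tree on z_m")
  n_tr <- round(cfg$n * cfg$train_fraction)
  tr <- seq_len(n_tr); te <- setdiff(seq_len(cfg$n), tr)
  z <- diva_encode(model, tensors)
  ft <- feature_table(records)
  th <- default_thresholds(ft[tr, ])
  fb <- binarize_features(ft, th)
  tcfg <- tree_config(max_depth = cfg$tree$max_depth,
                      min_samples = cfg$tree$min_samples,
                      min_acc = cfg$tree$min_acc, seed = cfg$seed + 2L)
  tree <- fit_latent_tree(z$z_m[tr, , drop = FALSE], tensors$y[tr],
                          fb[tr, , drop = FALSE], tcfg)
  tree_to_json(tree, file.path(cfg$out_dir, "tree.json"))
  writeLines(tree_to_dot(tree), file.path(cfg$out_dir, "tree.dot"))

  say("[describe] positive-path descriptions")
  desc <- format_descriptions(extract_descriptions(tree))
  writeLines(desc, file.path(cfg$out_dir, "descriptions.txt"))
  stage_files <- c(stage_files, file.path(cfg$out_dir, "tree.json"),
                   file.path(cfg$out_dir, "descriptions.txt"))

  say("[evaluate] held-out reconstruction and classification")
  pred <- predict(tree, z$z_m[te, , drop = FALSE])
  cls <- classification_report(tensors$y[te], pred)
  n_eval <- min(50L, length(te))
  dec <- diva_decode(model, z$z_m[te[1:n_eval], , drop = FALSE],
                     z$z_y[te[1:n_eval], , drop = FALSE],
                     z$z_x[te[1:n_eval], , drop = FALSE])
  imgs <- sample_decoded(dec, temperature = 0)
  rec <- do.call(rbind, lapply(seq_len(n_eval), function(i) {
    truth <- encode_image(records[[te[i]]])$image
    tryCatch(reconstruction_report(truth, imgs[[i]]),
             error = function(e) data.frame(mae = mae(truth, imgs[[i]]),
                                            nucleotide_accuracy = NA,
                                            mae_length = NA))
  }))
  report <- list(
    reconstruction = as.list(colMeans(rec, na.rm = TRUE)),
    classification = as.list(cls),
    descriptions = desc,
    description_families = description_families(tree)
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirdiva")),
    config = cfg,
    seeds = list(simulate = cfg$seed, train = cfg$seed + 1L,
                 tree = cfg$seed + 2L),
    elapsed_sec = proc.time()[["elapsed"]] - t_start,
    hashes = as.list(tools::md5sum(stage_files))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] report at %s", file.path(cfg$out_dir, "report.json"))
  invisible(manifest)
}

# ---- latent visualization --------------------------------------------------

#' Exact t-SNE embedding (small n)
#'
#' A compact O(n^2) implementation of t-distributed stochastic neighbor
#' embedding with the usual perplexity calibration, early exaggeration
#' and momentum schedule. Intended for qualitative latent-space figures
#' at desk scale (hundreds to a few thousand points).
#'
#' @param X numeric matrix (rows = points)
#' @param perplexity target perplexity
#' @param n_iter gradient iterations
#' @param seed RNG seed (embeddings are deterministic given the seed)
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, n_iter = 300L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sp
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100L) 4 else 1
    mom <- if (iter <= 20L) 0.5 else 0.8
    sqY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sqY, sqY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8))
    G <- mom * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Visualize a latent space in 2-D
#'
#' Qualitative helper: embeds one latent space with PCA or t-SNE and
#' colors the points by class or by a structural feature.
#'
#' @param model a trained `diva_model`
#' @param records list of `structured_rna` (or tensors)
#' @param space `"z_m"`, `"z_y"` or `"z_x"`
#' @param color_by `"label"` or a feature column name (needs `records`
#'   as a record list)
#' @param method `"pca"` or `"tsne"`
#' @param seed seed for t-SNE initialization
#' @return A ggplot object.
#' @export
plot_latent <- function(model, records, space = c("z_m", "z_y", "z_x"),
                        color_by = "label", method = c("pca", "tsne"),
                        seed = 1L) {
  space <- match.arg(space)
  method <- match.arg(method)
  z <- diva_encode(model, records)[[space]]
  emb <- if (method == "pca") {
    stats::prcomp(z, rank. = 2L)$x[, 1:2, drop = FALSE]
  } else {
    tsne_embed(z, seed = seed)
  }
  col <- if (color_by == "label") {
    if (is.list(records) && is.null(records$X)) {
      factor(dataset_labels(records), levels = c(0, 1),
             labels = c("other RNA", "pre-miRNA"))
    } else {
      factor(records$y, levels = c(0, 1), labels = c("other RNA", "pre-miRNA"))
    }
  } else {
    feature_table(records)[[color_by]]
  }
  df <- data.frame(d1 = emb[, 1L], d2 = emb[, 2L], color = col)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d1, y = .data$d2,
                                   color = .data$color)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(title = sprintf("%s (%s)", space, method),
                  x = "dim 1", y = "dim 2", color = color_by) +
    ggplot2::theme_minimal()
}

#' Save a trained model
#'
#' Single-file archive (RDS) with the configuration embedded; restore
#' with [diva_load()].
#'
#' @param model a `diva_model`; @param path output file
#' @export
diva_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname diva_save
#' @return The restored `diva_model`.
#' @export
diva_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "diva_model"))
  model
}
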