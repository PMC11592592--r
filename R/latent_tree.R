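# Decision tree over the shape latent space z_m. Each candidate split
# trains a linear SVM to predict one binary structural feature from the
# latent coordinates; among candidates whose resubstitution accuracy
# clears min_acc, the split with the highest information gain on the
# class label wins (ties broken by lowest feature-column index). The
# fitted separator is stored in the node, so prediction for a new point
# only needs its latent code. Paths ending in pre-miRNA-majority leaves
# are the learned structural description.

#' Configuration for the latent decision tree
#'
#' @param max_depth maximum tree depth (root = depth 0)
#' @param min_samples smallest node that may still be split
#' @param min_acc resubstitution accuracy a feature SVM must exceed for
#'   its split to be eligible
#' @param svm_cost soft-margin cost of the linear SVMs
#' @param seed RNG seed (SVM fitting is deterministic; the seed fixes any
#'   downstream sampling)
#' @return A validated list of class `tree_config`.
#' @export
tree_config <- function(max_depth = 5L, min_samples = 10L, min_acc = 0.8,
                        svm_cost = 1, seed = 1L) {
  cfg <- list(max_depth = as.integer(max_depth),
              min_samples = as.integer(min_samples),
              min_acc = min_acc, svm_cost = svm_cost, seed = as.integer(seed))
  stopifnot(cfg$max_depth >= 1L, cfg$min_samples >= 2L,
            cfg$min_acc > 0, cfg$min_acc <= 1, cfg$svm_cost > 0)
  class(cfg) <- "tree_config"
  cfg
}

#' Shannon entropy (bits) of a binary label vector
#' @param y 0/1 vector
#' @return Entropy in bits.
#' @keywords internal
#' @export
entropy_bits <- function(y) {
  if (!length(y)) return(0)
  p <- mean(y == 1)
  if (p == 0 || p == 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Information gain of a binary partition
#'
#' Parent entropy minus the size-weighted mean of the child entropies,
#' base 2.
#'
#' @param y_parent,y_left,y_right 0/1 label vectors; the children must
#'   partition the parent
#' @return Gain in bits (>= 0 for a true partition).
#' @examples
#' information_gain(c(1, 1, 0, 0), c(1, 1), c(0, 0))  # 1 bit
#' @export
information_gain <- function(y_parent, y_left, y_right) {
  n <- length(y_parent)
  if (!n) stop("empty parent node")
  stopifnot(length(y_left) + length(y_right) == n)
  entropy_bits(y_parent) -
    (length(y_left) / n) * entropy_bits(y_left) -
    (length(y_right) / n) * entropy_bits(y_right)
}

#' Fit a linear SVM predicting one binary feature from the latent space
#'
#' @param z latent matrix (rows = samples)
#' @param feature binary (0/1) vector, the SVM target
#' @param config a [tree_config()]
#' @return `NULL` when the feature is single-valued at this node (skip
#'   signal); otherwise a list with the linear separator (`w`, `b`, with
#'   prediction `1` iff `z %*% w + b > 0`), its resubstitution `accuracy`
#'   and the in-sample `pred`ictions.
#' @export
fit_split_svm <- function(z, feature, config = tree_config()) {
  if (length(unique(feature)) < 2L) return(NULL)
  fit <- tryCatch(
    e1071::svm(x = z, y = factor(feature, levels = c(0, 1)),
               kernel = "linear", cost = config$svm_cost, scale = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients decision values towards its internally-first class;
  # calibrate the stored separator so positive values mean feature == 1
  dec <- as.numeric(z %*% w + b)
  pred_raw <- as.integer(dec > 0)
  pred_svm <- as.integer(as.character(stats::predict(fit, z)))
  if (mean(pred_raw == pred_svm) < 0.5) {
    w <- -w; b <- -b
    pred_raw <- 1L - pred_raw
  }
  list(w = w, b = b, accuracy = mean(pred_svm == feature), pred = pred_svm)
}

#' Grow a (sub)tree with SVM-in-latent-space splits
#'
#' For every binary feature column, a linear SVM is fitted on the node's
#' latent codes; the node is partitioned by the SVM's predictions, the
#' information gain on the class label is computed, and the eligible
#' feature (SVM accuracy > `min_acc`) with the highest gain is chosen.
#' Stopping: depth limit, node smaller than `min_samples`, purity, or no
#' eligible feature with positive gain.
#'
#' @param z latent matrix; @param y 0/1 class labels
#' @param f_matrix binary feature matrix with named columns (from
#'   [binarize_features()])
#' @param depth current depth (root = 0)
#' @param config a [tree_config()]
#' @return A `tree_node` list.
#' @export
make_split <- function(z, y, f_matrix, depth = 0L, config = tree_config()) {
  node <- list(depth = depth, n = length(y),
               counts = c(neg = sum(y == 0), pos = sum(y == 1)),
               split = NULL, feature = NA_character_,
               left = NULL, right = NULL)
  class(node) <- "tree_node"
  pure <- length(unique(y)) < 2L
  if (depth >= config$max_depth || length(y) < config$min_samples || pure) {
    return(node)
  }
  best_gain <- 0
  best <- NULL
  for (j in seq_len(ncol(f_matrix))) {
    sv <- fit_split_svm(z, f_matrix[, j], config)
    if (is.null(sv) || sv$accuracy <= config$min_acc) next
    left <- sv$pred == 0L
    if (!any(left) || all(left)) next
    gain <- information_gain(y, y[left], y[!left])
    if (gain > best_gain) {  # strict: ties keep the lowest column index
      best_gain <- gain
      best <- list(j = j, sv = sv, left = left)
    }
  }
  if (is.null(best)) return(node)
  node$split <- list(w = best$sv$w, b = best$sv$b,
                     accuracy = best$sv$accuracy, gain = best_gain)
  node$feature <- colnames(f_matrix)[best$j]
  l <- best$left
  node$left <- make_split(z[l, , drop = FALSE], y[l],
                          f_matrix[l, , drop = FALSE], depth + 1L, config)
  node$right <- make_split(z[!l, , drop = FALSE], y[!l],
                           f_matrix[!l, , drop = FALSE], depth + 1L, config)
  node
}

#' Fit a latent decision tree
#'
#' @param z latent codes (typically z_m from [diva_encode()])
#' @param y binary class labels
#' @param f_matrix binarized feature matrix
#' @param config a [tree_config()]
#' @return A `latent_tree` object.
#' @export
fit_latent_tree <- function(z, y, f_matrix, config = tree_config()) {
  stopifnot(nrow(z) == length(y), nrow(f_matrix) == length(y))
  set.seed(config$seed)
  root <- make_split(as.matrix(z), y, as.matrix(f_matrix), 0L, config)
  structure(list(root = root, config = config,
                 features = colnames(f_matrix)),
            class = "latent_tree")
}

node_majority <- function(node) as.integer(node$counts["pos"] >= node$counts["neg"])

#' Predict classes (and leaf paths) for latent codes
#'
#' Each point is routed by the stored separators (left = feature
#' predicted 0, right = predicted 1) and labeled with the leaf majority.
#'
#' @param object a `latent_tree`
#' @param z latent matrix
#' @param paths also return the condition path per point
#' @param ... unused
#' @return Integer predictions, or a list with `class` and `path` when
#'   `paths = TRUE`.
#' @export
predict.latent_tree <- function(object, z, paths = FALSE, ...) {
  z <- as.matrix(z)
  route <- function(zi) {
    node <- object$root
    path <- character(0)
    while (!is.null(node$split)) {
      side <- as.integer(sum(zi * node$split$w) + node$split$b > 0)
      path <- c(path, sprintf("%s=%d", node$feature, side))
      node <- if (side == 0L) node$left else node$right
    }
    list(class = node_majority(node), path = path)
  }
  res <- lapply(seq_len(nrow(z)), function(i) route(z[i, ]))
  cls <- vapply(res, `[[`, 0L, "class")
  if (paths) list(class = cls, path = lapply(res, `[[`, "path")) else cls
}

#' Extract the learned pre-miRNA descriptions
#'
#' Every root-to-leaf path whose leaf majority is the pre-miRNA class,
#' as an ordered list of (feature, predicted side) conditions, sorted by
#' leaf support.
#'
#' @param tree a `latent_tree`
#' @return List of descriptions: `conditions` (character vector like
#'   `"pair_fraction>0.7=1"`), `support` (leaf size) and `purity`
#'   (fraction of positives in the leaf).
#' @export
extract_descriptions <- function(tree) {
  out <- list()
  walk <- function(node, conds) {
    if (is.null(node$split)) {
      if (node$n > 0L && node_majority(node) == 1L) {
        out[[length(out) + 1L]] <<- list(
          conditions = conds, support = node$n,
          purity = as.numeric(node$counts["pos"]) / node$n)
      }
      return(invisible(NULL))
    }
    walk(node$left, c(conds, sprintf("%s=0", node$feature)))
    walk(node$right, c(conds, sprintf("%s=1", node$feature)))
  }
  walk(tree$root, character(0))
  out[order(-vapply(out, `[[`, 0L, "support"))]
}

#' Render descriptions as text
#' @param descriptions result of [extract_descriptions()]
#' @return Character vector, one line per description.
#' @export
format_descriptions <- function(descriptions) {
  if (!length(descriptions)) return(character(0))
  vapply(descriptions, function(d) {
    lhs <- if (length(d$conditions)) paste(d$conditions, collapse = " AND ")
           else "(any)"
    sprintf("%s => pre-miRNA  [n=%d, purity=%.2f]", lhs, d$support, d$purity)
  }, "")
}

#' Feature families used in the positive descriptions
#' @param tree a `latent_tree`
#' @return Sorted unique base feature names on positive paths.
#' @export
description_features <- function(tree) {
  conds <- unlist(lapply(extract_descriptions(tree), `[[`, "conditions"))
  sort(unique(feature_family(sub("=[01]$", "", conds))))
}

#' Biological families of the features in the positive descriptions
#' @param tree a `latent_tree`
#' @return Sorted unique family names (see [FEATURE_FAMILIES]).
#' @export
description_families <- function(tree) {
  sort(unique(unname(FEATURE_FAMILIES[description_features(tree)])))
}

#' Serialize a tree to JSON
#'
#' Stores per node the separator coefficients, split feature, gain,
#' accuracy and class counts.
#'
#' @param tree a `latent_tree`; @param path optional output file
#' @return The JSON string, invisibly when written to `path`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    out <- list(depth = node$depth, n = node$n,
                counts = as.list(node$counts))
    if (!is.null(node$split)) {
      out$feature <- node$feature
      out$split <- node$split
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  js <- jsonlite::toJSON(strip(tree$root), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Render the tree as a DOT graph
#' @param tree a `latent_tree`
#' @return Character scalar with DOT source.
#' @export
tree_to_dot <- function(tree) {
  lines <- c("digraph latent_tree {", "  node [shape=box];")
  k <- 0L
  walk <- function(node) {
    k <<- k + 1L
    id <- k
    label <- if (is.null(node$split)) {
      sprintf("leaf n=%d (pos=%d)\\nclass=%s", node$n, node$counts["pos"],
              ifelse(node_majority(node) == 1L, "pre-miRNA", "other"))
    } else {
      sprintf("%s\\ngain=%.3f acc=%.2f", node$feature, node$split$gain,
              node$split$accuracy)
    }
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", id, label))
    if (!is.null(node$split)) {
      lid <- walk(node$left)
      rid <- walk(node$right)
      lines <<- c(lines,
                  sprintf("  n%d -> n%d [label=\"0\"];", id, lid),
                  sprintf("  n%d -> n%d [label=\"1\"];", id, rid))
    }
    id
  }
  walk(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}
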