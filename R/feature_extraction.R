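# Structural features of a stem-loop record, computed from the
# dot-bracket (and sequence, for bond strength) alone. These are the
# concepts the latent decision tree splits on.

#' Extract structural features from a record
#'
#' Definitions: the stem is the set of base-paired columns; its length is
#' the number of pairs. The pair fraction is the fraction of stem pairs
#' that are strong (Watson-Crick). The terminal loop is the unpaired run
#' enclosed by the innermost pair, counted as present when it has at
#' least 3 nt (the standard hairpin-loop minimum). Bulges are the
#' unpaired runs between consecutive stem pairs, one per arm; the
#' asymmetric-bulge statistic is the largest absolute difference between
#' the 5'-side and 3'-side run lengths across junctions.
#'
#' @param rna a `structured_rna`
#' @return One-row data frame: `id`, `has_terminal_loop`, `loop_length`,
#'   `stem_length`, `pair_fraction`, `total_length`, `n_bulges`,
#'   `max_bulge_size`, `max_asymmetric_bulge`. An unpaired (empty)
#'   structure yields an all-zero row.
#' @examples
#' extract_features(structured_rna("toy", "GGGAAACCC", "(((...)))", 1L))
#' @export
extract_features <- function(rna) {
  s <- strsplit(rna$sequence, "")[[1]]
  pairs <- parse_pairs(rna$structure)
  n <- nchar(rna$sequence)
  if (!nrow(pairs)) {
    return(data.frame(id = rna$id, has_terminal_loop = 0L, loop_length = 0L,
                      stem_length = 0L, pair_fraction = 0,
                      total_length = n, n_bulges = 0L, max_bulge_size = 0L,
                      max_asymmetric_bulge = 0L, stringsAsFactors = FALSE))
  }
  if (!is_single_stemloop(rna$structure)) {
    stop("features are defined for single stem-loops only: ", rna$id)
  }
  np <- nrow(pairs)
  strong <- vapply(seq_len(np), function(k) {
    classify_bond(s[pairs[k, 1L]], s[pairs[k, 2L]]) == "strong"
  }, TRUE)
  inner <- pairs[np, ]
  loop_len <- inner[2L] - inner[1L] - 1L
  r5 <- integer(0); r3 <- integer(0)
  if (np > 1L) {
    r5 <- pairs[-1L, 1L] - pairs[-np, 1L] - 1L
    r3 <- pairs[-np, 2L] - pairs[-1L, 2L] - 1L
  }
  runs <- c(r5, r3); runs <- runs[runs > 0L]
  asym <- abs(r5 - r3)
  data.frame(id = rna$id,
             has_terminal_loop = as.integer(loop_len >= 3L),
             loop_length = as.integer(loop_len),
             stem_length = np,
             pair_fraction = mean(strong),
             total_length = n,
             n_bulges = length(runs),
             max_bulge_size = if (length(runs)) max(runs) else 0L,
             max_asymmetric_bulge = if (length(asym)) max(asym) else 0L,
             stringsAsFactors = FALSE)
}

#' Feature table for a list of records
#'
#' @param records list of `structured_rna`
#' @return Data frame with one row per record, in input order.
#' @export
feature_table <- function(records) {
  do.call(rbind, lapply(records, extract_features))
}

CONTINUOUS_FEATURES <- c("loop_length", "stem_length", "pair_fraction",
                         "total_length", "n_bulges", "max_bulge_size",
                         "max_asymmetric_bulge")
BINARY_FEATURES <- c("has_terminal_loop")

#' Default per-feature thresholds: interior quintiles of the table
#'
#' @param table a feature table from [feature_table()]
#' @param features continuous features to threshold
#' @param probs quantile probabilities
#' @return Named list of strictly increasing threshold vectors (features
#'   that are constant in `table` are dropped).
#' @export
default_thresholds <- function(table, features = CONTINUOUS_FEATURES,
                               probs = c(0.2, 0.4, 0.6, 0.8)) {
  out <- lapply(features, function(f) {
    q <- unique(round(stats::quantile(table[[f]], probs, names = FALSE), 6))
    q[q > min(table[[f]]) & q <= max(table[[f]])]
  })
  names(out) <- features
  out[vapply(out, length, 1L) > 0L]
}

#' Binarize continuous features at given thresholds
#'
#' Each (feature, threshold) pair becomes a binary column named
#' `"feature>threshold"`; already-binary features pass through unchanged.
#' Binarization is monotone: raising a value can only turn columns on.
#'
#' @param table a feature table
#' @param thresholds named list of strictly increasing numeric vectors
#' @param binary names of pass-through binary features
#' @return Integer matrix, one named column per binary feature.
#' @examples
#' tab <- data.frame(pair_fraction = 0.8, has_terminal_loop = 1L)
#' binarize_features(tab, list(pair_fraction = c(0.5, 0.7, 0.9)))
#' @export
binarize_features <- function(table, thresholds,
                              binary = intersect(BINARY_FEATURES, names(table))) {
  stopifnot(is.list(thresholds), length(thresholds) > 0)
  cols <- list()
  for (f in names(thresholds)) {
    th <- thresholds[[f]]
    if (!length(th)) stop("empty threshold list for continuous feature '", f, "'")
    if (is.unsorted(th, strictly = TRUE)) {
      stop("thresholds for '", f, "' must be strictly increasing")
    }
    for (t in th) {
      cols[[sprintf("%s>%g", f, t)]] <- as.integer(table[[f]] > t)
    }
  }
  for (f in binary) cols[[f]] <- as.integer(table[[f]])
  do.call(cbind, cols)
}

#' Base feature name of a binarized column
#'
#' `"pair_fraction>0.7"` maps back to `"pair_fraction"`.
#'
#' @param colnames character vector of binarized column names
#' @return Character vector of feature names.
#' @export
feature_family <- function(colnames) {
  sub(">.*$", "", colnames)
}

#' Grouping of structural features into biological families
#'
#' `pair` — how Watson-Crick-bonded the stem is; `length` — how long the
#' molecule (equivalently its stem) is; `bulge` — how bulged the stem is;
#' `loop` — terminal-loop geometry. Used to compare a learned description
#' against a planted rule at the family level, mirroring the three
#' biologically validated split families (base pairs in the stem, short
#' sequences, large asymmetric bulges).
#'
#' @format Named character vector mapping feature name to family.
#' @export
FEATURE_FAMILIES <- c(pair_fraction = "pair",
                      total_length = "length", stem_length = "length",
                      max_asymmetric_bulge = "bulge", max_bulge_size = "bulge",
                      n_bulges = "bulge",
                      loop_length = "loop", has_terminal_loop = "loop")
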