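# Reconstruction metrics over bar images (mean absolute pixel error,
# per-bar nucleotide accuracy, per-bar length error) and the standard
# binary classification report.

#' Mean absolute pixel error between two images
#'
#' Averages |y - y_hat| over all pixel-channel entries of the full
#' 100 x 25 x 5 grid, background included.
#'
#' @param x,x_hat arrays of identical dimensions
#' @return Non-negative scalar.
#' @export
mae <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat))) {
    stop("image shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(x_hat), collapse = "x"))
  }
  mean(abs(x - x_hat))
}

# align the predicted bars to the true record's occupied columns; absent
# predicted bars get length 0 and NA color
aligned_bars <- function(bars_true, bars_hat) {
  if (!nrow(bars_true)) stop("no occupied bars in the reference image")
  idx <- match(bars_true$col, bars_hat$col)
  data.frame(
    col = bars_true$col,
    true_top_color = bars_true$top_color, true_top_len = bars_true$top_len,
    true_bottom_color = bars_true$bottom_color, true_bottom_len = bars_true$bottom_len,
    hat_top_color = bars_hat$top_color[idx],
    hat_top_len = ifelse(is.na(idx), 0L, bars_hat$top_len[idx]),
    hat_bottom_color = bars_hat$bottom_color[idx],
    hat_bottom_len = ifelse(is.na(idx), 0L, bars_hat$bottom_len[idx]),
    stringsAsFactors = FALSE
  )
}

# long (one row per bar) view over the occupied columns of the truth
bar_pairs <- function(bars_true, bars_hat) {
  al <- aligned_bars(bars_true, bars_hat)
  data.frame(
    color = c(al$true_top_color, al$true_bottom_color),
    color_hat = c(al$hat_top_color, al$hat_bottom_color),
    len = c(al$true_top_len, al$true_bottom_len),
    len_hat = c(al$hat_top_len, al$hat_bottom_len),
    stringsAsFactors = FALSE
  )
}

#' Per-bar color (nucleotide) accuracy
#'
#' Fraction of occupied reference bars whose predicted color matches the
#' true color; GAP counts as a fifth color class. Bars are enumerated
#' over the occupied columns of the reference, both rows, in column
#' order; the metric ignores bar lengths entirely.
#'
#' @param bars,bars_hat bar tables from [bars_from_image()] (truth and
#'   prediction)
#' @return Value in \[0, 1\].
#' @export
nucleotide_accuracy <- function(bars, bars_hat) {
  bp <- bar_pairs(bars, bars_hat)
  bp <- bp[bp$len > 0L, , drop = FALSE]
  if (!nrow(bp)) stop("alignment mismatch: no occupied bars to compare")
  mean(!is.na(bp$color_hat) & bp$color == bp$color_hat)
}

#' Mean absolute bar-length error
#'
#' Mean of |L_b - L_hat_b| over the occupied reference bars; invariant to
#' color errors.
#'
#' @inheritParams nucleotide_accuracy
#' @return Non-negative scalar (pixels).
#' @export
mae_length <- function(bars, bars_hat) {
  bp <- bar_pairs(bars, bars_hat)
  bp <- bp[bp$len > 0L, , drop = FALSE]
  if (!nrow(bp)) stop("alignment mismatch: no occupied bars to compare")
  mean(abs(bp$len - bp$len_hat))
}

#' Reconstruction report for one image pair
#'
#' @param x true image; @param x_hat reconstructed image
#' @return Data frame with `mae`, `nucleotide_accuracy`, `mae_length`.
#' @export
reconstruction_report <- function(x, x_hat) {
  bt <- bars_from_image(x)
  bh <- bars_from_image(x_hat)
  data.frame(mae = mae(x, x_hat),
             nucleotide_accuracy = nucleotide_accuracy(bt, bh),
             mae_length = mae_length(bt, bh))
}

#' Binary classification report
#'
#' Accuracy, sensitivity (recall on the pre-miRNA class, label 1) and
#' specificity (recall on label 0). When `y_true` contains a single
#' class the undefined rate is reported as `NaN` with a warning.
#'
#' @param y_true,y_pred binary (0/1) vectors of equal length
#' @return Data frame with `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' classification_report(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
classification_report <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  if (tp + fn == 0L || tn + fp == 0L) {
    warning("y_true contains a single class; sensitivity or specificity ",
            "is undefined")
  }
  data.frame(accuracy = (tp + tn) / length(y_true),
             sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NaN,
             specificity = if (tn + fp > 0L) tn / (tn + fp) else NaN)
}
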