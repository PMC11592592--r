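# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records every primitive operation as it executes; ad_backward()
# replays the tape in reverse, accumulating gradients into leaf nodes.
# All values are base-R numeric matrices (batch rows x feature columns);
# scalars are 1x1 matrices. This is the numerical core under the DIVA
# model: every loss term is assembled from these primitives so that the
# analytic gradient of the full objective is exact (and checkable against
# finite differences).

#' Create a fresh autodiff tape
#'
#' A tape is an environment collecting the nodes of one forward pass.
#' Build the computation with the `ad_*` primitives, then call
#' [ad_backward()] on the scalar loss node.
#'
#' @return An environment of class `ad_tape`.
#' @keywords internal
#' @export
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$k <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_node <- function(tape, value, parents = list(), backfn = NULL, const = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  n$const <- const
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$k]] <- n
  n
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' @keywords internal
ad_const <- function(tape, value) ad_node(tape, as_mat(value), const = TRUE)

#' Leaf node holding a trainable parameter matrix
#' @keywords internal
ad_leaf <- function(tape, value) ad_node(tape, as_mat(value), const = FALSE)

acc_grad <- function(p, g) {
  if (isTRUE(p$const)) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

#' Run reverse-mode accumulation from a scalar node
#'
#' @param tape the tape that recorded the forward pass
#' @param loss a 1x1 node on that tape
#' @keywords internal
#' @export
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  for (i in seq_len(tape$k)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$k))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backfn)) n$backfn(n)
  }
  invisible(NULL)
}

# ---- binary ops ------------------------------------------------------------

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(n) {
    acc_grad(a, tcrossprod(n$grad, b$value))
    acc_grad(b, crossprod(a$value, n$grad))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(n) {
    acc_grad(a, n$grad)
    acc_grad(b, n$grad)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(n) {
    acc_grad(a, n$grad)
    acc_grad(b, -n$grad)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(n) {
    acc_grad(a, n$grad * b$value)
    acc_grad(b, n$grad * a$value)
  })
}

# broadcast a 1 x d row vector across the rows of an n x d matrix
ad_add_row <- function(tape, a, row) {
  ad_node(tape, sweep(a$value, 2L, as.numeric(row$value), "+"), list(a, row), function(n) {
    acc_grad(a, n$grad)
    acc_grad(row, matrix(colSums(n$grad), 1L))
  })
}

ad_sub_row <- function(tape, a, row) {
  ad_node(tape, sweep(a$value, 2L, as.numeric(row$value), "-"), list(a, row), function(n) {
    acc_grad(a, n$grad)
    acc_grad(row, matrix(-colSums(n$grad), 1L))
  })
}

ad_mul_row <- function(tape, a, row) {
  ad_node(tape, sweep(a$value, 2L, as.numeric(row$value), "*"), list(a, row), function(n) {
    acc_grad(a, sweep(n$grad, 2L, as.numeric(row$value), "*"))
    acc_grad(row, matrix(colSums(n$grad * a$value), 1L))
  })
}

# broadcast an n x 1 column vector across the columns of an n x d matrix
ad_mul_col <- function(tape, a, col) {
  ad_node(tape, a$value * as.numeric(col$value), list(a, col), function(n) {
    acc_grad(a, n$grad * as.numeric(col$value))
    acc_grad(col, matrix(rowSums(n$grad * a$value), ncol = 1L))
  })
}

ad_scale <- function(tape, a, s) {  # s plain numeric scalar
  ad_node(tape, a$value * s, list(a), function(n) acc_grad(a, n$grad * s))
}

ad_shift <- function(tape, a, s) {  # s plain numeric scalar
  ad_node(tape, a$value + s, list(a), function(n) acc_grad(a, n$grad))
}

# ---- elementwise nonlinearities -------------------------------------------

ad_elu <- function(tape, a) {
  v <- a$value
  neg <- v <= 0
  out <- v
  out[neg] <- exp(v[neg]) - 1
  deriv <- array(1, dim(v))
  deriv[neg] <- out[neg] + 1
  ad_node(tape, out, list(a), function(n) {
    acc_grad(a, n$grad * deriv)
  })
}

ad_exp <- function(tape, a) {
  out <- exp(a$value)
  ad_node(tape, out, list(a), function(n) acc_grad(a, n$grad * out))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$value), list(a), function(n) acc_grad(a, n$grad / a$value))
}

ad_sigmoid <- function(tape, a) {
  out <- 1 / (1 + exp(-a$value))
  ad_node(tape, out, list(a), function(n) acc_grad(a, n$grad * out * (1 - out)))
}

ad_tanh <- function(tape, a) {
  out <- tanh(a$value)
  ad_node(tape, out, list(a), function(n) acc_grad(a, n$grad * (1 - out^2)))
}

# numerically stable log(1 + exp(x))
ad_softplus <- function(tape, a) {
  v <- a$value
  out <- pmax(v, 0) + log1p(exp(-abs(v)))
  ad_node(tape, out, list(a), function(n) {
    acc_grad(a, n$grad / (1 + exp(-v)))
  })
}

ad_square <- function(tape, a) {
  ad_node(tape, a$value^2, list(a), function(n) acc_grad(a, n$grad * 2 * a$value))
}

ad_powc <- function(tape, a, p) {
  ad_node(tape, a$value^p, list(a), function(n) {
    acc_grad(a, n$grad * p * a$value^(p - 1))
  })
}

# ---- reductions ------------------------------------------------------------

ad_sum <- function(tape, a) {
  dm <- dim(a$value)
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(n) {
    acc_grad(a, matrix(as.numeric(n$grad), dm[1L], dm[2L]))
  })
}

ad_mean <- function(tape, a) {
  dm <- dim(a$value)
  len <- prod(dm)
  ad_node(tape, matrix(mean(a$value), 1L, 1L), list(a), function(n) {
    acc_grad(a, matrix(as.numeric(n$grad) / len, dm[1L], dm[2L]))
  })
}

ad_row_sums <- function(tape, a) {  # n x d -> n x 1
  d <- ncol(a$value)
  ad_node(tape, matrix(rowSums(a$value), ncol = 1L), list(a), function(n) {
    acc_grad(a, matrix(as.numeric(n$grad), nrow(a$value), d))
  })
}

ad_col_means <- function(tape, a) {  # n x d -> 1 x d
  nr <- nrow(a$value)
  ad_node(tape, matrix(colMeans(a$value), 1L), list(a), function(n) {
    acc_grad(a, matrix(rep(as.numeric(n$grad) / nr, each = nr), nr))
  })
}

# row-wise log(sum(exp(.))): n x d -> n x 1, the normalizer of a softmax
ad_logsumexp_rows <- function(tape, a) {
  v <- a$value
  mx <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(v - mx)))
  sm <- exp(v - lse)  # row-softmax, reused in backward
  ad_node(tape, matrix(lse, ncol = 1L), list(a), function(n) {
    acc_grad(a, sm * as.numeric(n$grad))
  })
}

# ---- shape ops -------------------------------------------------------------

ad_cbind <- function(tape, ...) {
  parts <- list(...)
  widths <- vapply(parts, function(p) ncol(p$value), integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(parts, function(p) p$value)), parts, function(n) {
    for (i in seq_along(parts)) {
      acc_grad(parts[[i]], n$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_cols <- function(tape, a, idx) {
  dm <- dim(a$value)
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(n) {
    g <- matrix(0, dm[1L], dm[2L])
    g[, idx] <- g[, idx] + n$grad
    acc_grad(a, g)
  })
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(n) acc_grad(a, t(n$grad)))
}

# column-major reshape (R's native layout); gradient reshapes back
ad_reshape <- function(tape, a, nrow, ncol) {
  dm <- dim(a$value)
  ad_node(tape, matrix(a$value, nrow, ncol), list(a), function(n) {
    acc_grad(a, matrix(n$grad, dm[1L], dm[2L]))
  })
}
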