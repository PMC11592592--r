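# Neural-network building blocks on the autodiff tape: parameter trees,
# dense layers, batch normalization, MADE masks for the inverse
# autoregressive flow, Gaussian densities and the Adam optimizer.
# Parameters live as plain numeric matrices in nested named lists; each
# forward pass mirrors the tree with tape leaves so gradients can be
# collected in the same shape.

# ---- parameter trees -------------------------------------------------------

init_dense <- function(n_in, n_out, gain = 1) {
  sd <- gain * sqrt(2 / (n_in + n_out))
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = matrix(0, 1L, n_out))
}

init_dense_zero <- function(n_in, n_out) {
  list(W = matrix(0, n_in, n_out), b = matrix(0, 1L, n_out))
}

init_bn <- function(d) {
  list(gamma = matrix(1, 1L, d), beta = matrix(0, 1L, d))
}

ad_leaves <- function(tape, params) {
  if (is.matrix(params)) return(ad_leaf(tape, params))
  lapply(params, function(p) ad_leaves(tape, p))
}

ad_grads <- function(nodes) {
  if (is.environment(nodes)) {
    g <- nodes$grad
    if (is.null(g)) g <- matrix(0, nrow(nodes$value), ncol(nodes$value))
    return(g)
  }
  lapply(nodes, ad_grads)
}

param_map2 <- function(a, b, f) {
  if (is.matrix(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
  out
}

param_count <- function(params) {
  if (is.matrix(params)) return(length(params))
  sum(vapply(params, param_count, numeric(1L)))
}

# ---- layers ----------------------------------------------------------------

dense_fwd <- function(tape, p, x) {
  ad_add_row(tape, ad_mm(tape, x, p$W), p$b)
}

# Batch normalization over the batch (row) dimension. `state` is a mutable
# environment holding running mean/var; in training mode batch statistics
# are used (and flow through the gradient), in eval mode the running
# statistics enter as constants so repeated evaluation is deterministic.
bn_fwd <- function(tape, p, x, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- ad_col_means(tape, x)
    xc <- ad_sub_row(tape, x, mu)
    v <- ad_col_means(tape, ad_square(tape, xc))
    istd <- ad_powc(tape, ad_shift(tape, v, eps), -0.5)
    nb <- nrow(x$value)
    if (is.null(state$mu)) {
      state$mu <- as.numeric(mu$value)
      state$var <- as.numeric(v$value)
    } else {
      state$mu <- (1 - momentum) * state$mu + momentum * as.numeric(mu$value)
      ub <- if (nb > 1) nb / (nb - 1) else 1
      state$var <- (1 - momentum) * state$var + momentum * ub * as.numeric(v$value)
    }
    xhat <- ad_mul_row(tape, xc, istd)
  } else {
    mu <- state$mu
    if (is.null(mu)) {
      mu <- numeric(ncol(x$value))
      state$var <- rep(1, ncol(x$value))
    }
    xc <- ad_sub_row(tape, x, ad_const(tape, matrix(mu, 1L)))
    xhat <- ad_mul_row(tape, xc, ad_const(tape, matrix(1 / sqrt(state$var + eps), 1L)))
  }
  ad_add_row(tape, ad_mul_row(tape, xhat, p$gamma), p$beta)
}

# residual block: x + Dense2(elu(BN(Dense1(x)))), followed by ELU
resblock_fwd <- function(tape, p, x, bn_state, training) {
  h <- dense_fwd(tape, p$fc1, x)
  h <- bn_fwd(tape, p$bn1, h, bn_state, training)
  h <- ad_elu(tape, h)
  h <- dense_fwd(tape, p$fc2, h)
  ad_elu(tape, ad_add(tape, x, h))
}

init_resblock <- function(d, hidden) {
  list(fc1 = init_dense(d, hidden), bn1 = init_bn(hidden),
       fc2 = init_dense(hidden, d, gain = 0.5))
}

# ---- MADE masks & IAF ------------------------------------------------------

# Masks for a 2-layer masked autoencoder producing strictly autoregressive
# outputs: output unit i may depend only on inputs with degree < i under
# the given ordering.
made_masks <- function(d, hidden, reverse = FALSE) {
  deg_in <- if (reverse) rev(seq_len(d)) else seq_len(d)
  deg_h <- if (d > 1) rep(seq_len(d - 1), length.out = hidden) else rep(1L, hidden)
  m1 <- outer(deg_in, deg_h, FUN = function(i, j) as.numeric(j >= i))
  m2 <- outer(deg_h, deg_in, FUN = function(j, i) as.numeric(i > j))
  list(m1 = m1, m2 = m2)
}

init_iaf_block <- function(d, hidden, ctx_dim) {
  list(fc1 = init_dense(d, hidden), ctx = init_dense(ctx_dim, hidden),
       s = init_dense_zero(hidden, d), t = init_dense_zero(hidden, d))
}

# One affine autoregressive step z' = z * exp(s) + t with s, t masked MADE
# outputs. The s/t heads are zero-initialized, so an untrained flow is the
# identity with exactly zero log-determinant. s is smoothly bounded to
# (-2, 2) for stability; tanh(0) = 0 keeps the identity exact at init.
iaf_block_fwd <- function(tape, p, masks, z, ctx) {
  w1 <- ad_mul(tape, p$fc1$W, ad_const(tape, masks$m1))
  h <- ad_add_row(tape, ad_add(tape, ad_mm(tape, z, w1), ad_mm(tape, ctx, p$ctx$W)), p$fc1$b)
  h <- ad_elu(tape, h)
  ws <- ad_mul(tape, p$s$W, ad_const(tape, masks$m2))
  wt <- ad_mul(tape, p$t$W, ad_const(tape, masks$m2))
  s_raw <- ad_add_row(tape, ad_mm(tape, h, ws), p$s$b)
  s <- ad_scale(tape, ad_tanh(tape, ad_scale(tape, s_raw, 0.5)), 2)
  t_ <- ad_add_row(tape, ad_mm(tape, h, wt), p$t$b)
  z_new <- ad_add(tape, ad_mul(tape, z, ad_exp(tape, s)), t_)
  list(z = z_new, logdet = ad_row_sums(tape, s))
}

# ---- Gaussian densities ----------------------------------------------------

# row-wise log N(z; mu, exp(logsd)) summed over dimensions -> n x 1 node
gauss_logpdf_rows <- function(tape, z, mu, logsd) {
  diff <- ad_sub(tape, z, mu)
  q <- ad_mul(tape, diff, ad_exp(tape, ad_scale(tape, logsd, -1)))
  e <- ad_add(tape, ad_scale(tape, ad_square(tape, q), 0.5), logsd)
  e <- ad_shift(tape, ad_scale(tape, e, -1), -0.5 * log(2 * pi))
  ad_row_sums(tape, e)
}

#' Analytic KL divergence between diagonal Gaussians
#'
#' Computes \eqn{D_{KL}(N(\mu_1, \sigma_1^2) \| N(\mu_2, \sigma_2^2))}
#' summed over dimensions, the closed form used for the latent-space KL
#' terms when the posterior flow is the identity.
#'
#' @param mu1,sd1 mean and standard deviation vectors of the first Gaussian
#' @param mu2,sd2 mean and standard deviation vectors of the second Gaussian
#' @return A non-negative scalar.
#' @examples
#' kl_diag_gaussian(0, 1, 0, 1)        # 0
#' kl_diag_gaussian(c(1, 0), c(1, 2), c(0, 0), c(1, 1))
#' @export
kl_diag_gaussian <- function(mu1, sd1, mu2, sd2) {
  stopifnot(all(sd1 > 0), all(sd2 > 0))
  sum(log(sd2 / sd1) + (sd1^2 + (mu1 - mu2)^2) / (2 * sd2^2) - 0.5)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p, unused) matrix(0, nrow(p), ncol(p))
  list(m = param_map2(params, params, zero),
       v = param_map2(params, params, zero),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 5e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- param_map2(state$m, state$v, function(m, v) lr * (m * c1) / (sqrt(v * c2) + eps))
  params <- param_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
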