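# DIVA-style variational autoencoder with three latent subspaces:
# z_m (bond strength / shape), z_y (class) and z_x (remaining variance).
# Each subspace has its own encoder and an inverse autoregressive flow on
# the posterior; z_m and z_y have learned conditional priors (on the bond
# vector m and the label y respectively) while z_x keeps a standard
# normal prior. Auxiliary heads predict y from z_y, y from z_m and m from
# z_m to enforce disentanglement. The decoder factorizes each bar into a
# categorical height (over the codec's height vocabulary) and a
# categorical color, and the reconstruction likelihood is the product of
# the two per-bar categoricals.
#
# The objective is the three-KL evidence lower bound plus the
# alpha-weighted auxiliary log-likelihoods; it is a maximized quantity,
# and the implementation minimizes its negation (the sign convention
# lives only here, in diva_forward).

N_BARS <- 200L          # 100 columns x {top, bottom}
N_HEIGHTS <- 12L        # height vocabulary {0, 2, 3, ..., 12}
N_COLORS <- 5L
IMG_PIXELS <- 12500L    # 100 x 25 x 5

#' Model configuration for the DIVA VAE
#'
#' The `paper` scale mirrors the full-size architecture (latent dimension
#' 64, 8 IAF blocks of 2 MADE layers with context 32 and hidden size
#' 1080); the `desk` scale keeps every loss term and architectural role
#' but shrinks widths so the model trains in minutes on one CPU.
#'
#' @param scale `"desk"` or `"paper"` preset
#' @param latent_dim dimension of each of the three latent spaces
#' @param iaf_blocks number of IAF blocks (each of 2 MADE layers)
#' @param iaf_context dimension of the flow context vector from the encoder
#' @param iaf_hidden hidden width of the MADE layers
#' @param enc_hidden,enc_blocks encoder width and residual-block count
#' @param dec_hidden decoder width
#' @param prior_hidden,aux_hidden widths of the conditional-prior and
#'   auxiliary heads
#' @param beta_m,beta_x,beta_y KL weights
#' @param alpha_y1,alpha_y2 weights of the class heads on z_y and z_m
#' @param alpha_m weight of the bond-vector head on z_m
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param epochs maximum training epochs
#' @param tol relative improvement of the 5-epoch moving-average loss
#'   under which training is considered converged
#' @return A validated list of class `diva_config`.
#' @export
diva_config <- function(scale = c("desk", "paper"),
                        latent_dim = NULL, iaf_blocks = NULL,
                        iaf_context = NULL, iaf_hidden = NULL,
                        enc_hidden = NULL, enc_blocks = NULL,
                        dec_hidden = NULL, prior_hidden = NULL,
                        aux_hidden = NULL,
                        beta_m = 0.5, beta_x = 0.5, beta_y = 0.5,
                        alpha_y1 = 12, alpha_y2 = 12, alpha_m = 1,
                        lr = 5e-4, batch_size = 64L, epochs = 40L,
                        tol = 1e-3) {
  scale <- match.arg(scale)
  preset <- if (scale == "paper") {
    list(latent_dim = 64L, iaf_blocks = 8L, iaf_context = 32L,
         iaf_hidden = 1080L, enc_hidden = 256L, enc_blocks = 8L,
         dec_hidden = 512L, prior_hidden = 64L, aux_hidden = 64L)
  } else {
    list(latent_dim = 8L, iaf_blocks = 2L, iaf_context = 8L,
         iaf_hidden = 24L, enc_hidden = 64L, enc_blocks = 2L,
         dec_hidden = 128L, prior_hidden = 32L, aux_hidden = 24L)
  }
  pick <- function(x, d) if (is.null(x)) d else as.integer(x)
  cfg <- list(scale = scale,
              latent_dim = pick(latent_dim, preset$latent_dim),
              iaf_blocks = pick(iaf_blocks, preset$iaf_blocks),
              iaf_context = pick(iaf_context, preset$iaf_context),
              iaf_hidden = pick(iaf_hidden, preset$iaf_hidden),
              enc_hidden = pick(enc_hidden, preset$enc_hidden),
              enc_blocks = pick(enc_blocks, preset$enc_blocks),
              dec_hidden = pick(dec_hidden, preset$dec_hidden),
              prior_hidden = pick(prior_hidden, preset$prior_hidden),
              aux_hidden = pick(aux_hidden, preset$aux_hidden),
              beta_m = beta_m, beta_x = beta_x, beta_y = beta_y,
              alpha_y1 = alpha_y1, alpha_y2 = alpha_y2, alpha_m = alpha_m,
              lr = lr, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), tol = tol)
  stopifnot(cfg$latent_dim >= 1L, cfg$iaf_blocks >= 0L,
            all(c(cfg$beta_m, cfg$beta_x, cfg$beta_y,
                  cfg$alpha_y1, cfg$alpha_y2, cfg$alpha_m) >= 0),
            cfg$lr > 0, cfg$batch_size >= 1L)
  class(cfg) <- "diva_config"
  cfg
}

# ---- tensors ---------------------------------------------------------------

#' Encode a record list into training tensors
#'
#' @param records list of `structured_rna`
#' @return List with `X` (n x 12500 flattened images), `M` (n x 100 bond
#'   vectors), `y` (labels), `H` (n x 200 height-class indices), `C`
#'   (n x 200 color indices, `NA` for empty bars) and `occ` (n x 200
#'   occupancy indicators). Bar b <= 100 is the top bar of column b; bar
#'   b > 100 the bottom bar of column b - 100.
#' @export
dataset_tensors <- function(records) {
  n <- length(records)
  X <- matrix(0, n, IMG_PIXELS)
  M <- matrix(0, n, IMG_COLS)
  H <- matrix(1L, n, N_BARS)
  C <- matrix(NA_integer_, n, N_BARS)
  for (i in seq_len(n)) {
    enc <- encode_image(records[[i]])
    X[i, ] <- as.numeric(enc$image)
    M[i, ] <- enc$m
    aln <- align_arms(records[[i]])
    len <- bar_lengths(aln)
    for (k in seq_len(nrow(aln))) {
      H[i, aln$col[k]] <- match(len$top[k], BAR_HEIGHTS)
      H[i, aln$col[k] + IMG_COLS] <- match(len$bottom[k], BAR_HEIGHTS)
      if (len$top[k] > 0L) C[i, aln$col[k]] <- match(aln$top[k], COLOR_LEVELS)
      if (len$bottom[k] > 0L) {
        C[i, aln$col[k] + IMG_COLS] <- match(aln$bottom[k], COLOR_LEVELS)
      }
    }
  }
  list(X = X, M = M, y = dataset_labels(records), H = H, C = C,
       occ = (H > 1L) * 1)
}

tensor_slice <- function(tensors, idx) {
  list(X = tensors$X[idx, , drop = FALSE], M = tensors$M[idx, , drop = FALSE],
       y = tensors$y[idx], H = tensors$H[idx, , drop = FALSE],
       C = tensors$C[idx, , drop = FALSE], occ = tensors$occ[idx, , drop = FALSE])
}

one_hot <- function(idx, k) {
  out <- matrix(0, length(idx), k)
  keep <- !is.na(idx)
  out[cbind(which(keep), idx[keep])] <- 1
  out
}

# ---- initialization --------------------------------------------------------

init_encoder <- function(cfg, d_in) {
  blocks <- lapply(seq_len(cfg$enc_blocks), function(i) {
    init_resblock(cfg$enc_hidden, cfg$enc_hidden)
  })
  names(blocks) <- paste0("block", seq_len(cfg$enc_blocks))
  list(fc0 = init_dense(d_in, cfg$enc_hidden), bn0 = init_bn(cfg$enc_hidden),
       blocks = blocks,
       mu = init_dense(cfg$enc_hidden, cfg$latent_dim, gain = 0.5),
       logsd = init_dense(cfg$enc_hidden, cfg$latent_dim, gain = 0.5),
       ctx = init_dense(cfg$enc_hidden, cfg$iaf_context))
}

init_head2 <- function(d_in, hidden, d_out) {
  list(fc1 = init_dense(d_in, hidden), fc2 = init_dense(hidden, d_out))
}

#' Initialize an untrained DIVA model
#'
#' Flows are identity-initialized (zero log-determinant); all other
#' weights are Glorot draws from the current RNG stream.
#'
#' @param config a [diva_config()]
#' @return A `diva_model` list (params, flow masks, batch-norm state).
#' @export
diva_init <- function(config) {
  d <- config$latent_dim
  params <- list(
    enc_m = init_encoder(config, IMG_PIXELS),
    enc_y = init_encoder(config, IMG_PIXELS),
    enc_x = init_encoder(config, IMG_PIXELS),
    iaf_m = init_iaf_stack(config), iaf_y = init_iaf_stack(config),
    iaf_x = init_iaf_stack(config),
    # small-gain init keeps the conditional prior close to the standard
    # normal at the start and mutes input positions with little training
    # variation (bond columns beyond the stems seen in the data)
    prior_m = list(fc1 = init_dense(IMG_COLS, config$prior_hidden, gain = 0.3),
                   mu = init_dense(config$prior_hidden, d, gain = 0.5),
                   logsd = init_dense(config$prior_hidden, d, gain = 0.5)),
    prior_y = list(fc1 = init_dense(2L, config$prior_hidden),
                   mu = init_dense(config$prior_hidden, d, gain = 0.5),
                   logsd = init_dense(config$prior_hidden, d, gain = 0.5)),
    aux_y_zy = init_head2(d, config$aux_hidden, 2L),
    aux_y_zm = init_head2(d, config$aux_hidden, 2L),
    aux_m = init_head2(d, config$aux_hidden, IMG_COLS),
    dec = list(fc1 = init_dense(3L * d, config$dec_hidden),
               bn1 = init_bn(config$dec_hidden),
               height = init_dense(config$dec_hidden, N_BARS * N_HEIGHTS),
               color = init_dense(config$dec_hidden, N_BARS * N_COLORS))
  )
  masks <- lapply(seq_len(config$iaf_blocks), function(b) {
    made_masks(d, config$iaf_hidden, reverse = (b %% 2L == 0L))
  })
  bn <- new.env(parent = emptyenv())
  for (nm in c("enc_m.bn0", "enc_y.bn0", "enc_x.bn0", "dec.bn1",
               as.vector(outer(c("enc_m", "enc_y", "enc_x"),
                               paste0("block", seq_len(config$enc_blocks)),
                               paste, sep = ".")))) {
    bn[[nm]] <- new.env(parent = emptyenv())
  }
  structure(list(config = config, params = params, masks = masks, bn = bn,
                 trained = FALSE, history = NULL),
            class = "diva_model")
}

init_iaf_stack <- function(cfg) {
  out <- lapply(seq_len(cfg$iaf_blocks), function(b) {
    init_iaf_block(cfg$latent_dim, cfg$iaf_hidden, cfg$iaf_context)
  })
  names(out) <- paste0("block", seq_along(out))
  out
}

#' @export
print.diva_model <- function(x, ...) {
  cat(sprintf("<diva_model> %s scale, latent 3x%d, %s, %d parameters\n",
              x$config$scale, x$config$latent_dim,
              if (x$trained) "trained" else "untrained",
              round(param_count(x$params))))
  invisible(x)
}

# ---- forward pass ----------------------------------------------------------

encoder_fwd <- function(tape, pn, prefix, xn, model, training, eps, masks, iafn) {
  h <- dense_fwd(tape, pn$fc0, xn)
  h <- bn_fwd(tape, pn$bn0, h, model$bn[[paste0(prefix, ".bn0")]], training)
  h <- ad_elu(tape, h)
  for (b in seq_along(pn$blocks)) {
    h <- resblock_fwd(tape, pn$blocks[[b]], h,
                      model$bn[[paste0(prefix, ".block", b)]], training)
  }
  mu <- dense_fwd(tape, pn$mu, h)
  logsd <- ad_scale(tape, ad_tanh(tape, ad_scale(tape, dense_fwd(tape, pn$logsd, h), 0.5)), 2)
  ctx <- dense_fwd(tape, pn$ctx, h)
  epsn <- ad_const(tape, eps)
  z0 <- ad_add(tape, mu, ad_mul(tape, ad_exp(tape, logsd), epsn))
  logq <- gauss_logpdf_rows(tape, z0, mu, logsd)
  z <- z0
  logdet <- NULL
  for (b in seq_along(iafn)) {
    st <- iaf_block_fwd(tape, iafn[[b]], masks[[b]], z, ctx)
    z <- st$z
    logdet <- if (is.null(logdet)) st$logdet else ad_add(tape, logdet, st$logdet)
  }
  if (!is.null(logdet)) logq <- ad_sub(tape, logq, logdet)
  list(z = z, logq = logq, mu = mu, logsd = logsd, ctx = ctx,
       logdet = logdet)
}

prior_fwd <- function(tape, pn, inputn) {
  h <- ad_elu(tape, dense_fwd(tape, pn$fc1, inputn))
  list(mu = dense_fwd(tape, pn$mu, h),
       logsd = ad_scale(tape, ad_tanh(tape, ad_scale(tape, dense_fwd(tape, pn$logsd, h), 0.5)), 2))
}

head2_fwd <- function(tape, pn, z) {
  dense_fwd(tape, pn$fc2, ad_elu(tape, dense_fwd(tape, pn$fc1, z)))
}

# categorical log-likelihood: logits n x (bars*k) laid out class-major per
# bar; target index matrix n x bars (NA = skip); returns the summed
# log-likelihood divided by n (per-sample mean)
categorical_loglik <- function(tape, logits, target, k, mask = NULL) {
  n <- nrow(logits$value)
  bars <- ncol(logits$value) / k
  rows <- ad_t(tape, ad_reshape(tape, ad_t(tape, logits), k, n * bars))
  tgt <- as.integer(t(target))          # sample-major bar order
  onehot <- one_hot(tgt, k)
  picked <- ad_row_sums(tape, ad_mul(tape, rows, ad_const(tape, onehot)))
  ll <- ad_sub(tape, picked, ad_logsumexp_rows(tape, rows))
  keep <- if (is.null(mask)) !is.na(tgt) else (as.numeric(t(mask)) > 0) & !is.na(tgt)
  ll <- ad_mul_col(tape, ll, ad_const(tape, matrix(as.numeric(keep), ncol = 1L)))
  ad_scale(tape, ad_sum(tape, ll), 1 / n)
}

bernoulli_loglik <- function(tape, logits, target) {
  n <- nrow(logits$value)
  tn <- ad_const(tape, target)
  term1 <- ad_mul(tape, tn, ad_softplus(tape, ad_scale(tape, logits, -1)))
  term0 <- ad_mul(tape, ad_shift(tape, ad_scale(tape, tn, -1), 1),
                  ad_softplus(tape, logits))
  ad_scale(tape, ad_sum(tape, ad_add(tape, term1, term0)), -1 / n)
}

make_noise <- function(n, d) {
  list(m = matrix(stats::rnorm(n * d), n, d),
       y = matrix(stats::rnorm(n * d), n, d),
       x = matrix(stats::rnorm(n * d), n, d),
       zm_prior = matrix(stats::rnorm(n * d), n, d))
}

# Full forward pass; returns the loss node (minimized = -F_DIVA), the
# individual term nodes and the latent codes. `noise` fixes the
# reparameterization draws (needed for finite-difference checks and
# seed-exact evaluation).
diva_forward <- function(model, batch, training = FALSE, noise = NULL,
                         params = model$params) {
  cfg <- model$config
  n <- nrow(batch$X)
  d <- cfg$latent_dim
  if (is.null(noise)) noise <- make_noise(n, d)
  tape <- ad_tape()
  pn <- ad_leaves(tape, params)
  xn <- ad_const(tape, batch$X)
  enc <- list(
    m = encoder_fwd(tape, pn$enc_m, "enc_m", xn, model, training, noise$m,
                    model$masks, pn$iaf_m),
    y = encoder_fwd(tape, pn$enc_y, "enc_y", xn, model, training, noise$y,
                    model$masks, pn$iaf_y),
    x = encoder_fwd(tape, pn$enc_x, "enc_x", xn, model, training, noise$x,
                    model$masks, pn$iaf_x)
  )
  for (s in names(enc)) {
    if (any(!is.finite(enc[[s]]$z$value))) {
      stop("non-finite activations in encoder for z_", s)
    }
  }
  # priors
  pm <- prior_fwd(tape, pn$prior_m, ad_const(tape, batch$M))
  py <- prior_fwd(tape, pn$prior_y, ad_const(tape, one_hot(batch$y + 1L, 2L)))
  zeros <- ad_const(tape, matrix(0, n, d))
  logp_m <- gauss_logpdf_rows(tape, enc$m$z, pm$mu, pm$logsd)
  logp_y <- gauss_logpdf_rows(tape, enc$y$z, py$mu, py$logsd)
  logp_x <- gauss_logpdf_rows(tape, enc$x$z, zeros, zeros)
  kl <- list(
    m = ad_scale(tape, ad_sum(tape, ad_sub(tape, enc$m$logq, logp_m)), 1 / n),
    y = ad_scale(tape, ad_sum(tape, ad_sub(tape, enc$y$logq, logp_y)), 1 / n),
    x = ad_scale(tape, ad_sum(tape, ad_sub(tape, enc$x$logq, logp_x)), 1 / n)
  )
  for (s in names(kl)) {
    if (!is.finite(kl[[s]]$value)) stop("non-finite KL for latent space z_", s)
  }
  # decoder
  zcat <- ad_cbind(tape, enc$m$z, enc$y$z, enc$x$z)
  h <- dense_fwd(tape, pn$dec$fc1, zcat)
  h <- bn_fwd(tape, pn$dec$bn1, h, model$bn[["dec.bn1"]], training)
  h <- ad_elu(tape, h)
  hlogits <- dense_fwd(tape, pn$dec$height, h)
  clogits <- dense_fwd(tape, pn$dec$color, h)
  recon <- ad_add(tape,
                  categorical_loglik(tape, hlogits, batch$H, N_HEIGHTS),
                  categorical_loglik(tape, clogits, batch$C, N_COLORS,
                                     mask = batch$occ))
  # auxiliary heads
  yoh <- one_hot(batch$y + 1L, 2L)
  ll_y_zy <- categorical_loglik(tape, head2_fwd(tape, pn$aux_y_zy, enc$y$z),
                                matrix(batch$y + 1L, ncol = 1L), 2L)
  ll_y_zm <- categorical_loglik(tape, head2_fwd(tape, pn$aux_y_zm, enc$m$z),
                                matrix(batch$y + 1L, ncol = 1L), 2L)
  ll_m <- bernoulli_loglik(tape, head2_fwd(tape, pn$aux_m, enc$m$z), batch$M)
  elbo <- ad_sub(tape, recon,
                 ad_add(tape, ad_scale(tape, kl$m, cfg$beta_m),
                        ad_add(tape, ad_scale(tape, kl$x, cfg$beta_x),
                               ad_scale(tape, kl$y, cfg$beta_y))))
  f_diva <- ad_add(tape, elbo,
                   ad_add(tape, ad_scale(tape, ll_y_zy, cfg$alpha_y1),
                          ad_add(tape, ad_scale(tape, ll_y_zm, cfg$alpha_y2),
                                 ad_scale(tape, ll_m, cfg$alpha_m))))
  loss <- ad_scale(tape, f_diva, -1)
  list(tape = tape, pn = pn, loss = loss, f_diva = f_diva, elbo = elbo,
       terms = list(recon = as.numeric(recon$value),
                    kl_m = as.numeric(kl$m$value),
                    kl_x = as.numeric(kl$x$value),
                    kl_y = as.numeric(kl$y$value),
                    ll_y_zy = as.numeric(ll_y_zy$value),
                    ll_y_zm = as.numeric(ll_y_zm$value),
                    ll_m = as.numeric(ll_m$value)),
       enc = enc, hlogits = hlogits, clogits = clogits)
}

#' Term-wise evidence lower bound
#'
#' Computes the four summands of the objective separately: the per-sample
#' mean reconstruction log-likelihood and the three single-sample KL
#' estimates (posterior log-density minus prior log-density at the flow
#' output). Their beta-weighted combination equals the returned `elbo`
#' to machine precision.
#'
#' @param model a `diva_model`
#' @param batch tensors from [dataset_tensors()] (or a slice)
#' @param noise optional fixed reparameterization draws
#' @return List with `recon`, `kl_m`, `kl_x`, `kl_y`, `elbo`,
#'   `f_diva` (aux-augmented objective) and the auxiliary log-likelihoods.
#' @export
elbo_terms <- function(model, batch, noise = NULL) {
  fw <- diva_forward(model, batch, training = FALSE, noise = noise)
  c(fw$terms, list(elbo = as.numeric(fw$elbo$value),
                   f_diva = as.numeric(fw$f_diva$value)))
}

#' Full DIVA objective for a batch
#'
#' @inheritParams elbo_terms
#' @return Scalar value of the maximized objective F.
#' @export
diva_loss <- function(model, batch, noise = NULL) {
  as.numeric(diva_forward(model, batch, noise = noise)$f_diva$value)
}

#' Evaluate the training objective and (optionally) its exact gradient
#'
#' Instrumentation for gradient verification: with `noise` fixed the
#' minimized objective -F is a deterministic, smooth function of the
#' parameters, so its reverse-mode gradient can be compared against
#' central finite differences.
#'
#' @inheritParams elbo_terms
#' @param params parameter tree to evaluate at (defaults to the model's)
#' @param gradients also return the gradient tree
#' @param training use batch statistics in the normalization layers
#' @return List with `value` (the minimized objective, -F) and, when
#'   requested, `grads` (same nested shape as `params`).
#' @export
diva_objective <- function(model, batch, noise = NULL, params = model$params,
                           gradients = FALSE, training = TRUE) {
  fw <- diva_forward(model, batch, training = training, noise = noise,
                     params = params)
  out <- list(value = as.numeric(fw$loss$value), terms = fw$terms)
  if (gradients) {
    ad_backward(fw$tape, fw$loss)
    out$grads <- ad_grads(fw$pn)
  }
  out
}

#' Fixed reparameterization noise for a batch
#'
#' @param n batch size; @param d latent dimension
#' @return List of standard-normal matrices, one per latent space.
#' @export
diva_noise <- function(n, d) make_noise(n, d)

# ---- training --------------------------------------------------------------

#' Train a DIVA model
#'
#' Adam on minibatches; per-epoch means of every loss term are recorded.
#' Training stops at `config$epochs` or earlier when the 5-epoch moving
#' average of the loss improves by less than `config$tol` (relative). On
#' a non-finite loss the last finite parameters are kept and training
#' aborts with a warning.
#'
#' @param records list of `structured_rna`, or tensors from
#'   [dataset_tensors()]
#' @param config a [diva_config()]
#' @param seed integer seed controlling initialization, shuffling and
#'   reparameterization noise end to end
#' @param verbose print per-epoch losses
#' @return A trained `diva_model` with a `history` data frame.
#' @export
diva_train <- function(records, config = diva_config(), seed = 1L,
                       verbose = FALSE) {
  tensors <- if (is.list(records) && !is.null(records$X)) records
             else dataset_tensors(records)
  set.seed(seed)
  model <- diva_init(config)
  opt <- adam_init(model$params)
  n <- nrow(tensors$X)
  hist <- list()
  last_finite <- model$params
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep <- NULL
    diverged <- FALSE
    for (idx in splits) {
      batch <- tensor_slice(tensors, idx)
      fw <- diva_forward(model, batch, training = TRUE, params = model$params)
      lv <- as.numeric(fw$loss$value)
      if (!is.finite(lv)) {
        warning("training diverged (non-finite loss) in epoch ", epoch,
                "; keeping last finite checkpoint")
        model$params <- last_finite
        diverged <- TRUE
        break
      }
      last_finite <- model$params
      ad_backward(fw$tape, fw$loss)
      grads <- ad_grads(fw$pn)
      step <- adam_step(model$params, grads, opt, lr = config$lr)
      model$params <- step$params
      opt <- step$state
      ep <- rbind(ep, c(loss = lv, unlist(fw$terms)))
    }
    if (diverged) break
    hist[[epoch]] <- c(epoch = epoch, colMeans(ep))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.3f  recon %.3f  kl (%.3f %.3f %.3f)",
                      epoch, hist[[epoch]]["loss"], hist[[epoch]]["recon"],
                      hist[[epoch]]["kl_m"], hist[[epoch]]["kl_x"],
                      hist[[epoch]]["kl_y"]))
    }
    if (epoch >= 10L) {
      ma <- vapply(hist, `[[`, 0, "loss")
      prev <- mean(ma[(epoch - 9L):(epoch - 5L)])
      cur <- mean(ma[(epoch - 4L):epoch])
      if ((prev - cur) / abs(prev) < config$tol) break
    }
  }
  model$history <- as.data.frame(do.call(rbind, hist))
  model$trained <- TRUE
  model
}

# ---- inference -------------------------------------------------------------

#' Encode records (or images) into the three latent spaces
#'
#' Runs the encoders in evaluation mode (batch-norm running statistics).
#'
#' @param model a trained `diva_model`
#' @param records list of `structured_rna`, or tensors
#' @param sample draw the reparameterization noise (`TRUE`) or return the
#'   deterministic flow image of the posterior mean (`FALSE`)
#' @param seed RNG seed for the posterior draw
#' @return List with matrices `z_m`, `z_y`, `z_x` (rows = records).
#' @export
diva_encode <- function(model, records, sample = FALSE, seed = 1L) {
  tensors <- if (is.list(records) && !is.null(records$X)) records
             else dataset_tensors(records)
  set.seed(seed)
  n <- nrow(tensors$X)
  d <- model$config$latent_dim
  out <- list(z_m = NULL, z_y = NULL, z_x = NULL)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / 256L))) {
    batch <- tensor_slice(tensors, idx)
    noise <- make_noise(length(idx), d)
    if (!sample) {
      noise$m[] <- 0; noise$y[] <- 0; noise$x[] <- 0
    }
    fw <- diva_forward(model, batch, training = FALSE, noise = noise)
    out$z_m <- rbind(out$z_m, fw$enc$m$z$value)
    out$z_y <- rbind(out$z_y, fw$enc$y$z$value)
    out$z_x <- rbind(out$z_x, fw$enc$x$z$value)
  }
  out
}

# decoder-only forward from latent matrices; returns per-bar height and
# color probability arrays
decoder_probs <- function(model, z_m, z_y, z_x) {
  tape <- ad_tape()
  pn <- ad_leaves(tape, model$params$dec)
  zcat <- ad_const(tape, cbind(z_m, z_y, z_x))
  h <- dense_fwd(tape, pn$fc1, zcat)
  h <- bn_fwd(tape, pn$bn1, h, model$bn[["dec.bn1"]], training = FALSE)
  h <- ad_elu(tape, h)
  hl <- dense_fwd(tape, pn$height, h)$value
  cl <- dense_fwd(tape, pn$color, h)$value
  n <- nrow(hl)
  softmax3 <- function(logits, k) {
    a <- array(NA_real_, dim = c(n, N_BARS, k))
    for (i in seq_len(n)) {
      m <- matrix(logits[i, ], nrow = k)  # class-major per bar
      e <- exp(sweep(m, 2L, apply(m, 2L, max)))
      a[i, , ] <- t(sweep(e, 2L, colSums(e), "/"))
    }
    a
  }
  list(height = softmax3(hl, N_HEIGHTS), color = softmax3(cl, N_COLORS))
}

#' Decode latent codes into bar distributions and reconstructions
#'
#' @param model a trained `diva_model`
#' @param z_m,z_y,z_x latent matrices (rows aligned)
#' @return List with `height` (n x 200 x 12 probabilities over the height
#'   vocabulary), `color` (n x 200 x 5) and `expected` (n-list of
#'   expected images: per-pixel occupancy probability times color
#'   probability).
#' @export
diva_decode <- function(model, z_m, z_y, z_x) {
  pr <- decoder_probs(model, as_mat(z_m), as_mat(z_y), as_mat(z_x))
  n <- dim(pr$height)[1L]
  expected <- lapply(seq_len(n), function(i) {
    expected_image(pr$height[i, , ], pr$color[i, , ])
  })
  list(height = pr$height, color = pr$color, expected = expected)
}

#' Expected image of per-bar height and color distributions
#'
#' Pixel (column, row, channel) mass is P(bar reaches the row) times the
#' bar's color probability — the product construction of the factorized
#' decoder.
#'
#' @param height_probs 200 x 12 matrix; @param color_probs 200 x 5 matrix
#' @return A 100 x 25 x 5 array with entries in \[0, 1\].
#' @export
expected_image <- function(height_probs, color_probs) {
  img <- array(0, dim = c(IMG_COLS, IMG_ROWS, N_COLORS))
  for (b in seq_len(N_BARS)) {
    col <- if (b <= IMG_COLS) b else b - IMG_COLS
    top <- b <= IMG_COLS
    # occupancy of bar depth r = P(height >= r)
    occ <- vapply(1:12, function(r) sum(height_probs[b, BAR_HEIGHTS >= r]), 0)
    for (r in seq_len(12L)) {
      if (occ[r] <= 0) break
      row <- if (top) r else IMG_ROWS - r + 1L
      img[col, row, ] <- img[col, row, ] + occ[r] * color_probs[b, ]
    }
  }
  img
}

#' Sample discrete bar images from decoder distributions
#'
#' Draws a height class and a color per bar (softmax with `temperature`;
#' `temperature = 0` takes the argmax) and renders valid bar images.
#'
#' @param dec output of [diva_decode()]
#' @param temperature sampling temperature (0 = deterministic argmax)
#' @return List of 100 x 25 x 5 arrays.
#' @export
sample_decoded <- function(dec, temperature = 1) {
  n <- dim(dec$height)[1L]
  draw <- function(p) {
    if (temperature == 0) return(which.max(p))
    w <- p^(1 / temperature)
    sample.int(length(p), 1L, prob = w / sum(w))
  }
  lapply(seq_len(n), function(i) {
    bars <- NULL
    for (col in seq_len(IMG_COLS)) {
      ht <- BAR_HEIGHTS[draw(dec$height[i, col, ])]
      hb <- BAR_HEIGHTS[draw(dec$height[i, col + IMG_COLS, ])]
      ct <- COLOR_LEVELS[draw(dec$color[i, col, ])]
      cb <- COLOR_LEVELS[draw(dec$color[i, col + IMG_COLS, ])]
      if (ht + hb >= IMG_ROWS) hb <- IMG_ROWS - 1L - ht  # keep bars disjoint
      if (ht > 0L || hb > 0L) {
        bars <- rbind(bars, data.frame(col = col,
                                       top_color = if (ht > 0) ct else NA,
                                       top_len = ht,
                                       bottom_color = if (hb > 0) cb else NA,
                                       bottom_len = max(hb, 0L)))
      }
    }
    if (is.null(bars)) {
      array(0, dim = c(IMG_COLS, IMG_ROWS, N_COLORS))
    } else {
      bars_to_image(bars)
    }
  })
}

#' Conditional generation: swap the bond-strength vector
#'
#' Encodes `rna` to obtain z_y and z_x, samples z_m from the learned
#' conditional prior evaluated at `m_new`, and decodes — the bond-swap
#' experiment probing whether z_m controls the generated bond pattern.
#'
#' @param model a trained `diva_model`
#' @param rna a `structured_rna` (the source of z_y, z_x)
#' @param m_new length-100 binary bond vector to condition on
#' @param n_samples number of images to draw
#' @param seed RNG seed
#' @param temperature sampling temperature for the discrete bar draws
#' @return List of sampled 100 x 25 x 5 images.
#' @export
conditional_generate <- function(model, rna, m_new, n_samples = 1L, seed = 1L,
                                 temperature = 1) {
  if (!isTRUE(model$trained)) stop("conditional generation needs a trained model")
  stopifnot(length(m_new) == IMG_COLS)
  z <- diva_encode(model, list(rna), sample = FALSE)
  set.seed(seed)
  tape <- ad_tape()
  pm <- prior_fwd(tape, ad_leaves(tape, model$params$prior_m),
                  ad_const(tape, matrix(as.numeric(m_new), 1L)))
  mu <- as.numeric(pm$mu$value); sd <- exp(as.numeric(pm$logsd$value))
  d <- model$config$latent_dim
  z_m <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  z_m <- sweep(sweep(z_m, 2L, sd, "*"), 2L, mu, "+")
  dec <- diva_decode(model, z_m,
                     matrix(rep(z$z_y[1L, ], n_samples), n_samples, byrow = TRUE),
                     matrix(rep(z$z_x[1L, ], n_samples), n_samples, byrow = TRUE))
  sample_decoded(dec, temperature = temperature)
}

#' Linear probe accuracy of the class on a latent space
#'
#' Fits a logistic regression of the label on the latent coordinates and
#' reports its training accuracy — the standard read-out for how linearly
#' separable the classes are in a representation.
#'
#' @param z latent matrix; @param y binary labels
#' @return Accuracy in \[0, 1\].
#' @export
linear_probe_accuracy <- function(z, y) {
  df <- data.frame(y = y, z)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  mean((stats::predict(fit, type = "response") > 0.5) == (y == 1))
}
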