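# DIVA model: shape and determinism contracts, flow identity at
# initialization, loss decomposition, decoder consistency with the codec
# and training behavior on a tiny run.

test_that("encoding returns three latent vectors of the configured size", {
  model <- tiny_model()
  ds <- small_dataset()[1:2]
  z <- diva_encode(model, ds, sample = TRUE, seed = 5)
  expect_identical(dim(z$z_m), c(2L, 2L))
  expect_identical(dim(z$z_y), c(2L, 2L))
  expect_identical(dim(z$z_x), c(2L, 2L))
  z2 <- diva_encode(model, ds, sample = TRUE, seed = 5)
  expect_identical(z, z2)   # same seed, same draw
  z3 <- diva_encode(model, ds, sample = TRUE, seed = 6)
  expect_false(identical(z$z_m, z3$z_m))
})

test_that("identity-initialized flows pass samples through with zero log-det", {
  model <- tiny_model()
  tens <- dataset_tensors(small_dataset()[1:4])
  noise <- diva_noise(4, 2)
  fw <- mirdiva:::diva_forward(model, tens, noise = noise)
  for (s in c("m", "y", "x")) {
    expect_identical(as.numeric(fw$enc[[s]]$logdet$value), rep(0, 4))
  }
  # with the flow stack removed entirely the samples are identical
  noflow <- model
  noflow$params$iaf_m <- list(); noflow$params$iaf_y <- list()
  noflow$params$iaf_x <- list()
  fw2 <- mirdiva:::diva_forward(noflow, tens, noise = noise)
  for (s in c("m", "y", "x")) {
    expect_equal(fw$enc[[s]]$z$value, fw2$enc[[s]]$z$value, tolerance = 1e-12)
  }
})

test_that("the objective decomposes into its terms to machine precision", {
  model <- tiny_model()
  tens <- dataset_tensors(small_dataset()[1:6])
  noise <- diva_noise(6, 2)
  t <- elbo_terms(model, tens, noise = noise)
  cfg <- model$config
  elbo_manual <- t$recon - cfg$beta_m * t$kl_m - cfg$beta_x * t$kl_x -
    cfg$beta_y * t$kl_y
  f_manual <- elbo_manual + cfg$alpha_y1 * t$ll_y_zy +
    cfg$alpha_y2 * t$ll_y_zm + cfg$alpha_m * t$ll_m
  expect_equal(t$elbo, elbo_manual, tolerance = 1e-12)
  expect_equal(t$f_diva, f_manual, tolerance = 1e-12)
})

test_that("zero weights collapse the objective onto its components", {
  cfg0 <- diva_config("desk", latent_dim = 2L, iaf_blocks = 1L,
                      iaf_context = 4L, iaf_hidden = 8L, enc_hidden = 12L,
                      enc_blocks = 1L, dec_hidden = 16L, prior_hidden = 8L,
                      aux_hidden = 8L,
                      beta_m = 0, beta_x = 0, beta_y = 0,
                      alpha_y1 = 0, alpha_y2 = 0, alpha_m = 0)
  set.seed(11)
  model <- diva_init(cfg0)
  tens <- dataset_tensors(small_dataset()[1:4])
  t <- elbo_terms(model, tens, noise = diva_noise(4, 2))
  expect_equal(t$elbo, t$recon, tolerance = 1e-12)   # beta = 0: pure reconstruction
  expect_equal(t$f_diva, t$elbo, tolerance = 1e-12)  # alpha = 0: F == L_s
})

test_that("a posterior equal to its prior has exactly zero KL", {
  model <- tiny_model()
  # zero the z_x encoder heads: posterior becomes N(0, I), the z_x prior
  model$params$enc_x$mu$W[] <- 0; model$params$enc_x$mu$b[] <- 0
  model$params$enc_x$logsd$W[] <- 0; model$params$enc_x$logsd$b[] <- 0
  tens <- dataset_tensors(small_dataset()[1:4])
  t <- elbo_terms(model, tens, noise = diva_noise(4, 2))
  expect_equal(t$kl_x, 0, tolerance = 1e-12)
})

test_that("sampled KL estimates agree with the analytic form in expectation", {
  set.seed(26)
  mu1 <- rnorm(4); sd1 <- exp(rnorm(4) / 3)
  mu2 <- rnorm(4); sd2 <- exp(rnorm(4) / 3)
  n <- 20000L
  z <- matrix(rnorm(n * 4), n, 4)
  z <- sweep(sweep(z, 2, sd1, "*"), 2, mu1, "+")
  logq <- rowSums(stats::dnorm(z, rep(mu1, each = n), rep(sd1, each = n), log = TRUE))
  logp <- rowSums(stats::dnorm(z, rep(mu2, each = n), rep(sd2, each = n), log = TRUE))
  est <- logq - logp
  se <- stats::sd(est) / sqrt(n)
  expect_lt(abs(mean(est) - kl_diag_gaussian(mu1, sd1, mu2, sd2)), 3 * se)
})

test_that("the decoder's discrete rendering is consistent with the codec", {
  # a one-hot height of 2 px with GAP color reproduces the codec gap bar
  hp <- matrix(0, 200, 12); cp <- matrix(0, 200, 5)
  hp[, 1] <- 1                      # every bar empty ...
  hp[1, ] <- 0; hp[1, 2] <- 1       # ... except bar 1: height 2
  cp[, 5] <- 1                      # GAP color
  img <- expected_image(hp, cp)
  ref <- array(0, dim = c(100, 25, 5))
  ref[1, 1:2, 5] <- 1               # 2-px black bar attached to the top
  expect_identical(img, ref)
  # uniform color probabilities spread mass equally over the 5 channels
  cp_unif <- matrix(1 / 5, 200, 5)
  img_u <- expected_image(hp, cp_unif)
  expect_identical(unname(img_u[1, 1, ]), rep(0.2, 5))
})

test_that("argmax sampling equals the argmax of the expected rendering", {
  model <- tiny_model()
  set.seed(27)
  for (i in 1:20) {
    z <- matrix(rnorm(6), 1, 6)
    dec <- diva_decode(model, z[, 1:2, drop = FALSE], z[, 3:4, drop = FALSE],
                       z[, 5:6, drop = FALSE])
    samp <- sample_decoded(dec, temperature = 0)[[1]]
    hmax <- apply(dec$height[1, , ], 1, which.max)
    cmax <- apply(dec$color[1, , ], 1, which.max)
    # rebuild the argmax bars directly from the distributions
    for (b in which(BAR_HEIGHTS[hmax] > 0)) {
      col <- if (b <= 100) b else b - 100
      len <- BAR_HEIGHTS[hmax[b]]
      rows <- if (b <= 100) seq_len(len) else 25 - seq_len(len) + 1
      expect_identical(unname(samp[col, rows, cmax[b]]), rep(1, len))
    }
  }
})

test_that("a short training run is reproducible and improves the loss", {
  tens <- dataset_tensors(small_dataset())
  cfg <- diva_config("desk", latent_dim = 4L, iaf_blocks = 1L,
                     iaf_context = 4L, iaf_hidden = 8L, enc_hidden = 24L,
                     enc_blocks = 1L, dec_hidden = 32L, prior_hidden = 8L,
                     aux_hidden = 8L, epochs = 4L, batch_size = 32L)
  m1 <- diva_train(tens, cfg, seed = 13)
  m2 <- diva_train(tens, cfg, seed = 13)
  expect_identical(m1$history, m2$history)   # end-to-end determinism
  expect_lt(m1$history$loss[4], m1$history$loss[1])
  # frozen weights: evaluation is deterministic (batch-norm in eval mode)
  noise <- diva_noise(nrow(tens$X), 4)
  l1 <- diva_loss(m1, tens, noise = noise)
  l2 <- diva_loss(m1, tens, noise = noise)
  expect_identical(l1, l2)
})

test_that("conditional generation needs a trained model and yields n samples", {
  model <- tiny_model()
  expect_error(conditional_generate(model, small_dataset()[[1]], rep(1, 100)),
               "trained")
  trained <- model; trained$trained <- TRUE
  out <- conditional_generate(trained, small_dataset()[[1]], rep(1, 100),
                              n_samples = 3, seed = 2)
  expect_length(out, 3)
  expect_false(identical(out[[1]], out[[2]]))  # stochastic draws differ
})
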