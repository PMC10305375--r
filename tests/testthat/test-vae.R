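test_that("initialization: zero biases, He-normal weights, seed-deterministic", {
  arch <- vae_architecture(input_dim = 30, encoder_hidden = c(25, 25))
  m1 <- init_vae(arch, seed = 3)
  m2 <- init_vae(arch, seed = 3)
  m3 <- init_vae(arch, seed = 4)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  bias_names <- grep("_b", names(m1$params), value = TRUE)
  for (b in bias_names) expect_true(all(m1$params[[b]] == 0))
  # Monte-Carlo He check: 10,000 weights of fan_in-25 layers, var ~ 2/25
  w <- unlist(lapply(1:50, function(s) {
    p <- init_vae(vae_architecture(8, encoder_hidden = c(25, 25)), seed = s)$params
    as.vector(p$enc_W2)  # 25 x 25 layer, fan_in 25
  }))
  expect_gt(length(w), 10000)
  expect_lt(abs(var(w) - 2 / 25) / (2 / 25), 0.10)
})

test_that("encode returns finite latent statistics of the right shape", {
  arch <- vae_architecture(input_dim = 12)
  m <- init_vae(arch, seed = 1)
  ds <- simulate_formulations(small_spec())
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  st <- vae_encode(m, xn)
  expect_equal(dim(st$mu), c(60, 2))
  expect_equal(dim(st$logvar), c(60, 2))
  expect_true(all(is.finite(st$mu)), all(is.finite(st$logvar)))
  expect_identical(vae_encode(m, xn), st)
  expect_error(vae_encode(m, matrix(0, 2, 5)),
               class = "plc_error_dim_mismatch")
})

test_that("reparameterization has the right moments and degenerate limit", {
  st <- list(mu = c(1.5, -2), logvar = c(-50, -50))
  z <- vae_reparameterize(st, seed = 1)
  expect_equal(as.numeric(z), c(1.5, -2), tolerance = 1e-9)

  stats <- list(mu = matrix(c(0.7, -1.2), 1), logvar = matrix(c(0.5, -1), 1))
  draws <- vae_reparameterize(list(mu = matrix(rep(stats$mu, each = 1e5), 1e5, 2,
                                               byrow = FALSE),
                                   logvar = matrix(rep(stats$logvar, each = 1e5),
                                                   1e5, 2)),
                              seed = 2)
  for (j in 1:2) {
    v <- exp(stats$logvar[j])
    se_mean <- sqrt(v / 1e5)
    expect_lt(abs(mean(draws[, j]) - stats$mu[j]), 3 * se_mean)
    se_var <- v * sqrt(2 / (1e5 - 1))
    expect_lt(abs(var(draws[, j]) - v), 3 * se_var)
  }
  expect_identical(vae_reparameterize(st, seed = 9),
                   vae_reparameterize(st, seed = 9))
})

test_that("decoder outputs live strictly in (0, 1); zero weights give 0.5", {
  arch <- vae_architecture(input_dim = 7)
  m <- init_vae(arch, seed = 5)
  z <- matrix(rnorm(20), 10, 2)
  out <- vae_decode(m, z)
  expect_true(all(out > 0 & out < 1))
  m0 <- m
  m0$params <- lapply(m0$params, function(p) p * 0)
  expect_equal(as.numeric(vae_decode(m0, c(0, 0))), rep(0.5, 7))
})

test_that("the KL closed form is exact, non-negative, and permutation-invariant", {
  x <- rep(0.5, 4); xh <- rep(0.5, 4)
  expect_equal(vae_loss(x, xh, list(mu = c(0, 0), logvar = c(0, 0)))$kl, 0)
  expect_equal(vae_loss(x, xh, list(mu = c(1, 0), logvar = c(0, 0)))$kl, 0.5)
  withr::with_seed(31, {
    for (i in 1:20) {
      st <- list(mu = rnorm(2), logvar = rnorm(2))
      expect_gte(vae_loss(x, xh, st)$kl, 0)
    }
  })
  # KL = 0 iff posterior equals the prior
  expect_gt(vae_loss(x, xh, list(mu = c(0.1, 0), logvar = c(0, 0)))$kl, 0)
  # consistent feature permutation leaves the loss unchanged
  withr::with_seed(32, {
    xa <- runif(6); xha <- runif(6)
    st <- list(mu = rnorm(2), logvar = rnorm(2))
    perm <- sample(6)
    a <- vae_loss(xa, xha, st)
    b <- vae_loss(xa[perm], xha[perm], st)
    expect_equal(a$total, b$total)
  })
  expect_error(vae_loss(c(1.4, 0), c(0.5, 0.5), list(mu = 0, logvar = 0)),
               class = "plc_error_not_normalized")
})

test_that("KL closed form matches a Monte-Carlo estimate at random stats", {
  n_mc <- 1e5
  withr::with_seed(77, {
    for (rep in 1:5) {
      mu <- rnorm(2); logvar <- rnorm(2, sd = 0.7)
      kl_cf <- vae_loss(rep(0.5, 3), rep(0.5, 3),
                        list(mu = mu, logvar = logvar))$kl
      s <- exp(logvar / 2)
      z <- sweep(matrix(rnorm(n_mc * 2), n_mc, 2) *
                   rep(s, each = n_mc), 2, mu, "+")
      logq <- sapply(1:2, function(j) dnorm(z[, j], mu[j], s[j], log = TRUE))
      logp <- dnorm(z, log = TRUE)
      samples <- rowSums(logq - logp)
      se <- sd(samples) / sqrt(n_mc)
      expect_lt(abs(kl_cf - mean(samples)), 3 * se)
    }
  })
})

test_that("training reduces the loss, is bit-reproducible, and beats the untrained model", {
  ds <- simulate_formulations(small_spec(seed = 13))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  fit <- train_vae(xn, iterations = 800, seed = 2)
  h <- fit$history$total
  expect_equal(nrow(fit$history), 800L)
  expect_lt(mean(tail(h, 50)), mean(head(h, 50)))
  fit2 <- train_vae(xn, iterations = 800, seed = 2)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)

  # reconstruction error far below the untrained model's
  recon_err <- function(model) {
    st <- vae_encode(model, xn)
    xh <- vae_decode(model, vae_reparameterize(st, seed = 5))
    mean((as.matrix(xn[1:12]) - xh)^2)
  }
  untrained <- init_vae(vae_architecture(12), seed = 2)
  expect_lt(recon_err(fit), recon_err(untrained) / 2)

  # latent means cluster by class (positive silhouette)
  lc <- latent_coordinates(fit, xn)
  d <- as.matrix(dist(lc[, c("z1", "z2")]))
  sil <- sapply(seq_len(nrow(lc)), function(i) {
    same <- lc$label == lc$label[i]; same[i] <- FALSE
    a <- mean(d[i, same]); b <- mean(d[i, !same])
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0)
  expect_error(train_vae(ds$train, iterations = 5),
               class = "plc_error_not_normalized")
})

test_that("R and compiled training engines perform the same arithmetic", {
  ds <- simulate_formulations(small_spec(seed = 4))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  a <- train_vae(xn, iterations = 40, seed = 9, engine = "r")
  b <- train_vae(xn, iterations = 40, seed = 9, engine = "cpp")
  expect_equal(a$history$total, b$history$total, tolerance = 1e-10)
  expect_equal(a$model$params, b$model$params, tolerance = 1e-10)
})

test_that("pool generation yields labeled minority rows near the minority cloud", {
  ds <- simulate_formulations(small_spec(seed = 6))
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  fit <- train_vae(xn, iterations = 1500, seed = 3)
  minority <- xn[xn$label == 0L, ]
  pool <- vae_generate_pool(fit, minority, n_pool = 500, seed = 8)
  expect_equal(nrow(pool), 500L)
  expect_true(all(pool$label == 0L))
  xs <- as.matrix(pool[1:12])
  expect_true(all(xs > 0 & xs < 1))
  expect_error(vae_generate_pool(fit, minority, n_pool = 0),
               class = "plc_error_bad_pool")
  expect_error(vae_generate_pool(fit, minority[0, ], n_pool = 5),
               class = "plc_error_empty_table")

  # label fidelity: most pool rows have a minority nearest neighbour
  xtr <- as.matrix(xn[1:12])
  nn_lab <- apply(xs, 1, function(r) {
    xn$label[which.min(colSums((t(xtr) - r)^2))]
  })
  expect_gte(mean(nn_lab == 0L), 0.8)
})

test_that("balancing adds exactly the class gap and keeps originals intact", {
  ds <- simulate_formulations(small_spec(seed = 10))  # 40 / 20
  xn <- apply_minmax(fit_minmax(ds$train), ds$train)
  fit <- train_vae(xn, iterations = 300, seed = 1)
  bal <- balance_with_vae(xn, fit, n_pool = 100, seed = 4)
  cc <- class_counts(bal)
  expect_equal(cc$n_success, cc$n_failure)
  expect_equal(nrow(bal), 80L)
  expect_equal(as.matrix(bal[1:60, 1:12]), as.matrix(xn[, 1:12]))
  expect_equal(attr(bal, "origin"),
               rep(c("original", "generated"), c(60, 20)))

  already <- xn[c(1:20, 41:60), ]  # force balance
  already$label <- rep(c(1L, 0L), each = 20)
  out <- balance_with_vae(already, fit, n_pool = 100, seed = 4)
  expect_equal(nrow(out), 40L)

  expect_error(balance_with_vae(xn, fit, n_pool = 10, seed = 4),
               class = "plc_error_pool_too_small")
})
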