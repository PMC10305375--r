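#' Variational autoencoder architecture
#'
#' Fully connected encoder/decoder for normalized descriptor tables. The
#' default mirrors the augmentation model used throughout the package:
#' encoder hidden layers of 50 and 25 rectified units, a 2-dimensional
#' Gaussian latent space (mean and log-variance heads), and a decoder
#' symmetric to the encoder ending in a logistic output layer so that
#' reconstructions live in (0, 1), matching min-max-normalized inputs.
#'
#' @param input_dim Number of descriptor columns.
#' @param encoder_hidden Integer vector of encoder hidden-layer widths
#'   (default `c(50, 25)`).
#' @param latent_dim Latent dimensionality (default 2).
#' @param decoder_hidden Decoder hidden widths; defaults to the reverse of
#'   `encoder_hidden`.
#' @return An object of class `"vae_architecture"`.
#' @export
vae_architecture <- function(input_dim, encoder_hidden = c(50, 25),
                             latent_dim = 2,
                             decoder_hidden = rev(encoder_hidden)) {
  arch <- list(input_dim = as.integer(input_dim),
               encoder_hidden = as.integer(encoder_hidden),
               latent_dim = as.integer(latent_dim),
               decoder_hidden = as.integer(decoder_hidden))
  if (any(c(arch$input_dim, arch$encoder_hidden, arch$latent_dim,
            arch$decoder_hidden) < 1L)) {
    abort("All layer sizes must be positive.", class = "plc_error_bad_arch")
  }
  structure(arch, class = "vae_architecture")
}

#' Initialize a variational autoencoder
#'
#' Biases start at exactly zero; weights are drawn from a He-normal
#' distribution (zero mean, variance `2 / fan_in`). Initialization is
#' deterministic per seed.
#'
#' @param arch A [vae_architecture()].
#' @param seed Integer seed.
#' @return An object of class `"plc_vae"`: the architecture plus a named
#'   list of parameter arrays.
#' @export
init_vae <- function(arch, seed = 1) {
  stopifnot(inherits(arch, "vae_architecture"))
  params <- with_seed(seed, {
    p <- list()
    sizes <- c(arch$input_dim, arch$encoder_hidden)
    for (i in seq_along(arch$encoder_hidden)) {
      p[[paste0("enc_W", i)]] <- he_normal(c(sizes[i], sizes[i + 1]), sizes[i])
      p[[paste0("enc_b", i)]] <- numeric(sizes[i + 1])
    }
    top <- sizes[length(sizes)]
    p$mu_W <- he_normal(c(top, arch$latent_dim), top)
    p$mu_b <- numeric(arch$latent_dim)
    p$lv_W <- he_normal(c(top, arch$latent_dim), top)
    p$lv_b <- numeric(arch$latent_dim)
    sizes <- c(arch$latent_dim, arch$decoder_hidden, arch$input_dim)
    for (i in seq_len(length(sizes) - 1L)) {
      p[[paste0("dec_W", i)]] <- he_normal(c(sizes[i], sizes[i + 1]), sizes[i])
      p[[paste0("dec_b", i)]] <- numeric(sizes[i + 1])
    }
    p
  })
  structure(list(arch = arch, params = params), class = "plc_vae")
}

#' @export
print.plc_vae <- function(x, ...) {
  cat(sprintf("<plc_vae> %d -> [%s] -> %d -> [%s] -> %d\n",
              x$arch$input_dim, paste(x$arch$encoder_hidden, collapse = ", "),
              x$arch$latent_dim, paste(x$arch$decoder_hidden, collapse = ", "),
              x$arch$input_dim))
  invisible(x)
}

as_vae_model <- function(model) {
  if (inherits(model, "plc_vae_fit")) model$model
  else if (inherits(model, "plc_vae")) model
  else abort("Expected a 'plc_vae' or 'plc_vae_fit' object.",
             class = "plc_error_bad_model")
}

vae_input_matrix <- function(x, input_dim, label = "label") {
  if (is.data.frame(x)) {
    x <- table_parts(x, label = label, require_label = FALSE)$x
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != input_dim) {
    abort(sprintf("Input has %d columns; the model expects %d.",
                  ncol(x), input_dim),
          class = "plc_error_dim_mismatch")
  }
  x
}

# row-broadcast bias addition without sweep()'s aperm overhead
add_bias <- function(y, b) y + rep(b, rep.int(nrow(y), length(b)))

# forward through the encoder trunk, returning hidden activations too
vae_encode_full <- function(model, x) {
  p <- model$params
  hs <- list()
  h <- x
  for (i in seq_along(model$arch$encoder_hidden)) {
    h <- relu(add_bias(h %*% p[[paste0("enc_W", i)]],
                       p[[paste0("enc_b", i)]]))
    hs[[i]] <- h
  }
  list(hidden = hs,
       mu = add_bias(h %*% p$mu_W, p$mu_b),
       logvar = add_bias(h %*% p$lv_W, p$lv_b))
}

# forward through the decoder, returning logits and hidden activations
vae_decode_full <- function(model, z) {
  p <- model$params
  n_dec <- length(model$arch$decoder_hidden) + 1L
  hs <- list()
  h <- z
  for (i in seq_len(n_dec - 1L)) {
    h <- relu(add_bias(h %*% p[[paste0("dec_W", i)]],
                       p[[paste0("dec_b", i)]]))
    hs[[i]] <- h
  }
  logits <- add_bias(h %*% p[[paste0("dec_W", n_dec)]],
                     p[[paste0("dec_b", n_dec)]])
  list(hidden = hs, logits = logits)
}

#' Encode descriptors into latent statistics
#'
#' Maps each (normalized) descriptor row to the mean and log-variance of
#' its Gaussian posterior in latent space.
#'
#' @param model A `"plc_vae"` or `"plc_vae_fit"` object.
#' @param x A numeric matrix/vector of normalized descriptors, or a
#'   descriptor tibble (the label column, if present, is ignored).
#' @param label Label column name to drop when `x` is a data frame.
#' @return A list with matrices `mu` and `logvar` (rows by latent
#'   dimensions).
#' @export
vae_encode <- function(model, x, label = "label") {
  model <- as_vae_model(model)
  x <- vae_input_matrix(x, model$arch$input_dim, label)
  enc <- vae_encode_full(model, x)
  list(mu = enc$mu, logvar = enc$logvar)
}

#' Sample latent vectors by the reparameterization trick
#'
#' Draws `z = mu + exp(logvar / 2) * eps` with standard-normal `eps`,
#' keeping latent sampling differentiable during training and reproducible
#' per seed here.
#'
#' @param stats A list with `mu` and `logvar` (vectors or matrices), as
#'   returned by [vae_encode()].
#' @param seed Integer seed.
#' @return A matrix of latent draws with the same shape as `stats$mu`.
#' @export
vae_reparameterize <- function(stats, seed = 1) {
  mu <- rbind(stats$mu)
  logvar <- rbind(stats$logvar)
  stopifnot(all(is.finite(mu)), all(is.finite(logvar)),
            all(dim(mu) == dim(logvar)))
  eps <- with_seed(seed, matrix(rnorm(length(mu)), nrow(mu), ncol(mu)))
  mu + exp(logvar / 2) * eps
}

#' Decode latent vectors into descriptor space
#'
#' @param model A `"plc_vae"` or `"plc_vae_fit"` object.
#' @param z Latent vector or matrix (rows by latent dimensions).
#' @return A matrix of reconstructions, every entry strictly in (0, 1).
#' @export
vae_decode <- function(model, z) {
  model <- as_vae_model(model)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$arch$latent_dim) {
    abort(sprintf("Latent input has %d columns; the model expects %d.",
                  ncol(z), model$arch$latent_dim),
          class = "plc_error_dim_mismatch")
  }
  sigmoid(vae_decode_full(model, z)$logits)
}

#' VAE training loss
#'
#' The objective combines a reconstruction term and a Kullback-Leibler
#' regularizer pulling each posterior toward the standard-normal prior:
#' `total = recon_weight * recon + kl`, with
#' `kl = -0.5 * sum(1 + logvar - mu^2 - exp(logvar))` (closed form for
#' diagonal Gaussians) and `recon` the element-summed binary cross-entropy
#' between input and reconstruction (the consistent likelihood for data in
#' \[0, 1\] under a logistic output; squared error is available in
#' [train_vae()]).
#'
#' For matrix inputs the three terms are averaged over rows.
#'
#' @param x Input vector/matrix with entries in \[0, 1\].
#' @param x_hat Reconstruction with entries in (0, 1).
#' @param stats List with `mu` and `logvar` matching `x`'s rows.
#' @param recon_weight Positive weight on the reconstruction term
#'   (default 1000).
#' @return A list with `total`, `recon` and `kl`.
#' @examples
#' vae_loss(c(0.5, 0.5), c(0.5, 0.5), list(mu = c(0, 0), logvar = c(0, 0)))
#' @export
vae_loss <- function(x, x_hat, stats, recon_weight = 1000) {
  x <- rbind(x); x_hat <- rbind(x_hat)
  if (any(x < 0 | x > 1)) {
    abort("vae_loss expects inputs in [0, 1]; normalize first.",
          class = "plc_error_not_normalized")
  }
  stopifnot(all(x_hat > 0 & x_hat < 1), recon_weight > 0)
  mu <- rbind(stats$mu); logvar <- rbind(stats$logvar)
  eps <- 1e-12
  recon <- rowSums(-(x * log(x_hat + eps) + (1 - x) * log(1 - x_hat + eps)))
  kl <- -0.5 * rowSums(1 + logvar - mu^2 - exp(logvar))
  list(total = mean(recon_weight * recon + kl),
       recon = mean(recon), kl = mean(kl))
}

#' Train a variational autoencoder on a normalized training split
#'
#' Runs exactly `iterations` full-batch Adam steps on the weighted
#' evidence lower bound (see [vae_loss()]); gradients flow through the
#' reparameterized latent draw. Both classes of the training split are
#' used, so the latent space organizes successes and failures into
#' separate clusters that the generator later samples from.
#'
#' @param data Normalized training descriptor table (all features in
#'   \[0, 1\]; see [apply_minmax()]).
#' @param arch Optional [vae_architecture()]; defaults to the 50-25-2
#'   architecture sized to `data`.
#' @param recon_weight Weight on the reconstruction loss (default 1000).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param iterations Number of full-batch steps (default 5000).
#' @param recon_loss `"bce"` (default) or `"mse"`.
#' @param seed Integer seed controlling initialization and the per-step
#'   latent noise; runs are bit-reproducible.
#' @param engine `"cpp"` (default) runs the compiled Armadillo training
#'   loop; `"r"` runs the pure-R reference implementation of the same
#'   arithmetic (slower; useful for checking the compiled port).
#' @param label Label column name.
#' @return An object of class `"plc_vae_fit"`: `model` (trained
#'   `"plc_vae"`), `history` (tibble of iteration, total, recon, kl) and
#'   the configuration.
#' @export
train_vae <- function(data, arch = NULL, recon_weight = 1000,
                      learning_rate = 0.001, iterations = 5000,
                      recon_loss = c("bce", "mse"), seed = 1,
                      engine = c("cpp", "r"), label = "label") {
  recon_loss <- match.arg(recon_loss)
  engine <- match.arg(engine)
  parts <- table_parts(data, label = label, require_label = FALSE)
  x <- parts$x
  if (nrow(x) < 2L) {
    abort("Need at least 2 rows to train the autoencoder.",
          class = "plc_error_empty_table")
  }
  if (any(x < 0 | x > 1)) {
    abort("train_vae expects all features in [0, 1]; apply min-max normalization first.",
          class = "plc_error_not_normalized")
  }
  stopifnot(iterations >= 1, recon_weight > 0, learning_rate > 0)
  arch <- arch %||% vae_architecture(ncol(x))
  if (arch$input_dim != ncol(x)) {
    abort("Architecture input_dim does not match the data.",
          class = "plc_error_dim_mismatch")
  }
  model <- init_vae(arch, seed = seed)
  n <- nrow(x)
  k <- arch$latent_dim
  hist_total <- hist_recon <- hist_kl <- numeric(iterations)

  if (engine == "cpp") {
    n_enc <- length(arch$encoder_hidden)
    n_dec <- length(arch$decoder_hidden) + 1L
    p <- model$params
    res <- with_seed(child_seed(seed, 1L), .vae_train_cpp(
      x,
      lapply(seq_len(n_enc), function(i) p[[paste0("enc_W", i)]]),
      lapply(seq_len(n_enc), function(i) p[[paste0("enc_b", i)]]),
      p$mu_W, p$mu_b, p$lv_W, p$lv_b,
      lapply(seq_len(n_dec), function(i) p[[paste0("dec_W", i)]]),
      lapply(seq_len(n_dec), function(i) p[[paste0("dec_b", i)]]),
      recon_weight, learning_rate, as.integer(iterations),
      recon_loss == "bce"))
    for (i in seq_len(n_enc)) {
      p[[paste0("enc_W", i)]] <- res$enc_W[[i]]
      p[[paste0("enc_b", i)]] <- as.numeric(res$enc_b[[i]])
    }
    p$mu_W <- res$mu_W; p$mu_b <- as.numeric(res$mu_b)
    p$lv_W <- res$lv_W; p$lv_b <- as.numeric(res$lv_b)
    for (i in seq_len(n_dec)) {
      p[[paste0("dec_W", i)]] <- res$dec_W[[i]]
      p[[paste0("dec_b", i)]] <- as.numeric(res$dec_b[[i]])
    }
    model$params <- p
    return(structure(
      list(model = model,
           history = tibble(iteration = seq_len(iterations),
                            total = as.numeric(res$total),
                            recon = as.numeric(res$recon),
                            kl = as.numeric(res$kl)),
           config = list(recon_weight = recon_weight,
                         learning_rate = learning_rate,
                         iterations = as.integer(iterations),
                         recon_loss = recon_loss,
                         seed = as.integer(seed), engine = engine),
           features = parts$features),
      class = "plc_vae_fit"))
  }

  run <- with_seed(child_seed(seed, 1L), {
    params <- model$params
    state <- adam_init(params)
    n_enc <- length(arch$encoder_hidden)
    n_dec <- length(arch$decoder_hidden) + 1L
    enc_W <- paste0("enc_W", seq_len(n_enc)); enc_b <- paste0("enc_b", seq_len(n_enc))
    dec_W <- paste0("dec_W", seq_len(n_dec)); dec_b <- paste0("dec_b", seq_len(n_dec))
    for (it in seq_len(iterations)) {
      m <- list(arch = arch, params = params)
      enc <- vae_encode_full(m, x)
      mu <- enc$mu; logvar <- enc$logvar
      epsm <- matrix(rnorm(n * k), n, k)
      s <- exp(logvar / 2)
      z <- mu + s * epsm
      dec <- vae_decode_full(m, z)
      a <- dec$logits
      xhat <- sigmoid(a)

      recon <- if (recon_loss == "bce") rowSums(softplus(a) - x * a)
               else rowSums((x - xhat)^2)
      kl <- -0.5 * rowSums(1 + logvar - mu^2 - exp(logvar))
      hist_total[it] <- mean(recon_weight * recon + kl)
      hist_recon[it] <- mean(recon)
      hist_kl[it] <- mean(kl)

      # ---- backward pass (objective = mean over rows) ----
      grads <- vector("list", length(params))
      names(grads) <- names(params)
      ga <- if (recon_loss == "bce") recon_weight * (xhat - x) / n
            else recon_weight * 2 * (xhat - x) * xhat * (1 - xhat) / n
      # decoder
      g <- ga
      for (i in rev(seq_len(n_dec))) {
        inp <- if (i == 1L) z else dec$hidden[[i - 1L]]
        grads[[dec_W[i]]] <- crossprod(inp, g)
        grads[[dec_b[i]]] <- colSums(g)
        g <- tcrossprod(g, params[[dec_W[i]]])
        if (i > 1L) g <- g * (dec$hidden[[i - 1L]] > 0)
      }
      gz <- g
      gmu <- gz + mu / n
      glv <- gz * epsm * s * 0.5 + 0.5 * (exp(logvar) - 1) / n
      # encoder heads
      top <- enc$hidden[[n_enc]]
      grads$mu_W <- crossprod(top, gmu); grads$mu_b <- colSums(gmu)
      grads$lv_W <- crossprod(top, glv); grads$lv_b <- colSums(glv)
      g <- (tcrossprod(gmu, params$mu_W) + tcrossprod(glv, params$lv_W)) *
        (top > 0)
      for (i in rev(seq_len(n_enc))) {
        inp <- if (i == 1L) x else enc$hidden[[i - 1L]]
        grads[[enc_W[i]]] <- crossprod(inp, g)
        grads[[enc_b[i]]] <- colSums(g)
        if (i > 1L) {
          g <- tcrossprod(g, params[[enc_W[i]]]) *
            (enc$hidden[[i - 1L]] > 0)
        }
      }
      upd <- adam_step(params, grads, state, lr = learning_rate)
      params <- upd$params
      state <- upd$state
    }
    list(params = params, total = hist_total,
         recon = hist_recon, kl = hist_kl)
  })

  model$params <- run$params
  structure(list(model = model,
                 history = tibble(iteration = seq_len(iterations),
                                  total = run$total, recon = run$recon,
                                  kl = run$kl),
                 config = list(recon_weight = recon_weight,
                               learning_rate = learning_rate,
                               iterations = as.integer(iterations),
                               recon_loss = recon_loss,
                               seed = as.integer(seed), engine = engine),
                 features = parts$features),
            class = "plc_vae_fit")
}

#' @export
print.plc_vae_fit <- function(x, ...) {
  cat(sprintf("<plc_vae_fit> %d iterations, final total loss %.4g\n",
              nrow(x$history), x$history$total[nrow(x$history)]))
  print(x$model)
  invisible(x)
}

#' Generate a pool of synthetic minority-class rows
#'
#' Each synthetic row is produced by drawing one of the supplied minority
#' rows uniformly at random, encoding it, sampling a latent vector from its
#' posterior (reparameterization trick) and decoding. Sampling around the
#' minority posteriors — rather than the prior — guarantees the synthetic
#' rows land in the minority region of latent space and can carry the
#' minority label.
#'
#' @param model A trained `"plc_vae_fit"` (or `"plc_vae"`).
#' @param minority Descriptor table of minority-class rows (normalized).
#' @param n_pool Number of rows to generate (>= 1); the reference workflow
#'   draws a pool of 500.
#' @param seed Integer seed.
#' @param label Label column name; if present in `minority` it must be
#'   single-valued and is used to label the synthetic rows.
#' @return A descriptor tibble of `n_pool` synthetic rows (values in
#'   (0, 1)) labeled with the minority class.
#' @export
vae_generate_pool <- function(model, minority, n_pool = 500, seed = 1,
                              label = "label") {
  vae <- as_vae_model(model)
  parts <- table_parts(minority, label = label, require_label = FALSE)
  if (nrow(parts$x) == 0L) {
    abort("Minority set is empty.", class = "plc_error_empty_table")
  }
  if (n_pool < 1) {
    abort("n_pool must be at least 1.", class = "plc_error_bad_pool")
  }
  lab <- 1L
  if (!is.null(parts$y)) {
    lab <- unique(parts$y)
    if (length(lab) != 1L) {
      abort("`minority` must contain a single class.",
            class = "plc_error_label_levels")
    }
  }
  xs <- with_seed(seed, {
    idx <- sample.int(nrow(parts$x), n_pool, replace = TRUE)
    enc <- vae_encode(vae, parts$x[idx, , drop = FALSE])
    epsm <- matrix(rnorm(n_pool * vae$arch$latent_dim),
                   n_pool, vae$arch$latent_dim)
    z <- enc$mu + exp(enc$logvar / 2) * epsm
    vae_decode(vae, z)
  })
  rebuild_table(xs, rep(lab, n_pool), parts$features, label = label)
}

#' Balance a training split with VAE-generated minority rows
#'
#' Generates a pool of `n_pool` synthetic minority rows (see
#' [vae_generate_pool()]), draws exactly `n_majority - n_minority` of them
#' uniformly without replacement, and appends them to the original table.
#' Original rows are never modified; with the reference counts of 179
#' successes and 93 failures this adds 86 rows for a balanced 358-row
#' table.
#'
#' @param data Normalized training descriptor table (with labels).
#' @param model A trained `"plc_vae_fit"` (or `"plc_vae"`).
#' @param n_pool Pool size (default 500); must be at least the class gap.
#' @param seed Integer seed.
#' @param label Label column name.
#' @return A balanced descriptor tibble; the attribute `"origin"` marks
#'   each row as `"original"` or `"generated"`.
#' @export
balance_with_vae <- function(data, model, n_pool = 500, seed = 1,
                             label = "label") {
  parts <- table_parts(data, label = label)
  counts <- class_counts(data, label = label)
  gap <- abs(counts$n_success - counts$n_failure)
  if (gap == 0L) {
    out <- rebuild_table(parts$x, parts$y, parts$features, label = label)
    attr(out, "origin") <- rep("original", nrow(out))
    return(out)
  }
  if (n_pool < gap) {
    abort(sprintf("Pool size %d is smaller than the class gap %d.",
                  n_pool, gap),
          class = "plc_error_pool_too_small")
  }
  minority_lab <- if (counts$n_success < counts$n_failure) 1L else 0L
  minority <- data[parts$y == minority_lab, , drop = FALSE]
  pool <- vae_generate_pool(model, minority, n_pool = n_pool,
                            seed = child_seed(seed, 2L), label = label)
  pick <- with_seed(child_seed(seed, 3L), sample.int(n_pool, gap))
  out <- dplyr::bind_rows(
    rebuild_table(parts$x, parts$y, parts$features, label = label),
    pool[pick, , drop = FALSE])
  attr(out, "origin") <- rep(c("original", "generated"),
                             c(nrow(data), gap))
  out
}

#' Latent coordinates of a descriptor table
#'
#' Encodes every row and returns the posterior means as a tidy table,
#' ready for a two-dimensional latent scatter of original vs. generated
#' data.
#'
#' @param model A `"plc_vae_fit"` or `"plc_vae"`.
#' @param data Normalized descriptor table.
#' @param label Label column name (carried through when present).
#' @param origin Optional character vector (e.g. `"original"` /
#'   `"generated"`) recycled to the rows.
#' @return A tibble with `z1`, `z2`, ... plus `label` and `origin` columns.
#' @export
latent_coordinates <- function(model, data, label = "label", origin = NULL) {
  vae <- as_vae_model(model)
  parts <- table_parts(data, label = label, require_label = FALSE)
  enc <- vae_encode(vae, parts$x)
  out <- as_tibble(as.data.frame(enc$mu))
  names(out) <- paste0("z", seq_len(ncol(out)))
  if (!is.null(parts$y)) out$label <- parts$y
  if (!is.null(origin)) out$origin <- rep_len(origin, nrow(out))
  out
}
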