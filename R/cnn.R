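#' Skip-connected 1D-CNN architecture
#'
#' The prediction block treats the reduced descriptor vector as a
#' length-`input_length` sequence with one channel and passes it through
#' three 1-D convolutions with channel widths growing 8, 16, 32 (kernel
#' size and stride 1 by default, so every convolution preserves sequence
#' length and acts as a per-position channel mix). The feature maps of the
#' first convolution are concatenated onto those of the third — a skip
#' connection preserving low-level information — followed by max pooling
#' (size 2), one further convolution, a second pooling, a flatten and a
#' single logistic output unit.
#'
#' @param input_length Sequence length (default 10, the post-PCA width).
#' @param input_channels Input channels (default 1).
#' @param conv_channels Channel widths of the three stacked convolutions;
#'   must be strictly increasing (default `c(8, 16, 32)`).
#' @param kernel_size,stride Convolution kernel size and stride
#'   (defaults 1).
#' @param pool_size Max-pooling window (default 2; floor division).
#' @param post_skip_channels Channel width of the convolution after the
#'   skip/pool (default 32; the width is not pinned down by the reference
#'   description).
#' @param pool `"max"` (default) or `"average"`.
#' @return An object of class `"cnn_architecture"`.
#' @export
cnn_architecture <- function(input_length = 10, input_channels = 1,
                             conv_channels = c(8, 16, 32),
                             kernel_size = 1, stride = 1, pool_size = 2,
                             post_skip_channels = 32,
                             pool = c("max", "average")) {
  pool <- match.arg(pool)
  arch <- list(input_length = as.integer(input_length),
               input_channels = as.integer(input_channels),
               conv_channels = as.integer(conv_channels),
               kernel_size = as.integer(kernel_size),
               stride = as.integer(stride),
               pool_size = as.integer(pool_size),
               post_skip_channels = as.integer(post_skip_channels),
               pool = pool)
  if (arch$kernel_size < 1L || arch$pool_size < 1L || arch$stride < 1L) {
    abort("kernel_size, stride and pool_size must be >= 1.",
          class = "plc_error_bad_arch")
  }
  if (length(arch$conv_channels) != 3L ||
      any(diff(arch$conv_channels) <= 0L)) {
    abort("conv_channels must be three strictly increasing widths.",
          class = "plc_error_bad_arch")
  }
  trace <- cnn_length_trace(arch)
  if (trace$flatten < 1L) {
    abort("input_length is too short for two pooling stages.",
          class = "plc_error_bad_arch")
  }
  arch
  structure(arch, class = "cnn_architecture")
}

conv_out_len <- function(len, k, stride) {
  if (len < k) 0L else as.integer(floor((len - k) / stride) + 1L)
}

# Sequence-length bookkeeping through the layer graph.
cnn_length_trace <- function(arch) {
  k <- arch$kernel_size; s <- arch$stride; p <- arch$pool_size
  l1 <- conv_out_len(arch$input_length, k, s)
  l2 <- conv_out_len(l1, k, s)
  l3 <- conv_out_len(l2, k, s)
  # concatenation requires equal lengths; with kernel/stride 1 they match
  l_skip <- min(l1, l3)
  lp1 <- l_skip %/% p
  l4 <- conv_out_len(lp1, k, s)
  lp2 <- l4 %/% p
  list(conv = c(l1, l2, l3), skip = l_skip, pool1 = lp1, conv4 = l4,
       pool2 = lp2,
       flatten = lp2 * arch$post_skip_channels,
       skip_channels = arch$conv_channels[1] + arch$conv_channels[3])
}

#' Number of learnable parameters of an architecture
#'
#' A pure function of the architecture (weights + biases of the four
#' convolutions and the dense output). The default configuration has
#' 2081 parameters.
#'
#' @param arch A [cnn_architecture()].
#' @return Integer parameter count.
#' @export
cnn_parameter_count <- function(arch) {
  stopifnot(inherits(arch, "cnn_architecture"))
  k <- arch$kernel_size
  tr <- cnn_length_trace(arch)
  ch <- c(arch$input_channels, arch$conv_channels)
  n <- 0L
  for (i in 1:3) n <- n + k * ch[i] * ch[i + 1] + ch[i + 1]
  n <- n + k * tr$skip_channels * arch$post_skip_channels +
    arch$post_skip_channels
  n + tr$flatten + 1L
}

#' Build (initialize) a skip-connected 1D-CNN
#'
#' Biases start at zero; weights are He-normal with fan-in
#' `kernel_size * in_channels`. Deterministic per seed.
#'
#' @param arch A [cnn_architecture()].
#' @param seed Integer seed.
#' @return An object of class `"plc_cnn"` with the parameter list, the
#'   architecture, `n_parameters` and the sequence-length `trace`.
#' @export
build_cnn <- function(arch, seed = 1) {
  stopifnot(inherits(arch, "cnn_architecture"))
  k <- arch$kernel_size
  tr <- cnn_length_trace(arch)
  ch <- c(arch$input_channels, arch$conv_channels)
  params <- with_seed(seed, {
    p <- list()
    for (i in 1:3) {
      p[[paste0("conv", i, "_W")]] <- he_normal(c(k, ch[i], ch[i + 1]),
                                                k * ch[i])
      p[[paste0("conv", i, "_b")]] <- numeric(ch[i + 1])
    }
    p$conv4_W <- he_normal(c(k, tr$skip_channels, arch$post_skip_channels),
                           k * tr$skip_channels)
    p$conv4_b <- numeric(arch$post_skip_channels)
    p$dense_W <- he_normal(c(tr$flatten, 1), tr$flatten)
    p$dense_b <- 0
    p
  })
  structure(list(arch = arch, params = params,
                 n_parameters = cnn_parameter_count(arch), trace = tr),
            class = "plc_cnn")
}

#' @export
print.plc_cnn <- function(x, ...) {
  cat(sprintf("<plc_cnn> input %d; channels %s (+skip concat) -> %d; %d parameters\n",
              x$arch$input_length,
              paste(x$arch$conv_channels, collapse = "/"),
              x$arch$post_skip_channels, x$n_parameters))
  invisible(x)
}

# --- low-level conv / pool primitives -----------------------------------
#
# Feature maps are stored as (n * L, C) matrices in which row
# i + (l - 1) * n holds sample i at sequence position l. In this layout a
# kernel-1 convolution is a single matrix multiply; general kernels need
# one multiply per tap, gathering input rows through index vectors that
# are precomputed once per (architecture, batch-size) pair in cnn_plan().

rows_at <- function(n, positions) {
  rep((positions - 1L) * n, each = n) + rep.int(seq_len(n), length(positions))
}

# Index plan for a batch of n samples.
cnn_plan <- function(arch, tr, n) {
  k <- arch$kernel_size; s <- arch$stride; p <- arch$pool_size
  conv_taps <- function(len) {
    starts <- seq.int(1L, len - k + 1L, s)
    lapply(seq_len(k), function(j) rows_at(n, starts + j - 1L))
  }
  pool_windows <- function(lout) {
    lapply(seq_len(p), function(w) rows_at(n, (seq_len(lout) - 1L) * p + w))
  }
  list(n = n,
       conv1 = conv_taps(arch$input_length),
       conv2 = conv_taps(tr$conv[1]),
       conv3 = conv_taps(tr$conv[2]),
       skip_rows = rows_at(n, seq_len(tr$skip)),
       pool1 = pool_windows(tr$pool1),
       conv4 = conv_taps(tr$pool1),
       pool2 = pool_windows(tr$pool2))
}

# xm: (n * Lin, Cin); taps: list of row-index vectors, each of length
# n * Lout; w: (k, Cin, Cout) array.
conv1d_forward <- function(xm, taps, w, b) {
  k <- dim(w)[1]; cin <- dim(w)[2]; cout <- dim(w)[3]
  y <- xm[taps[[1]], , drop = FALSE] %*% matrix(w[1, , ], cin, cout)
  if (k > 1L) {
    for (j in 2:k) {
      y <- y + xm[taps[[j]], , drop = FALSE] %*% matrix(w[j, , ], cin, cout)
    }
  }
  sweep(y, 2, b, "+")
}

conv1d_backward <- function(xm, taps, w, gym) {
  k <- dim(w)[1]; cin <- dim(w)[2]; cout <- dim(w)[3]
  gw <- array(0, dim(w))
  gx <- matrix(0, nrow(xm), cin)
  for (j in seq_len(k)) {
    gw[j, , ] <- crossprod(xm[taps[[j]], , drop = FALSE], gym)
    gx[taps[[j]], ] <- gx[taps[[j]], , drop = FALSE] +
      gym %*% t(matrix(w[j, , ], cin, cout))
  }
  list(gw = gw, gb = colSums(gym), gx = gx)
}

pool1d_forward <- function(xm, windows, type) {
  y <- xm[windows[[1]], , drop = FALSE]
  if (type == "average") {
    for (w in seq_along(windows)[-1]) {
      y <- y + xm[windows[[w]], , drop = FALSE]
    }
    return(list(y = y / length(windows), arg = NULL))
  }
  arg <- matrix(1L, nrow(y), ncol(y))
  for (w in seq_along(windows)[-1]) {
    cand <- xm[windows[[w]], , drop = FALSE]
    better <- cand > y
    y[better] <- cand[better]
    arg[better] <- w
  }
  list(y = y, arg = arg)
}

pool1d_backward <- function(cache, windows, type, in_rows, gym) {
  gx <- matrix(0, in_rows, ncol(gym))
  for (w in seq_along(windows)) {
    gx[windows[[w]], ] <- if (type == "average") gym / length(windows)
                          else gym * (cache$arg == w)
  }
  gx
}

# Full forward pass with caches for backprop. x: matrix n x input_length.
cnn_forward_full <- function(model, x, plan = NULL) {
  a <- model$arch; p <- model$params; tr <- model$trace
  n <- nrow(x)
  plan <- plan %||% cnn_plan(a, tr, n)
  xm <- matrix(x, n * a$input_length, a$input_channels)
  c1 <- relu(conv1d_forward(xm, plan$conv1, p$conv1_W, p$conv1_b))
  c2 <- relu(conv1d_forward(c1, plan$conv2, p$conv2_W, p$conv2_b))
  c3 <- relu(conv1d_forward(c2, plan$conv3, p$conv3_W, p$conv3_b))
  skip <- cbind(c1[plan$skip_rows, , drop = FALSE],
                c3[plan$skip_rows, , drop = FALSE])
  p1 <- pool1d_forward(skip, plan$pool1, a$pool)
  c4 <- relu(conv1d_forward(p1$y, plan$conv4, p$conv4_W, p$conv4_b))
  p2 <- pool1d_forward(c4, plan$pool2, a$pool)
  flat <- p2$y
  dim(flat) <- c(n, tr$flatten)  # row i + (l-1)n, channel c -> col (c-1)L+l
  logit <- as.vector(flat %*% p$dense_W) + p$dense_b
  list(xm = xm, c1 = c1, c2 = c2, c3 = c3, skip = skip, p1 = p1,
       c4 = c4, p2 = p2, flat = flat, logit = logit,
       prob = sigmoid(logit), plan = plan)
}

#' Forward pass of the classifier
#'
#' @param model A `"plc_cnn"` or `"plc_cnn_fit"`.
#' @param x Numeric matrix/vector of reduced features, or a descriptor
#'   tibble (label ignored).
#' @param label Label column dropped when `x` is a data frame.
#' @return A vector of probabilities strictly in (0, 1).
#' @export
cnn_forward <- function(model, x, label = "label") {
  model <- as_cnn_model(model)
  if (is.data.frame(x)) {
    x <- table_parts(x, label = label, require_label = FALSE)$x
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$arch$input_length) {
    abort(sprintf("Input has %d columns; the model expects %d.",
                  ncol(x), model$arch$input_length),
          class = "plc_error_dim_mismatch")
  }
  cnn_forward_full(model, x)$prob
}

as_cnn_model <- function(model) {
  if (inherits(model, "plc_cnn_fit")) model$model
  else if (inherits(model, "plc_cnn")) model
  else abort("Expected a 'plc_cnn' or 'plc_cnn_fit' object.",
             class = "plc_error_bad_model")
}

#' Train the skip-connected 1D-CNN
#'
#' Runs exactly `iterations` full-batch Adam steps on the binary
#' cross-entropy loss. Histories (loss and training accuracy per
#' iteration) are logged and runs are bit-reproducible per seed.
#'
#' @param model A `"plc_cnn"` from [build_cnn()]; if `NULL`, a default
#'   architecture sized to the data is built.
#' @param data Reduced training descriptor table with a binary label.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param iterations Full-batch steps (default 2500).
#' @param threshold Probability cut-off used for the logged training
#'   accuracy (default 0.5).
#' @param seed Integer seed (initialization only; training itself is
#'   deterministic).
#' @param engine `"cpp"` (default) runs the compiled Armadillo training
#'   loop; `"r"` runs the pure-R reference implementation of the same
#'   arithmetic (useful for checking the compiled port, and ~50x slower).
#' @param label Label column name.
#' @return An object of class `"plc_cnn_fit"`: trained `model`, `history`
#'   tibble (iteration, loss, accuracy) and the configuration.
#' @export
train_cnn <- function(model = NULL, data, learning_rate = 0.001,
                      iterations = 2500, threshold = 0.5, seed = 1,
                      engine = c("cpp", "r"), label = "label") {
  engine <- match.arg(engine)
  parts <- table_parts(data, label = label)
  if (is.null(parts$y) || !all(parts$y %in% c(0L, 1L))) {
    abort("Training labels must be binary.", class = "plc_error_label_levels")
  }
  stopifnot(iterations >= 1)
  if (is.null(model)) {
    model <- build_cnn(cnn_architecture(input_length = ncol(parts$x)),
                       seed = seed)
  }
  if (model$arch$input_length != ncol(parts$x)) {
    abort("Model input_length does not match the data.",
          class = "plc_error_dim_mismatch")
  }
  x <- parts$x
  y <- as.numeric(parts$y)
  n <- nrow(x)
  a <- model$arch
  params <- model$params
  state <- adam_init(params)
  loss_hist <- acc_hist <- numeric(iterations)
  plan <- cnn_plan(a, model$trace, n)

  if (engine == "cpp") {
    split_w <- function(w) {
      lapply(seq_len(dim(w)[1]),
             function(j) matrix(w[j, , ], dim(w)[2], dim(w)[3]))
    }
    res <- .cnn_train_cpp(
      matrix(x, n * a$input_length, a$input_channels),
      y,
      lapply(paste0("conv", 1:4, "_W"), function(nm) split_w(params[[nm]])),
      lapply(paste0("conv", 1:4, "_b"), function(nm) params[[nm]]),
      as.numeric(params$dense_W), params$dense_b,
      plan, n, model$trace$flatten, a$conv_channels[1],
      a$pool == "average", learning_rate, as.integer(iterations),
      threshold)
    for (i in 1:4) {
      nm <- paste0("conv", i, "_W")
      w <- params[[nm]]
      for (j in seq_len(dim(w)[1])) w[j, , ] <- res$conv_w[[i]][[j]]
      params[[nm]] <- w
      params[[paste0("conv", i, "_b")]] <- as.numeric(res$conv_b[[i]])
    }
    params$dense_W <- matrix(res$dense_W, ncol = 1)
    params$dense_b <- res$dense_b
    model$params <- params
    return(structure(
      list(model = model,
           history = tibble(iteration = seq_len(iterations),
                            loss = as.numeric(res$loss),
                            accuracy = as.numeric(res$accuracy)),
           config = list(learning_rate = learning_rate,
                         iterations = as.integer(iterations),
                         threshold = threshold, seed = as.integer(seed),
                         engine = engine),
           features = parts$features),
      class = "plc_cnn_fit"))
  }

  for (it in seq_len(iterations)) {
    m <- model; m$params <- params
    fw <- cnn_forward_full(m, x, plan = plan)
    # stable BCE from logits
    loss_hist[it] <- mean(softplus(fw$logit) - y * fw$logit)
    acc_hist[it] <- mean((fw$prob >= threshold) == (y == 1))

    glogit <- matrix((fw$prob - y) / n, n, 1)
    grads <- list()
    grads$dense_W <- crossprod(fw$flat, glogit)
    grads$dense_b <- sum(glogit)
    gp2 <- glogit %*% t(params$dense_W)
    dim(gp2) <- dim(fw$p2$y)
    gc4 <- pool1d_backward(fw$p2, plan$pool2, a$pool, nrow(fw$c4), gp2) *
      (fw$c4 > 0)
    bk4 <- conv1d_backward(fw$p1$y, plan$conv4, params$conv4_W, gc4)
    grads$conv4_W <- bk4$gw; grads$conv4_b <- bk4$gb
    gskip <- pool1d_backward(fw$p1, plan$pool1, a$pool, nrow(fw$skip),
                             bk4$gx)
    ch1 <- a$conv_channels[1]
    gc1_skip <- gskip[, seq_len(ch1), drop = FALSE]
    # conv3 may be longer than the skip window; pad gradient with zeros
    gc3 <- matrix(0, nrow(fw$c3), ncol(fw$c3))
    gc3[plan$skip_rows, ] <- gskip[, (ch1 + 1):ncol(gskip), drop = FALSE]
    gc3 <- gc3 * (fw$c3 > 0)
    bk3 <- conv1d_backward(fw$c2, plan$conv3, params$conv3_W, gc3)
    grads$conv3_W <- bk3$gw; grads$conv3_b <- bk3$gb
    gc2 <- bk3$gx * (fw$c2 > 0)
    bk2 <- conv1d_backward(fw$c1, plan$conv2, params$conv2_W, gc2)
    grads$conv2_W <- bk2$gw; grads$conv2_b <- bk2$gb
    gc1 <- bk2$gx
    gc1[plan$skip_rows, ] <- gc1[plan$skip_rows, , drop = FALSE] + gc1_skip
    gc1 <- gc1 * (fw$c1 > 0)
    bk1 <- conv1d_backward(fw$xm, plan$conv1, params$conv1_W, gc1)
    grads$conv1_W <- bk1$gw; grads$conv1_b <- bk1$gb

    grads <- grads[names(params)]
    upd <- adam_step(params, grads, state, lr = learning_rate)
    params <- upd$params
    state <- upd$state
  }
  model$params <- params
  structure(list(model = model,
                 history = tibble(iteration = seq_len(iterations),
                                  loss = loss_hist, accuracy = acc_hist),
                 config = list(learning_rate = learning_rate,
                               iterations = as.integer(iterations),
                               threshold = threshold,
                               seed = as.integer(seed), engine = engine),
                 features = parts$features),
            class = "plc_cnn_fit")
}

#' @export
print.plc_cnn_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<plc_cnn_fit> %d iterations; final loss %.4f, train accuracy %.3f\n",
              n, x$history$loss[n], x$history$accuracy[n]))
  print(x$model)
  invisible(x)
}

#' Predict complex formation for new formulations
#'
#' @param object A `"plc_cnn_fit"`.
#' @param newdata Reduced descriptor table (or matrix) matching the
#'   model's input length.
#' @param threshold Probability cut-off; a row is predicted as a success
#'   when its probability is `>= threshold` (default 0.5).
#' @param label Label column dropped if present.
#' @param ... Unused.
#' @return A tibble with `.prob` (probability of complex formation) and
#'   `.pred` (0/1 label).
#' @export
predict.plc_cnn_fit <- function(object, newdata, threshold = 0.5,
                                label = "label", ...) {
  stopifnot(threshold >= 0, threshold <= 1)
  prob <- cnn_forward(object, newdata, label = label)
  tibble(.prob = prob, .pred = as.integer(prob >= threshold))
}
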