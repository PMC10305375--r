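#' Specification for a synthetic formulation dataset
#'
#' Describes a class-conditional Gaussian generator that emulates the
#' statistical structure of curated drug–phospholipid formulation tables:
#' a small imbalanced training split, a handful of informative descriptors,
#' many pure-noise descriptors, large per-column scale disparities (raw
#' units ranging from molecular weights in the hundreds of Daltons to log
#' partition coefficients near zero), and degenerate constant columns such
#' as a lipid heavy-atom count that is identical for every formulation.
#'
#' Within each class the informative descriptors are Gaussian with a
#' covariance shared by both classes (equicorrelated at
#' `informative_correlation`, scale `noise_sd`); the class means are
#' separated by `class_separation` in Mahalanobis distance, which fixes the
#' achievable Bayes accuracy in closed form (see [bayes_accuracy()]), with
#' the shift laid along the shared factor. Non-informative
#' descriptors are label-independent Gaussian noise. Each non-constant
#' column is then affinely mapped into its configured `(offset, range)`
#' interval; a per-feature monotone affine map leaves the Bayes accuracy
#' unchanged.
#'
#' @param n_train Number of training rows (default 272).
#' @param n_test Number of test rows (default 69).
#' @param n_success,n_failure Training class counts (defaults 179 / 93);
#'   must sum to `n_train`.
#' @param n_features Total descriptor count (default 46).
#' @param n_informative Number of class-informative descriptors (default 10).
#' @param class_separation Mahalanobis distance between the class means on
#'   the informative subspace (default 4; `>= 0`).
#' @param informative_correlation Common within-class correlation of the
#'   informative descriptors (default 0.7, in \[0, 1)). Descriptors of the
#'   same molecule are strongly correlated in real formulation tables
#'   (molecular weight, heavy-atom count and complexity all track size);
#'   the class shift is placed along this shared factor, which is what
#'   makes the two classes appear as dense clusters in low-dimensional
#'   projections. The Mahalanobis separation — and therefore the Bayes
#'   accuracy — does not depend on this value.
#' @param feature_scales Either `NULL` for raw (unscaled) features or a data
#'   frame with columns `feature` (index), `offset`, `range` giving the
#'   target interval per non-constant feature. [default_feature_scales()]
#'   supplies a molecular-weight-like column on \[200, 1100\], a logP-like
#'   column on \[-2, 8\], and unit intervals elsewhere.
#' @param n_constant Number of zero-variance descriptors (default 1).
#' @param constant_value Value filling the constant descriptors (default 52,
#'   a lipid heavy-atom count).
#' @param noise_sd Within-class standard deviation (default 1; `> 0`).
#' @param seed Integer seed; the generator is bit-reproducible per seed.
#' @return An object of class `"synthetic_spec"` (a list of the arguments).
#' @seealso [simulate_formulations()], [bayes_accuracy()]
#' @export
synthetic_spec <- function(n_train = 272, n_test = 69,
                           n_success = 179, n_failure = 93,
                           n_features = 46, n_informative = 10,
                           class_separation = 4,
                           informative_correlation = 0.7,
                           feature_scales = default_feature_scales(n_features),
                           n_constant = 1, constant_value = 52,
                           noise_sd = 1, seed = 1) {
  spec <- list(n_train = as.integer(n_train), n_test = as.integer(n_test),
               n_success = as.integer(n_success),
               n_failure = as.integer(n_failure),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               class_separation = as.numeric(class_separation),
               informative_correlation = as.numeric(informative_correlation),
               feature_scales = feature_scales,
               n_constant = as.integer(n_constant),
               constant_value = as.numeric(constant_value),
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed))
  if (spec$n_success + spec$n_failure != spec$n_train) {
    abort("n_success + n_failure must equal n_train.",
          class = "plc_error_infeasible_spec")
  }
  if (spec$n_informative + spec$n_constant > spec$n_features) {
    abort("n_informative + n_constant must not exceed n_features.",
          class = "plc_error_infeasible_spec")
  }
  if (spec$class_separation < 0 || spec$noise_sd <= 0) {
    abort("class_separation must be >= 0 and noise_sd > 0.",
          class = "plc_error_infeasible_spec")
  }
  if (spec$informative_correlation < 0 || spec$informative_correlation >= 1) {
    abort("informative_correlation must lie in [0, 1).",
          class = "plc_error_infeasible_spec")
  }
  structure(spec, class = "synthetic_spec")
}

#' Default per-feature scale presets
#'
#' Feature 1 is scaled to \[200, 1100\] (a molecular-weight analog), feature
#' 2 to \[-2, 8\] (a logP analog), and all remaining features to \[0, 1\].
#'
#' @param n_features Number of descriptors.
#' @return A tibble with columns `feature`, `offset`, `range`.
#' @export
default_feature_scales <- function(n_features) {
  offset <- rep(0, n_features)
  range <- rep(1, n_features)
  if (n_features >= 1) { offset[1] <- 200; range[1] <- 900 }
  if (n_features >= 2) { offset[2] <- -2; range[2] <- 10 }
  tibble(feature = seq_len(n_features), offset = offset, range = range)
}

# Deterministic descriptor names + group map mirroring the api / lipid /
# solvent / condition block structure of curated formulation tables. The
# constant columns land in the lipid block (heavy-atom-count analogs).
synthetic_feature_names <- function(n_features, n_constant) {
  n_var <- n_features - n_constant
  # proportions loosely matching 11/18/13/2 out of 44 listed descriptors
  n_api <- max(1L, round(n_var * 11 / 44))
  n_cond <- if (n_var >= 4L) 2L else 0L
  n_solvent <- max(0L, round(n_var * 13 / 44))
  n_lipid <- n_var - n_api - n_solvent - n_cond
  grp <- c(rep("api", n_api), rep("lipid", n_lipid),
           rep("solvent", n_solvent), rep("condition", n_cond),
           rep("lipid", n_constant))
  nm <- character(n_features)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    nm[idx] <- sprintf("%s_%02d", g, seq_along(idx))
  }
  if (n_constant > 0) {
    nm[(n_var + 1):n_features] <- sprintf("lipid_heavy_atoms_%02d",
                                          seq_len(n_constant))
  }
  list(names = nm, groups = stats::setNames(grp, nm))
}

#' Generate a synthetic formulation dataset
#'
#' Draws a train and a test descriptor table from the class-conditional
#' Gaussian model described in [synthetic_spec()]. Training class counts
#' match the spec exactly; test labels are drawn from the training prior
#' and test features from the same class-conditional distributions.
#'
#' The informative descriptors occupy the first `n_informative` non-constant
#' columns; the constant descriptors occupy the last `n_constant` columns
#' and are exactly `constant_value` in both splits. Affine scaling into the
#' configured intervals uses the pooled min/max of both splits, so every
#' sample range lies inside its `(offset, offset + range)` interval.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `"plc_dataset"` with elements `train`, `test`
#'   (descriptor tibbles carrying a `"groups"` attribute),
#'   `bayes_accuracy` (closed-form optimum, see [bayes_accuracy()]) and
#'   `spec`.
#' @examples
#' ds <- simulate_formulations(synthetic_spec(seed = 7))
#' class_counts(ds$train)
#' @export
simulate_formulations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_features
  m <- spec$n_informative
  n_const <- spec$n_constant
  n_var <- p - n_const
  naming <- synthetic_feature_names(p, n_const)

  # Informative block: within-class covariance
  # noise_sd^2 * [(1 - rho) I + rho J] (equicorrelated; shared by both
  # classes), class-mean shift of c on every informative feature, i.e.
  # along the common factor. c is chosen so the Mahalanobis distance
  # between the class means equals class_separation:
  # c = d * noise_sd * sqrt((1 - rho + rho m) / m).
  rho <- spec$informative_correlation
  shift <- if (m > 0) {
    spec$class_separation * spec$noise_sd * sqrt((1 - rho + rho * m) / m)
  } else 0

  draw_split <- function(y) {
    n <- length(y)
    x <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
    if (m > 0 && n > 0) {
      info <- sqrt(1 - rho) * x[, seq_len(m), drop = FALSE] +
        tcrossprod(rnorm(n, sd = spec$noise_sd), rep(sqrt(rho), m))
      x[, seq_len(m)] <- info + shift * y
    }
    if (n_const > 0 && n > 0) {
      x[, (n_var + 1):p] <- spec$constant_value
    }
    x
  }

  out <- with_seed(spec$seed, {
    y_train <- sample(rep(c(1L, 0L), c(spec$n_success, spec$n_failure)))
    p1 <- spec$n_success / spec$n_train
    y_test <- as.integer(runif(spec$n_test) < p1)
    x_train <- draw_split(y_train)
    x_test <- draw_split(y_test)
    list(y_train = y_train, y_test = y_test,
         x_train = x_train, x_test = x_test)
  })

  if (!is.null(spec$feature_scales)) {
    sc <- spec$feature_scales
    for (j in seq_len(n_var)) {
      row <- which(sc$feature == j)
      if (length(row) != 1L) next
      pooled <- c(out$x_train[, j], out$x_test[, j])
      lo <- min(pooled); hi <- max(pooled)
      if (hi > lo) {
        f <- function(v) sc$offset[row] + sc$range[row] * (v - lo) / (hi - lo)
        out$x_train[, j] <- f(out$x_train[, j])
        out$x_test[, j] <- f(out$x_test[, j])
      }
    }
  }

  train <- rebuild_table(out$x_train, out$y_train, naming$names)
  test <- rebuild_table(out$x_test, out$y_test, naming$names)
  attr(train, "groups") <- naming$groups
  attr(test, "groups") <- naming$groups
  structure(list(train = train, test = test,
                 bayes_accuracy = bayes_accuracy(spec), spec = spec),
            class = "plc_dataset")
}

#' Closed-form Bayes accuracy of a synthetic spec
#'
#' For two Gaussian classes sharing covariance, with Mahalanobis distance
#' `d` between the means and priors `(pi1, pi0)` taken from the training
#' class counts, the optimal (LDA) rule achieves accuracy
#' `pi1 * Phi(d/2 + log(pi1/pi0)/d) + pi0 * Phi(d/2 - log(pi1/pi0)/d)`;
#' with `d = 0` no rule beats the larger prior. This bounds the expected
#' performance of any classifier trained on data from the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A single number in \[0.5, 1\].
#' @examples
#' # equal priors, separation 2 -> Phi(1)
#' sp <- synthetic_spec(n_train = 200, n_success = 100, n_failure = 100,
#'                      class_separation = 2)
#' bayes_accuracy(sp)
#' @export
bayes_accuracy <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pi1 <- spec$n_success / spec$n_train
  pi0 <- 1 - pi1
  d <- spec$class_separation
  if (spec$n_informative == 0 || d == 0) {
    return(max(pi1, pi0))
  }
  shift <- log(pi1 / pi0) / d
  pi1 * pnorm(d / 2 + shift) + pi0 * pnorm(d / 2 - shift)
}
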