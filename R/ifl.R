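# Inspiratory flow limitation (IFL): seven shape features of the
# inspiratory airflow and a small 7-14-14-1 sigmoid network separating
# flattened (flow-limited) from rounded inspirations. The network is
# hand-written (two hidden layers; trained by BFGS on cross-entropy) and
# deterministic given the seed.

#' Shape features of an inspiratory airflow segment
#'
#' Seven features summarizing flow limitation: number of peaks, peak
#' amplitude normalized by the 2-minute baseline, scooping index (1 minus
#' the mean flow over the middle half of inspiration relative to peak),
#' kurtosis and skewness of the flow-versus-time curve, deviation index
#' (RMS deviation from the best-fit half-sine, normalized by peak), and
#' flattening index (fraction of the inspiration within 15% of peak).
#' A half-sine inspiration has flattening near 0; a plateau-clipped one
#' near 1 with a larger scooping index.
#'
#' @param insp_flow inspiratory airflow samples (nonnegative ramp up/down).
#' @param baseline_amp 2-minute pre-event peak-amplitude baseline used to
#'   normalize the peak.
#' @return object of class `ifl_features`: named numeric vector of length 7
#'   (`peak_count`, `norm_peak_amp`, `scooping_index`, `kurtosis`,
#'   `deviation_index`, `flattening_index`, `skewness`), all finite. A flat
#'   segment yields the features of a flat template with attribute
#'   `degenerate = TRUE`.
#' @export
extract_ifl_features <- function(insp_flow, baseline_amp = 1) {
  n <- length(insp_flow)
  if (n < 8) stop("extract_ifl_features: inspiration shorter than 8 samples")
  x <- as.numeric(insp_flow)
  pk <- max(x)
  degenerate <- !is.finite(pk) || pk <= .Machine$double.eps ||
    stats::sd(x) <= .Machine$double.eps
  if (degenerate) {
    out <- c(peak_count = 0, norm_peak_amp = 0, scooping_index = 0,
             kurtosis = 0, deviation_index = 0, flattening_index = 1,
             skewness = 0)
    class(out) <- "ifl_features"
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # peaks: strict local maxima above 20% of the global peak
  i <- 2:(n - 1)
  loc <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > 0.2 * pk]
  # suppress plateau runs: count maximal runs of consecutive indices
  peak_count <- if (!length(loc)) 1 else sum(diff(c(-10L, loc)) > 1L)

  mid <- x[ceiling(n * 0.25):floor(n * 0.75)]
  scooping <- 1 - mean(mid) / pk

  m <- mean(x); s <- stats::sd(x)
  z <- (x - m) / s
  kurt <- mean(z^4) - 3
  skew <- mean(z^3)

  u <- (seq_len(n) - 0.5) / n
  half_sine <- sin(pi * u)
  a_hat <- sum(x * half_sine) / sum(half_sine^2)
  deviation <- sqrt(mean((x - a_hat * half_sine)^2)) / pk

  flattening <- mean(x >= 0.85 * pk)

  out <- c(peak_count = peak_count,
           norm_peak_amp = pk / max(baseline_amp, .Machine$double.eps),
           scooping_index = scooping, kurtosis = kurt,
           deviation_index = deviation, flattening_index = flattening,
           skewness = skew)
  class(out) <- "ifl_features"
  attr(out, "degenerate") <- FALSE
  out
}

# ---- minimal 7-14-14-1 multilayer perceptron -------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_unpack <- function(w, sizes) {
  out <- list(); off <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nin <- sizes[l]; nout <- sizes[l + 1L]
    W <- matrix(w[off + seq_len(nin * nout)], nin, nout); off <- off + nin * nout
    b <- w[off + seq_len(nout)]; off <- off + nout
    out[[l]] <- list(W = W, b = b)
  }
  out
}

mlp_forward <- function(layers, X) {
  a <- X
  for (l in seq_along(layers)) {
    a <- sigmoid(sweep(a %*% layers[[l]]$W, 2, layers[[l]]$b, "+"))
  }
  a
}

# forward pass keeping activations, for backpropagation
mlp_activations <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(layers))
    acts[[l + 1L]] <- sigmoid(sweep(acts[[l]] %*% layers[[l]]$W, 2,
                                    layers[[l]]$b, "+"))
  acts
}

# gradient of the regularized cross-entropy wrt the packed weight vector
mlp_grad <- function(w, sizes, X, y, lambda) {
  layers <- mlp_unpack(w, sizes)
  acts <- mlp_activations(layers, X)
  n <- nrow(X)
  L <- length(layers)
  # with sigmoid output and cross-entropy, delta at the output is (p - y)/n
  delta <- (acts[[L + 1L]] - y) / n
  g <- numeric(length(w))
  offs <- cumsum(c(0L, (sizes[-length(sizes)] + 1L) * sizes[-1L]))
  for (l in L:1) {
    gW <- crossprod(acts[[l]], delta) + 2 * lambda * layers[[l]]$W
    gb <- colSums(delta) + 2 * lambda * layers[[l]]$b
    g[(offs[l] + 1L):offs[l + 1L]] <- c(as.vector(gW), gb)
    if (l > 1) {
      a <- acts[[l]]
      delta <- (delta %*% t(layers[[l]]$W)) * a * (1 - a)
    }
  }
  g
}

#' Train the inspiratory-flow-limitation classifier
#'
#' Fits the 7-14-14-1 sigmoid network on a labelled feature corpus by
#' minimizing cross-entropy (L2-regularized) with BFGS. Features are
#' standardized internally; training is deterministic given `seed`.
#'
#' @param features numeric matrix, one row per example, 7 columns in the
#'   order of [extract_ifl_features()] (a list of `ifl_features` is also
#'   accepted).
#' @param labels logical or 0/1 vector, `TRUE` = flow-limited.
#' @param seed integer seed for the weight initialization.
#' @param maxit BFGS iteration cap.
#' @param lambda L2 penalty on the weights.
#' @return object of class `ifl_model`.
#' @export
train_ifl_model <- function(features, labels, seed = 42L, maxit = 300,
                            lambda = 1e-4) {
  if (is.list(features) && !is.matrix(features))
    features <- do.call(rbind, features)
  X <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(ncol(X) == 7, nrow(X) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("train_ifl_model: corpus must contain both classes")
  if (max(n1, n0) / min(n1, n0) > 10)
    stop("train_ifl_model: class imbalance exceeds 10:1")

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  sizes <- c(7L, 14L, 14L, 1L)
  n_par <- sum((sizes[-length(sizes)] + 1L) * sizes[-1L])
  set.seed(seed)
  w0 <- stats::rnorm(n_par, 0, 0.5)

  loss <- function(w) {
    p <- mlp_forward(mlp_unpack(w, sizes), Xs)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p)) + lambda * sum(w^2)
  }
  grad <- function(w) mlp_grad(w, sizes, Xs, y, lambda)
  fit <- stats::optim(w0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  structure(list(layers = mlp_unpack(fit$par, sizes), sizes = sizes,
                 mu = mu, sd = sdv, value = fit$value, seed = seed),
            class = "ifl_model")
}

#' @export
print.ifl_model <- function(x, ...) {
  cat("<ifl_model> 7-14-14-1 sigmoid network, training loss",
      format(x$value, digits = 4), "\n")
  invisible(x)
}

#' Classify an inspiration as flow-limited
#'
#' @param features an `ifl_features` vector (or 7-column matrix for a
#'   batch).
#' @param model a trained `ifl_model`.
#' @return logical: `TRUE` when the network output exceeds 0.5.
#' @export
classify_ifl <- function(features, model) {
  if (is.null(model) || !inherits(model, "ifl_model"))
    stop("classify_ifl: model not trained; see train_ifl_model()")
  X <- if (is.matrix(features)) features else matrix(as.numeric(features), 1)
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  as.vector(mlp_forward(model$layers, Xs)) > 0.5
}

#' Synthetic corpus of inspiratory shapes for IFL training
#'
#' Generates rounded (half-sine, jittered) and flow-limited
#' (plateau-clipped, jittered) inspirations, extracts the seven features
#' of each, and returns features with labels. Used to train the default
#' classifier in the absence of a scored clinical corpus.
#'
#' @param n_per_class examples per class.
#' @param seed integer seed.
#' @return list with `features` (matrix), `labels` (logical).
#' @export
ifl_training_corpus <- function(n_per_class = 400L, seed = 42L) {
  set.seed(seed)
  one <- function(limited) {
    n <- sample(16:40, 1)
    u <- (seq_len(n) - 0.5) / n
    # amplitudes span normal breaths down to deep hypopneas in both
    # classes, so the normalized peak is not a class shortcut
    a <- exp(stats::rnorm(1, -0.35, 0.4))
    x <- a * sin(pi * u)
    if (limited) {
      clip <- stats::runif(1, 0.55, 0.8)
      x <- pmin(x, clip * a) * (1 + 0.3 * (1 - clip))
      # mild mid-inspiratory scooping typical of limited breaths
      x <- x * (1 - stats::runif(1, 0, 0.15) * sin(pi * u)^2)
    }
    x <- x + stats::rnorm(n, 0, 0.02 * a)
    x[x < 0] <- 0
    extract_ifl_features(x, baseline_amp = 1)
  }
  feats <- rbind(
    do.call(rbind, lapply(seq_len(n_per_class), function(i) one(FALSE))),
    do.call(rbind, lapply(seq_len(n_per_class), function(i) one(TRUE))))
  list(features = feats,
       labels = rep(c(FALSE, TRUE), each = n_per_class))
}

#' Train the default IFL classifier from the synthetic corpus
#'
#' @param n_per_class examples per class.
#' @param seed integer seed (corpus and initialization).
#' @return a trained `ifl_model`.
#' @export
default_ifl_model <- function(n_per_class = 400L, seed = 42L) {
  corpus <- ifl_training_corpus(n_per_class, seed)
  train_ifl_model(corpus$features, corpus$labels, seed = seed)
}
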