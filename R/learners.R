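#' Leaky rectified linear unit
#'
#' `x` for positive inputs, `alpha * x` otherwise; `alpha` controls the
#' leakiness of the negative branch.
#'
#' @param x numeric vector/matrix.
#' @param alpha negative-branch slope.
#' @return same shape as `x`.
#' @export
leaky_relu <- function(x, alpha = 0.01) {
  ifelse(x > 0, x, alpha * x)
}

.lrelu_grad <- function(x, alpha) ifelse(x > 0, 1, alpha)
.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Learner configuration
#'
#' @param arch one of `"mlp"`, `"lstm"`, `"bilstm"`.
#' @param input_dim number of input features.
#' @param hidden_size width of the hidden layers (default 350, the
#'   production size; tests use small nets).
#' @param alpha LeakyReLU negative slope (default 0.01).
#' @param window sequence length consumed by the recurrent architectures
#'   (default 30 timesteps).
#' @param seed seed for the random weight initialization.
#' @return a `learner_config` object.
#' @export
learner_config <- function(arch = c("mlp", "lstm", "bilstm"), input_dim,
                           hidden_size = 350L, alpha = 0.01, window = 30L,
                           seed = 1L) {
  arch <- match.arg(arch)
  if (hidden_size < 1) stopf("`hidden_size` must be >= 1")
  if (alpha <= 0 || alpha > 1) stopf("`alpha` must be in (0, 1]")
  structure(list(arch = arch, input_dim = as.integer(input_dim),
                 hidden_size = as.integer(hidden_size), alpha = alpha,
                 window = as.integer(window), seed = as.integer(seed)),
            class = "learner_config")
}

# one uniformly initialized weight matrix with fan-in scaling
.init_w <- function(nin, nout) {
  s <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

.param_template <- function(cfg) {
  d <- cfg$input_dim; h <- cfg$hidden_size
  switch(cfg$arch,
    mlp = list(W1 = c(d, h), b1 = h, W2 = c(h, h), b2 = h, W3 = c(h, 1), b3 = 1),
    lstm = list(Wx = c(d, 4 * h), Wh = c(h, 4 * h), b = 4 * h,
                W2 = c(h, h), b2 = h, W3 = c(h, 1), b3 = 1),
    bilstm = list(Wxf = c(d, 4 * h), Whf = c(h, 4 * h), bf = 4 * h,
                  Wxb = c(d, 4 * h), Whb = c(h, 4 * h), bb = 4 * h,
                  W2 = c(2 * h, h), b2 = h, W3 = c(h, 1), b3 = 1))
}

#' Build a differentiable regressor
#'
#' `"mlp"` is three weight layers (input -> hidden -> hidden -> scalar) with
#' LeakyReLU between them and consumes instantaneous feature rows. `"lstm"`
#' and `"bilstm"` replace the first layer with a recurrent cell consuming a
#' `(window, features)` sequence; the prediction head (the remaining two
#' dense layers) is identical. The recurrent output is the final hidden
#' state (forward direction) or the concatenated final states of the two
#' directions (bidirectional). Weights are uniform with fan-in scaling,
#' biases zero except the LSTM forget gate (1); initialization is a pure
#' function of `cfg$seed`.
#'
#' @param cfg a [learner_config()].
#' @return a `learner`: list with `config` and `params` (named arrays).
#' @export
build_learner <- function(cfg) {
  stopifnot(inherits(cfg, "learner_config"))
  h <- cfg$hidden_size
  params <- with_seed(cfg$seed, {
    tpl <- .param_template(cfg)
    p <- list()
    for (nm in names(tpl)) {
      dd <- tpl[[nm]]
      p[[nm]] <- if (length(dd) == 2) .init_w(dd[1], dd[2]) else numeric(dd)
    }
    # forget-gate bias 1 stabilizes early recurrent training
    gate_bias <- function(b) { b[(h + 1):(2 * h)] <- 1; b }
    if (cfg$arch == "lstm") p$b <- gate_bias(p$b)
    if (cfg$arch == "bilstm") { p$bf <- gate_bias(p$bf); p$bb <- gate_bias(p$bb) }
    p
  })
  structure(list(config = cfg, params = params), class = "learner")
}

#' Flatten / restore learner parameters
#'
#' The flat vector is the concatenation of the parameter arrays in a fixed
#' order; `set_params` is the exact inverse of `get_params`.
#'
#' @param learner a `learner`.
#' @return `get_params`: numeric vector; `set_params`: the updated learner.
#' @export
get_params <- function(learner) {
  unlist(learner$params, use.names = FALSE)
}

#' @rdname get_params
#' @param theta flat parameter vector of length `n_params(learner)`.
#' @export
set_params <- function(learner, theta) {
  pos <- 0L
  for (nm in names(learner$params)) {
    p <- learner$params[[nm]]
    n <- length(p)
    v <- theta[(pos + 1L):(pos + n)]
    learner$params[[nm]] <- if (is.matrix(p)) matrix(v, nrow(p), ncol(p)) else v
    pos <- pos + n
  }
  if (pos != length(theta)) stopf("parameter vector has wrong length")
  learner
}

#' @rdname get_params
#' @export
n_params <- function(learner) length(get_params(learner))

# ---- forward passes (with caches for backprop) ----

.fwd_head <- function(p, h1, alpha) {
  a2 <- sweep(h1 %*% p$W2, 2, p$b2, `+`)
  h2 <- leaky_relu(a2, alpha)
  yhat <- drop(h2 %*% p$W3) + p$b3
  list(a2 = a2, h2 = h2, yhat = yhat, h1 = h1)
}

.fwd_mlp <- function(p, x, alpha) {
  a1 <- sweep(x %*% p$W1, 2, p$b1, `+`)
  h1 <- leaky_relu(a1, alpha)
  c(list(a1 = a1, x = x), .fwd_head(p, h1, alpha))
}

# one direction of an LSTM over x (n, T, d); returns final hidden state and
# the per-step cache needed for backpropagation through time
.fwd_lstm_dir <- function(Wx, Wh, b, x, reverse = FALSE) {
  n <- dim(x)[1]; T_ <- dim(x)[2]; h <- nrow(Wh)
  H <- matrix(0, n, h); C <- matrix(0, n, h)
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  cache <- vector("list", T_)
  for (k in seq_along(steps)) {
    t <- steps[k]
    xt <- matrix(x[, t, ], n, dim(x)[3])
    z <- sweep(xt %*% Wx + H %*% Wh, 2, b, `+`)
    i <- .sigmoid(z[, 1:h, drop = FALSE])
    f <- .sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- .sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    C_new <- f * C + i * g
    tc <- tanh(C_new)
    cache[[k]] <- list(xt = xt, H_prev = H, C_prev = C, i = i, f = f, g = g,
                       o = o, tc = tc)
    C <- C_new
    H <- o * tc
  }
  list(H = H, cache = cache)
}

.fwd_learner <- function(learner, x) {
  p <- learner$params; cfg <- learner$config
  switch(cfg$arch,
    mlp = .fwd_mlp(p, x, cfg$alpha),
    lstm = {
      d1 <- .fwd_lstm_dir(p$Wx, p$Wh, p$b, x)
      c(list(dir_f = d1), .fwd_head(p, d1$H, cfg$alpha))
    },
    bilstm = {
      d1 <- .fwd_lstm_dir(p$Wxf, p$Whf, p$bf, x)
      d2 <- .fwd_lstm_dir(p$Wxb, p$Whb, p$bb, x, reverse = TRUE)
      c(list(dir_f = d1, dir_b = d2), .fwd_head(p, cbind(d1$H, d2$H), cfg$alpha))
    })
}

#' Forward evaluation of a learner
#'
#' @param learner a `learner`.
#' @param x matrix `(n, features)` for the MLP, array
#'   `(n, window, features)` for recurrent architectures.
#' @return numeric vector of predictions.
#' @export
predict_learner <- function(learner, x) {
  .check_input_shape(learner, x)
  .fwd_learner(learner, x)$yhat
}

.check_input_shape <- function(learner, x) {
  cfg <- learner$config
  if (cfg$arch == "mlp") {
    if (!is.matrix(x) || ncol(x) != cfg$input_dim)
      stopf("schema error: mlp expects a (n, %d) matrix", cfg$input_dim)
  } else {
    if (length(dim(x)) != 3 || dim(x)[3] != cfg$input_dim)
      stopf("schema error: %s expects a (n, window, %d) array",
            cfg$arch, cfg$input_dim)
  }
}

# BPTT through one LSTM direction; dH is the gradient at the final hidden
# state. Returns parameter gradients (same shapes as Wx, Wh, b).
.bwd_lstm_dir <- function(Wx, Wh, cache, dH) {
  T_ <- length(cache)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(ncol(Wx))
  dC <- matrix(0, nrow(dH), ncol(dH))
  for (k in rev(seq_len(T_))) {
    cc <- cache[[k]]
    do_ <- dH * cc$tc
    dpre_o <- do_ * cc$o * (1 - cc$o)
    dC <- dC + dH * cc$o * (1 - cc$tc^2)
    di <- dC * cc$g
    dpre_i <- di * cc$i * (1 - cc$i)
    dg <- dC * cc$i
    dpre_g <- dg * (1 - cc$g^2)
    df <- dC * cc$C_prev
    dpre_f <- df * cc$f * (1 - cc$f)
    dZ <- cbind(dpre_i, dpre_f, dpre_g, dpre_o)
    dWx <- dWx + crossprod(cc$xt, dZ)
    dWh <- dWh + crossprod(cc$H_prev, dZ)
    db <- db + colSums(dZ)
    dH <- dZ %*% t(Wh)
    dC <- dC * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

#' Mean-squared-error loss and its gradient
#'
#' Returns the MSE over the batch and the exact gradient with respect to the
#' flat parameter vector (same ordering as [get_params()]); gradients are
#' hand-derived backpropagation, verified against central finite differences
#' in the test suite.
#'
#' @param learner a `learner`.
#' @param x inputs (see [predict_learner()]).
#' @param y numeric target vector of length `n`.
#' @return list with `loss` (scalar MSE) and `grad` (flat numeric vector).
#' @export
loss_and_grad <- function(learner, x, y) {
  .check_input_shape(learner, x)
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  if (length(y) != n) stopf("schema error: %d inputs vs %d targets", n, length(y))
  p <- learner$params; cfg <- learner$config; alpha <- cfg$alpha
  fw <- .fwd_learner(learner, x)
  res <- fw$yhat - y
  loss <- mean(res^2)
  r <- matrix(2 * res / n, ncol = 1)
  g <- list()
  g$W3 <- crossprod(fw$h2, r)
  g$b3 <- sum(r)
  dh2 <- r %*% t(p$W3)
  da2 <- dh2 * .lrelu_grad(fw$a2, alpha)
  g$W2 <- crossprod(fw$h1, da2)
  g$b2 <- colSums(da2)
  dh1 <- da2 %*% t(p$W2)
  if (cfg$arch == "mlp") {
    da1 <- dh1 * .lrelu_grad(fw$a1, alpha)
    g$W1 <- crossprod(fw$x, da1)
    g$b1 <- colSums(da1)
    flat <- c(g$W1, g$b1, g$W2, g$b2, g$W3, g$b3)
  } else if (cfg$arch == "lstm") {
    gb <- .bwd_lstm_dir(p$Wx, p$Wh, fw$dir_f$cache, dh1)
    flat <- c(gb$dWx, gb$dWh, gb$db, g$W2, g$b2, g$W3, g$b3)
  } else {
    h <- cfg$hidden_size
    gf <- .bwd_lstm_dir(p$Wxf, p$Whf, fw$dir_f$cache, dh1[, 1:h, drop = FALSE])
    gb <- .bwd_lstm_dir(p$Wxb, p$Whb, fw$dir_b$cache,
                        dh1[, (h + 1):(2 * h), drop = FALSE])
    flat <- c(gf$dWx, gf$dWh, gf$db, gb$dWx, gb$dWh, gb$db,
              g$W2, g$b2, g$W3, g$b3)
  }
  list(loss = loss, grad = flat)
}

#' Save / load a learner checkpoint
#'
#' Checkpoints are portable JSON archives holding the configuration and the
#' flat parameter vector at full precision.
#'
#' @param learner a `learner`.
#' @param path file path (`.json`).
#' @export
save_learner <- function(learner, path) {
  jsonlite::write_json(list(config = unclass(learner$config),
                            theta = get_params(learner)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_learner
#' @export
load_learner <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- learner_config(arch = x$config$arch, input_dim = x$config$input_dim,
                        hidden_size = x$config$hidden_size,
                        alpha = x$config$alpha, window = x$config$window,
                        seed = x$config$seed)
  set_params(build_learner(cfg), as.numeric(x$theta))
}
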