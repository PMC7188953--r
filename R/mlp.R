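# Small tanh multilayer perceptron (default 20-10-7-5-2) trained by the
# Levenberg-Marquardt algorithm with validation-based early stopping.

#' Initialize the classifier network
#'
#' Weights and biases are drawn uniformly from `[-0.5, 0.5]` using the
#' seeded generator; the same seed always yields the same network. All
#' hidden and output nodes use the hyperbolic tangent, so outputs are
#' bounded in `(-1, 1)`.
#'
#' @param seed integer initializer seed.
#' @param layer_sizes node counts per layer, input first (default
#'   `c(20, 10, 7, 5, 2)`).
#' @return An object of class `mlp_net` with `W` (list of out x in weight
#'   matrices), `b` (bias vectors), `layer_sizes` and `seed`.
#' @export
init_network <- function(seed, layer_sizes = c(20L, 10L, 7L, 5L, 2L)) {
  L <- length(layer_sizes) - 1L
  pars <- with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::runif(layer_sizes[l + 1] * layer_sizes[l],
                                    -0.5, 0.5),
                       layer_sizes[l + 1], layer_sizes[l])
      b[[l]] <- stats::runif(layer_sizes[l + 1], -0.5, 0.5)
    }
    list(W = W, b = b)
  })
  structure(list(W = pars$W, b = pars$b,
                 layer_sizes = as.integer(layer_sizes),
                 seed = as.integer(seed), record = NULL),
            class = "mlp_net")
}

n_params <- function(net) {
  sum(vapply(seq_along(net$W), function(l)
    length(net$W[[l]]) + length(net$b[[l]]), 0))
}

params_to_vector <- function(net) {
  unlist(lapply(seq_along(net$W), function(l) c(net$W[[l]], net$b[[l]])))
}

vector_to_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}

# X: n x p. Returns activations per layer (a[[1]] = input) and pre-tanh z.
forward_pass <- function(net, X) {
  L <- length(net$W)
  a <- vector("list", L + 1L); z <- vector("list", L)
  a[[1]] <- X
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% t(net$W[[l]]), 2, net$b[[l]], `+`)
    a[[l + 1]] <- tanh(z[[l]])
  }
  list(a = a, z = z)
}

#' Forward evaluation of the network
#'
#' @param net an [init_network()] (possibly trained) model.
#' @param x numeric vector of `layer_sizes[1]` feature values, or a matrix
#'   with one row per observation.
#' @return A length-2 output vector in `(-1, 1)^2` (or an `n x 2` matrix).
#' @export
forward <- function(net, x) {
  if (is.null(dim(x))) {
    if (length(x) != net$layer_sizes[1])
      stopf("expected %d inputs, got %d", net$layer_sizes[1], length(x))
    drop(forward_pass(net, matrix(x, 1))$a[[length(net$W) + 1]])
  } else {
    if (ncol(x) != net$layer_sizes[1])
      stopf("expected %d inputs, got %d", net$layer_sizes[1], ncol(x))
    forward_pass(net, x)$a[[length(net$W) + 1]]
  }
}

# Jacobian of all outputs w.r.t. all parameters.
# Returns J ((n*K) x P, rows ordered sample-major: sample 1 outputs 1..K,
# sample 2 outputs 1..K, ...) and the n x K output matrix.
mlp_jacobian <- function(net, X) {
  L <- length(net$W)
  fp <- forward_pass(net, X)
  n <- nrow(X); K <- net$layer_sizes[length(net$layer_sizes)]
  P <- n_params(net)
  J <- matrix(0, n * K, P)
  dz <- lapply(fp$z, function(zz) 1 - tanh(zz)^2)   # tanh'
  for (i in seq_len(n)) {
    for (o in seq_len(K)) {
      delta <- vector("list", L)
      dL <- numeric(K); dL[o] <- dz[[L]][i, o]
      delta[[L]] <- dL
      for (l in rev(seq_len(L - 1)))
        delta[[l]] <- drop(t(net$W[[l + 1]]) %*% delta[[l + 1]]) * dz[[l]][i, ]
      row <- unlist(lapply(seq_len(L), function(l)
        c(outer(delta[[l]], fp$a[[l]][i, ]), delta[[l]])))
      J[(i - 1L) * K + o, ] <- row
    }
  }
  list(J = J, Y = fp$a[[L + 1]])
}

#' Train the network by Levenberg-Marquardt
#'
#' Fits the tanh network to two-node targets in the +/-1 encoding (positive
#' class `(+1, -1)`, negative `(-1, +1)`). Each epoch builds the Jacobian
#' of all residuals with respect to all parameters and solves the damped
#' normal equations `(J'J + mu I) delta = J' e`; a step is accepted only if
#' the training MSE decreases (then `mu` shrinks by `mu_factor`), otherwise
#' `mu` grows until a step is accepted or `mu` overflows `mu_max`. Training
#' stops on reaching the MSE `goal`, `max_epochs`, `mu` overflow, or
#' `max_val_fail` consecutive validation-MSE increases; with a validation
#' set the returned parameters are those with the best validation MSE.
#'
#' @param x numeric matrix, observations x features.
#' @param y 0/1 class labels (1 = positive class), or an `n x 2` matrix of
#'   +/-1 targets.
#' @param validation optional list with elements `x` and `y` of the same
#'   form, used for early stopping.
#' @param seed initializer seed for [init_network()].
#' @param hidden hidden layer sizes (default `c(10, 7, 5)`).
#' @param goal training MSE goal (default `1e-3`).
#' @param max_epochs epoch cap (default 1000).
#' @param max_val_fail consecutive validation failures allowed (default 6).
#' @param mu0,mu_factor,mu_max Levenberg-Marquardt damping schedule.
#' @return A trained `mlp_net`; `$record` holds `epochs_run`, `mse_trace`,
#'   `val_trace`, `stop_reason` and the final `mu`.
#' @examples
#' xor_x <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4)
#' xor_y <- c(0, 1, 1, 0)
#' net <- train_mlp(xor_x, xor_y, hidden = c(4), seed = 3)
#' predict(net, xor_x, type = "class")
#' @export
train_mlp <- function(x, y, validation = NULL, seed = 1L,
                      hidden = c(10L, 7L, 5L), goal = 1e-3,
                      max_epochs = 1000L, max_val_fail = 6L,
                      mu0 = 1e-3, mu_factor = 10, mu_max = 1e10) {
  x <- as.matrix(x)
  Tg <- targets_pm1(y, nrow(x))
  net <- init_network(seed, c(ncol(x), hidden, 2L))
  theta <- params_to_vector(net)
  P <- length(theta)
  mu <- mu0
  mse_of <- function(th) {
    nt <- vector_to_params(net, th)
    mean((Tg - forward_pass(nt, x)$a[[length(net$W) + 1]])^2)
  }
  val_mse_of <- function(th) {
    if (is.null(validation)) return(NA_real_)
    nt <- vector_to_params(net, th)
    Tv <- targets_pm1(validation$y, nrow(as.matrix(validation$x)))
    mean((Tv - forward_pass(nt, as.matrix(validation$x))$a[[length(net$W) + 1]])^2)
  }
  mse <- mse_of(theta)
  mse_trace <- numeric(); val_trace <- numeric()
  best_val <- Inf; best_theta <- theta; val_fail <- 0L
  stop_reason <- "max_epochs"; epochs <- 0L
  if (mse < goal) stop_reason <- "goal_reached"
  else for (ep in seq_len(max_epochs)) {
    jac <- mlp_jacobian(vector_to_params(net, theta), x)
    e <- as.numeric(t(Tg - jac$Y))            # sample-major residuals
    JtJ <- crossprod(jac$J)
    Jte <- crossprod(jac$J, e)
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(solve(JtJ + mu * diag(P), Jte),
                        error = function(err) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        cmse <- mse_of(cand)
        if (is.finite(cmse) && cmse < mse) {
          theta <- cand; mse <- cmse
          mu <- max(mu / mu_factor, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * mu_factor
      if (mu > mu_max) break
    }
    if (!accepted) { stop_reason <- "mu_overflow"; break }
    epochs <- ep
    mse_trace <- c(mse_trace, mse)
    vm <- val_mse_of(theta)
    val_trace <- c(val_trace, vm)
    if (!is.na(vm)) {
      if (vm < best_val) {
        best_val <- vm; best_theta <- theta; val_fail <- 0L
      } else {
        val_fail <- val_fail + 1L
        if (val_fail >= max_val_fail) { stop_reason <- "val_fail"; break }
      }
    }
    if (mse < goal) { stop_reason <- "goal_reached"; break }
  }
  final <- if (is.null(validation)) theta else best_theta
  net <- vector_to_params(net, final)
  net$record <- list(epochs_run = epochs, mse_trace = mse_trace,
                     val_trace = val_trace, stop_reason = stop_reason,
                     mu = mu)
  net
}

# y as 0/1 labels or ready-made n x 2 +/-1 target matrix
targets_pm1 <- function(y, n) {
  if (is.matrix(y)) {
    if (!all(y %in% c(-1, 1))) stopf("target matrix must be +/-1 encoded")
    return(y)
  }
  if (length(y) != n) stopf("one label per observation required")
  cbind(ifelse(y == 1, 1, -1), ifelse(y == 1, -1, 1))
}

#' Score and classify observations
#'
#' The decision score is the difference of the two output nodes,
#' `f = output(positive node) - output(negative node)`; the predicted label
#' is positive iff `f > 0` (an exact 0 maps to the negative class).
#'
#' @param net a trained `mlp_net`.
#' @param x feature vector or matrix.
#' @return A list with `score` and `label` (0/1).
#' @export
score_and_classify <- function(net, x) {
  out <- forward(net, x)
  if (is.null(dim(out))) out <- matrix(out, 1)
  f <- out[, 1] - out[, 2]
  list(score = f, label = as.integer(f > 0))
}

#' @export
predict.mlp_net <- function(object, newdata,
                            type = c("score", "class", "raw"), ...) {
  type <- match.arg(type)
  sc <- score_and_classify(object, as.matrix(newdata))
  switch(type,
         score = sc$score,
         class = sc$label,
         raw = forward(object, as.matrix(newdata)))
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf("<mlp_net> %s tanh network, %d parameters, seed %d\n",
              paste(x$layer_sizes, collapse = "-"), n_params(x), x$seed))
  if (!is.null(x$record))
    cat(sprintf("  trained %d epochs, final MSE %.4g, stop: %s\n",
                x$record$epochs_run,
                if (length(x$record$mse_trace))
                  utils::tail(x$record$mse_trace, 1) else NA,
                x$record$stop_reason))
  invisible(x)
}

#' @export
summary.mlp_net <- function(object, ...) {
  print(object)
  if (!is.null(object$record) && length(object$record$mse_trace) > 1) {
    cat(sprintf("  MSE %.4g -> %.4g over %d accepted steps\n",
                object$record$mse_trace[1],
                utils::tail(object$record$mse_trace, 1),
                length(object$record$mse_trace)))
  }
  invisible(object)
}

#' @export
coef.mlp_net <- function(object, ...) {
  params_to_vector(object)
}
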