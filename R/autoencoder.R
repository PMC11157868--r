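#' Train a sparse auto-encoder on an integrated similarity matrix
#'
#' Compresses each row of a `p x p` integrated similarity matrix into a
#' `k`-dimensional code. The encoder maps a row `x` to a hidden code
#' `y = sigma(x W1 + b1)` (`W1`: `p x k`) and a second layer maps the code to
#' an output `z = sigma(y W2 + b2)` (`W2`: `k x k`). Training is plain
#' full-batch gradient descent.
#'
#' Two objectives are available:
#' \describe{
#'   \item{`"hidden_output"` (default)}{minimises the mean squared
#'     discrepancy between the hidden code and the second-layer output,
#'     `Loss = (1/p) * sum_i ||y_i - z_i||^2`; the returned embedding `Z` is
#'     the per-row output `z`.}
#'   \item{`"reconstruction"`}{the conventional auto-encoder: a decoder
#'     `W2: k x p` reconstructs the input, `Loss = (1/p) * sum_i ||x_i - z_i||^2`,
#'     and the returned embedding is the hidden code `y`.}
#' }
#' Sparsity is an optional L1 penalty on the hidden activations
#' (`l1_penalty`, default 0).
#'
#' @param X Square numeric matrix (`p x p`), e.g. an integrated similarity.
#' @param k Hidden width, `k <= p`.
#' @param epochs Number of full-batch gradient steps.
#' @param lr Learning rate.
#' @param l1_penalty Weight of the L1 penalty on hidden activations.
#' @param seed Seed for weight initialisation (standard normal scaled by
#'   `1/sqrt(fan-in)`).
#' @param objective `"hidden_output"` or `"reconstruction"` (see Details).
#' @param activation `"sigmoid"` (default) or `"identity"`.
#' @param init Optional list with entries `W1`, `b1`, `W2`, `b2` overriding
#'   the random initialisation (used mainly for testing).
#' @return Object of class `sparse_autoencoder`: a list with `params`
#'   (`W1`, `b1`, `W2`, `b2`), `Z` (the `p x k` embedding), `loss`
#'   (per-epoch trace, element 1 = loss before the first update), and the
#'   call configuration.
#' @export
train_autoencoder <- function(X, k, epochs = 200, lr = 1e-3, l1_penalty = 0,
                              seed = 1, objective = c("hidden_output", "reconstruction"),
                              activation = c("sigmoid", "identity"), init = NULL) {
  objective <- match.arg(objective)
  activation <- match.arg(activation)
  X <- unclass(X)
  p <- nrow(X)
  if (ncol(X) != p) abort("`X` must be square.")
  k <- check_scalar_int(k, "k")
  if (k > p) abort(sprintf("Hidden width k = %d exceeds input dimension p = %d.", k, p))
  epochs <- check_scalar_int(epochs, "epochs", min = 0L)
  out_dim <- if (objective == "hidden_output") k else p

  params <- if (is.null(init)) {
    with_local_seed(derive_seed(seed, "autoencoder"), list(
      W1 = matrix(rnorm(p * k) / sqrt(p), p, k),
      b1 = numeric(k),
      W2 = matrix(rnorm(k * out_dim) / sqrt(k), k, out_dim),
      b2 = numeric(out_dim)
    ))
  } else {
    stopifnot(all(c("W1", "b1", "W2", "b2") %in% names(init)))
    init
  }

  act <- if (activation == "sigmoid") function(u) 1 / (1 + exp(-u)) else identity
  act_grad <- if (activation == "sigmoid") function(a) a * (1 - a) else function(a) 1

  forward <- function(pr) {
    Y <- act(sweep(X %*% pr$W1, 2L, pr$b1, "+"))
    Z <- act(sweep(Y %*% pr$W2, 2L, pr$b2, "+"))
    list(Y = Y, Z = Z)
  }
  loss_of <- function(fw) {
    target <- if (objective == "hidden_output") fw$Y else X
    base <- sum((target - fw$Z)^2) / p
    base + l1_penalty * sum(abs(fw$Y)) / p
  }

  trace <- numeric(epochs + 1L)
  fw <- forward(params)
  trace[1L] <- loss_of(fw)
  for (e in seq_len(epochs)) {
    Y <- fw$Y; Z <- fw$Z
    if (objective == "hidden_output") {
      diff <- Y - Z           # dLoss/dY (direct) = 2*diff/p ; dLoss/dZ = -2*diff/p
      dZ <- -2 * diff / p
      dY_direct <- 2 * diff / p
    } else {
      dZ <- -2 * (X - Z) / p
      dY_direct <- 0
    }
    dZpre <- dZ * act_grad(Z)
    gW2 <- crossprod(Y, dZpre)
    gb2 <- colSums(dZpre)
    dY <- dY_direct + dZpre %*% t(params$W2) + (l1_penalty / p) * sign(Y)
    dYpre <- dY * act_grad(Y)
    gW1 <- crossprod(X, dYpre)
    gb1 <- colSums(dYpre)
    params$W1 <- params$W1 - lr * gW1
    params$b1 <- params$b1 - lr * gb1
    params$W2 <- params$W2 - lr * gW2
    params$b2 <- params$b2 - lr * gb2
    fw <- forward(params)
    trace[e + 1L] <- loss_of(fw)
    if (!is.finite(trace[e + 1L])) {
      abort(sprintf("Auto-encoder loss became non-finite at epoch %d.", e))
    }
  }

  Z_out <- if (objective == "hidden_output") fw$Z else fw$Y
  rownames(Z_out) <- rownames(X)
  structure(
    list(params = params, Z = Z_out, loss = trace, k = k, objective = objective,
         activation = activation, lr = lr, l1_penalty = l1_penalty,
         epochs = epochs, seed = seed),
    class = "sparse_autoencoder"
  )
}

#' @export
print.sparse_autoencoder <- function(x, ...) {
  cat(sprintf("<sparse_autoencoder> %d -> %d (%s, %s), %d epochs, final loss %.6g\n",
              nrow(x$Z), x$k, x$objective, x$activation, x$epochs,
              x$loss[length(x$loss)]))
  invisible(x)
}

#' Per-epoch training loss of a sparse auto-encoder
#' @param x A `sparse_autoencoder`.
#' @param ... Unused.
#' @return Tibble with columns `epoch` (0 = before training) and `loss`.
#' @export
tidy.sparse_autoencoder <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss) - 1L, loss = x$loss)
}

#' Stack circRNA and disease embeddings into the node feature matrix
#'
#' The node feature matrix `Q` row-stacks the circRNA embedding block on top
#' of the disease embedding block, matching the CDHN node order (circRNAs
#' first).
#'
#' @param Zc `n x k` circRNA feature block (`n >= 1`).
#' @param Zd `m x k` disease feature block (`m >= 1`).
#' @return `(n+m) x k` matrix with an attribute `n_circ`.
#' @export
build_node_features <- function(Zc, Zd) {
  Zc <- as.matrix(Zc); Zd <- as.matrix(Zd)
  if (nrow(Zc) < 1L || nrow(Zd) < 1L) abort("Both feature blocks need at least one row.")
  if (ncol(Zc) != ncol(Zd)) {
    abort(sprintf("Feature width mismatch: %d vs %d.", ncol(Zc), ncol(Zd)))
  }
  if (!all(is.finite(Zc)) || !all(is.finite(Zd))) abort("Node features must be finite.")
  q <- rbind(Zc, Zd)
  attr(q, "n_circ") <- nrow(Zc)
  q
}
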