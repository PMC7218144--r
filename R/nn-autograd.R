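# Minimal reverse-mode tape for the network zoo.  Values are plain R arrays:
# dense activations are B x F matrices, sequences are B x T x C arrays.  Each
# forward op pushes a backward closure onto the tape; nn_backward() replays
# them in reverse, accumulating gradients into node/parameter environments.

nn_tape <- function(training = FALSE) {
  t <- new.env(parent = emptyenv())
  t$ops <- list()
  t$training <- training
  t
}

nn_node <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n
}

nn_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- array(0, dim = dim_or_len(value))
  p$v <- array(0, dim = dim_or_len(value))
  class(p) <- "nn_param"
  p
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

nn_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

tape_push <- function(tape, out, backward) {
  tape$ops[[length(tape$ops) + 1L]] <- list(out = out, backward = backward)
  out
}

nn_backward <- function(tape, loss) {
  loss$grad <- 1
  for (op in rev(tape$ops)) {
    g <- op$out$grad
    if (!is.null(g)) op$backward(g)
  }
  invisible(NULL)
}

glorot_init <- function(fan_in, fan_out, shape = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(shape), -lim, lim), dim = shape)
}

## ---- dense ops -------------------------------------------------------------

op_dense <- function(tape, x, W, b) {
  out <- nn_node(sweep(x$value %*% W$value, 2, b$value, `+`))
  tape_push(tape, out, function(g) {
    W$grad <- zsum(W$grad, crossprod(x$value, g))
    b$grad <- zsum(b$grad, colSums(g))
    nn_accum(x, g %*% t(W$value))
  })
}

zsum <- function(a, b) if (is.null(a)) b else a + b

op_relu <- function(tape, x) {
  mask <- x$value > 0
  out <- nn_node(x$value * mask)
  tape_push(tape, out, function(g) nn_accum(x, g * mask))
}

op_dropout <- function(tape, x, rate) {
  if (!tape$training || rate <= 0) return(x)
  keep <- array(runif(length(x$value)) >= rate, dim = dim_or_len(x$value))
  scale <- 1 / (1 - rate)
  out <- nn_node(x$value * keep * scale)
  tape_push(tape, out, function(g) nn_accum(x, g * keep * scale))
}

op_concat <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  out <- nn_node(do.call(cbind, lapply(nodes, function(n) n$value)))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  tape_push(tape, out, function(g) {
    for (i in seq_along(nodes)) {
      nn_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

## ---- sequence ops ----------------------------------------------------------

# x: B x T x C; W: (k*C) x F; 'same' zero padding.
op_conv1d <- function(tape, x, W, b, kernel) {
  dims <- dim(x$value)
  B <- dims[1]; T_ <- dims[2]; C <- dims[3]
  Fo <- ncol(W$value)
  pad_l <- (kernel - 1L) %/% 2L
  xp <- array(0, dim = c(B, T_ + kernel - 1L, C))
  xp[, pad_l + seq_len(T_), ] <- x$value
  cols <- vector("list", kernel)
  for (j in seq_len(kernel)) {
    slab <- xp[, (j - 1L) + seq_len(T_), , drop = FALSE]
    cols[[j]] <- matrix(slab, nrow = B * T_, ncol = C)
  }
  X2 <- do.call(cbind, cols)                       # (B*T) x (k*C)
  Y2 <- sweep(X2 %*% W$value, 2, b$value, `+`)
  out <- nn_node(array(Y2, dim = c(B, T_, Fo)))
  tape_push(tape, out, function(g) {
    g2 <- matrix(g, nrow = B * T_, ncol = Fo)
    W$grad <- zsum(W$grad, crossprod(X2, g2))
    b$grad <- zsum(b$grad, colSums(g2))
    gX2 <- g2 %*% t(W$value)
    gxp <- array(0, dim = c(B, T_ + kernel - 1L, C))
    for (j in seq_len(kernel)) {
      part <- array(gX2[, (j - 1L) * C + seq_len(C), drop = FALSE],
                    dim = c(B, T_, C))
      idx <- (j - 1L) + seq_len(T_)
      gxp[, idx, ] <- gxp[, idx, , drop = FALSE] + part
    }
    nn_accum(x, gxp[, pad_l + seq_len(T_), , drop = FALSE])
  })
}

op_relu3 <- function(tape, x) {
  mask <- x$value > 0
  out <- nn_node(x$value * mask)
  tape_push(tape, out, function(g) nn_accum(x, g * mask))
}

# Global average pooling over time: B x T x C -> B x C.
op_gap <- function(tape, x) {
  dims <- dim(x$value)
  B <- dims[1]; T_ <- dims[2]; C <- dims[3]
  out <- nn_node(colMeans(aperm(x$value, c(2, 1, 3))))
  dim(out$value) <- c(B, C)
  tape_push(tape, out, function(g) {
    nn_accum(x, aperm(array(g / T_, dim = c(B, C, T_)), c(1, 3, 2)))
  })
}

# Tile a per-instance vector (B x P) along time and concatenate to a sequence
# (B x T x C) -> B x T x (C+P).  The spec-mandated broadcast for conv-path
# fusion.
op_tile_concat <- function(tape, x, f) {
  dims <- dim(x$value)
  B <- dims[1]; T_ <- dims[2]; C <- dims[3]
  P <- ncol(f$value)
  out_val <- array(0, dim = c(B, T_, C + P))
  out_val[, , seq_len(C)] <- x$value
  out_val[, , C + seq_len(P)] <- aperm(array(f$value, dim = c(B, P, T_)), c(1, 3, 2))
  out <- nn_node(out_val)
  tape_push(tape, out, function(g) {
    nn_accum(x, g[, , seq_len(C), drop = FALSE])
    gf <- apply(g[, , C + seq_len(P), drop = FALSE], c(1, 3), sum)
    dim(gf) <- c(B, P)
    nn_accum(f, gf)
  })
}

# LSTM returning the final hidden state; compiled recurrence.
op_lstm_last <- function(tape, x, Wx, Wh, b) {
  xc <- aperm(x$value, c(1, 3, 2))                 # B x C x T for the kernel
  fwd <- lstm_forward_cpp(xc, Wx$value, Wh$value, matrix(b$value, nrow = 1))
  out <- nn_node(fwd$h_last)
  tape_push(tape, out, function(g) {
    bwd <- lstm_backward_cpp(xc, Wx$value, Wh$value, fwd$acts, fwd$cells,
                             fwd$hiddens, g)
    Wx$grad <- zsum(Wx$grad, bwd$dWx)
    Wh$grad <- zsum(Wh$grad, bwd$dWh)
    b$grad <- zsum(b$grad, as.vector(bwd$db))
    nn_accum(x, aperm(bwd$dX, c(1, 3, 2)))
  })
}

## ---- loss ------------------------------------------------------------------

# Fused sigmoid + binary cross-entropy on logits (B x 1).
op_sigmoid_bce <- function(tape, z, y) {
  p <- stats::plogis(z$value)
  eps <- 1e-12
  loss_val <- -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  out <- nn_node(loss_val)
  B <- length(y)
  tape_push(tape, out, function(g) {
    nn_accum(z, g * (p - matrix(y, ncol = 1)) / B)
  })
}

## ---- optimiser -------------------------------------------------------------

adam_step <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

flatten_params <- function(x) {
  if (inherits(x, "nn_param")) return(list(x))
  if (is.list(x)) return(unlist(lapply(x, flatten_params), recursive = FALSE))
  list()
}

param_values <- function(params) lapply(params, function(p) p$value)

set_param_values <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$value <- values[[i]]
  invisible(NULL)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
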