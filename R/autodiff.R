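# Minimal reverse-mode gradient tape.
#
# Every forward pass builds a fresh tape: each operation appends a node
# (an environment holding the value and a backward closure) in execution
# order, and `tape_backward()` replays the closures in reverse.  Feature
# maps are channels-last (D, H, W, C) arrays throughout; parameters are
# plain arrays held in the network's parameter store.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

node_new <- function(tape, val, bwd = NULL, track = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bwd <- bwd
  if (track && !is.null(tape)) {
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

node_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

ag_leaf <- function(tape, val) node_new(tape, val, bwd = NULL)

tape_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bwd)) nd$bwd(nd$grad)
  }
  invisible(NULL)
}

dims4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  as.integer(d)
}

## --- tensor ops ------------------------------------------------------------

# b = NULL runs bias-free (convolutions followed by batch norm: a bias
# there is removed again by the normalisation, so none is allocated)
ag_conv3 <- function(tape, x, w, b, k, pad = (k - 1L) %/% 2L) {
  din <- dims4(x$val)
  bv <- if (is.null(b)) numeric(ncol(w$val)) else b$val
  out <- cpp_conv3d_fwd(x$val, din, w$val, bv, as.integer(k),
                        as.integer(pad))
  node_new(tape, out, bwd = function(g) {
    gr <- cpp_conv3d_bwd(x$val, din, w$val, g, as.integer(k), as.integer(pad))
    node_accum(x, gr$gx)
    node_accum(w, gr$gW)
    if (!is.null(b)) node_accum(b, as.numeric(gr$gb))
  })
}

ag_convt2 <- function(tape, x, w, b) {
  din <- dims4(x$val)
  out <- cpp_convt2_fwd(x$val, din, w$val, b$val)
  node_new(tape, out, bwd = function(g) {
    gr <- cpp_convt2_bwd(x$val, din, w$val, g)
    node_accum(x, gr$gx)
    node_accum(w, gr$gW)
    node_accum(b, as.numeric(gr$gb))
  })
}

ag_maxpool <- function(tape, x, k) {
  din <- dims4(x$val)
  fw <- cpp_maxpool_fwd(x$val, din, as.integer(k))
  node_new(tape, fw$out, bwd = function(g) {
    node_accum(x, cpp_maxpool_bwd(g, fw$argmax, din))
  })
}

ag_resize_lin <- function(tape, x, out_dhw) {
  din <- dims4(x$val)
  out_dhw <- as.integer(out_dhw)
  out <- cpp_resize3_lin(x$val, din[1:3], out_dhw, din[4])
  dim(out) <- c(out_dhw, din[4])
  node_new(tape, out, bwd = function(g) {
    gx <- cpp_resize3_lin_adj(g, din[1:3], out_dhw, din[4])
    dim(gx) <- din
    node_accum(x, gx)
  })
}

# batch statistics per channel over all voxels of the sample
ag_batchnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dims4(x$val)
  V <- prod(d[1:3])
  X <- matrix(x$val, nrow = V, ncol = d[4])
  mu <- colMeans(X)
  xc <- X - rep(mu, each = V)
  va <- colMeans(xc * xc)
  sd_ <- sqrt(va + eps)
  xhat <- xc / rep(sd_, each = V)
  out <- array(xhat * rep(gamma$val, each = V) + rep(beta$val, each = V),
               dim = d)
  node_new(tape, out, bwd = function(g) {
    G <- matrix(g, nrow = V, ncol = d[4])
    Gx <- G * xhat
    dgamma <- colSums(Gx)
    dbeta <- colSums(G)
    dX <- (G - rep(dbeta / V, each = V) - xhat * rep(dgamma / V, each = V)) *
      rep(gamma$val / sd_, each = V)
    node_accum(x, array(dX, dim = d))
    node_accum(gamma, dgamma)
    node_accum(beta, dbeta)
  })
}

ag_relu <- function(tape, x) {
  mask <- x$val > 0
  node_new(tape, x$val * mask, bwd = function(g) node_accum(x, g * mask))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  node_new(tape, s, bwd = function(g) node_accum(x, g * s * (1 - s)))
}

ag_concat <- function(tape, xs) {
  ds <- lapply(xs, function(n) dims4(n$val))
  chans <- vapply(ds, `[`, integer(1), 4L)
  d0 <- ds[[1]]
  out <- array(0, dim = c(d0[1:3], sum(chans)))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, , , off + seq_len(chans[i])] <- xs[[i]]$val
    off <- off + chans[i]
  }
  node_new(tape, out, bwd = function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      node_accum(xs[[i]], g[, , , off + seq_len(chans[i]), drop = FALSE])
      off <- off + chans[i]
    }
  })
}

# global average pool: (D,H,W,C) -> length-C vector
ag_gap <- function(tape, x) {
  d <- dims4(x$val)
  V <- prod(d[1:3])
  v <- colMeans(matrix(x$val, nrow = V, ncol = d[4]))
  node_new(tape, v, bwd = function(g) {
    node_accum(x, array(rep(g / V, each = V), dim = d))
  })
}

# dense layer on a vector: out = v %*% W + b
ag_dense <- function(tape, v, w, b) {
  out <- drop(v$val %*% w$val) + b$val
  node_new(tape, out, bwd = function(g) {
    node_accum(v, drop(w$val %*% g))
    node_accum(w, outer(v$val, g))
    node_accum(b, g)
  })
}

ag_vec_relu <- function(tape, v) {
  mask <- v$val > 0
  node_new(tape, v$val * mask, bwd = function(g) node_accum(v, g * mask))
}

ag_vec_sigmoid <- function(tape, v) {
  s <- 1 / (1 + exp(-v$val))
  node_new(tape, s, bwd = function(g) node_accum(v, g * s * (1 - s)))
}

# channel-wise rescale of a feature map by a gate vector
ag_scale_channels <- function(tape, x, s) {
  d <- dims4(x$val)
  V <- prod(d[1:3])
  out <- array(matrix(x$val, V) * rep(s$val, each = V), dim = d)
  node_new(tape, out, bwd = function(g) {
    node_accum(x, array(matrix(g, V) * rep(s$val, each = V), dim = d))
    node_accum(s, colSums(matrix(g, V) * matrix(x$val, V)))
  })
}

# mean of a list of same-shaped volumes (prediction fusion)
ag_mean_maps <- function(tape, xs) {
  n <- length(xs)
  acc <- xs[[1]]$val
  if (n > 1) for (i in 2:n) acc <- acc + xs[[i]]$val
  node_new(tape, acc / n, bwd = function(g) {
    for (x in xs) node_accum(x, g / n)
  })
}

# mean of scalar loss nodes (deep-supervision aggregation)
ag_mean_scalars <- function(tape, xs) {
  n <- length(xs)
  node_new(tape, mean(vapply(xs, function(x) x$val, numeric(1))),
           bwd = function(g) for (x in xs) node_accum(x, g / n))
}

# combined focal + DWD objective with analytic gradient wrt the prediction;
# the DWD weights are treated as constants of the current prediction
ag_total_loss <- function(tape, p, y, cfg) {
  val <- total_loss(y, p$val, cfg)
  node_new(tape, val, bwd = function(g) {
    node_accum(p, g * array(total_loss_grad(y, p$val, cfg), dim = dim(p$val)))
  })
}
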