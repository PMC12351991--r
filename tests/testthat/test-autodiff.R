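# The tensor primitives and their gradients, checked against naive
# reference implementations and central finite differences.

naive_conv3 <- function(x, Wm, b, k, pad) {
  d <- dim(x); D <- d[1]; H <- d[2]; W <- d[3]; Cin <- d[4]
  Cout <- ncol(Wm)
  out <- array(0, c(D, H, W, Cout))
  for (co in seq_len(Cout)) for (dd in 1:D) for (h in 1:H) for (w in 1:W) {
    acc <- b[co]
    for (ci in seq_len(Cin)) for (dz in 0:(k - 1)) for (dy in 0:(k - 1))
      for (dx in 0:(k - 1)) {
        sz <- dd + dz - pad; sy <- h + dy - pad; sx <- w + dx - pad
        if (sz >= 1 && sz <= D && sy >= 1 && sy <= H && sx >= 1 && sx <= W) {
          j <- (ci - 1) * k^3 + dz + k * (dy + k * dx) + 1
          acc <- acc + x[sz, sy, sx, ci] * Wm[j, co]
        }
      }
    out[dd, h, w, co] <- acc
  }
  out
}

fd_grad <- function(f, v, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    v1 <- v; v1[i] <- v1[i] + eps
    v2 <- v; v2[i] <- v2[i] - eps
    (f(v1) - f(v2)) / (2 * eps)
  }, numeric(1))
}

test_that("3D convolution matches a naive reference and its gradients match
           finite differences", {
  set.seed(1)
  ns <- asNamespace("esunet3d")
  for (case in list(list(k = 3L, pad = 1L), list(k = 1L, pad = 0L))) {
    x <- array(rnorm(5 * 4 * 6 * 3), c(5, 4, 6, 3))
    Wm <- matrix(rnorm(case$k^3 * 3 * 2), case$k^3 * 3, 2)
    b <- rnorm(2)
    out <- ns$cpp_conv3d_fwd(x, dim(x), Wm, b, case$k, case$pad)
    expect_equal(out, naive_conv3(x, Wm, b, case$k, case$pad),
                 tolerance = 1e-10, ignore_attr = TRUE)
    R <- array(rnorm(length(out)), dim(out))
    g <- ns$cpp_conv3d_bwd(x, dim(x), Wm, R, case$k, case$pad)
    idx <- sample(length(x), 5)
    expect_equal(g$gx[idx],
                 fd_grad(function(v) sum(ns$cpp_conv3d_fwd(
                   array(v, dim(x)), dim(x), Wm, b, case$k, case$pad) * R),
                   x, idx), tolerance = 1e-5)
    idx <- sample(length(Wm), 5)
    expect_equal(g$gW[idx],
                 fd_grad(function(v) sum(ns$cpp_conv3d_fwd(
                   x, dim(x), matrix(v, nrow(Wm)), b, case$k, case$pad) * R),
                   Wm, idx), tolerance = 1e-5)
  }
})

test_that("transposed convolution doubles dims and its gradients check out", {
  set.seed(2)
  ns <- asNamespace("esunet3d")
  x <- array(rnorm(4 * 3 * 5 * 2), c(4, 3, 5, 2))
  Wt <- matrix(rnorm(2 * 3 * 8), 2, 24)
  bt <- rnorm(3)
  out <- ns$cpp_convt2_fwd(x, dim(x), Wt, bt)
  expect_equal(dim(out), c(8L, 6L, 10L, 3L))
  R <- array(rnorm(length(out)), dim(out))
  g <- ns$cpp_convt2_bwd(x, dim(x), Wt, R)
  idx <- sample(length(x), 5)
  expect_equal(g$gx[idx],
               fd_grad(function(v) sum(ns$cpp_convt2_fwd(
                 array(v, dim(x)), dim(x), Wt, bt) * R), x, idx),
               tolerance = 1e-5)
  idx <- sample(length(Wt), 5)
  expect_equal(g$gW[idx],
               fd_grad(function(v) sum(ns$cpp_convt2_fwd(
                 x, dim(x), matrix(v, 2), bt) * R), Wt, idx),
               tolerance = 1e-5)
})

test_that("max pooling picks block maxima and routes gradients to them", {
  set.seed(3)
  ns <- asNamespace("esunet3d")
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  fw <- ns$cpp_maxpool_fwd(x, dim(x), 2L)
  for (c in 1:2) for (d in 1:2) for (h in 1:2) for (w in 1:2)
    expect_equal(fw$out[d, h, w, c],
                 max(x[2 * d - 1:0, 2 * h - 1:0, 2 * w - 1:0, c]))
  g <- ns$cpp_maxpool_bwd(array(1, dim(fw$out)), fw$argmax, dim(x))
  expect_equal(sum(g), 16)
  expect_true(all(g[g != 0] == 1))
})

test_that("trilinear resize is exact on identity and adjoint-consistent", {
  set.seed(4)
  ns <- asNamespace("esunet3d")
  x <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
  expect_identical(as.numeric(ns$cpp_resize3_lin(x, c(6L, 5L, 4L),
                                                 c(6L, 5L, 4L), 2L)),
                   as.numeric(x))
  out_d <- c(9L, 7L, 5L)
  y <- ns$cpp_resize3_lin(x, c(6L, 5L, 4L), out_d, 2L)
  r <- array(rnorm(prod(out_d) * 2), c(out_d, 2))
  adj <- ns$cpp_resize3_lin_adj(r, c(6L, 5L, 4L), out_d, 2L)
  # <A x, r> == <x, A' r>
  expect_equal(sum(y * r), sum(x * adj), tolerance = 1e-10)
})

test_that("batch norm gradient matches finite differences", {
  set.seed(5)
  ns <- asNamespace("esunet3d")
  x <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
  R <- array(rnorm(length(x)), dim(x))
  run <- function(xx, gg = gamma, bb = beta) {
    tape <- ns$tape_new()
    out <- ns$ag_batchnorm(tape, ns$ag_leaf(tape, array(xx, dim(x))),
                           ns$ag_leaf(tape, gg), ns$ag_leaf(tape, bb))
    sum(out$val * R)
  }
  tape <- ns$tape_new()
  xn <- ns$ag_leaf(tape, x); gn <- ns$ag_leaf(tape, gamma)
  bn <- ns$ag_leaf(tape, beta)
  out <- ns$ag_batchnorm(tape, xn, gn, bn)
  ns$node_accum(out, R)
  out$bwd(out$grad)
  idx <- sample(length(x), 6)
  expect_equal(xn$grad[idx], fd_grad(run, x, idx), tolerance = 1e-4)
  expect_equal(gn$grad,
               fd_grad(function(v) run(x, gg = v), gamma, 1:3),
               tolerance = 1e-5)
  expect_equal(bn$grad,
               fd_grad(function(v) run(x, bb = v), beta, 1:3),
               tolerance = 1e-5)
})

test_that("whole-network gradient matches finite differences on the focal
           objective", {
  # focal-only so nothing in the loss is held fixed during differentiation
  set.seed(6)
  ns <- asNamespace("esunet3d")
  cfg <- toy_net_config(base = 4, C = 4)
  net <- build_network(cfg, seed = 3)
  img <- array(rnorm(2 * 16^3), c(16, 16, 16, 2))
  y <- as.numeric(rbinom(16^3, 1, 0.05))
  lcfg <- loss_config(alpha = 0)
  lossfun <- function(params) {
    tape <- ns$tape_new()
    fw <- ns$net_forward_tape(params, cfg, img, tape)
    tot <- ns$ag_mean_scalars(tape, lapply(fw$heads, function(h)
      ns$ag_total_loss(tape, h, y, lcfg)))
    list(val = tot$val, tape = tape, tot = tot, fw = fw)
  }
  r <- lossfun(net$params)
  ns$tape_backward(r$tape, r$tot)
  grads <- lapply(r$fw$P, function(nd) nd$grad)
  for (nm in sample(names(net$params), 6)) {
    i <- sample(length(net$params[[nm]]), 1)
    eps <- 1e-5
    p1 <- net$params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- net$params; p2[[nm]][i] <- p2[[nm]][i] - eps
    fd <- (lossfun(p1)$val - lossfun(p2)$val) / (2 * eps)
    # mixed tolerance: relative where the gradient is sizeable, absolute floor
    # where finite differencing itself is noise-limited
    expect_lt(abs(grads[[nm]][i] - fd) / max(1e-4, abs(fd)), 1e-2)
  }
})
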