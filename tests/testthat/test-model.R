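# ES-UNet architecture contracts: encoder schedule, skip routing, heads,
# fusion and the skip-topology ablation variants.

test_that("encoder follows the halving/doubling schedule at toy scale", {
  net <- build_network(toy_net_config(base = 4, in_channels = 1), seed = 1)
  img <- array(rnorm(16^3), c(1, 16, 16, 16))
  pyr <- encoder_forward(net, img)
  expect_equal(lapply(pyr, dim),
               list(c(4L, 16L, 16L, 16L), c(8L, 8L, 8L, 8L),
                    c(16L, 4L, 4L, 4L), c(32L, 2L, 2L, 2L)))
})

test_that("indivisible spatial dims are rejected, naming the divisor", {
  net <- build_network(toy_net_config(), seed = 1)
  err <- expect_error(encoder_forward(net, array(0, c(2, 50, 50, 50))))
  expect_match(conditionMessage(err), "divisible by 8")
})

test_that("channel attention gates the feature map channel-wise", {
  set.seed(2)
  fmap <- array(rnorm(32 * 4 * 4 * 4), c(32, 4, 4, 4))
  pars <- attention_params(32, 0.25)
  expect_equal(dim(pars$w1), c(32L, 8L))  # bottleneck width C/4
  out <- channel_attention(fmap, 0.25, pars)
  expect_equal(dim(out), dim(fmap))

  # saturate the gate at 1: output equals input
  open_ <- pars; open_$w2[] <- 0; open_$b2[] <- 40
  expect_equal(channel_attention(fmap, 0.25, open_), fmap, tolerance = 1e-8)
  # gate at 0: output vanishes
  shut <- pars; shut$w2[] <- 0; shut$b2[] <- -40
  expect_lt(max(abs(channel_attention(fmap, 0.25, shut))), 1e-8)
})

test_that("skip paths land at the target level with path channels", {
  cfg <- toy_net_config(base = 4, C = 4)
  net <- build_network(cfg, seed = 5)
  # encoder level 1 at 16^3 routed down to decoder level 3 (pool stride 4)
  f1 <- array(rnorm(4 * 16^3), c(4, 16, 16, 16))
  expect_equal(dim(skip_path(net, f1, 1, 3, "encoder")), c(4L, 4L, 4L, 4L))
  # same-level path keeps resolution
  f3 <- array(rnorm(16 * 4^3), c(16, 4, 4, 4))
  expect_equal(dim(skip_path(net, f3, 3, 3, "encoder")), c(4L, 4L, 4L, 4L))
  # decoder level 4 (16 = 4 paths * C channels) up to level 2 via trilinear x4
  f4 <- array(rnorm(16 * 2^3), c(16, 2, 2, 2))
  expect_equal(dim(skip_path(net, f4, 4, 2, "decoder")), c(4L, 8L, 8L, 8L))
  # adjacent decoder path uses the transposed convolution
  f3d <- array(rnorm(16 * 4^3), c(16, 4, 4, 4))
  expect_equal(dim(skip_path(net, f3d, 3, 2, "decoder")), c(4L, 8L, 8L, 8L))

  expect_error(skip_path(net, f1, 3, 1, "encoder"), "level_i <= level_j")
  expect_error(skip_path(net, f1, 1, 3, "decoder"), "level_i > level_j")
})

test_that("decoder outputs are standardised to n_paths * C channels", {
  cfg <- toy_net_config(base = 4, C = 4)
  net <- build_network(cfg, seed = 6)
  pyr <- encoder_forward(net, array(rnorm(2 * 16^3), c(2, 16, 16, 16)))
  dec <- decoder_forward(net, pyr)
  # full variant: every decoder has exactly N = 4 incoming paths
  expect_equal(vapply(dec, function(d) dim(d)[1], integer(1)),
               rep(16L, 4))
  expect_equal(dim(dec[[2]])[2:4], c(8L, 8L, 8L))

  # base variant: {same-level enc, adjacent dec} only -> 2C channels (C at
  # the deepest level, which has no deeper decoder)
  ns <- asNamespace("esunet3d")
  base_cfg <- toy_net_config(base = 4, C = 4, variant = "base")
  expect_equal(vapply(1:4, function(j) ns$dec_ch(base_cfg, j), integer(1)),
               c(8L, 8L, 8L, 4L))
  bnet <- build_network(base_cfg, seed = 6)
  bdec <- decoder_forward(bnet, pyr)
  expect_equal(vapply(bdec, function(d) dim(d)[1], integer(1)),
               c(8L, 8L, 8L, 4L))
})

test_that("deepest decoder receives only encoder paths", {
  ns <- asNamespace("esunet3d")
  cfg <- toy_net_config()
  paths <- ns$routing(cfg, 4)
  expect_true(all(vapply(paths, function(p) p$source, "") == "enc"))
  expect_equal(vapply(paths, function(p) p$i, 1L), 1:4)
})

test_that("aux heads upsample by 2^(level-1) and saturate at 0.5 on zeros", {
  fmap <- array(rnorm(6 * 4^3), c(6, 4, 4, 4))
  out <- aux_head(fmap, 3, c(16, 16, 16))
  expect_equal(dim(out), c(1L, 16L, 16L, 16L))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(aux_head(fmap, 2, c(16, 16, 16)), "2\\^\\(level-1\\)")

  same <- aux_head(fmap, 1, c(4, 4, 4))
  expect_equal(dim(same), c(1L, 4L, 4L, 4L))

  zero <- aux_head(array(0, c(6, 4, 4, 4)), 3, c(16, 16, 16))
  expect_true(all(zero == 0.5))
})

test_that("prediction fusion is the arithmetic mean", {
  maps <- lapply(c(0.2, 0.4, 0.6, 0.8), function(v) array(v, c(4, 4, 4)))
  expect_equal(fuse_predictions(maps), array(0.5, c(4, 4, 4)))
  expect_identical(fuse_predictions(maps[2]), maps[[2]])
  expect_equal(fuse_predictions(list(maps[[1]], maps[[1]])), maps[[1]])
  expect_error(fuse_predictions(list(maps[[1]], array(0, c(2, 2, 2)))),
               "share one shape")
})

test_that("full forward keeps shape and probability range; variants differ in
           size as expected", {
  cfg <- toy_net_config(base = 4, C = 4)
  net <- build_network(cfg, seed = 7)
  img <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  out <- predict_volume(net, img)
  expect_equal(dim(out$prob), c(16L, 16L, 16L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_length(out$heads, 4)
  expect_equal(fuse_predictions(out$heads), out$prob, tolerance = 1e-12)
  expect_true(all(out$mask %in% c(0L, 1L)))

  base_net <- build_network(toy_net_config(base = 4, C = 4,
                                           variant = "base"), seed = 7)
  expect_gt(net$param_count, base_net$param_count)

  single <- build_network(toy_net_config(base = 4, C = 4,
                                         deep_supervision = FALSE), seed = 7)
  expect_length(predict_volume(single, img)$heads, 1)

  err <- expect_error(network_config(variant = "full"))
  expect_match(conditionMessage(err), "both, enc_only, dec_only, base")
})

test_that("spatial/channel schedules hold across random configurations", {
  ns <- asNamespace("esunet3d")
  set.seed(31)
  for (rep in 1:5) {
    nl <- sample(2:4, 1)
    base <- sample(c(2, 4, 6), 1)
    cfg <- network_config(n_levels = nl, in_channels = sample(1:2, 1),
                          base_channels = base, path_channels = 4)
    ce <- ns$enc_channels(cfg)
    expect_equal(ce, base * 2^(0:(nl - 1)))
    expect_equal(ce[-1] / ce[-nl], rep(2, nl - 1))
    net <- build_network(cfg, seed = rep)
    side <- 8L * 2L^(nl - 2L)
    img <- array(rnorm(cfg$in_channels * side^3),
                 c(cfg$in_channels, side, side, side))
    pyr <- encoder_forward(net, img)
    for (i in seq_len(nl)) {
      expect_equal(dim(pyr[[i]])[1], ce[i])
      expect_equal(dim(pyr[[i]])[2:4], rep(side %/% 2L^(i - 1L), 3L))
    }
  }
})

test_that("deep supervision drives a gradient into every parameter group", {
  ns <- asNamespace("esunet3d")
  cfg <- toy_net_config(base = 4, C = 4)
  net <- build_network(cfg, seed = 11)
  ph <- tiny_phantom(seed = 21, shape = c(16, 16, 16), radii = c(3, 4))
  ph <- normalize_volume(ph)
  st <- ns$train_step(net$params, cfg, ph, loss_config())
  dead <- names(st$grads)[vapply(st$grads, function(g)
    is.null(g) || sum(abs(g)) == 0, logical(1))]
  expect_identical(dead, character(0))
})
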