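# Training pipeline: splits, scheduler, optimisation and evaluation.

test_that("the floor-rule split reproduces the published 80:20 partitions", {
  s <- split_cases(seq_len(224), 0.2, seed = 1)
  expect_length(s$train, 180)
  expect_length(s$val, 44)
  s <- split_cases(seq_len(20), 0.2, seed = 1)
  expect_length(s$train, 16)
  expect_length(s$val, 4)
  s <- split_cases(seq_len(41), 0.2, seed = 1)
  expect_length(s$train, 33)
  expect_length(s$val, 8)
})

test_that("splits are disjoint, exhaustive and deterministic", {
  for (n in c(5, 17, 101)) for (seed in c(1, 9)) {
    ids <- paste0("case", seq_len(n))
    a <- split_cases(ids, 0.25, seed)
    b <- split_cases(ids, 0.25, seed)
    expect_identical(a, b)
    expect_length(intersect(a$train, a$val), 0)
    expect_setequal(c(a$train, a$val), ids)
  }
  expect_error(split_cases(character(0), 0.2, 1), "no cases")
  expect_error(split_cases(1:3, 0.2, 1), "empty partition")
})

test_that("cosine annealing with warm restarts hits the stated anchors", {
  cfg <- train_config(epochs = 100, restart_period = 25)
  expect_equal(lr_at(0, cfg), 1e-3)
  expect_equal(lr_at(25, cfg), 1e-3)   # restart snaps back to the maximum
  expect_equal(lr_at(50, cfg), 1e-3)
  expect_equal(lr_at(12.5, cfg), 1e-5 + 0.5 * (1e-3 - 1e-5), tolerance = 1e-12)
  expect_equal(lr_at(25 - 1e-9, cfg), 1e-5, tolerance = 1e-6)
  eps <- seq(0, 100, by = 0.25)
  lrs <- lr_at(eps, cfg)
  expect_true(all(lrs >= 1e-5 - 1e-15 & lrs <= 1e-3 + 1e-15))
  expect_equal(lr_at(eps, cfg), lr_at(eps + 25, cfg), tolerance = 1e-15)
})

test_that("training runs, records history, and replays under its seed", {
  cases <- lapply(1:4, function(i)
    normalize_volume(tiny_phantom(seed = 40 + i, shape = c(16, 16, 16),
                                  radii = c(3, 4))))
  cfg <- train_config(epochs = 2, restart_period = 2, seed = 5,
                      val_fraction = 0.25,
                      model = toy_net_config(base = 2, C = 2),
                      augment = augment_config(rotation_max_deg = 5))
  r1 <- train(cfg, cases)
  expect_equal(nrow(r1$history), 2)
  expect_true(all(is.finite(r1$history$train_loss)))
  expect_true(all(c("val_dsc", "val_iou", "val_voe") %in%
                    names(r1$history)))
  r2 <- train(cfg, cases)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
})

test_that("one Adam step at a small rate decreases the loss on a fixed batch", {
  ns <- asNamespace("esunet3d")
  cfg <- toy_net_config(base = 2, C = 2)
  net <- build_network(cfg, seed = 3)
  ph <- normalize_volume(tiny_phantom(seed = 51, shape = c(16, 16, 16),
                                      radii = c(3, 4)))
  lcfg <- loss_config()
  st0 <- ns$train_step(net$params, cfg, ph, lcfg)
  state <- ns$adam_state_new(net$params)
  up <- ns$adam_step(net$params, st0$grads, state, 1e-4, c(0.9, 0.99))
  st1 <- ns$train_step(up$params, cfg, ph, lcfg)
  expect_lt(st1$loss, st0$loss)
})

test_that("the deep-supervision loss equals the mean of per-head losses", {
  ns <- asNamespace("esunet3d")
  cfg <- toy_net_config(base = 2, C = 2)
  net <- build_network(cfg, seed = 4)
  ph <- normalize_volume(tiny_phantom(seed = 52, shape = c(16, 16, 16),
                                      radii = c(3, 4)))
  st <- ns$train_step(net$params, cfg, ph, loss_config())
  pv <- predict_volume(net, ph$image)
  manual <- mean(vapply(pv$heads, function(h)
    total_loss(as.numeric(ph$label), as.numeric(h), loss_config()),
    numeric(1)))
  expect_equal(st$loss, manual, tolerance = 1e-10)
})

test_that("a constant-0.5 predictor floods the volume under the tie rule", {
  # zeroing every head projection makes each head output sigmoid(0) = 0.5;
  # with threshold 0.5 and ties to foreground the whole volume is predicted
  cfg <- toy_net_config(base = 2, C = 2)
  net <- build_network(cfg, seed = 8)
  for (j in 1:4) {
    net$params[[sprintf("head%d_w", j)]][] <- 0
    net$params[[sprintf("head%d_b", j)]][] <- 0
  }
  ph <- tiny_phantom(seed = 53, shape = c(16, 16, 16), radii = c(3, 4))
  pv <- predict_volume(net, ph$image)
  expect_true(all(pv$prob == 0.5))
  expect_true(all(pv$mask == 1L))
  tab <- evaluate(net, list(ph))
  V <- prod(dim(ph$label)); ny <- sum(ph$label)
  expect_equal(tab$dsc[tab$case == ph$meta$case_id], 2 * ny / (ny + V),
               tolerance = 1e-12)
})

test_that("evaluation reports per-case rows plus a mean row", {
  cfg <- toy_net_config(base = 2, C = 2)
  net <- build_network(cfg, seed = 9)
  cases <- lapply(1:2, function(i)
    normalize_volume(tiny_phantom(seed = 60 + i, shape = c(16, 16, 16),
                                  radii = c(3, 4))))
  tab <- evaluate(net, cases)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$case[3], "mean")
  expect_equal(tab$dsc[3], mean(tab$dsc[1:2]))
  expect_error(evaluate(net, list()), "empty case list")
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- train_config(epochs = 1, restart_period = 1, seed = 2,
                      val_fraction = 0.34,
                      model = toy_net_config(base = 2, C = 2),
                      augment = NULL)
  cases <- lapply(1:3, function(i)
    normalize_volume(tiny_phantom(seed = 70 + i, shape = c(16, 16, 16),
                                  radii = c(3, 4))))
  r <- train(cfg, cases)
  p <- file.path(dir, "ckpt.rds")
  save_checkpoint(r$checkpoint, p)
  ck <- load_checkpoint(p)
  expect_identical(ck$params, r$checkpoint$params)
  ev <- evaluate(ck, cases[1])
  expect_true(all(is.finite(ev$dsc)))
})
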