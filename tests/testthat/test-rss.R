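# Region Specific Scaling and the mirror/rotation augmentations.

test_that("per-axis probability solves the at-least-one-axis equation", {
  p <- per_axis_probability(0.5, 3)
  expect_equal(round(p, 4), 0.2063)
  expect_equal(1 - (1 - p)^3, 0.5, tolerance = 1e-12)
  expect_equal(per_axis_probability(0, 3), 0)
  expect_equal(per_axis_probability(1, 3), 1)
  expect_equal(per_axis_probability(0.5, 1), 0.5)
  expect_error(per_axis_probability(1.2, 3), "0, 1")
})

test_that("rss_config derives a consistent per-axis probability", {
  cfg <- rss_config()
  expect_equal((1 - cfg$p_axis)^cfg$n_axes, 1 - cfg$p_overall,
               tolerance = 1e-12)
  expect_error(rss_config(r1 = 1.2), "r1")
})

test_that("label bounds are the global min/max over all nonzero voxels", {
  lab <- array(0L, c(16, 16, 16))
  lab[6, 8, 10] <- 1L
  expect_equal(label_bounds(lab, "depth"), c(6, 6))
  expect_equal(label_bounds(lab, "height"), c(8, 8))
  expect_equal(label_bounds(lab, "width"), c(10, 10))

  lab[3:5, 3:5, 2] <- 1L
  lab[10:12, 10:12, 14] <- 1L
  idx <- which(lab == 1, arr.ind = TRUE)  # brute-force oracle
  for (ax in 1:3)
    expect_equal(label_bounds(lab, ax), c(min(idx[, ax]), max(idx[, ax])))

  expect_null(label_bounds(array(0L, c(4, 4, 4)), "height"))
})

test_that("rss_axis at r = 1 is the bit-exact identity", {
  ph <- tiny_phantom(seed = 3)
  out <- rss_axis(ph, "height", 1)
  expect_identical(out$image, ph$image)
  expect_identical(out$label, ph$label)
})

test_that("rss_axis rescales the label extent to round(r * extent)", {
  ph <- tiny_phantom(seed = 4, shape = c(48, 48, 48), radii = c(8, 12))
  for (ax in c("depth", "height", "width")) {
    b0 <- label_bounds(ph$label, ax)
    ext0 <- b0[2] - b0[1] + 1
    for (r in c(2 / 3, 0.8, 1.25, 3 / 2)) {
      out <- rss_axis(ph, ax, r)
      expect_equal(dim(out$image), dim(ph$image))
      expect_true(all(out$label %in% c(0L, 1L)))
      b1 <- label_bounds(out$label, ax)
      ext1 <- b1[2] - b1[1] + 1
      expect_lte(abs(ext1 - round(r * ext0)), 1)
      # total mass scales roughly with r along one axis
      ratio <- sum(out$label) / sum(ph$label)
      expect_gte(ratio, 0.8 * r)
      expect_lte(ratio, 1.2 * r)
    }
  }
})

test_that("enlargement keeps surviving outer-slab content, translated", {
  # distinctive outer-slab pattern: a coordinate ramp in the image
  ph <- tiny_phantom(seed = 5)
  D <- dim(ph$label)[1]
  ramp <- array(rep(seq_len(D), times = D * D), dim = dim(ph$label))
  ph$image[1, , , ] <- ramp
  b <- label_bounds(ph$label, "depth")
  r <- 3 / 2
  out <- rss_axis(ph, "depth", r)
  new_len <- round(r * (b[2] - b[1] + 1))
  excess <- (b[1] - 1) + new_len + (D - b[2]) - D
  crop_lo <- floor(excess / 2)
  # low outer slab slices crop_lo+1 .. b[1]-1 of the assembly came from
  # original slices 1 .. b[1]-1-crop_lo shifted by crop_lo
  if (b[1] - 1 - crop_lo >= 1) {
    surv <- out$image[1, seq_len(b[1] - 1 - crop_lo), , ]
    orig <- ph$image[1, crop_lo + seq_len(b[1] - 1 - crop_lo), , ]
    expect_identical(surv, orig)
  }
})

test_that("shrinking then enlarging by 1/r restores the extent", {
  ph <- tiny_phantom(seed = 6, shape = c(48, 48, 48), radii = c(8, 12))
  b0 <- label_bounds(ph$label, "height")
  for (r in c(0.7, 5 / 6)) {
    once <- rss_axis(ph, "height", r)
    back <- rss_axis(once, "height", 1 / r)
    b2 <- label_bounds(back$label, "height")
    expect_lte(abs((b2[2] - b2[1]) - (b0[2] - b0[1])), 2)
  }
})

test_that("reduction extent is monotone in r", {
  ph <- tiny_phantom(seed = 8, shape = c(48, 48, 48), radii = c(8, 12))
  ext <- function(r) {
    b <- label_bounds(rss_axis(ph, "width", r)$label, "width")
    b[2] - b[1] + 1
  }
  rs <- c(2 / 3, 0.75, 0.85, 0.95, 1)
  es <- vapply(rs, ext, numeric(1))
  expect_true(all(diff(es) >= -1))
})

test_that("empty labels pass through rss untouched, with a notice", {
  ph <- make_fixture_suite(2)$empty_label
  expect_message(out <- rss_axis(ph, "depth", 0.8), "empty label")
  expect_identical(out$image, ph$image)
  expect_error(rss_axis(tiny_phantom(1), "depth", 0.5), "outside")
})

test_that("apply_rss is deterministic under seed and records its choices", {
  ph <- tiny_phantom(seed = 10)
  set.seed(99); a <- apply_rss(ph)
  set.seed(99); b <- apply_rss(ph)
  expect_identical(a$image, b$image)
  expect_identical(a$label, b$label)
  expect_true(is.list(attr(a, "rss_applied")))
})

test_that("mirror is an involution and zero rotation the identity", {
  ph <- tiny_phantom(seed = 11)
  expect_identical(flip_sample(flip_sample(ph, 2), 2)$image, ph$image)
  expect_identical(rotate_sample(ph, c(0, 0, 0))$image, ph$image)
})

test_that("rotating +15 then -15 degrees nearly restores the label", {
  ph <- tiny_phantom(seed = 12, shape = c(48, 48, 48), radii = c(8, 12))
  fwd <- rotate_sample(ph, c(15, 0, 0))
  back <- rotate_sample(fwd, c(-15, 0, 0))
  m <- segmentation_metrics(back$label, ph$label)
  expect_gte(m$dsc, 0.9)
  expect_equal(dim(back$image), dim(ph$image))
  expect_true(all(back$label %in% c(0L, 1L)))
})

test_that("mirror_and_rotate preserves shape and label closure", {
  ph <- tiny_phantom(seed = 13)
  set.seed(3)
  out <- mirror_and_rotate(ph, augment_config())
  expect_equal(dim(out$image), dim(ph$image))
  expect_true(all(out$label %in% c(0L, 1L)))
})

test_that("full pipeline keeps shape, label closure and determinism", {
  ph <- tiny_phantom(seed = 14)
  cfg <- augment_config()
  set.seed(21); a <- augment_sample(ph, cfg)
  set.seed(21); b <- augment_sample(ph, cfg)
  expect_identical(a$label, b$label)
  expect_equal(dim(a$image), dim(ph$image))
  expect_true(all(a$label %in% c(0L, 1L)))
})
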