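# The ES-UNet network family: a 3D encoder-decoder with full-scale skip
# connections, squeeze-and-excitation channel attention on every
# encoder-to-decoder path, and deep-supervision heads fused by an
# equally-weighted mean.
#
# Feature maps are channels-last (D, H, W, C) internally; all public
# entry points accept and return channels-first (C, D, H, W) arrays to
# match the package's sample convention.

#' Network configuration
#'
#' @param n_levels Number of encoder/decoder levels `N` (default 4).
#'   Level `i` halves the spatial dims of level `i - 1`.
#' @param in_channels Input channels: 2 for CT + PET, 1 for a single
#'   modality.
#' @param base_channels Encoder channels at level 1; level `i` has
#'   `2^(i-1) * base_channels` (default 32).
#' @param path_channels Channels `C` every skip path is projected to before
#'   decoder concatenation (default 32).
#' @param attention_ratio Squeeze-and-excitation bottleneck ratio (default
#'   0.25; bottleneck width `round(ratio * C_in)`, floor 1).
#' @param variant Skip topology: `"both"` (full-scale encoder paths plus
#'   all decoder-to-decoder paths, the complete design), `"enc_only"`
#'   (full-scale encoder paths, only the adjacent decoder path),
#'   `"dec_only"` (same-level encoder path, all decoder paths), `"base"`
#'   (same-level encoder path and adjacent decoder path only — the
#'   conventional U-Net wiring).
#' @param deep_supervision If `TRUE` (default) every decoder level gets an
#'   auxiliary prediction head; predictions are fused by their mean.
#' @param threshold Probability threshold for binarising the fused map
#'   (default 0.5; ties go to foreground).
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_levels = 4, in_channels = 2, base_channels = 32,
                           path_channels = 32, attention_ratio = 0.25,
                           variant = c("both", "enc_only", "dec_only",
                                       "base"),
                           deep_supervision = TRUE, threshold = 0.5) {
  if (is.character(variant) && length(variant) == 1L &&
      !variant %in% c("both", "enc_only", "dec_only", "base"))
    stop("unknown variant '", variant,
         "'; valid variants: both, enc_only, dec_only, base")
  variant <- match.arg(variant)
  stopifnot(n_levels >= 2, in_channels %in% 1:2, base_channels >= 1,
            path_channels >= 1, attention_ratio > 0,
            threshold > 0, threshold < 1)
  structure(list(n_levels = as.integer(n_levels),
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 path_channels = as.integer(path_channels),
                 attention_ratio = attention_ratio, variant = variant,
                 deep_supervision = isTRUE(deep_supervision),
                 threshold = threshold),
            class = "network_config")
}

enc_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$n_levels) - 1L)

# incoming paths for decoder level j under the configured skip topology
routing <- function(cfg, j) {
  N <- cfg$n_levels
  enc_srcs <- if (cfg$variant %in% c("both", "enc_only")) seq_len(j) else j
  dec_srcs <- if (j >= N) integer(0)
  else if (cfg$variant %in% c("both", "dec_only")) (j + 1L):N
  else j + 1L
  c(lapply(enc_srcs, function(i) list(source = "enc", i = i)),
    lapply(dec_srcs, function(i) list(source = "dec", i = i)))
}

n_paths <- function(cfg, j) length(routing(cfg, j))
dec_ch <- function(cfg, j) n_paths(cfg, j) * cfg$path_channels

## --- parameter construction ------------------------------------------------

init_conv <- function(k, cin, cout) {
  fan <- k^3 * cin
  matrix(stats::rnorm(fan * cout, sd = sqrt(2 / fan)), fan, cout)
}

init_convt <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout * 8, sd = sqrt(2 / cin)), cin, cout * 8)
}

init_dense <- function(n, m) {
  matrix(stats::rnorm(n * m, sd = sqrt(2 / n)), n, m)
}

# no conv bias: batch norm directly after would cancel it anyway
add_conv_bn <- function(p, base, k, cin, cout) {
  p[[paste0(base, "_w")]] <- init_conv(k, cin, cout)
  p[[paste0(base, "_bng")]] <- rep(1, cout)
  p[[paste0(base, "_bnb")]] <- numeric(cout)
  p
}

add_attention <- function(p, base, cin, ratio) {
  width <- max(1L, as.integer(round(ratio * cin)))
  p[[paste0(base, "_w1")]] <- init_dense(cin, width)
  # start the squeeze bottleneck active so narrow gates cannot be born dead
  p[[paste0(base, "_b1")]] <- rep(1, width)
  p[[paste0(base, "_w2")]] <- init_dense(width, cin)
  p[[paste0(base, "_b2")]] <- numeric(cin)
  p
}

#' Build an ES-UNet network
#'
#' Assembles parameters for the encoder, the skip paths of the configured
#' topology (channel attention on every encoder-to-decoder path, none on
#' decoder-to-decoder paths), the decoder fusion blocks and the
#' deep-supervision heads.
#'
#' @param cfg A [network_config()].
#' @param seed Optional seed for the weight initialisation (fan-in-scaled
#'   Gaussian).
#' @return An object of class `es_network` with the parameter store and
#'   `param_count`, the total number of trainable values.
#' @export
build_network <- function(cfg = network_config(), seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  build <- function() {
    p <- list()
    ce <- enc_channels(cfg)
    C <- cfg$path_channels
    N <- cfg$n_levels
    for (i in seq_len(N)) {
      cin <- if (i == 1L) cfg$in_channels else ce[i - 1L]
      p <- add_conv_bn(p, sprintf("enc%d_c1", i), 3L, cin, ce[i])
      p <- add_conv_bn(p, sprintf("enc%d_c2", i), 3L, ce[i], ce[i])
    }
    for (j in seq_len(N)) {
      for (path in routing(cfg, j)) {
        i <- path$i
        base <- sprintf("p_%s%d_%d", path$source, i, j)
        if (path$source == "enc") {
          p <- add_attention(p, paste0(base, "_att"), ce[i],
                             cfg$attention_ratio)
          if (i < j) {
            p <- add_conv_bn(p, paste0(base, "_conv"), 3L, ce[i], C)
          } else {
            p <- add_conv_bn(p, paste0(base, "_c1"), 3L, ce[i], C)
            p <- add_conv_bn(p, paste0(base, "_c2"), 3L, C, C)
            p <- add_conv_bn(p, paste0(base, "_c3"), 1L, C, C)
          }
        } else if (i == j + 1L) {
          p[[paste0(base, "_tw")]] <- init_convt(dec_ch(cfg, i), C)
          p[[paste0(base, "_tb")]] <- numeric(C)
          p <- add_conv_bn(p, paste0(base, "_conv"), 3L, C, C)
        } else {
          p <- add_conv_bn(p, paste0(base, "_conv"), 3L, dec_ch(cfg, i), C)
        }
      }
      p <- add_conv_bn(p, sprintf("dec%d_conv", j), 3L,
                       n_paths(cfg, j) * C, dec_ch(cfg, j))
    }
    head_levels <- if (cfg$deep_supervision) seq_len(N) else 1L
    for (j in head_levels) {
      p[[sprintf("head%d_w", j)]] <- init_conv(1L, dec_ch(cfg, j), 1L)
      p[[sprintf("head%d_b", j)]] <- numeric(1)
    }
    p
  }
  params <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(cfg = cfg, params = params,
                 param_count = sum(vapply(params, length, numeric(1)))),
            class = "es_network")
}

#' @export
print.es_network <- function(x, ...) {
  cat(sprintf(
    "<es_network> variant '%s', %d levels, base %d, path channels %d, %s param(s)\n",
    x$cfg$variant, x$cfg$n_levels, x$cfg$base_channels, x$cfg$path_channels,
    format(x$param_count, big.mark = ",")))
  invisible(x)
}

## --- tape forward ----------------------------------------------------------

fw_conv_bn_relu <- function(tape, x, P, base, k) {
  h <- ag_conv3(tape, x, P[[paste0(base, "_w")]], NULL, k)
  h <- ag_batchnorm(tape, h, P[[paste0(base, "_bng")]],
                    P[[paste0(base, "_bnb")]])
  ag_relu(tape, h)
}

fw_attention <- function(tape, x, P, base) {
  v <- ag_gap(tape, x)
  h <- ag_vec_relu(tape, ag_dense(tape, v, P[[paste0(base, "_w1")]],
                                  P[[paste0(base, "_b1")]]))
  g <- ag_vec_sigmoid(tape, ag_dense(tape, h, P[[paste0(base, "_w2")]],
                                     P[[paste0(base, "_b2")]]))
  ag_scale_channels(tape, x, g)
}

check_divisible <- function(sp, cfg) {
  div <- 2L^(cfg$n_levels - 1L)
  if (any(sp %% div != 0L))
    stop("input spatial dims (", paste(sp, collapse = ","),
         ") must be divisible by ", div)
  invisible(div)
}

# full forward pass on the tape; image is channels-last (D,H,W,C)
net_forward_tape <- function(params, cfg, image, tape) {
  P <- lapply(params, function(v) ag_leaf(tape, v))
  sp <- dim(image)[1:3]
  check_divisible(as.integer(sp), cfg)
  N <- cfg$n_levels
  x <- ag_leaf(tape, image)
  enc <- vector("list", N)
  for (i in seq_len(N)) {
    if (i > 1L) x <- ag_maxpool(tape, x, 2L)
    x <- fw_conv_bn_relu(tape, x, P, sprintf("enc%d_c1", i), 3L)
    x <- fw_conv_bn_relu(tape, x, P, sprintf("enc%d_c2", i), 3L)
    enc[[i]] <- x
  }
  dec <- vector("list", N)
  for (j in seq(N, 1L)) {
    paths <- list()
    for (path in routing(cfg, j)) {
      i <- path$i
      base <- sprintf("p_%s%d_%d", path$source, i, j)
      if (path$source == "enc") {
        h <- fw_attention(tape, enc[[i]], P, paste0(base, "_att"))
        if (i < j) {
          h <- ag_maxpool(tape, h, 2L^(j - i))
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
        } else {
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c1"), 3L)
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c2"), 3L)
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c3"), 1L)
        }
      } else if (i == j + 1L) {
        h <- ag_convt2(tape, dec[[i]], P[[paste0(base, "_tw")]],
                       P[[paste0(base, "_tb")]])
        h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
      } else {
        h <- ag_resize_lin(tape, dec[[i]], sp %/% 2L^(j - 1L))
        h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
      }
      paths <- c(paths, list(h))
    }
    h <- if (length(paths) > 1L) ag_concat(tape, paths) else paths[[1L]]
    dec[[j]] <- fw_conv_bn_relu(tape, h, P, sprintf("dec%d_conv", j), 3L)
  }
  head_levels <- if (cfg$deep_supervision) seq_len(N) else 1L
  heads <- lapply(head_levels, function(j) {
    h <- ag_conv3(tape, dec[[j]], P[[sprintf("head%d_w", j)]],
                  P[[sprintf("head%d_b", j)]], 1L)
    if (j > 1L) h <- ag_resize_lin(tape, h, sp)
    ag_sigmoid(tape, h)
  })
  fused <- if (length(heads) > 1L) ag_mean_maps(tape, heads) else heads[[1L]]
  list(enc = enc, dec = dec, heads = heads, fused = fused, P = P)
}

## --- public forward wrappers (channels-first in/out) -----------------------

to_clast <- function(image) aperm(image, c(2, 3, 4, 1))
to_cfirst <- function(x) aperm(x, c(4, 1, 2, 3))

#' Run the encoder
#'
#' @param net An [build_network()] result.
#' @param image 4-D array `(C, D, H, W)`; spatial dims must be divisible by
#'   `2^(n_levels - 1)`.
#' @return List of `n_levels` feature maps `(C_i, D/2^(i-1), ...)`: channels
#'   double and spatial dims halve at every level.
#' @export
encoder_forward <- function(net, image) {
  stopifnot(inherits(net, "es_network"))
  if (length(dim(image)) == 3L) dim(image) <- c(1L, dim(image))
  stopifnot(dim(image)[1] == net$cfg$in_channels)
  check_divisible(as.integer(dim(image)[2:4]), net$cfg)
  tape <- tape_new()
  P <- lapply(net$params, function(v) ag_leaf(tape, v))
  x <- ag_leaf(tape, to_clast(image))
  out <- vector("list", net$cfg$n_levels)
  for (i in seq_len(net$cfg$n_levels)) {
    if (i > 1L) x <- ag_maxpool(tape, x, 2L)
    x <- fw_conv_bn_relu(tape, x, P, sprintf("enc%d_c1", i), 3L)
    x <- fw_conv_bn_relu(tape, x, P, sprintf("enc%d_c2", i), 3L)
    out[[i]] <- to_cfirst(x$val)
  }
  out
}

#' Run the full network on one volume
#'
#' @param net An `es_network`.
#' @param image 4-D array `(C, D, H, W)` (or 3-D for single-channel nets).
#' @return List with `prob` (fused probability volume, `(D, H, W)` in
#'   `[0, 1]`), `heads` (per-head probability volumes), and `mask` (the
#'   fused map thresholded at `cfg$threshold`, ties to foreground).
#' @export
predict_volume <- function(net, image) {
  stopifnot(inherits(net, "es_network"))
  if (length(dim(image)) == 3L) dim(image) <- c(1L, dim(image))
  tape <- tape_new()
  fw <- net_forward_tape(net$params, net$cfg, to_clast(image), tape)
  sp <- dim(image)[2:4]
  prob <- array(fw$fused$val, dim = sp)
  list(prob = prob,
       heads = lapply(fw$heads, function(h) array(h$val, dim = sp)),
       mask = array(as.integer(prob >= net$cfg$threshold), dim = sp))
}

#' Squeeze-and-excitation channel attention
#'
#' Global average pool per channel, bottleneck dense layer with ReLU of
#' width `round(ratio * C)` (floor 1), expansion back to `C` with sigmoid,
#' then channel-wise rescaling.  Output shape equals input shape; a gate
#' saturated at 1 returns the input unchanged.
#'
#' @param fmap Feature map `(C, D, H, W)`.
#' @param ratio Bottleneck ratio (default 0.25).
#' @param params Optional list with `w1`, `b1`, `w2`, `b2`; when `NULL`,
#'   weights are drawn from the current RNG via [attention_params()].
#' @return The gated feature map, same shape.
#' @export
channel_attention <- function(fmap, ratio = 0.25, params = NULL) {
  C <- dim(fmap)[1]
  if (is.null(params)) params <- attention_params(C, ratio)
  tape <- tape_new()
  P <- list(att_w1 = ag_leaf(tape, params$w1),
            att_b1 = ag_leaf(tape, params$b1),
            att_w2 = ag_leaf(tape, params$w2),
            att_b2 = ag_leaf(tape, params$b2))
  x <- ag_leaf(tape, to_clast(fmap))
  to_cfirst(fw_attention(tape, x, P, "att")$val)
}

#' @param C Channel count.
#' @rdname channel_attention
#' @export
attention_params <- function(C, ratio = 0.25) {
  width <- max(1L, as.integer(round(ratio * C)))
  if (width < 1L) stop("C * ratio must round to >= 1")
  list(w1 = init_dense(C, width), b1 = numeric(width),
       w2 = init_dense(width, C), b2 = numeric(C))
}

#' Run one skip path of a built network
#'
#' Applies the (level_i -> level_j) path module of `net` to a feature map:
#' encoder sources require `level_i <= level_j` (attention, then
#' down-sampling for `i < j` or the same-level conv stack for `i == j`);
#' decoder sources require `level_i > level_j` (transposed convolution for
#' the adjacent level, trilinear upsampling otherwise).
#'
#' @param net An `es_network`.
#' @param fmap Feature map `(C_in, D, H, W)` at level `level_i` resolution.
#' @param level_i Source level.
#' @param level_j Target decoder level.
#' @param source `"encoder"` or `"decoder"`.
#' @return Feature map `(path_channels, ...)` at level-`level_j` resolution.
#' @export
skip_path <- function(net, fmap, level_i, level_j,
                      source = c("encoder", "decoder")) {
  stopifnot(inherits(net, "es_network"))
  source <- match.arg(source)
  src <- if (source == "encoder") "enc" else "dec"
  if (src == "enc" && level_i > level_j)
    stop("encoder source requires level_i <= level_j")
  if (src == "dec" && level_i <= level_j)
    stop("decoder source requires level_i > level_j")
  base <- sprintf("p_%s%d_%d", src, level_i, level_j)
  if (!any(startsWith(names(net$params), base)))
    stop("no such path in variant '", net$cfg$variant, "': ", base)
  tape <- tape_new()
  P <- lapply(net$params, function(v) ag_leaf(tape, v))
  h <- ag_leaf(tape, to_clast(fmap))
  sp <- dim(fmap)[2:4]
  if (src == "enc") {
    h <- fw_attention(tape, h, P, paste0(base, "_att"))
    if (level_i < level_j) {
      h <- ag_maxpool(tape, h, 2L^(level_j - level_i))
      h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
    } else {
      h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c1"), 3L)
      h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c2"), 3L)
      h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c3"), 1L)
    }
  } else if (level_i == level_j + 1L) {
    h <- ag_convt2(tape, h, P[[paste0(base, "_tw")]],
                   P[[paste0(base, "_tb")]])
    h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
  } else {
    h <- ag_resize_lin(tape, h, sp * 2L^(level_i - level_j))
    h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
  }
  to_cfirst(h$val)
}

#' Run the decoder over an encoder pyramid
#'
#' @param net An `es_network`.
#' @param pyramid List of encoder feature maps `(C_i, ...)`, e.g. from
#'   [encoder_forward()].
#' @return List of `n_levels` decoder outputs; level `j` has
#'   `n_paths(j) * path_channels` channels at level-`j` resolution.
#' @export
decoder_forward <- function(net, pyramid) {
  stopifnot(inherits(net, "es_network"),
            length(pyramid) == net$cfg$n_levels)
  cfg <- net$cfg
  sp <- as.integer(dim(pyramid[[1]])[2:4])
  tape <- tape_new()
  P <- lapply(net$params, function(v) ag_leaf(tape, v))
  enc <- lapply(pyramid, function(f) ag_leaf(tape, to_clast(f)))
  dec <- vector("list", cfg$n_levels)
  for (j in seq(cfg$n_levels, 1L)) {
    paths <- list()
    for (path in routing(cfg, j)) {
      i <- path$i
      base <- sprintf("p_%s%d_%d", path$source, i, j)
      if (path$source == "enc") {
        h <- fw_attention(tape, enc[[i]], P, paste0(base, "_att"))
        if (i < j) {
          h <- ag_maxpool(tape, h, 2L^(j - i))
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
        } else {
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c1"), 3L)
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c2"), 3L)
          h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_c3"), 1L)
        }
      } else if (i == j + 1L) {
        h <- ag_convt2(tape, dec[[i]], P[[paste0(base, "_tw")]],
                       P[[paste0(base, "_tb")]])
        h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
      } else {
        h <- ag_resize_lin(tape, dec[[i]], sp %/% 2L^(j - 1L))
        h <- fw_conv_bn_relu(tape, h, P, paste0(base, "_conv"), 3L)
      }
      paths <- c(paths, list(h))
    }
    h <- if (length(paths) > 1L) ag_concat(tape, paths) else paths[[1L]]
    dec[[j]] <- fw_conv_bn_relu(tape, h, P, sprintf("dec%d_conv", j), 3L)
  }
  lapply(dec, function(d) to_cfirst(d$val))
}

#' Auxiliary deep-supervision head
#'
#' A `1x1x1` convolution to one channel, trilinear up-sampling by
#' `2^(level - 1)` to the full input resolution, then a sigmoid.
#'
#' @param fmap Decoder output `(C, D, H, W)` at level `level` resolution.
#' @param level Decoder level `L_j` (1 = full resolution).
#' @param full_shape Spatial dims of the network input; must equal the map
#'   dims times `2^(level - 1)`.
#' @param params Optional list with `w` (`C x 1` matrix) and `b`; defaults
#'   to RNG-drawn weights with zero bias (all-zero features then map to a
#'   constant 0.5).
#' @return Probability volume `(1, full_shape)` with values in `[0, 1]`.
#' @export
aux_head <- function(fmap, level, full_shape, params = NULL) {
  C <- dim(fmap)[1]
  sp <- as.integer(dim(fmap)[2:4])
  full_shape <- as.integer(full_shape)
  if (!identical(as.integer(sp * 2^(level - 1)), full_shape))
    stop("full_shape must equal the map dims times 2^(level-1)")
  if (is.null(params))
    params <- list(w = init_conv(1L, C, 1L), b = numeric(1))
  tape <- tape_new()
  h <- ag_conv3(tape, ag_leaf(tape, to_clast(fmap)),
                ag_leaf(tape, params$w), ag_leaf(tape, params$b), 1L)
  if (level > 1L) h <- ag_resize_lin(tape, h, full_shape)
  to_cfirst(ag_sigmoid(tape, h)$val)
}

#' Fuse deep-supervision predictions
#'
#' Voxel-wise equally weighted arithmetic mean of the head outputs.
#'
#' @param head_outputs List of probability volumes of identical shape.
#' @return The fused probability volume.
#' @export
fuse_predictions <- function(head_outputs) {
  stopifnot(length(head_outputs) >= 1L)
  d <- dim(head_outputs[[1]])
  for (h in head_outputs)
    if (!identical(dim(h), d))
      stop("head outputs must share one shape")
  Reduce(`+`, head_outputs) / length(head_outputs)
}
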