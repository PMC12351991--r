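# Region Specific Scaling (RSS) and the companion mirror/rotation
# augmentations.
#
# RSS rescales only the slab of the volume spanning the labelled region
# along one axis: the slab is resampled by a ratio r, the outer slabs are
# reattached unscaled, and the original extent is restored by mirror
# padding (r < 1) or symmetric cropping (r > 1).  Axis selection follows
# the per-axis probability calculus that makes the overall application
# probability come out at a chosen value.

AXES <- c("depth", "height", "width")

axis_index <- function(axis) {
  if (is.numeric(axis)) {
    stopifnot(axis %in% 1:3)
    return(as.integer(axis))
  }
  match(match.arg(axis, AXES), AXES)
}

#' Per-axis application probability
#'
#' Solves `1 - (1 - p)^n_axes = p_overall` for the probability `p` with
#' which each axis must be independently selected so that at least one axis
#' is transformed with overall probability `p_overall`.  For
#' `p_overall = 0.5` over 3 axes this gives `1 - 0.5^(1/3) ~= 0.2063`.
#'
#' @param p_overall Target overall probability in `[0, 1]`.
#' @param n_axes Number of independently selectable axes (default 3).
#' @return The per-axis probability.
#' @export
per_axis_probability <- function(p_overall, n_axes = 3) {
  if (p_overall < 0 || p_overall > 1)
    stop("`p_overall` must lie in [0, 1]")
  stopifnot(n_axes >= 1)
  1 - (1 - p_overall)^(1 / n_axes)
}

#' RSS configuration
#'
#' @param r1 Lower bound of the scaling ratio (default 2/3).
#' @param r2 Upper bound of the scaling ratio (default 3/2).
#' @param p_overall Probability that at least one axis is transformed
#'   (default 0.5); the per-axis probability is derived from it.
#' @param n_axes Number of axes (3).
#' @param split_draw If `TRUE`, draw `r` by a fair coin between
#'   `Uniform(r1, 1)` and `Uniform(1, r2)` instead of one
#'   `Uniform(r1, r2)` draw (default `FALSE`).
#' @return A list of class `rss_config` with the derived `p_axis`.
#' @export
rss_config <- function(r1 = 2 / 3, r2 = 3 / 2, p_overall = 0.5, n_axes = 3,
                       split_draw = FALSE) {
  if (!(r1 > 0 && r1 <= 1 && r2 >= 1))
    stop("need 0 < r1 <= 1 <= r2")
  p_axis <- per_axis_probability(p_overall, n_axes)
  structure(list(r1 = r1, r2 = r2, p_overall = p_overall, n_axes = n_axes,
                 p_axis = p_axis, split_draw = split_draw),
            class = "rss_config")
}

#' Augmentation configuration
#'
#' Fixed pipeline order: mirror, then rotation, then RSS.
#'
#' @param mirror_prob Probability of flipping along one randomly chosen
#'   spatial axis (default 0.5).
#' @param rotation_max_deg Maximum absolute rotation angle in degrees about
#'   each axis (default 15).
#' @param rss An [rss_config()].
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(mirror_prob = 0.5, rotation_max_deg = 15,
                           rss = rss_config()) {
  stopifnot(mirror_prob >= 0, mirror_prob <= 1, rotation_max_deg >= 0,
            inherits(rss, "rss_config"))
  structure(list(mirror_prob = mirror_prob,
                 rotation_max_deg = rotation_max_deg, rss = rss),
            class = "augment_config")
}

#' Label bounds along an axis
#'
#' Global inclusive (min, max) 1-based indices, along the given axis, of
#' all nonzero voxels of the whole 3-D label — the two lesion-bounding
#' planes RSS scales between.  Disjoint lesions contribute jointly, so the
#' bounds span all of them.
#'
#' @param label 3-D binary array.
#' @param axis `"depth"`, `"height"`, `"width"` or 1:3.
#' @return Integer `c(lo, hi)`, or `NULL` for an all-zero label.
#' @export
label_bounds <- function(label, axis) {
  ax <- axis_index(axis)
  check_binary_label(as.integer(label))
  present <- apply(label != 0, ax, any)
  idx <- which(present)
  if (length(idx) == 0L) return(NULL)
  c(min(idx), max(idx))
}

# concatenate arrays along spatial axis `ax` (1..3); arrays are either 3-D
# labels or 4-D (C,D,H,W) images, `off` shifts the axis for 4-D input
cat_axis <- function(parts, ax) {
  parts <- parts[vapply(parts, function(p) dim(p)[ax] > 0, logical(1))]
  if (length(parts) == 1L) return(parts[[1]])
  nd <- length(dim(parts[[1]]))
  perm <- c(ax, setdiff(seq_len(nd), ax))
  rot <- lapply(parts, aperm, perm = perm)
  lens <- vapply(rot, function(p) dim(p)[1], integer(1))
  rest <- dim(rot[[1]])[-1]
  flat <- prod(rest)
  out <- matrix(0, sum(lens), flat)
  at <- 0L
  for (i in seq_along(rot)) {
    out[at + seq_len(lens[i]), ] <- matrix(rot[[i]], nrow = lens[i],
                                           ncol = flat)
    at <- at + lens[i]
  }
  dim(out) <- c(sum(lens), rest)
  aperm(out, order(perm))
}

slice_axis <- function(x, ax, idx) {
  nd <- length(dim(x))
  args <- rep(list(quote(expr = )), nd)
  args[[ax]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

# reflect-style indices (edge voxel not repeated) for a pad of length p
mirror_idx <- function(n, p, low) {
  if (p == 0L) return(integer(0))
  # reflect across the boundary, cycling if the pad outruns the data
  base <- if (low) 2:n else (n - 1):1
  if (length(base) == 0L) base <- rep(1L, p)
  idx <- rep_len(c(base, rev(base)), p)
  if (low) rev(idx) else idx
}

resize_along_axis <- function(x, ax, new_len, nearest = FALSE) {
  nd <- length(dim(x))
  if (nd == 3L) {
    out_shape <- dim(x)
    out_shape[ax] <- new_len
    if (nearest) {
      array(as.integer(cpp_resize3_nn(array(as.numeric(x), dim = dim(x)),
                                      as.integer(dim(x)),
                                      as.integer(out_shape))),
            dim = out_shape)
    } else {
      array(cpp_resize3_lin(array(as.numeric(x), dim = dim(x)),
                            as.integer(dim(x)), as.integer(out_shape), 1L),
            dim = out_shape)
    }
  } else {
    nc <- dim(x)[1]
    sp <- dim(x)[2:4]
    out_sp <- sp
    out_sp[ax - 1L] <- new_len
    out <- array(0, dim = c(nc, out_sp))
    for (c in seq_len(nc))
      out[c, , , ] <- cpp_resize3_lin(array(x[c, , , ], dim = sp),
                                      as.integer(sp), as.integer(out_sp), 1L)
    out
  }
}

#' Apply RSS along one axis
#'
#' Rescales the slab spanning the labelled region by the ratio `r` along
#' `axis` (image channels trilinear, label nearest-neighbour), reattaches
#' the outer slabs unscaled, and restores the original extent: for `r < 1`
#' the assembly is centred and both ends are mirror-padded (odd remainder
#' on the low-index end); for `r > 1` the excess is cropped symmetrically
#' (odd remainder from the high-index end).  An empty label returns the
#' input unchanged with a notice.
#'
#' @param sample A [seg_sample()].
#' @param axis `"depth"`, `"height"`, `"width"` or 1:3.
#' @param r Scaling ratio in `[r1, r2]`.
#' @param cfg An [rss_config()] supplying the admissible ratio range.
#' @return The transformed [seg_sample()] (same shape, binary label).
#' @export
rss_axis <- function(sample, axis, r, cfg = rss_config()) {
  stopifnot(is_seg_sample(sample))
  ax <- axis_index(axis)
  if (r < cfg$r1 - 1e-12 || r > cfg$r2 + 1e-12)
    stop("r = ", r, " outside configured range [", cfg$r1, ", ", cfg$r2, "]")
  b <- label_bounds(sample$label, ax)
  if (is.null(b)) {
    message("rss_axis: empty label, returning input unchanged")
    return(sample)
  }
  L <- dim(sample$label)[ax]
  len <- b[2] - b[1] + 1L
  new_len <- max(1L, as.integer(round(r * len)))
  if (new_len == len) return(sample)  # reassembly would be the identity

  iax <- ax + 1L  # image axis offset for (C,D,H,W)
  pieces_img <- list()
  pieces_lab <- list()
  if (b[1] > 1L) {
    pieces_img <- c(pieces_img, list(slice_axis(sample$image, iax,
                                                seq_len(b[1] - 1L))))
    pieces_lab <- c(pieces_lab, list(slice_axis(sample$label, ax,
                                                seq_len(b[1] - 1L))))
  }
  slab_img <- slice_axis(sample$image, iax, b[1]:b[2])
  slab_lab <- slice_axis(sample$label, ax, b[1]:b[2])
  if (new_len != len) {
    slab_img <- resize_along_axis(slab_img, iax, new_len)
    slab_lab <- resize_along_axis(slab_lab, ax, new_len, nearest = TRUE)
  }
  pieces_img <- c(pieces_img, list(slab_img))
  pieces_lab <- c(pieces_lab, list(slab_lab))
  if (b[2] < L) {
    pieces_img <- c(pieces_img, list(slice_axis(sample$image, iax,
                                                (b[2] + 1L):L)))
    pieces_lab <- c(pieces_lab, list(slice_axis(sample$label, ax,
                                                (b[2] + 1L):L)))
  }
  img <- cat_axis(pieces_img, iax)
  lab <- cat_axis(pieces_lab, ax)
  Lp <- dim(lab)[ax]

  if (Lp < L) {
    pad <- L - Lp
    pad_lo <- as.integer(ceiling(pad / 2))
    pad_hi <- pad - pad_lo
    ilo <- mirror_idx(Lp, pad_lo, low = TRUE)
    ihi <- mirror_idx(Lp, pad_hi, low = FALSE)
    img <- cat_axis(list(slice_axis(img, iax, ilo), img,
                         slice_axis(img, iax, ihi))[c(length(ilo) > 0, TRUE,
                                                      length(ihi) > 0)], iax)
    lab <- cat_axis(list(slice_axis(lab, ax, ilo), lab,
                         slice_axis(lab, ax, ihi))[c(length(ilo) > 0, TRUE,
                                                     length(ihi) > 0)], ax)
  } else if (Lp > L) {
    excess <- Lp - L
    crop_lo <- as.integer(floor(excess / 2))
    keep <- (crop_lo + 1L):(crop_lo + L)
    img <- slice_axis(img, iax, keep)
    lab <- slice_axis(lab, ax, keep)
  }
  out <- sample
  out$image <- img
  out$label <- array(as.integer(lab), dim = dim(sample$label))
  out
}

#' Apply RSS over all axes with the configured probability calculus
#'
#' Visits the axes in the fixed order depth, height, width; each axis is
#' independently selected with probability `cfg$p_axis`, and a selected
#' axis draws `r ~ Uniform(r1, r2)` and applies [rss_axis()].  Per axis the
#' RNG is consumed as: one uniform for the selection, then (only if
#' selected) one uniform for the ratio — so seeded runs replay exactly.
#' Bounds are recomputed per axis, so an earlier axis's transform
#' influences later bounds (sequential semantics).
#'
#' @param sample A [seg_sample()].
#' @param cfg An [rss_config()].
#' @return The augmented sample; attribute `"rss_applied"` records the
#'   chosen axes and ratios.
#' @export
apply_rss <- function(sample, cfg = rss_config()) {
  applied <- list()
  for (ax in 1:3) {
    if (stats::runif(1) < cfg$p_axis) {
      r <- if (isTRUE(cfg$split_draw)) {
        if (stats::runif(1) < 0.5) stats::runif(1, cfg$r1, 1)
        else stats::runif(1, 1, cfg$r2)
      } else {
        stats::runif(1, cfg$r1, cfg$r2)
      }
      sample <- suppressMessages(rss_axis(sample, ax, r, cfg))
      applied[[AXES[ax]]] <- r
    }
  }
  attr(sample, "rss_applied") <- applied
  sample
}

#' Flip a sample along one spatial axis
#'
#' @param sample A [seg_sample()].
#' @param axis Spatial axis (1:3 or name).
#' @return The flipped sample.
#' @export
flip_sample <- function(sample, axis) {
  ax <- axis_index(axis)
  n <- dim(sample$label)[ax]
  sample$image <- slice_axis(sample$image, ax + 1L, n:1)
  sample$label <- array(as.integer(slice_axis(sample$label, ax, n:1)),
                        dim = dim(sample$label))
  sample
}

#' Rotate a sample about the three axes
#'
#' Applies rotations about depth, height and width (in that order) by the
#' given angles, composed into a single resampling pass about the volume
#' centre.  Image channels are interpolated trilinearly, the label with
#' nearest neighbour; voxels mapped from outside the volume are filled
#' with 0.
#'
#' @param sample A [seg_sample()].
#' @param angles_deg Length-3 numeric, degrees about (depth, height, width).
#' @return The rotated sample (same shape, binary label).
#' @export
rotate_sample <- function(sample, angles_deg) {
  stopifnot(length(angles_deg) == 3L)
  if (all(angles_deg == 0)) return(sample)
  th <- angles_deg * pi / 180
  # rotation about axis k mixes the other two voxel axes (z=depth, y=height,
  # x=width); forward map M = R_w %*% R_h %*% R_d, resampler takes inverse
  rot <- function(k, a) {
    M <- diag(3)
    ij <- setdiff(1:3, k)
    M[ij[1], ij[1]] <- cos(a); M[ij[2], ij[2]] <- cos(a)
    M[ij[1], ij[2]] <- -sin(a); M[ij[2], ij[1]] <- sin(a)
    M
  }
  M <- rot(3, th[3]) %*% rot(2, th[2]) %*% rot(1, th[1])
  A <- t(M)  # inverse of an orthogonal matrix
  sp <- dim(sample$label)
  nc <- dim(sample$image)[1]
  for (c in seq_len(nc)) {
    sample$image[c, , , ] <- cpp_warp3(array(sample$image[c, , , ], dim = sp),
                                       as.integer(sp), A, 1L, 0)
  }
  sample$label <- array(as.integer(cpp_warp3(array(as.numeric(sample$label),
                                                   dim = sp),
                                             as.integer(sp), A, 0L, 0)),
                        dim = sp)
  sample
}

#' Mirror and rotation augmentation
#'
#' With probability `mirror_prob` flips along one randomly chosen spatial
#' axis, then rotates about each of the three axes by angles drawn from
#' `Uniform(-rotation_max_deg, rotation_max_deg)`.  RNG consumption order:
#' one uniform for the mirror decision, one axis draw (always consumed),
#' then the three angles.
#'
#' @param sample A [seg_sample()].
#' @param cfg An [augment_config()].
#' @return The augmented sample.
#' @export
mirror_and_rotate <- function(sample, cfg = augment_config()) {
  do_mirror <- stats::runif(1) < cfg$mirror_prob
  ax <- sample.int(3L, 1L)
  if (do_mirror) sample <- flip_sample(sample, ax)
  angles <- stats::runif(3, -cfg$rotation_max_deg, cfg$rotation_max_deg)
  rotate_sample(sample, angles)
}

#' Full augmentation pipeline: mirror, rotate, then RSS
#'
#' @param sample A [seg_sample()].
#' @param cfg An [augment_config()].
#' @return The augmented sample.
#' @export
augment_sample <- function(sample, cfg = augment_config()) {
  apply_rss(mirror_and_rotate(sample, cfg), cfg$rss)
}
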