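# Seeded PET/CT-like phantoms with binary lesion masks.
#
# The phantoms stand in for co-registered head-and-neck style PET/CT cases:
# a structure channel with a few tissue-level intensity plateaus plus noise,
# an uptake channel with elevated signal confined to the lesion, and a
# connected, irregular-boundary lesion mask occupying a small voxel
# fraction (the class-imbalance regime the losses are designed for).

#' Phantom specification
#'
#' @param shape Volume dims (D, H, W), default `c(64, 64, 64)`.
#' @param n_lesions Number of lesions (default 1; 0 gives an empty label).
#' @param lesion_radius_range Min/max lesion semi-axis in voxels, default
#'   `c(6, 10)`; each lesion draws one semi-axis per spatial axis from this
#'   interval.
#' @param boundary_irregularity Amplitude of the low-order radial
#'   perturbation of the lesion surface, as a fraction of the radius
#'   (default 0.15; 0 gives exact ellipsoids).
#' @param noise_sd Gaussian noise standard deviation added to both channels
#'   (default 0.05, i.e. about 7\% of the smallest plateau step).
#' @param uptake_contrast Peak added uptake intensity inside the lesion
#'   relative to the uptake background (default 3).
#' @param seed RNG seed; identical spec + seed reproduces the phantom
#'   bit-for-bit.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), n_lesions = 1,
                         lesion_radius_range = c(6, 10),
                         boundary_irregularity = 0.15, noise_sd = 0.05,
                         uptake_contrast = 3, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0), n_lesions >= 0,
            length(lesion_radius_range) == 2L,
            lesion_radius_range[1] <= lesion_radius_range[2],
            boundary_irregularity >= 0, noise_sd >= 0, uptake_contrast > 0)
  rmax_eff <- lesion_radius_range[2] * (1 + boundary_irregularity)
  if (n_lesions > 0 && any(2 * rmax_eff + 4 > shape))
    stop("lesion radii too large for shape: need 2*",
         round(rmax_eff, 1), " + margin within (",
         paste(shape, collapse = ","), ")")
  structure(list(shape = shape, n_lesions = n_lesions,
                 lesion_radius_range = lesion_radius_range,
                 boundary_irregularity = boundary_irregularity,
                 noise_sd = noise_sd, uptake_contrast = uptake_contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# normalised direction-dependent radial perturbation, bounded in [-1, 1];
# a low-order polynomial in the direction cosines gives smooth lobes
# without external data
radial_perturbation <- function(nx, ny, nz, coef) {
  b <- cbind(nx, ny, nz, nx * ny, ny * nz, nx * nz,
             nx * nx - ny * ny, 3 * nz * nz - 1)
  drop(b %*% coef) / sum(abs(coef))
}

rasterize_lesion <- function(shape, centre, radii, irregularity, coef) {
  ax <- lapply(1:3, function(k) seq_len(shape[k]) - centre[k])
  dz <- array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape)
  dy <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
              dim = shape)
  dx <- array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  rho <- sqrt((dz / radii[1])^2 + (dy / radii[2])^2 + (dx / radii[3])^2)
  if (irregularity > 0) {
    nr <- sqrt(dz^2 + dy^2 + dx^2)
    nr[nr == 0] <- 1
    pert <- radial_perturbation(dz / nr, dy / nr, dx / nr, coef)
    lim <- 1 + irregularity * array(pert, dim = shape)
  } else {
    lim <- 1
  }
  list(mask = rho <= lim, rho = rho, lim = lim)
}

#' Generate a PET/CT-like phantom
#'
#' Channel 1 (structure-like) is a piecewise background of three intensity
#' plateaus (ambient, body, inner organ) plus Gaussian noise; channel 2
#' (uptake-like) is a low background with a smooth elevated signal inside
#' the lesion (peak height `uptake_contrast`) plus noise.  The label is the
#' union of `n_lesions` radially perturbed ellipsoids; each lesion is
#' 6-connected (the perturbation keeps the region star-shaped about its
#' centre).
#'
#' @param spec A [phantom_spec()].
#' @return A [seg_sample()] with 2 channels.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(32, 32, 32),
#'                                 lesion_radius_range = c(4, 6), seed = 7))
#' ph
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$shape
    label <- array(FALSE, dim = shape)
    uptake_signal <- array(0, dim = shape)
    rrange <- spec$lesion_radius_range
    rmax_eff <- rrange[2] * (1 + spec$boundary_irregularity)
    for (k in seq_len(spec$n_lesions)) {
      radii <- stats::runif(3, rrange[1], rrange[2])
      lo <- rmax_eff + 2
      centre <- vapply(1:3, function(a)
        stats::runif(1, 1 + lo, shape[a] - lo), numeric(1))
      coef <- stats::rnorm(8)
      les <- rasterize_lesion(shape, centre, radii,
                              spec$boundary_irregularity, coef)
      label <- label | les$mask
      # smooth profile: 1 at the centre, 1/2 at the lesion surface
      s <- pmax(0, 1 - les$rho / (2 * les$lim))
      uptake_signal <- pmax(uptake_signal, s * les$mask)
    }
    # structure channel: ambient 0, body plateau 0.35, inner organ 0.7
    body <- rasterize_lesion(shape, (shape + 1) / 2, 0.42 * shape, 0, 1)$mask
    organ <- rasterize_lesion(shape, (shape + 1) / 2 + 0.12 * shape,
                              0.16 * shape, 0, 1)$mask
    ct <- 0.35 * body + 0.35 * organ +
      stats::rnorm(prod(shape), sd = spec$noise_sd)
    pet <- 0.1 + spec$uptake_contrast * uptake_signal +
      stats::rnorm(prod(shape), sd = spec$noise_sd)
    image <- array(0, dim = c(2L, shape))
    image[1, , , ] <- ct
    image[2, , , ] <- pet
    seg_sample(image, array(as.integer(label), dim = shape),
               case_id = sprintf("phantom_seed%d", spec$seed))
  })
}

#' Deterministic fixture suite of edge-case phantoms
#'
#' Returns named samples covering the degenerate label configurations the
#' augmentation and metric code must survive: an empty label, a
#' single-voxel label, a full-volume label, a standard one-lesion case and
#' a two-lesion case (whose per-axis label bounds span both lesions).
#' Each case derives its own RNG stream from `(seed, case index)`.
#'
#' @param seed Integer seed.
#' @param shape Volume dims for all cases, default `c(32, 32, 32)`.
#' @return Named list of [seg_sample()] objects.
#' @export
make_fixture_suite <- function(seed = 1, shape = c(32, 32, 32)) {
  shape <- as.integer(shape)
  sub <- function(k) as.integer((seed * 131L + k) %% .Machine$integer.max)
  base_spec <- function(k, n, rr)
    phantom_spec(shape = shape, n_lesions = n, lesion_radius_range = rr,
                 seed = sub(k))
  empty <- make_phantom(base_spec(1L, 0L, c(3, 4)))
  empty$meta$case_id <- "empty_label"

  single <- make_phantom(base_spec(2L, 0L, c(3, 4)))
  ctr <- pmax(1L, shape %/% 2L)
  single$label[ctr[1], ctr[2], ctr[3]] <- 1L
  single$meta$case_id <- "single_voxel"

  full <- make_phantom(base_spec(3L, 0L, c(3, 4)))
  full$label[] <- 1L
  full$meta$case_id <- "full_volume"

  one <- make_phantom(base_spec(4L, 1L, c(4, 6)))
  one$meta$case_id <- "one_lesion"

  # two lesions at fixed, well-separated centres so the per-axis bounds
  # genuinely span two disjoint blobs
  two <- make_phantom(base_spec(5L, 0L, c(3, 4)))
  two_label <- array(FALSE, dim = shape)
  uptake <- array(0, dim = shape)
  centres <- rbind(0.3 * shape, 0.7 * shape)
  coefs <- with_seed(sub(6L), list(stats::rnorm(8), stats::rnorm(8)))
  for (k in 1:2) {
    les <- rasterize_lesion(shape, centres[k, ], c(3, 3.5, 4), 0.1,
                            coefs[[k]])
    two_label <- two_label | les$mask
    uptake <- pmax(uptake, pmax(0, 1 - les$rho / (2 * les$lim)) * les$mask)
  }
  two$label <- array(as.integer(two_label), dim = shape)
  two$image[2, , , ] <- two$image[2, , , ] + 3 * uptake
  two$meta$case_id <- "two_lesions"

  list(empty_label = empty, single_voxel = single, full_volume = full,
       one_lesion = one, two_lesions = two)
}

#' Write a set of phantoms as NIfTI cases with a manifest
#'
#' @param n Number of cases.
#' @param out_dir Output directory (created if missing).
#' @param shape Volume dims per case.
#' @param seed Base seed; case `i` uses `seed + i`.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return The manifest data.frame (also written to `manifest.csv`).
#' @export
write_phantom_cases <- function(n, out_dir, shape = c(64, 64, 64), seed = 1,
                                ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    ph <- make_phantom(phantom_spec(shape = shape, seed = seed + i, ...))
    id <- sprintf("case%03d", i)
    ct <- file.path(out_dir, paste0(id, "_ct.nii.gz"))
    pet <- file.path(out_dir, paste0(id, "_pet.nii.gz"))
    lab <- file.path(out_dir, paste0(id, "_label.nii.gz"))
    write_channel(array(ph$image[1, , , ], dim = shape), ph$meta, ct)
    write_channel(array(ph$image[2, , , ], dim = shape), ph$meta, pet)
    write_mask(ph$label, ph, lab)
    data.frame(case_id = id, ct = ct, pet = pet, label = lab,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
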