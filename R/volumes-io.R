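# Reading, writing and canonicalising NIfTI cases.

read_nifti_canonical <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  code <- if (inherits(xf, "try-error")) 0L else attr(xf, "code")
  if (!is.null(code) && isTRUE(code > 0)) {
    # one canonical anatomical orientation for all volumes
    RNifti::orientation(img) <- "RAS"
    xf <- RNifti::xform(img)
  }
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = if (inherits(xf, "try-error")) NULL else unclass(xf),
       spacing = RNifti::pixdim(img))
}

#' Read a PET/CT case from NIfTI files
#'
#' Loads a structure-like (CT) volume and optionally a co-registered
#' uptake-like (PET) volume plus a binary label mask, reorients everything
#' to a single canonical anatomical orientation, and stacks the channels in
#' (CT, PET) order.
#'
#' @param ct_path Path to the CT NIfTI file.
#' @param pet_path Optional path to the PET NIfTI file; must match the CT
#'   shape and affine.
#' @param label_path Optional path to the label NIfTI file; absent labels
#'   yield an all-zero mask and flag the sample as inference-only.
#' @param case_id Case identifier recorded in the metadata (defaults to the
#'   CT file name).
#' @return A [seg_sample()].
#' @export
read_case <- function(ct_path, pet_path = NULL, label_path = NULL,
                      case_id = NULL) {
  ct <- read_nifti_canonical(ct_path)
  if (length(dim(ct$data)) != 3L)
    stop("expected a 3-D volume in ", ct_path)
  vols <- list(ct$data)
  if (!is.null(pet_path)) {
    pet <- read_nifti_canonical(pet_path)
    if (!identical(dim(pet$data), dim(ct$data)))
      stop("CT/PET shape mismatch: (", paste(dim(ct$data), collapse = ","),
           ") vs (", paste(dim(pet$data), collapse = ","), ")")
    if (!is.null(ct$affine) && !is.null(pet$affine) &&
        max(abs(ct$affine - pet$affine)) > 1e-4)
      stop("CT/PET affine mismatch; volumes must be co-registered")
    vols <- c(vols, list(pet$data))
  }
  image <- array(0, dim = c(length(vols), dim(ct$data)))
  for (i in seq_along(vols)) image[i, , , ] <- vols[[i]]
  label <- NULL
  if (!is.null(label_path)) {
    lab <- read_nifti_canonical(label_path)
    if (!identical(dim(lab$data), dim(ct$data)))
      stop("label shape mismatch: (", paste(dim(lab$data), collapse = ","),
           ") vs (", paste(dim(ct$data), collapse = ","), ")")
    lv <- lab$data
    if (any(abs(lv - round(lv)) > 1e-6)) stop("non-integer label values")
    label <- array(as.integer(round(lv)), dim = dim(lv))
  }
  seg_sample(image, label, spacing = ct$spacing[1:3], affine = ct$affine,
             case_id = if (is.null(case_id)) basename(ct_path) else case_id)
}

#' Resample a sample to a target grid
#'
#' Image channels are resampled with trilinear interpolation and the label
#' with nearest-neighbour interpolation, so the label stays binary.  Voxel
#' spacing is rescaled to preserve physical extent.  When the target equals
#' the current shape the sample is returned unchanged.
#'
#' @param sample A [seg_sample()].
#' @param target_shape Integer vector of 3 positive dims (D, H, W).
#' @return The resampled [seg_sample()].
#' @export
resize_volume <- function(sample, target_shape) {
  stopifnot(is_seg_sample(sample))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("`target_shape` must be 3 positive integers")
  old <- dim(sample$image)[2:4]
  if (identical(as.integer(old), target_shape)) return(sample)
  nc <- dim(sample$image)[1]
  img <- array(0, dim = c(nc, target_shape))
  for (c in seq_len(nc)) {
    img[c, , , ] <- cpp_resize3_lin(array(sample$image[c, , , ], dim = old),
                                    as.integer(old), target_shape, 1L)
  }
  lab <- array(as.integer(cpp_resize3_nn(array(as.numeric(sample$label),
                                               dim = old),
                                         as.integer(old), target_shape)),
               dim = target_shape)
  meta <- sample$meta
  meta$spacing <- meta$spacing * as.numeric(old) / as.numeric(target_shape)
  out <- seg_sample(img, lab, spacing = meta$spacing, affine = meta$affine,
                    case_id = meta$case_id)
  out$meta$inference <- meta$inference
  out
}

#' Normalise image intensities
#'
#' Applies per-channel whole-volume intensity normalisation; the label is
#' untouched.  A constant-valued channel maps to all zeros under either
#' scheme rather than dividing by zero.
#'
#' @param sample A [seg_sample()].
#' @param scheme One of `"zscore_per_channel"` (default),
#'   `"minmax_per_channel"`, `"none"`.
#' @return The normalised [seg_sample()].
#' @export
normalize_volume <- function(sample,
                             scheme = c("zscore_per_channel",
                                        "minmax_per_channel", "none")) {
  stopifnot(is_seg_sample(sample))
  if (is.character(scheme) && length(scheme) == 1L &&
      !scheme %in% c("zscore_per_channel", "minmax_per_channel", "none"))
    stop("unknown scheme '", scheme, "'; valid schemes: ",
         "zscore_per_channel, minmax_per_channel, none")
  scheme <- match.arg(scheme)
  if (scheme == "none") return(sample)
  nc <- dim(sample$image)[1]
  for (c in seq_len(nc)) {
    v <- sample$image[c, , , ]
    if (scheme == "zscore_per_channel") {
      s <- stats::sd(v)
      sample$image[c, , , ] <- if (s == 0) 0 else (v - mean(v)) / s
    } else {
      rng <- range(v)
      sample$image[c, , , ] <- if (rng[1] == rng[2]) 0 else
        (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  sample
}

#' Write a binary mask as NIfTI
#'
#' Writes the mask with the affine/orientation and spacing of the reference
#' sample so it overlays the source volumes; a round-trip read reproduces
#' the mask exactly.
#'
#' @param mask 3-D binary array matching the reference spatial shape.
#' @param ref A [seg_sample()] (or its `meta` list) supplying affine and
#'   spacing.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @export
write_mask <- function(mask, ref, path) {
  meta <- if (is_seg_sample(ref)) ref$meta else ref
  ref_shape <- if (is_seg_sample(ref)) dim(ref$image)[2:4] else dim(mask)
  if (!identical(as.integer(dim(mask)), as.integer(ref_shape)))
    stop("mask shape (", paste(dim(mask), collapse = ","),
         ") does not match reference (", paste(ref_shape, collapse = ","), ")")
  check_binary_label(as.integer(mask))
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  if (!is.null(meta$spacing)) RNifti::pixdim(img) <- meta$spacing
  if (!is.null(meta$affine)) {
    RNifti::sform(img) <- structure(meta$affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an image channel as NIfTI (phantom export helper)
#' @noRd
write_channel <- function(vol, meta, path) {
  img <- RNifti::asNifti(vol)
  if (!is.null(meta$spacing)) RNifti::pixdim(img) <- meta$spacing
  if (!is.null(meta$affine)) RNifti::sform(img) <- structure(meta$affine,
                                                             code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write a case manifest
#'
#' A manifest is a comma-separated table with columns `case_id`, `ct`,
#' `pet`, `label` (empty entries for missing modalities).
#'
#' @param path Manifest file path.
#' @return `read_manifest()` returns a data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "ct")
  if (!all(need %in% names(df)))
    stop("manifest must have at least columns: ", paste(need, collapse = ", "))
  df
}

#' @param manifest Data.frame with columns `case_id`, `ct`, `pet`, `label`.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

# load every case of a manifest as seg_samples
load_manifest_cases <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    pet <- if (!is.null(row$pet) && nzchar(row$pet) && !is.na(row$pet))
      row$pet else NULL
    lab <- if (!is.null(row$label) && nzchar(row$label) && !is.na(row$label))
      row$label else NULL
    read_case(row$ct, pet, lab, case_id = row$case_id)
  })
}
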