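# The canonical in-memory case representation shared by every module.

#' Construct a segmentation sample
#'
#' A sample couples a multi-channel intensity volume with an aligned binary
#' label mask and spatial metadata.  The image uses axis order
#' (channel, depth, height, width); channel 1 is the structure-like (CT)
#' channel and channel 2, if present, the uptake-like (PET) channel.
#'
#' @param image 4-D numeric array `(C, D, H, W)` with `C` in `{1, 2}`, or a
#'   3-D array which is treated as a single channel.
#' @param label 3-D array of 0/1 with spatial dims matching `image`; `NULL`
#'   creates an all-zero mask and flags the sample as inference-only.
#' @param spacing Voxel spacing in mm per spatial axis (length 3).
#' @param affine Optional 4x4 voxel-to-world matrix kept for write-back.
#' @param case_id Case identifier string.
#' @return Object of class `seg_sample` with fields `image`, `label`, `meta`.
#' @export
seg_sample <- function(image, label = NULL, spacing = c(1, 1, 1),
                       affine = NULL, case_id = "case") {
  if (length(dim(image)) == 3L) dim(image) <- c(1L, dim(image))
  if (length(dim(image)) != 4L)
    stop("`image` must be a (C, D, H, W) array")
  nc <- dim(image)[1]
  if (!nc %in% c(1L, 2L))
    stop("channel count must be 1 (single modality) or 2 (CT + PET), got ", nc)
  sp <- dim(image)[2:4]
  inference <- is.null(label)
  if (inference) {
    label <- array(0L, dim = sp)
  } else {
    if (!identical(as.integer(dim(label)), as.integer(sp)))
      stop("label dims (", paste(dim(label), collapse = ","),
           ") do not match image spatial dims (", paste(sp, collapse = ","), ")")
    lv <- as.numeric(label)
    if (any(abs(lv - round(lv)) > 1e-8))
      stop("label contains non-integer values")
    if (any(!round(lv) %in% c(0, 1)))
      stop("label values must be 0 or 1")
    label <- array(as.integer(round(lv)), dim = sp)
  }
  structure(list(image = image, label = label,
                 meta = list(spacing = as.numeric(spacing), affine = affine,
                             case_id = case_id, inference = inference)),
            class = "seg_sample")
}

#' @export
print.seg_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<seg_sample %s> %d channel(s), %dx%dx%d, %d labelled voxels%s\n",
              x$meta$case_id, d[1], d[2], d[3], d[4], sum(x$label),
              if (isTRUE(x$meta$inference)) " [inference]" else ""))
  invisible(x)
}

is_seg_sample <- function(x) inherits(x, "seg_sample")

check_binary_label <- function(label) {
  if (any(!label %in% c(0L, 1L))) stop("label must be binary")
  invisible(NULL)
}
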