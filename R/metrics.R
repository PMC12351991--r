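# Volumetric overlap metrics on binary mask pairs.

#' Segmentation overlap metrics
#'
#' Computes the Dice similarity coefficient, intersection-over-union
#' (Jaccard index), and volume overlap error between a predicted and a
#' reference binary mask, always on the full 3-D volumes:
#' `DSC = 2|A ∩ B| / (|A| + |B|)`, `IoU = |A ∩ B| / |A ∪ B|`,
#' `VOE = 1 - IoU`.
#'
#' When both masks are empty the pair is scored as a perfect match
#' (`DSC = IoU = 1`, `VOE = 0`) and flagged via `both_empty`, rewarding a
#' correct prediction of absence.
#'
#' @param pred Predicted binary mask (array of 0/1 or logical).
#' @param gt Reference binary mask, same shape as `pred`.
#' @return A list of class `seg_metrics` with `dsc`, `iou`, `voe`, the raw
#'   counts `intersection`, `pred_size`, `gt_size`, `union`, and the
#'   `both_empty` flag.
#' @examples
#' a <- array(0L, c(4, 4, 4)); b <- a
#' a[1:2, 1, 1] <- 1L; b[2:3, 1, 1] <- 1L
#' segmentation_metrics(a, b)
#' @export
segmentation_metrics <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("mask shapes differ: (", paste(dim(pred), collapse = ","),
         ") vs (", paste(dim(gt), collapse = ","), ")")
  pred <- as.numeric(pred); gt <- as.numeric(gt)
  if (any(pred != 0 & pred != 1) || any(gt != 0 & gt != 1))
    stop("masks must be binary")
  inter <- sum(pred * gt)
  np <- sum(pred); ng <- sum(gt)
  uni <- np + ng - inter
  both_empty <- np == 0 && ng == 0
  if (both_empty) {
    dsc <- 1; iou <- 1
  } else {
    dsc <- 2 * inter / (np + ng)
    iou <- inter / uni
  }
  structure(list(dsc = dsc, iou = iou, voe = 1 - iou,
                 intersection = inter, pred_size = np, gt_size = ng,
                 union = uni, both_empty = both_empty),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("DSC %.4f | IoU %.4f | VOE %.4f (|pred| %d, |gt| %d, |∩| %d)%s\n",
              x$dsc, x$iou, x$voe, as.integer(x$pred_size),
              as.integer(x$gt_size), as.integer(x$intersection),
              if (x$both_empty) " [both empty]" else ""))
  invisible(x)
}

# one data.frame row per metrics record, plus a mean row
metrics_table <- function(records, ids = names(records)) {
  if (is.null(ids)) ids <- as.character(seq_along(records))
  rows <- do.call(rbind, lapply(seq_along(records), function(i) {
    m <- records[[i]]
    data.frame(case = ids[i], dsc = m$dsc, iou = m$iou, voe = m$voe,
               stringsAsFactors = FALSE)
  }))
  rbind(rows, data.frame(case = "mean", dsc = mean(rows$dsc),
                         iou = mean(rows$iou), voe = mean(rows$voe),
                         stringsAsFactors = FALSE))
}
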