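# Training objectives: focal loss, Dice loss, and the Dynamically Weighted
# Dice (DWD) loss whose denominator terms are reweighted by the gap between
# soft precision and soft recall coefficients.

#' Loss configuration
#'
#' Bundles every constant of the combined focal + DWD training objective.
#'
#' @param gamma Focusing parameter of the focal term, in `[0, 5]`.  Larger
#'   values down-weight easy voxels more aggressively.  Default 2.
#' @param alpha Weight of the DWD component relative to the focal component
#'   in the total loss.  Default 1.
#' @param epsilon Smoothing constant added to every ratio denominator so
#'   empty masks and saturated predictions stay finite.  Default `1e-6`.
#' @param pairing Which denominator term each dynamic weight multiplies.
#'   `"narrative"` (default) puts the precision weight `w_P` on the
#'   prediction mass `sum(p^2)` so that `w_P > 1` penalises false positives
#'   more strongly and the loss is magnified under precision/recall
#'   disparity; `"as_printed"` pairs the weights the other way round, which
#'   provably shrinks the loss under disparity, and is kept selectable to
#'   document the discrepancy.
#' @param weight_clip Length-2 numeric, bounds to which the dynamic weights
#'   are clamped.  With soft predictions the raw coefficients can exceed 1
#'   (e.g. `y = 1`, `p = 0.5` gives a soft precision of 2), driving a raw
#'   weight negative; clipping to `c(0, 2)` keeps the loss well defined
#'   while preserving the degenerate-to-Dice behaviour near equality.
#' @return An object of class `dwd_loss_config`.
#' @seealso [total_loss()], [dwd_loss()]
#' @export
loss_config <- function(gamma = 2, alpha = 1, epsilon = 1e-6,
                        pairing = c("narrative", "as_printed"),
                        weight_clip = c(0, 2)) {
  pairing <- match.arg(pairing)
  if (gamma < 0 || gamma > 5)
    stop("`gamma` must lie in [0, 5]")
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (length(weight_clip) != 2L || weight_clip[1] > weight_clip[2])
    stop("`weight_clip` must be c(low, high) with low <= high")
  structure(list(gamma = gamma, alpha = alpha, epsilon = epsilon,
                 pairing = pairing, weight_clip = weight_clip),
            class = "dwd_loss_config")
}

check_yp <- function(y, p) {
  if (length(y) != length(p))
    stop("`y` and `p` must have the same length (got ",
         length(y), " and ", length(p), ")")
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  if (any(y != 0 & y != 1)) stop("`y` must be binary")
  invisible(NULL)
}

#' Focal loss term
#'
#' Mean focal cross-entropy over all voxels: with
#' `p_t = y*p + (1-y)*(1-p)` the per-voxel term is
#' `-(1 - p_t)^gamma * log(p_t + epsilon)`.
#'
#' @param y Binary ground-truth vector/array (flattened internally).
#' @param p Predicted probabilities in `[0, 1]`, same length as `y`.
#' @param gamma Focusing parameter (default 2).
#' @param epsilon Log smoothing (default `1e-6`).
#' @return Non-negative scalar; 0 when `p == y` exactly (up to the effect
#'   of `epsilon`).
#' @export
focal_term <- function(y, p, gamma = 2, epsilon = 1e-6) {
  y <- as.numeric(y); p <- as.numeric(p)
  check_yp(y, p)
  pt <- y * p + (1 - y) * (1 - p)
  mean(-(1 - pt)^gamma * log(pt + epsilon))
}

#' Soft Dice loss
#'
#' `1 - 2*sum(y*p) / (sum(y^2) + sum(p^2) + epsilon)`.  Two empty masks
#' score 0 by convention.
#'
#' @inheritParams focal_term
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(y, p, epsilon = 1e-6) {
  y <- as.numeric(y); p <- as.numeric(p)
  check_yp(y, p)
  den <- sum(y * y) + sum(p * p)
  if (den == 0) return(0)
  1 - 2 * sum(y * p) / (den + epsilon)
}

#' Soft precision/recall coefficients and dynamic weights
#'
#' Computes the soft precision coefficient `C_P = sum(y*p) / sum(p^2)`, the
#' soft recall coefficient `C_R = sum(y*p) / sum(y^2)`, and the dynamic
#' weights `w_P = 1 - (C_P - C_R)` and `w_R = 1 - (C_R - C_P)`, clipped to
#' `weight_clip`.  Before clipping `w_P + w_R == 2`, and equality of the
#' coefficients gives both weights exactly 1.
#'
#' @inheritParams focal_term
#' @param weight_clip Clamp bounds for the weights (see [loss_config()]).
#' @return List with elements `c_p`, `c_r`, `w_p`, `w_r`.
#' @export
pr_coefficients <- function(y, p, epsilon = 1e-6, weight_clip = c(0, 2)) {
  y <- as.numeric(y); p <- as.numeric(p)
  check_yp(y, p)
  inter <- sum(y * p)
  c_p <- inter / (sum(p * p) + epsilon)
  c_r <- inter / (sum(y * y) + epsilon)
  w_p <- min(max(1 - (c_p - c_r), weight_clip[1]), weight_clip[2])
  w_r <- min(max(1 - (c_r - c_p), weight_clip[1]), weight_clip[2])
  list(c_p = c_p, c_r = c_r, w_p = w_p, w_r = w_r)
}

#' Dynamically Weighted Dice loss
#'
#' A Dice-style loss whose denominator terms are reweighted each call by
#' the current precision/recall imbalance.  Under the default
#' `"narrative"` pairing the loss is
#' `1 - 2*sum(y*p) / (w_R*sum(y^2) + w_P*sum(p^2) + epsilon)`,
#' which equals the plain Dice loss whenever `C_P == C_R` and grows
#' (is "magnified") as the coefficients diverge.
#'
#' @inheritParams focal_term
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
dwd_loss <- function(y, p, cfg = loss_config()) {
  y <- as.numeric(y); p <- as.numeric(p)
  check_yp(y, p)
  sy <- sum(y * y); sp <- sum(p * p)
  if (sy + sp == 0) return(0)
  co <- pr_coefficients(y, p, cfg$epsilon, cfg$weight_clip)
  den <- if (cfg$pairing == "narrative") {
    co$w_r * sy + co$w_p * sp
  } else {
    co$w_p * sy + co$w_r * sp
  }
  1 - 2 * sum(y * p) / (den + cfg$epsilon)
}

#' Combined training objective
#'
#' `focal_term(y, p, gamma) + alpha * dwd_loss(y, p)`, the per-sample
#' objective applied to every deep-supervision head during training.
#'
#' @inheritParams dwd_loss
#' @return Scalar loss, finite for all `p` in `[0, 1]`.
#' @export
total_loss <- function(y, p, cfg = loss_config()) {
  focal_term(y, p, cfg$gamma, cfg$epsilon) + cfg$alpha * dwd_loss(y, p, cfg)
}

# Analytic gradient of total_loss wrt p.  The DWD weights are treated as
# constants of the current prediction (the "dynamic" reading: the weights
# describe the present precision/recall state and are not differentiated
# through).  Verified against central finite differences in the tests.
total_loss_grad <- function(y, p, cfg = loss_config()) {
  y <- as.numeric(y); p <- as.numeric(p)
  V <- length(y)
  pt <- y * p + (1 - y) * (1 - p)
  dpt <- 2 * y - 1
  gfoc <- (cfg$gamma * (1 - pt)^(pmax(cfg$gamma - 1, 0)) * log(pt + cfg$epsilon) -
             (1 - pt)^cfg$gamma / (pt + cfg$epsilon)) * dpt / V
  sy <- sum(y * y); sp <- sum(p * p); inter <- sum(y * p)
  if (sy + sp == 0) return(gfoc)
  co <- pr_coefficients(y, p, cfg$epsilon, cfg$weight_clip)
  if (cfg$pairing == "narrative") {
    den <- co$w_r * sy + co$w_p * sp + cfg$epsilon
    wp_eff <- co$w_p
  } else {
    den <- co$w_p * sy + co$w_r * sp + cfg$epsilon
    wp_eff <- co$w_r
  }
  gdwd <- -2 * y / den + 4 * inter * wp_eff * p / den^2
  gfoc + cfg$alpha * gdwd
}
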