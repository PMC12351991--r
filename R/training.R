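# Training orchestration: case splitting, cosine-annealing warm restarts,
# Adam optimisation with deep-supervision loss aggregation, checkpointing
# and evaluation.

#' Training configuration
#'
#' @param epochs Total training epochs (default 100).
#' @param restart_period Warm-restart period in epochs (default 25); must
#'   divide `epochs`.
#' @param lr_max,lr_min Learning-rate bounds of the cosine schedule
#'   (defaults `1e-3` and `1e-5`).
#' @param adam_betas Adam first/second moment decay rates, default
#'   `c(0.9, 0.99)`.
#' @param batch_size Cases per optimisation step (default 1).
#' @param val_fraction Hold-out fraction for validation (default 0.2; the
#'   validation size is `floor(val_fraction * n)`).
#' @param seed Master seed: initialisation, shuffling and augmentation all
#'   derive from it.
#' @param loss A [loss_config()].
#' @param augment An [augment_config()], or `NULL` to train without
#'   augmentation.
#' @param model A [network_config()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, restart_period = 25, lr_max = 1e-3,
                         lr_min = 1e-5, adam_betas = c(0.9, 0.99),
                         batch_size = 1, val_fraction = 0.2, seed = 1,
                         loss = loss_config(), augment = augment_config(),
                         model = network_config()) {
  stopifnot(lr_min < lr_max, val_fraction > 0, val_fraction < 1,
            batch_size >= 1, epochs >= 1, restart_period >= 1)
  if (epochs %% restart_period != 0)
    stop("`restart_period` must divide `epochs`")
  structure(list(epochs = as.integer(epochs),
                 restart_period = as.integer(restart_period),
                 lr_max = lr_max, lr_min = lr_min, adam_betas = adam_betas,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 loss = loss, augment = augment, model = model),
            class = "train_config")
}

#' Split cases into optimisation and evaluation sets
#'
#' Shuffles the ids with the given seed and holds out
#' `floor(val_fraction * n)` cases for evaluation — the floor rule
#' reproduces an 80:20 split such as 224 -> (180, 44), 20 -> (16, 4),
#' 41 -> (33, 8).
#'
#' @param case_ids Vector of case identifiers.
#' @param val_fraction Hold-out fraction in (0, 1).
#' @param seed Shuffle seed.
#' @return List with `train` and `val` id vectors (disjoint, exhaustive).
#' @export
split_cases <- function(case_ids, val_fraction = 0.2, seed = 1) {
  n <- length(case_ids)
  if (n == 0L) stop("no cases to split")
  stopifnot(val_fraction > 0, val_fraction < 1)
  n_val <- floor(val_fraction * n)
  if (n_val == 0L || n_val == n)
    stop("split would leave an empty partition (n = ", n,
         ", val_fraction = ", val_fraction, ")")
  perm <- with_seed(seed, sample.int(n))
  list(train = case_ids[sort(perm[(n_val + 1L):n])],
       val = case_ids[sort(perm[seq_len(n_val)])])
}

#' Learning rate under cosine annealing with warm restarts
#'
#' Within each restart cycle of length `restart_period`,
#' `lr = lr_min + (lr_max - lr_min)/2 * (1 + cos(pi * t / period))` with
#' `t = epoch mod period`: the rate starts at `lr_max`, decays towards
#' `lr_min`, and snaps back to `lr_max` at every restart.
#'
#' @param step_epoch Epoch position (may be fractional).
#' @param cfg A [train_config()] (or any list with `lr_max`, `lr_min`,
#'   `restart_period`).
#' @return The learning rate, in `[lr_min, lr_max]`.
#' @export
lr_at <- function(step_epoch, cfg = train_config()) {
  t <- step_epoch %% cfg$restart_period
  cfg$lr_min + 0.5 * (cfg$lr_max - cfg$lr_min) *
    (1 + cos(pi * t / cfg$restart_period))
}

adam_state_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# one optimisation step on one sample; returns loss and updated params/state
train_step <- function(params, cfg_model, sample, loss_cfg) {
  tape <- tape_new()
  fw <- net_forward_tape(params, cfg_model, to_clast(sample$image), tape)
  y <- as.numeric(sample$label)
  losses <- lapply(fw$heads, function(h) ag_total_loss(tape, h, y, loss_cfg))
  total <- if (length(losses) > 1L) ag_mean_scalars(tape, losses)
  else losses[[1L]]
  tape_backward(tape, total)
  grads <- lapply(fw$P, function(nd) nd$grad)
  list(loss = total$val, grads = grads)
}

#' Train an ES-UNet model
#'
#' Per step the pipeline augments the sample (mirror/rotation then RSS),
#' runs the forward pass, scores every deep-supervision head with the
#' combined focal + DWD objective, averages the head losses, and takes an
#' Adam step at the cosine-annealed learning rate.  All randomness derives
#' from `cfg$seed`, so runs replay exactly.
#'
#' @param cfg A [train_config()].
#' @param cases List of [seg_sample()] objects, or a manifest data.frame
#'   (columns `case_id`, `ct`, `pet`, `label`) whose cases are loaded from
#'   disk.
#' @param split Optional precomputed [split_cases()] result; by default the
#'   cases are split internally with `cfg$val_fraction` and `cfg$seed`.
#' @param verbose Print one line per epoch.
#' @return List with `checkpoint` (the best-validation-DSC parameter set
#'   plus config) and `history` (per-epoch data.frame with train loss and
#'   validation DSC/IoU/VOE).
#' @export
train <- function(cfg, cases, split = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.data.frame(cases)) cases <- load_manifest_cases(cases)
  if (length(cases) == 0L) stop("empty case list")
  ids <- vapply(cases, function(s) s$meta$case_id, character(1))
  if (is.null(split)) {
    split <- if (length(cases) >= 2L)
      split_cases(seq_along(cases), cfg$val_fraction, cfg$seed)
    else list(train = 1L, val = integer(0))
  }
  tr_cases <- cases[split$train]
  va_cases <- cases[split$val]
  if (length(tr_cases) == 0L) stop("empty training split")

  net <- build_network(cfg$model, seed = cfg$seed)
  params <- net$params
  state <- adam_state_new(params)
  history <- NULL
  best <- list(dsc = -Inf, params = params)
  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$epochs)) {
    order_ <- sample.int(length(tr_cases))
    losses <- numeric(0)
    for (s in seq_along(order_)) {
      smp <- tr_cases[[order_[s]]]
      if (!is.null(cfg$augment)) smp <- augment_sample(smp, cfg$augment)
      lr <- lr_at(epoch - 1 + (s - 1) / length(order_), cfg)
      st <- train_step(params, cfg$model, smp, cfg$loss)
      if (!is.finite(st$loss))
        stop("non-finite loss at epoch ", epoch, ", step ", s,
             " (case ", smp$meta$case_id, ")")
      up <- adam_step(params, st$grads, state, lr, cfg$adam_betas)
      params <- up$params
      state <- up$state
      losses <- c(losses, st$loss)
    }
    val_row <- c(dsc = NA_real_, iou = NA_real_, voe = NA_real_)
    if (length(va_cases) > 0L) {
      net$params <- params
      ev <- evaluate(list(params = params, cfg = cfg$model,
                          threshold = cfg$model$threshold), va_cases)
      mr <- ev[ev$case == "mean", ]
      val_row <- c(dsc = mr$dsc, iou = mr$iou, voe = mr$voe)
      if (mr$dsc > best$dsc) best <- list(dsc = mr$dsc, params = params)
    } else {
      best <- list(dsc = NA_real_, params = params)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr_at(epoch - 1, cfg),
                                train_loss = mean(losses),
                                val_dsc = val_row[["dsc"]],
                                val_iou = val_row[["iou"]],
                                val_voe = val_row[["voe"]]))
    if (verbose)
      cat(sprintf("epoch %3d  lr %.2e  loss %.4f  val DSC %s\n", epoch,
                  lr_at(epoch - 1, cfg), mean(losses),
                  ifelse(is.na(val_row[["dsc"]]), "-",
                         sprintf("%.4f", val_row[["dsc"]]))))
  }
  checkpoint <- list(params = best$params, cfg = cfg$model,
                     threshold = cfg$model$threshold,
                     train_cfg = cfg,
                     train_ids = ids[split$train], val_ids = ids[split$val])
  list(checkpoint = checkpoint, history = history)
}

checkpoint_network <- function(checkpoint) {
  net <- structure(list(cfg = checkpoint$cfg, params = checkpoint$params,
                        param_count = sum(vapply(checkpoint$params, length,
                                                 numeric(1)))),
                   class = "es_network")
  net
}

#' Evaluate a checkpoint on a case list
#'
#' Runs the full volume through the network (no patching, no test-time
#' augmentation), thresholds the fused probability map (ties to
#' foreground), and computes DSC/IoU/VOE per case plus a mean row.  Cases
#' that fail (e.g. indivisible shapes) are reported and skipped.
#'
#' @param checkpoint A checkpoint from [train()] (any list with `params`
#'   and `cfg`), or an `es_network`.
#' @param cases List of [seg_sample()] objects or a manifest data.frame.
#' @return Data.frame with columns `case`, `dsc`, `iou`, `voe`.
#' @export
evaluate <- function(checkpoint, cases) {
  if (is.data.frame(cases)) cases <- load_manifest_cases(cases)
  if (length(cases) == 0L) stop("empty case list")
  net <- if (inherits(checkpoint, "es_network")) checkpoint
  else checkpoint_network(checkpoint)
  records <- list()
  ids <- character(0)
  for (smp in cases) {
    res <- try(predict_volume(net, smp$image), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("case ", smp$meta$case_id, " failed: ",
              attr(res, "condition")$message)
      next
    }
    records <- c(records, list(segmentation_metrics(res$mask, smp$label)))
    ids <- c(ids, smp$meta$case_id)
  }
  if (length(records) == 0L) stop("no case evaluated successfully")
  metrics_table(records, ids)
}

#' Save / load a checkpoint
#'
#' @param checkpoint A checkpoint list from [train()].
#' @param path File path (RDS).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Single-case memorization capacity check
#'
#' Overfits a toy network on one phantom: a fast end-to-end sanity check
#' that the architecture, losses and optimiser can drive the training DSC
#' towards 1 on a volume the model has the capacity to memorise.  Runs
#' plain Adam steps at a fixed learning rate (no augmentation, no
#' validation split, no annealing — this is a capacity probe, not a
#' training protocol) and stops as soon as the target DSC is reached.
#'
#' @param seed Seed for both the phantom (offset) and the initialisation.
#' @param shape Phantom dims (default `c(32, 32, 32)`).
#' @param base_channels,path_channels Toy network widths (default 8).
#' @param max_steps Step budget (default 200).
#' @param target_dsc Early-stop threshold (default 0.9).
#' @param check_every Evaluate the training DSC every this many steps.
#' @param lr Fixed Adam learning rate (default `1e-3`).
#' @return List with `dsc` (last measured), `steps` (steps taken),
#'   `reached` (whether the target was met), and the trained `net`.
#' @export
memorize_phantom <- function(seed = 1, shape = c(32, 32, 32),
                             base_channels = 8, path_channels = 8,
                             max_steps = 200, target_dsc = 0.9,
                             check_every = 10, lr = 1e-3) {
  ph <- normalize_volume(make_phantom(phantom_spec(
    shape = shape, lesion_radius_range = c(4, 6), seed = 100L + seed)))
  cfg <- network_config(base_channels = base_channels,
                        path_channels = path_channels)
  net <- build_network(cfg, seed = seed)
  params <- net$params
  state <- adam_state_new(params)
  lcfg <- loss_config()
  dsc <- 0; steps <- 0L
  for (step in seq_len(max_steps)) {
    st <- train_step(params, cfg, ph, lcfg)
    if (!is.finite(st$loss)) stop("non-finite loss at step ", step)
    up <- adam_step(params, st$grads, state, lr, c(0.9, 0.99))
    params <- up$params
    state <- up$state
    steps <- step
    if (step %% check_every == 0 || step == max_steps) {
      net$params <- params
      m <- segmentation_metrics(predict_volume(net, ph$image)$mask, ph$label)
      dsc <- m$dsc
      if (dsc > target_dsc) break
    }
  }
  list(dsc = dsc, steps = steps, reached = dsc > target_dsc, net = net)
}
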