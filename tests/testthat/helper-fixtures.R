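# Shared fixtures: everything is generated in code at test time.

# small two-channel phantom with one interior lesion
tiny_phantom <- function(seed = 7, shape = c(32, 32, 32), radii = c(4, 6),
                         irregularity = 0.15) {
  make_phantom(phantom_spec(shape = shape, n_lesions = 1,
                            lesion_radius_range = radii,
                            boundary_irregularity = irregularity,
                            seed = seed))
}

toy_net_config <- function(base = 4, C = 4, in_channels = 2, ...) {
  network_config(n_levels = 4, in_channels = in_channels,
                 base_channels = base, path_channels = C, ...)
}

# independent 6-connected flood fill used as a connectivity oracle
flood_fill_6 <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(TRUE)
  d <- dim(mask)
  visited <- array(FALSE, dim = d)
  queue <- matrix(idx[1, ], ncol = 3)
  visited[queue] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue) > 0) {
    nxt <- NULL
    for (s in seq_len(6)) {
      cand <- sweep(queue, 2, shifts[s, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
        cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) next
      keep <- mask[cand] == 1 & !visited[cand]
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) > 0) {
        visited[cand] <- TRUE
        nxt <- rbind(nxt, cand)
      }
    }
    queue <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else unique(nxt)
  }
  sum(visited) == nrow(idx)
}

# brute-force overlap metrics used as the oracle against the implementation
oracle_metrics <- function(pred, gt) {
  p <- which(pred == 1)
  g <- which(gt == 1)
  i <- length(intersect(p, g))
  u <- length(union(p, g))
  if (length(p) == 0 && length(g) == 0)
    return(list(dsc = 1, iou = 1, voe = 0))
  list(dsc = 2 * i / (length(p) + length(g)), iou = i / u, voe = 1 - i / u)
}

# straight-from-formula total loss oracle, independent of the package path
oracle_total_loss <- function(y, p, gamma = 2, alpha = 1, eps = 1e-6,
                              clip = c(0, 2)) {
  pt <- y * p + (1 - y) * (1 - p)
  focal <- mean(-(1 - pt)^gamma * log(pt + eps))
  inter <- sum(y * p); sy <- sum(y^2); sp <- sum(p^2)
  if (sy + sp == 0) return(focal)
  cp <- inter / (sp + eps); cr <- inter / (sy + eps)
  wp <- min(max(1 - (cp - cr), clip[1]), clip[2])
  wr <- min(max(1 - (cr - cp), clip[1]), clip[2])
  focal + alpha * (1 - 2 * inter / (wr * sy + wp * sp + eps))
}
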