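# Independent brute-force oracles used to validate the package's image and
# statistics primitives. Deliberately naive implementations: per-voxel
# loops, queue-based flood fill, direct likelihood maximization.

# per-voxel counting of the density indices
oracle_density <- function(values, mask, spacing) {
  v <- numeric(sum(mask)); j <- 0L
  for (i in seq_along(values)) if (mask[i]) { j <- j + 1L; v[j] <- values[i] }
  n <- length(v)
  list(mld_hu = mean(v),
       perc15_hu = unname(stats::quantile(v, 0.15, type = 7)),
       ei_pct = 100 * sum(v < -950) / n,
       ggoi_pct = 100 * sum(v >= -800 & v < -700) / n,
       fibi_pct = 100 * sum(v >= -700) / n,
       volume_ml = n * prod(spacing) / 1000)
}

# queue-based flood fill labelling (26- or 6-connectivity)
oracle_flood_fill <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nextlab <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    nextlab <- nextlab + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- nextlab
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- q + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nextlab
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  attr(lab, "n_labels") <- nextlab
  lab
}

# cluster table from the flood-fill labels
oracle_cluster_table <- function(values, mask, spacing, threshold = -950,
                                 connectivity = 26L) {
  emph <- mask & values < threshold
  lab <- oracle_flood_fill(emph, connectivity)
  n <- attr(lab, "n_labels")
  counts <- if (n) tabulate(lab[lab > 0], nbins = n) else integer(0)
  data.frame(voxel_count = sort(counts, decreasing = TRUE),
             volume_mm3 = sort(counts, decreasing = TRUE) * prod(spacing))
}

# direct per-voxel distance minimization over all background voxels
oracle_edt <- function(mask, spacing) {
  d <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  bgmm <- sweep(bg, 2, spacing, `*`)
  out <- array(0, d)
  fg <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    p <- fg[r, ] * spacing
    out[fg[r, 1], fg[r, 2], fg[r, 3]] <-
      sqrt(min(colSums((t(bgmm) - p)^2)))
  }
  out
}

# logistic log-likelihood maximized with a generic optimizer
oracle_logistic <- function(X, y) {
  X <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# exhaustive signed-rank two-sided p over all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mu <- sum(r) / 2
  min(1, 2 * min(mean(ws <= W + 1e-9), mean(ws >= W - 1e-9)))
}

# exhaustive Mann-Whitney two-sided p over all group assignments
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - n1 * (n1 + 1) / 2
  }
  U <- u_of(x, y)
  mu <- n1 * length(y) / 2
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(U - mu) - 1e-9)
}

# build a ct_volume + mask pair from a raw HU array (whole array in-mask)
as_ct <- function(values, spacing = c(1, 1, 1)) {
  qctlung::ct_volume(values, spacing)
}
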