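# Independent reference implementations ("oracles") used to cross-check the
# package's compiled / vectorised code paths. They are deliberately written
# as plain exhaustive enumeration, sharing no code with the implementation.

oracle_quantize <- function(arr, mask, ng) {
  v <- arr[mask]
  vmin <- min(v)
  vmax <- max(v)
  lev <- array(0L, dim(arr))
  if (vmax > vmin) {
    lev[mask] <- pmin(floor((arr[mask] - vmin) / (vmax - vmin) * ng) + 1, ng)
  } else {
    lev[mask] <- 1L
  }
  lev
}

# all signed in-plane co-occurrence offsets at a distance (8 = 4 directions
# in both orientations; enumerating ordered pairs once per signed offset
# counts every unordered pair twice, i.e. builds the symmetric GLCM)
oracle_offsets <- function(distance) {
  base <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  rbind(base, -base) * distance
}

oracle_glcm_counts <- function(lev, mask, center, axes, radius, distance, ng) {
  counts <- matrix(0, ng, ng)
  dims <- dim(lev)
  offs <- oracle_offsets(distance)
  for (a in -radius:radius) {
    for (b in -radius:radius) {
      p1 <- center
      p1[axes] <- p1[axes] + c(a, b)
      if (any(p1 < 1) || any(p1 > dims)) next
      if (!mask[p1[1], p1[2], p1[3]]) next
      l1 <- lev[p1[1], p1[2], p1[3]]
      for (o in seq_len(nrow(offs))) {
        ab2 <- c(a, b) + offs[o, ]
        if (any(abs(ab2) > radius)) next
        p2 <- center
        p2[axes] <- p2[axes] + ab2
        if (any(p2 < 1) || any(p2 > dims)) next
        if (!mask[p2[1], p2[2], p2[3]]) next
        l2 <- lev[p2[1], p2[2], p2[3]]
        counts[l1, l2] <- counts[l1, l2] + 1
      }
    }
  }
  counts
}

oracle_autocorr <- function(counts) {
  n <- sum(counts)
  if (n == 0) {
    return(NA_real_)
  }
  idx <- seq_len(nrow(counts))
  sum(outer(idx, idx) * counts) / n
}

oracle_texture_map <- function(arr, mask, radius = 1, distance = 1, ng = 8) {
  lev <- oracle_quantize(arr, mask, ng)
  plane_axes <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- array(NA_real_, dim(arr))
  for (idx in which(mask)) {
    center <- arrayInd(idx, dim(arr))[1, ]
    vals <- numeric(0)
    for (axes in plane_axes) {
      counts <- oracle_glcm_counts(lev, mask, center, axes, radius, distance,
                                   ng)
      ac <- oracle_autocorr(counts)
      if (!is.na(ac)) vals <- c(vals, ac)
    }
    if (length(vals) > 0) out[idx] <- mean(vals)
  }
  out
}

# breadth-first flood fill over a logical 3D grid
oracle_flood_fill <- function(x, connectivity) {
  dims <- dim(x)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  for (start in which(x)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(start, dims)[1, ])
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (x[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}

# per-voxel OLS t statistic via lm(), independent of the vectorised path
oracle_voxel_t <- function(X, y, contrast) {
  fit <- stats::lm(y ~ X - 1)
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  sum(contrast * b) / sqrt(drop(t(contrast) %*% V %*% contrast))
}

# dense grid search over (d50, dx) minimising RSS of the decline sigmoid
oracle_grid_d50 <- function(t, score, d50_grid, dx_grid) {
  best <- list(rss = Inf)
  for (dx in dx_grid) {
    pred <- 48 / (1 + exp(outer(t, d50_grid, `-`) / dx))
    rss <- colSums((pred - score)^2)
    i <- which.min(rss)
    if (rss[i] < best$rss) {
      best <- list(d50 = d50_grid[i], dx = dx, rss = rss[i])
    }
  }
  best
}

# minimal t_map construction for cluster tests
make_tmap <- function(tarr, df = 30, mask = NULL, voxel_size = c(1, 1, 1)) {
  if (is.null(mask)) mask <- !is.na(tarr)
  structure(
    list(t = tarr, df = df, mask = mask, contrast = c(1, -1),
         label = "synthetic", effect = "group_contrast",
         voxel_size = voxel_size, affine = diag(c(voxel_size, 1))),
    class = "t_map"
  )
}

# noisy decline series from known parameters
make_series <- function(d50, dx, times, noise_sd = 0, round_scores = FALSE) {
  s <- alsfrs_sigmoid(times, d50, dx)
  if (noise_sd > 0) s <- s + rnorm(length(times), 0, noise_sd)
  s <- pmin(pmax(s, 0), 48)
  if (round_scores) s <- round(s)
  list(t = times, score = s)
}

random_masked_volume <- function(shape, mask_p = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- array(rnorm(prod(shape)), shape)
  mask <- array(runif(prod(shape)) < mask_p, shape)
  if (!any(mask)) mask[ceiling(prod(shape) / 2)] <- TRUE
  masked_volume(arr, mask)
}
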