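# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (enumeration,
# O(n^2) scans) distinct from the library code paths.

# --- SUV -------------------------------------------------------------------

oracle_suv <- function(C, W, D, t, thalf) {
  C * 2^(t / thalf) * (W / D)
}

# --- histogram / first-order ----------------------------------------------

oracle_entropy <- function(values, n_levels) {
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) return(0)
  width <- (hi - lo) / n_levels
  lev <- pmin(n_levels, floor((values - lo) / width) + 1)
  ent <- 0
  for (k in seq_len(n_levels)) {
    p <- sum(lev == k) / length(values)
    if (p > 0) ent <- ent - p * log2(p)
  }
  ent
}

oracle_first_order <- function(values, n_levels = 32) {
  n <- length(values)
  mu <- sum(values) / n
  m2 <- sum((values - mu)^2) / n
  m3 <- sum((values - mu)^3) / n
  m4 <- sum((values - mu)^4) / n
  lo <- min(values)
  hi <- max(values)
  if (hi > lo) {
    width <- (hi - lo) / n_levels
    lev <- pmin(n_levels, floor((values - lo) / width) + 1)
  } else lev <- rep(1, n)
  pr <- as.numeric(table(lev)) / n
  srt <- sort(values)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  c(energy = sum(values^2),
    entropy = -sum(pr * log2(pr)),
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    maximum = hi,
    mean = mu,
    mad = sum(abs(values - mu)) / n,
    median = med,
    minimum = lo,
    range = hi - lo,
    rms = sqrt(sum(values^2) / n),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    sd = sqrt(m2),
    uniformity = sum(pr^2),
    variance = m2)
}

# --- texture ---------------------------------------------------------------

oracle_dirs13 <- matrix(c(
  1, 0, 0,  0, 1, 0,  0, 0, 1,
  1, 1, 0,  1, -1, 0, 1, 0, 1,  1, 0, -1,
  0, 1, 1,  0, 1, -1,
  1, 1, 1,  1, 1, -1, 1, -1, 1, 1, -1, -1), ncol = 3, byrow = TRUE)

# symmetric pooled GLCM counts by O(n^2) ordered-pair enumeration
oracle_glcm_counts <- function(level_array, n_levels, dirs = oracle_dirs13) {
  idx <- which(level_array > 0)
  co <- arrayInd(idx, dim(level_array))
  lev <- level_array[idx]
  counts <- matrix(0, n_levels, n_levels)
  dirs_both <- rbind(dirs, -dirs)
  # enumerate all ordered voxel pairs and keep those whose offset is one of
  # the distance-1 directions
  dx <- outer(co[, 1], co[, 1], "-")
  dy <- outer(co[, 2], co[, 2], "-")
  dz <- outer(co[, 3], co[, 3], "-")
  for (k in seq_len(nrow(dirs_both))) {
    hit <- which(dx == dirs_both[k, 1] & dy == dirs_both[k, 2] &
                   dz == dirs_both[k, 3], arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 2]  # column index is the source voxel of the offset j - i
      j <- hit[r, 1]
      counts[lev[i], lev[j]] <- counts[lev[i], lev[j]] + 1
    }
  }
  counts
}

# pooled run-length counts by explicit run walking
oracle_glrlm_counts <- function(level_array, n_levels, dirs = oracle_dirs13) {
  d <- dim(level_array)
  maxlen <- max(d)
  counts <- matrix(0, n_levels, maxlen)
  at <- function(p) {
    if (any(p < 1) || any(p > d)) return(0L)
    level_array[p[1], p[2], p[3]]
  }
  idx <- which(level_array > 0)
  co <- arrayInd(idx, d)
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    for (i in seq_len(nrow(co))) {
      p <- co[i, ]
      lev <- at(p)
      if (at(p - dd) == lev) next  # not a run start
      len <- 1
      q <- p + dd
      while (at(q) == lev) {
        len <- len + 1
        q <- q + dd
      }
      counts[lev, len] <- counts[lev, len] + 1
    }
  }
  counts
}

oracle_glcm_features <- function(counts) {
  p <- counts / sum(counts)
  K <- nrow(p)
  i <- matrix(seq_len(K), K, K)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(K) * px)
  v <- sum((seq_len(K) - mu)^2 * px)
  lg <- function(q) ifelse(q > 0, log2(q), 0)
  kd <- 0:(K - 1)
  pd <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * K)
  psum <- vapply(ks, function(k) sum(p[(i + j) == k]), numeric(1))
  hxy <- -sum(p * lg(p))
  pxy <- outer(px, px)
  hx <- -sum(px * lg(px))
  sa <- sum(ks * psum)
  mud <- sum(kd * pd)
  c(glcm_autocorrelation = sum(i * j * p),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * p),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = if (v > 0) (sum(i * j * p) - mu^2) / v else 0,
    glcm_difference_entropy = -sum(pd * lg(pd)),
    glcm_difference_variance = sum((kd - mud)^2 * pd),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_energy = sum(p^2),
    glcm_entropy = hxy,
    glcm_homogeneity1 = sum(p / (1 + abs(i - j))),
    glcm_homogeneity2 = sum(p / (1 + (i - j)^2)),
    glcm_imc1 = if (hx > 0) (hxy - (-sum(p * lg(pxy)))) / hx else 0,
    glcm_imc2 = sqrt(max(0, 1 - exp(-2 * ((-sum(pxy * lg(pxy))) - hxy)))),
    glcm_idmn = sum(p / (1 + (i - j)^2 / K^2)),
    glcm_idn = sum(p / (1 + abs(i - j) / K)),
    glcm_inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    glcm_max_probability = max(p),
    glcm_sum_average = sa,
    glcm_sum_entropy = -sum(psum * lg(psum)),
    glcm_sum_variance = sum((ks - sa)^2 * psum),
    glcm_variance = sum((i - mu)^2 * p))
}

oracle_glrlm_features <- function(counts, n_voxels, n_dirs) {
  nr <- sum(counts)
  out <- c(sre = 0, lre = 0, gln = 0, rln = 0, rp = nr / (n_dirs * n_voxels),
           lgre = 0, hgre = 0, srlge = 0, srhge = 0, lrlge = 0, lrhge = 0)
  for (g in seq_len(nrow(counts))) for (l in seq_len(ncol(counts))) {
    r <- counts[g, l]
    if (r == 0) next
    out["sre"] <- out["sre"] + r / l^2
    out["lre"] <- out["lre"] + r * l^2
    out["lgre"] <- out["lgre"] + r / g^2
    out["hgre"] <- out["hgre"] + r * g^2
    out["srlge"] <- out["srlge"] + r / (g^2 * l^2)
    out["srhge"] <- out["srhge"] + r * g^2 / l^2
    out["lrlge"] <- out["lrlge"] + r * l^2 / g^2
    out["lrhge"] <- out["lrhge"] + r * g^2 * l^2
  }
  for (nm in c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge"))
    out[nm] <- out[nm] / nr
  out["gln"] <- sum(rowSums(counts)^2) / nr
  out["rln"] <- sum(colSums(counts)^2) / nr
  names(out) <- paste0("glrlm_", names(out))
  out
}

# --- watershed flood -------------------------------------------------------

neighbours6 <- function(dims) {
  n <- prod(dims)
  co <- arrayInd(seq_len(n), dims)
  nb <- matrix(0L, n, 6)
  k <- 0
  for (a in 1:3) for (s in c(-1L, 1L)) {
    k <- k + 1
    cc <- co
    cc[, a] <- cc[, a] + s
    ok <- cc[, a] >= 1 & cc[, a] <= dims[a]
    lin <- rep(0L, n)
    lin[ok] <- as.integer(cc[ok, 1] + dims[1] * ((cc[ok, 2] - 1) +
                                                   dims[2] * (cc[ok, 3] - 1)))
    nb[, k] <- lin
  }
  nb
}

# brute-force grayscale reconstruction of (f - h) under f, 6-connected
oracle_reconstruct <- function(f, h, nb) {
  rec <- f - h
  repeat {
    m <- rec
    for (k in 1:6) {
      ok <- nb[, k] > 0
      m[ok] <- pmax(m[ok], rec[nb[ok, k]])
    }
    m <- pmin(f, m)
    if (isTRUE(all.equal(m, rec, tolerance = 0))) return(rec)
    rec <- m
  }
}

# label 26-connected components of a logical vector by BFS in ascending
# linear-index order
oracle_cc26 <- function(maskvec, dims) {
  n <- length(maskvec)
  co <- arrayInd(seq_len(n), dims)
  lab <- integer(n)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in seq_len(n)) {
    if (!maskvec[s] || lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        p <- co[v, ] + offs[r, ]
        if (any(p < 1) || any(p > dims)) next
        u <- p[1] + dims[1] * ((p[2] - 1) + dims[2] * (p[3] - 1))
        if (maskvec[u] && lab[u] == 0L) {
          lab[u] <- nxt
          queue <- c(queue, u)
        }
      }
    }
  }
  lab
}

# Exhaustive marker flood: repeatedly take the unassigned mask voxel of
# maximal SUV among those 6-adjacent to an assigned voxel (ties towards the
# smaller linear index), assigning the label of its assigned 6-neighbour
# with maximal SUV (same tie rule). Markers recomputed from scratch via the
# brute reconstruction above.
oracle_watershed <- function(suvvec, maskvec, dims, h = 1.0) {
  nb <- neighbours6(dims)
  f <- rep(-Inf, length(maskvec))
  f[maskvec] <- suvvec[maskvec]
  rec <- oracle_reconstruct(f, h, nb)
  markers <- maskvec & (f - rec >= h - 1e-7)
  lab <- oracle_cc26(markers, dims)
  repeat {
    unass <- which(maskvec & lab == 0L)
    if (length(unass) == 0L) break
    touch <- rep(FALSE, length(unass))
    for (k in 1:6) {
      nk <- nb[unass, k]
      ok <- nk > 0
      touch[ok] <- touch[ok] | lab[nk[ok]] > 0L
    }
    frontier <- unass[touch]
    if (length(frontier) == 0L) break
    v <- frontier[order(-suvvec[frontier], frontier)][1]
    nbs <- nb[v, ]
    nbs <- nbs[nbs > 0]
    nbs <- nbs[lab[nbs] > 0L]
    best <- nbs[order(-suvvec[nbs], nbs)][1]
    lab[v] <- lab[best]
  }
  lab
}

# --- constrained assignment ------------------------------------------------

feasible_labelings_cache <- new.env(parent = emptyenv())

feasible_labelings <- function(n_regions) {
  key <- as.character(n_regions)
  if (!is.null(feasible_labelings_cache[[key]]))
    return(feasible_labelings_cache[[key]])
  cls <- tissue_classes()
  grid <- as.matrix(expand.grid(rep(list(seq_along(cls)), n_regions)))
  normal <- which(cls != "tumor")
  ok <- rep(TRUE, nrow(grid))
  for (cl in normal) ok <- ok & rowSums(grid == cl) <= 1
  out <- grid[ok, , drop = FALSE]
  feasible_labelings_cache[[key]] <- out
  out
}

oracle_assignment <- function(prob) {
  logp <- log(prob + 1e-9)
  labs <- feasible_labelings(nrow(prob))
  obj <- rep(0, nrow(labs))
  for (r in seq_len(nrow(prob))) obj <- obj + unname(logp[r, labs[, r]])
  best <- which.max(obj)
  list(labels = tissue_classes()[labs[best, ]], objective = obj[best])
}

# --- geometry fixtures -----------------------------------------------------

make_sphere_mask <- function(dims, centre, radius) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  r2 <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 +
    (co[, 3] - centre[3])^2
  array(r2 <= radius^2, dims)
}

# region object from a mask + SUV array on a unit-origin grid
make_region <- function(mask, suv_arr, spacing = 1) {
  lab <- array(0L, dim(mask))
  lab[mask] <- 1L
  regs <- extract_regions(region_label_map(lab, spacing),
                          suv_volume(suv_arr, spacing), min_volume_ml = 0)
  regs[[1]]
}

# random blob region inside a small grid (for feature-oracle fuzzing)
random_small_region <- function(dims = c(6, 6, 6), p_fill = 0.7,
                                suv_range = c(2, 8)) {
  repeat {
    mask <- array(runif(prod(dims)) < p_fill, dims)
    if (sum(mask) >= 4) break
  }
  suv_arr <- array(runif(prod(dims), suv_range[1], suv_range[2]), dims)
  make_region(mask, suv_arr)
}
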