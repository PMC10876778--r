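maps_to_matrix <- function(maps) {
  stopifnot(length(maps) >= 2L)
  d <- dim(maps[[1]]$data)
  y <- vapply(maps, function(m) {
    if (!all(dim(m$data) == d)) stop("maps must share one grid")
    as.numeric(m$data)
  }, numeric(prod(d)))
  y
}

pooled_t <- function(y, ga, gb) {
  n1 <- length(ga); n2 <- length(gb)
  m1 <- rowMeans(y[, ga, drop = FALSE])
  m2 <- rowMeans(y[, gb, drop = FALSE])
  v1 <- rowSums((y[, ga, drop = FALSE] - m1)^2)
  v2 <- rowSums((y[, gb, drop = FALSE] - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  t[se == 0] <- 0
  t
}

#' Voxel-wise two-sample t-test between two groups of maps
#'
#' Pooled-variance two-sample t per in-mask voxel (group B minus group A),
#' with `df = n1 + n2 - 2` and two-sided p-values. Voxels with zero pooled
#' variance get t = 0 (counted in attribute `"n_zero_variance"`).
#'
#' @param maps_a,maps_b lists of [activity_map()]s on a shared grid
#'   (at least 2 per group).
#' @param mask logical/0-1 3D array.
#' @return list with `t` and `p` (both `activity_map`s carrying `df`).
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask) {
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need at least 2 maps per group")
  y <- maps_to_matrix(c(maps_a, maps_b))
  d <- dim(maps_a[[1]]$data)
  mask <- array(as.logical(mask), dim = d)
  idx <- which(mask)
  n1 <- length(maps_a); n2 <- length(maps_b)
  tv <- pooled_t(y[idx, , drop = FALSE], seq_len(n1), n1 + seq_len(n2))
  df <- n1 + n2 - 2
  pv <- 2 * stats::pt(-abs(tv), df)
  tmap <- array(0, dim = d); tmap[idx] <- tv
  pmap <- array(1, dim = d); pmap[idx] <- pv
  affine <- maps_a[[1]]$affine
  out <- list(t = activity_map(tmap, affine, metric = "t", mask = mask, df = df),
              p = activity_map(pmap, affine, metric = "p", mask = mask, df = df))
  attr(out, "n_zero_variance") <- sum(tv == 0 & pv == 1)
  out
}

#' Label 26-connected clusters among flagged voxels
#'
#' Breadth-first labelling of `TRUE` voxels, where two voxels are connected
#' when they differ by at most one step along each axis (26-connectivity,
#' matching the 27-voxel ReHo neighbourhood convention).
#'
#' @param flag logical 3D array.
#' @return integer 3D array of cluster labels (0 = background), with the
#'   number of clusters in attribute `"n_clusters"`.
#' @export
label_clusters <- function(flag) {
  d <- dim(flag)
  labels <- array(0L, dim = d)
  idx <- which(flag)
  if (!length(idx)) {
    attr(labels, "n_clusters") <- 0L
    return(labels)
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin_off <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  coords <- arrayInd(idx, d)
  nlab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    labels[start] <- nlab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ci <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        ni <- ci + offs[o, ]
        if (any(ni < 1L) || any(ni > d)) next
        nv <- v + lin_off[o]
        if (flag[nv] && labels[nv] == 0L) {
          labels[nv] <- nlab
          queue <- c(queue, nv)
        }
      }
    }
  }
  attr(labels, "n_clusters") <- nlab
  labels
}

# sizes of two-sided supra-threshold clusters of a t vector laid on a grid;
# positive and negative exceedances are clustered separately
supra_cluster_sizes <- function(tvals, idx, dims, tcrit) {
  sizes <- integer()
  for (sign in c(1, -1)) {
    flag <- array(FALSE, dim = dims)
    flag[idx[sign * tvals > tcrit]] <- TRUE
    if (any(flag)) {
      lab <- label_clusters(flag)
      sizes <- c(sizes, tabulate(lab[lab > 0L]))
    }
  }
  sizes
}

#' Cluster-level family-wise-error inference by group-label permutation
#'
#' Thresholds the observed t-map two-sidedly at the cluster-defining p-value,
#' groups supra-threshold voxels by 26-connectivity (positive and negative
#' exceedances separately), and builds a null distribution of the maximum
#' cluster size by permuting group labels. The FWE-corrected p of a cluster
#' of size s is `(1 + #{perm maxima >= s}) / (1 + n_perm)`. When the number
#' of distinct group splits does not exceed `n_perm`, all splits are
#' enumerated instead of sampled.
#'
#' @param maps_a,maps_b lists of [activity_map()]s per group.
#' @param mask logical/0-1 3D array.
#' @param cdt_p two-sided cluster-defining p threshold (default 0.001).
#' @param fwe_alpha cluster-level significance level (default 0.05).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed for the permutation draw.
#' @return an object of class `cluster_set`: list of clusters (voxel indices,
#'   size, peak MNI coordinate, peak t, FWE p, sign, significance flag) plus
#'   the observed t-map and the settings used. Empty when no voxel passes the
#'   cluster-defining threshold.
#' @export
cluster_fwe <- function(maps_a, maps_b, mask, cdt_p = 0.001, fwe_alpha = 0.05,
                        n_perm = 1000, seed = 1) {
  if (n_perm < 100) warning("fewer than 100 permutations is unreliable")
  n1 <- length(maps_a); n2 <- length(maps_b)
  y <- maps_to_matrix(c(maps_a, maps_b))
  d <- dim(maps_a[[1]]$data)
  affine <- maps_a[[1]]$affine
  mask <- array(as.logical(mask), dim = d)
  idx <- which(mask)
  ym <- y[idx, , drop = FALSE]
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - cdt_p / 2, df)
  tv <- pooled_t(ym, seq_len(n1), n1 + seq_len(n2))

  # observed clusters, both signs
  clusters <- list()
  for (sgn in c(1, -1)) {
    flag <- array(FALSE, dim = d)
    flag[idx[sgn * tv > tcrit]] <- TRUE
    if (!any(flag)) next
    lab <- label_clusters(flag)
    for (l in seq_len(attr(lab, "n_clusters"))) {
      vox <- which(lab == l)
      tvox <- array(0, dim = d); tvox[idx] <- tv
      peak <- vox[which.max(sgn * tvox[vox])]
      clusters[[length(clusters) + 1L]] <- list(
        voxels = vox, size = length(vox),
        peak_mm = drop(voxel_to_mm(affine, arrayInd(peak, d))),
        peak_t = tvox[peak], sign = sgn)
    }
  }

  # permutation null of the maximum cluster size (exhaustive when feasible)
  n <- n1 + n2
  n_exact <- choose(n, n1)
  max_sizes <- numeric(0)
  if (length(clusters)) {
    if (n_exact <= n_perm) {
      splits <- utils::combn(n, n1)
      perm_sets <- lapply(seq_len(ncol(splits)), function(j) splits[, j])
    } else {
      set.seed(seed)
      perm_sets <- replicate(n_perm, sample.int(n, n1), simplify = FALSE)
    }
    ga_cols <- lapply(perm_sets, function(ga) {
      g <- numeric(n); g[ga] <- 1; g
    })
    gmat <- do.call(cbind, ga_cols)
    s1 <- ym %*% gmat
    ss1 <- (ym^2) %*% gmat
    stot <- rowSums(ym)
    sstot <- rowSums(ym^2)
    max_sizes <- vapply(seq_along(perm_sets), function(j) {
      m1 <- s1[, j] / n1
      m2 <- (stot - s1[, j]) / n2
      v1 <- ss1[, j] - n1 * m1^2
      v2 <- (sstot - ss1[, j]) - n2 * m2^2
      se <- sqrt(pmax(v1 + v2, 0) / df * (1 / n1 + 1 / n2))
      tp <- (m2 - m1) / se
      tp[!is.finite(tp)] <- 0
      sz <- supra_cluster_sizes(tp, idx, d, tcrit)
      if (length(sz)) max(sz) else 0
    }, numeric(1))
    for (i in seq_along(clusters)) {
      s <- clusters[[i]]$size
      clusters[[i]]$p_fwe <- (1 + sum(max_sizes >= s)) / (1 + length(max_sizes))
      clusters[[i]]$significant <- clusters[[i]]$p_fwe < fwe_alpha
    }
  }

  tmap <- array(0, dim = d); tmap[idx] <- tv
  structure(list(clusters = clusters,
                 t = activity_map(tmap, affine, metric = "t", mask = mask,
                                  df = df),
                 cdt_p = cdt_p, t_threshold = tcrit, fwe_alpha = fwe_alpha,
                 n_perm = length(max_sizes), exhaustive = n_exact <= n_perm,
                 null_max_sizes = max_sizes),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) at CDT p = %g (|t| > %.3f), %s perms\n",
              length(x$clusters), x$cdt_p, x$t_threshold, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  size %d, peak t = %.3f at (%g, %g, %g) mm, FWE p = %.4f%s\n",
                cl$size, cl$peak_t, cl$peak_mm[1], cl$peak_mm[2], cl$peak_mm[3],
                cl$p_fwe, if (isTRUE(cl$significant)) " *" else ""))
  invisible(x)
}

#' Cohen's d (pooled standard deviation)
#'
#' `(mean_b - mean_a) / s_pooled` with the df-weighted pooled SD.
#'
#' @param values_a,values_b numeric vectors (at least 2 each).
#' @return effect size d.
#' @export
cohens_d <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group")
  sp2 <- ((n1 - 1) * stats::var(values_a) + (n2 - 1) * stats::var(values_b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled standard deviation; d is undefined")
  (mean(values_b) - mean(values_a)) / sqrt(sp2)
}

#' Mean map value over a cluster of voxels
#'
#' @param map an [activity_map()].
#' @param voxels integer vector of linear voxel indices (nonempty, in-grid).
#' @return scalar mean.
#' @export
extract_roi_mean <- function(map, voxels) {
  stopifnot(inherits(map, "activity_map"))
  if (!length(voxels)) stop("empty cluster")
  if (any(voxels < 1L | voxels > length(map$data)))
    stop("cluster voxels outside the grid")
  mean(map$data[voxels])
}

#' Dice overlap between two voxel sets
#'
#' @param a,b integer vectors of linear voxel indices.
#' @return `2 |a intersect b| / (|a| + |b|)`.
#' @export
dice_overlap <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
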