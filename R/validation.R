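# Running box sum of width k along one dimension of a 3D array, zero-padded
# at the borders. Used for separable box-kernel erosion.
run_sum_dim <- function(arr, k, dim_idx) {
  h <- (k - 1L) %/% 2L
  d <- dim(arr)
  perm <- switch(dim_idx, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  da <- dim(a)
  mat <- matrix(a, nrow = da[1L])
  cs <- rbind(0, apply(mat, 2L, cumsum))
  n <- da[1L]
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h - 1L, 0L)
  out <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  aperm(array(out, dim = da), order(perm))
}

# Binary erosion with a k x k x k box structuring element; voxels outside
# the volume count as background (conservative at the borders).
erode_box <- function(vol, k) {
  s <- run_sum_dim(run_sum_dim(run_sum_dim(vol + 0, k, 1L), k, 2L), k, 3L)
  (abs(s - k^3) < 0.5) + 0L
}

#' Brain-edge mask by box erosion
#'
#' The brain edge is defined as the in-brain voxels removed by eroding the
#' brain mask with a cubic (default 5 x 5 x 5) structuring element:
#' edge = brain AND NOT erode(brain). Voxels beyond the volume border are
#' treated as background, so the edge follows the volume boundary too.
#'
#' @param brain A \code{\link{mask3d}}.
#' @param kernel_width Odd box width >= 3 (default 5).
#' @return A \code{mask3d} of edge voxels (a subset of the brain mask).
#' @export
brain_edge <- function(brain, kernel_width = 5L) {
  stopifnot(inherits(brain, "mask3d"))
  if (kernel_width %% 2L != 1L || kernel_width < 3L)
    stop("kernel_width must be an odd integer >= 3", call. = FALSE)
  core <- erode_box(brain$data, as.integer(kernel_width))
  mask3d(brain$data * (1L - core), affine = brain$affine)
}

#' Overlap of the clustering mask with a reference vein mask
#'
#' Quantifies how much of the graph-clustering mask falls inside an
#' externally derived vein mask (e.g. from SWI segmentation), and inside the
#' union of that mask with the brain edge.
#'
#' @param cluster_mask Nonempty \code{mask3d} from graph clustering.
#' @param vein_mask Reference vein \code{mask3d} on the same grid.
#' @param brain Brain \code{mask3d}.
#' @param kernel_width Erosion kernel width for the brain edge (default 5).
#' @return An \code{overlap_report}: list with \code{n_cluster_voxels},
#'   \code{n_brain_voxels}, \code{frac_of_brain}, \code{frac_in_vein},
#'   \code{frac_in_vein_or_edge}.
#' @export
overlap_report <- function(cluster_mask, vein_mask, brain,
                           kernel_width = 5L) {
  stopifnot(inherits(cluster_mask, "mask3d"), inherits(vein_mask, "mask3d"),
            inherits(brain, "mask3d"))
  check_same_grid(dim(cluster_mask$data), cluster_mask$affine,
                  dim(brain$data), brain$affine, what = "cluster and brain masks")
  check_same_grid(dim(vein_mask$data), vein_mask$affine,
                  dim(brain$data), brain$affine, what = "vein and brain masks")
  ncl <- sum(cluster_mask$data)
  if (ncl == 0L) stop("cluster mask is empty", call. = FALSE)
  edge <- brain_edge(brain, kernel_width)$data
  vein_or_edge <- pmin(vein_mask$data + edge, 1L)
  structure(list(
    n_cluster_voxels = ncl,
    n_brain_voxels = sum(brain$data),
    frac_of_brain = ncl / sum(brain$data),
    frac_in_vein = sum(cluster_mask$data * vein_mask$data) / ncl,
    frac_in_vein_or_edge = sum(cluster_mask$data * vein_or_edge) / ncl),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<overlap_report>\n",
    "  cluster voxels:        %d (%.1f%% of brain)\n",
    "  in vein mask:          %.1f%%\n",
    "  in vein or brain edge: %.1f%%\n"),
    x$n_cluster_voxels, 100 * x$frac_of_brain, 100 * x$frac_in_vein,
    100 * x$frac_in_vein_or_edge))
  invisible(x)
}

#' Compare temporal SD inside vs. outside the clustering mask
#'
#' Welch two-sample (unequal-variance) t-test of per-voxel temporal standard
#' deviations, contrasting voxels inside the clustering mask with in-brain
#' voxels outside it. Venous voxels are expected to show elevated SD, but
#' the distributions overlap, so this is a supporting check rather than a
#' classifier.
#'
#' @param sd An \code{sd_map} from \code{\link{temporal_sd_map}}.
#' @param cluster_mask \code{mask3d} of clustered (venous) voxels.
#' @param brain Brain \code{mask3d}.
#' @return An \code{sd_comparison}: list with \code{mean_sd_in},
#'   \code{mean_sd_out}, \code{statistic} (Welch t), \code{p_value},
#'   \code{n_in}, \code{n_out}.
#' @export
sd_comparison <- function(sd, cluster_mask, brain) {
  stopifnot(inherits(sd, "sd_map"), inherits(cluster_mask, "mask3d"),
            inherits(brain, "mask3d"))
  inside <- cluster_mask$data == 1L & brain$data == 1L
  outside <- cluster_mask$data == 0L & brain$data == 1L
  x_in <- sd$values[inside]
  x_out <- sd$values[outside]
  if (length(x_in) < 2L || length(x_out) < 2L)
    stop("both groups need at least 2 voxels", call. = FALSE)
  tt <- tryCatch(
    stats::t.test(x_in, x_out, var.equal = FALSE),
    error = function(e) {
      # degenerate constant groups: equal means have nothing to test
      if (isTRUE(all.equal(mean(x_in), mean(x_out))))
        list(statistic = c(t = 0), p.value = 1)
      else stop(e)
    })
  structure(list(mean_sd_in = mean(x_in), mean_sd_out = mean(x_out),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 n_in = length(x_in), n_out = length(x_out)),
            class = "sd_comparison")
}

#' @export
print.sd_comparison <- function(x, ...) {
  cat(sprintf(
    "<sd_comparison> mean SD in mask %.4g (n=%d) vs outside %.4g (n=%d); Welch t = %.2f, p = %.3g\n",
    x$mean_sd_in, x$n_in, x$mean_sd_out, x$n_out, x$statistic, x$p_value))
  invisible(x)
}

#' Seed-based correlation map
#'
#' Pearson correlation of one in-mask voxel's time course against every
#' in-mask voxel, as used to visualize how venous seeds reach supra-threshold
#' correlations while adjacent parenchyma seeds do not.
#'
#' @param x A \code{vox_matrix}.
#' @param seed 0-based (i, j, k) voxel coordinate; must be inside the mask
#'   and have nonzero variance.
#' @param graph_threshold Absolute-correlation cutoff marking voxels that
#'   would enter the binarized graph (e.g. the selected scan threshold).
#' @param display_threshold Display cutoff for the map (default 0.25).
#' @return A list with \code{map} (3D array of signed r, 0 outside the
#'   mask), \code{supra_graph} (\code{mask3d}, |r| >= graph_threshold),
#'   \code{supra_display} (\code{mask3d}, |r| >= display_threshold) and
#'   \code{seed}.
#' @export
seed_correlation_map <- function(x, seed, graph_threshold,
                                 display_threshold = 0.25) {
  stopifnot(inherits(x, "vox_matrix"))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3L)
  map <- x$index_map
  node <- which(map$coords[, 1L] == seed[1L] & map$coords[, 2L] == seed[2L] &
                map$coords[, 3L] == seed[3L])
  if (length(node) != 1L)
    stop("seed voxel (", paste(seed, collapse = ", "),
         ") is not inside the mask", call. = FALSE)
  z <- standardize_columns(x$values)
  if (all(z[, node] == 0))
    stop("seed voxel has zero variance", call. = FALSE)
  r <- clamp_corr(as.numeric(crossprod(z, z[, node])))
  vol <- array(0, dim = map$dim)
  vol[map$linear] <- r
  supra <- function(thr) {
    v <- array(0L, dim = map$dim)
    v[map$linear[abs(r) >= thr]] <- 1L
    mask3d(v)
  }
  list(map = vol, supra_graph = supra(graph_threshold),
       supra_display = supra(display_threshold), seed = seed)
}
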