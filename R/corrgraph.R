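# Center columns and scale to unit L2 norm so that crossprod(Z) is the
# Pearson correlation matrix. Zero-variance columns become all-zero and can
# never form an edge.
standardize_columns <- function(values) {
  mu <- colMeans(values)
  z <- sweep(values, 2L, mu, "-")
  nrm <- sqrt(colSums(z^2))
  ok <- nrm > 0
  if (!any(ok))
    stop("all voxel time courses have zero variance", call. = FALSE)
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, nrm[ok], "/")
  z[, !ok] <- 0
  z
}

# Clamp correlations into [-1, 1] and snap values within 1e-12 of +/-1 so
# that identical (or sign-flipped) columns survive an inclusive threshold
# of exactly 1.
clamp_corr <- function(r) {
  r[r > 1] <- 1
  r[r < -1] <- -1
  hi <- abs(r) > 1 - 1e-12
  r[hi] <- sign(r[hi])
  r
}

tile_starts <- function(n, tile_size) {
  seq.int(1L, n, by = tile_size)
}

#' Thresholded all-pairs Pearson correlations (tiled)
#'
#' Computes Pearson correlation for every unordered voxel pair and returns
#' the pairs whose absolute correlation reaches the threshold. The
#' computation is tiled so the dense N x N matrix is never held in memory;
#' the result is independent of the tile size. Both strongly positive and
#' strongly negative correlations pass the (inclusive) absolute-value
#' threshold; the signed coefficient is stored as the edge weight.
#'
#' @param x A \code{vox_matrix} (from \code{\link{extract_matrix}}) with at
#'   least 3 time points.
#' @param threshold Absolute correlation cutoff in (0, 1].
#' @param tile_size Number of columns per tile (>= 1).
#' @return A \code{corr_graph}: list with \code{n_nodes}, \code{edges}
#'   (data.frame with 1-based node indices \code{i < j} and signed
#'   correlation \code{r}), \code{threshold} and \code{index_map}.
#' @export
pearson_edges <- function(x, threshold, tile_size = 512L) {
  stopifnot(inherits(x, "vox_matrix"))
  if (nrow(x$values) < 3L)
    stop("need at least 3 time points for correlation", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (tile_size < 1L) stop("tile_size must be >= 1", call. = FALSE)
  z <- standardize_columns(x$values)
  n <- ncol(z)
  starts <- tile_starts(n, tile_size)
  res_i <- list(); res_j <- list(); res_r <- list(); nres <- 0L
  for (sa in starts) {
    ia <- sa:min(sa + tile_size - 1L, n)
    for (sb in starts[starts >= sa]) {
      ib <- sb:min(sb + tile_size - 1L, n)
      r <- clamp_corr(crossprod(z[, ia, drop = FALSE], z[, ib, drop = FALSE]))
      hit <- which(abs(r) >= threshold, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        gi <- ia[hit[, 1L]]; gj <- ib[hit[, 2L]]
        keep <- gi < gj
        if (any(keep)) {
          nres <- nres + 1L
          res_i[[nres]] <- gi[keep]
          res_j[[nres]] <- gj[keep]
          res_r[[nres]] <- r[hit][keep]
        }
      }
    }
  }
  ei <- unlist(res_i); ej <- unlist(res_j); er <- unlist(res_r)
  if (is.null(ei)) { ei <- integer(0); ej <- integer(0); er <- numeric(0) }
  ord <- order(ei, ej)
  edges <- data.frame(i = ei[ord], j = ej[ord], r = er[ord])
  structure(list(n_nodes = n, edges = edges, threshold = threshold,
                 index_map = x$index_map),
            class = "corr_graph")
}

#' @export
print.corr_graph <- function(x, ...) {
  cat(sprintf("<corr_graph> %d nodes, %d edges, |r| >= %g\n",
              x$n_nodes, nrow(x$edges), x$threshold))
  invisible(x)
}

#' Graph sparsity statistic S = log(E) / log(K)
#'
#' K = 2E/N is the average node degree. S is undefined (flagged, not
#' silently numeric) when the graph has no edges or K <= 1; such degenerate
#' graphs never satisfy the sparsity criterion.
#'
#' @param n_nodes Number of nodes N (>= 1).
#' @param n_edges Number of edges E (>= 0).
#' @return A \code{sparsity_summary}: list with \code{n_nodes},
#'   \code{n_edges}, \code{avg_degree}, \code{s_value} (NA when undefined)
#'   and \code{defined}.
#' @export
sparsity_summary <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 1, n_edges >= 0)
  k <- 2 * n_edges / n_nodes
  defined <- n_edges >= 1 && k > 1
  s <- if (defined) log(n_edges) / log(k) else NA_real_
  structure(list(n_nodes = as.integer(n_nodes),
                 n_edges = as.numeric(n_edges),
                 avg_degree = k, s_value = s, defined = defined),
            class = "sparsity_summary")
}

#' @export
print.sparsity_summary <- function(x, ...) {
  cat(sprintf("<sparsity> N = %d, E = %g, K = %.3f, S = %s\n",
              x$n_nodes, x$n_edges, x$avg_degree,
              if (x$defined) sprintf("%.4f", x$s_value) else "undefined"))
  invisible(x)
}

#' Select the binarization threshold by the sparsity criterion
#'
#' Scans thresholds downward from \code{start} in decrements of \code{step}
#' and returns the first (i.e. largest) threshold whose graph is
#' non-degenerate (E >= 1 and K > 1) and satisfies S = log(E)/log(K) <
#' \code{s_max}. Edge counts for every candidate threshold are accumulated
#' in a single tiled pass over all voxel pairs, so the scan costs one
#' correlation sweep regardless of how many steps it takes.
#'
#' @param x A \code{vox_matrix}.
#' @param s_max Sparsity bound (default 4).
#' @param start First threshold scanned (default 1.0).
#' @param step Scan decrement (default 0.01); thresholds below \code{step}
#'   are not scanned.
#' @param tile_size Tile width for the correlation sweep.
#' @return A list with \code{threshold}, \code{summary} (the
#'   \code{\link{sparsity_summary}} at the selected threshold) and
#'   \code{scan}, a data.frame logging (threshold, E, K, S) for every
#'   threshold visited down to the selected one.
#' @export
select_threshold <- function(x, s_max = 4, start = 1.0, step = 0.01,
                             tile_size = 512L) {
  stopifnot(inherits(x, "vox_matrix"))
  if (nrow(x$values) < 3L)
    stop("need at least 3 time points for correlation", call. = FALSE)
  if (!(step > 0 && step < start && start <= 1))
    stop("need 0 < step < start <= 1", call. = FALSE)
  n_steps <- floor((start - step) / step + 1e-9)
  thresholds <- start - step * (0:n_steps)   # descending
  grid_asc <- rev(thresholds)
  z <- standardize_columns(x$values)
  n <- ncol(z)
  counts <- numeric(length(grid_asc))        # pairs landing in [grid[k], grid[k+1])
  starts <- tile_starts(n, tile_size)
  for (sa in starts) {
    ia <- sa:min(sa + tile_size - 1L, n)
    for (sb in starts[starts >= sa]) {
      ib <- sb:min(sb + tile_size - 1L, n)
      r <- clamp_corr(crossprod(z[, ia, drop = FALSE], z[, ib, drop = FALSE]))
      a <- abs(r)
      if (sa == sb) a[upper.tri(a, diag = TRUE)] <- -1  # i < j only
      idx <- findInterval(a, grid_asc)                   # 0 = below all
      tab <- tabulate(idx, nbins = length(grid_asc))
      counts <- counts + tab
    }
  }
  scan <- data.frame(threshold = numeric(0), E = numeric(0),
                     K = numeric(0), S = numeric(0))
  cum <- rev(cumsum(rev(counts)))  # cum[k] = pairs with |r| >= grid_asc[k]
  for (t_idx in seq_along(thresholds)) {
    thr <- thresholds[t_idx]
    e <- cum[length(grid_asc) - t_idx + 1L]
    sm <- sparsity_summary(n, e)
    scan <- rbind(scan, data.frame(threshold = thr, E = e,
                                   K = sm$avg_degree,
                                   S = ifelse(sm$defined, sm$s_value, NA)))
    if (sm$defined && sm$s_value < s_max) {
      return(list(threshold = thr, summary = sm, scan = scan))
    }
  }
  stop("no threshold >= ", step, " satisfies the sparsity criterion S < ",
       s_max, " (scanned ", length(thresholds), " thresholds)",
       call. = FALSE)
}

#' Build the thresholded correlation graph
#'
#' All in-mask voxels are nodes (isolated nodes allowed); edges connect
#' pairs whose absolute Pearson correlation reaches the threshold, weighted
#' by the signed coefficient. By construction the graph is simple: no
#' self-loops, no multiple edges.
#'
#' @inheritParams pearson_edges
#' @return A \code{corr_graph}.
#' @export
build_graph <- function(x, threshold, tile_size = 512L) {
  pearson_edges(x, threshold, tile_size = tile_size)
}

#' Export a graph edge list as text
#'
#' Whitespace-separated \code{i j r} rows with a one-line header.
#'
#' @param g A \code{corr_graph}.
#' @param path Output path.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "corr_graph"))
  utils::write.table(g$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
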