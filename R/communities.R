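#' Weighted modularity of a partition
#'
#' Q = sum_c (e_c / m - (d_c / 2m)^2), where m is the total edge weight,
#' e_c the weight of edges internal to community c, and d_c the weighted
#' degree sum of its nodes. Q of an edgeless graph is defined as 0.
#'
#' @param g A \code{corr_graph}.
#' @param labels Integer community id per node (all nodes labeled).
#' @param weights Non-negative edge weights, one per edge; defaults to the
#'   absolute correlation |r|.
#' @return Modularity Q in [-1, 1].
#' @export
graph_modularity <- function(g, labels, weights = NULL) {
  stopifnot(inherits(g, "corr_graph"))
  if (length(labels) != g$n_nodes)
    stop("labels must cover all ", g$n_nodes, " nodes", call. = FALSE)
  if (is.null(weights)) weights <- abs(g$edges$r)
  if (length(weights) != nrow(g$edges))
    stop("one weight per edge required", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be non-negative", call. = FALSE)
  if (nrow(g$edges) == 0L) return(0)
  m <- sum(weights)
  if (m <= 0)
    stop("graph has zero total edge weight", call. = FALSE)
  li <- labels[g$edges$i]; lj <- labels[g$edges$j]
  e_c <- tapply(weights[li == lj], li[li == lj], sum)
  deg <- numeric(g$n_nodes)
  for (col in c("i", "j")) {
    agg <- tapply(weights, g$edges[[col]], sum)
    idx <- as.integer(names(agg))
    deg[idx] <- deg[idx] + agg
  }
  d_c <- tapply(deg, labels, sum)
  q <- sum(e_c) / m - sum((d_c / (2 * m))^2)
  as.numeric(q)
}

#' Fast-greedy modularity community detection
#'
#' Agglomerative clustering in the style of Newman's fast-greedy modularity
#' optimization: starting from singleton communities, repeatedly merge the
#' connected community pair with the largest modularity gain, and cut the
#' merge sequence at the level of maximum modularity. Determinism is
#' guaranteed by fixed tie-breaking: among equal gains the pair with the
#' lexicographically smallest community ids is merged, and among equal-Q cut
#' levels the one with fewer communities is chosen. Isolated nodes remain
#' singleton communities. Edge weights are the absolute correlations |r|
#' (signed coefficients are kept on the graph, but modularity with negative
#' weights is ill-defined for the greedy merge rule).
#'
#' @param g A \code{corr_graph}.
#' @return A \code{graph_partition}: list with \code{labels} (1-based
#'   community id per node), \code{sizes} (voxel count per community),
#'   \code{modularity} (Q at the cut), \code{n_communities}, and
#'   \code{q_trace} (Q after 0, 1, 2, ... merges).
#' @export
fast_greedy_partition <- function(g) {
  stopifnot(inherits(g, "corr_graph"))
  n <- g$n_nodes
  edges <- g$edges
  if (nrow(edges) == 0L) {
    labels <- seq_len(n)
    return(new_partition(labels, modularity = 0, q_trace = 0))
  }
  w <- abs(edges$r)
  m <- sum(w)
  active_nodes <- sort(unique(c(edges$i, edges$j)))
  na <- length(active_nodes)
  node2a <- integer(n); node2a[active_nodes] <- seq_len(na)
  # Dense inter-community weight matrix over the non-isolated nodes.
  W <- matrix(0, na, na)
  ai <- node2a[edges$i]; aj <- node2a[edges$j]
  for (e in seq_along(w)) {
    W[ai[e], aj[e]] <- W[ai[e], aj[e]] + w[e]
    W[aj[e], ai[e]] <- W[aj[e], ai[e]] + w[e]
  }
  d <- rowSums(W)            # weighted degree per community
  e_in <- numeric(na)        # internal weight per community
  alive <- rep(TRUE, na)
  q <- -sum((d / (2 * m))^2) # all-singleton modularity
  q_trace <- q
  merges <- matrix(0L, 0L, 2L)
  two_m2 <- 2 * m * m
  repeat {
    # gain of merging communities a < b: w_ab/m - d_a d_b / (2 m^2)
    gain <- W / m - outer(d, d) / two_m2
    gain[W == 0] <- NA
    gain[lower.tri(gain, diag = TRUE)] <- NA
    if (all(is.na(gain))) break
    best <- max(gain, na.rm = TRUE)
    cand <- which(gain == best, arr.ind = TRUE)
    pick <- cand[order(cand[, 1L], cand[, 2L])[1L], ]
    a <- pick[1L]; b <- pick[2L]
    q <- q + best
    e_in[a] <- e_in[a] + e_in[b] + W[a, b]
    d[a] <- d[a] + d[b]
    W[a, ] <- W[a, ] + W[b, ]
    W[, a] <- W[, a] + W[, b]
    W[a, a] <- 0
    W[b, ] <- 0; W[, b] <- 0
    d[b] <- 0; e_in[b] <- 0
    alive[b] <- FALSE
    merges <- rbind(merges, c(a, b))
    q_trace <- c(q_trace, q)
  }
  # Cut at maximum Q; ties resolved toward more merges (fewer communities).
  cut_level <- max(which(q_trace == max(q_trace))) - 1L
  parent <- seq_len(na)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (cut_level > 0L) {
    for (l in seq_len(cut_level)) parent[merges[l, 2L]] <- merges[l, 1L]
  }
  roots <- vapply(seq_len(na), find, integer(1L))
  labels <- integer(n)
  labels[active_nodes] <- roots
  iso <- setdiff(seq_len(n), active_nodes)
  labels[iso] <- na + seq_along(iso)
  labels <- match(labels, sort(unique(labels)))
  new_partition(labels, modularity = q_trace[cut_level + 1L],
                q_trace = q_trace)
}

new_partition <- function(labels, modularity, q_trace) {
  sizes <- tabulate(labels)
  structure(list(labels = labels, sizes = sizes,
                 n_communities = length(sizes),
                 modularity = modularity, q_trace = q_trace),
            class = "graph_partition")
}

#' @export
print.graph_partition <- function(x, ...) {
  big <- sum(x$sizes >= 50L)
  cat(sprintf(
    "<graph_partition> %d communities over %d nodes, Q = %.4f (%d with >= 50 voxels)\n",
    x$n_communities, length(x$labels), x$modularity, big))
  invisible(x)
}

#' Pool large communities into a venous-voxel mask
#'
#' Renders the union of all communities whose size reaches \code{min_size}
#' (inclusive, default 50 voxels) as a 3D mask on the brain grid.
#'
#' @param p A \code{graph_partition}.
#' @param index_map The \code{voxel_map} the partition's nodes refer to.
#' @param brain The brain \code{\link{mask3d}} (supplies grid and affine).
#' @param min_size Minimum community size to pool (>= 1).
#' @return A \code{vein_mask_result}: list with \code{mask} (a
#'   \code{mask3d}), \code{included_clusters} (data.frame of community id and
#'   size), \code{min_size} and \code{n_voxels}.
#' @export
pool_large_clusters <- function(p, index_map, brain, min_size = 50L) {
  stopifnot(inherits(p, "graph_partition"), inherits(index_map, "voxel_map"),
            inherits(brain, "mask3d"))
  if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
  if (length(p$labels) != index_map$n_nodes)
    stop("partition labels inconsistent with the voxel map", call. = FALSE)
  big <- which(p$sizes >= min_size)
  vol <- array(0L, dim = index_map$dim)
  keep <- p$labels %in% big
  vol[index_map$linear[keep]] <- 1L
  included <- data.frame(community = big, size = p$sizes[big])
  included <- included[order(-included$size, included$community), ]
  rownames(included) <- NULL
  structure(list(mask = mask3d(vol, affine = brain$affine),
                 included_clusters = included,
                 min_size = as.integer(min_size),
                 n_voxels = sum(vol)),
            class = "vein_mask_result")
}

#' @export
print.vein_mask_result <- function(x, ...) {
  cat(sprintf("<vein_mask_result> %d voxels pooled from %d communities (size >= %d)\n",
              x$n_voxels, nrow(x$included_clusters), x$min_size))
  invisible(x)
}

#' Render a partition as a 3D label image
#'
#' Integer community labels on the voxel grid; 0 marks background (voxels
#' outside the map).
#'
#' @inheritParams pool_large_clusters
#' @return A 3D integer array.
#' @export
community_labels_image <- function(p, index_map) {
  stopifnot(inherits(p, "graph_partition"), inherits(index_map, "voxel_map"))
  vol <- array(0L, dim = index_map$dim)
  vol[index_map$linear] <- p$labels
  vol
}
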