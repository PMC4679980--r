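#' Identify venous voxels by connectivity-graph clustering
#'
#' End-to-end pipeline: band-pass filter the 4D series, extract the in-mask
#' voxel-by-time matrix, select the largest absolute-correlation threshold
#' whose binarized graph satisfies the sparsity criterion S = log(E)/log(K)
#' < \code{s_max}, build the graph, cluster it by fast-greedy modularity
#' optimization, and pool all communities of \code{min_cluster_size} or more
#' voxels into a venous-voxel mask. If a reference vein mask is supplied,
#' overlap statistics (including the brain edge obtained by box erosion) are
#' reported. The whole pipeline is deterministic given its inputs.
#'
#' @param bold A \code{\link{ts_image}} or path to a 4D NIfTI file.
#' @param brain A \code{\link{mask3d}} or path to a 3D NIfTI mask on the
#'   same grid.
#' @param veins Optional reference vein mask (\code{mask3d} or path) for
#'   validation.
#' @param tr Repetition time override in seconds (required if the BOLD
#'   header carries none).
#' @param low_hz,high_hz Pass-band in Hz (defaults 0.01 and 0.2).
#' @param s_max Sparsity bound (default 4).
#' @param start,step Threshold scan start (1.0) and decrement (0.01).
#' @param tile_size Tile width for the correlation engine.
#' @param min_cluster_size Minimum community size pooled into the mask
#'   (default 50).
#' @param kernel_width Brain-edge erosion kernel width (default 5).
#' @param verbose Log the threshold scan and stage progress.
#' @return An object of class \code{veinclust}; see Details.
#' @details The returned object contains \code{threshold}, \code{sparsity},
#'   \code{partition}, \code{vein_mask} (a \code{vein_mask_result}),
#'   \code{scan} (threshold-scan trajectory), \code{sd_comparison},
#'   \code{overlap} (when \code{veins} given), \code{report} (flat summary
#'   list mirroring the per-subject report rows), and the configuration.
#' @seealso \code{\link{write_outputs}}, \code{\link{generate_phantom}}
#' @export
veinclust <- function(bold, brain, veins = NULL, tr = NULL,
                      low_hz = 0.01, high_hz = 0.2, s_max = 4,
                      start = 1.0, step = 0.01, tile_size = 512L,
                      min_cluster_size = 50L, kernel_width = 5L,
                      verbose = FALSE) {
  cl <- match.call()
  if (is.character(bold)) bold <- read_timeseries(bold, tr = tr)
  if (is.character(brain)) brain <- read_mask(brain)
  if (is.character(veins)) veins <- read_mask(veins)
  stopifnot(inherits(bold, "ts_image"), inherits(brain, "mask3d"))
  check_same_grid(spatial_dim(bold), bold$affine, spatial_dim(brain),
                  brain$affine, what = "BOLD series and brain mask")
  if (!is.null(veins))
    check_same_grid(spatial_dim(veins), veins$affine, spatial_dim(brain),
                    brain$affine, what = "vein and brain masks")

  say <- function(...) if (verbose) message(...)
  say(sprintf("band-pass %g-%g Hz (TR = %g s)", low_hz, high_hz, bold$tr))
  filtered <- bandpass(bold, low_hz, high_hz)
  x <- extract_matrix(filtered, brain)
  sdmap <- temporal_sd_map(filtered, brain)

  say("scanning thresholds from ", start, " downward (step ", step, ")")
  sel <- select_threshold(x, s_max = s_max, start = start, step = step,
                          tile_size = tile_size)
  if (verbose) {
    for (row in seq_len(nrow(sel$scan)))
      say(sprintf("  t = %.2f: E = %g, K = %.3f, S = %s",
                  sel$scan$threshold[row], sel$scan$E[row],
                  sel$scan$K[row],
                  ifelse(is.na(sel$scan$S[row]), "undef",
                         sprintf("%.3f", sel$scan$S[row]))))
  }
  say(sprintf("selected threshold %.2f (S = %.3f)", sel$threshold,
              sel$summary$s_value))

  g <- build_graph(x, sel$threshold, tile_size = tile_size)
  say(sprintf("graph: %d nodes, %d edges", g$n_nodes, nrow(g$edges)))
  part <- fast_greedy_partition(g)
  say(sprintf("communities: %d (Q = %.4f)", part$n_communities,
              part$modularity))
  vm <- pool_large_clusters(part, x$index_map, brain,
                            min_size = min_cluster_size)
  if (vm$n_voxels == 0L)
    warning("no community reached min_cluster_size = ", min_cluster_size,
            "; the venous-voxel mask is empty", call. = FALSE)

  sdcmp <- if (vm$n_voxels > 1L &&
               sum(brain$data) - vm$n_voxels > 1L)
    sd_comparison(sdmap, vm$mask, brain) else NULL
  ovl <- if (!is.null(veins) && vm$n_voxels > 0L)
    overlap_report(vm$mask, veins, brain, kernel_width) else NULL

  n_brain <- sum(brain$data)
  report <- list(
    correlation_threshold = sel$threshold,
    n_nodes = g$n_nodes,
    n_edges = nrow(g$edges),
    avg_degree = sel$summary$avg_degree,
    sparsity_s = sel$summary$s_value,
    n_communities = part$n_communities,
    included_cluster_sizes = vm$included_clusters$size,
    voxels_in_brain_mask = n_brain,
    voxels_in_clustering_mask = vm$n_voxels,
    pct_of_brain_mask = 100 * vm$n_voxels / n_brain,
    pct_overlap_veins = if (!is.null(ovl)) 100 * ovl$frac_in_vein else NA,
    pct_overlap_veins_or_edge =
      if (!is.null(ovl)) 100 * ovl$frac_in_vein_or_edge else NA)

  structure(list(
    threshold = sel$threshold, sparsity = sel$summary, scan = sel$scan,
    graph = g, partition = part, vein_mask = vm, sd_map = sdmap,
    sd_comparison = sdcmp, overlap = ovl, report = report, brain = brain,
    config = list(low_hz = low_hz, high_hz = high_hz, s_max = s_max,
                  start = start, step = step, tile_size = tile_size,
                  min_cluster_size = min_cluster_size,
                  kernel_width = kernel_width, tr = bold$tr),
    call = cl), class = "veinclust")
}

#' Extract the pooled venous-voxel mask
#'
#' @param fit A \code{veinclust} object.
#' @return A \code{\link{mask3d}}.
#' @export
vein_mask <- function(fit) {
  stopifnot(inherits(fit, "veinclust"))
  fit$vein_mask$mask
}

#' @export
print.veinclust <- function(x, ...) {
  r <- x$report
  cat("Venous-voxel identification by connectivity-graph clustering\n")
  cat(sprintf("  correlation threshold:  %.2f (S = %.3f < %g)\n",
              r$correlation_threshold, r$sparsity_s, x$config$s_max))
  cat(sprintf("  graph:                  %d nodes, %d edges (K = %.2f)\n",
              r$n_nodes, r$n_edges, r$avg_degree))
  cat(sprintf("  communities >= %d:      %d (total %d voxels, %.1f%% of brain)\n",
              x$config$min_cluster_size, length(r$included_cluster_sizes),
              r$voxels_in_clustering_mask, r$pct_of_brain_mask))
  if (!is.na(r$pct_overlap_veins))
    cat(sprintf("  overlap with veins:     %.1f%% (%.1f%% incl. brain edge)\n",
                r$pct_overlap_veins, r$pct_overlap_veins_or_edge))
  invisible(x)
}

#' @export
summary.veinclust <- function(object, ...) {
  structure(list(report = object$report,
                 sd_comparison = object$sd_comparison,
                 config = object$config,
                 q = object$partition$modularity),
            class = "summary.veinclust")
}

#' @export
print.summary.veinclust <- function(x, ...) {
  r <- x$report
  fmt <- function(label, value) cat(sprintf("  %-34s %s\n", label, value))
  cat("Per-subject report\n")
  fmt("Correlation threshold", sprintf("%.2f", r$correlation_threshold))
  fmt("Voxels in brain mask", format(r$voxels_in_brain_mask))
  fmt("Voxels in clustering mask", format(r$voxels_in_clustering_mask))
  fmt("Idem, in % of brain mask", sprintf("%.1f%%", r$pct_of_brain_mask))
  if (!is.na(r$pct_overlap_veins)) {
    fmt("Overlap with reference veins", sprintf("%.1f%%", r$pct_overlap_veins))
    fmt("Overlap with veins or brain edge",
        sprintf("%.1f%%", r$pct_overlap_veins_or_edge))
  }
  fmt("Sparsity S at threshold", sprintf("%.3f", r$sparsity_s))
  fmt("Modularity Q", sprintf("%.4f", x$q))
  fmt("Included cluster sizes",
      paste(r$included_cluster_sizes, collapse = ", "))
  if (!is.null(x$sd_comparison))
    fmt("SD in vs out (Welch t, p)",
        sprintf("%.3g vs %.3g (t = %.1f, p = %.2g)",
                x$sd_comparison$mean_sd_in, x$sd_comparison$mean_sd_out,
                x$sd_comparison$statistic, x$sd_comparison$p_value))
  invisible(x)
}

#' Plot orthogonal slices of the venous-voxel mask
#'
#' Simple base-graphics overlay of the pooled mask (red) on the brain mask
#' (gray) at three orthogonal mid-slices through the mask's center of mass.
#'
#' @param x A \code{veinclust} object.
#' @param ... Unused.
#' @export
plot.veinclust <- function(x, ...) {
  brain <- x$brain$data
  vm <- x$vein_mask$mask$data
  d <- dim(brain)
  com <- if (sum(vm) > 0) {
    idx <- arrayInd(which(vm == 1L), d)
    round(colMeans(idx))
  } else round(d / 2)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  panes <- list(
    list(b = brain[com[1], , ], v = vm[com[1], , ], t = sprintf("x = %d", com[1])),
    list(b = brain[, com[2], ], v = vm[, com[2], ], t = sprintf("y = %d", com[2])),
    list(b = brain[, , com[3]], v = vm[, , com[3]], t = sprintf("z = %d", com[3])))
  for (p in panes) {
    graphics::image(p$b, col = c("black", "gray60"), axes = FALSE,
                    main = p$t, useRaster = TRUE)
    ov <- p$v; ov[ov == 0L] <- NA
    graphics::image(ov, col = "red", add = TRUE, useRaster = TRUE)
  }
  invisible(x)
}

#' Persist pipeline outputs
#'
#' Writes \code{veinmask.nii.gz}, \code{labels.nii.gz} (community labels),
#' \code{report.json}, \code{report.txt} and \code{scan_log.tsv} into a
#' directory.
#'
#' @param fit A \code{veinclust} object.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "veinclust"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mask(fit$vein_mask$mask, file.path(dir, "veinmask.nii.gz"))
  labels <- community_labels_image(fit$partition, fit$graph$index_map)
  nim <- as_nifti_grid(labels, fit$brain$affine)
  RNifti::writeNifti(nim, file.path(dir, "labels.nii.gz"), datatype = "int32")
  jsonlite::write_json(fit$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(summary(fit)))
  writeLines(txt, file.path(dir, "report.txt"))
  utils::write.table(fit$scan, file.path(dir, "scan_log.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
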