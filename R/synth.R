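#' Specify a synthetic fMRI phantom
#'
#' Defaults describe the reference phantom used throughout the test suite:
#' a 32 x 32 x 16 ellipsoidal "brain" scanned for 600 volumes at TR = 0.333 s,
#' containing three contiguous 100-voxel vein branches that share one
#' band-limited low-frequency signal (one branch sign-flipped), two 150-voxel
#' "network" regions with moderate internal correlation, and independent
#' background noise, with vein voxels' temporal SD elevated 1.8-fold.
#'
#' @param grid Volume dimensions (nx, ny, nz).
#' @param t Number of volumes (>= 3).
#' @param tr Repetition time, seconds.
#' @param n_vein_branches,vein_voxels_per_branch Vein geometry.
#' @param flip_fraction Fraction of branches carrying the sign-inverted
#'   vein signal.
#' @param vein_r_target Intended within-vein pairwise |r| on the raw series.
#' @param n_networks,network_voxels Network geometry.
#' @param network_r_target Intended within-network pairwise r; must be below
#'   \code{vein_r_target}.
#' @param vein_sd_scale Temporal-SD multiplier for vein voxels relative to
#'   background.
#' @param noise_sd Background noise scale.
#' @param seed RNG seed; the generator consumes one seeded stream in a fixed
#'   order (vein geometry, network geometry, shared signals, noise, SD
#'   jitter), so equal specs give bit-identical phantoms.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(grid = c(32L, 32L, 16L), t = 600L, tr = 0.333,
                         n_vein_branches = 3L, vein_voxels_per_branch = 100L,
                         flip_fraction = 1 / 3, vein_r_target = 0.9,
                         n_networks = 2L, network_voxels = 150L,
                         network_r_target = 0.4, vein_sd_scale = 1.8,
                         noise_sd = 1, seed = 42L) {
  spec <- list(grid = as.integer(grid), t = as.integer(t), tr = tr,
               n_vein_branches = as.integer(n_vein_branches),
               vein_voxels_per_branch = as.integer(vein_voxels_per_branch),
               flip_fraction = flip_fraction, vein_r_target = vein_r_target,
               n_networks = as.integer(n_networks),
               network_voxels = as.integer(network_voxels),
               network_r_target = network_r_target,
               vein_sd_scale = vein_sd_scale, noise_sd = noise_sd,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(length(grid) == 3L, all(grid >= 4L), t >= 3L, tr > 0,
              n_vein_branches >= 1L, vein_voxels_per_branch >= 1L,
              flip_fraction >= 0, flip_fraction <= 1,
              n_networks >= 0L, network_voxels >= 1L,
              vein_sd_scale > 0, noise_sd > 0)
    if (!(network_r_target > 0 && network_r_target < vein_r_target &&
          vein_r_target <= 1))
      stop("need 0 < network_r_target < vein_r_target <= 1", call. = FALSE)
  })
  structure(spec, class = "phantom_spec")
}

# Ellipsoidal brain mask centered in the grid. The semi-axes sit a couple
# of voxels inside the volume so a genuine brain edge exists, and keep the
# default volume near 5000 voxels: the sparsity statistic of the complete
# within-vein graph, S = log(E) / log(2E/N), must stay below the criterion
# bound for the planted veins to be separable from diffuse network
# correlations, which bounds N from above for a fixed vein budget.
phantom_brain_mask <- function(grid) {
  ctr <- (grid + 1) / 2
  semi <- pmax(grid / 2 - c(2.5, 2.5, 1.5), grid / 4)
  idx <- arrayInd(seq_len(prod(grid)), grid)
  d2 <- ((idx[, 1] - ctr[1]) / semi[1])^2 +
        ((idx[, 2] - ctr[2]) / semi[2])^2 +
        ((idx[, 3] - ctr[3]) / semi[3])^2
  array(as.integer(d2 <= 1), dim = grid)
}

# 6-neighbourhood of a voxel (1-based coords), kept inside allowed cells.
free_neighbours <- function(v, allowed, occupied) {
  d <- dim(allowed)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  nb <- sweep(shifts, 2L, v, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb <- nb[ok, , drop = FALSE]
  if (nrow(nb) == 0L) return(nb)
  lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
  nb[allowed[lin] == 1L & !occupied[lin], , drop = FALSE]
}

# Grow a contiguous voxel set of given size by a self-avoiding axis-aligned
# random walk; when walled in, growth resumes from a random already-placed
# voxel with a free neighbour (region stays connected, roughly tubular for
# small sizes).
grow_region <- function(size, allowed, occupied) {
  d <- dim(allowed)
  open <- which(allowed == 1L & !occupied)
  if (length(open) < size)
    stop("region budget exceeds available brain volume", call. = FALSE)
  start <- open[sample.int(length(open), 1L)]
  cells <- matrix(arrayInd(start, d), nrow = 1L)
  occupied[start] <- TRUE
  cur <- cells[1L, ]
  while (nrow(cells) < size) {
    nb <- free_neighbours(cur, allowed, occupied)
    if (nrow(nb) == 0L) {
      # backtrack: continue from any placed voxel that still has room
      cand <- sample.int(nrow(cells))
      cur <- NULL
      for (ci in cand) {
        nb <- free_neighbours(cells[ci, ], allowed, occupied)
        if (nrow(nb) > 0L) { cur <- cells[ci, ]; break }
      }
      if (is.null(cur))
        stop("region growth walled in; reduce region sizes", call. = FALSE)
    }
    nxt <- nb[sample.int(nrow(nb), 1L), ]
    lin <- nxt[1] + d[1] * (nxt[2] - 1) + d[1] * d[2] * (nxt[3] - 1)
    occupied[lin] <- TRUE
    cells <- rbind(cells, nxt)
    cur <- nxt
  }
  list(cells = cells, occupied = occupied)
}

# White noise band-passed to the analysis band and standardized to unit SD;
# the shared low-frequency signal model for veins and networks.
bandlimited_signal <- function(t, tr, low_hz = 0.01, high_hz = 0.2) {
  flt <- design_bandpass(tr, low_hz, high_hz)
  v <- filtfilt_matrix(flt$b, flt$a, matrix(stats::rnorm(t), ncol = 1L))[, 1L]
  (v - mean(v)) / stats::sd(v)
}

#' Generate a ground-truth fMRI phantom
#'
#' Builds a brain-masked 4D series realizing the signal structure the
#' venous-voxel method assumes: vein branches sharing one band-limited
#' (0.01-0.2 Hz) signal with very high pairwise |r| (sign-flipped on a
#' fraction of branches), network regions with moderate internal
#' correlation, and independent background noise. Pairwise correlation
#' targets are met through the noise-to-signal variance ratio: a voxel
#' carrying unit-variance shared signal plus independent noise of variance
#' \code{eps2} correlates with a same-signal voxel at rho = 1 / (1 + eps2),
#' so \code{eps2 = 1/rho - 1}. Each voxel's series is then rescaled so vein
#' voxels' temporal SD sits near \code{vein_sd_scale} times the background
#' SD, with mild lognormal per-voxel SD jitter so the vein and background SD
#' distributions overlap (as real data do).
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list with \code{image} (a \code{\link{ts_image}}) and
#'   \code{truth}: \code{brain}, \code{veins}, \code{networks} (list of
#'   \code{mask3d}), plus \code{branches} (list of per-branch masks) and
#'   \code{flipped} (logical per branch).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  grid <- spec$grid
  brain <- phantom_brain_mask(grid)
  n_brain <- sum(brain)
  budget <- spec$n_vein_branches * spec$vein_voxels_per_branch +
    spec$n_networks * spec$network_voxels
  if (budget > n_brain)
    stop("vein/network voxel budget (", budget,
         ") exceeds brain volume (", n_brain, ")", call. = FALSE)
  occupied <- rep(FALSE, prod(grid))
  # 1) vein branch geometry
  branches <- vector("list", spec$n_vein_branches)
  for (b in seq_len(spec$n_vein_branches)) {
    g <- grow_region(spec$vein_voxels_per_branch, brain, occupied)
    branches[[b]] <- g$cells
    occupied <- g$occupied
  }
  # 2) network geometry
  networks <- vector("list", spec$n_networks)
  for (k in seq_len(spec$n_networks)) {
    g <- grow_region(spec$network_voxels, brain, occupied)
    networks[[k]] <- g$cells
    occupied <- g$occupied
  }
  # 3) shared signals
  v_sig <- bandlimited_signal(spec$t, spec$tr)
  w_sig <- lapply(seq_len(spec$n_networks), function(k)
    bandlimited_signal(spec$t, spec$tr))
  # 4) per-voxel noise for all in-brain voxels
  brain_lin <- which(brain == 1L)
  noise <- matrix(stats::rnorm(spec$t * n_brain), nrow = spec$t)
  # 5) per-voxel SD jitter (lognormal, sdlog 0.2)
  jitter <- exp(stats::rnorm(n_brain, 0, 0.2))

  lin_of <- function(cells)
    cells[, 1] + grid[1] * (cells[, 2] - 1) + grid[1] * grid[2] * (cells[, 3] - 1)
  pos_in_brain <- integer(prod(grid))
  pos_in_brain[brain_lin] <- seq_len(n_brain)

  n_flip <- round(spec$flip_fraction * spec$n_vein_branches)
  flipped <- seq_len(spec$n_vein_branches) <= n_flip

  # background: unit-signal-free noise, scaled to noise_sd
  series <- noise * rep(spec$noise_sd * jitter, each = spec$t)

  eps_vein <- sqrt(1 / spec$vein_r_target - 1)
  for (b in seq_len(spec$n_vein_branches)) {
    cols <- pos_in_brain[lin_of(branches[[b]])]
    s <- if (flipped[b]) -1 else 1
    raw <- s * v_sig + eps_vein * noise[, cols, drop = FALSE]
    scale <- spec$vein_sd_scale * spec$noise_sd * jitter[cols] /
      sqrt(1 + eps_vein^2)
    series[, cols] <- raw * rep(scale, each = spec$t)
  }
  eps_net <- sqrt(1 / spec$network_r_target - 1)
  for (k in seq_len(spec$n_networks)) {
    cols <- pos_in_brain[lin_of(networks[[k]])]
    raw <- w_sig[[k]] + eps_net * noise[, cols, drop = FALSE]
    scale <- spec$noise_sd * jitter[cols] / sqrt(1 + eps_net^2)
    series[, cols] <- raw * rep(scale, each = spec$t)
  }

  data4d <- array(0, dim = c(grid, spec$t))
  flat <- matrix(data4d, nrow = prod(grid))
  flat[brain_lin, ] <- t(series)
  data4d <- array(flat, dim = c(grid, spec$t))

  affine <- diag(c(1.7, 1.7, 4, 1))
  as_truth_mask <- function(cells) {
    vol <- array(0L, dim = grid)
    vol[lin_of(cells)] <- 1L
    mask3d(vol, affine = affine)
  }
  vein_cells <- do.call(rbind, branches)
  truth <- list(
    brain = mask3d(brain, affine = affine),
    veins = as_truth_mask(vein_cells),
    networks = lapply(networks, as_truth_mask),
    branches = lapply(branches, as_truth_mask),
    flipped = flipped)
  img <- ts_image(data4d, tr = spec$tr, affine = affine,
                  voxel_size = c(1.7, 1.7, 4))
  list(image = img, truth = truth, spec = spec)
}

#' Write a phantom to disk
#'
#' Writes the 4D series, brain mask, truth vein mask, per-network truth
#' masks (NIfTI-1) and the generating spec as JSON.
#'
#' @param phantom Output of \code{\link{generate_phantom}}.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_timeseries(phantom$image, file.path(dir, "bold.nii.gz"))
  write_mask(phantom$truth$brain, file.path(dir, "brain.nii.gz"))
  write_mask(phantom$truth$veins, file.path(dir, "veins.nii.gz"))
  for (k in seq_along(phantom$truth$networks))
    write_mask(phantom$truth$networks[[k]],
               file.path(dir, sprintf("network%02d.nii.gz", k)))
  jsonlite::write_json(unclass(phantom$spec),
                       file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
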