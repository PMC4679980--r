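# Shared fixtures. Expensive objects (the reference phantom and its full
# pipeline fit) are generated once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The reference phantom: all defaults (seed 42).
default_phantom <- function() memo("phantom", generate_phantom(phantom_spec()))

# Band-passed in-mask matrix of the reference phantom.
default_matrix <- function() memo("matrix", {
  ph <- default_phantom()
  extract_matrix(bandpass(ph$image), ph$truth$brain)
})

# Full pipeline fit of the reference phantom.
default_fit <- function() memo("fit", {
  ph <- default_phantom()
  veinclust(ph$image, ph$truth$brain)
})

# A small, fast phantom for module-level tests.
small_spec <- function(seed = 7L, ...) {
  phantom_spec(grid = c(16L, 16L, 10L), t = 240L,
               n_vein_branches = 2L, vein_voxels_per_branch = 60L,
               n_networks = 1L, network_voxels = 40L, seed = seed, ...)
}
small_phantom <- function() memo("small_phantom", generate_phantom(small_spec()))

small_fit <- function() memo("small_fit", {
  ph <- small_phantom()
  veinclust(ph$image, ph$truth$brain)
})

# Random 4D image on a trivial grid.
random_ts <- function(dim = c(4L, 5L, 3L), t = 8L, tr = 0.5, seed = 1L) {
  set.seed(seed)
  ts_image(array(rnorm(prod(dim) * t), dim = c(dim, t)), tr = tr)
}

# Build a corr_graph by hand (for community tests that need exact edges).
manual_graph <- function(n, i, j, r, threshold = 0.5) {
  structure(list(n_nodes = as.integer(n),
                 edges = data.frame(i = as.integer(i), j = as.integer(j),
                                    r = as.numeric(r)),
                 threshold = threshold, index_map = NULL),
            class = "corr_graph")
}

# Edges of a clique over the given nodes.
clique_edges <- function(nodes) {
  p <- t(utils::combn(nodes, 2L))
  data.frame(i = p[, 1L], j = p[, 2L])
}

# Enumerate all set partitions of n elements as restricted growth strings
# (rows of a matrix of community labels).
all_partitions <- function(n) {
  rows <- list()
  rec <- function(labels, k, maxlab) {
    if (k > n) {
      rows[[length(rows) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      labels[k] <- lab
      rec(labels, k + 1L, max(maxlab, lab))
    }
  }
  rec(integer(n), 1L, 0L)
  do.call(rbind, rows)
}

# Modularity of a labeling, computed directly from the formula (independent
# of the package's tapply-based implementation).
modularity_direct <- function(n, ei, ej, w, labels) {
  m <- sum(w)
  intra <- sum(w[labels[ei] == labels[ej]])
  deg <- numeric(n)
  for (e in seq_along(w)) {
    deg[ei[e]] <- deg[ei[e]] + w[e]
    deg[ej[e]] <- deg[ej[e]] + w[e]
  }
  d_c <- tapply(deg, labels, sum)
  intra / m - sum((d_c / (2 * m))^2)
}

# Are two labelings the same partition (up to renaming)?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(match(a, unique(a)) == match(b, unique(b)))
}

# 6-connectivity check of a voxel set given as an n x 3 matrix of 1-based
# coordinates (BFS).
is_connected6 <- function(cells) {
  n <- nrow(cells)
  if (n <= 1L) return(TRUE)
  key <- paste(cells[, 1], cells[, 2], cells[, 3])
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    nb <- sweep(shifts, 2L, cells[cur, ], "+")
    hits <- match(paste(nb[, 1], nb[, 2], nb[, 3]), key)
    hits <- hits[!is.na(hits) & !seen[hits]]
    seen[hits] <- TRUE
    queue <- c(queue, hits)
  }
  all(seen)
}

# Brute-force box erosion oracle: voxel kept iff its full k^3 neighbourhood
# (zero-padded) is inside the mask.
erode_box_oracle <- function(vol, k) {
  h <- (k - 1L) %/% 2L
  d <- dim(vol)
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    if (i - h < 1 || i + h > d[1] || j - h < 1 || j + h > d[2] ||
        l - h < 1 || l + h > d[3]) next
    if (all(vol[(i - h):(i + h), (j - h):(j + h), (l - h):(l + h)] == 1L))
      out[i, j, l] <- 1L
  }
  out
}
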