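vox_from_matrix <- function(values, tr = 1) {
  n <- ncol(values)
  m <- mask3d(array(1L, dim = c(n, 1, 1)))
  structure(list(values = values, tr = tr, index_map = voxel_index_map(m)),
            class = "vox_matrix")
}

naive_edges <- function(values, threshold) {
  n <- ncol(values)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::sd(values[, i]) == 0 || stats::sd(values[, j]) == 0) next
    r <- stats::cor(values[, i], values[, j])
    if (abs(r) >= threshold) out <- rbind(out, c(i, j, r))
  }
  if (is.null(out)) data.frame(i = integer(0), j = integer(0), r = numeric(0))
  else data.frame(i = out[, 1], j = out[, 2], r = out[, 3])
}

test_that("perfect positive and negative correlations hit the threshold", {
  set.seed(8)
  base <- rnorm(20)
  x <- vox_from_matrix(cbind(base, base))
  g <- pearson_edges(x, threshold = 0.9)
  expect_equal(nrow(g$edges), 1L)
  expect_identical(g$edges$r, 1.0)

  x2 <- vox_from_matrix(cbind(base, -base))
  g2 <- pearson_edges(x2, threshold = 0.8)
  expect_equal(nrow(g2$edges), 1L)
  expect_identical(g2$edges$r, -1.0)
})

test_that("tiled engine equals the naive all-pairs oracle for any tiling", {
  set.seed(9)
  values <- matrix(rnorm(30 * 50), 30, 50)
  values[, 7] <- values[, 7] + 0.8 * values[, 3]  # some structure
  x <- vox_from_matrix(values)
  for (threshold in c(0.15, 0.4)) {
    ref <- naive_edges(values, threshold)
    for (ts in c(1L, 7L, 50L)) {
      g <- pearson_edges(x, threshold, tile_size = ts)
      expect_equal(g$edges$i, ref$i)
      expect_equal(g$edges$j, ref$j)
      expect_lt(max(abs(g$edges$r - ref$r)), 1e-10)
    }
  }
})

test_that("zero-variance voxels never form edges; degenerate inputs error", {
  set.seed(10)
  values <- matrix(rnorm(20 * 5), 20, 5)
  values[, 2] <- 3  # constant voxel
  x <- vox_from_matrix(values)
  g <- pearson_edges(x, threshold = 0.01)
  expect_false(any(g$edges$i == 2L | g$edges$j == 2L))
  expect_equal(g$n_nodes, 5L)

  allzero <- vox_from_matrix(matrix(1, 10, 4))
  expect_error(pearson_edges(allzero, 0.5), "zero variance")
  expect_error(pearson_edges(x, 1.5), "threshold")
  short <- vox_from_matrix(matrix(rnorm(4), 2, 2))
  expect_error(pearson_edges(short, 0.5), "3 time points")
  expect_error(select_threshold(short), "3 time points")
})

test_that("sparsity statistic follows S = log(E)/log(K), undefined when K <= 1", {
  s <- sparsity_summary(200, 1000)
  expect_equal(s$avg_degree, 10)
  expect_equal(s$s_value, 3)
  s2 <- sparsity_summary(8, 16)
  expect_equal(s2$avg_degree, 4)
  expect_equal(s2$s_value, 2)
  s3 <- sparsity_summary(10, 5)  # K = 1: log K = 0
  expect_false(s3$defined)
  expect_true(is.na(s3$s_value))
  expect_false(sparsity_summary(10, 0)$defined)
})

test_that("S decreases in K at fixed N (denser graphs look less sparse)", {
  n <- 500
  k <- seq(1.5, 60, by = 0.5)
  s <- vapply(k, function(kk) {
    sm <- sparsity_summary(n, kk * n / 2)
    sm$s_value
  }, numeric(1))
  expect_true(all(diff(s) < 0))
  # closed form S = 1 + (log N - log 2)/log K
  expect_equal(s, 1 + (log(n) - log(2)) / log(k), tolerance = 1e-12)
})

test_that("threshold scan selects 1.0 for mutually identical columns", {
  base <- rnorm(12)
  values <- matrix(base, 12, 100)
  sel <- select_threshold(vox_from_matrix(values))
  expect_equal(sel$threshold, 1.0)
  expect_equal(sel$summary$n_edges, choose(100, 2))
  expect_equal(sel$summary$avg_degree, 99)
  expect_equal(sel$summary$s_value, log(4950) / log(99))
})

test_that("scan result matches a brute-force per-threshold oracle and is maximal", {
  ph <- small_phantom()
  x <- extract_matrix(bandpass(ph$image), ph$truth$brain)
  sel <- select_threshold(x)

  # brute force: walk the same grid downward, evaluating each graph directly
  thresholds <- 1.0 - 0.01 * (0:99)
  first_ok <- NA
  for (thr in thresholds) {
    g <- pearson_edges(x, thr)
    sm <- sparsity_summary(g$n_nodes, nrow(g$edges))
    if (sm$defined && sm$s_value < 4) { first_ok <- thr; break }
  }
  expect_equal(sel$threshold, first_ok)

  # the summary describes the graph at the selected threshold
  g_sel <- pearson_edges(x, sel$threshold)
  expect_equal(sel$summary$n_edges, nrow(g_sel$edges))

  # maximality: one step up the criterion fails or the graph is degenerate
  g_up <- pearson_edges(x, sel$threshold + 0.01)
  sm_up <- sparsity_summary(g_up$n_nodes, nrow(g_up$edges))
  expect_true(!sm_up$defined || sm_up$s_value >= 4)
})

test_that("scan fails explicitly when no threshold satisfies the criterion", {
  set.seed(12)
  # 4 voxels can never reach K > 1 with S < 4 at high thresholds of pure noise
  values <- matrix(rnorm(10 * 3), 10, 3)
  expect_error(select_threshold(vox_from_matrix(values), s_max = 0.1),
               "no threshold")
})

test_that("build_graph keeps all nodes and stores signed weights", {
  set.seed(13)
  values <- matrix(rnorm(30 * 6), 30, 6)
  x <- vox_from_matrix(values)
  g <- build_graph(x, threshold = 0.999)
  expect_equal(g$n_nodes, 6L)
  expect_equal(nrow(g$edges), 0L)

  base <- rnorm(30)
  values2 <- cbind(base, -0.9 * base + sqrt(1 - 0.81) * rnorm(30) * sd(base),
                   rnorm(30))
  x2 <- vox_from_matrix(values2)
  r12 <- cor(values2[, 1], values2[, 2])
  g2 <- build_graph(x2, threshold = min(abs(r12), 0.999) - 0.01)
  hit <- g2$edges[g2$edges$i == 1 & g2$edges$j == 2, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$r, 0)  # signed storage under absolute thresholding
  expect_equal(g2$n_nodes, x2$index_map$n_nodes)
})

test_that("edge lists export as plain text", {
  set.seed(14)
  x <- vox_from_matrix(matrix(rnorm(20 * 4), 20, 4))
  g <- pearson_edges(x, 0.05)
  p <- tempfile(fileext = ".txt")
  write_edgelist(g, p)
  txt <- read.table(p, header = TRUE)
  expect_equal(nrow(txt), nrow(g$edges))
  expect_equal(txt$r, g$edges$r, tolerance = 1e-12)
})
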