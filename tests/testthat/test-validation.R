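test_that("box erosion reproduces the cube geometry of the edge definition", {
  vol <- array(0L, dim = c(11, 11, 11))
  vol[3:9, 3:9, 3:9] <- 1L  # solid 7x7x7 cube
  brain <- mask3d(vol)
  edge <- brain_edge(brain, kernel_width = 5L)
  core <- vol - edge$data
  expect_equal(sum(core), 27)        # 3x3x3 survives
  expect_equal(sum(edge$data), 343 - 27)
})

test_that("masks thinner than the kernel erode away entirely", {
  vol <- array(0L, dim = c(10, 10, 4))
  vol[2:9, 2:9, 2:3] <- 1L  # 2 voxels thick in z
  edge <- brain_edge(mask3d(vol), 5L)
  expect_identical(edge$data, vol)   # edge = whole mask
})

test_that("separable erosion matches a brute-force neighbourhood oracle", {
  set.seed(31)
  vol <- array(as.integer(runif(9 * 8 * 7) < 0.7), dim = c(9, 8, 7))
  for (k in c(3L, 5L)) {
    expect_identical(veingraph:::erode_box(vol, k), erode_box_oracle(vol, k))
  }
})

test_that("the edge is inside the brain and disjoint from the eroded core", {
  set.seed(32)
  vol <- array(as.integer(runif(12^3) < 0.6), dim = c(12, 12, 12))
  brain <- mask3d(vol)
  edge <- brain_edge(brain, 5L)
  expect_true(all(edge$data <= vol))
  core <- veingraph:::erode_box(vol, 5L)
  expect_equal(sum(edge$data * core), 0)
  expect_error(brain_edge(brain, 4L), "odd")
})

test_that("overlap fractions follow the definitions", {
  d <- c(12, 12, 12)
  brain <- mask3d(array(1L, dim = d))
  cl <- array(0L, dim = d); cl[6, 6, c(4:8, 2, 3, 9, 10, 11)] <- 1L # 10 voxels
  vein <- array(0L, dim = d); vein[6, 6, c(4:8, 2, 3)] <- 1L        # 7 overlap
  rep1 <- overlap_report(mask3d(cl), mask3d(vein), brain)
  expect_equal(rep1$n_cluster_voxels, 10)
  expect_equal(rep1$frac_in_vein, 0.7)
  expect_equal(rep1$frac_of_brain, 10 / prod(d))
  expect_gte(rep1$frac_in_vein_or_edge, rep1$frac_in_vein)
  expect_true(all(c(rep1$frac_in_vein, rep1$frac_in_vein_or_edge,
                    rep1$frac_of_brain) >= 0))
  expect_true(all(c(rep1$frac_in_vein, rep1$frac_in_vein_or_edge,
                    rep1$frac_of_brain) <= 1))

  # cluster contained in the vein mask
  rep2 <- overlap_report(mask3d(vein), mask3d(cl), brain)
  expect_equal(rep2$frac_in_vein, 1.0)

  # cluster on the brain edge only: vein overlap 0, vein-or-edge 1
  cl_edge <- array(0L, dim = d); cl_edge[1, 1, 1:5] <- 1L
  novein <- mask3d(array(0L, dim = d))
  rep3 <- overlap_report(mask3d(cl_edge), novein, brain, kernel_width = 5L)
  expect_equal(rep3$frac_in_vein, 0)
  expect_equal(rep3$frac_in_vein_or_edge, 1)

  expect_error(overlap_report(novein, novein, brain), "empty")
})

test_that("growing the vein mask never decreases the overlap fraction", {
  set.seed(33)
  d <- c(10, 10, 10)
  brain <- mask3d(array(1L, dim = d))
  cl <- mask3d(array(as.integer(runif(prod(d)) < 0.2), dim = d))
  vein <- array(0L, dim = d)
  prev <- 0
  for (fill in c(0.1, 0.3, 0.6)) {
    vein[runif(prod(d)) < fill] <- 1L   # monotone growth
    cur <- overlap_report(cl, mask3d(vein), brain)$frac_in_vein
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("SD comparison runs a Welch test and handles degenerate groups", {
  d <- c(8, 8, 4)
  brain <- mask3d(array(1L, dim = d))
  cl <- array(0L, dim = d); cl[1:4, , ] <- 1L
  cl <- mask3d(cl)

  # equal-mean groups: statistic near zero
  vals <- array(rep(c(1, 3), prod(d) / 2), dim = d)
  sdm <- structure(list(values = vals, mask = brain), class = "sd_map")
  cmp0 <- sd_comparison(sdm, cl, brain)
  expect_lt(abs(cmp0$statistic), 1e-10)

  # constant identical groups: nothing to test, statistic defined as 0
  sdc <- structure(list(values = array(2, dim = d), mask = brain),
                   class = "sd_map")
  cmp1 <- sd_comparison(sdc, cl, brain)
  expect_equal(cmp1$statistic, 0)
  expect_equal(cmp1$p_value, 1)

  # in-group SD double the out-group: overwhelming evidence
  set.seed(34)
  vals2 <- array(abs(rnorm(prod(d), mean = 1, sd = 0.05)), dim = d)
  vals2[cl$data == 1L] <- vals2[cl$data == 1L] * 2
  sdm2 <- structure(list(values = vals2, mask = brain), class = "sd_map")
  cmp2 <- sd_comparison(sdm2, cl, brain)
  expect_lt(cmp2$p_value, 0.001)
  expect_gt(cmp2$mean_sd_in, cmp2$mean_sd_out)
  # agrees with stats::t.test directly
  ref <- t.test(vals2[cl$data == 1L], vals2[cl$data == 0L])
  expect_equal(cmp2$statistic, unname(ref$statistic))
  expect_equal(cmp2$p_value, ref$p.value)

  # single-voxel group is refused
  tiny <- array(0L, dim = d); tiny[1, 1, 1] <- 1L
  expect_error(sd_comparison(sdm2, mask3d(tiny), brain), "2 voxels")
})

test_that("seed correlation maps agree with the pairwise engine", {
  ph <- small_phantom()
  x <- extract_matrix(ph$image, ph$truth$brain)
  seed <- head(which(ph$truth$veins$data == 1L), 1)
  seed_ijk <- arrayInd(seed, dim(ph$truth$veins$data)) - 1L
  res <- seed_correlation_map(x, seed_ijk, graph_threshold = 0.8)

  # r at the seed itself is 1
  expect_equal(res$map[seed], 1.0)
  expect_true(all(abs(res$map) <= 1))

  # agreement with pearson_edges for the seed's pairs
  node <- which(x$index_map$linear == seed)
  g <- pearson_edges(x, threshold = 0.3)
  inc <- g$edges[g$edges$i == node | g$edges$j == node, ]
  other <- ifelse(inc$i == node, inc$j, inc$i)
  expect_lt(max(abs(res$map[x$index_map$linear[other]] - inc$r)), 1e-10)

  expect_error(seed_correlation_map(x, c(0, 0, 0), 0.8), "not inside")
})

test_that("venous seeds light up their branch; network voxels stay below", {
  ph <- small_phantom()
  x <- extract_matrix(ph$image, ph$truth$brain)
  branch1 <- which(ph$truth$branches[[1]]$data == 1L)
  seed_ijk <- arrayInd(branch1[1], dim(ph$truth$brain$data)) - 1L
  res <- seed_correlation_map(x, seed_ijk, graph_threshold = 0.8)
  expect_true(all(res$supra_graph$data[branch1] == 1L))
  net <- which(ph$truth$networks[[1]]$data == 1L)
  expect_true(all(res$supra_graph$data[net] == 0L))
})

test_that("zero-variance seeds are rejected", {
  vol <- array(0L, dim = c(3, 1, 1)); vol[1:2, 1, 1] <- 1L
  m <- mask3d(vol)
  values <- cbind(rep(1, 10), rnorm(10))
  x <- structure(list(values = values, tr = 1, index_map = voxel_index_map(m)),
                 class = "vox_matrix")
  expect_error(seed_correlation_map(x, c(0, 0, 0), 0.5), "zero variance")
})
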