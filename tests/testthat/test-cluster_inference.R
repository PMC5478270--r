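# 1-D chain adjacency helper
chain_adjacency <- function(n) {
  structure(lapply(seq_len(n), function(i)
    intersect(c(i - 1L, i + 1L), seq_len(n))), class = "adjacency")
}

test_that("extract_clusters on a 1-D chain matches the worked example", {
  adj <- chain_adjacency(5)
  res <- extract_clusters(c(0, 3, 3.2, 0, 3.1), adj, threshold = 2.8)
  expect_identical(nrow(res$clusters), 2L)
  masses <- sort(res$clusters$mass)
  expect_equal(masses, c(3.1, 6.2))
  expect_setequal(res$members[[which(res$clusters$mass == 6.2)]],
                  c(2L, 3L))
  # sign symmetry: negated map gives the same clusters, negative sign
  neg <- extract_clusters(-c(0, 3, 3.2, 0, 3.1), adj, threshold = 2.8)
  expect_equal(sort(neg$clusters$mass), c(-6.2, -3.1))
  expect_true(all(neg$clusters$sign == -1))
  expect_error(extract_clusters(1:5, adj, df = 0), "positive")
})

test_that("connected components match a brute-force flood fill on 2-D maps", {
  flood_oracle <- function(above, nr, nc) {
    lab <- matrix(0L, nr, nc); cur <- 0L
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!above[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
        if (!above[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
    lab
  }
  mask <- array(TRUE, c(5, 5, 1))
  adj <- mask_adjacency(mask)
  set.seed(17)
  for (i in 1:5) {
    z <- matrix(rnorm(25), 5, 5)
    res <- extract_clusters(as.numeric(z), adj, threshold = 0.5)
    lab <- flood_oracle(z > 0.5, 5, 5)
    pos <- res$clusters$sign == 1
    expect_identical(sum(pos), max(lab))
    sizes_pkg <- sort(res$clusters$size[pos])
    sizes_orc <- sort(as.integer(table(lab[lab > 0])))
    expect_identical(sizes_pkg, sizes_orc)
  }
})

test_that("sensor_adjacency uses the distance threshold", {
  pos <- rbind(c(0, 0, 0), c(0.03, 0, 0), c(0.10, 0, 0))
  expect_warning(adj <- sensor_adjacency(pos, 0.04), "disconnected")
  expect_identical(adj[[1]], 2L)
  expect_identical(adj[[3]], integer(0))
  # radius 0 -> empty edges
  expect_warning(a0 <- sensor_adjacency(pos, 0), "disconnected")
  expect_true(all(lengths(a0) == 0))
  # regular grid vs hand-computed neighbour list
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0))
  adj_g <- sensor_adjacency(g, 1.0)
  for (i in seq_len(nrow(g))) {
    d <- sqrt(rowSums((g - rep(g[i, ], each = nrow(g)))^2))
    expect_setequal(adj_g[[i]], setdiff(which(d <= 1.0), i))
  }
  expect_error(sensor_adjacency(rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
})

test_that("permutation test: exhaustive n = 3 single-node case gives p = 0.25", {
  adj1 <- chain_adjacency(1)
  res <- permutation_cluster_test(matrix(c(1, 2, 3), ncol = 1), adj1,
                                  n_perm = 1000, node_p = 0.5)
  expect_true(res$exhaustive)
  expect_identical(res$n_perm, 8L)
  expect_equal(res$clusters$p, 0.25)
  # exhaustive enumeration oracle: |t| of all 8 sign patterns
  flips <- expand.grid(c(1, -1), c(1, -1), c(1, -1))
  tval <- apply(flips, 1, function(fl) {
    d <- c(1, 2, 3) * as.numeric(fl)
    abs(mean(d) / (sd(d) / sqrt(3)))
  })
  thr <- qt(1 - 0.5 / 2, 2)
  null_oracle <- ifelse(tval > thr, tval, 0)
  expect_equal(sort(res$null), sort(null_oracle), tolerance = 1e-12)
})

test_that("permutation test properties: relabeling, empty input, validity", {
  set.seed(19)
  D <- matrix(rnorm(8 * 12, mean = 0.8), 8, 12)
  adj <- chain_adjacency(12)
  r1 <- permutation_cluster_test(D, adj, n_perm = 300, node_p = 0.05,
                                 seed = 5)
  # permuting node order leaves cluster masses unchanged (chain
  # adjacency is symmetric under reversal)
  r2 <- permutation_cluster_test(D[, 12:1], adj, n_perm = 300,
                                 node_p = 0.05, seed = 5)
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass),
               tolerance = 1e-10)
  # all-zero differences: valid empty result
  r0 <- permutation_cluster_test(matrix(0, 5, 4), chain_adjacency(4),
                                 n_perm = 100, seed = 1)
  expect_identical(nrow(r0$clusters), 0L)
  # sampled p-values never fall below the add-one floor
  expect_true(all(r1$clusters$p >= 1 / 301))
})

test_that("permutation p-values are valid on null data", {
  set.seed(23)
  adj <- chain_adjacency(8)
  pvals <- replicate(60, {
    D <- matrix(rnorm(6 * 8), 6, 8)
    r <- permutation_cluster_test(D, adj, n_perm = 200, node_p = 0.1,
                                  seed = sample.int(1e6, 1))
    if (nrow(r$clusters)) min(r$clusters$p) else 1
  })
  # P(min p <= alpha) <= alpha + simulation slack at the tested grid
  for (a in c(0.05, 0.1, 0.2)) {
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / 60))
  }
})

test_that("estimate_acf recovers known parameters from synthetic fields", {
  mask <- ellipsoid_mask(c(10, 10, 10), c(4.5, 4.5, 4.5))
  true_acf <- function(r) 0.7 * exp(-r^2 / (2 * 3^2)) +
    0.3 * exp(-r / 8)
  sroot <- threatconn:::make_field_sampler(mask, true_acf, 3)
  set.seed(29)
  resid <- sapply(1:80, function(i)
    threatconn:::sample_acf_field(sroot))
  fit <- estimate_acf(resid, mask, voxel_mm = 3)
  expect_gt(fit$a, 0.7 * 0.8); expect_lt(fit$a, min(1, 0.7 * 1.25))
  expect_gt(fit$b, 3 * 0.8); expect_lt(fit$b, 3 * 1.25)
  # model constraint: ACF(0) = 1, decreasing
  expect_equal(fit$acf_fun(0), 1)
  r <- seq(0, 30, 1)
  expect_true(all(diff(fit$acf_fun(r)) <= 1e-12))
  # white noise: near-zero correlation at one voxel spacing
  white <- matrix(rnorm(sum(mask) * 60), sum(mask), 60)
  fw <- estimate_acf(white, mask, voxel_mm = 3)
  expect_lt(fw$acf_fun(3), 0.1)
  expect_error(estimate_acf(white[, 1, drop = FALSE], mask), "frames")
})

test_that("covariance-root field synthesis reproduces the target ACF", {
  mask <- ellipsoid_mask(c(8, 8, 8), c(3.5, 3.5, 3.5))
  acf_fun <- function(r) exp(-r^2 / (2 * 4^2))
  sroot <- threatconn:::make_field_sampler(mask, acf_fun, 3)
  set.seed(31)
  f <- sapply(1:300, function(i)
    threatconn:::sample_acf_field(sroot))
  # unit variance and neighbour correlation ~ ACF(3 mm)
  expect_equal(mean(apply(f, 1, var)), 1, tolerance = 0.1)
  co <- threatconn:::mask_coords(mask, 3)
  d <- as.matrix(dist(co))
  nb <- which(abs(d - 3) < 1e-9, arr.ind = TRUE)
  nb <- nb[nb[, 1] < nb[, 2], ][1:40, ]
  emp <- mean(sapply(seq_len(nrow(nb)), function(k)
    cor(f[nb[k, 1], ], f[nb[k, 2], ])))
  expect_equal(emp, acf_fun(3), tolerance = 0.1)
})

test_that("Monte-Carlo cluster threshold: white-noise oracle and monotonicity", {
  mask <- ellipsoid_mask(c(10, 10, 10), c(4.5, 4.5, 4.5))
  # near-white ACF: threshold should be tiny (binomial expectation:
  # with p = 0.005 per voxel, isolated suprathreshold voxels dominate)
  white_acf <- structure(list(acf_fun = function(r)
    ifelse(r == 0, 1, 0)), class = "acf_model")
  thr_w <- simulate_cluster_threshold(mask, white_acf, voxel_p = 0.005,
                                      n_iter = 300, seed = 7)
  expect_lte(thr_w$min_cluster_size, 2L)
  # independent iid-normal oracle for the same quantile
  set.seed(8)
  adj <- mask_adjacency(mask)
  zthr <- qnorm(1 - 0.005 / 2)
  null_oracle <- replicate(300, {
    z <- rnorm(sum(mask))
    nodes <- which(abs(z) > zthr)
    if (!length(nodes)) 0L else {
      pos <- nodes[z[nodes] > 0]; neg <- nodes[z[nodes] < 0]
      m <- 0L
      if (length(pos)) m <- max(m, max(tabulate(
        threatconn:::connected_components(pos, adj))))
      if (length(neg)) m <- max(m, max(tabulate(
        threatconn:::connected_components(neg, adj))))
      m
    }
  })
  oracle_thr <- sort(null_oracle)[ceiling(0.95 * 300)]
  expect_lte(abs(thr_w$min_cluster_size - oracle_thr), 1L)
  # alpha = 1 returns the minimum of the null distribution
  expect_identical(
    simulate_cluster_threshold(mask, white_acf, n_iter = 200,
                               alpha = 1, seed = 3)$min_cluster_size,
    min(simulate_cluster_threshold(mask, white_acf, n_iter = 200,
                                   alpha = 1, seed = 3)$null))
  expect_error(simulate_cluster_threshold(mask, white_acf,
                                          n_iter = 50), "at least 200")
})

test_that("cluster_overlap counts intersections", {
  a <- array(FALSE, c(4, 4, 4)); a[1:3, 1:3, 1] <- TRUE
  expect_identical(cluster_overlap(a, a),
                   list(intersection = 9L, n_a = 9L, n_b = 9L))
  b <- array(FALSE, c(4, 4, 4)); b[4, 4, 4] <- TRUE
  expect_identical(cluster_overlap(a, b)$intersection, 0L)
  # random masks vs direct set intersection
  set.seed(37)
  m1 <- array(runif(64) < 0.4, c(4, 4, 4))
  m2 <- array(runif(64) < 0.4, c(4, 4, 4))
  expect_identical(cluster_overlap(m1, m2)$intersection,
                   length(intersect(which(m1), which(m2))))
  expect_error(cluster_overlap(a, array(FALSE, c(3, 3, 3))), "grids")
})
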