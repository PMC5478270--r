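#' Face-connectivity adjacency for in-mask voxels
#'
#' Nodes are the in-mask voxels in `which(mask)` order; edges connect
#' voxels sharing a face (6-neighbourhood).
#'
#' @param mask logical 3-D array.
#' @return adjacency list: for each node, an integer vector of neighbour
#'   node ids (class `adjacency`).
#' @export
mask_adjacency <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  node_of <- integer(prod(dims))
  node_of[idx] <- seq_along(idx)
  coord <- cbind((idx - 1L) %% dims[1],
                 ((idx - 1L) %/% dims[1]) %% dims[2],
                 (idx - 1L) %/% (dims[1] * dims[2])) + 1L
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  adj <- vector("list", length(idx))
  for (k in seq_len(nrow(steps))) {
    nb <- coord + rep(steps[k, ], each = nrow(coord))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
      (nb[, 3] - 1L) * dims[1] * dims[2]
    valid <- ok
    valid[ok] <- mask[lin[ok]]
    for (i in which(valid)) adj[[i]] <- c(adj[[i]], node_of[lin[i]])
  }
  structure(lapply(adj, function(v) sort(unique(v %||% integer(0)))),
            class = "adjacency")
}

#' Distance-threshold adjacency for sensors
#'
#' Edge between two sensors iff their Euclidean distance is at most
#' `radius` (default 4 cm); warns if the resulting graph is
#' disconnected.
#'
#' @param pos sensors x 3 position matrix (metres).
#' @param radius neighbourhood radius in the units of `pos`,
#'   default 0.04.
#' @return adjacency list (class `adjacency`).
#' @export
sensor_adjacency <- function(pos, radius = 0.04) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 2L) stop("need at least 2 sensors")
  D <- as.matrix(stats::dist(pos))
  if (any(D[upper.tri(D)] == 0)) stop("duplicate sensor positions")
  adj <- lapply(seq_len(nrow(pos)), function(i) {
    v <- unname(which(D[i, ] <= radius))
    v[v != i]
  })
  adj <- structure(adj, class = "adjacency")
  comp <- connected_components(seq_len(nrow(pos)), adj)
  if (max(comp) > 1L)
    warning(sprintf("sensor adjacency graph has %d disconnected components",
                    max(comp)))
  adj
}

# Connected components of the node subset `nodes` under `adj`
# (adjacency over the full node set).  Returns component id per entry of
# `nodes`.  Plain BFS; `nodes` is usually the small suprathreshold set.
connected_components <- function(nodes, adj) {
  in_set <- logical(length(adj))
  in_set[nodes] <- TRUE
  pos_in_nodes <- integer(length(adj))
  pos_in_nodes[nodes] <- seq_along(nodes)
  comp <- integer(length(nodes))
  cur <- 0L
  for (s in seq_along(nodes)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- nodes[s]
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nbr <- adj[[v]]
      nbr <- nbr[in_set[nbr]]
      new <- nbr[comp[pos_in_nodes[nbr]] == 0L]
      comp[pos_in_nodes[new]] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Applies a two-sided forming threshold (`|t| > t(1 - node_p / 2, df)`,
#' or an explicit `threshold`), finds connected components separately
#' for positive and negative suprathreshold nodes, and records each
#' cluster's size, mass (summed statistic), sign and peak node.
#'
#' @param stat numeric statistic per node.
#' @param adjacency an `adjacency` list covering the nodes.
#' @param df degrees of freedom of the statistic (for the threshold).
#' @param node_p two-sided node-level forming p, default 0.005.
#' @param threshold explicit forming threshold overriding `df`/`node_p`.
#' @return list of class `cluster_result`: `clusters` data.frame (id,
#'   sign, size, mass, peak node, peak stat), `members` list of node id
#'   vectors, and the `threshold` used.
#' @export
extract_clusters <- function(stat, adjacency, df = NULL, node_p = 0.005,
                             threshold = NULL) {
  if (is.null(threshold)) {
    if (is.null(df)) stop("supply either `df` or `threshold`")
    if (df <= 0) stop("df must be positive")
    threshold <- stats::qt(1 - node_p / 2, df)
  }
  res <- list(clusters = data.frame(id = integer(0), sign = integer(0),
                                    size = integer(0), mass = numeric(0),
                                    peak = integer(0), peak_stat = numeric(0)),
              members = list(), threshold = threshold)
  out_id <- 0L
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * stat > threshold)
    if (!length(nodes)) next
    comp <- connected_components(nodes, adjacency)
    for (cid in seq_len(max(comp))) {
      mem <- nodes[comp == cid]
      out_id <- out_id + 1L
      pk <- mem[which.max(sgn * stat[mem])]
      res$clusters <- rbind(res$clusters, data.frame(
        id = out_id, sign = sgn, size = length(mem),
        mass = sum(stat[mem]), peak = pk, peak_stat = stat[pk]))
      res$members[[out_id]] <- mem
    }
  }
  class(res) <- "cluster_result"
  res
}

#' Sign-flip permutation cluster-mass test for paired differences
#'
#' One-sample t statistics are computed per node from the per-subject
#' paired difference maps, clusters formed at a two-sided node-level
#' threshold, and each cluster's mass (summed t) compared against the
#' permutation null of the maximum absolute cluster mass obtained by
#' flipping the sign of whole difference maps per subject (the
#' exchangeable scheme for a paired design in which condition labels are
#' shuffled within subject).  All `2^n` flips are enumerated when
#' `2^n <= n_perm`; otherwise `n_perm` random flips are sampled.
#'
#' @param diffs subjects x nodes matrix of paired differences
#'   (threat - safe).
#' @param adjacency an `adjacency` list over the nodes.
#' @param n_perm permutations, default 1000.
#' @param node_p two-sided node-level forming p, default 0.005.
#' @param alpha cluster-level two-tailed alpha, default 0.05.
#' @param seed RNG seed for sampled permutations.
#' @return `cluster_result` with per-cluster corrected `p` and
#'   `significant` flag, the max-mass `null` distribution, its
#'   `mass_threshold` at `1 - alpha`, and whether enumeration was
#'   `exhaustive`.
#' @export
permutation_cluster_test <- function(diffs, adjacency, n_perm = 1000L,
                                     node_p = 0.005, alpha = 0.05,
                                     seed = NULL) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2L) stop("need at least 2 subjects")
  if (length(adjacency) != ncol(diffs))
    stop("adjacency does not cover the nodes")

  node_t <- function(D) {
    m <- colMeans(D)
    s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
    t <- m / (s / sqrt(n))
    t[!is.finite(t)] <- 0
    t
  }
  thr <- stats::qt(1 - node_p / 2, n - 1L)
  obs <- extract_clusters(node_t(diffs), adjacency, threshold = thr)

  # max |cluster mass| for one t map without data.frame overhead; most
  # null maps have no suprathreshold node, so short-circuit those
  max_mass_t <- function(t) {
    mx <- 0
    for (sgn in c(1, -1)) {
      nodes <- which(sgn * t > thr)
      if (!length(nodes)) next
      comp <- connected_components(nodes, adjacency)
      mx <- max(mx, abs(vapply(seq_len(max(comp)), function(ci)
        sum(t[nodes[comp == ci]]), numeric(1))))
    }
    mx
  }

  exhaustive <- 2^n <= n_perm
  flips <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(1, -1), n_perm * n, replace = TRUE),
                           n_perm, n))
  }
  # vectorized t maps across permutations: the second moment is
  # flip-invariant, only the mean flips
  ss <- colSums(diffs^2)
  M <- flips %*% diffs / n
  S <- sqrt(sweep(-n * M^2, 2L, ss, `+`) / (n - 1))
  Tm <- M / (S / sqrt(n))
  Tm[!is.finite(Tm)] <- 0
  any_sup <- rowSums(abs(Tm) > thr) > 0
  null <- numeric(nrow(Tm))
  for (i in which(any_sup)) null[i] <- max_mass_t(Tm[i, ])
  pfun <- if (exhaustive) {
    function(m) mean(null >= m - 1e-12)
  } else {
    # add-one rule keeps sampled p-values valid
    function(m) (1 + sum(null >= m - 1e-12)) / (n_perm + 1)
  }
  mass_thr <- stats::quantile(null, 1 - alpha, names = FALSE, type = 1)
  cl <- obs$clusters
  cl$p <- if (nrow(cl)) vapply(abs(cl$mass), pfun, numeric(1)) else numeric(0)
  cl$significant <- cl$p <= alpha
  structure(list(clusters = cl, members = obs$members,
                 threshold = thr, null = null, mass_threshold = mass_thr,
                 exhaustive = exhaustive, n_perm = length(null)),
            class = "cluster_result")
}

#' Fit a Gaussian + mono-exponential spatial autocorrelation model
#'
#' The empirical spatial autocorrelation of residual volumes is computed
#' over in-mask voxel pairs binned by distance and fitted with
#' `ACF(r) = a * exp(-r^2 / (2 b^2)) + (1 - a) * exp(-r / c)` by
#' nonlinear least squares with the constraints `a` in \[0, 1\] and
#' `b, c > 0` (so ACF(0) = 1 and the fit decreases monotonically).
#'
#' @param resid in-mask voxels x frames residual matrix.
#' @param mask logical 3-D array (defines voxel coordinates).
#' @param voxel_mm voxel size in mm.
#' @param max_pairs maximum number of voxel pairs used, default 50000
#'   (sampled deterministically by taking every k-th pair).
#' @return list of class `acf_model` with `a`, `b`, `c`, the binned
#'   empirical ACF, and `acf_fun(r)`.
#' @export
estimate_acf <- function(resid, mask, voxel_mm = 3, max_pairs = 50000L) {
  if (ncol(resid) < 2L) stop("need at least 2 residual frames")
  coords <- mask_coords(mask, voxel_mm)
  nv <- nrow(coords)
  Xs <- resid - rowMeans(resid)
  Xs <- Xs / sqrt(rowSums(Xs^2))
  pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[as.integer(seq(1L, nrow(pairs),
                                  length.out = max_pairs)), ]
  d <- sqrt(rowSums((coords[pairs[, 1], ] - coords[pairs[, 2], ])^2))
  r <- numeric(nrow(pairs))
  for (chunk in split(seq_len(nrow(pairs)),
                      ceiling(seq_len(nrow(pairs)) / 5000))) {
    r[chunk] <- rowSums(Xs[pairs[chunk, 1], , drop = FALSE] *
                          Xs[pairs[chunk, 2], , drop = FALSE])
  }
  # bin by exact grid distance (rounding to voxel multiples would mix
  # face and diagonal neighbours and bias the short-range curve)
  bin <- round(d, 3)
  emp <- tapply(r, bin, mean)
  dist_bin <- as.numeric(names(emp))
  emp <- c(1, as.numeric(emp))          # r = 0 bin: ACF(0) = 1 by definition
  dist_bin <- c(0, dist_bin)
  wt <- c(1, as.numeric(table(bin)) / length(bin))

  obj <- function(par) {
    a <- stats::plogis(par[1]); b <- exp(par[2]); cc <- exp(par[3])
    fit <- a * exp(-dist_bin^2 / (2 * b^2)) + (1 - a) * exp(-dist_bin / cc)
    sum(wt * (fit - emp)^2)
  }
  best <- NULL
  for (start in list(c(0.8, log(3), log(8)), c(0, log(2), log(4)),
                     c(-0.8, log(5), log(12)))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value))
    stop("ACF fit did not converge; last iterate: ",
         paste(signif(best$par, 4), collapse = ", "))
  a <- stats::plogis(best$par[1]); b <- exp(best$par[2])
  cc <- exp(best$par[3])
  structure(list(a = a, b = b, c = cc,
                 empirical = data.frame(dist = dist_bin, acf = emp),
                 acf_fun = function(r)
                   a * exp(-r^2 / (2 * b^2)) + (1 - a) * exp(-r / cc)),
            class = "acf_model")
}

# Exact Gaussian-random-field sampler for the in-mask voxels: the
# target covariance K = ACF(distance) is factorized once by symmetric
# eigendecomposition and fields drawn as K^(1/2) z.  At desk scale
# (<= a few thousand in-mask voxels) this is cheap and, unlike
# spectral/FFT colouring, does not alias the sharp mono-exponential
# kernel at coarse voxel sampling.
make_field_sampler <- function(mask, acf_fun, voxel_mm) {
  coords <- mask_coords(mask, voxel_mm)
  K <- acf_fun(as.matrix(stats::dist(coords)))
  diag(K) <- 1
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(root = e$vectors %*% (sqrt(lam) * t(e$vectors)),
       n = nrow(coords))
}

sample_acf_field <- function(sampler, mask = NULL) {
  drop(sampler$root %*% stats::rnorm(sampler$n))
}

#' Monte-Carlo cluster-size threshold
#'
#' Simulates Gaussian random fields with the target spatial ACF over
#' the in-mask voxels (exact covariance-root synthesis),
#' applies the two-sided voxelwise threshold, records the largest
#' suprathreshold cluster per iteration, and returns the cluster size at
#' the `1 - alpha` quantile of that null: clusters at least this large
#' are corrected-significant at `alpha`.
#'
#' @param mask logical 3-D array.
#' @param acf an `acf_model` (or any list with `acf_fun`).
#' @param voxel_p two-sided voxelwise alpha, default 0.005.
#' @param n_iter Monte-Carlo iterations (>= 200).
#' @param alpha corrected cluster alpha, default 0.05.
#' @param voxel_mm voxel size in mm.
#' @param seed RNG seed.
#' @return list with `min_cluster_size` (the `ceiling((1 - alpha) *
#'   n_iter)`-th order statistic of the null) and the full `null`
#'   distribution of largest cluster sizes.
#' @export
simulate_cluster_threshold <- function(mask, acf, voxel_p = 0.005,
                                       n_iter = 500L, alpha = 0.05,
                                       voxel_mm = 3, seed = NULL) {
  if (n_iter < 200L) stop("n_iter must be at least 200")
  adjacency <- mask_adjacency(mask)
  sampler <- make_field_sampler(mask, acf$acf_fun, voxel_mm)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  null <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    z <- sample_acf_field(sampler)
    nodes <- which(abs(z) > zthr)
    if (!length(nodes)) return(0L)
    pos <- nodes[z[nodes] > 0]
    neg <- nodes[z[nodes] < 0]
    mx <- 0L
    if (length(pos))
      mx <- max(mx, max(tabulate(connected_components(pos, adjacency))))
    if (length(neg))
      mx <- max(mx, max(tabulate(connected_components(neg, adjacency))))
    as.integer(mx)
  }, integer(1)))
  k <- sort(null)[max(1L, ceiling((1 - alpha) * n_iter))]
  list(min_cluster_size = as.integer(k), null = null,
       voxel_threshold = zthr)
}

#' Overlap between two cluster masks
#'
#' @param mask_a,mask_b logical arrays (or index vectors on a common
#'   grid).
#' @return list with `intersection`, `n_a`, `n_b`.
#' @export
cluster_overlap <- function(mask_a, mask_b) {
  if (is.logical(mask_a) && is.logical(mask_b)) {
    if (!identical(dim(mask_a), dim(mask_b)))
      stop("cluster masks are on different grids")
    list(intersection = sum(mask_a & mask_b),
         n_a = sum(mask_a), n_b = sum(mask_b))
  } else {
    list(intersection = length(intersect(mask_a, mask_b)),
         n_a = length(mask_a), n_b = length(mask_b))
  }
}
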