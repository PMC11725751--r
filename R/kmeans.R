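# From-scratch k-means with k-means++ seeding, written out rather than
# delegated because the clustering configuration (best of n_init seedings,
# Lloyd iterations with an inertia-based stop, deterministic tie-breaks,
# empty-cluster re-seeding) is the core of the grouping method and every
# piece of it is asserted by tests. stats::kmeans appears only as an
# independent cross-check in the test suite.

# Squared Euclidean distances from each row of X (n x d) to each row of
# C (k x d); negative round-off clipped to zero.
squared_distances <- function(X, C) {
  d2 <- matrix(rowSums(X^2), nrow(X), nrow(C)) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE) -
    2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

#' k-means++ selection probabilities
#'
#' Given squared distances from each candidate point to its nearest
#' already-chosen centroid, returns the probability with which each
#' candidate becomes the next centroid: `D(x_i)^2 / sum_j D(x_j)^2`.
#' Points coincident with an existing centroid (distance 0) have
#' probability 0; the probabilities sum to 1.
#'
#' @param d2 non-negative squared distances, at least one positive.
#' @return probability vector of the same length.
#' @export
kmeanspp_probs <- function(d2) {
  if (any(d2 < 0)) stop("squared distances must be non-negative")
  total <- sum(d2)
  if (total <= 0) stop("all candidate distances are zero: seeding infeasible")
  d2 / total
}

#' k-means++ seeding
#'
#' Draws `k` initial centroids from `points`: the first uniformly at random,
#' each subsequent one with probability proportional to its squared distance
#' to the nearest centroid chosen so far. Consumes the current R random
#' stream; seed via `set.seed()` or [fit_kmeans()].
#'
#' @param points numeric matrix, one point per row.
#' @param k number of centroids; must not exceed the number of distinct rows.
#' @return k x ncol(points) matrix of initial centroids.
#' @export
kmeanspp_seed <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (nrow(unique(points)) < k) {
    stop("fewer distinct points than k: seeding infeasible")
  }
  centroids <- matrix(NA_real_, k, ncol(points))
  centroids[1, ] <- points[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- squared_distances(points, centroids[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      idx <- sample.int(n, 1, prob = kmeanspp_probs(d2))
      centroids[j, ] <- points[idx, ]
      d2 <- pmin(d2, squared_distances(points,
                                       centroids[j, , drop = FALSE])[, 1])
    }
  }
  centroids
}

# One Lloyd run from the given initial centroids. Assignment breaks distance
# ties to the lowest cluster index; an emptied cluster is re-seeded at the
# point currently farthest from its assigned centroid. Returns centroids as
# used for the final assignment, so assignments are exactly
# nearest-centroid with respect to the returned centroids.
lloyd_run <- function(X, centroids, max_iter, tol) {
  n <- nrow(X)
  k <- nrow(centroids)
  inertia_trace <- numeric(0)
  prev_inertia <- Inf
  assignment <- rep(NA_integer_, n)
  inertia <- NA_real_
  for (iter in seq_len(max_iter)) {
    d2 <- squared_distances(X, centroids)
    assignment <- max.col(-d2, ties.method = "first")
    point_d2 <- d2[cbind(seq_len(n), assignment)]
    counts <- tabulate(assignment, k)
    while (any(counts == 0)) {
      j <- which(counts == 0)[1]
      centroids[j, ] <- X[which.max(point_d2), ]
      d2[, j] <- squared_distances(X, centroids[j, , drop = FALSE])[, 1]
      assignment <- max.col(-d2, ties.method = "first")
      point_d2 <- d2[cbind(seq_len(n), assignment)]
      counts <- tabulate(assignment, k)
    }
    inertia <- sum(point_d2)
    inertia_trace <- c(inertia_trace, inertia)
    used_centroids <- centroids  # the centroids this assignment is nearest to
    converged <- inertia == 0 ||
      (is.finite(prev_inertia) && (prev_inertia - inertia) < tol * prev_inertia)
    if (converged) break
    prev_inertia <- inertia
    centroids <- rowsum(X, assignment) / counts
  }
  list(centroids = used_centroids, cluster = assignment, inertia = inertia,
       inertia_trace = inertia_trace, iterations = length(inertia_trace))
}

#' Fit k-means by best-of-n k-means++ restarts
#'
#' Runs Lloyd iterations (assign each point to its nearest centroid by
#' Euclidean distance, then recompute centroids as assignment means) from
#' `n_init` independent k-means++ seedings and keeps the run with the lowest
#' inertia (sum of squared point-to-centroid distances). Within every run
#' the inertia is monotonically non-increasing; a run stops when the
#' relative inertia change drops below `tol` or after `max_iter` iterations.
#' Distance ties break to the lowest cluster index and an emptied cluster is
#' re-seeded at the point farthest from its current centroid, so the fit is
#' fully deterministic given `seed`.
#'
#' @param points numeric matrix of points (rows), typically abs z-scores.
#' @param k number of clusters (9 in the farm-grading model).
#' @param n_init number of independent seedings.
#' @param max_iter Lloyd iteration cap per run.
#' @param tol relative inertia-change stopping threshold.
#' @param seed integer seed driving all randomness in the fit.
#' @return object of class `kmeans_model`: `centroids` (k x d), `cluster`
#'   (assignment of the training points), `inertia`, `inertia_trace` of the
#'   winning run, and the fit configuration. Cluster labels are arbitrary
#'   until [relabel_and_group()] is applied.
#' @seealso [fit_pig_clusters()] for the full standardize-fit-relabel
#'   pipeline on pig records.
#' @export
fit_kmeans <- function(points, k = 9, n_init = 200, max_iter = 1000,
                       tol = 1e-6, seed = 0) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("no points to cluster")
  if (nrow(unique(points)) < k) stop("fewer distinct points than k")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    run <- lloyd_run(points, kmeanspp_seed(points, k), max_iter, tol)
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  structure(list(centroids = best$centroids,
                 cluster = best$cluster,
                 inertia = best$inertia,
                 inertia_trace = best$inertia_trace,
                 k = k, n_init = n_init, max_iter = max_iter, tol = tol,
                 seed = seed,
                 relabeled = FALSE, group_map = NULL, params = NULL),
            class = "kmeans_model")
}

#' Relabel clusters by distance from the origin and map them to groups
#'
#' Renumbers clusters 1..k by ascending Euclidean norm of their centroid in
#' abs z-space, so cluster 1 holds the pigs closest to the population mean
#' ("least variation") and higher numbers hold progressively more deviant
#' pigs. Ties in norm break by the carcass-weight coordinate, then backfat.
#' For k = 9 the group map is fixed: cluster 1 -> group I, clusters 2-3 ->
#' II, 4-6 -> III, 7-9 -> IV. The partition of the points is unchanged;
#' relabeling twice is a no-op.
#'
#' @param model a fitted `kmeans_model`.
#' @return the model with ordered centroids, remapped `cluster` labels and
#'   `group_map` set (for k = 9).
#' @export
relabel_and_group <- function(model) {
  stopifnot(inherits(model, "kmeans_model"))
  C <- model$centroids
  ord <- order(sqrt(rowSums(C^2)), C[, 1], C[, 2])
  model$centroids <- C[ord, , drop = FALSE]
  rownames(model$centroids) <- paste0("cluster", seq_len(model$k))
  if (!is.null(model$cluster)) {
    model$cluster <- match(model$cluster, ord)
  }
  if (model$k == 9) {
    model$group_map <- setNames(
      rep(PIG_GROUPS, times = c(1, 2, 3, 3)), 1:9)
  }
  model$relabeled <- TRUE
  model
}

#' Assign carcasses to clusters and groups with a fitted model
#'
#' Standardizes the measurements with the model's stored whole-population
#' parameters, assigns each point to the nearest centroid (ties to the
#' lowest cluster index) and maps clusters to groups.
#'
#' @param model a fitted, relabeled `kmeans_model` carrying
#'   `standardization_params` (as produced by [fit_pig_clusters()]).
#' @param carcass_weight,backfat measurements, kg / mm (vectorized).
#' @return data.frame with columns `cluster` (1..k) and `group` (I..IV, NA
#'   if the model has no group map).
#' @export
assign_cluster <- function(model, carcass_weight, backfat) {
  stopifnot(inherits(model, "kmeans_model"))
  if (!isTRUE(model$relabeled) || is.null(model$params)) {
    stop("model must be fitted with standardization params and relabeled")
  }
  X <- cbind(abs_z(carcass_weight, model$params$mu_cw, model$params$sigma_cw),
             abs_z(backfat, model$params$mu_bf, model$params$sigma_bf))
  d2 <- squared_distances(X, model$centroids)
  cl <- max.col(-d2, ties.method = "first")
  grp <- if (is.null(model$group_map)) NA_character_ else model$group_map[cl]
  data.frame(cluster = cl, group = unname(grp))
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("k-means model: k = %d, best of %d k-means++ seedings\n",
              x$k, x$n_init))
  cat(sprintf("  inertia %.6g after %d iteration(s), seed %d\n",
              x$inertia, length(x$inertia_trace), x$seed))
  if (isTRUE(x$relabeled)) {
    cat("  clusters ordered by centroid distance from the origin\n")
  }
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Standardize, cluster and group a herd of pigs
#'
#' The full pig-grouping model fit: whole-population abs z-score
#' standardization of carcass weight and backfat, k-means (k-means++
#' seeding, best of `n_init` restarts) on the standardized pairs, and
#' relabeling of the clusters by distance from the population mean with the
#' fixed 9-cluster to 4-group map.
#'
#' @inheritParams fit_kmeans
#' @param pigs pig data.frame with `carcass_weight_kg` and `backfat_mm`.
#' @return a relabeled `kmeans_model` with `params` set.
#' @export
fit_pig_clusters <- function(pigs, k = 9, n_init = 200, max_iter = 1000,
                             tol = 1e-6, seed = 0) {
  params <- fit_standardization(pigs)
  model <- fit_kmeans(abs_z_matrix(pigs, params), k = k, n_init = n_init,
                      max_iter = max_iter, tol = tol, seed = seed)
  model$params <- params
  relabel_and_group(model)
}

#' Annotate a pig table with cluster and group
#'
#' @param pigs pig data.frame.
#' @param model fitted model from [fit_pig_clusters()].
#' @return `pigs` with `cluster` and `group` columns.
#' @export
assign_pigs <- function(pigs, model) {
  a <- assign_cluster(model, pigs$carcass_weight_kg, pigs$backfat_mm)
  pigs$cluster <- a$cluster
  pigs$group <- a$group
  pigs
}
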