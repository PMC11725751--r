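# Standardization, k-means++ seeding, Lloyd iterations, relabeling and
# assignment, each checked against independent oracles.

test_that("standardization uses population mean and SD and rejects", {
  pigs <- data.frame(carcass_weight_kg = c(80, 90), backfat_mm = c(20, 24))
  p <- fit_standardization(pigs)
  expect_equal(p$mu_cw, 85)
  expect_equal(p$sigma_cw, 5)  # divisor n, not n - 1
  expect_equal(p$mu_bf, 22)
  expect_equal(p$sigma_bf, 2)

  const_bf <- data.frame(carcass_weight_kg = c(80, 90), backfat_mm = c(20, 20))
  expect_error(fit_standardization(const_bf), "zero variance")
})

test_that("abs z-score is symmetric about the mean and scales by sigma", {
  expect_equal(abs_z(86, 86, 3), 0)
  expect_equal(abs_z(86 + 2 * 3, 86, 3), 2)
  expect_equal(abs_z(86 - 1.5 * 3, 86, 3), 1.5)
  d <- runif(20, 0, 10)
  expect_equal(abs_z(50 + d, 50, 2), abs_z(50 - d, 50, 2))
  expect_error(abs_z(1, 0, 0), "sigma")
})

test_that("standardization recovers the configured herd mean", {
  cfg <- default_herd_config(n_pigs = 10000L, n_farms = 20L,
                             farm_effect_sd_cw = 0, farm_effect_sd_bf = 0,
                             seed = 11)
  p <- fit_standardization(generate_herd(cfg))
  se <- cfg$sd_cw / sqrt(cfg$n_pigs)
  expect_lt(abs(p$mu_cw - cfg$mean_cw), 3 * se)
})

test_that("k-means++ selection probabilities follow the squared distances", {
  expect_equal(kmeanspp_probs(c(1, 3)), c(0.25, 0.75))
  expect_equal(kmeanspp_probs(c(0, 2, 2)), c(0, 0.5, 0.5))
  expect_equal(kmeanspp_probs(rep(5, 4)), rep(0.25, 4))
  expect_equal(sum(kmeanspp_probs(runif(17))), 1)
  expect_error(kmeanspp_probs(c(0, 0)), "infeasible")
  expect_error(kmeanspp_probs(c(-1, 1)), "non-negative")
})

test_that("k-means++ seeding picks data points and needs enough of them", {
  pts <- cbind(c(0, 0, 5, 5, 9), c(0, 1, 5, 6, 9))
  set.seed(42)
  C <- kmeanspp_seed(pts, 3)
  expect_identical(dim(C), c(3L, 2L))
  for (i in 1:3) {
    expect_true(any(pts[, 1] == C[i, 1] & pts[, 2] == C[i, 2]))
  }
  dup <- pts[c(1, 1, 1), ]
  expect_error(kmeanspp_seed(dup, 2), "distinct")
})

test_that("k-means collapses repeated point-sites to zero inertia", {
  sites <- cbind(c(0, 5, 9), c(0, 5, 1))
  pts <- sites[rep(1:3, each = 7), ]
  m <- fit_kmeans(pts, k = 3, n_init = 5, seed = 1)
  expect_equal(m$inertia, 0)
  m <- relabel_and_group(m)
  expect_equal(sort(unname(m$centroids[, 1])), sort(sites[, 1]))
  expect_equal(tabulate(m$cluster, 3), rep(7L, 3))
})

test_that("k-means finds the global optimum on 12 points (exhaustive oracle)", {
  set.seed(3)
  pts <- rbind(matrix(rnorm(8, 0, 0.4), ncol = 2),
               matrix(rnorm(8, 4, 0.4), ncol = 2),
               matrix(rnorm(8, c(8, 0), 0.4), ncol = 2))
  k <- 3
  n <- nrow(pts)
  # oracle: enumerate every assignment of 12 points to 3 clusters and
  # compute its within-cluster sum of squares directly
  A <- as.matrix(expand.grid(rep(list(1:k), n)))
  sq <- rowSums(pts^2)
  total <- numeric(nrow(A))
  for (j in 1:k) {
    M <- (A == j) * 1
    cnt <- rowSums(M)
    sx <- M %*% pts[, 1]
    sy <- M %*% pts[, 2]
    ssq <- M %*% sq
    within <- ssq - ifelse(cnt > 0, (sx^2 + sy^2) / cnt, 0)
    total <- total + within
  }
  best_inertia <- min(total)
  best_assign <- A[which.min(total), ]

  m <- fit_kmeans(pts, k = k, n_init = 50, seed = 0)
  expect_equal(m$inertia, best_inertia, tolerance = 1e-10)
  # identical partition, label-invariantly: same co-membership relation
  same <- function(a) outer(a, a, "==")
  expect_identical(same(m$cluster), same(as.integer(best_assign)))
})

test_that("inertia is monotone within runs and best-of-n beats single seeds", {
  set.seed(7)
  pts <- matrix(rnorm(300), ncol = 2)
  m <- fit_kmeans(pts, k = 4, n_init = 25, seed = 2)
  expect_true(all(diff(m$inertia_trace) <= 1e-12))
  singles <- vapply(1:10, function(s) {
    fit_kmeans(pts, k = 4, n_init = 1, seed = s)$inertia
  }, numeric(1))
  expect_true(all(m$inertia <= singles + 1e-12))
  # every point is assigned to exactly one cluster and sizes sum to n
  expect_identical(sum(tabulate(m$cluster, 4)), nrow(pts))
})

test_that("final inertia agrees with stats::kmeans on small data", {
  set.seed(19)
  pts <- matrix(c(rnorm(120, 0, 1), rnorm(80, 3, 1)), ncol = 2)
  ours <- fit_kmeans(pts, k = 5, n_init = 60, seed = 4)$inertia
  ref <- stats::kmeans(pts, centers = 5, nstart = 60,
                       iter.max = 100)$tot.withinss
  expect_lt(abs(ours - ref) / ref, 0.001)
})

test_that("relabeling orders centroids by norm, is idempotent, keeps partition", {
  set.seed(5)
  pts <- matrix(abs(rnorm(400)), ncol = 2)
  m <- fit_kmeans(pts, k = 9, n_init = 10, seed = 6)
  pre_partition <- m$cluster
  r <- relabel_and_group(m)
  norms <- sqrt(rowSums(r$centroids^2))
  expect_true(all(diff(norms) >= 0))
  # partition unchanged under relabeling (co-membership identical)
  expect_identical(outer(r$cluster, r$cluster, "=="),
                   outer(pre_partition, pre_partition, "=="))
  r2 <- relabel_and_group(r)
  expect_identical(r2$centroids, r$centroids)
  expect_identical(r2$cluster, r$cluster)
  # fixed 9 -> 4 map: cluster 1 -> I, 2-3 -> II, 4-6 -> III, 7-9 -> IV
  expect_identical(unname(r$group_map),
                   c("I", "II", "II", "III", "III", "III", "IV", "IV", "IV"))
  expect_identical(unname(r$group_map[5]), "III")
})

test_that("assignment matches a brute-force nearest-centroid search", {
  model <- calibrated_model()
  expect_s3_class(model, "kmeans_model")
  # the population mean standardizes to the origin: cluster 1, group I
  a <- assign_cluster(model, model$params$mu_cw, model$params$mu_bf)
  expect_identical(a$cluster, 1L)
  expect_identical(a$group, "I")
  # points placed exactly at centroids return their own cluster
  for (j in c(1, 5, 9)) {
    cw <- model$params$mu_cw + model$centroids[j, 1] * model$params$sigma_cw
    bf <- model$params$mu_bf + model$centroids[j, 2] * model$params$sigma_bf
    expect_identical(assign_cluster(model, cw, bf)$cluster, as.integer(j))
  }
  # random probes against the independent oracle
  set.seed(23)
  cw <- runif(200, 60, 120)
  bf <- runif(200, 5, 40)
  got <- assign_cluster(model, cw, bf)$cluster
  z <- cbind(abs_z(cw, model$params$mu_cw, model$params$sigma_cw),
             abs_z(bf, model$params$mu_bf, model$params$sigma_bf))
  oracle <- vapply(seq_len(200),
                   function(i) brute_nearest(z[i, ], model$centroids),
                   numeric(1))
  expect_identical(got, as.integer(oracle))
})

test_that("group shares on the calibrated herd are ordered as published", {
  pigs <- calibrated_pigs()
  shares <- table(factor(pigs$group, levels = c("I", "II", "III", "IV")))
  expect_true(shares[["IV"]] == min(shares))
  expect_gt(shares[["II"]], shares[["IV"]])
  expect_gt(shares[["III"]], shares[["IV"]])
})
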