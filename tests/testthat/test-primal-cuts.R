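# Per-group OLS of cut weights, prediction from the bundled coefficients,
# production ratios and the group-comparison statistics.

test_that("bundled coefficient table has the full group x cut layout", {
  ref <- reference_cut_coefficients()
  expect_identical(nrow(ref), 20L)
  expect_identical(sort(unique(ref$group)), c("I", "II", "III", "IV"))
  expect_identical(length(unique(ref$cut)), 5L)
  expect_true(all(ref$mae >= 0))
  expect_true(all(ref$r2 >= 0 & ref$r2 <= 1))
})

test_that("prediction evaluates the plane at the given carcass", {
  ref <- reference_cut_coefficients()
  ham1 <- ref[ref$group == "I" & ref$cut == "ham", ]
  expect_equal(round(predict_cut(ham1, 86.43, 21.99), 4), 19.0323)
  loin1 <- ref[ref$group == "I" & ref$cut == "loin", ]
  expect_equal(round(predict_cut(loin1, 86.43, 21.99), 4), 9.9692)
  flat <- list(beta0 = 4.2, beta1 = 0, beta2 = 0)
  expect_equal(predict_cut(flat, c(70, 100), c(10, 35)), c(4.2, 4.2))
})

test_that("production ratio is the cut's percentage of the carcass", {
  expect_equal(production_ratio(0, 90), 0)
  expect_equal(production_ratio(45, 90), 50)
  expect_error(production_ratio(10, 0), "carcass_weight")
})

test_that("group I reference planes reproduce the published ratios at the
           group means", {
  ref <- reference_cut_coefficients()
  at_means <- function(cut) {
    row <- ref[ref$group == "I" & ref$cut == cut, ]
    production_ratio(predict_cut(row, 86.43, 21.99), 86.43)
  }
  expect_equal(round(at_means("shoulder_picnic"), 2), 12.93)
  expect_equal(round(at_means("loin"), 2), 11.53)
  expect_equal(round(at_means("belly"), 2), 19.06)
  expect_equal(round(at_means("ham"), 2), 22.02)
  # shoulder blade: ratio-of-means differs from the published
  # mean-of-ratios by about 0.01, so only a tolerance check is possible
  expect_lt(abs(at_means("shoulder_blade") - 6.65), 0.015)
})

test_that("OLS interpolates noiseless planes and saturated fits exactly", {
  set.seed(31)
  n <- 60
  d <- data.frame(group = "II",
                  carcass_weight_kg = runif(n, 70, 100),
                  backfat_mm = runif(n, 10, 35))
  d$loin_kg <- 1 + 0.2 * d$carcass_weight_kg - 0.01 * d$backfat_mm
  f <- fit_group_ols(d, "II", "loin")
  expect_equal(c(f$beta0, f$beta1, f$beta2), c(1, 0.2, -0.01),
               tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$mae, 0, tolerance = 1e-12)

  # n = 3 non-collinear points: saturated, all residuals zero
  d3 <- data.frame(group = "I",
                   carcass_weight_kg = c(80, 90, 85),
                   backfat_mm = c(20, 22, 30),
                   ham_kg = c(17, 19, 18.2))
  f3 <- fit_group_ols(d3, "I", "ham")
  pred <- predict_cut(f3, d3$carcass_weight_kg, d3$backfat_mm)
  expect_equal(pred, d3$ham_kg, tolerance = 1e-10)

  # collinear predictors are rejected
  dd <- d
  dd$backfat_mm <- 2 * dd$carcass_weight_kg
  expect_error(fit_group_ols(dd, "II", "loin"), "singular")
})

test_that("residuals are orthogonal to the design and metrics are invariant", {
  set.seed(33)
  n <- 200
  d <- data.frame(group = "III",
                  carcass_weight_kg = rnorm(n, 86, 5),
                  backfat_mm = rnorm(n, 22, 4))
  d$belly_kg <- -3 + 0.21 * d$carcass_weight_kg + 0.07 * d$backfat_mm +
    rnorm(n, 0, 0.6)
  f <- fit_group_ols(d, "III", "belly")
  res <- d$belly_kg - predict_cut(f, d$carcass_weight_kg, d$backfat_mm)
  expect_lt(abs(sum(res)), 1e-8)
  expect_lt(abs(sum(res * d$carcass_weight_kg)), 1e-6)
  expect_lt(abs(sum(res * d$backfat_mm)), 1e-6)
  # MAE unchanged when a constant shifts y; R^2 unchanged by affine y
  d2 <- d
  d2$belly_kg <- 3 * d$belly_kg + 10
  f2 <- fit_group_ols(d2, "III", "belly")
  expect_equal(f2$r2, f$r2, tolerance = 1e-10)
  expect_equal(f2$mae, 3 * f$mae, tolerance = 1e-10)
})

test_that("fitted coefficients recover the generator truth within 3 SE", {
  pigs <- calibrated_pigs()
  cfg <- default_herd_config()
  for (cut in c("ham", "belly")) {
    col <- paste0(cut, "_kg")
    fit <- lm(pigs[[col]] ~ pigs$carcass_weight_kg + pigs$backfat_mm)
    est <- coef(summary(fit))
    truth <- unname(cfg$true_cut_coeffs[cut, ])
    for (j in 1:3) {
      expect_lt(abs(est[j, "Estimate"] - truth[j]),
                3 * est[j, "Std. Error"])
    }
  }
})

test_that("ANOVA reduces to t^2 for two groups and flags no fake effects", {
  set.seed(41)
  a <- rnorm(20, 10, 2)
  b <- rnorm(25, 12, 2)
  out <- compare_groups(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(out$anova$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$anova$p, tt$p.value, tolerance = 1e-10)

  same <- rep(5, 10)
  out2 <- compare_groups(list(a = same, b = same, c = same, d = same))
  expect_true(all(out2$pairwise$p_adj == 1))
  expect_identical(unname(out2$letters), rep("a", 4))
})

test_that("F, p and Bonferroni-adjusted p match hand-computed pooled formulas", {
  set.seed(47)
  vals <- list(I = rnorm(20, 10, 1.5), II = rnorm(20, 10.5, 1.5),
               III = rnorm(20, 11.5, 1.5), IV = rnorm(20, 13, 1.5))
  out <- compare_groups(vals)
  # oracle: classical one-way fixed-effects ANOVA computed from sums of
  # squares, and pooled two-sample t statistics from first principles
  k <- length(vals)
  n <- sum(lengths(vals))
  grand <- mean(unlist(vals))
  ssb <- sum(vapply(vals, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  p_oracle <- pf(f_oracle, k - 1, n - k, lower.tail = FALSE)
  expect_equal(out$anova$f, f_oracle, tolerance = 1e-8)
  expect_equal(out$anova$p, p_oracle, tolerance = 1e-8)

  for (r in seq_len(nrow(out$pairwise))) {
    x <- vals[[out$pairwise$group1[r]]]
    y <- vals[[out$pairwise$group2[r]]]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    t_oracle <- (mean(x) - mean(y)) /
      sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    p_raw <- 2 * pt(abs(t_oracle), length(x) + length(y) - 2,
                    lower.tail = FALSE)
    expect_equal(out$pairwise$t[r], t_oracle, tolerance = 1e-8)
    expect_equal(out$pairwise$p_adj[r], min(6 * p_raw, 1), tolerance = 1e-8)
  }
  # the clearly separated extremes must not share a letter
  expect_false(any(strsplit(out$letters[["I"]], "")[[1]] %in%
                     strsplit(out$letters[["IV"]], "")[[1]]))
})
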