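# Per-group regression of primal-cut weights on carcass weight and backfat:
# cut_kg = beta0 + beta1 * carcass_weight_kg + beta2 * backfat_mm,
# fitted by QR least squares (stats::lm). R^2 and MAE are in-sample.

#' Bundled reference regression coefficients
#'
#' The 20 published (group x cut) regression rows — intercept, carcass
#' weight and backfat coefficients plus in-sample MAE (kg) and R² — shipped
#' as plain CSV package data. These are the reference planes used for
#' prediction when no refit is wanted, and the group IV rows seed the
#' synthetic generator's true cut-weight plane.
#'
#' @return data.frame with columns `group`, `cut`, `beta0`, `beta1`,
#'   `beta2`, `mae`, `r2` (4 groups x 5 cuts).
#' @export
reference_cut_coefficients <- function() {
  path <- system.file("extdata", "reference_cut_coefficients.csv",
                      package = "farmgrade", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(group = "character",
                                       cut = "character"))
}

new_cut_regression <- function(group, cut, beta0, beta1, beta2, r2, mae, n) {
  structure(list(group = group, cut = cut,
                 beta0 = unname(beta0), beta1 = unname(beta1),
                 beta2 = unname(beta2),
                 r2 = r2, mae = mae, n = n),
            class = "cut_regression")
}

#' @export
print.cut_regression <- function(x, ...) {
  cat(sprintf(
    "Group %s %s: y = %.4f + %.4f cw + %.4f bf  (R² %.3f, MAE %.3f kg, n = %d)\n",
    x$group, x$cut, x$beta0, x$beta1, x$beta2, x$r2, x$mae, x$n))
  invisible(x)
}

#' Fit one per-group primal-cut regression
#'
#' Ordinary least squares of one cut weight on carcass weight and backfat
#' within one pig group, with in-sample R² (1 - SSE/SST about the group
#' mean) and MAE (mean absolute residual).
#'
#' @param pigs pig data.frame with a `group` column (see [assign_pigs()])
#'   and the cut-weight column.
#' @param group group label I..IV.
#' @param cut one of `"shoulder_blade"`, `"shoulder_picnic"`, `"loin"`,
#'   `"belly"`, `"ham"`.
#' @return object of class `cut_regression`.
#' @export
fit_group_ols <- function(pigs, group, cut) {
  cut <- match.arg(cut, PRIMAL_CUTS)
  col <- cut_column(cut)
  if (!col %in% names(pigs)) stop("missing cut-weight column: ", col)
  if (!"group" %in% names(pigs)) stop("pigs must carry a 'group' column")
  d <- pigs[pigs$group == group & !is.na(pigs[[col]]), ]
  if (nrow(d) < 3) {
    stop(sprintf("group %s has %d usable records for %s; need >= 3",
                 group, nrow(d), cut))
  }
  fit <- lm(d[[col]] ~ d$carcass_weight_kg + d$backfat_mm)
  if (anyNA(coef(fit))) {
    stop(sprintf("singular design in group %s for %s (collinear predictors)",
                 group, cut))
  }
  res <- fit$residuals
  y <- d[[col]]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("degenerate response: zero variance in ", col)
  new_cut_regression(group, cut,
                     beta0 = coef(fit)[1], beta1 = coef(fit)[2],
                     beta2 = coef(fit)[3],
                     r2 = 1 - sum(res^2) / sst,
                     mae = mean(abs(res)),
                     n = nrow(d))
}

#' Fit all (group x cut) regressions
#'
#' @param pigs clustered pig data.frame with a `group` column and the five
#'   cut-weight columns.
#' @param groups groups to fit (those present by default).
#' @return data.frame of 5 rows per group: `group`, `cut`, `beta0`,
#'   `beta1`, `beta2`, `mae`, `r2`, `n`.
#' @export
fit_cut_regressions <- function(pigs,
                                groups = intersect(PIG_GROUPS,
                                                   unique(pigs$group))) {
  rows <- list()
  for (g in groups) {
    for (cut in PRIMAL_CUTS) {
      f <- fit_group_ols(pigs, g, cut)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, cut = cut, beta0 = f$beta0, beta1 = f$beta1,
        beta2 = f$beta2, mae = f$mae, r2 = f$r2, n = f$n)
    }
  }
  do.call(rbind, rows)
}

#' Predict a primal-cut weight from a regression plane
#'
#' Evaluates `beta0 + beta1 * carcass_weight + beta2 * backfat`.
#'
#' @param coeffs a `cut_regression`, or any list/one-row data.frame with
#'   `beta0`, `beta1`, `beta2`.
#' @param carcass_weight kg (vectorized).
#' @param backfat mm (vectorized).
#' @return predicted cut weight(s), kg.
#' @examples
#' ref <- reference_cut_coefficients()
#' ham1 <- ref[ref$group == "I" & ref$cut == "ham", ]
#' predict_cut(ham1, 86.43, 21.99)  # 19.0323 kg
#' @export
predict_cut <- function(coeffs, carcass_weight, backfat) {
  coeffs$beta0 + coeffs$beta1 * carcass_weight + coeffs$beta2 * backfat
}

#' Production ratio of a primal cut
#'
#' `100 * cut_weight / carcass_weight`, the percentage of the carcass the
#' cut accounts for.
#'
#' @param cut_weight kg.
#' @param carcass_weight kg, > 0.
#' @return percentage (vectorized).
#' @export
production_ratio <- function(cut_weight, carcass_weight) {
  if (any(carcass_weight <= 0)) stop("carcass_weight must be > 0")
  100 * cut_weight / carcass_weight
}

# Compact letter display: groups not significantly different share a
# letter. Insert/absorb over the significant pairs, letters assigned in
# order of descending group mean (Table-style superscripts).
assign_letters <- function(group_names, means, sig_pairs) {
  ord <- group_names[order(-means)]
  sets <- list(ord)
  for (p in sig_pairs) {
    repeat {
      offending <- which(vapply(sets, function(s) all(p %in% s), logical(1)))
      if (!length(offending)) break
      i <- offending[1]
      s <- sets[[i]]
      sets <- c(sets[-i], list(setdiff(s, p[1])), list(setdiff(s, p[2])))
      # drop sets absorbed by a superset
      keep <- vapply(seq_along(sets), function(j) {
        !any(vapply(seq_along(sets), function(l) {
          l != j && all(sets[[j]] %in% sets[[l]]) &&
            length(sets[[l]]) > length(sets[[j]])
        }, logical(1)))
      }, logical(1))
      sets <- unique(sets[keep])
    }
  }
  # order letter sets by the best mean they contain
  best <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(best)]
  letters_of <- setNames(rep("", length(group_names)), group_names)
  for (j in seq_along(sets)) {
    for (g in sets[[j]]) {
      letters_of[g] <- paste0(letters_of[g], letters[j])
    }
  }
  letters_of
}

#' Compare groups by one-way ANOVA with Bonferroni pairwise tests
#'
#' Fixed-effects one-way ANOVA across the groups, followed by pooled-variance
#' two-sample t-tests for every pair with Bonferroni adjustment (raw p times
#' the number of pairs, capped at 1) and compact significance letters at
#' alpha = 0.05: groups sharing no letter differ significantly.
#'
#' @param values named list of numeric vectors, one per group (>= 2 groups
#'   with >= 2 values each).
#' @param alpha significance level for the letter display.
#' @return list with `anova` (`f`, `p`, `df1`, `df2`), `pairwise`
#'   (data.frame `group1`, `group2`, `t`, `p_raw`, `p_adj`) and `letters`
#'   (named character vector).
#' @export
compare_groups <- function(values, alpha = 0.05) {
  if (length(values) < 2) stop("need at least 2 groups")
  if (is.null(names(values)) || any(names(values) == "")) {
    names(values) <- paste0("g", seq_along(values))
  }
  sizes <- lengths(values)
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  if (all(vapply(values, function(v) sd(v) == 0, logical(1))) &&
      length(unique(vapply(values, function(v) v[1], numeric(1)))) == 1) {
    # all observations identical: F is 0/0; report no differences
    pairs <- t(utils::combn(names(values), 2))
    pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                           t = 0, p_raw = 1, p_adj = 1)
    return(list(anova = list(f = NaN, p = 1, df1 = length(values) - 1,
                             df2 = sum(sizes) - length(values)),
                pairwise = pairwise,
                letters = setNames(rep("a", length(values)), names(values))))
  }
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    group = factor(rep(names(values), sizes), levels = names(values)))
  a <- summary(aov(value ~ group, data = df))[[1]]
  anova_out <- list(f = a[1, "F value"], p = a[1, "Pr(>F)"],
                    df1 = a[1, "Df"], df2 = a[2, "Df"])

  pairs <- utils::combn(names(values), 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    tt <- t.test(values[[g1]], values[[g2]], var.equal = TRUE)
    data.frame(group1 = g1, group2 = g2,
               t = unname(tt$statistic), p_raw = tt$p.value)
  })
  pairwise <- do.call(rbind, pw)
  pairwise$p_adj <- pmin(pairwise$p_raw * m, 1)

  sig <- pairwise[pairwise$p_adj < alpha, c("group1", "group2")]
  sig_pairs <- lapply(seq_len(nrow(sig)),
                      function(i) c(sig$group1[i], sig$group2[i]))
  means <- vapply(values, mean, numeric(1))
  list(anova = anova_out, pairwise = pairwise,
       letters = assign_letters(names(values), means, sig_pairs))
}
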