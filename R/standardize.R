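# Absolute z-score standardization: |x - mu| / sigma, with mu and sigma the
# whole-population mean and SD (divisor n). Both clustering dimensions are
# scaled this way, so distance from the origin of abs z-space measures how
# far a carcass sits from the population mean in SD units, sign discarded.

#' Standardization parameters
#'
#' Bundles population mean and standard deviation for carcass weight and
#' backfat thickness. The SDs use divisor n (population SD): the model
#' standardizes with moments of the data population it was fitted on, and at
#' herd sizes in the tens of thousands the n vs n-1 distinction changes abs
#' z-scores by well under 0.01%.
#'
#' @param mu_cw,sigma_cw mean and SD of carcass weight, kg.
#' @param mu_bf,sigma_bf mean and SD of backfat thickness, mm.
#' @return object of class `standardization_params`.
#' @export
standardization_params <- function(mu_cw, sigma_cw, mu_bf, sigma_bf) {
  if (!is.finite(sigma_cw) || sigma_cw <= 0 ||
      !is.finite(sigma_bf) || sigma_bf <= 0) {
    stop("sigma_cw and sigma_bf must be positive and finite")
  }
  structure(list(mu_cw = mu_cw, sigma_cw = sigma_cw,
                 mu_bf = mu_bf, sigma_bf = sigma_bf),
            class = "standardization_params")
}

#' @export
print.standardization_params <- function(x, ...) {
  cat(sprintf(
    "Standardization: carcass weight %.3f +/- %.3f kg, backfat %.3f +/- %.3f mm\n",
    x$mu_cw, x$sigma_cw, x$mu_bf, x$sigma_bf))
  invisible(x)
}

#' Fit standardization parameters from pig records
#'
#' Computes the whole-population mean and population SD (divisor n) of
#' carcass weight and backfat thickness.
#'
#' @param pigs pig data.frame with `carcass_weight_kg` and `backfat_mm`.
#' @return [standardization_params()] object.
#' @export
fit_standardization <- function(pigs) {
  cw <- pigs$carcass_weight_kg
  bf <- pigs$backfat_mm
  if (length(cw) < 2) stop("need at least 2 records to standardize")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  s_cw <- pop_sd(cw)
  s_bf <- pop_sd(bf)
  if (s_cw == 0) stop("degenerate data: carcass weight has zero variance")
  if (s_bf == 0) stop("degenerate data: backfat has zero variance")
  standardization_params(mean(cw), s_cw, mean(bf), s_bf)
}

#' Absolute z-score
#'
#' `|x - mu| / sigma`: distance from the population mean in SD units with
#' the sign discarded, so carcasses above and below the mean are treated
#' alike — the clustering cares about deviation from the standard pig, not
#' its direction.
#'
#' @param x measurement(s).
#' @param mu population mean, same units.
#' @param sigma population SD, same units; must be > 0.
#' @return non-negative dimensionless value(s).
#' @examples
#' abs_z(90, 86, 2)   # 2
#' abs_z(83, 86, 2)   # 1.5
#' @export
abs_z <- function(x, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  abs(x - mu) / sigma
}

# Pigs -> n x 2 matrix of (|z_cw|, |z_bf|).
abs_z_matrix <- function(pigs, params) {
  cbind(z_cw = abs_z(pigs$carcass_weight_kg, params$mu_cw, params$sigma_cw),
        z_bf = abs_z(pigs$backfat_mm, params$mu_bf, params$sigma_bf))
}
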