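#' Predictive ability (Pearson correlation)
#'
#' The standard genomic-selection accuracy measure: the sample Pearson
#' correlation between predicted and observed phenotypes in the validation
#' set. Undefined cases (fewer than 3 complete pairs, or zero variance on
#' either side) return `NA` with a warning.
#'
#' @param pred,obs Numeric vectors of equal length; `NA` pairs are dropped.
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' predictive_ability(c(1, 2, 3, 4), c(2, 1, 4, 3))
predictive_ability <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]
  obs <- obs[ok]
  if (length(obs) < 3L) {
    warn("fewer than 3 complete pairs; predictive ability is NA")
    return(NA_real_)
  }
  if (sd(pred) == 0 || sd(obs) == 0) {
    warn("zero variance in predictions or observations; predictive ability is NA")
    return(NA_real_)
  }
  cor(pred, obs)
}

#' Mean arctangent absolute percentage error (MAAPE)
#'
#' `mean(atan(|(obs - pred) / obs|))` over pairs, in radians, bounded in
#' `[0, pi/2]`. Pairs with `obs == 0` contribute `pi/2` (the limit of the
#' arctangent as the relative error diverges) unless the prediction is also
#' exactly 0, in which case the error is 0.
#'
#' @param pred,obs Numeric vectors of equal length; `NA` pairs are dropped.
#' @return MAAPE in radians.
#' @export
#' @examples
#' maape(c(1, 5), c(2, 4))
maape <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]
  obs <- obs[ok]
  if (length(obs) == 0L) abort("maape needs at least one complete pair")
  ratio <- abs((obs - pred) / obs)
  ratio[obs == 0 & pred == 0] <- 0
  ratio[obs == 0 & pred != 0] <- Inf
  mean(atan(ratio))
}

#' Root mean square error
#'
#' @param pred,obs Numeric vectors of equal length; `NA` pairs are dropped.
#' @return RMSE in the units of the trait.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  ok <- !is.na(pred) & !is.na(obs)
  if (!any(ok)) abort("rmse needs at least one complete pair")
  sqrt(mean((obs[ok] - pred[ok])^2))
}

#' Genetic correlation from line effects and genotypic variances
#'
#' Computes `Cov_xy / sqrt(var_x * var_y)` where `Cov_xy` is the sample
#' covariance of the paired line-effect vectors and `var_x`, `var_y` are the
#' genotypic variances of the two traits (or environments). With
#' standardized effects and their own variances this reduces to the plain
#' Pearson correlation.
#'
#' @param x_effects,y_effects Paired per-line effect vectors.
#' @param var_x,var_y Genotypic variances (must be positive); default to
#'   the sample variances of the effect vectors.
#' @return Genetic correlation estimate.
#' @export
genetic_correlation <- function(x_effects, y_effects,
                                var_x = var(x_effects),
                                var_y = var(y_effects)) {
  stopifnot(length(x_effects) == length(y_effects))
  if (!is.finite(var_x) || !is.finite(var_y) || var_x <= 0 || var_y <= 0) {
    abort("genotypic variances must be positive")
  }
  stats::cov(x_effects, y_effects) / sqrt(var_x * var_y)
}
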