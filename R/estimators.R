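# per-variant ratio estimates shared by every estimator
ratio_estimates <- function(variants, se_method = c("first_order", "second_order")) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(variants, "harmonized_variants"))
  if (any(variants$beta_exp == 0)) {
    stop("Wald ratio undefined: beta_exp = 0 for ",
         paste(variants$snp[variants$beta_exp == 0], collapse = ", "),
         call. = FALSE)
  }
  theta <- variants$beta_out / variants$beta_exp
  se <- if (se_method == "first_order") {
    variants$se_out / abs(variants$beta_exp)
  } else {
    sqrt(variants$se_out^2 / variants$beta_exp^2 +
           variants$beta_out^2 * variants$se_exp^2 / variants$beta_exp^4)
  }
  tibble::tibble(snp = variants$snp, theta = theta, se_theta = se,
                 weight = 1 / se^2)
}

#' Per-variant Wald ratio estimates
#'
#' The variant-specific causal estimate `theta = beta_out / beta_exp`. The
#' first-order (delta-method) standard error `se_out / |beta_exp|` ignores
#' uncertainty in the exposure beta; the second-order form adds it.
#'
#' @param variants A `harmonized_variants` tibble with nonzero exposure
#'   betas.
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @return A tibble (`snp`, `theta`, `se_theta`, `weight`) with
#'   `weight = 1/se_theta^2`.
#' @export
wald_ratio <- function(variants, se_method = c("first_order", "second_order")) {
  ratio_estimates(variants, se_method)
}

# assemble one estimate row on the log-odds scale with OR + 95% CI
mr_estimate_row <- function(method, nsnp, beta, se, pval) {
  ci <- to_odds_ratio(beta, se)
  tibble::tibble(method = method, nsnp = nsnp, beta = beta, se = se,
                 pval = pval, or = ci[["or"]],
                 or_lci95 = ci[["or_lci95"]], or_uci95 = ci[["or_uci95"]])
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines the variant-specific Wald ratios with inverse-variance weights
#' `w_j = se(theta_j)^-2`: `beta = sum(w theta) / sum(w)` (equivalently a
#' weighted zero-intercept regression of outcome on exposure betas when
#' `se_method = "first_order"`). The fixed-effect standard error is
#' `sum(w)^-0.5`; under the multiplicative random-effects model (default) it
#' is inflated by `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's Q about
#' the fixed-effect estimate, so heterogeneity widens but never narrows the
#' interval. The p-value is two-sided standard normal.
#'
#' @param variants A `harmonized_variants` tibble with at least 2 rows.
#' @param model `"multiplicative_random_effects"` (default) or `"fixed"`.
#' @param se_method Passed to [wald_ratio()].
#' @return A one-row estimate tibble (`method`, `nsnp`, `beta`, `se`,
#'   `pval`, `or`, `or_lci95`, `or_uci95`) with attributes `q` (Cochran's Q
#'   about the fixed-effect estimate) and `se_fixed`.
#' @export
mr_ivw <- function(variants,
                   model = c("multiplicative_random_effects", "fixed"),
                   se_method = c("first_order", "second_order")) {
  model <- match.arg(model)
  r <- ratio_estimates(variants, se_method)
  if (nrow(r) < 2) stop("IVW needs at least 2 variants", call. = FALSE)
  if (!all(is.finite(r$weight)) || sum(r$weight) <= 0) {
    stop("IVW weights must be finite and positive", call. = FALSE)
  }
  w <- r$weight
  beta <- sum(w * r$theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (r$theta - beta)^2)
  se <- if (model == "fixed") se_fixed else {
    se_fixed * max(1, sqrt(q / (nrow(r) - 1)))
  }
  pval <- 2 * pnorm(-abs(beta / se))
  out <- mr_estimate_row("IVW", nrow(r), beta, se, pval)
  attr(out, "q") <- q
  attr(out, "se_fixed") <- se_fixed
  attr(out, "model") <- model
  out
}

# Interpolated weighted median of theta with normalized weights.
# Standardized cumulative weights s_j = cumsum(p)_j - p_j/2 define a
# piecewise-linear quantile curve; the estimate is its value at s = 0.5,
# clamped to the extreme ratios when 0.5 falls outside [s_1, s_J].
weighted_median_point <- function(theta, w, warn_clamp = FALSE) {
  stopifnot(length(theta) == length(w), all(w > 0))
  o <- order(theta)
  th <- theta[o]
  p <- w[o] / sum(w)
  s <- cumsum(p) - p / 2
  j <- length(th)
  if (s[1] >= 0.5) {
    if (warn_clamp) warning("weighted median clamped to the smallest ratio",
                            call. = FALSE)
    return(th[1])
  }
  if (s[j] <= 0.5) {
    if (warn_clamp) warning("weighted median clamped to the largest ratio",
                            call. = FALSE)
    return(th[j])
  }
  k <- max(which(s < 0.5))
  th[k] + (th[k + 1] - th[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median causal estimate with parametric bootstrap standard error
#'
#' Point estimate: the Wald ratios are sorted and the weighted 50th
#' percentile taken by linear interpolation of the standardized cumulative
#' weights (see [weighted_median_point()] construction); it is consistent
#' even when up to 50% of the weight comes from invalid instruments.
#' Standard error: parametric bootstrap — each iteration redraws every
#' exposure and outcome beta from normal distributions centred at the
#' observed values with their standard errors, recomputes ratios, weights
#' and the weighted median; the SE is the standard deviation across
#' iterations. The p-value is two-sided standard normal.
#'
#' @param variants A `harmonized_variants` tibble with at least 3 rows.
#' @param n_boot Bootstrap iterations, at least 100 (default 1000).
#' @param seed RNG seed for the bootstrap, recorded in the output metadata
#'   (default 20221011). The global RNG state is left untouched.
#' @param se_method Passed to [wald_ratio()].
#' @return A one-row estimate tibble with attributes `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(variants, n_boot = 1000, seed = 20221011L,
                               se_method = c("first_order", "second_order")) {
  se_method <- match.arg(se_method)
  r <- ratio_estimates(variants, se_method)
  if (nrow(r) < 3) stop("weighted median needs at least 3 variants", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)

  beta <- weighted_median_point(r$theta, r$weight, warn_clamp = TRUE)

  j <- nrow(variants)
  boots <- withr::with_seed(seed, {
    bx <- matrix(rnorm(n_boot * j, mean = rep(variants$beta_exp, each = n_boot),
                       sd = rep(variants$se_exp, each = n_boot)), n_boot, j)
    by <- matrix(rnorm(n_boot * j, mean = rep(variants$beta_out, each = n_boot),
                       sd = rep(variants$se_out, each = n_boot)), n_boot, j)
    vapply(seq_len(n_boot), function(b) {
      th <- by[b, ] / bx[b, ]
      se <- if (se_method == "first_order") {
        variants$se_out / abs(bx[b, ])
      } else {
        sqrt(variants$se_out^2 / bx[b, ]^2 +
               by[b, ]^2 * variants$se_exp^2 / bx[b, ]^4)
      }
      weighted_median_point(th, 1 / se^2)
    }, numeric(1))
  })
  se <- sd(boots)
  pval <- 2 * pnorm(-abs(beta / se))
  out <- mr_estimate_row("WeightedMedian", j, beta, se, pval)
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with a
#' free intercept, weights `se_out^-2`, after orienting all exposure betas
#' non-negative ([orient_to_positive_exposure()]). The slope is the
#' pleiotropy-adjusted causal estimate; a nonzero intercept indicates
#' directional horizontal pleiotropy. Coefficient standard errors use the
#' fixed-weight covariance inflated by `max(1, sigma)` where
#' `sigma = sqrt(RSS_w / (J - 2))` is the weighted residual scale; p-values
#' come from the t-distribution with `J - 2` degrees of freedom.
#'
#' @param variants A `harmonized_variants` tibble with at least 3 rows.
#' @param se_method Standard-error method label recorded on the slope row
#'   (the regression itself weights by `se_out^-2`).
#' @return An `egger_fit` list: `slope` (one-row estimate tibble, method
#'   `Egger_slope`), `intercept`, `intercept_se`, `intercept_pval`, `df`
#'   (`J - 2`) and `sigma`.
#' @export
mr_egger <- function(variants, se_method = c("first_order", "second_order")) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(variants, "harmonized_variants"))
  if (nrow(variants) < 3) stop("MR-Egger needs at least 3 variants", call. = FALSE)
  v <- orient_to_positive_exposure(variants)
  if (stats::var(v$beta_exp) == 0) {
    stop("MR-Egger undefined: no variance in the oriented exposure betas",
         call. = FALSE)
  }
  w <- 1 / v$se_out^2
  fit <- lm(beta_out ~ beta_exp, data = v, weights = w)
  cf <- coef(fit)
  res <- v$beta_out - cf[[1]] - cf[[2]] * v$beta_exp
  j <- nrow(v)
  df <- j - 2L
  rss_w <- sum(w * res^2)
  sigma <- sqrt(rss_w / df)
  # fixed-weight (sigma = 1) covariance, then the max(1, sigma) inflation
  xmat <- cbind(1, v$beta_exp)
  vcov_unit <- solve(crossprod(xmat * sqrt(w)))
  se_unit <- sqrt(diag(vcov_unit))
  infl <- max(1, sigma)
  se_int <- se_unit[1] * infl
  se_slope <- se_unit[2] * infl
  p_int <- 2 * pt(-abs(cf[[1]] / se_int), df)
  p_slope <- 2 * pt(-abs(cf[[2]] / se_slope), df)

  structure(
    list(
      slope = mr_estimate_row("Egger_slope", j, cf[[2]], se_slope, p_slope),
      intercept = cf[[1]],
      intercept_se = se_int,
      intercept_pval = p_int,
      df = df,
      sigma = sigma,
      rss_w = rss_w
    ),
    class = "egger_fit"
  )
}

#' @export
print.egger_fit <- function(x, ...) {
  cat("MR-Egger regression (", x$slope$nsnp, " variants)\n", sep = "")
  cat(sprintf("  slope     % .4f (se %.4f, p = %.4g)\n",
              x$slope$beta, x$slope$se, x$slope$pval))
  cat(sprintf("  intercept % .4f (se %.4f, p = %.4g, t with %d df)\n",
              x$intercept, x$intercept_se, x$intercept_pval, x$df))
  invisible(x)
}

#' Odds ratio and 95% confidence interval from a log-odds estimate
#'
#' `exp(beta)` with the interval `exp(beta -/+ 1.96 * se)`.
#'
#' @param beta Log odds ratio.
#' @param se Its standard error, `> 0`.
#' @return Named numeric vector `or`, `or_lci95`, `or_uci95`.
#' @export
#' @examples
#' round(to_odds_ratio(-0.644, 0.213), 3)
to_odds_ratio <- function(beta, se) {
  stopifnot(se > 0)
  c(or = exp(beta), or_lci95 = exp(beta - 1.96 * se),
    or_uci95 = exp(beta + 1.96 * se))
}
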