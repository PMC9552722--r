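#' Cochran's Q heterogeneity statistic
#'
#' Measures dispersion of the per-variant causal estimates beyond what their
#' standard errors predict. About the fixed-effect IVW estimate:
#' `Q = sum(w_j (theta_j - theta_fixed)^2)` with `J - 1` degrees of freedom.
#' About the MR-Egger fit: the weighted residual sum of squares with `J - 2`
#' degrees of freedom. The p-value is the upper tail of the chi-square
#' distribution; `Q_p > 0.05` is conventionally read as no significant
#' heterogeneity.
#'
#' @param variants A `harmonized_variants` tibble (`>= 2` rows for
#'   `"ivw_fixed"`, `>= 3` for `"egger"`).
#' @param about `"ivw_fixed"` or `"egger"`.
#' @param se_method Passed to the underlying estimator.
#' @return A one-row tibble (`method`, `q`, `q_df`, `q_pval`).
#' @export
cochran_q <- function(variants, about = c("ivw_fixed", "egger"),
                      se_method = c("first_order", "second_order")) {
  about <- match.arg(about)
  se_method <- match.arg(se_method)
  if (about == "ivw_fixed") {
    est <- mr_ivw(variants, model = "fixed", se_method = se_method)
    q <- attr(est, "q")
    df <- est$nsnp - 1L
    method <- "IVW"
  } else {
    fit <- mr_egger(variants, se_method = se_method)
    q <- fit$rss_w
    df <- fit$df
    method <- "MR_Egger"
  }
  tibble::tibble(method = method, q = q, q_df = as.integer(df),
                 q_pval = pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' If the instruments are not pleiotropic the Egger intercept should tend to
#' zero; the verdict is "no significant pleiotropy" iff the intercept
#' p-value exceeds `alpha`.
#'
#' @param fit An `egger_fit` from [mr_egger()].
#' @param alpha Significance level for the verdict (default 0.05, the
#'   conventional table-footnote rule).
#' @return A list: `intercept`, `se`, `pval`, `significant`, `verdict`.
#' @export
egger_intercept_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "egger_fit"))
  sig <- fit$intercept_pval <= alpha
  list(
    intercept = fit$intercept,
    se = fit$intercept_se,
    pval = fit$intercept_pval,
    significant = sig,
    verdict = if (sig) "significant pleiotropy" else "no significant pleiotropy"
  )
}

# Leave-one-out IVW slopes for every variant of every row of the matrices
# bx, by (n_rep x J), with fixed outcome-se weights w. Returns the per-SNP
# weighted squared residuals about each leave-one-out slope (n_rep x J).
presso_residuals <- function(bx, by, w) {
  wj <- matrix(w, nrow(bx), length(w), byrow = TRUE)
  m1 <- wj * bx * by
  m2 <- wj * bx^2
  s1 <- rowSums(m1)
  s2 <- rowSums(m2)
  theta_loo <- (s1 - m1) / (s2 - m2)
  wj * (by - theta_loo * bx)^2
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' statistic is `RSS = sum_j w_j (beta_out_j - theta_(-j) beta_exp_j)^2`
#' where `theta_(-j)` is the IVW slope excluding variant j and
#' `w_j = se_out_j^-2`. Its null distribution is simulated: each replicate
#' redraws `beta_exp*_j ~ N(beta_exp_j, se_exp_j)` and
#' `beta_out*_j ~ N(theta_(-j) beta_exp_j, se_out_j)` and recomputes RSS the
#' same leave-one-out way; the global p is `(1 + #[RSS* >= RSS]) /
#' (n_sim + 1)`. If the global test is significant at `outlier_alpha`, each
#' variant's observed squared residual is compared with its own simulated
#' residual distribution (empirical proportion, Bonferroni-adjusted over J)
#' to flag outliers; if any are flagged, the distortion test compares the
#' change in the IVW estimate after their removal against a resampled null
#' of that difference, and the outlier-corrected IVW estimate is reported.
#'
#' @param variants A `harmonized_variants` tibble with at least 4 rows
#'   (leave-one-out fitting needs 3 remaining).
#' @param n_sim Simulated replicates, at least 100 (default 1000).
#' @param seed RNG seed (default 20221011); global RNG state untouched.
#' @param outlier_alpha Significance level for the global gate and the
#'   Bonferroni-adjusted outlier calls (default 0.05).
#' @return A `presso_result` list: `rss_obs`, `global_pval`, `n_sim`,
#'   `outlier_pvals` (Bonferroni-adjusted, `NULL` when the global test is
#'   not significant), `outliers`, `distortion_pval` and
#'   `corrected_estimate` (both `NULL` unless outliers were flagged).
#' @export
mr_presso <- function(variants, n_sim = 1000, seed = 20221011L,
                      outlier_alpha = 0.05) {
  stopifnot(inherits(variants, "harmonized_variants"))
  j <- nrow(variants)
  if (j < 4) stop("MR-PRESSO needs at least 4 variants", call. = FALSE)
  if (n_sim < 100) stop("n_sim must be at least 100", call. = FALSE)

  bx <- variants$beta_exp; by <- variants$beta_out
  sx <- variants$se_exp; sy <- variants$se_out
  w <- 1 / sy^2

  obs_res <- presso_residuals(matrix(bx, 1), matrix(by, 1), w)[1, ]
  rss_obs <- sum(obs_res)
  s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
  theta_loo_obs <- (s1 - w * bx * by) / (s2 - w * bx^2)

  res <- withr::with_seed(seed, {
    bx_sim <- matrix(rnorm(n_sim * j, mean = rep(bx, each = n_sim),
                           sd = rep(sx, each = n_sim)), n_sim, j)
    by_sim <- matrix(rnorm(n_sim * j, mean = rep(theta_loo_obs * bx, each = n_sim),
                           sd = rep(sy, each = n_sim)), n_sim, j)
    sim_res <- presso_residuals(bx_sim, by_sim, w)
    rss_sim <- rowSums(sim_res)
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

    outlier_pvals <- NULL
    outliers <- character(0)
    distortion_pval <- NULL
    corrected <- NULL

    if (global_pval < outlier_alpha) {
      p_raw <- colMeans(sweep(sim_res, 2, obs_res, ">="))
      outlier_pvals <- setNames(pmin(1, p_raw * j), variants$snp)
      outliers <- variants$snp[outlier_pvals < outlier_alpha]

      if (length(outliers) > 0 && (j - length(outliers)) >= 2) {
        keep <- !(variants$snp %in% outliers)
        corrected <- mr_ivw(variants[keep, ])
        ivw_slope <- function(bxm, bym, sel) {
          rowSums(sweep(bxm[, sel, drop = FALSE] * bym[, sel, drop = FALSE],
                        2, w[sel], "*")) /
            rowSums(sweep(bxm[, sel, drop = FALSE]^2, 2, w[sel], "*"))
        }
        theta_sub <- sum(w[keep] * bx[keep] * by[keep]) /
          sum(w[keep] * bx[keep]^2)
        d_obs <- s1 / s2 - theta_sub
        bx0 <- matrix(rnorm(n_sim * j, mean = rep(bx, each = n_sim),
                            sd = rep(sx, each = n_sim)), n_sim, j)
        by0 <- matrix(rnorm(n_sim * j, mean = rep(theta_sub * bx, each = n_sim),
                            sd = rep(sy, each = n_sim)), n_sim, j)
        d_sim <- ivw_slope(bx0, by0, rep(TRUE, j)) - ivw_slope(bx0, by0, keep)
        distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
      }
    }
    list(global_pval = global_pval, outlier_pvals = outlier_pvals,
         outliers = outliers, distortion_pval = distortion_pval,
         corrected = corrected)
  })

  structure(
    list(
      rss_obs = rss_obs,
      global_pval = res$global_pval,
      n_sim = n_sim,
      seed = seed,
      outlier_pvals = res$outlier_pvals,
      outliers = res$outliers,
      distortion_pval = res$distortion_pval,
      corrected_estimate = res$corrected
    ),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat("MR-PRESSO global test: RSS =", format(x$rss_obs, digits = 4),
      ", p =", format(x$global_pval, digits = 3),
      paste0("(", x$n_sim, " simulations)"), "\n")
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$distortion_pval))
      cat("  distortion p =", format(x$distortion_pval, digits = 3), "\n")
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect with each instrument removed in turn;
#' sign changes or large shifts reveal estimates driven by a single variant.
#'
#' @param variants A `harmonized_variants` tibble with at least 3 rows.
#' @param model,se_method Passed to [mr_ivw()].
#' @return A tibble with one row per left-out SNP: `label` (the SNP
#'   omitted), `beta`, `se`, `lci`, `uci`, `pval`.
#' @export
leave_one_out <- function(variants,
                          model = c("multiplicative_random_effects", "fixed"),
                          se_method = c("first_order", "second_order")) {
  stopifnot(inherits(variants, "harmonized_variants"))
  if (nrow(variants) < 3) {
    stop("leave-one-out needs at least 3 variants", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    est <- mr_ivw(variants[-i, , drop = FALSE], model = model,
                  se_method = se_method)
    tibble::tibble(label = variants$snp[i], beta = est$beta, se = est$se,
                   lci = est$beta - 1.96 * est$se,
                   uci = est$beta + 1.96 * est$se, pval = est$pval)
  })
  do.call(rbind, rows)
}

#' Per-variant effect table for forest plots
#'
#' One Wald-ratio row per SNP with a 95% confidence interval, followed by
#' summary rows for the IVW (when `>= 2` variants) and weighted-median
#' (when `>= 3` variants) estimates. Plot-ready: any plotting layer can
#' render it as a forest plot.
#'
#' @param variants A nonempty `harmonized_variants` tibble.
#' @param se_method Passed to [wald_ratio()].
#' @param n_boot,seed Weighted-median bootstrap settings, see
#'   [mr_weighted_median()].
#' @return A tibble (`label`, `beta`, `se`, `lci`, `uci`).
#' @export
single_snp_table <- function(variants,
                             se_method = c("first_order", "second_order"),
                             n_boot = 1000, seed = 20221011L) {
  stopifnot(inherits(variants, "harmonized_variants"), nrow(variants) >= 1)
  se_method <- match.arg(se_method)
  r <- wald_ratio(variants, se_method)
  out <- tibble::tibble(label = r$snp, beta = r$theta, se = r$se_theta,
                        lci = r$theta - 1.96 * r$se_theta,
                        uci = r$theta + 1.96 * r$se_theta)
  out <- out[order(out$label), , drop = FALSE]
  if (nrow(variants) >= 2) {
    ivw <- mr_ivw(variants, se_method = se_method)
    out <- rbind(out, tibble::tibble(
      label = "All - IVW", beta = ivw$beta, se = ivw$se,
      lci = ivw$beta - 1.96 * ivw$se, uci = ivw$beta + 1.96 * ivw$se))
  }
  if (nrow(variants) >= 3) {
    wm <- mr_weighted_median(variants, n_boot = n_boot, seed = seed,
                             se_method = se_method)
    out <- rbind(out, tibble::tibble(
      label = "All - Weighted median", beta = wm$beta, se = wm$se,
      lci = wm$beta - 1.96 * wm$se, uci = wm$beta + 1.96 * wm$se))
  }
  out
}
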