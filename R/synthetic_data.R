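#' Configuration for the synthetic summary-statistics generator
#'
#' Encodes the standard two-sample MR structural model: each instrument j
#' has a true exposure effect `gamma_j`, the true outcome effect is
#' `theta * gamma_j + alpha_j`, and `alpha_j` is a direct (pleiotropic)
#' effect on the outcome drawn independently of `gamma_j` (so the InSIDE
#' assumption holds by construction).
#'
#' @param n_snps Number of instruments (`>= 2`).
#' @param theta True causal effect on the log-odds scale.
#' @param gamma_mean,gamma_sd Normal distribution of true exposure effects;
#'   ignored when `gamma_fixed` is given.
#' @param gamma_fixed Optional fixed vector of true exposure effects (length
#'   `n_snps`).
#' @param eaf_bounds Uniform bounds for effect-allele frequencies, inside
#'   `(0.05, 0.95)`; equal bounds give a degenerate (fixed) frequency.
#' @param n_exp,n_out GWAS sample sizes (`>= 100`). Analytic standard
#'   errors assume a unit-variance phenotype:
#'   `se = (2 eaf (1 - eaf) n)^-0.5`.
#' @param pleiotropy `"none"` (all `alpha_j = 0`), `"balanced"`
#'   (`alpha_j ~ N(0, alpha_sd)`), or `"directional"`
#'   (`alpha_j ~ N(alpha_mean, alpha_sd)` with `alpha_mean != 0`).
#' @param alpha_mean,alpha_sd Pleiotropy distribution parameters
#'   (`alpha_sd >= 0`).
#' @param outlier_index,outlier_shift Optional planted outlier: the outcome
#'   beta of the designated SNP is shifted by `outlier_shift` multiples of
#'   its standard error.
#' @param palindromic_frac Fraction of SNPs assigned strand-ambiguous
#'   (A/T or C/G) allele pairs, to exercise harmonization (default 0.2).
#' @param seed RNG seed making the dataset fully deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 20, theta = 0, gamma_mean = 0.12,
                       gamma_sd = 0.03, gamma_fixed = NULL,
                       eaf_bounds = c(0.1, 0.9), n_exp = 5e5, n_out = 5e5,
                       pleiotropy = c("none", "balanced", "directional"),
                       alpha_mean = 0, alpha_sd = 0,
                       outlier_index = NULL, outlier_shift = 0,
                       palindromic_frac = 0.2, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_snps >= 2, n_exp >= 100, n_out >= 100, alpha_sd >= 0,
            length(eaf_bounds) == 2, eaf_bounds[1] <= eaf_bounds[2],
            eaf_bounds[1] >= 0.05, eaf_bounds[2] <= 0.95,
            palindromic_frac >= 0, palindromic_frac <= 1)
  if (!is.null(gamma_fixed) && length(gamma_fixed) != n_snps) {
    stop("gamma_fixed must have length n_snps", call. = FALSE)
  }
  if (pleiotropy == "balanced" && alpha_mean != 0) {
    stop("balanced pleiotropy requires alpha_mean = 0", call. = FALSE)
  }
  if (!is.null(outlier_index) &&
      (outlier_index < 1 || outlier_index > n_snps)) {
    stop("outlier_index out of range", call. = FALSE)
  }
  structure(
    list(n_snps = as.integer(n_snps), theta = theta,
         gamma_mean = gamma_mean, gamma_sd = gamma_sd,
         gamma_fixed = gamma_fixed, eaf_bounds = eaf_bounds,
         n_exp = as.integer(n_exp), n_out = as.integer(n_out),
         pleiotropy = pleiotropy, alpha_mean = alpha_mean,
         alpha_sd = alpha_sd, outlier_index = outlier_index,
         outlier_shift = outlier_shift,
         palindromic_frac = palindromic_frac, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Draws, per SNP: an effect-allele frequency, a true exposure effect
#' `gamma_j`, a pleiotropic effect `alpha_j` per the configured mode, and
#' allele pairs (a configurable fraction palindromic). Analytic standard
#' errors are `(2 eaf (1 - eaf) n)^-0.5` for each sample; observed betas
#' are drawn normal around the truth (`gamma_j` for the exposure,
#' `theta gamma_j + alpha_j` for the outcome) with those standard errors,
#' the optional outlier shift is added to the designated outcome beta, and
#' p-values are two-sided normal (floored at 1e-300 to stay in `(0, 1]`).
#' Fully deterministic given the config seed; the global RNG state is left
#' untouched.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_dataset` list: `exposure` and `outcome` (both
#'   `summary_stats`), and `truth` (`theta`, per-SNP `gamma` and `alpha`).
#' @export
simulate_mr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  j <- config$n_snps
  withr::with_seed(config$seed, {
    eaf <- if (config$eaf_bounds[1] == config$eaf_bounds[2]) {
      rep(config$eaf_bounds[1], j)
    } else {
      runif(j, config$eaf_bounds[1], config$eaf_bounds[2])
    }
    gamma <- if (!is.null(config$gamma_fixed)) config$gamma_fixed else {
      rnorm(j, config$gamma_mean, config$gamma_sd)
    }
    alpha <- switch(config$pleiotropy,
      none = rep(0, j),
      balanced = rnorm(j, 0, config$alpha_sd),
      directional = rnorm(j, config$alpha_mean, config$alpha_sd)
    )
    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exp)
    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_out)
    beta_exp <- rnorm(j, gamma, se_exp)
    beta_out_true <- config$theta * gamma + alpha
    beta_out <- rnorm(j, beta_out_true, se_out)
    if (!is.null(config$outlier_index)) {
      k <- config$outlier_index
      beta_out[k] <- beta_out[k] + config$outlier_shift * se_out[k]
    }

    pal <- runif(j) < config$palindromic_frac
    pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    ord_pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
    pick <- function(is_pal) {
      if (is_pal) pal_pairs[sample.int(4, 1), ] else ord_pairs[sample.int(8, 1), ]
    }
    pairs <- t(vapply(pal, pick, character(2)))

    pv <- function(b, s) pmax(2 * pnorm(-abs(b / s)), 1e-300)
    ids <- sprintf("rs%07d", seq_len(j))
    exposure <- new_summary_stats(
      tibble::tibble(snp = ids, ea = pairs[, 1], nea = pairs[, 2], eaf = eaf,
                     beta = beta_exp, se = se_exp, pval = pv(beta_exp, se_exp),
                     n = config$n_exp),
      trait = "simulated exposure"
    )
    outcome <- new_summary_stats(
      tibble::tibble(snp = ids, ea = pairs[, 1], nea = pairs[, 2], eaf = eaf,
                     beta = beta_out, se = se_out, pval = pv(beta_out, se_out),
                     n = config$n_out),
      trait = "simulated outcome"
    )
    structure(
      list(exposure = exposure, outcome = outcome,
           truth = list(theta = config$theta, gamma = gamma, alpha = alpha),
           config = config),
      class = "sim_dataset"
    )
  })
}

#' Harmonized view of a simulated dataset
#'
#' Simulated exposure and outcome records share alleles and orientation by
#' construction, so they can be paired directly without the allele
#' reconciliation (and palindromic attrition) of [harmonize()]. Useful for
#' calibration studies that need the instrument count held fixed.
#'
#' @param sim A `sim_dataset` from [simulate_mr()].
#' @return A `harmonized_variants` tibble in simulation order.
#' @export
sim_harmonized <- function(sim) {
  stopifnot(inherits(sim, "sim_dataset"))
  harmonized_variants(tibble::tibble(
    snp = sim$exposure$snp, ea = sim$exposure$ea, nea = sim$exposure$nea,
    beta_exp = sim$exposure$beta, se_exp = sim$exposure$se,
    beta_out = sim$outcome$beta, se_out = sim$outcome$se,
    eaf_exp = sim$exposure$eaf, eaf_out = sim$outcome$eaf
  ))
}

#' Named scenario battery covering every diagnostic
#'
#' Standard study conditions for calibration testing, chosen once: 20
#' instruments with exposure effects `N(0.12, 0.03)`, frequencies uniform
#' on (0.1, 0.9) and both sample sizes 5e5 (strong instruments, median
#' F in the thousands), causal effect -0.3 for the causal scenarios,
#' balanced pleiotropy SD 0.01, directional pleiotropy mean 0.02, and a
#' single outlier shifted by 10 outcome standard errors. `paper_like`
#' mirrors the pyroglutamine/COVID-19 fixture dimensions: 4 SNPs, causal
#' effect -0.6, exposure-effect magnitudes 0.022-0.059, exposure n 7,354
#' and outcome n 1,299,010.
#'
#' @return A named list of [sim_config()] objects: `null`,
#'   `causal_no_pleiotropy`, `balanced_pleiotropy`,
#'   `directional_pleiotropy`, `single_outlier`, `paper_like`.
#' @export
scenario_battery <- function() {
  list(
    null = sim_config(theta = 0, seed = 101L),
    causal_no_pleiotropy = sim_config(theta = -0.3, seed = 102L),
    balanced_pleiotropy = sim_config(theta = -0.3, pleiotropy = "balanced",
                                     alpha_sd = 0.01, seed = 103L),
    directional_pleiotropy = sim_config(theta = -0.3,
                                        pleiotropy = "directional",
                                        alpha_mean = 0.02, alpha_sd = 0.01,
                                        seed = 104L),
    single_outlier = sim_config(theta = -0.3, outlier_index = 7L,
                                outlier_shift = 10, seed = 105L),
    paper_like = sim_config(n_snps = 4, theta = -0.6,
                            gamma_fixed = c(0.037, 0.022, 0.059, 0.036),
                            n_exp = 7354, n_out = 1299010,
                            palindromic_frac = 0, seed = 106L)
  )
}

#' Write a simulated dataset as standard summary-statistics files
#'
#' Emits `exposure.tsv` and `outcome.tsv` in the canonical format (readable
#' by [read_summary_stats()]) plus `truth.tsv` with the generative per-SNP
#' effects, so the pipeline runs unchanged on synthetic data.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_stats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  truth <- data.frame(SNP = sim$exposure$snp,
                      GAMMA = sim$truth$gamma, ALPHA = sim$truth$alpha,
                      THETA = sim$truth$theta)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
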