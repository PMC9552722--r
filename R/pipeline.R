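#' End-to-end pipeline configuration
#'
#' A single declarative object holding every setting of the analysis chain.
#' Defaults reproduce the packaged pyroglutamine/COVID-19 analysis.
#'
#' @param exposure,outcome Fixture name (see [load_fixture()]) or path to a
#'   summary-statistics file.
#' @param ld Path to an LD table or a data frame (`snp_a`, `snp_b`, `r2`);
#'   defaults to the packaged pairwise table for the pyroglutamine
#'   instruments.
#' @param pval_threshold,ld_r2_max,exclusion_ids Instrument-selection
#'   criteria, see [instrument_criteria()].
#' @param r2_method Variance-explained method for the strength report.
#' @param proxies Optional proxy map, see [read_proxy_map()].
#' @param palindromic_policy,eaf_ambiguity_band See [harmonize()].
#' @param se_method,ivw_model Estimator settings, see [mr_ivw()].
#' @param n_boot Weighted-median bootstrap iterations.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param outlier_alpha MR-PRESSO significance level.
#' @param seed Seed for every stochastic stage (bootstrap, PRESSO).
#' @param strict If `TRUE`, significant pleiotropy or heterogeneity aborts
#'   the run instead of being flagged (off by default: diagnostics are
#'   reported alongside the estimates, mirroring the check-then-estimate
#'   reporting style of applied MR studies).
#' @param out_dir Optional directory; when set the report is also written
#'   as delimited tables plus a manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(exposure = "pyroglutamine_exposure",
                       outcome = "covid19_outcome",
                       ld = system.file("extdata", "pyroglutamine_ld.tsv",
                                        package = "mrpipe"),
                       pval_threshold = 5e-8, ld_r2_max = 0.001,
                       exclusion_ids = character(),
                       r2_method = c("z_based", "af_beta"),
                       proxies = NULL,
                       palindromic_policy = "keep_if_eaf_informative",
                       eaf_ambiguity_band = 0.08,
                       se_method = c("first_order", "second_order"),
                       ivw_model = c("multiplicative_random_effects", "fixed"),
                       n_boot = 1000, n_sim = 1000, outlier_alpha = 0.05,
                       seed = 20221011L, strict = FALSE, out_dir = NULL) {
  structure(
    list(exposure = exposure, outcome = outcome, ld = ld,
         pval_threshold = pval_threshold, ld_r2_max = ld_r2_max,
         exclusion_ids = as.character(exclusion_ids),
         r2_method = match.arg(r2_method), proxies = proxies,
         palindromic_policy = palindromic_policy,
         eaf_ambiguity_band = eaf_ambiguity_band,
         se_method = match.arg(se_method), ivw_model = match.arg(ivw_model),
         n_boot = n_boot, n_sim = n_sim, outlier_alpha = outlier_alpha,
         seed = as.integer(seed), strict = strict, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file's keys are the arguments of [run_config()]; unknown keys are an
#' error. Missing keys take the defaults that reproduce the packaged
#' pyroglutamine/COVID-19 analysis.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

resolve_input <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (x %in% c("pyroglutamine_exposure", "covid19_outcome")) {
      return(load_fixture(x))
    }
    if (file.exists(x)) return(read_summary_stats(x))
    stop("input '", x, "' is neither a packaged fixture name nor an ",
         "existing file", call. = FALSE)
  }
  stop("inputs must be summary_stats objects, fixture names or file paths",
       call. = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full two-sample MR pipeline
#'
#' Fixed stage order: instrument selection, harmonization, instrument
#' strength, heterogeneity (Cochran's Q about IVW and Egger), MR-Egger with
#' intercept test, MR-PRESSO, IVW and weighted-median estimation with odds
#' ratios, then leave-one-out and single-SNP sensitivity tables.
#' Significant pleiotropy or heterogeneity never aborts the run (unless
#' `strict = TRUE`) but is flagged in `$flags`; a hard failure in any stage
#' aborts with the stage named.
#'
#' @param config A [run_config()] object.
#' @return A `run_report` list: `instrument_table`, `strength_table`,
#'   `harmonized_table`, `diagnostics_table`, `presso`, `estimates_table`,
#'   `leave_one_out`, `single_snp`, `flags` and `manifest`. Written to
#'   `config$out_dir` when set (see [write_run_report()]).
#' @export
run_mr_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  exposure <- run_stage("read_exposure", resolve_input(config$exposure))
  outcome <- run_stage("read_outcome", resolve_input(config$outcome))

  criteria <- instrument_criteria(config$pval_threshold, config$ld_r2_max,
                                  config$exclusion_ids)
  instruments <- run_stage("select_instruments",
                           select_instruments(exposure, criteria, config$ld))
  harmonized <- run_stage("harmonize",
    harmonize(instruments, outcome, proxies = config$proxies,
              palindromic_policy = config$palindromic_policy,
              eaf_ambiguity_band = config$eaf_ambiguity_band))
  strength <- run_stage("strength_report",
                        strength_report(instruments, config$r2_method))

  q_ivw <- run_stage("cochran_q_ivw",
                     cochran_q(harmonized, "ivw_fixed", config$se_method))
  q_egger <- if (nrow(harmonized) >= 3) {
    run_stage("cochran_q_egger",
              cochran_q(harmonized, "egger", config$se_method))
  } else NULL
  egger <- if (nrow(harmonized) >= 3) {
    run_stage("mr_egger", mr_egger(harmonized, config$se_method))
  } else NULL
  intercept <- if (!is.null(egger)) egger_intercept_test(egger) else NULL
  presso <- if (nrow(harmonized) >= 4) {
    run_stage("mr_presso",
              mr_presso(harmonized, n_sim = config$n_sim,
                        seed = config$seed,
                        outlier_alpha = config$outlier_alpha))
  } else NULL

  ivw <- run_stage("ivw", mr_ivw(harmonized, config$ivw_model,
                                 config$se_method))
  wm <- if (nrow(harmonized) >= 3) {
    run_stage("weighted_median",
              mr_weighted_median(harmonized, n_boot = config$n_boot,
                                 seed = config$seed,
                                 se_method = config$se_method))
  } else NULL
  estimates <- rbind(ivw, wm,
                     if (!is.null(egger)) egger$slope else NULL)

  loo <- if (nrow(harmonized) >= 3) {
    run_stage("leave_one_out",
              leave_one_out(harmonized, config$ivw_model, config$se_method))
  } else NULL
  single <- run_stage("single_snp_table",
    single_snp_table(harmonized, config$se_method,
                     n_boot = config$n_boot, seed = config$seed))

  diagnostics <- rbind(q_ivw, q_egger)
  flags <- c(
    pleiotropy_egger_intercept =
      !is.null(intercept) && isTRUE(intercept$significant),
    pleiotropy_presso =
      !is.null(presso) && presso$global_pval <= config$outlier_alpha,
    heterogeneity_ivw = q_ivw$q_pval <= 0.05,
    heterogeneity_egger = !is.null(q_egger) && q_egger$q_pval <= 0.05,
    weak_instruments = any(strength$weak)
  )
  if (config$strict && any(flags)) {
    stop("strict mode: diagnostics flagged ",
         paste(names(flags)[flags], collapse = ", "), call. = FALSE)
  }

  hash_cfg <- config
  hash_cfg$out_dir <- NULL
  manifest <- list(
    package = "mrpipe",
    version = as.character(packageVersion("mrpipe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_boot = config$n_boot,
    n_sim = config$n_sim,
    config_hash = rlang::hash(hash_cfg),
    exposure_trait = attr(exposure, "trait"),
    outcome_trait = attr(outcome, "trait"),
    n_instruments = nrow(instruments),
    n_harmonized = nrow(harmonized),
    n_dropped = nrow(attr(harmonized, "dropped"))
  )

  report <- structure(
    list(
      instrument_table = tibble::as_tibble(instruments),
      strength_table = strength,
      total_r2 = attr(strength, "total_r2"),
      harmonized_table = tibble::as_tibble(harmonized),
      dropped_table = attr(harmonized, "dropped"),
      diagnostics_table = diagnostics,
      egger = egger,
      egger_intercept = intercept,
      presso = presso,
      estimates_table = estimates,
      leave_one_out = loo,
      single_snp = single,
      flags = flags,
      manifest = manifest,
      config = config
    ),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a pipeline report as delimited tables plus a manifest
#'
#' One tab-separated file per table (`instrument_table.tsv`,
#' `strength_table.tsv`, `harmonized_table.tsv`, `diagnostics_table.tsv`,
#' `estimates_table.tsv`, `leave_one_out.tsv`, `single_snp.tsv`,
#' `presso.tsv`) and `manifest.yaml` with versions, seeds and the config
#' hash. Table bytes are reproducible given the same config and seeds.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    write.table(as.data.frame(df), file.path(dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  emit(report$instrument_table, "instrument_table")
  emit(report$strength_table, "strength_table")
  emit(report$harmonized_table, "harmonized_table")
  emit(report$diagnostics_table, "diagnostics_table")
  emit(report$estimates_table, "estimates_table")
  emit(report$leave_one_out, "leave_one_out")
  emit(report$single_snp, "single_snp")
  if (!is.null(report$presso)) {
    emit(data.frame(rss_obs = report$presso$rss_obs,
                    global_pval = report$presso$global_pval,
                    n_sim = report$presso$n_sim,
                    n_outliers = length(report$presso$outliers),
                    outliers = paste(report$presso$outliers, collapse = ",")),
         "presso")
  }
  yaml::write_yaml(c(report$manifest, list(flags = as.list(report$flags))),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  m <- x$manifest
  cat("Two-sample MR run: ", m$exposure_trait, " -> ", m$outcome_trait,
      "\n", sep = "")
  cat("  instruments: ", m$n_instruments, " selected, ", m$n_harmonized,
      " harmonized, ", m$n_dropped, " dropped\n", sep = "")
  if (!is.null(x$total_r2)) {
    cat(sprintf("  variance explained: %.2f%%\n", 100 * x$total_r2))
  }
  cat("\nEstimates:\n")
  print(x$estimates_table)
  cat("\nDiagnostics:\n")
  print(x$diagnostics_table)
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept % .3f (se %.3f, p = %.3f): %s\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$pval, x$egger_intercept$verdict))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.3f, %d outlier(s)\n",
                x$presso$global_pval, length(x$presso$outliers)))
  }
  if (any(x$flags)) {
    cat("  FLAGS:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  }
  invisible(x)
}
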