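# Shared fixtures and small random-input generators for the suite.

fixture_harmonized <- function() {
  harmonize(load_fixture("pyroglutamine_exposure"),
            load_fixture("covid19_outcome"))
}

# random harmonized set with well-behaved betas/SEs (no near-zero exposure)
random_harmonized <- function(j, seed) {
  withr::with_seed(seed, {
    harmonized_variants(tibble::tibble(
      snp = sprintf("rs%03d", seq_len(j)),
      beta_exp = sample(c(-1, 1), j, TRUE) * runif(j, 0.05, 0.3),
      se_exp = runif(j, 0.005, 0.05),
      beta_out = rnorm(j, 0, 0.2),
      se_out = runif(j, 0.01, 0.1)
    ))
  })
}

# random valid summary-statistic tibble for IO round-trips
random_sumstats <- function(j, seed) {
  withr::with_seed(seed, {
    pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "T"), c("G", "C"))
    k <- sample.int(4, j, TRUE)
    new_summary_stats(tibble::tibble(
      snp = sprintf("rs%06d", sample.int(1e6, j)),
      ea = pairs[k, 1], nea = pairs[k, 2],
      eaf = runif(j, 0.05, 0.95),
      beta = rnorm(j, 0, 0.1),
      se = runif(j, 1e-4, 0.1),
      pval = runif(j, 1e-12, 1),
      n = sample(100:1e6, j, TRUE)
    ), trait = "random")
  })
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
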