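simple_set <- function(snp, ea, nea, beta, se = 0.01, eaf = NA_real_,
                       trait = "t") {
  new_summary_stats(tibble::tibble(
    snp = snp, ea = ea, nea = nea, eaf = eaf, beta = beta, se = se,
    pval = 0.001, n = 1000L), trait = trait)
}

test_that("the fixture harmonizes to the four printed beta pairs unchanged", {
  h <- fixture_harmonized()
  expect_equal(nrow(h), 4)
  expect_equal(h$snp, c("rs11613331", "rs1600760", "rs17279437", "rs715"))
  expect_equal(h$beta_exp, c(0.037, -0.022, 0.059, -0.036))
  expect_equal(h$beta_out, c(-0.024, -0.002, -0.067, 0.015))
  expect_equal(h$se_out, c(0.013, 0.013, 0.023, 0.014))
  expect_true(all(h$action == "none"))
  expect_equal(nrow(attr(h, "dropped")), 0)
})

test_that("swapped and strand-complemented outcome alleles flip the outcome beta", {
  exp <- simple_set("rs1", "A", "G", 0.2, eaf = 0.3)
  # same alleles, swapped roles
  out_sw <- simple_set("rs1", "G", "A", 0.1, eaf = 0.6)
  h <- harmonize(exp, out_sw)
  expect_equal(h$beta_out, -0.1)
  expect_equal(h$eaf_out, 0.4)
  expect_equal(h$action, "flipped")
  # other strand, same orientation: T/C complements to A/G
  out_strand <- simple_set("rs1", "T", "C", 0.1, eaf = 0.3)
  expect_equal(harmonize(exp, out_strand)$beta_out, 0.1)
  # other strand, swapped: C/T complements to G/A
  out_both <- simple_set("rs1", "C", "T", 0.1, eaf = 0.6)
  expect_equal(harmonize(exp, out_both)$beta_out, -0.1)
})

test_that("irreconcilable allele sets are dropped with a reason; losing all is an error", {
  exp <- simple_set(c("rs1", "rs2"), "A", c("C", "G"), 0.2, eaf = 0.3)
  out <- simple_set(c("rs1", "rs2"), "A", c("G", "G"), 0.1, eaf = 0.3)
  h <- harmonize(exp, out)
  expect_equal(h$snp, "rs2")
  expect_equal(attr(h, "dropped")$reason, "irreconcilable_alleles")

  exp1 <- simple_set("rs1", "A", "C", 0.2, eaf = 0.3)
  out1 <- simple_set("rs1", "A", "G", 0.1, eaf = 0.3)
  expect_error(harmonize(exp1, out1), "every variant")
})

test_that("palindromic policy uses the EAF ambiguity band as stated", {
  exp <- simple_set("rs1", "A", "T", 0.2, eaf = 0.28)
  keepable <- simple_set("rs1", "A", "T", 0.1, eaf = 0.27)
  ambiguous <- simple_set("rs1", "A", "T", 0.1, eaf = 0.51)
  discordant <- simple_set("rs1", "A", "T", 0.1, eaf = 0.72)

  expect_equal(nrow(harmonize(exp, keepable, eaf_ambiguity_band = 0.08)), 1)
  expect_error(harmonize(exp, ambiguous))  # only variant -> hard error
  expect_error(harmonize(exp, discordant))  # informative but opposite sides

  # alongside a safe companion the ambiguous palindrome is dropped with reason
  exp2 <- simple_set(c("rs1", "rs2"), "A", c("T", "G"), 0.2, eaf = 0.28)
  amb2 <- simple_set(c("rs1", "rs2"), "A", c("T", "G"), 0.1, eaf = 0.51)
  h <- harmonize(exp2, amb2, eaf_ambiguity_band = 0.08)
  expect_equal(h$snp, "rs2")
  expect_equal(attr(h, "dropped")$reason, "dropped_palindromic")

  # missing EAF: the check cannot fire, the variant is kept
  no_eaf <- simple_set("rs1", "A", "T", 0.1)
  expect_equal(nrow(harmonize(exp, no_eaf)), 1)
  # policy overrides: drop always drops, keep_all always keeps
  expect_error(harmonize(exp, keepable, palindromic_policy = "drop"))
  expect_equal(nrow(harmonize(exp, ambiguous, palindromic_policy = "keep_all")), 1)
})

test_that("proxy substitution fills outcome gaps and records the action", {
  exp <- simple_set(c("rs1", "rs2"), "A", "G", c(0.2, 0.3), eaf = 0.3)
  out <- simple_set(c("rs2", "rsP"), "A", "G", c(0.15, 0.1), eaf = 0.3)
  proxies <- tibble::tibble(target_snp = "rs1", proxy_snp = "rsP",
                            r2 = 0.95, ea_match = "yes")
  h <- harmonize(exp, out, proxies = proxies)
  expect_equal(nrow(h), 2)
  expect_equal(h$action[h$snp == "rs1"], "proxy_substituted")
  expect_equal(h$beta_out[h$snp == "rs1"], 0.1)
  # allele correspondence 'no' negates the proxy's beta
  proxies$ea_match <- "no"
  h2 <- harmonize(exp, out, proxies = proxies)
  expect_equal(h2$beta_out[h2$snp == "rs1"], -0.1)
  # without proxies the missing variant is dropped and counted
  h3 <- harmonize(exp, out)
  expect_equal(attr(h3, "dropped")$reason, "missing_in_outcome")
  expect_equal(nrow(h3) + nrow(attr(h3, "dropped")), nrow(exp))
})

test_that("the proxy map reader enforces its r2 threshold and vocabulary", {
  good <- write_tmp_lines(c("target_snp\tproxy_snp\tr2\tea_match",
                            "rs1\trsP\t0.95\tyes"))
  expect_equal(nrow(read_proxy_map(good)), 1)
  weak <- write_tmp_lines(c("target_snp\tproxy_snp\tr2\tea_match",
                            "rs1\trsP\t0.5\tyes"))
  expect_error(read_proxy_map(weak), "0.8")
  bad <- write_tmp_lines(c("target_snp\tproxy_snp\tr2\tea_match",
                           "rs1\trsP\t0.95\tmaybe"))
  expect_error(read_proxy_map(bad), "ea_match")
})

test_that("harmonization is idempotent and preserves Wald ratios under joint flips", {
  exp <- load_fixture("pyroglutamine_exposure")
  out <- load_fixture("covid19_outcome")
  h1 <- harmonize(exp, out)
  # feed the harmonized outcome back in: nothing changes
  out2 <- new_summary_stats(tibble::tibble(
    snp = h1$snp, ea = h1$ea, nea = h1$nea, eaf = h1$eaf_out,
    beta = h1$beta_out, se = h1$se_out, pval = 0.5, n = 1299010L),
    trait = "re-harmonized")
  h2 <- harmonize(exp, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$beta_exp, h1$beta_exp)
  expect_true(all(h2$action == "none"))

  # flipping both datasets' alleles together leaves Wald ratios invariant
  flip_set <- function(s) {
    new_summary_stats(tibble::tibble(
      snp = s$snp, ea = s$nea, nea = s$ea,
      eaf = ifelse(is.na(s$eaf), NA_real_, 1 - s$eaf),
      beta = -s$beta, se = s$se, pval = s$pval, n = s$n),
      trait = attr(s, "trait"))
  }
  h_flipped <- harmonize(flip_set(exp), flip_set(out))
  expect_equal(h_flipped$beta_out / h_flipped$beta_exp,
               h1$beta_out / h1$beta_exp)
})

test_that("orienting to positive exposure negates pairs and preserves ratios", {
  h <- fixture_harmonized()
  o <- orient_to_positive_exposure(h)
  expect_true(all(o$beta_exp >= 0))
  expect_equal(o$beta_out / o$beta_exp, h$beta_out / h$beta_exp)
  expect_equal(o$se_exp, h$se_exp)
  expect_equal(o$se_out, h$se_out)
  # the printed rs715 pair (-0.036, 0.015) becomes (0.036, -0.015)
  rs715 <- o[o$snp == "rs715", ]
  expect_equal(rs715$beta_exp, 0.036)
  expect_equal(rs715$beta_out, -0.015)
  # already-positive rows are untouched, and the transform is idempotent
  expect_equal(o[o$snp == "rs17279437", ]$beta_out, -0.067)
  expect_equal(orient_to_positive_exposure(o), o)
})
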