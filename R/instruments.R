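#' Instrument selection criteria
#'
#' @param pval_threshold Genome-wide significance cutoff; variants with
#'   exposure p-values at or above it are not candidate instruments. Default
#'   `5e-8`.
#' @param ld_r2_max Clumping threshold: an accepted instrument must have
#'   pairwise LD r-squared below this with every already-accepted instrument.
#'   Default `0.001` (near-complete independence).
#' @param exclusion_ids SNP IDs to remove a priori, e.g. variants associated
#'   with stated confounders (body-mass index, smoking, blood pressure in the
#'   pyroglutamine analysis). The screen is an explicit list because no
#'   algorithmic confounder lookup is defined; it is the caller's audit trail.
#' @return An `instrument_criteria` list.
#' @export
instrument_criteria <- function(pval_threshold = 5e-8, ld_r2_max = 0.001,
                                exclusion_ids = character()) {
  stopifnot(is.numeric(pval_threshold), length(pval_threshold) == 1,
            pval_threshold > 0, pval_threshold < 1,
            is.numeric(ld_r2_max), length(ld_r2_max) == 1,
            ld_r2_max >= 0, ld_r2_max <= 1)
  structure(
    list(pval_threshold = pval_threshold, ld_r2_max = ld_r2_max,
         exclusion_ids = as.character(exclusion_ids)),
    class = "instrument_criteria"
  )
}

#' Read a pairwise LD table
#'
#' Three-column delimited text (`snp_a`, `snp_b`, `r2`); the symmetric
#' closure is applied on load, and self-pairs are implied with r2 = 1.
#' LD is consumed as user-supplied data (e.g. exported from an LD-matrix
#' service for the relevant reference panel); the package never computes LD
#' from genotypes.
#'
#' @param path Path to the file.
#' @return A tibble with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ""
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  needed <- c("snp_a", "snp_b", "r2")
  if (!all(needed %in% names(raw))) {
    stop("LD table must have columns snp_a, snp_b, r2", call. = FALSE)
  }
  ld <- tibble::tibble(snp_a = as.character(raw$snp_a),
                       snp_b = as.character(raw$snp_b),
                       r2 = parse_number(raw$r2))
  if (any(is.na(ld$r2) | ld$r2 < 0 | ld$r2 > 1)) {
    stop("LD r2 values must be numeric in [0,1]", call. = FALSE)
  }
  as_ld_table(ld)
}

# symmetric closure, used by both the reader and data-frame input
as_ld_table <- function(ld) {
  ld <- tibble::as_tibble(ld)[, c("snp_a", "snp_b", "r2")]
  rbind(ld, tibble::tibble(snp_a = ld$snp_b, snp_b = ld$snp_a, r2 = ld$r2))
}

# r2 for one pair; a missing pair is a data error, never assumed zero
ld_pair_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  hit <- ld$r2[ld$snp_a == a & ld$snp_b == b]
  if (length(hit) == 0) {
    stop("LD r2 missing for pair (", a, ", ", b, ")", call. = FALSE)
  }
  max(hit)
}

#' Select genetic instruments by significance, exclusion list and LD clumping
#'
#' Retains exposure variants with p-value below the significance threshold,
#' removes the exclusion IDs, then performs greedy clumping: survivors are
#' sorted by ascending p-value (ties broken lexicographically by SNP ID for
#' determinism) and a variant is accepted iff its LD r-squared with every
#' already-accepted variant is below `ld_r2_max`.
#'
#' @param exposure A `summary_stats` object.
#' @param criteria An [instrument_criteria()] list.
#' @param ld Pairwise LD: a path readable by [read_ld_table()] or a data
#'   frame with columns `snp_a`, `snp_b`, `r2` (symmetric closure applied).
#'   Required whenever more than one variant survives filtering; a missing
#'   pair among survivors is an error, never treated as r2 = 0.
#' @return A `summary_stats` subset ordered by ascending p-value.
#' @export
select_instruments <- function(exposure, criteria = instrument_criteria(),
                               ld = NULL) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(criteria, "instrument_criteria"))
  x <- tibble::as_tibble(exposure)
  x <- x[x$pval < criteria$pval_threshold, , drop = FALSE]
  x <- x[!(x$snp %in% criteria$exclusion_ids), , drop = FALSE]
  if (nrow(x) == 0) {
    stop("no instruments: no variant passes the significance threshold ",
         "after exclusions", call. = FALSE)
  }
  x <- x[order(x$pval, x$snp), , drop = FALSE]

  if (nrow(x) > 1) {
    if (is.null(ld)) {
      stop("an LD table is required when more than one candidate survives ",
           "filtering", call. = FALSE)
    }
    if (is.character(ld)) ld <- read_ld_table(ld)
    ld <- as_ld_table(ld)
  }

  accepted <- integer(0)
  for (i in seq_len(nrow(x))) {
    ok <- all(vapply(
      accepted,
      function(j) ld_pair_r2(ld, x$snp[i], x$snp[j]) < criteria$ld_r2_max,
      logical(1)
    ))
    if (ok) accepted <- c(accepted, i)
  }
  out <- x[accepted, , drop = FALSE]
  new_summary_stats(out, trait = attr(exposure, "trait"),
                    ancestry = attr(exposure, "ancestry"))
}

#' Proportion of exposure variance explained by one variant
#'
#' Two estimators are exposed because published tables rarely state which was
#' used:
#' \describe{
#'   \item{`z_based`}{`r2 = z^2 / (z^2 + n - 2)` with `z = beta/se` — needs
#'     only beta, SE and sample size (the default).}
#'   \item{`af_beta`}{`r2 = 2 * eaf * (1 - eaf) * beta^2` — assumes a
#'     unit-variance phenotype and additionally needs the effect-allele
#'     frequency.}
#' }
#'
#' @param beta,se,n Per-variant effect, standard error and sample size
#'   (vectorized).
#' @param eaf Effect-allele frequency, required for `"af_beta"`.
#' @param method `"z_based"` or `"af_beta"`.
#' @return Variance explained, in `[0, 1)`.
#' @export
variance_explained <- function(beta, se, n, eaf = NULL,
                               method = c("z_based", "af_beta")) {
  method <- match.arg(method)
  stopifnot(all(se > 0), all(n > 2))
  if (method == "z_based") {
    z2 <- (beta / se)^2
    z2 / (z2 + n - 2)
  } else {
    if (is.null(eaf) || any(is.na(eaf))) {
      stop("method 'af_beta' requires non-missing effect-allele frequencies",
           call. = FALSE)
    }
    2 * eaf * (1 - eaf) * beta^2
  }
}

#' Instrument-strength F-statistic
#'
#' `F = r2 * (n - 2) / (1 - r2)`. `r2` may come from
#' [variance_explained()] or be supplied externally (e.g. a published
#' variance-explained column), so published F columns are reproducible from
#' their own printed R-squared values.
#'
#' @param r2 Variance explained, in `[0, 1)` (vectorized).
#' @param n Sample size, `> 2`.
#' @return The F-statistic(s), `>= 0`.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must be in [0, 1)", call. = FALSE)
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Per-instrument strength report
#'
#' Per-SNP variance explained and F-statistic, the total variance explained
#' (sum over instruments), and a weak-instrument flag at the conventional
#' threshold F < 10.
#'
#' @param exposure A nonempty `summary_stats` object.
#' @param method Variance-explained method, see [variance_explained()].
#' @param weak_threshold F below which an instrument is flagged weak
#'   (default 10).
#' @return A tibble (`snp`, `r2`, `f_stat`, `weak`) with attributes
#'   `total_r2` and `method`.
#' @export
strength_report <- function(exposure, method = c("z_based", "af_beta"),
                            weak_threshold = 10) {
  stopifnot(inherits(exposure, "summary_stats"), nrow(exposure) > 0)
  method <- match.arg(method)
  r2 <- variance_explained(exposure$beta, exposure$se, exposure$n,
                           eaf = exposure$eaf, method = method)
  f <- f_statistic(r2, exposure$n)
  out <- tibble::tibble(snp = exposure$snp, r2 = r2, f_stat = f,
                        weak = f < weak_threshold)
  attr(out, "total_r2") <- sum(r2)
  attr(out, "method") <- method
  out
}
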