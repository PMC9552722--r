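allele_complement <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, nea) unname(allele_complement[ea]) == nea

#' Construct a harmonized variant table programmatically
#'
#' A `harmonized_variants` object is a tibble with one row per variant
#' aligned to a common effect allele: columns `snp`, `ea`, `nea`,
#' `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#' `action`. [harmonize()] is the usual constructor; this one is for
#' simulated or already-aligned inputs.
#'
#' @param x Data frame with at least `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; missing allele/frequency columns are filled with
#'   placeholders, `action` with `"none"`.
#' @return A `harmonized_variants` tibble.
#' @export
harmonized_variants <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("harmonized variants need columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"ea" %in% names(x)) x$ea <- "A"
  if (!"nea" %in% names(x)) x$nea <- "G"
  if (!"eaf_exp" %in% names(x)) x$eaf_exp <- NA_real_
  if (!"eaf_out" %in% names(x)) x$eaf_out <- NA_real_
  if (!"action" %in% names(x)) x$action <- "none"
  if (any(x$se_exp <= 0) || any(x$se_out <= 0)) {
    stop("all standard errors must be > 0", call. = FALSE)
  }
  cols <- c("snp", "ea", "nea", "beta_exp", "se_exp", "beta_out", "se_out",
            "eaf_exp", "eaf_out", "action")
  structure(x[, cols], class = c("harmonized_variants", class(tibble::tibble())))
}

#' Read a proxy-substitution map
#'
#' Delimited text with columns `target_snp`, `proxy_snp`, `r2`,
#' `ea_match` (`yes` if the proxy's effect allele tags the target's effect
#' allele, `no` if it tags the other allele).
#'
#' @param path Path to the file.
#' @param r2_min Minimum LD r-squared a proxy must reach (default 0.8);
#'   entries below it are an error.
#' @return A tibble usable as the `proxies` argument of [harmonize()].
#' @export
read_proxy_map <- function(path, r2_min = 0.8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ""
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  needed <- c("target_snp", "proxy_snp", "r2", "ea_match")
  if (!all(needed %in% names(raw))) {
    stop("proxy map must have columns target_snp, proxy_snp, r2, ea_match",
         call. = FALSE)
  }
  out <- tibble::tibble(target_snp = as.character(raw$target_snp),
                        proxy_snp = as.character(raw$proxy_snp),
                        r2 = parse_number(raw$r2),
                        ea_match = tolower(as.character(raw$ea_match)))
  if (any(is.na(out$r2) | out$r2 < r2_min)) {
    stop("proxy entries must have r2 >= ", r2_min, call. = FALSE)
  }
  if (!all(out$ea_match %in% c("yes", "no"))) {
    stop("ea_match must be 'yes' or 'no'", call. = FALSE)
  }
  out
}

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' For each exposure instrument: an exact ID match in the outcome is used
#' directly; if absent and a proxy map is given, the proxy locus's outcome
#' statistics are substituted verbatim (recorded as `proxy_substituted`).
#' Alleles are then aligned to the exposure effect allele: if the outcome
#' effect allele equals the exposure other allele (directly or after strand
#' complementation A<->T, C<->G), the outcome beta is negated and its EAF
#' replaced by 1 - EAF (`flipped`). Palindromic variants (A/T or C/G) are
#' handled by `palindromic_policy`:
#' \describe{
#'   \item{`keep_if_eaf_informative`}{kept only when both EAFs are available,
#'     both lie outside `0.5 +/- eaf_ambiguity_band`, and both fall on the
#'     same side of 0.5; when either EAF is missing the check cannot fire and
#'     the variant is kept (graceful degradation for outcome exports that
#'     omit EAF). Default, with band 0.08.}
#'   \item{`drop`}{always dropped.}
#'   \item{`keep_all`}{always kept.}
#' }
#' Variants with irreconcilable allele sets are dropped with the reason
#' recorded; losing every variant is a hard error.
#'
#' @param exposure,outcome `summary_stats` objects (exposure nonempty).
#' @param proxies Optional proxy map, see [read_proxy_map()].
#' @param palindromic_policy See above.
#' @param eaf_ambiguity_band Half-width of the ambiguous frequency window
#'   around 0.5 (default 0.08).
#' @return A `harmonized_variants` tibble ordered by SNP ID, with attribute
#'   `dropped` (tibble of `snp`, `reason`).
#' @export
harmonize <- function(exposure, outcome, proxies = NULL,
                      palindromic_policy = c("keep_if_eaf_informative",
                                             "drop", "keep_all"),
                      eaf_ambiguity_band = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), nrow(exposure) > 0,
            inherits(outcome, "summary_stats"))
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(eaf_ambiguity_band >= 0, eaf_ambiguity_band < 0.5)

  exposure <- tibble::as_tibble(exposure)
  exposure <- exposure[order(exposure$snp), , drop = FALSE]
  out_idx <- setNames(seq_len(nrow(outcome)), outcome$snp)

  kept <- list()
  dropped_snp <- character(0); dropped_reason <- character(0)
  drop <- function(snp, why) {
    dropped_snp <<- c(dropped_snp, snp)
    dropped_reason <<- c(dropped_reason, why)
  }

  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    action <- "none"
    j <- out_idx[ex$snp]

    if (is.na(j) && !is.null(proxies)) {
      hit <- proxies[proxies$target_snp == ex$snp, , drop = FALSE]
      if (nrow(hit) > 0) {
        hit <- hit[which.max(hit$r2), ]
        j <- out_idx[hit$proxy_snp]
        if (!is.na(j)) {
          action <- "proxy_substituted"
          ov <- outcome[j, ]
          b_out <- ov$beta; s_out <- ov$se; f_out <- ov$eaf
          if (hit$ea_match == "no") {
            b_out <- -b_out
            f_out <- if (is.na(f_out)) NA_real_ else 1 - f_out
          }
          row <- tibble::tibble(
            snp = ex$snp, ea = ex$ea, nea = ex$nea,
            beta_exp = ex$beta, se_exp = ex$se,
            beta_out = b_out, se_out = s_out,
            eaf_exp = ex$eaf, eaf_out = f_out, action = action
          )
          kept[[length(kept) + 1L]] <- row
          next
        }
      }
    }
    if (is.na(j)) { drop(ex$snp, "missing_in_outcome"); next }

    ov <- outcome[j, ]
    b_out <- ov$beta; f_out <- ov$eaf
    oea <- ov$ea; onea <- ov$nea
    flip <- NA  # NA = irreconcilable
    if (oea == ex$ea && onea == ex$nea) {
      flip <- FALSE
    } else if (oea == ex$nea && onea == ex$ea) {
      flip <- TRUE
    } else {
      cea <- unname(allele_complement[oea])
      cnea <- unname(allele_complement[onea])
      if (cea == ex$ea && cnea == ex$nea) flip <- FALSE
      else if (cea == ex$nea && cnea == ex$ea) flip <- TRUE
    }
    if (is.na(flip)) { drop(ex$snp, "irreconcilable_alleles"); next }
    if (flip) {
      action <- "flipped"
      b_out <- -b_out
      f_out <- if (is.na(f_out)) NA_real_ else 1 - f_out
    }

    if (is_palindromic(ex$ea, ex$nea)) {
      if (palindromic_policy == "drop") { drop(ex$snp, "dropped_palindromic"); next }
      if (palindromic_policy == "keep_if_eaf_informative" &&
          !is.na(ex$eaf) && !is.na(f_out)) {
        informative <- abs(ex$eaf - 0.5) > eaf_ambiguity_band &&
          abs(f_out - 0.5) > eaf_ambiguity_band
        concordant <- (ex$eaf < 0.5) == (f_out < 0.5)
        if (!informative || !concordant) {
          drop(ex$snp, "dropped_palindromic"); next
        }
      }
    }

    kept[[length(kept) + 1L]] <- tibble::tibble(
      snp = ex$snp, ea = ex$ea, nea = ex$nea,
      beta_exp = ex$beta, se_exp = ex$se,
      beta_out = b_out, se_out = ov$se,
      eaf_exp = ex$eaf, eaf_out = f_out, action = action
    )
  }

  dropped <- tibble::tibble(snp = dropped_snp, reason = dropped_reason)
  if (length(kept) == 0) {
    stop("harmonization dropped every variant (",
         paste0(dropped$snp, ": ", dropped$reason, collapse = "; "), ")",
         call. = FALSE)
  }
  out <- harmonized_variants(do.call(rbind, kept))
  attr(out, "dropped") <- dropped
  out
}

#' Orient harmonized variants so all exposure effects are non-negative
#'
#' The conventional orientation for MR-Egger regression: for each variant
#' with a negative exposure beta, both betas are negated (standard errors
#' unchanged, alleles swapped, frequencies complemented). Wald ratios are
#' unchanged by the transform.
#'
#' @param variants A nonempty `harmonized_variants` tibble.
#' @return The re-oriented `harmonized_variants` tibble.
#' @export
orient_to_positive_exposure <- function(variants) {
  stopifnot(inherits(variants, "harmonized_variants"), nrow(variants) > 0)
  neg <- variants$beta_exp < 0
  if (any(neg)) {
    ea <- variants$ea[neg]
    variants$ea[neg] <- variants$nea[neg]
    variants$nea[neg] <- ea
    variants$beta_exp[neg] <- -variants$beta_exp[neg]
    variants$beta_out[neg] <- -variants$beta_out[neg]
    variants$eaf_exp[neg] <- 1 - variants$eaf_exp[neg]
    variants$eaf_out[neg] <- 1 - variants$eaf_out[neg]
  }
  variants
}
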