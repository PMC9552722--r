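# Canonical on-disk header for summary statistics. column_map lets callers
# read files with arbitrary source headers into the same internal fields.
sumstat_header <- c(
  snp = "SNP", ea = "EA", nea = "NEA", eaf = "EAF",
  beta = "BETA", se = "SE", pval = "P", n = "N"
)

valid_alleles <- c("A", "C", "G", "T")

#' Construct a validated set of GWAS summary statistics
#'
#' A `summary_stats` object is a tibble with one row per variant and columns
#' `snp`, `ea` (effect allele), `nea` (non-effect allele), `eaf`
#' (effect-allele frequency, may be `NA`), `beta`, `se`, `pval` and `n`.
#' Betas are per-allele effects on the trait: log odds ratios for binary
#' traits, SD or raw units for quantitative traits.
#'
#' @param x A data frame with at least columns `snp`, `ea`, `nea`, `beta`,
#'   `se`, `pval`, `n`; an `eaf` column is optional (filled with `NA` when
#'   absent, since many outcome GWAS exports omit it).
#' @param trait Trait label carried as an attribute.
#' @param ancestry Optional ancestry label.
#' @return A `summary_stats` tibble. Invalid rows are an error here (use
#'   [read_summary_stats()] for the tolerant file-reading path).
#' @export
#' @examples
#' new_summary_stats(
#'   data.frame(snp = "rs1", ea = "A", nea = "G", eaf = 0.3,
#'              beta = 0.1, se = 0.02, pval = 1e-9, n = 1000),
#'   trait = "example"
#' )
new_summary_stats <- function(x, trait = "trait", ancestry = NULL) {
  x <- tibble::as_tibble(x)
  needed <- c("snp", "ea", "nea", "beta", "se", "pval", "n")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("summary statistics are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  x <- x[, names(sumstat_header)]
  x$snp <- as.character(x$snp)
  x$ea <- toupper(as.character(x$ea))
  x$nea <- toupper(as.character(x$nea))
  for (col in c("eaf", "beta", "se", "pval")) x[[col]] <- as.numeric(x[[col]])
  x$n <- as.integer(round(as.numeric(x$n)))

  issues <- validate_sumstat_rows(x)
  if (nrow(issues) > 0) {
    stop("invalid summary-statistic rows:\n",
         paste0("  row ", issues$row, " (", issues$snp, "): ", issues$reason,
                collapse = "\n"),
         call. = FALSE)
  }
  dup <- unique(x$snp[duplicated(x$snp)])
  if (length(dup) > 0) {
    stop("duplicate snp_id in summary statistics: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(
    x,
    class = c("summary_stats", class(tibble::tibble())),
    trait = trait,
    ancestry = ancestry
  )
}

# One reason string per offending row; valid rows are absent from the result.
validate_sumstat_rows <- function(x) {
  rows <- integer(0); snps <- character(0); reasons <- character(0)
  flag <- function(i, why) {
    rows <<- c(rows, i); snps <<- c(snps, x$snp[i]); reasons <<- c(reasons, why)
  }
  for (i in seq_len(nrow(x))) {
    if (is.na(x$snp[i]) || !nzchar(x$snp[i])) flag(i, "empty snp_id")
    if (!(x$ea[i] %in% valid_alleles)) flag(i, paste0("effect allele '", x$ea[i], "' not in A/C/G/T"))
    if (!(x$nea[i] %in% valid_alleles)) flag(i, paste0("other allele '", x$nea[i], "' not in A/C/G/T"))
    if (!is.na(x$ea[i]) && !is.na(x$nea[i]) && x$ea[i] == x$nea[i])
      flag(i, "effect and other allele identical")
    if (is.na(x$beta[i])) flag(i, "beta not numeric")
    if (is.na(x$se[i]) || x$se[i] <= 0) flag(i, "se not numeric or not > 0")
    if (!is.na(x$eaf[i]) && (x$eaf[i] <= 0 || x$eaf[i] >= 1))
      flag(i, "eaf outside (0,1)")
    if (is.na(x$pval[i]) || x$pval[i] <= 0 || x$pval[i] > 1)
      flag(i, "p-value outside (0,1]")
    if (is.na(x$n[i]) || x$n[i] < 2) flag(i, "sample size < 2")
  }
  tibble::tibble(row = rows, snp = snps, reason = reasons)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or whitespace-delimited file with a header row. Numbers may be
#' in decimal or scientific notation; the Unicode minus sign is normalized to
#' ASCII. Rows violating the field invariants (see [new_summary_stats()]) are
#' rejected, reported with their file line numbers in a warning, and returned
#' in the `rejected` attribute; they are never silently dropped.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping internal fields (`snp`,
#'   `ea`, `nea`, `eaf`, `beta`, `se`, `pval`, `n`) to the file's headers.
#'   Defaults to the canonical header `SNP EA NEA EAF BETA SE P N`. The `eaf`
#'   column may be absent from the file (stored as `NA`); a missing mapped
#'   column for any other field is a configuration error.
#' @param trait,ancestry Labels attached to the result; `trait` defaults to
#'   the file name.
#' @return A `summary_stats` tibble with attribute `rejected` (tibble of
#'   `line`, `snp`, `reason` for rejected rows).
#' @export
read_summary_stats <- function(path, column_map = NULL, trait = NULL,
                               ancestry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  map <- sumstat_header
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown) > 0) {
      stop("column_map names must be internal fields; unknown: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }

  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ""
  raw <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), quote = "", comment.char = "")

  required <- setdiff(names(map), "eaf")
  absent <- map[required][!(map[required] %in% names(raw))]
  if (length(absent) > 0) {
    stop("mapped column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  x <- tibble::tibble(
    snp = as.character(raw[[map[["snp"]]]]),
    ea = toupper(as.character(raw[[map[["ea"]]]])),
    nea = toupper(as.character(raw[[map[["nea"]]]])),
    eaf = if (map[["eaf"]] %in% names(raw)) parse_number(raw[[map[["eaf"]]]]) else NA_real_,
    beta = parse_number(raw[[map[["beta"]]]]),
    se = parse_number(raw[[map[["se"]]]]),
    pval = parse_number(raw[[map[["pval"]]]]),
    n = as.integer(round(parse_number(raw[[map[["n"]]]])))
  )

  issues <- validate_sumstat_rows(x)
  # data rows start on file line 2 (after the header)
  if (nrow(issues) > 0) {
    bad_rows <- unique(issues$row)
    issues$line <- issues$row + 1L
    issues <- issues[, c("line", "snp", "reason")]
    warning("rejected ", length(bad_rows), " row(s) in ", path, ":\n",
            paste0("  line ", issues$line, " (", issues$snp, "): ",
                   issues$reason, collapse = "\n"),
            call. = FALSE)
    x <- x[-bad_rows, , drop = FALSE]
  } else {
    issues <- tibble::tibble(line = integer(0), snp = character(0),
                             reason = character(0))
  }

  out <- new_summary_stats(x, trait = trait, ancestry = ancestry)
  attr(out, "rejected") <- issues
  out
}

# Scientific or decimal notation; the Unicode minus U+2212 and stray spaces
# after a sign (as printed in typeset tables) are normalized first.
parse_number <- function(x) {
  x <- gsub("−", "-", as.character(x))
  x <- gsub("^([+-])\\s+", "\\1", x)
  suppressWarnings(as.numeric(x))
}

#' Write summary statistics to the canonical tab-separated format
#'
#' Writes the header `SNP EA NEA EAF BETA SE P N`; missing EAF is written as
#' `NA`. Round-trips through [read_summary_stats()] to full double precision.
#'
#' @param x A `summary_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  num <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 15))
  df <- data.frame(
    SNP = x$snp, EA = x$ea, NEA = x$nea, EAF = num(x$eaf),
    BETA = num(x$beta), SE = num(x$se), P = num(x$pval),
    N = as.character(x$n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a packaged summary-statistics fixture
#'
#' Two fixtures ship with the package, transcribed from the published
#' pyroglutamine/COVID-19 Mendelian-randomization tables:
#' \describe{
#'   \item{`pyroglutamine_exposure`}{The 4 independent pyroglutamine
#'     instruments from the blood-metabolite GWAS (7,800 Europeans; per-SNP
#'     n = 7,354 as printed).}
#'   \item{`covid19_outcome`}{The same 4 SNPs' effects in the COVID-19 Host
#'     Genetics Initiative release-4 susceptibility GWAS (14,134 cases,
#'     1,284,876 controls; n = 1,299,010). The source table prints outcome
#'     betas already oriented to the pyroglutamine-raising effect allele and
#'     omits outcome alleles and EAF, so the fixture carries the exposure
#'     alleles (an orientation assumption, not printed data) and `eaf = NA`.}
#' }
#'
#' @param name `"pyroglutamine_exposure"` or `"covid19_outcome"`.
#' @return A `summary_stats` tibble of 4 records.
#' @export
#' @examples
#' load_fixture("pyroglutamine_exposure")
load_fixture <- function(name = c("pyroglutamine_exposure", "covid19_outcome")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "mrpipe")
  trait <- switch(name,
    pyroglutamine_exposure = "blood pyroglutamine",
    covid19_outcome = "COVID-19 susceptibility"
  )
  out <- read_summary_stats(path, trait = trait, ancestry = "European")
  if (name == "covid19_outcome") {
    attr(out, "ncase") <- 14134L
    attr(out, "ncontrol") <- 1284876L
  }
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("GWAS summary statistics: ", attr(x, "trait"),
      " (", nrow(x), " variants", sep = "")
  if (!is.null(attr(x, "ancestry"))) cat(", ", attr(x, "ancestry"), sep = "")
  cat(")\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
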