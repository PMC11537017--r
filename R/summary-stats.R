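#' Construct a validated table of GWAS summary statistics
#'
#' A `summary_stats` object is a tibble with one row per variant and the
#' canonical columns `variant_id`, `chromosome`, `position`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`. Betas for binary
#' traits are interpreted on the natural-log-odds scale; odds ratios are
#' always derived views (`exp(beta)`), never stored.
#'
#' Rows violating the per-variant invariants are dropped (with a reason) and
#' recorded in the `dropped` attribute:
#' \itemize{
#'   \item `se` must be strictly positive, `pvalue` in (0, 1];
#'   \item alleles must be single bases in A/C/G/T and distinct;
#'   \item `eaf` missing or in [0, 1]; `n` a positive count;
#'   \item `variant_id` unique (the first occurrence is kept).
#' }
#'
#' @param data A data frame holding the canonical columns (`eaf` optional).
#' @param trait_label Human-readable trait name carried into reports.
#' @param trait_type `"quantitative"` (betas in SD units) or `"binary"`
#'   (betas are log odds ratios).
#' @param quiet Suppress the dropped-row message.
#' @return A tibble of class `summary_stats` with attributes `trait_label`,
#'   `trait_type` and `dropped` (a tibble of `variant_id`, `reason`).
#' @examples
#' ss <- summary_stats(
#'   data.frame(
#'     variant_id = c("rs1", "rs2"), chromosome = "1",
#'     position = c(1000L, 2000L), effect_allele = c("A", "C"),
#'     other_allele = c("G", "T"), eaf = c(0.3, 0.4),
#'     beta = c(0.12, -0.05), se = c(0.02, 0.03),
#'     pvalue = c(1e-9, 0.1), n = 10000L
#'   ),
#'   trait_label = "example trait", trait_type = "quantitative"
#' )
#' @export
summary_stats <- function(data, trait_label, trait_type = c("quantitative", "binary"),
                          quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chromosome", "position", "effect_allele",
                "other_allele", "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_config(paste0("summary statistics are missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(data)
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  x <- dplyr::mutate(
    x,
    variant_id = as.character(.data$variant_id),
    chromosome = as.character(.data$chromosome),
    position = as.integer(.data$position),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pvalue = as.numeric(.data$pvalue),
    n = as.integer(.data$n)
  )
  x <- dplyr::select(x, dplyr::all_of(c(required[1:5], "eaf", required[6:9])))

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- flag(!is.finite(x$beta) | !is.finite(x$se), "missing_effect")
  reason <- flag(x$se <= 0, "nonpositive_se")
  reason <- flag(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1,
                 "pvalue_out_of_range")
  reason <- flag(!(x$effect_allele %in% bases) | !(x$other_allele %in% bases),
                 "invalid_allele")
  reason <- flag(x$effect_allele == x$other_allele, "identical_alleles")
  reason <- flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf_out_of_range")
  reason <- flag(is.na(x$n) | x$n <= 0, "nonpositive_n")
  reason <- flag(duplicated(x$variant_id), "duplicate_variant_id")

  dropped <- tibble(variant_id = x$variant_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  x <- x[is.na(reason), , drop = FALSE]
  if (nrow(x) == 0) {
    abort_input(sprintf("no usable rows for trait '%s' after validation",
                        trait_label))
  }
  if (nrow(dropped) > 0 && !quiet) {
    inform(sprintf("summary_stats('%s'): dropped %d invalid row(s)",
                   trait_label, nrow(dropped)))
  }
  new_summary_stats(x, trait_label, trait_type, dropped)
}

new_summary_stats <- function(x, trait_label, trait_type, dropped) {
  structure(
    x,
    trait_label = trait_label,
    trait_type = trait_type,
    dropped = dropped,
    class = c("summary_stats", class(tibble()))
  )
}

# Reapply summary_stats attributes after a dplyr verb stripped them.
restore_ss <- function(x, template, dropped = attr(template, "dropped")) {
  new_summary_stats(as_tibble(x),
                    trait_label = attr(template, "trait_label"),
                    trait_type = attr(template, "trait_type"),
                    dropped = dropped)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %s (%s), %d variant(s)\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  NextMethod()
}

#' Trait metadata accessors
#'
#' @param x A `summary_stats` object.
#' @return `trait_label()`/`trait_type()` return the stored strings;
#'   `dropped_rows()` the tibble of rows removed during validation or
#'   harmonization, with reasons.
#' @export
trait_label <- function(x) attr(x, "trait_label")

#' @rdname trait_label
#' @export
trait_type <- function(x) attr(x, "trait_type")

#' @rdname trait_label
#' @export
dropped_rows <- function(x) attr(x, "dropped") %||% tibble(variant_id = character(), reason = character())

#' Column dialects for delimited summary-statistic files
#'
#' A dialect maps the canonical semantic column names to the header names
#' used by a particular file format. `dialect_canonical()` is the identity
#' mapping (and the format written by [write_summary_stats()]);
#' `dialect_gwas_catalog()` follows GWAS-Catalog-style headers;
#' `dialect_generic()` follows the exposure/outcome style common in MR
#' tooling.
#'
#' @return A named character vector; names are canonical columns, values are
#'   file headers.
#' @export
dialect_canonical <- function() {
  cols <- c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "eaf", "beta", "se", "pvalue", "n")
  setNames(cols, cols)
}

#' @rdname dialect_canonical
#' @export
dialect_gwas_catalog <- function() {
  c(variant_id = "variant_id", chromosome = "chromosome",
    position = "base_pair_location", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "effect_allele_frequency",
    beta = "beta", se = "standard_error", pvalue = "p_value", n = "n")
}

#' @rdname dialect_canonical
#' @export
dialect_generic <- function() {
  c(variant_id = "SNP", chromosome = "chr", position = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pval", n = "samplesize")
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a header-ed delimited file (tab by default; comma accepted, and
#' auto-detected for `.csv` paths), renames columns according to `dialect`,
#' and validates rows via [summary_stats()].
#'
#' @param path File path.
#' @param trait_label,trait_type Passed to [summary_stats()].
#' @param dialect Named character vector mapping canonical column names to
#'   file headers; see [dialect_canonical()]. The `eaf` mapping is optional.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @param quiet Suppress the dropped-row message.
#' @return A `summary_stats` tibble.
#' @export
read_summary_stats <- function(path, trait_label,
                               trait_type = c("quantitative", "binary"),
                               dialect = dialect_canonical(),
                               delim = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- setdiff(names(dialect_canonical()), "eaf")
  have <- dialect[names(dialect) %in% c(required, "eaf")]
  missing_map <- setdiff(required, names(have))
  if (length(missing_map) > 0) {
    abort_config(paste0("dialect does not map required column(s): ",
                        paste(missing_map, collapse = ", ")))
  }
  absent <- setdiff(unname(have[names(have) %in% required]), names(raw))
  if (length(absent) > 0) {
    abort_config(paste0("file '", path, "' is missing mapped column(s): ",
                        paste(absent, collapse = ", ")))
  }
  keep <- have[unname(have) %in% names(raw)]
  out <- raw[, unname(keep), drop = FALSE]
  names(out) <- names(keep)
  summary_stats(out, trait_label = trait_label, trait_type = trait_type,
                quiet = quiet)
}

#' Write summary statistics as canonical TSV
#'
#' Emits the canonical tab-separated dialect ([dialect_canonical()]), which
#' [read_summary_stats()] reads back without a dialect argument.
#'
#' @param x A `summary_stats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
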