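# GWAS summary-statistic tables: domain type, validation, readers and report
# writers. A `sumstats` object is a data.frame with one row per SNP and the
# canonical columns below, carrying the study identifier and trait type as
# attributes.

SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n", "n_case")
SUMSTATS_MANDATORY <- c("rsid", "effect_allele", "other_allele",
                        "beta", "se", "pval")

#' Construct a validated GWAS summary-statistics table
#'
#' One row per SNP with canonical columns `rsid`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#' `n_case`. Missing optional columns are filled with `NA`. Every row must
#' satisfy the per-SNP invariants (positive standard error, allele frequency
#' in \[0, 1\], distinct single-nucleotide alleles, p-value in (0, 1\],
#' sample size at least 1, case count no larger than the sample size);
#' violations raise an error naming the offending rows.
#'
#' @param df data.frame holding the columns above (optional ones may be
#'   absent).
#' @param trait_id study identifier string (e.g. a GWAS accession).
#' @param trait_type `"case_control"` or `"quantitative"`.
#' @param provenance free-text source note.
#' @return A `sumstats` object (data.frame subclass).
#' @export
sumstats <- function(df, trait_id = "trait", trait_type = c("case_control", "quantitative"),
                     provenance = NA_character_) {
  trait_type <- match.arg(trait_type)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMSTATS_MANDATORY, names(df))
  if (length(missing_cols)) {
    stop_tsmr("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "),
              class = "tsmr_config_error")
  }
  for (col in setdiff(SUMSTATS_COLS, names(df))) {
    df[[col]] <- if (col %in% c("rsid", "chrom")) NA_character_ else NA_real_
  }
  df <- df[SUMSTATS_COLS]
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  # Upstream sources print p = 0 for very strong associations; floor it so
  # downstream -log transforms stay finite.
  zero_p <- which(!is.na(df$pval) & df$pval == 0)
  if (length(zero_p)) {
    warning(sprintf("%d p-value(s) of 0 floored to 1e-300", length(zero_p)))
    df$pval[zero_p] <- 1e-300
  }

  dup <- unique(df$rsid[duplicated(df$rsid)])
  if (length(dup)) {
    stop_tsmr("duplicate rsid(s): %s", paste(dup, collapse = ", "),
              class = "tsmr_validation_error")
  }

  problems <- validate_snp_rows(df)
  if (length(problems)) {
    stop_tsmr("invalid summary-statistic rows:\n%s",
              paste(problems, collapse = "\n"), class = "tsmr_validation_error")
  }

  structure(df,
            trait_id = trait_id,
            trait_type = trait_type,
            provenance = provenance,
            class = c("sumstats", "data.frame"))
}

# Row-indexed invariant checks; returns a character vector of messages,
# empty when the table is clean.
validate_snp_rows <- function(df) {
  msgs <- character()
  bad <- function(idx, what) {
    if (length(idx)) {
      msgs <<- c(msgs, sprintf("row %d (%s): %s", idx, df$rsid[idx], what))
    }
  }
  nt <- c("A", "C", "G", "T")
  bad(which(is.na(df$rsid) | !nzchar(df$rsid)), "missing rsid")
  bad(which(!(df$effect_allele %in% nt)), "effect_allele not a single nucleotide A/C/G/T")
  bad(which(!(df$other_allele %in% nt)), "other_allele not a single nucleotide A/C/G/T")
  bad(which(df$effect_allele %in% nt & df$effect_allele == df$other_allele),
      "alleles identical")
  bad(which(is.na(df$beta)), "missing beta")
  bad(which(is.na(df$se) | df$se <= 0), "se not > 0")
  bad(which(is.na(df$pval) | df$pval <= 0 | df$pval > 1), "pval not in (0, 1]")
  bad(which(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)), "eaf not in [0, 1]")
  bad(which(!is.na(df$n) & df$n < 1), "n < 1")
  bad(which(!is.na(df$n_case) & !is.na(df$n) & df$n_case > df$n), "n_case > n")
  msgs
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a TSV with a header row and returns a validated [sumstats] table.
#' Non-canonical column names (e.g. `SNP`/`A1`/`A2`/`BETA`/`SE`/`P`) are
#' supported through `column_map`, a named character vector or list mapping
#' canonical names to the file's names, or the path to a YAML file holding
#' such a mapping.
#'
#' @param path path to a tab-separated text file, UTF-8, header required.
#' @param column_map optional mapping canonical -> file column name, or a
#'   YAML file path.
#' @param trait_id,trait_type,provenance passed to [sumstats()]; `trait_id`
#'   defaults to the file name.
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL,
                          trait_type = "case_control", provenance = NULL) {
  if (!file.exists(path)) {
    stop_tsmr("file not found: %s", path, class = "tsmr_config_error")
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(column_map) && length(column_map) == 1 && file.exists(column_map)) {
    column_map <- yaml::read_yaml(column_map)
  }
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      stop_tsmr("column_map refers to absent column(s): %s",
                paste(missing_src, collapse = ", "), class = "tsmr_config_error")
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  sumstats(raw,
           trait_id = trait_id %||% basename(path),
           trait_type = trait_type,
           provenance = provenance %||% path)
}

#' Write an MR / meta-analysis / colocalization report table
#'
#' Renders result rows to a tab-separated report with a fixed header per
#' layout. Odds ratios and confidence limits are rendered with 3 decimal
#' places and p-values with 3 significant digits, matching the published
#' table style, so reading the file back reproduces the values to rendered
#' precision.
#'
#' @param rows a data.frame of result rows: for layout `"mr"` columns
#'   `disease`, `outcome_id`, `exposure_id`, `method`, `nsnp`, `or`,
#'   `or_lci95`, `or_uci95`, `pval` (optionally `fdr_p`); for `"meta"` the
#'   columns of [meta_group()] output; for `"coloc"` the per-SNP table of a
#'   [coloc_abf()] fit.
#' @param path output file path.
#' @param layout one of `"mr"`, `"meta"`, `"coloc"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, layout = c("mr", "meta", "coloc")) {
  layout <- match.arg(layout)
  rows <- as.data.frame(rows)
  if (!nrow(rows)) stop_tsmr("no rows to write", class = "tsmr_validation_error")

  num3 <- function(x) ifelse(is.na(x), NA, formatC(x, format = "f", digits = 3))
  sig3 <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 3))

  cols <- switch(layout,
    mr = c("disease", "outcome_id", "exposure_id", "method", "nsnp",
           "or", "or_lci95", "or_uci95", "pval", "fdr_p"),
    meta = c("disease", "exposure_id", "k_studies",
             "fixed_or", "fixed_lci", "fixed_uci", "fixed_p",
             "random_or", "random_lci", "random_uci", "random_p",
             "q_stat", "tau2", "i2", "sensitivity_p"),
    coloc = c("SNP", "V.df1", "z.df1", "r.df1", "lABF.df1",
              "V.df2", "z.df2", "r.df2", "lABF.df2",
              "internal.sum.lABF", "SNP.PP.H4"))
  for (col in setdiff(cols, names(rows))) rows[[col]] <- NA
  out <- rows[cols]

  or_cols <- switch(layout,
    mr = c("or", "or_lci95", "or_uci95"),
    meta = c("fixed_or", "fixed_lci", "fixed_uci", "random_or", "random_lci", "random_uci"),
    coloc = character())
  p_cols <- switch(layout,
    mr = c("pval", "fdr_p"),
    meta = c("fixed_p", "random_p", "q_stat", "tau2", "i2", "sensitivity_p"),
    coloc = character())
  for (col in or_cols) out[[col]] <- num3(out[[col]])
  for (col in p_cols) out[[col]] <- sig3(out[[col]])
  if (layout == "coloc") {
    # Bayes factors need more precision than report ORs; 9 significant
    # digits matches the published table style.
    for (col in setdiff(cols, "SNP")) {
      out[[col]] <- formatC(as.numeric(out[[col]]), format = "g", digits = 9)
    }
  }

  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
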