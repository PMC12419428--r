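# Instrument selection, LD clumping, and exposure/outcome harmonization.

#' Select instrumental variables from an exposure GWAS
#'
#' Keeps SNPs associated with the exposure below a significance threshold
#' (default `5e-6`, the relaxed genome-wide threshold used when few variants
#' reach `5e-8`) and not named on a confounder exclusion list (the offline
#' stand-in for PhenoScanner-style confounder lookups). Input order is
#' preserved and per-filter attrition counts are recorded.
#'
#' @param exposure a [sumstats] table.
#' @param p_threshold association p-value cutoff in (0, 1).
#' @param exclusion_list character vector of rsids to drop, or a path to a
#'   text file with one rsid per line (`#` comments allowed).
#' @return The filtered [sumstats] table with an `attrition` attribute
#'   (counts at each filter) and a `removed` attribute (rsid + reason).
#' @export
select_instruments <- function(exposure, p_threshold = 5e-6,
                               exclusion_list = character()) {
  stopifnot(inherits(exposure, "sumstats"),
            p_threshold > 0, p_threshold < 1)
  if (is.character(exclusion_list) && length(exclusion_list) == 1 &&
      file.exists(exclusion_list)) {
    lines <- trimws(readLines(exclusion_list))
    lines <- sub("#.*$", "", lines)
    exclusion_list <- trimws(lines[nzchar(trimws(lines))])
  }

  sig <- exposure$pval < p_threshold
  confounder <- sig & exposure$rsid %in% exclusion_list
  keep <- sig & !confounder

  removed <- data.frame(
    rsid = c(exposure$rsid[!sig], exposure$rsid[confounder]),
    reason = c(rep("above_threshold", sum(!sig)),
               rep("confounder", sum(confounder))),
    stringsAsFactors = FALSE)
  attrition <- c(input = nrow(exposure),
                 below_threshold = sum(sig),
                 confounder_excluded = sum(confounder),
                 kept = sum(keep))
  message(sprintf(
    "select_instruments [%s]: %d input, %d below p<%g, %d confounder-excluded, %d kept",
    attr(exposure, "trait_id"), attrition[["input"]],
    attrition[["below_threshold"]], p_threshold,
    attrition[["confounder_excluded"]], attrition[["kept"]]))
  if (!any(keep)) {
    stop_tsmr(
      "no instruments survive: %d/%d below p<%g, of which %d confounder-excluded",
      sum(sig), nrow(exposure), p_threshold, sum(confounder),
      class = "tsmr_empty_instruments")
  }
  out <- exposure[keep, , drop = FALSE]
  attr(out, "attrition") <- attrition
  attr(out, "removed") <- removed
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Candidates are sorted by ascending p-value (ties broken by chromosome,
#' position, then rsid, so the result is independent of input row order) and
#' accepted greedily: a SNP is kept iff its squared correlation with every
#' already-accepted SNP on the same chromosome within `window_kb` is below
#' `r2_threshold`. Defaults mirror the conventional stringent clumping
#' settings (r^2 < 0.001 within 10,000 kb).
#'
#' @param candidates a [sumstats] table.
#' @param ld square matrix of squared correlations (r^2) with rsid dimnames
#'   covering the candidates, or a path to a TSV with an rsid header
#'   row/column.
#' @param r2_threshold r^2 cutoff.
#' @param window_kb distance window in kb beyond which SNPs are treated as
#'   independent.
#' @return The clumped [sumstats] table in canonical (p-value) order.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(candidates, "sumstats"))
  if (is.character(ld) && length(ld) == 1) ld <- read_ld_matrix(ld)
  ld <- as.matrix(ld)
  if (nrow(ld) != ncol(ld) || is.null(rownames(ld)) ||
      !all(candidates$rsid %in% rownames(ld))) {
    stop_tsmr("LD matrix must be square with rsid dimnames covering all candidates",
              class = "tsmr_config_error")
  }
  ld <- ld[candidates$rsid, candidates$rsid, drop = FALSE]

  ord <- order(candidates$pval, candidates$chrom, candidates$pos,
               candidates$rsid)
  x <- candidates[ord, , drop = FALSE]
  accepted <- integer()
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    for (j in accepted) {
      same_chr <- !is.na(x$chrom[i]) && !is.na(x$chrom[j]) &&
        x$chrom[i] == x$chrom[j]
      in_window <- same_chr && !is.na(x$pos[i]) && !is.na(x$pos[j]) &&
        abs(x$pos[i] - x$pos[j]) / 1000 <= window_kb
      if (in_window && ld[x$rsid[i], x$rsid[j]] >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  x[accepted, , drop = FALSE]
}

#' Read a square LD matrix from a TSV with rsid header row and column
#' @param path file path.
#' @return numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          row.names = 1)
  as.matrix(df)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1] == a2)

#' Harmonize exposure and outcome summary statistics to a common effect
#' allele
#'
#' Inner-joins the two tables on rsid and aligns every outcome effect to the
#' exposure's effect allele: swapped alleles negate `beta_y` and flip
#' `eaf_y`; strand-complemented alleles are complemented then aligned.
#' Palindromic SNPs (A/T or C/G), whose strand cannot be resolved from
#' alleles alone, are kept only when both allele frequencies fall outside
#' the ambiguity band `[palindromic_eaf_limit, 1 - palindromic_eaf_limit]`
#' and agree in direction (both minor or both major); otherwise they are
#' removed with reason `"palindromic"`. Irreconcilable allele sets are
#' removed with reason `"allele_mismatch"`.
#'
#' @param exposure,outcome [sumstats] tables.
#' @param palindromic_eaf_limit lower edge of the frequency ambiguity band
#'   (default 0.42, i.e. band 0.42-0.58).
#' @return A `harmonized` object: list with `exposure_id`, `outcome_id`,
#'   `pairs` (aligned per-SNP effects) and `removed` (rsid + reason).
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (!length(shared)) {
    stop_tsmr("no shared rsids between exposure and outcome",
              class = "tsmr_empty_join")
  }
  ex <- exposure[match(shared, exposure$rsid), ]
  ou <- outcome[match(shared, outcome$rsid), ]

  n <- length(shared)
  beta_y <- ou$beta
  eaf_y <- ou$eaf
  status <- character(n) # "" = keep

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]

    if (is_palindromic(ea_x, oa_x)) {
      # A/T and C/G SNPs: alleles cannot distinguish strand; use allele
      # frequencies, and only when both are clearly away from 0.5.
      aligned_same <- ea_y == ea_x && oa_y == oa_x
      aligned_swap <- ea_y == oa_x && oa_y == ea_x
      if (!aligned_same && !aligned_swap) {
        status[i] <- "allele_mismatch"
        next
      }
      fx <- ex$eaf[i]
      fy <- ou$eaf[i]
      if (aligned_swap && !is.na(fy)) fy <- 1 - fy
      band_lo <- palindromic_eaf_limit
      band_hi <- 1 - palindromic_eaf_limit
      unambiguous <- !is.na(fx) && !is.na(fy) &&
        (fx < band_lo || fx > band_hi) && (fy < band_lo || fy > band_hi) &&
        ((fx < 0.5) == (fy < 0.5))
      if (!unambiguous) {
        status[i] <- "palindromic"
        next
      }
      if (aligned_swap) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- if (is.na(eaf_y[i])) NA else 1 - eaf_y[i]
      }
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {
      # already aligned
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- if (is.na(eaf_y[i])) NA else 1 - eaf_y[i]
    } else {
      cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
      if (cea == ea_x && coa == oa_x) {
        # other strand, same orientation
      } else if (cea == oa_x && coa == ea_x) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- if (is.na(eaf_y[i])) NA else 1 - eaf_y[i]
      } else {
        status[i] <- "allele_mismatch"
      }
    }
  }

  keep <- status == ""
  if (!any(keep)) {
    stop_tsmr("all %d shared SNPs removed during harmonization", n,
              class = "tsmr_empty_join")
  }
  pairs <- data.frame(
    rsid = shared[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = beta_y[keep], se_y = ou$se[keep],
    eaf_x = ex$eaf[keep], eaf_y = eaf_y[keep],
    pval_x = ex$pval[keep], pval_y = ou$pval[keep],
    n_x = ex$n[keep], n_y = ou$n[keep],
    stringsAsFactors = FALSE)
  removed <- data.frame(rsid = shared[!keep], reason = status[!keep],
                        stringsAsFactors = FALSE)
  structure(list(exposure_id = attr(exposure, "trait_id"),
                 outcome_id = attr(outcome, "trait_id"),
                 pairs = pairs, removed = removed),
            class = "harmonized")
}

#' @export
print.harmonized <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s; %d SNPs kept, %d removed\n",
              x$exposure_id, x$outcome_id, nrow(x$pairs), nrow(x$removed)))
  if (nrow(x$removed)) {
    print(table(x$removed$reason))
  }
  invisible(x)
}

# Internal constructor used by tests and simulators to build a harmonized
# set directly from aligned effect vectors.
harmonized_set <- function(beta_x, se_x, beta_y, se_y,
                           rsid = sprintf("rs%06d", seq_along(beta_x)),
                           n_x = NA_real_, n_y = NA_real_,
                           exposure_id = "exposure", outcome_id = "outcome") {
  structure(list(
    exposure_id = exposure_id, outcome_id = outcome_id,
    pairs = data.frame(rsid = rsid, effect_allele = "A", other_allele = "G",
                       beta_x = beta_x, se_x = se_x,
                       beta_y = beta_y, se_y = se_y,
                       eaf_x = NA_real_, eaf_y = NA_real_,
                       pval_x = p_normal(beta_x, se_x),
                       pval_y = p_normal(beta_y, se_y),
                       n_x = n_x, n_y = n_y, stringsAsFactors = FALSE),
    removed = data.frame(rsid = character(), reason = character(),
                         stringsAsFactors = FALSE)),
    class = "harmonized")
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies where exposure and outcome
#' effects are already expressed on a common effect allele.
#'
#' @param beta_x,se_x,beta_y,se_y aligned per-SNP effects and standard errors.
#' @param rsid optional SNP identifiers.
#' @param n_x,n_y optional sample sizes (needed for Steiger directionality).
#' @param exposure_id,outcome_id labels.
#' @return A `harmonized` object.
#' @export
as_harmonized <- function(beta_x, se_x, beta_y, se_y,
                          rsid = sprintf("rs%06d", seq_along(beta_x)),
                          n_x = NA_real_, n_y = NA_real_,
                          exposure_id = "exposure", outcome_id = "outcome") {
  stopifnot(length(beta_x) == length(beta_y), all(se_x > 0), all(se_y > 0))
  harmonized_set(beta_x, se_x, beta_y, se_y, rsid, n_x, n_y,
                 exposure_id, outcome_id)
}
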