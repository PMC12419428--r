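# Sensitivity battery: Cochran's Q heterogeneity, MR-Egger intercept
# (surfaced from mr_egger, its single source of truth), Steiger
# directionality, leave-one-out influence, and grouped Benjamini-Hochberg
# FDR adjustment.

#' Cochran's Q heterogeneity test over per-SNP ratios (or per-study effects)
#'
#' `Q = sum(w_j (x_j - x_ivw)^2)` with inverse-variance weights; p-value
#' from the upper tail of a chi-square with k-1 degrees of freedom; I^2 is
#' the proportion-of-variance restatement `max(0, (Q - df)/Q)`.
#'
#' @param ratio,ratio_se per-unit estimates and standard errors (k >= 2).
#' @return List with `q_stat`, `q_df`, `q_pval`, `i2`.
#' @export
cochran_q <- function(ratio, ratio_se) {
  k <- length(ratio)
  if (k < 2) stop_tsmr("Cochran's Q needs >= 2 estimates", class = "tsmr_degenerate")
  stopifnot(length(ratio_se) == k, all(ratio_se > 0))
  w <- 1 / ratio_se^2
  center <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - center)^2)
  list(q_stat = q, q_df = k - 1,
       q_pval = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0)
}

#' Steiger directionality test
#'
#' Checks that the instruments explain more variance in the exposure than in
#' the outcome (guarding against reverse causation). Per SNP the variance
#' explained is approximated by `r2 = z^2 / (z^2 + n)`; the per-trait sums
#' are compared, and a p-value comes from the two-sided normal test on the
#' difference of Fisher-z-transformed pooled correlations,
#' `(atanh(r_x) - atanh(r_y)) / sqrt(1/(n_x-3) + 1/(n_y-3))`.
#'
#' @param h a `harmonized` object with sample sizes on both sides.
#' @return List with `direction` (`TRUE` when the exposure explains more
#'   variance; ties are `FALSE`) and `steiger_pval`.
#' @export
steiger_direction <- function(h) {
  p <- h$pairs
  if (anyNA(p$n_x) || anyNA(p$n_y)) {
    stop_tsmr(paste("Steiger test needs per-SNP sample sizes; supply n_x/n_y",
                    "via the sumstats `n` column or as_harmonized(n_x=, n_y=)"),
              class = "tsmr_config_error")
  }
  zx <- p$beta_x / p$se_x
  zy <- p$beta_y / p$se_y
  r2x <- zx^2 / (zx^2 + p$n_x)
  r2y <- zy^2 / (zy^2 + p$n_y)
  rx <- sqrt(min(sum(r2x), 1 - 1e-12))
  ry <- sqrt(min(sum(r2y), 1 - 1e-12))
  nx <- mean(p$n_x)
  ny <- mean(p$n_y)
  z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
  list(direction = sum(r2x) > sum(r2y),
       steiger_pval = 2 * stats::pnorm(-abs(z)))
}

#' Leave-one-out IVW analysis
#'
#' Re-fits the IVW estimator k times, each omitting one SNP, and flags as
#' influential any SNP whose omission flips the sign of the estimate or
#' moves the p-value across `alpha`.
#'
#' @param h a `harmonized` object with at least 3 SNPs.
#' @param alpha significance level used for the influence flag.
#' @param effects_model IVW effects model for the re-fits.
#' @return List with `loo` (data.frame: omitted rsid, beta, se, pval) and
#'   `influential` (character vector of rsids).
#' @export
leave_one_out <- function(h, alpha = 0.05, effects_model = "fixed") {
  k <- nrow(h$pairs)
  if (k < 3) stop_tsmr("leave-one-out needs >= 3 SNPs", class = "tsmr_degenerate")
  full <- mr_ivw(h, effects_model)
  loo <- do.call(rbind, lapply(seq_len(k), function(i) {
    hi <- h
    hi$pairs <- h$pairs[-i, , drop = FALSE]
    e <- mr_ivw(hi, effects_model)
    data.frame(rsid = h$pairs$rsid[i], beta = e$beta, se = e$se,
               pval = e$pval, stringsAsFactors = FALSE)
  }))
  flips_sign <- sign(loo$beta) != sign(full$beta)
  crosses_alpha <- (loo$pval < alpha) != (full$pval < alpha)
  list(loo = loo, influential = loo$rsid[flips_sign | crosses_alpha])
}

#' Benjamini-Hochberg FDR adjustment within groups
#'
#' Step-up adjustment applied independently within each group of tests
#' (e.g. all exposure-method tests sharing one outcome dataset), returning
#' adjusted p-values in the input order.
#'
#' @param pvals p-values in (0, 1].
#' @param grouping factor/vector partitioning the tests; `NULL` treats all
#'   p-values as one family.
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
bh_adjust <- function(pvals, grouping = NULL) {
  if (!length(pvals)) stop_tsmr("empty p-value set", class = "tsmr_degenerate")
  stopifnot(all(pvals > 0 & pvals <= 1))
  if (is.null(grouping)) grouping <- rep(1L, length(pvals))
  stopifnot(length(grouping) == length(pvals))
  out <- numeric(length(pvals))
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    out[idx] <- stats::p.adjust(pvals[idx], method = "BH")
  }
  out
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q (+ I^2), the MR-Egger intercept test, the Steiger
#' directionality test (when sample sizes are available), and the
#' leave-one-out influence analysis.
#'
#' @param h a `harmonized` object.
#' @param alpha significance level for the influence flag.
#' @return An object of class `mr_sensitivity`.
#' @export
mr_sensitivity <- function(h, alpha = 0.05) {
  wr <- wald_ratios(h)
  q <- cochran_q(wr$ratio, wr$ratio_se)
  egger <- if (nrow(h$pairs) >= 3) mr_egger(h)$extra else NULL
  steiger <- tryCatch(steiger_direction(h), error = function(e) NULL)
  loo <- if (nrow(h$pairs) >= 3) leave_one_out(h, alpha) else NULL
  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval, i2 = q$i2,
    egger_intercept = egger$intercept,
    egger_intercept_se = egger$intercept_se,
    egger_intercept_p = egger$intercept_p,
    steiger_direction = steiger$direction,
    steiger_pval = steiger$steiger_pval,
    loo = loo$loo, influential = loo$influential),
    class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf("Heterogeneity: Q = %.3f (df %d), p = %.3g, I2 = %.1f%%\n",
              x$q_stat, x$q_df, x$q_pval, 100 * x$i2))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept: %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  if (!is.null(x$steiger_direction)) {
    cat(sprintf("Steiger direction: %s (p = %.3g)\n",
                x$steiger_direction, x$steiger_pval))
  }
  if (!is.null(x$loo)) {
    cat(sprintf("Leave-one-out: %d refits, influential: %s\n",
                nrow(x$loo),
                if (length(x$influential)) paste(x$influential, collapse = ", ")
                else "none"))
  }
  invisible(x)
}
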