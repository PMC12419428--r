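# ROC curves, AUC and confidence intervals for candidate-gene
# discrimination. Curve construction and CIs are delegated to pROC; the
# result is repackaged with the fields downstream reporting needs. Scores
# are never direction-flipped automatically: an AUC below 0.5 is reported
# as computed (silent flipping would hide label errors), with an advisory
# message.

roc_object <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop_tsmr("both classes must be present", class = "tsmr_validation_error")
  }
  stopifnot(all(labels %in% c(0L, 1L)), length(scores) == length(labels))
  pROC::roc(response = labels, predictor = as.numeric(scores),
            levels = c(0, 1), direction = "<", quiet = TRUE)
}

#' ROC curve for a score vector against binary labels
#'
#' Thresholds sit at the unique observed scores plus infinite sentinels;
#' tied scores are grouped at one threshold. Cases are labelled 1, controls
#' 0, and higher scores are treated as more case-like.
#'
#' @param scores per-sample numeric scores.
#' @param labels binary labels (1 = case, 0 = control).
#' @return An object of class `roc_result` with `thresholds` (descending),
#'   `tpr`, `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  r <- roc_object(scores, labels)
  ord <- order(r$thresholds, decreasing = TRUE)
  structure(list(thresholds = r$thresholds[ord],
                 tpr = r$sensitivities[ord],
                 fpr = 1 - r$specificities[ord],
                 auc = as.numeric(r$auc),
                 ci_low = NA_real_, ci_high = NA_real_, method = NA_character_,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
            class = "roc_result")
}

#' AUC with a 95% confidence interval
#'
#' The AUC equals the Mann-Whitney statistic (ties counted 0.5), i.e. the
#' probability that a random case scores above a random control, and the
#' trapezoidal area under the ROC curve. The default CI is DeLong's
#' paired-placement variance; a stratified percentile bootstrap is
#' available (and is fallen back to, with a warning, when either group has
#' fewer than 2 samples). An AUC above 0.6 is flagged as discriminative,
#' the working threshold for calling a marker diagnostic.
#'
#' @param scores per-sample numeric scores.
#' @param labels binary labels (1 = case, 0 = control).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param auc_flag_threshold AUC level above which the `discriminative`
#'   flag is set (default 0.6).
#' @return An object of class `roc_result` with the curve fields plus
#'   `ci_low`, `ci_high`, `method`, `discriminative`.
#' @export
auc_with_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                        n_boot = 2000, seed = NULL,
                        auc_flag_threshold = 0.6) {
  method <- match.arg(method)
  out <- roc_curve(scores, labels)
  if (method == "delong" && (out$n_pos < 2 || out$n_neg < 2)) {
    warning("fewer than 2 samples in a class; falling back to bootstrap CI")
    method <- "bootstrap"
  }
  r <- roc_object(scores, labels)
  ci <- with_seed(seed, {
    if (method == "delong") {
      pROC::ci.auc(r, method = "delong")
    } else {
      pROC::ci.auc(r, method = "bootstrap", boot.n = n_boot,
                   boot.stratified = TRUE)
    }
  })
  out$ci_low <- max(0, as.numeric(ci[1]))
  out$ci_high <- min(1, as.numeric(ci[3]))
  out$method <- method
  out$discriminative <- out$auc > auc_flag_threshold
  if (out$auc < 0.5) {
    message(sprintf(
      "AUC %.3f < 0.5: scores run opposite to the case labels (not flipped)",
      out$auc))
  }
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d cases vs %d controls; AUC = %.3f", x$n_pos, x$n_neg,
              x$auc))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" [95%% CI %.3f-%.3f, %s]", x$ci_low, x$ci_high, x$method))
  }
  cat("\n")
  if (!is.null(x$discriminative)) {
    cat(sprintf("Discriminative (AUC > 0.6): %s\n", x$discriminative))
  }
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Per-gene ROC evaluation of an expression matrix
#'
#' Runs [auc_with_ci()] on each requested gene row of a genes-by-samples
#' matrix.
#'
#' @param mat numeric matrix, genes in rows, samples in columns.
#' @param labels binary labels per sample (1 = case).
#' @param genes gene names to evaluate (default: all rows).
#' @param ... passed to [auc_with_ci()].
#' @return data.frame with one row per gene: `gene`, `auc`, `ci_low`,
#'   `ci_high`, `discriminative`.
#' @export
roc_genes <- function(mat, labels, genes = rownames(mat), ...) {
  missing_g <- setdiff(genes, rownames(mat))
  if (length(missing_g)) {
    stop_tsmr("gene(s) not in matrix: %s", paste(missing_g, collapse = ", "),
              class = "tsmr_config_error")
  }
  do.call(rbind, lapply(genes, function(g) {
    r <- auc_with_ci(mat[g, ], labels, ...)
    data.frame(gene = g, auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
               discriminative = r$discriminative, stringsAsFactors = FALSE)
  }))
}
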