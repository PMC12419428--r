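# Two-sample MR estimators. The per-SNP Wald ratio is the shared primitive;
# the five reported methods (IVW, MR-Egger, weighted median, simple mode,
# weighted mode) combine the ratios in different ways. `mr_fit()` is the
# model-fitting entry point and returns a classed object with the usual
# print/summary/coef/confint/plot methods.

#' Per-SNP Wald ratios
#'
#' The causal-effect estimate contributed by one SNP is the outcome effect
#' divided by the exposure effect; its first-order standard error is
#' `se_y / |beta_x|` (exposure-side uncertainty ignored, the conventional
#' default).
#'
#' @param h a `harmonized` object (see [harmonize()], [as_harmonized()]).
#' @return data.frame with `rsid`, `ratio`, `ratio_se`.
#' @export
wald_ratios <- function(h) {
  p <- h$pairs
  zero <- p$rsid[p$beta_x == 0]
  if (length(zero)) {
    stop_tsmr("zero exposure effect for: %s", paste(zero, collapse = ", "),
              class = "tsmr_degenerate")
  }
  data.frame(rsid = p$rsid,
             ratio = p$beta_y / p$beta_x,
             ratio_se = p$se_y / abs(p$beta_x),
             stringsAsFactors = FALSE)
}

mr_estimate <- function(method, nsnp, beta, se, pval, extra = list()) {
  structure(list(method = method, nsnp = nsnp, beta = beta, se = se,
                 pval = pval,
                 or = exp(beta),
                 or_lci95 = exp(beta - Z975 * se),
                 or_uci95 = exp(beta + Z975 * se),
                 extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (nsnp = %d): beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$nsnp, x$beta, x$se, x$or, x$or_lci95, x$or_uci95,
              x$pval))
  invisible(x)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted average of the Wald ratios with weights `1/ratio_se^2`. The
#' fixed-effect standard error is `sqrt(1/sum(w))`; the (multiplicative)
#' random-effects standard error inflates it by
#' `sqrt(max(1, Q/(k-1)))` where Q is Cochran's heterogeneity statistic.
#' `effects_model = "auto"` follows the conventional switching rule: random
#' effects iff the heterogeneity p-value is below 0.05.
#'
#' @param h a `harmonized` object with at least 2 SNPs ([wald_ratio_fit()]
#'   covers the single-SNP case).
#' @param effects_model `"fixed"`, `"random"`, or `"auto"`.
#' @return An `mr_estimate`; `extra` carries Q, its d.f. and p-value, and
#'   the effects model actually used.
#' @export
mr_ivw <- function(h, effects_model = c("fixed", "random", "auto")) {
  effects_model <- match.arg(effects_model)
  wr <- wald_ratios(h)
  k <- nrow(wr)
  if (k < 2) {
    stop_tsmr("IVW needs >= 2 SNPs (got %d); use wald_ratio_fit()", k,
              class = "tsmr_degenerate")
  }
  w <- 1 / wr$ratio_se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (wr$ratio - beta)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  used <- switch(effects_model,
                 fixed = "fixed",
                 random = "random",
                 auto = if (q_p < 0.05) "random" else "fixed")
  se <- if (used == "random") se_fixed * sqrt(max(1, q / (k - 1))) else se_fixed
  mr_estimate(if (used == "random") "IVW_random" else "IVW_fixed",
              k, beta, se, p_normal(beta, se),
              extra = list(q_stat = q, q_df = k - 1, q_pval = q_p,
                           effects_model = used))
}

#' Single-SNP Wald-ratio estimate
#' @param h a `harmonized` object with exactly 1 SNP.
#' @return An `mr_estimate` of method `"WaldRatio"`.
#' @export
wald_ratio_fit <- function(h) {
  wr <- wald_ratios(h)
  stopifnot(nrow(wr) == 1)
  mr_estimate("WaldRatio", 1L, wr$ratio, wr$ratio_se,
              p_normal(wr$ratio, wr$ratio_se))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1/se_y^2`, after orienting every pair so the
#' exposure effect is positive (negating both effects on a flip, as the
#' estimator requires). The slope is the causal estimate; the intercept
#' estimates average directional pleiotropy. Standard errors use the WLS
#' residual dispersion `RSS_w/(k-2)` (not floored) and p-values come from a
#' t distribution with k-2 degrees of freedom.
#'
#' @param h a `harmonized` object with at least 3 SNPs.
#' @return An `mr_estimate`; `extra` carries `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
mr_egger <- function(h) {
  p <- h$pairs
  k <- nrow(p)
  if (k < 3) {
    stop_tsmr("MR-Egger needs >= 3 SNPs (got %d)", k, class = "tsmr_degenerate")
  }
  if (any(p$beta_x == 0)) {
    stop_tsmr("MR-Egger requires nonzero exposure effects",
              class = "tsmr_degenerate")
  }
  s <- sign(p$beta_x)
  bx <- s * p$beta_x
  by <- s * p$beta_y
  fit <- stats::lm(by ~ bx, weights = 1 / p$se_y^2)
  cf <- summary(fit)$coefficients
  mr_estimate("Egger", k,
              beta = cf["bx", "Estimate"], se = cf["bx", "Std. Error"],
              pval = cf["bx", "Pr(>|t|)"],
              extra = list(intercept = cf["(Intercept)", "Estimate"],
                           intercept_se = cf["(Intercept)", "Std. Error"],
                           intercept_p = cf["(Intercept)", "Pr(>|t|)"]))
}

# Weighted median of `x` with weights `w`: linear interpolation of the
# ordered values at standardized cumulative weight 0.5.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(wr, point_fun, n_boot, seed) {
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      r <- stats::rnorm(nrow(wr), wr$ratio, wr$ratio_se)
      point_fun(r)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' Inverse-variance weighted median of the Wald ratios: the ordered ratios
#' are interpolated at standardized cumulative weight 0.5. Consistent when
#' at least half the weight comes from valid instruments. The standard
#' error is the SD of the estimate over parametric-bootstrap resamples
#' (`ratio_j ~ Normal(ratio_j, ratio_se_j^2)`).
#'
#' @param h a `harmonized` object with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (reported tables should be
#'   reproducible).
#' @return An `mr_estimate`; `extra` carries `n_boot`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  wr <- wald_ratios(h)
  k <- nrow(wr)
  if (k < 3) {
    stop_tsmr("weighted median needs >= 3 SNPs (got %d)", k,
              class = "tsmr_degenerate")
  }
  w <- 1 / wr$ratio_se^2
  beta <- weighted_median_point(wr$ratio, w)
  se <- boot_se(wr, function(r) weighted_median_point(r, w), n_boot, seed)
  mr_estimate("WeightedMedian", k, beta, se, p_normal(beta, se),
              extra = list(n_boot = n_boot))
}

# Kernel-density mode of the ratios; Silverman-type bandwidth scaled by phi.
mode_point <- function(ratio, w, phi) {
  k <- length(ratio)
  spread <- min(stats::sd(ratio), stats::IQR(ratio) / 1.349)
  bw <- phi * 0.9 * spread * k^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[1]) # all ratios identical
  d <- stats::density(ratio, weights = w / sum(w), bw = bw, n = 512,
                      from = min(ratio) - 3 * bw, to = max(ratio) + 3 * bw,
                      kernel = "gaussian")
  d$x[which.max(d$y)]
}

#' Mode-based estimator (simple or weighted)
#'
#' The estimate is the mode of a Gaussian kernel density over the Wald
#' ratios, evaluated on a 512-point grid spanning the data range plus three
#' bandwidths. The bandwidth is `phi * 0.9 * min(SD, IQR/1.349) * k^(-1/5)`
#' (Silverman-type). The simple mode weights every ratio equally; the
#' weighted mode uses inverse-variance weights. Consistent when the largest
#' group of instruments sharing an effect (plurality) is valid. Standard
#' error by parametric bootstrap as in [mr_weighted_median()].
#'
#' @param h a `harmonized` object with at least 3 SNPs.
#' @param weighted use inverse-variance weights?
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return An `mr_estimate`; `extra` carries `phi` and `n_boot`.
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = NULL) {
  wr <- wald_ratios(h)
  k <- nrow(wr)
  if (k < 3) {
    stop_tsmr("mode estimator needs >= 3 SNPs (got %d)", k,
              class = "tsmr_degenerate")
  }
  w <- if (weighted) 1 / wr$ratio_se^2 else rep(1, k)
  beta <- mode_point(wr$ratio, w, phi)
  se <- boot_se(wr, function(r) mode_point(r, w, phi), n_boot, seed)
  mr_estimate(if (weighted) "WeightedMode" else "SimpleMode",
              k, beta, se, p_normal(beta, se),
              extra = list(phi = phi, n_boot = n_boot))
}

#' Fit the two-sample Mendelian randomization model
#'
#' Runs every estimator whose instrument-count minimum is met on a
#' harmonized exposure/outcome set: the single-SNP Wald ratio (k = 1), IVW
#' (k >= 2), and MR-Egger, weighted median, simple mode and weighted mode
#' (k >= 3). Primary inference is the IVW estimate at level `alpha`. All
#' estimates are reported as odds ratios with 95% confidence intervals
#' (`exp(beta +/- 1.959964 se)`).
#'
#' @param h a `harmonized` object.
#' @param effects_model IVW effects model; `"auto"` (default) switches to
#'   multiplicative random effects when Cochran's Q has p < 0.05.
#' @param alpha significance level for the primary (IVW) inference flag.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed for the bootstraps.
#' @param methods subset of
#'   `c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")`.
#' @return An object of class `mr_fit`.
#' @examples
#' sim <- simulate_mr_pair(n_snps = 20, theta = 0.3, seed = 1)
#' h <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(h, seed = 1)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(h, effects_model = "auto", alpha = 0.05, n_boot = 1000,
                   seed = NULL,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_mode", "weighted_mode")) {
  stopifnot(inherits(h, "harmonized"))
  k <- nrow(h$pairs)
  if (k < 1) stop_tsmr("empty harmonized set", class = "tsmr_degenerate")
  ests <- list()
  if (k == 1) {
    ests$wald <- wald_ratio_fit(h)
  } else {
    if ("ivw" %in% methods) ests$ivw <- mr_ivw(h, effects_model)
    if (k >= 3) {
      if ("egger" %in% methods) ests$egger <- mr_egger(h)
      if ("weighted_median" %in% methods) {
        ests$weighted_median <- mr_weighted_median(h, n_boot, seed)
      }
      if ("simple_mode" %in% methods) {
        ests$simple_mode <- mr_mode(h, weighted = FALSE, n_boot = n_boot,
                                    seed = seed)
      }
      if ("weighted_mode" %in% methods) {
        ests$weighted_mode <- mr_mode(h, weighted = TRUE, n_boot = n_boot,
                                      seed = seed)
      }
    }
  }
  primary <- ests$ivw %||% ests$wald
  structure(list(estimates = ests, data = h, alpha = alpha,
                 primary = primary$method,
                 significant = primary$pval < alpha,
                 nsnp = k, seed = seed),
            class = "mr_fit")
}

mr_fit_table <- function(fit) {
  do.call(rbind, lapply(fit$estimates, function(e) {
    data.frame(method = e$method, nsnp = e$nsnp, beta = e$beta, se = e$se,
               pval = e$pval, or = e$or, or_lci95 = e$or_lci95,
               or_uci95 = e$or_uci95, stringsAsFactors = FALSE)
  }))
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d SNPs)\n",
              x$data$exposure_id, x$data$outcome_id, x$nsnp))
  tab <- mr_fit_table(x)
  tab[c("beta", "se", "or", "or_lci95", "or_uci95")] <-
    lapply(tab[c("beta", "se", "or", "or_lci95", "or_uci95")], round,
           digits = digits)
  tab$pval <- signif(tab$pval, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Primary inference (%s): %s at alpha = %g\n", x$primary,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  tab <- mr_fit_table(object)
  stats::setNames(tab$beta, tab$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- mr_fit_table(object)
  out <- cbind(tab$beta - z * tab$se, tab$beta + z * tab$se)
  dimnames(out) <- list(tab$method,
                        sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object, table = mr_fit_table(object),
                 sensitivity = tryCatch(mr_sensitivity(object$data,
                                                       alpha = object$alpha),
                                        error = function(e) NULL)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$sensitivity)) print(x$sensitivity)
  invisible(x)
}

#' Scatter plot of outcome against exposure effects with estimator lines
#' @param x an `mr_fit` object.
#' @param ... passed to [plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$data$pairs
  s <- sign(p$beta_x)
  bx <- s * p$beta_x
  by <- s * p$beta_y
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 main = sprintf("%s -> %s", x$data$exposure_id,
                                x$data$outcome_id), ...)
  graphics::segments(bx, by - Z975 * p$se_y, bx, by + Z975 * p$se_y,
                     col = "grey70")
  cols <- stats::setNames(seq_along(x$estimates) + 1, names(x$estimates))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    intercept <- if (e$method == "Egger") e$extra$intercept else 0
    graphics::abline(intercept, e$beta, col = cols[[nm]], lty = 2)
  }
  graphics::legend("topleft",
                   legend = vapply(x$estimates, `[[`, "", "method"),
                   col = cols, lty = 2, cex = 0.8, bty = "n")
  invisible(x)
}
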