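# Meta-analysis of per-study MR estimates within disease groups: inverse-
# variance fixed-effect pooling and DerSimonian-Laird random effects, on the
# log odds-ratio scale throughout (exponentiated only for display).

#' Recover a log-OR and its standard error from a reported OR and CI
#'
#' Published MR tables report odds ratios with 95% confidence limits;
#' pooling needs the effect on the log scale with a standard error:
#' `log_or = log(or)` and `se = (log(uci) - log(lci)) / (2 * 1.959964)`.
#'
#' @param or_,lci,uci odds ratio and its confidence limits
#'   (`0 < lci <= or_ <= uci`, `lci < uci`).
#' @param level confidence level of the interval (default 0.95).
#' @return List with `log_or`, `se`, `source = "from_ci"`.
#' @export
ci_to_logse <- function(or_, lci, uci, level = 0.95) {
  if (any(lci <= 0) || any(lci > or_) || any(or_ > uci)) {
    stop_tsmr("need 0 < lci <= or <= uci", class = "tsmr_validation_error")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (level == 0.95) z <- Z975
  se <- (log(uci) - log(lci)) / (2 * z)
  if (any(se <= 0)) {
    stop_tsmr("degenerate interval (lci = uci) gives se = 0",
              class = "tsmr_validation_error")
  }
  list(log_or = log(or_), se = se, source = "from_ci")
}

#' Fixed-effect inverse-variance pooling
#'
#' @param y effects on the log scale.
#' @param se standard errors (> 0).
#' @return List with `est`, `se`, `pval`.
#' @export
pool_fixed <- function(y, se) {
  stopifnot(length(y) >= 1, length(se) == length(y), all(se > 0))
  w <- 1 / se^2
  est <- sum(w * y) / sum(w)
  se_p <- sqrt(1 / sum(w))
  list(est = est, se = se_p, pval = p_normal(est, se_p))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance:
#' `Q = sum(w (y - est_fixed)^2)`, `C = sum(w) - sum(w^2)/sum(w)`,
#' `tau2 = max(0, (Q - (k-1))/C)`; studies are then re-pooled with weights
#' `1/(se^2 + tau2)`. Homogeneous inputs (Q <= k-1) give `tau2 = 0` and the
#' fixed-effect answer.
#'
#' @param y effects on the log scale (k >= 2).
#' @param se standard errors (> 0).
#' @return List with `est`, `se`, `pval`, `tau2`, `q_stat`, `q_pval`, `i2`.
#' @export
pool_random_dl <- function(y, se) {
  k <- length(y)
  if (k < 2) {
    stop_tsmr("random-effects pooling needs >= 2 studies; use pool_fixed()",
              class = "tsmr_degenerate")
  }
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  fixed <- pool_fixed(y, se)
  q <- sum(w * (y - fixed$est)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / C)
  wr <- 1 / (se^2 + tau2)
  est <- sum(wr * y) / sum(wr)
  se_p <- sqrt(1 / sum(wr))
  list(est = est, se = se_p, pval = p_normal(est, se_p), tau2 = tau2,
       q_stat = q, q_pval = stats::pchisq(q, k - 1, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0)
}

#' Pool per-study MR estimates within disease groups
#'
#' For each (disease, exposure) cell, converts every study's reported IVW
#' OR and 95% CI to a log-OR and standard error via [ci_to_logse()], then
#' pools by fixed-effect inverse variance and DerSimonian-Laird random
#' effects. The heterogeneity p-value of the pooled studies is surfaced as
#' the sensitivity column of the report.
#'
#' @param table1 data.frame of per-study rows with columns `outcome_id`,
#'   `exposure_id`, `or`, `or_lci95`, `or_uci95` (one IVW row per study),
#'   and optionally `disease`.
#' @param grouping named list mapping disease labels to the outcome ids in
#'   each group; every `outcome_id` present must be mapped exactly once.
#' @return A data.frame of class `meta_result` ordered by (disease,
#'   exposure), with fixed and random pooled ORs, CIs and p-values, `q_stat`,
#'   `q_pval`, `tau2`, `i2`, and `sensitivity_p`.
#' @export
meta_group <- function(table1, grouping) {
  table1 <- as.data.frame(table1)
  map <- stats::setNames(
    rep(names(grouping), lengths(grouping)), unlist(grouping))
  if (anyDuplicated(names(map))) {
    stop_tsmr("outcome id(s) mapped to more than one disease: %s",
              paste(unique(names(map)[duplicated(names(map))]), collapse = ", "),
              class = "tsmr_config_error")
  }
  unmapped <- setdiff(unique(table1$outcome_id), names(map))
  if (length(unmapped)) {
    stop_tsmr("unmapped outcome id(s): %s", paste(unmapped, collapse = ", "),
              class = "tsmr_config_error")
  }
  table1$disease <- unname(map[table1$outcome_id])

  cells <- unique(table1[c("disease", "exposure_id")])
  cells <- cells[order(cells$disease, cells$exposure_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table1$disease == cells$disease[i] &
      table1$exposure_id == cells$exposure_id[i]
    st <- ci_to_logse(table1$or[sel], table1$or_lci95[sel],
                      table1$or_uci95[sel])
    k <- sum(sel)
    fx <- pool_fixed(st$log_or, st$se)
    if (k >= 2) {
      rd <- pool_random_dl(st$log_or, st$se)
    } else {
      rd <- c(fx, list(tau2 = 0, q_stat = 0, q_pval = NA_real_, i2 = 0))
    }
    data.frame(
      disease = cells$disease[i], exposure_id = cells$exposure_id[i],
      k_studies = k,
      fixed_or = exp(fx$est), fixed_lci = exp(fx$est - Z975 * fx$se),
      fixed_uci = exp(fx$est + Z975 * fx$se), fixed_p = fx$pval,
      random_or = exp(rd$est), random_lci = exp(rd$est - Z975 * rd$se),
      random_uci = exp(rd$est + Z975 * rd$se), random_p = rd$pval,
      q_stat = rd$q_stat, q_pval = rd$q_pval, tau2 = rd$tau2, i2 = rd$i2,
      sensitivity_p = rd$q_pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis: %d (disease, exposure) cells\n", nrow(x)))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
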