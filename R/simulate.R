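# Seed-deterministic simulators for GWAS summary statistics, LD-coherent
# regional association signals, and two-group expression matrices. These
# emulate the statistical structure of the real data sources (binary dietary
# exposures with small per-variant effects, binary disease outcomes, a
# +/-500 kb LD region with a shared or distinct causal variant, and a
# 111-case / 46-control expression study) so every downstream stage can be
# exercised without downloads.

#' Simulate an exposure/outcome GWAS summary-statistic pair
#'
#' Generates per-SNP summary statistics for `n_snps` independent instruments.
#' For SNP j a minor-allele frequency is drawn uniformly from `maf_range`;
#' the true exposure effect is drawn as
#' `b_xj ~ Normal(0, h2_per_snp / (2 maf_j (1 - maf_j)))`, so each
#' instrument explains `h2_per_snp` of exposure variance in expectation.
#' Sampling noise uses the standard standardized-trait approximation
#' `se = 1 / sqrt(2 maf (1 - maf) n)` on each side. The observed outcome
#' effect is generated conditional on the *measured* exposure effect,
#' `b_yj = theta * b_xj_obs + s_j alpha_j + Normal(0, se_yj^2)` with
#' `alpha_j ~ Normal(pleiotropy_mean, pleiotropy_sd^2)` a direct
#' (pleiotropic) SNP-outcome effect and `s_j` the sign of the true exposure
#' effect, i.e. directional pleiotropy acts on the exposure-increasing
#' allele. p-values are two-sided normal.
#'
#' @param n_snps number of instruments K.
#' @param theta true causal effect of exposure on outcome (log-odds scale
#'   for binary traits).
#' @param n_exp,n_out GWAS sample sizes (>= 100).
#' @param maf_range minor-allele frequency interval, a subset of (0, 0.5].
#' @param h2_per_snp expected per-instrument variance explained.
#' @param pleiotropy_sd,pleiotropy_mean SD and mean of the direct SNP-outcome
#'   effects; both 0 gives valid instruments, nonzero mean gives directional
#'   pleiotropy.
#' @param instrument_z relevance floor: true effects are redrawn until the
#'   expected association z-score `|b_xj| / se_xj` is at least this value,
#'   emulating the p-value selection real instruments pass (the default 5
#'   corresponds roughly to a 5e-6 threshold). Set to 0 to disable.
#' @param seed RNG seed (fixed seed gives identical output).
#' @return A list with `exposure` and `outcome` ([sumstats] tables) and
#'   `truth` (theta, per-SNP true effects and pleiotropy).
#' @export
simulate_mr_pair <- function(n_snps = 30, theta = 0, n_exp = 100000,
                             n_out = 100000, maf_range = c(0.05, 0.5),
                             h2_per_snp = 0.001, pleiotropy_sd = 0,
                             pleiotropy_mean = 0, instrument_z = 5,
                             seed = NULL) {
  stopifnot(n_snps >= 1, n_exp >= 100, n_out >= 100,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], h2_per_snp >= 0, pleiotropy_sd >= 0,
            instrument_z >= 0)
  with_seed(seed, {
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    v_g <- 2 * maf * (1 - maf)
    se_x <- 1 / sqrt(v_g * n_exp)
    beta_x_true <- stats::rnorm(n_snps, 0, sqrt(h2_per_snp / v_g))
    # Relevance floor: SNPs with no detectable exposure effect are not
    # instruments; redraw them (rejection sampling on the true effect, so
    # observed effects stay conditionally normal).
    if (instrument_z > 0) {
      for (iter in seq_len(1000)) {
        weak <- abs(beta_x_true) / se_x < instrument_z
        if (!any(weak)) break
        beta_x_true[weak] <- stats::rnorm(sum(weak), 0,
                                          sqrt(h2_per_snp / v_g[weak]))
      }
      if (any(abs(beta_x_true) / se_x < instrument_z)) {
        stop_tsmr("instrument_z unreachable with h2_per_snp = %g at n = %d",
                  h2_per_snp, n_exp, class = "tsmr_config_error")
      }
    }
    se_y <- 1 / sqrt(v_g * n_out)
    beta_x_obs <- beta_x_true + stats::rnorm(n_snps, 0, se_x)
    alpha <- stats::rnorm(n_snps, pleiotropy_mean, pleiotropy_sd)
    beta_y_obs <- theta * beta_x_obs + sign(beta_x_true) * alpha +
      stats::rnorm(n_snps, 0, se_y)

    rsid <- sprintf("rs%06d", seq_len(n_snps))
    base <- data.frame(
      rsid = rsid, chrom = "1",
      pos = seq(1e6, by = 1e5, length.out = n_snps),
      stringsAsFactors = FALSE)
    mk <- function(beta, se, n, id) {
      df <- base
      df$effect_allele <- "A"
      df$other_allele <- "G"
      df$eaf <- maf
      df$beta <- beta
      df$se <- se
      df$pval <- pmax(p_normal(beta, se), 1e-300)
      df$n <- n
      sumstats(df, trait_id = id, trait_type = "case_control")
    }
    list(exposure = mk(beta_x_obs, se_x, n_exp, "sim-exposure"),
         outcome = mk(beta_y_obs, se_y, n_out, "sim-outcome"),
         truth = list(theta = theta, beta_x_true = beta_x_true,
                      alpha = alpha, maf = maf))
  })
}

#' Simulate regional association statistics for two traits under a
#' colocalization scenario
#'
#' Builds an exponential-decay LD correlation matrix
#' `R[i, j] = exp(-ld_decay * |i - j|)` over `n_snps` markers placed on a
#' uniform grid across a +/-500 kb window, then draws each trait's z-scores
#' from `MVN(R lambda, R)`, where `lambda` is the scenario's non-centrality
#' vector: all zero (H0), causal in trait 1 only (H1), trait 2 only (H2),
#' two distinct indices (H3), or one shared index (H4). The causal
#' non-centrality is `effect_size * sqrt(2 maf (1 - maf) n)`, the expected
#' z-score of a variant with per-allele effect `effect_size`. Betas and
#' standard errors consistent with the z-scores and sample sizes are
#' emitted (`se = 1 / sqrt(2 maf (1 - maf) n)`, `beta = z * se`).
#'
#' @param n_snps region SNP count Q (>= 2 for scenario H3).
#' @param ld_decay correlation decay rate per index step (larger = weaker LD).
#' @param scenario one of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param effect_size_1,effect_size_2 per-allele causal effects for each
#'   trait. The defaults give expected causal z-scores around 12 at
#'   `n = 1e5`, the magnitude seen at strongly colocalized loci.
#' @param n_1,n_2 sample sizes.
#' @param causal_1,causal_2 optional causal indices; defaults are the region
#'   midpoint (H4 shares `causal_1`; H3 separates the two by half the
#'   region).
#' @param seed RNG seed.
#' @return List with `trait1` and `trait2` ([sumstats] tables over the same
#'   rsids) and `truth` (scenario, causal indices, LD matrix).
#' @export
simulate_coloc_region <- function(n_snps = 100, ld_decay = 0.2,
                                  scenario = c("H0", "H1", "H2", "H3", "H4"),
                                  effect_size_1 = 0.06, effect_size_2 = 0.06,
                                  n_1 = 100000, n_2 = 100000,
                                  causal_1 = NULL, causal_2 = NULL,
                                  seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n_snps >= 1, ld_decay > 0, n_1 >= 100, n_2 >= 100)
  if (scenario == "H3" && n_snps < 2) {
    stop_tsmr("scenario H3 needs at least 2 SNPs", class = "tsmr_config_error")
  }
  with_seed(seed, {
    idx <- seq_len(n_snps)
    R <- exp(-ld_decay * abs(outer(idx, idx, "-")))
    ch <- tryCatch(chol(R + diag(1e-10, n_snps)),
                   error = function(e) {
                     stop_tsmr("LD matrix not positive definite after jitter",
                               class = "tsmr_numeric_error")
                   })
    maf <- stats::runif(n_snps, 0.05, 0.5)
    causal_1 <- causal_1 %||% max(1L, n_snps %/% 2L)
    causal_2 <- causal_2 %||% switch(scenario,
      H3 = ((causal_1 + n_snps %/% 2L - 1L) %% n_snps) + 1L,
      causal_1)

    ncp <- function(idx_c, eff, n) {
      lambda <- numeric(n_snps)
      lambda[idx_c] <- eff * sqrt(2 * maf[idx_c] * (1 - maf[idx_c]) * n)
      lambda
    }
    lambda1 <- switch(scenario,
      H0 = numeric(n_snps), H2 = numeric(n_snps),
      ncp(causal_1, effect_size_1, n_1))
    lambda2 <- switch(scenario,
      H0 = numeric(n_snps), H1 = numeric(n_snps),
      ncp(causal_2, effect_size_2, n_2))

    draw_z <- function(lambda) drop(R %*% lambda + crossprod(ch, stats::rnorm(n_snps)))
    z1 <- draw_z(lambda1)
    z2 <- draw_z(lambda2)

    pos <- round(seq(-500000, 500000, length.out = n_snps)) + 10^7
    mk <- function(z, n, id) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n)
      df <- data.frame(
        rsid = sprintf("rs%06d", idx), chrom = "1", pos = pos,
        effect_allele = "A", other_allele = "G", eaf = maf,
        beta = z * se, se = se, pval = pmax(p_normal(z, 1), 1e-300), n = n,
        stringsAsFactors = FALSE)
      sumstats(df, trait_id = id, trait_type = "case_control")
    }
    list(trait1 = mk(z1, n_1, "sim-region-trait1"),
         trait2 = mk(z2, n_2, "sim-region-trait2"),
         truth = list(scenario = scenario, causal_1 = causal_1,
                      causal_2 = causal_2, ld = R, maf = maf,
                      z1 = z1, z2 = z2))
  })
}

#' Simulate a two-group expression matrix
#'
#' Emulates a case/control peripheral-blood expression study: entries are
#' `Normal(shift_g * group, noise_sd^2)` with `group` 1 for cases and 0 for
#' controls. Default group sizes match the motivating 111-case / 46-control
#' design.
#'
#' @param n_cases,n_controls group sizes (>= 2).
#' @param n_genes number of genes.
#' @param effect_genes named numeric vector mapping gene name to a
#'   standardized mean shift in cases (genes not named shift by 0).
#' @param noise_sd within-group SD (> 0).
#' @param seed RNG seed.
#' @return List with `matrix` (genes x samples) and `labels`
#'   (1 = case, 0 = control).
#' @export
simulate_expression <- function(n_cases = 111, n_controls = 46, n_genes = 10,
                                effect_genes = NULL, noise_sd = 1,
                                seed = NULL) {
  stopifnot(n_cases >= 2, n_controls >= 2, n_genes >= 1, noise_sd > 0)
  with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    if (!is.null(names(effect_genes))) {
      unknown <- setdiff(names(effect_genes), genes)
      if (length(unknown)) genes[seq_along(unknown)] <- unknown
    }
    shift <- stats::setNames(numeric(n_genes), genes)
    if (length(effect_genes)) shift[names(effect_genes)] <- effect_genes

    labels <- c(rep(1L, n_cases), rep(0L, n_controls))
    m <- matrix(stats::rnorm(n_genes * length(labels), 0, noise_sd),
                nrow = n_genes,
                dimnames = list(genes, sprintf("s%03d", seq_along(labels))))
    m <- m + outer(shift, as.numeric(labels))
    list(matrix = m, labels = labels)
  })
}
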