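# Bayesian colocalization of two traits over a genomic window via Wakefield
# approximate Bayes factors. Per SNP, evidence of association is
# lABF = 0.5 * (log(1 - r) + r z^2) with shrinkage ratio r = W/(V + W),
# where V is the variance of the effect estimate and W the prior effect
# variance. Regional evidence for the five hypotheses (H0 no association,
# H1/H2 one trait only, H3 two distinct causal variants, H4 one shared
# causal variant) combines the per-SNP lABFs under a single-causal-variant
# assumption per trait.

#' Log approximate Bayes factor for one SNP
#'
#' `r = W / (V + W)`; `labf = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param z z-score (`beta / sqrt(V)`).
#' @param V variance of the effect estimate (> 0).
#' @param W prior variance of the true effect (> 0).
#' @return List with `labf` and `r` (vectors when the inputs are vectors).
#' @seealso [labf_from_zr()] to evaluate from a pre-computed shrinkage
#'   ratio.
#' @export
compute_labf <- function(z, V, W) {
  if (any(V <= 0) || any(W <= 0)) {
    stop_tsmr("V and W must be > 0", class = "tsmr_config_error")
  }
  r <- W / (V + W)
  list(labf = labf_from_zr(z, r), r = r)
}

#' Log approximate Bayes factor from a z-score and shrinkage ratio
#' @param z z-score.
#' @param r shrinkage ratio `W/(V+W)` in (0, 1).
#' @return Numeric lABF.
#' @export
labf_from_zr <- function(z, r) {
  stopifnot(all(r > 0), all(r < 1))
  0.5 * (log(1 - r) + r * z^2)
}

#' Prior effect variance for one trait
#'
#' Case/control traits use `W = 0.2^2` on the log-odds scale; quantitative
#' traits use `W = (0.15 * sdY)^2`, estimating the trait SD from the effect
#' variances, allele frequencies and sample sizes when it is not supplied
#' (regression of `2 n maf (1 - maf)` on `1/V` through the origin).
#'
#' @param trait_type `"case_control"` or `"quantitative"`.
#' @param sdY trait SD (quantitative only).
#' @param V,maf,n per-SNP effect variances, allele frequencies and sample
#'   sizes, used to estimate `sdY` when absent.
#' @return Scalar prior variance W.
#' @export
prior_variance <- function(trait_type = c("case_control", "quantitative"),
                           sdY = NULL, V = NULL, maf = NULL, n = NULL) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "case_control") return(0.2^2)
  if (is.null(sdY)) {
    if (is.null(V) || is.null(maf) || is.null(n)) {
      stop_tsmr("quantitative trait needs sdY or (V, maf, n) to estimate it",
                class = "tsmr_config_error")
    }
    oneover <- 1 / V
    nvx <- 2 * n * maf * (1 - maf)
    sdY <- sqrt(stats::coef(stats::lm(nvx ~ oneover - 1))[[1]])
  }
  (0.15 * sdY)^2
}

#' Restrict a summary-statistics table to a genomic window
#'
#' Keeps SNPs on the centre's chromosome with position inside the closed
#' interval `[pos - half_width_bp, pos + half_width_bp]` (default +/-500 kb),
#' preserving row order.
#'
#' @param table a [sumstats] table with positions.
#' @param chrom,pos window centre.
#' @param half_width_bp half-width in base pairs.
#' @return The filtered [sumstats] table.
#' @export
extract_region <- function(table, chrom, pos, half_width_bp = 500000) {
  stopifnot(inherits(table, "sumstats"))
  keep <- !is.na(table$chrom) & table$chrom == as.character(chrom) &
    !is.na(table$pos) & abs(table$pos - pos) <= half_width_bp
  if (!any(keep)) {
    stop_tsmr("no SNPs in window %s:%d +/- %d bp", chrom, pos, half_width_bp,
              class = "tsmr_empty_region")
  }
  table[keep, , drop = FALSE]
}

coloc_trait_prep <- function(x, sdY = NULL, label = "trait") {
  if (inherits(x, "sumstats")) {
    tt <- attr(x, "trait_type")
    V <- x$se^2
    W <- prior_variance(tt, sdY = sdY, V = V, maf = x$eaf, n = x$n)
    list(rsid = x$rsid, z = x$beta / x$se, V = V, W = W,
         trait_id = attr(x, "trait_id"))
  } else if (is.list(x) && all(c("rsid", "z", "V") %in% names(x))) {
    W <- x$W %||% prior_variance(x$trait_type %||% "case_control",
                                 sdY = sdY, V = x$V, maf = x$maf, n = x$n)
    list(rsid = x$rsid, z = x$z, V = x$V, W = W,
         trait_id = x$trait_id %||% label)
  } else {
    stop_tsmr("%s must be a sumstats table or a list with rsid/z/V", label,
              class = "tsmr_config_error")
  }
}

#' Colocalization posteriors for two traits over a shared SNP set
#'
#' Computes per-SNP Wakefield log approximate Bayes factors for each trait
#' and combines them into posterior probabilities of the five
#' configurations. With `L1 = logsumexp(labf1)`, `L2 = logsumexp(labf2)`
#' and `L12 = logsumexp(labf1 + labf2)`, the log posterior weights are
#' `H0: 0`, `H1: log(p1) + L1`, `H2: log(p2) + L2`,
#' `H3: log(p1) + log(p2) + logdiff(L1 + L2, L12)`,
#' `H4: log(p12) + L12`; the five are softmax-normalized. The per-SNP
#' posterior for being the shared variant under H4 is
#' `exp(labf1_j + labf2_j - L12)`. A single-SNP region has no H3
#' configuration (its weight is -Inf).
#'
#' @param trait1,trait2 [sumstats] tables over the same rsids in the same
#'   order, or lists with elements `rsid`, `z`, `V` (and optionally `W`,
#'   `trait_type`, `maf`, `n`, `trait_id`). By convention trait 1 is the
#'   outcome GWAS and trait 2 the exposure.
#' @param p1,p2 prior probability that a SNP is causal for trait 1 / 2 only.
#' @param p12 prior probability that a SNP is causal for both.
#' @param sdY1,sdY2 trait SDs for quantitative traits (optional).
#' @return An object of class `coloc_fit`: posterior probabilities `pp`
#'   (H0-H4), the per-SNP table (`labf` pairs, `internal.sum.lABF`,
#'   `SNP.PP.H4`), and the priors used.
#' @examples
#' reg <- simulate_coloc_region(n_snps = 50, scenario = "H4", seed = 7)
#' fit <- coloc_abf(reg$trait1, reg$trait2)
#' fit
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      sdY1 = NULL, sdY2 = NULL) {
  t1 <- coloc_trait_prep(trait1, sdY1, "trait1")
  t2 <- coloc_trait_prep(trait2, sdY2, "trait2")
  if (length(t1$rsid) != length(t2$rsid) || !all(t1$rsid == t2$rsid)) {
    only1 <- setdiff(t1$rsid, t2$rsid)
    only2 <- setdiff(t2$rsid, t1$rsid)
    stop_tsmr("rsid sets differ or are reordered (only trait1: %s; only trait2: %s)",
              paste(utils::head(only1, 5), collapse = ","),
              paste(utils::head(only2, 5), collapse = ","),
              class = "tsmr_validation_error")
  }
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1)

  ab1 <- compute_labf(t1$z, t1$V, t1$W)
  ab2 <- compute_labf(t2$z, t2$V, t2$W)
  post <- coloc_posteriors(ab1$labf, ab2$labf, p1 = p1, p2 = p2, p12 = p12)

  snp <- data.frame(
    SNP = t1$rsid,
    V.df1 = t1$V, z.df1 = t1$z, r.df1 = ab1$r, lABF.df1 = ab1$labf,
    V.df2 = t2$V, z.df2 = t2$z, r.df2 = ab2$r, lABF.df2 = ab2$labf,
    stringsAsFactors = FALSE)
  snp$internal.sum.lABF <- ab1$labf + ab2$labf
  snp$SNP.PP.H4 <- post$snp_pp_h4

  structure(list(pp = post$pp, snp = snp,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_snps = nrow(snp),
                 trait1_id = t1$trait_id, trait2_id = t2$trait_id),
            class = "coloc_fit")
}

#' Posterior probabilities of the five colocalization configurations from
#' per-SNP log Bayes factors
#'
#' The combination step of [coloc_abf()], exposed for use with lABFs
#' computed elsewhere.
#'
#' @param labf1,labf2 per-SNP log approximate Bayes factors for each trait,
#'   same SNPs in the same order.
#' @param p1,p2,p12 priors as in [coloc_abf()].
#' @return List with `pp` (named H0-H4 vector summing to 1) and
#'   `snp_pp_h4` (per-SNP posterior for being the shared variant, summing
#'   to 1).
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(length(labf1) == length(labf2), length(labf1) >= 1)
  L1 <- logsumexp(labf1)
  L2 <- logsumexp(labf2)
  L12 <- logsumexp(labf1 + labf2)
  lw <- c(H0 = 0,
          H1 = log(p1) + L1,
          H2 = log(p2) + L2,
          H3 = if (length(labf1) > 1) {
            log(p1) + log(p2) + logdiff(L1 + L2, L12)
          } else {
            -Inf
          },
          H4 = log(p12) + L12)
  pp <- exp(lw - logsumexp(lw))
  list(pp = pp / sum(pp), snp_pp_h4 = exp(labf1 + labf2 - L12))
}

#' @export
print.coloc_fit <- function(x, ...) {
  cat(sprintf("Colocalization: %s vs %s over %d SNPs\n",
              x$trait1_id, x$trait2_id, x$n_snps))
  cat("Posterior probabilities:\n")
  print(round(x$pp, 4))
  best <- which.max(x$snp$SNP.PP.H4)
  cat(sprintf("Top shared-variant candidate: %s (SNP.PP.H4 = %.3f)\n",
              x$snp$SNP[best], x$snp$SNP.PP.H4[best]))
  invisible(x)
}
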