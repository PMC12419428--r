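test_that("the log approximate Bayes factor follows the shrinkage formula", {
  ab <- compute_labf(z = 3, V = 0.01, W = 0.04)
  expect_equal(ab$r, 0.04 / 0.05)
  expect_equal(ab$labf, 0.5 * (log(1 - 0.8) + 0.8 * 9))

  # null association: labf reduces to the negative shrinkage penalty
  ab0 <- compute_labf(z = 0, V = 0.01, W = 0.04)
  expect_equal(ab0$labf, 0.5 * log(1 - 0.8))
  expect_lt(ab0$labf, 0)

  expect_error(compute_labf(1, 0, 0.04), class = "tsmr_config_error")
  expect_error(compute_labf(1, 0.01, -1), class = "tsmr_config_error")
})

test_that("prior variances follow the trait-type conventions", {
  expect_equal(prior_variance("case_control"), 0.04)
  expect_equal(prior_variance("quantitative", sdY = 1), 0.0225)
  expect_equal(prior_variance("quantitative", sdY = 2), 0.09)
  expect_error(prior_variance("quantitative"), class = "tsmr_config_error")

  # sdY estimation from (V, maf, n): exact when V = 1/(2 n maf (1-maf)) * sdY^2
  set.seed(3)
  maf <- runif(30, 0.05, 0.5)
  n <- rep(5e4, 30)
  sdY <- 1.7
  V <- sdY^2 / (2 * n * maf * (1 - maf))
  expect_equal(prior_variance("quantitative", V = V, maf = maf, n = n),
               (0.15 * sdY)^2, tolerance = 1e-6)
})

test_that("posterior weights enumerate the five configurations", {
  # Q = 1 with flat evidence: pp proportional to {1, p1, p2, 0, p12}
  post <- coloc_posteriors(0, 0)
  expect_equal(sum(post$pp), 1)
  expect_equal(post$pp[["H0"]], 1 / (1 + 1e-4 + 1e-4 + 1e-5))
  expect_equal(post$pp[["H3"]], 0)
  expect_equal(post$snp_pp_h4, 1)

  # direct enumeration oracle on a 3-SNP region
  l1 <- c(4, 0.5, -1)
  l2 <- c(3.5, 1, 0)
  post3 <- coloc_posteriors(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)
  L1 <- log(sum(exp(l1))); L2 <- log(sum(exp(l2))); L12 <- log(sum(exp(l1 + l2)))
  w <- c(1, 1e-4 * exp(L1), 1e-4 * exp(L2),
         1e-8 * (exp(L1 + L2) - exp(L12)), 1e-5 * exp(L12))
  expect_equal(unname(post3$pp), w / sum(w), tolerance = 1e-12)
  expect_equal(post3$snp_pp_h4, exp(l1 + l2 - L12))
  expect_equal(sum(post3$snp_pp_h4), 1)

  # shift invariance: adding a constant to one trait's labf rescales the
  # weights of every configuration involving that trait equally, so the
  # per-SNP H4 attribution and the odds among those configurations are
  # unchanged (absolute pp against H0 legitimately moves with the evidence)
  base <- coloc_posteriors(l1, l2)
  shifted <- coloc_posteriors(l1 + 7, l2)
  expect_equal(shifted$snp_pp_h4, base$snp_pp_h4, tolerance = 1e-12)
  expect_equal(shifted$pp[["H4"]] / shifted$pp[["H1"]],
               base$pp[["H4"]] / base$pp[["H1"]], tolerance = 1e-9)
  expect_equal(shifted$pp[["H4"]] / shifted$pp[["H3"]],
               base$pp[["H4"]] / base$pp[["H3"]], tolerance = 1e-9)

  # overflow safety at extreme evidence
  big <- coloc_posteriors(c(1e4, 30), c(1e4, 20))
  expect_false(any(is.na(big$pp)))
  expect_equal(sum(big$pp), 1)
  expect_equal(big$pp[["H4"]], 1, tolerance = 1e-6)
})

test_that("coloc_abf reproduces the published worked example from printed z and r", {
  tab <- read.delim(system.file("extdata", "coloc_worked_example.tsv",
                                package = "tsmr"))
  labf1 <- labf_from_zr(tab$z.df1, tab$r.df1)
  labf2 <- labf_from_zr(tab$z.df2, tab$r.df2)
  # printed z and r are themselves rounded, so agreement is to ~6 figures
  expect_equal(labf1, c(65.70855752, 46.06330165), tolerance = 1e-7)
  expect_equal(labf2, c(-3.853938267, -3.775752874), tolerance = 1e-6)
  expect_equal(labf1 + labf2, tab$internal.sum.lABF, tolerance = 1e-6)

  # the same numbers flow through compute_labf via W backed out of r
  W1 <- tab$r.df1 * tab$V.df1 / (1 - tab$r.df1)
  ab <- compute_labf(tab$z.df1, tab$V.df1, W1)
  expect_equal(ab$labf, labf1, tolerance = 1e-10)
  # and the case/control prior W = 0.2^2 is consistent with the printed r
  expect_equal(W1[1], 0.04, tolerance = 0.05)
})

test_that("region extraction uses a closed +/- window", {
  df <- toy_sumstats_df()[rep(1, 7), ]
  df$rsid <- sprintf("rs%d", 1:7)
  df$chrom <- c(rep("1", 6), "2")
  center <- 10^7
  df$pos <- c(center, center + 500000, center + 500001, center - 500000,
              center - 500001, center + 123, center)
  tab <- sumstats(df)
  reg <- extract_region(tab, "1", center)
  expect_setequal(reg$rsid, c("rs1", "rs2", "rs4", "rs6"))
  expect_error(extract_region(tab, "9", center), class = "tsmr_empty_region")
})

test_that("mismatched rsid sets are rejected with the symmetric difference", {
  r <- simulate_coloc_region(n_snps = 5, scenario = "H4", seed = 1)
  t2 <- r$trait2
  t2$rsid[3] <- "rsXXX"
  err <- tryCatch(coloc_abf(r$trait1, sumstats(as.data.frame(t2))),
                  error = identity)
  expect_s3_class(err, "tsmr_validation_error")
  expect_match(conditionMessage(err), "rsXXX")
})

test_that("shared-causal-variant regions colocalize and distinct ones do not", {
  h4_pp <- vapply(1:25, function(i) {
    r <- simulate_coloc_region(n_snps = 60, scenario = "H4", seed = 800 + i)
    coloc_abf(r$trait1, r$trait2)$pp[["H4"]]
  }, numeric(1))
  expect_gte(mean(h4_pp > 0.7), 0.8)

  h3_top <- vapply(1:25, function(i) {
    r <- simulate_coloc_region(n_snps = 60, scenario = "H3", ld_decay = 1,
                               seed = 900 + i)
    names(which.max(coloc_abf(r$trait1, r$trait2)$pp))
  }, character(1))
  expect_gt(mean(h3_top == "H3"), 0.5)

  h1 <- simulate_coloc_region(n_snps = 60, scenario = "H1", seed = 5)
  expect_equal(names(which.max(coloc_abf(h1$trait1, h1$trait2)$pp)), "H1")
  h2 <- simulate_coloc_region(n_snps = 60, scenario = "H2", seed = 5)
  expect_equal(names(which.max(coloc_abf(h2$trait1, h2$trait2)$pp)), "H2")
})
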