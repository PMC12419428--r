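test_that("instrument selection applies the p-value and confounder filters", {
  df <- toy_sumstats_df()
  df$pval <- c(1e-7, 1e-5, 1e-4)
  tab <- sumstats(df)
  suppressMessages({
    kept <- select_instruments(tab, p_threshold = 5e-6)
  })
  expect_equal(kept$rsid, "rs1")

  # 10 SNPs, 4 below threshold, 1 of those excluded -> 3 kept
  df10 <- do.call(rbind, replicate(4, toy_sumstats_df(), simplify = FALSE))[1:10, ]
  df10$rsid <- sprintf("rs%d", 1:10)
  df10$pval <- c(rep(1e-8, 4), rep(1e-3, 6))
  tab10 <- sumstats(df10)
  suppressMessages({
    kept10 <- select_instruments(tab10, 5e-6, exclusion_list = "rs2")
  })
  expect_equal(kept10$rsid, c("rs1", "rs3", "rs4"))
  removed <- attr(kept10, "removed")
  expect_equal(removed$reason[removed$rsid == "rs2"], "confounder")

  # exclusion list as a file with comments
  f <- tempfile()
  writeLines(c("# confounder hits", "rs2"), f)
  suppressMessages({
    kept_f <- select_instruments(tab10, 5e-6, exclusion_list = f)
  })
  expect_equal(kept_f$rsid, kept10$rsid)

  suppressMessages(
    expect_error(select_instruments(tab, p_threshold = 1e-12),
                 class = "tsmr_empty_instruments"))
})

test_that("greedy LD clumping keeps the strongest SNP per correlated clique", {
  df <- toy_sumstats_df()
  df$chrom <- "1"
  df$pos <- c(1000, 2000, 3000)
  df$pval <- c(1e-8, 1e-7, 1e-6)
  tab <- sumstats(df)
  ld <- matrix(c(1, 0.5, 5e-4,
                 0.5, 1, 2e-4,
                 5e-4, 2e-4, 1), 3, 3,
               dimnames = list(df$rsid, df$rsid))
  kept <- ld_clump(tab, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_equal(sort(kept$rsid), c("rs1", "rs3"))

  # a single candidate survives trivially
  one <- ld_clump(tab[1, ], ld[1, 1, drop = FALSE])
  expect_equal(one$rsid, "rs1")

  # correlated SNPs beyond the distance window are both kept
  far <- df
  far$pos <- c(1000, 2e7 + 1000, 3000)
  fart <- sumstats(far)
  ld2 <- ld
  ld2["rs1", "rs2"] <- ld2["rs2", "rs1"] <- 0.9
  kept_far <- ld_clump(fart, ld2, r2_threshold = 0.001, window_kb = 10000)
  expect_true(all(c("rs1", "rs2") %in% kept_far$rsid))
})

test_that("clumping output is independent of input row order", {
  set.seed(33)
  n <- 12
  df <- toy_sumstats_df()[rep(1, n), ]
  df$rsid <- sprintf("rs%02d", 1:n)
  df$pos <- seq(1e5, by = 5e4, length.out = n)
  df$pval <- runif(n, 1e-10, 1e-5)
  ld <- outer(1:n, 1:n, function(i, j) 0.8^abs(i - j))
  dimnames(ld) <- list(df$rsid, df$rsid)
  tab <- sumstats(df)
  shuf <- sumstats(df[sample(n), ])
  expect_equal(ld_clump(tab, ld, 0.1, 10000)$rsid,
               ld_clump(shuf, ld, 0.1, 10000)$rsid)
})

test_that("harmonization aligns swapped and strand-flipped outcome alleles", {
  ex <- sumstats(data.frame(
    rsid = c("rs1", "rs2", "rs3"), chrom = "1", pos = 1:3 * 1000,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.01, pval = 1e-8, n = 1e5))
  # rs1 aligned, rs2 swapped, rs3 on the other strand (T/C = complement of A/G)
  ou <- sumstats(data.frame(
    rsid = c("rs1", "rs2", "rs3"), chrom = "1", pos = 1:3 * 1000,
    effect_allele = c("A", "G", "T"), other_allele = c("G", "A", "C"),
    eaf = c(0.3, 0.7, 0.3),
    beta = c(-0.05, -0.05, -0.05), se = 0.02, pval = 0.01, n = 1e5))
  h <- harmonize(ex, ou)
  expect_equal(h$pairs$beta_y, c(-0.05, 0.05, -0.05))
  expect_equal(h$pairs$eaf_y, c(0.3, 0.3, 0.3))
  expect_equal(nrow(h$removed), 0)
})

test_that("palindromic SNPs are resolved by frequency or removed", {
  pal_ex <- sumstats(data.frame(
    rsid = c("rs1", "rs2"), chrom = "1", pos = c(1000, 2000),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.49, 0.2), beta = 0.1, se = 0.01, pval = 1e-8, n = 1e5))
  pal_ou <- sumstats(data.frame(
    rsid = c("rs1", "rs2"), chrom = "1", pos = c(1000, 2000),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.49, 0.22), beta = -0.05, se = 0.02, pval = 0.01, n = 1e5))
  h <- harmonize(pal_ex, pal_ou)
  # rs1 sits inside the 0.42-0.58 ambiguity band -> removed; rs2 is clear
  expect_equal(h$removed$rsid, "rs1")
  expect_equal(h$removed$reason, "palindromic")
  expect_equal(h$pairs$rsid, "rs2")

  # frequency disagreement outside the band is also ambiguous
  pal_ou2_df <- data.frame(
    rsid = c("rs1", "rs2"), chrom = "1", pos = c(1000, 2000),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.2, 0.8), beta = -0.05, se = 0.02, pval = 0.01, n = 1e5)
  pal_ex2 <- sumstats(data.frame(
    rsid = c("rs1", "rs2"), chrom = "1", pos = c(1000, 2000),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.2, 0.2), beta = 0.1, se = 0.01, pval = 1e-8, n = 1e5))
  h2 <- harmonize(pal_ex2, sumstats(pal_ou2_df))
  expect_equal(h2$pairs$rsid, "rs1")
  expect_equal(h2$removed$rsid, "rs2")
  expect_equal(h2$removed$reason, "palindromic")
})

test_that("irreconcilable alleles are dropped and empty joins error", {
  ex <- sumstats(toy_sumstats_df())
  mism <- toy_sumstats_df()
  mism$effect_allele[3] <- "C"   # exposure rs3 is G/A; C/A is irreconcilable
  ou <- sumstats(mism)
  h <- harmonize(ex, ou)
  expect_equal(h$removed$rsid, "rs3")
  expect_equal(h$removed$reason, "allele_mismatch")
  expect_setequal(h$pairs$rsid, c("rs1", "rs2"))

  other <- toy_sumstats_df()
  other$rsid <- c("rsX", "rsY", "rsZ")
  expect_error(harmonize(ex, sumstats(other)), class = "tsmr_empty_join")
})

test_that("harmonization is idempotent and partitions the joined rsids", {
  set.seed(8)
  n <- 15
  df <- toy_sumstats_df()[rep(1, n), ]
  df$rsid <- sprintf("rs%02d", 1:n)
  df$pos <- 1:n * 1000
  alle <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("G", "C"))
  pick <- sample(4, n, replace = TRUE)
  df$effect_allele <- vapply(pick, function(i) alle[[i]][1], "")
  df$other_allele <- vapply(pick, function(i) alle[[i]][2], "")
  df$eaf <- runif(n, 0.05, 0.95)
  ex <- sumstats(df)
  ou_df <- df
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ou_df$effect_allele[swap] <- df$other_allele[swap]
  ou_df$other_allele[swap] <- df$effect_allele[swap]
  ou_df$eaf[swap] <- 1 - df$eaf[swap]
  ou_df$beta <- ifelse(swap, -0.02, 0.02)
  ou <- sumstats(ou_df)

  h <- harmonize(ex, ou)
  # partition: kept and removed cover the join exactly once
  expect_setequal(c(h$pairs$rsid, h$removed$rsid), df$rsid)
  expect_length(intersect(h$pairs$rsid, h$removed$rsid), 0)

  # idempotence: re-harmonizing the aligned pairs changes nothing
  ou2_df <- df[match(h$pairs$rsid, df$rsid), ]
  ou2_df$beta <- h$pairs$beta_y
  ou2_df$se <- h$pairs$se_y
  ou2_df$eaf <- h$pairs$eaf_y
  ou2_df$pval <- h$pairs$pval_y
  h2 <- harmonize(ex, sumstats(ou2_df))
  expect_equal(h2$pairs$beta_y, h$pairs$beta_y)
  expect_equal(h2$pairs$eaf_y, h$pairs$eaf_y)
})
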