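# Shared fixtures, built in code at test time.

# A clean 3-row canonical sumstats data.frame.
toy_sumstats_df <- function() {
  data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1000, 2000, 3000),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.12, 0.45),
    beta = c(0.05, -0.04, 0.03),
    se = c(0.01, 0.011, 0.008),
    pval = c(7.6e-9, 6.3e-5, 2e-6),
    n = c(250000, 250000, 250000),
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Harmonized set simulated under the package's generator, as most MR tests
# need one.
sim_harmonized <- function(n_snps = 20, theta = 0, seed = 1, ...) {
  s <- simulate_mr_pair(n_snps = n_snps, theta = theta, seed = seed, ...)
  as_harmonized(s$exposure$beta, s$exposure$se,
                s$outcome$beta, s$outcome$se,
                rsid = s$exposure$rsid,
                n_x = s$exposure$n, n_y = s$outcome$n)
}
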