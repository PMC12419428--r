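test_that("Wald ratios follow the first-order formula and reject zero exposure effects", {
  h <- as_harmonized(beta_x = c(0.1, 0.2), se_x = c(0.01, 0.01),
                     beta_y = c(0.2, 0), se_y = c(0.05, 0.05))
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(2, 0))
  expect_equal(wr$ratio_se, c(0.5, 0.25))

  h0 <- as_harmonized(beta_x = c(0.1, 0), se_x = c(0.01, 0.01),
                      beta_y = c(0.2, 0.1), se_y = c(0.05, 0.05))
  err <- tryCatch(wald_ratios(h0), error = identity)
  expect_s3_class(err, "tsmr_degenerate")
  expect_match(conditionMessage(err), "rs000002")
})

test_that("IVW matches hand inverse-variance arithmetic and the WLS identity", {
  # ratios {2.0 (se 0.5), 1.0 (se 0.25)} -> beta 1.2, fixed se sqrt(1/20)
  h <- as_harmonized(beta_x = c(1, 1), se_x = c(0.01, 0.01),
                     beta_y = c(2, 1), se_y = c(0.5, 0.25))
  e <- mr_ivw(h, "fixed")
  expect_equal(e$beta, 1.2)
  expect_equal(e$se, sqrt(1 / 20))

  # algebraic identity: IVW fixed = zero-intercept WLS with weights 1/se_y^2
  hh <- sim_harmonized(n_snps = 25, theta = 0.3, seed = 21)
  ivw <- mr_ivw(hh, "fixed")
  wls <- lm(beta_y ~ beta_x - 1, data = hh$pairs, weights = 1 / hh$pairs$se_y^2)
  expect_equal(ivw$beta, unname(coef(wls)), tolerance = 1e-12)

  # homogeneous ratios: fixed and random agree (Q <= k-1 floor)
  hom <- as_harmonized(beta_x = c(1, 1, 1), se_x = rep(0.01, 3),
                       beta_y = c(0.5, 0.5, 0.5), se_y = rep(0.1, 3))
  expect_equal(mr_ivw(hom, "fixed")$se, mr_ivw(hom, "random")$se)

  expect_error(mr_ivw(as_harmonized(1, 0.1, 1, 0.1)),
               class = "tsmr_degenerate")
  expect_equal(wald_ratio_fit(as_harmonized(0.1, 0.01, 0.2, 0.05))$beta, 2)
})

test_that("the auto effects model switches on heterogeneity", {
  het <- as_harmonized(beta_x = rep(1, 4), se_x = rep(0.01, 4),
                       beta_y = c(0, 1, 2, 4), se_y = rep(0.1, 4))
  auto <- mr_ivw(het, "auto")
  expect_equal(auto$method, "IVW_random")
  expect_gt(auto$se, mr_ivw(het, "fixed")$se)

  hom <- sim_harmonized(n_snps = 10, theta = 0.2, seed = 31)
  expect_equal(mr_ivw(hom, "auto")$extra$effects_model,
               if (mr_ivw(hom, "fixed")$extra$q_pval < 0.05) "random" else "fixed")
})

test_that("MR-Egger reproduces an exact linear relation and the normal-equations solution", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  by <- 0.02 + 0.5 * bx
  h <- as_harmonized(bx, rep(0.01, 5), by, rep(0.05, 5))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extra$intercept, 0.02, tolerance = 1e-10)

  # explicit (X'WX)^-1 X'Wy oracle on noisy data
  hh <- sim_harmonized(n_snps = 5, theta = 0.4, seed = 17)
  s <- sign(hh$pairs$beta_x)
  X <- cbind(1, s * hh$pairs$beta_x)
  W <- diag(1 / hh$pairs$se_y^2)
  y <- s * hh$pairs$beta_y
  coefs <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  ee <- mr_egger(hh)
  expect_equal(ee$extra$intercept, coefs[1], tolerance = 1e-10)
  expect_equal(ee$beta, coefs[2], tolerance = 1e-10)

  expect_error(mr_egger(as_harmonized(c(1, 1), c(0.1, 0.1), c(1, 1), c(0.1, 0.1))),
               class = "tsmr_degenerate")
})

test_that("weighted median interpolates the standardized cumulative weights", {
  # equal weights, ratios {1, 2, 10}: s = {1/6, 1/2, 5/6} -> estimate 2
  h <- as_harmonized(rep(1, 3), rep(0.01, 3), c(1, 2, 10), rep(1, 3))
  wm <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 2)

  # all ratios equal c -> estimate c with small bootstrap se
  hc <- as_harmonized(rep(1, 4), rep(0.01, 4), rep(0.7, 4), rep(0.01, 4))
  wc <- mr_weighted_median(hc, n_boot = 200, seed = 1)
  expect_equal(wc$beta, 0.7)
  expect_lt(wc$se, 0.02)

  # seeded bootstrap is reproducible
  a <- mr_weighted_median(h, n_boot = 100, seed = 5)
  b <- mr_weighted_median(h, n_boot = 100, seed = 5)
  expect_identical(a$se, b$se)
})

test_that("mode estimators find the dominant ratio cluster", {
  # 7 tight ratios at 1.0, 2 loose at 5.0 -> weighted mode near 1
  bx <- rep(1, 9)
  by <- c(rep(1, 7), rep(5, 2))
  se_y <- c(rep(0.05, 7), rep(1, 2))
  h <- as_harmonized(bx, rep(0.01, 9), by, se_y)
  wmode <- mr_mode(h, weighted = TRUE, n_boot = 100, seed = 2)
  expect_lt(abs(wmode$beta - 1), 0.3)

  # identical ratios collapse to that value
  hc <- as_harmonized(rep(1, 3), rep(0.01, 3), rep(0.4, 3), rep(0.1, 3))
  expect_equal(mr_mode(hc, n_boot = 50, seed = 1)$beta, 0.4)

  # equal weights make the simple and weighted modes coincide
  heq <- as_harmonized(rep(1, 5), rep(0.01, 5), c(1, 1.1, 0.9, 1.05, 3),
                       rep(0.2, 5))
  expect_equal(mr_mode(heq, weighted = TRUE, n_boot = 50, seed = 3)$beta,
               mr_mode(heq, weighted = FALSE, n_boot = 50, seed = 3)$beta)
})

test_that("mr_fit runs every admissible method and flags the primary inference", {
  h1 <- as_harmonized(0.1, 0.01, 0.2, 0.05)
  f1 <- mr_fit(h1)
  expect_named(f1$estimates, "wald")

  h5 <- sim_harmonized(n_snps = 5, theta = 0.5, seed = 12)
  f5 <- mr_fit(h5, n_boot = 100, seed = 1)
  expect_setequal(vapply(f5$estimates, `[[`, "", "method"),
                  c("IVW_fixed", "Egger", "WeightedMedian", "SimpleMode",
                    "WeightedMode"))
  # with strong instruments all five agree within each other's CIs
  tab <- do.call(rbind, lapply(f5$estimates, function(e) {
    data.frame(b = e$beta, lo = e$beta - 1.959964 * e$se,
               hi = e$beta + 1.959964 * e$se)
  }))
  for (i in seq_len(nrow(tab))) {
    expect_true(all(tab$b >= tab$lo[i] - 1e-9 & tab$b <= tab$hi[i] + 1e-9))
  }

  expect_equal(unname(coef(f5)["IVW_fixed"]), f5$estimates$ivw$beta)
  ci <- confint(f5)
  expect_true(all(ci[, 1] < coef(f5) & coef(f5) < ci[, 2]))
})

test_that("estimates transform correctly under sign and scale changes", {
  h <- sim_harmonized(n_snps = 12, theta = 0.4, seed = 44)
  flip <- h
  flip$pairs$beta_y <- -h$pairs$beta_y
  scaled <- h
  scaled$pairs$beta_x <- 2 * h$pairs$beta_x
  scaled$pairs$se_x <- 2 * h$pairs$se_x

  for (fit in list(mr_ivw, mr_egger,
                   function(x) mr_weighted_median(x, n_boot = 50, seed = 3),
                   function(x) mr_mode(x, n_boot = 50, seed = 3))) {
    expect_equal(fit(flip)$beta, -fit(h)$beta, tolerance = 1e-8)
    expect_equal(fit(scaled)$beta, fit(h)$beta / 2, tolerance = 1e-8)
  }
})

test_that("CIs exponentiate with the fixed 97.5% quantile", {
  h <- sim_harmonized(n_snps = 8, theta = 0.2, seed = 50)
  e <- mr_ivw(h)
  expect_equal(e$or, exp(e$beta))
  expect_equal(e$or_lci95, exp(e$beta - 1.959964 * e$se))
  expect_equal(e$or_uci95, exp(e$beta + 1.959964 * e$se))
})

test_that("Egger is consistent under directional pleiotropy where IVW is biased", {
  s <- simulate_mr_pair(n_snps = 200, theta = 0.5, pleiotropy_mean = 0.05,
                        pleiotropy_sd = 0.01, n_exp = 5e5, n_out = 5e5,
                        seed = 77)
  h <- as_harmonized(s$exposure$beta, s$exposure$se,
                     s$outcome$beta, s$outcome$se)
  egger <- mr_egger(h)
  ivw <- mr_ivw(h, "fixed")
  expect_lt(abs(egger$beta - 0.5), abs(ivw$beta - 0.5))
  expect_gt(ivw$beta, 0.55) # mean pleiotropy pushes IVW upward
})
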