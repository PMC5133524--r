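## Data generated directly from the recursive lag structure, so the path
## coefficients have known truth.
lag_generator <- function(n, lambda, gamma_sex, n_visits = 4, seed = 1,
                          sigma = 5, snp_beta = 0, maf = 0.3,
                          families = NULL) {
  set.seed(seed)
  sex <- rep(c(1, 0), length.out = n)
  snp <- rbinom(n, 2, maf)
  sbp <- matrix(0, n, n_visits)
  sbp[, 1] <- 120 + gamma_sex * sex + snp_beta * snp + rnorm(n, 0, sigma)
  for (t in 2:n_visits)
    sbp[, t] <- 30 + lambda * sbp[, t - 1] + gamma_sex * sex +
      snp_beta * snp + rnorm(n, 0, sigma)
  wide <- data.frame(individual_id = sprintf("p%04d", 1:n),
                     family_id = families %||% sprintf("p%04d", 1:n),
                     sex = ifelse(sex == 1, "male", "female"),
                     smoking = FALSE, stringsAsFactors = FALSE)
  for (t in 1:n_visits) {
    wide[[paste0("sbp_", t)]] <- sbp[, t]
    wide[[paste0("age_", t)]] <- 40 + 5 * (t - 1)
  }
  list(wide = wide, snp = setNames(snp, wide$individual_id))
}

test_that("lag coefficients are recovered, and vanish when visits are independent", {
  d0 <- lag_generator(500, lambda = 0, gamma_sex = 3, seed = 11)
  f0 <- fit_lagged_path_model(d0$wide, covariates = "sex")
  lags <- subset(f0$coefficients, term == "lag_sbp")
  expect_true(all(abs(lags$estimate) < 3 * lags$se))

  d1 <- lag_generator(500, lambda = 0.6, gamma_sex = 3, seed = 12)
  f1 <- fit_lagged_path_model(d1$wide, covariates = "sex")
  lags1 <- subset(f1$coefficients, term == "lag_sbp")
  expect_true(all(abs(lags1$estimate - 0.6) < 3 * lags1$se))
  ## no lag equation into the first visit
  expect_false(any(f1$coefficients$equation == 1 &
                     f1$coefficients$term == "lag_sbp"))
})

test_that("a constant direct sex effect is recovered at every visit", {
  d <- lag_generator(500, lambda = 0.5, gamma_sex = 5, seed = 13)
  f <- fit_lagged_path_model(d$wide, covariates = "sex")
  sx <- subset(f$coefficients, term == "sex")
  expect_identical(nrow(sx), 4L)
  expect_true(all(abs(sx$estimate - 5) < 3 * sx$se))
  ## indirect effects are products of path coefficients
  ind <- subset(f$indirect, covariate == "sex" & from == 1 & to == 2)
  g1 <- sx$estimate[sx$equation == 1]
  l2 <- subset(f$coefficients, term == "lag_sbp" & equation == 2)$estimate
  expect_equal(ind$estimate, g1 * l2, tolerance = 1e-12)
})

test_that("singleton families give classical heteroskedasticity-robust SEs", {
  d <- lag_generator(200, lambda = 0.5, gamma_sex = 5, seed = 14)
  f <- fit_lagged_path_model(d$wide, covariates = "sex")   # singleton clusters
  ## oracle: plain HC1 sandwich on the same equation
  eq2 <- stats::lm(sbp_2 ~ sbp_1 + I(sex == "male"), data = d$wide)
  se_hc1 <- sqrt(diag(sandwich::vcovHC(eq2, type = "HC1")))
  got <- subset(f$coefficients, equation == 2)$se
  expect_equal(sort(got), sort(unname(se_hc1)), tolerance = 1e-8)
})

test_that("SNPs with sparse genotype classes are skipped, not fitted", {
  d <- lag_generator(200, lambda = 0.5, gamma_sex = 5, seed = 15, maf = 0.05)
  ## with maf 0.05 and n = 200, homozygote-rare count is far below 30
  expect_error(fit_lagged_path_model(d$wide, snp = d$snp, covariates = "sex"),
               class = "trajgwas_snp_skip")
})

test_that("equation-wise estimates equal full-system GLS for the recursive model", {
  ## with independent homoskedastic errors the joint covariance is diagonal,
  ## so stacked GLS must reproduce the per-equation fits
  d <- lag_generator(120, lambda = 0.5, gamma_sex = 4, n_visits = 3, seed = 16)
  f <- fit_lagged_path_model(d$wide, covariates = "sex")
  w <- d$wide
  sexn <- as.numeric(w$sex == "male")
  Xs <- list(cbind(1, sexn),
             cbind(1, w$sbp_1, sexn),
             cbind(1, w$sbp_2, sexn))
  ys <- list(w$sbp_1, w$sbp_2, w$sbp_3)
  s2 <- mapply(function(X, y) mean(stats::lm.fit(X, y)$residuals^2), Xs, ys)
  bigX <- as.matrix(Matrix::bdiag(Xs))
  bigy <- unlist(ys)
  wgt <- rep(1 / s2, each = nrow(w))
  gls <- solve(crossprod(bigX * wgt, bigX), crossprod(bigX * wgt, bigy))
  expect_equal(f$coefficients$estimate, as.vector(gls), tolerance = 1e-8)
})

test_that("fit indices follow the standard formulas and adequacy gates", {
  fake <- function(chisq_m, df_m, chisq_i, df_i, n) {
    structure(list(loglik_sat = 0, loglik_model = -chisq_m / 2, p_model = 10,
                   p_sat = 10 + df_m, loglik_indep = -chisq_i / 2,
                   p_indep = 10 + df_m - df_i, n = n),
              class = "path_model_fit")
  }
  ## saturated model: zero discrepancy
  sat <- compute_fit_indices(fake(0, 5, 80, 9, 100))
  expect_equal(sat$rmsea, 0)
  expect_equal(sat$cfi, 1)
  ## model as bad as the independence baseline
  worst <- compute_fit_indices(fake(80, 9, 80, 9, 100))
  expect_equal(worst$cfi, 0)
  ## adequate fit passes the gates (rmsea 0.05 by construction)
  df_m <- 10; n <- 100
  good <- compute_fit_indices(fake(df_m + 0.05^2 * df_m * n, df_m, 500, 12, n))
  expect_equal(good$rmsea, 0.05)
  expect_true(good$model_ok)
  bad <- compute_fit_indices(fake(df_m + 0.09^2 * df_m * n, df_m, 500, 12, n))
  expect_false(bad$model_ok)
  ## zero df: rmsea defined as 0 with a warning
  expect_warning(z <- compute_fit_indices(fake(0, 0, 80, 9, 100)))
  expect_equal(z$rmsea, 0)
  expect_true(z$zero_df)
})

test_that("the covariate-retention rule requires 2 visits in 2 SNP models", {
  mkfit <- function(p_sex, p_smoke) {
    structure(list(
      coefficients = data.frame(
        equation = rep(1:4, 2), term = rep(c("sex", "smoking"), each = 4),
        estimate = 1, se = 1, p_value = c(p_sex, p_smoke)),
      covariates = c("sex", "smoking")),
      class = "path_model_fit")
  }
  ## sex significant at 2 visits in models A and B -> retained;
  ## smoking significant at 3 visits but only in model A -> dropped
  a <- mkfit(c(0.01, 0.02, 0.5, 0.5), c(0.01, 0.01, 0.01, 0.9))
  b <- mkfit(c(0.03, 0.5, 0.001, 0.9), c(0.5, 0.6, 0.7, 0.8))
  expect_identical(select_covariates(list(a, b)), "sex")
  ## nothing significant -> empty set
  c0 <- mkfit(rep(0.5, 4), rep(0.5, 4))
  expect_identical(select_covariates(list(c0, c0)), character(0))
  ## monotone in alpha: a larger alpha never shrinks the retained set
  r1 <- select_covariates(list(a, b), alpha = 0.05)
  r2 <- select_covariates(list(a, b), alpha = 0.2)
  expect_true(all(r1 %in% r2))
})
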