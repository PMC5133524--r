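test_that("recursive kinship reproduces textbook coefficients", {
  phi <- kinship_matrix(hand_pedigree())
  expect_equal(unname(diag(phi)), rep(0.5, 7))       # non-inbred
  expect_equal(phi["f1", "c1"], 0.25)                # parent-offspring
  expect_equal(phi["c1", "c2"], 0.25)                # full siblings
  expect_equal(phi["f1", "m1"], 0)                   # unrelated founders
  expect_equal(phi["g1", "g2"], 0.25)                # full sibs, gen 3
  expect_equal(phi["c2", "g1"], 0.125)               # avuncular
  expect_equal(phi["f1", "g1"], 0.125)               # grandparent
  expect_true(isSymmetric(phi))
})

test_that("half siblings have kinship 1/8", {
  ped <- data.frame(
    family_id = "F1",
    individual_id = c("dad", "m1", "m2", "k1", "k2"),
    father_id = c(NA, NA, NA, "dad", "dad"),
    mother_id = c(NA, NA, NA, "m1", "m2"),
    sex = c("male", "female", "female", "male", "male"),
    stringsAsFactors = FALSE)
  phi <- kinship_matrix(ped)
  expect_equal(phi["k1", "k2"], 0.125)
})

test_that("recursive kinship agrees with gene-dropping Monte Carlo", {
  ped <- hand_pedigree()
  phi <- kinship_matrix(ped)
  mc <- kinship_gene_drop(ped, n_drops = 3e4, seed = 2)
  expect_lt(max(abs(phi - mc)), 0.01)
})

test_that("relationship matrices are positive semidefinite", {
  for (s in 1:3) {
    ped <- simulate_pedigree(3, 3, 4, seed = s)
    ev <- eigen(2 * kinship_matrix(ped), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("REML recovers heritability on a deep pedigree", {
  ## balanced design: sigma_g2 = sigma_e2 -> h2 = 0.5
  h2hat <- vapply(1:50, function(r) {
    ped <- simulate_pedigree(10, 3, 5, seed = 300 + r)
    phi <- kinship_matrix(ped)
    y <- trajgwas:::with_seed(400 + r, {
      g <- trajgwas:::draw_polygenic(phi, 1)
      setNames(g + rnorm(nrow(ped)), rownames(phi))
    })
    estimate_h2(y, NULL, phi)$h2
  }, numeric(1))
  expect_equal(mean(h2hat), 0.5, tolerance = 0.05)
})

test_that("REML optimum matches a dense grid search", {
  co <- small_cohort()
  y <- trajgwas:::with_seed(77, {
    g <- trajgwas:::draw_polygenic(co$phi, 2)
    setNames(g + rnorm(nrow(co$ped), 0, sqrt(2)), rownames(co$phi))
  })
  fit <- estimate_h2(y, NULL, co$phi)
  grid <- seq(0, 1, by = 0.01)
  ll <- vapply(grid, function(h)
    estimate_h2(y, NULL, co$phi, fix_h2 = h)$loglik, numeric(1))
  expect_lt(abs(fit$h2 - grid[which.max(ll)]), 0.01 + 1e-9)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("heritability is invariant to affine trait rescaling", {
  co <- small_cohort()
  y <- trajgwas:::with_seed(78, {
    g <- trajgwas:::draw_polygenic(co$phi, 1)
    setNames(g + rnorm(nrow(co$ped)), rownames(co$phi))
  })
  f1 <- estimate_h2(y, NULL, co$phi)
  f2 <- estimate_h2(3 * y + 7, NULL, co$phi)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-5)
  expect_equal(f2$sigma_g2, 9 * f1$sigma_g2, tolerance = 1e-3)
})

test_that("the no-genetics model reduces to the OLS restricted likelihood", {
  co <- small_cohort()
  n <- nrow(co$ped)
  y <- trajgwas:::with_seed(79, setNames(rnorm(n, 10, 2), rownames(co$phi)))
  f0 <- estimate_h2(y, NULL, co$phi, fix_h2 = 0)
  expect_identical(f0$h2, 0)
  ## closed-form restricted likelihood of the intercept-only normal model
  p <- 1
  rss <- sum((y - mean(y))^2)
  s2 <- rss / (n - p)
  ll_oracle <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(s2)) + log(n))
  expect_equal(f0$loglik, ll_oracle, tolerance = 1e-8)
})

test_that("the boundary LRT is calibrated under the null", {
  ped <- simulate_pedigree(6, 3, 4, seed = 80)
  phi <- kinship_matrix(ped)
  n <- nrow(ped)
  pv <- vapply(1:400, function(r) {
    y <- trajgwas:::with_seed(1000 + r, setNames(rnorm(n), rownames(phi)))
    estimate_h2(y, NULL, phi)$p_value
  }, numeric(1))
  ## 99% binomial envelope around a nominal 5% rate at 400 draws
  expect_lte(mean(pv < 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 400))
})

test_that("misuse of estimate_h2 is caught", {
  co <- small_cohort()
  y <- setNames(rnorm(nrow(co$ped)), rownames(co$phi))
  expect_error(estimate_h2(unname(y), NULL, co$phi),
               class = "trajgwas_param_error")
  X <- cbind(a = rep(1, length(y)), b = rep(1, length(y)))
  rownames(X) <- names(y)
  expect_error(estimate_h2(y, X, co$phi), class = "trajgwas_param_error")
})

test_that("kinship TSV round-trips", {
  phi <- kinship_matrix(hand_pedigree())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kinship(phi, path)
  back <- read_kinship(path)
  expect_equal(back[rownames(phi), colnames(phi)], phi, tolerance = 1e-12)
})

test_that("LD pruning drops duplicates and keeps independent SNPs", {
  set.seed(21)
  n <- 500
  dos <- matrix(rbinom(n * 60, 2, 0.3), n, 60)
  dos[, 31] <- dos[, 30]                      # exact duplicate
  gen <- geno_from_dosage(dos)
  kept <- ld_prune(gen, r2_max = 0.2, window = 20, step = 5)
  expect_true(xor("s0030" %in% kept, "s0031" %in% kept))
  ## independent SNPs are nearly all retained
  expect_gte(length(kept) / 60, 0.95)
  ## vacuous threshold keeps everything
  expect_length(ld_prune(gen, r2_max = 1, window = 20, step = 5), 60L)
  expect_error(ld_prune(gen, window = 1), class = "trajgwas_param_error")
})

test_that("founder PCA separates founder subpopulations and projects everyone", {
  ## two founder subpopulations with divergent allele frequencies
  set.seed(22)
  n_per <- 60; p <- 800
  f0 <- runif(p, 0.2, 0.8)
  delta <- 0.11                       # Fst ~ 0.05-scale divergence
  f1 <- pmin(pmax(f0 + delta, 0.02), 0.98)
  f2 <- pmin(pmax(f0 - delta, 0.02), 0.98)
  dos <- rbind(
    sapply(1:p, function(j) rbinom(n_per, 2, f1[j])),
    sapply(1:p, function(j) rbinom(n_per, 2, f2[j])))
  rownames(dos) <- sprintf("i%04d", seq_len(2 * n_per))
  gen <- geno_from_dosage(dos)
  ped <- singleton_pedigree(2 * n_per)
  pcs <- founder_pca(gen, ped, m = 4)
  expect_identical(ncol(pcs$scores), 4L)
  ## founder score vectors are mutually orthogonal
  g <- crossprod(pcs$founder_scores)
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)) / max(diag(g)), 1e-8)
  ## PC1 separates the two groups with no overlap
  pc1 <- pcs$scores[, 1]
  a <- pc1[1:n_per]; b <- pc1[(n_per + 1):(2 * n_per)]
  expect_true(max(a) < min(b) || max(b) < min(a))
  ## eigenvalues nonincreasing
  expect_true(all(diff(pcs$eigenvalues) <= 1e-9))
  expect_error(founder_pca(gen, ped, m = 200),
               class = "trajgwas_param_error")
})

test_that("non-founders are projected using founder loadings", {
  co <- small_cohort()
  kept <- ld_prune(co$gen, ids = founders(co$ped))
  pcs <- founder_pca(co$gen, co$ped, pruned = kept, m = 2)
  expect_identical(nrow(pcs$scores), nrow(co$ped))
  expect_true(all(rownames(co$gen$dosage) %in% rownames(pcs$scores)))
})
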