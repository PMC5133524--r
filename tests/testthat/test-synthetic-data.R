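test_that("simulated pedigrees have the requested structure and are reproducible", {
  ped <- simulate_pedigree(20, 3, 3, seed = 1)
  expect_length(unique(ped$family_id), 20L)
  expect_identical(ped, simulate_pedigree(20, 3, 3, seed = 1))

  ## two-generation family: generation 1 members are exactly the founders
  p1 <- simulate_pedigree(1, 2, 2, seed = 7)
  gen1 <- p1$individual_id[p1$generation == 1L]
  expect_setequal(gen1, founders(p1))
  expect_true(all(is.na(p1$father_id[p1$generation == 1L])))

  ## every non-founder has two in-pedigree parents of opposite sex
  nf <- ped[!is.na(ped$father_id), ]
  expect_true(all(nf$father_id %in% ped$individual_id))
  expect_true(all(nf$mother_id %in% ped$individual_id))
  sex_of <- setNames(ped$sex, ped$individual_id)
  expect_true(all(sex_of[nf$father_id] == "male"))
  expect_true(all(sex_of[nf$mother_id] == "female"))

  expect_error(simulate_pedigree(0, 3, 3, 1), class = "trajgwas_param_error")
  expect_error(simulate_pedigree(2, 1, 3, 1), class = "trajgwas_param_error")
})

test_that("pedigree validation rejects cycles and cross-family parents", {
  ped <- hand_pedigree()
  expect_silent(validate_pedigree(ped))
  cyc <- ped
  cyc$father_id[cyc$individual_id == "f1"] <- "g1"   # ancestor loop
  expect_error(validate_pedigree(cyc), class = "trajgwas_invariant_error")
  dup <- rbind(ped, ped[1L, ])
  expect_error(validate_pedigree(dup), class = "trajgwas_invariant_error")
})

test_that("gene dropping is Mendelian-consistent and reproducible", {
  ped <- simulate_pedigree(6, 3, 4, seed = 3)
  gen <- simulate_genotypes(ped, 150, c(0.1, 0.5), seed = 4)
  expect_identical(gen, simulate_genotypes(ped, 150, c(0.1, 0.5), seed = 4))
  expect_identical(mendelian_errors(gen, ped), 0L)
  ## realized EAF stored in the metadata
  expect_equal(gen$snp_meta$eaf, unname(colMeans(gen$dosage) / 2))
  ## positions strictly increasing within chromosome
  by_chr <- split(gen$snp_meta$position, gen$snp_meta$chromosome)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
  ## no monomorphic SNP
  expect_true(all(gen$snp_meta$eaf > 0 & gen$snp_meta$eaf < 1))
})

test_that("founder genotypes at fixed frequency follow Hardy-Weinberg", {
  ## all founders, maf fixed at 0.3: pooled genotype counts should match
  ## the Binomial(2, 0.3) expectation (chi-square, alpha = 0.001)
  ped <- singleton_pedigree(400)
  gen <- simulate_genotypes(ped, 1500, c(0.3, 0.3), seed = 5)
  obs <- c(sum(gen$dosage == 0L), sum(gen$dosage == 1L), sum(gen$dosage == 2L))
  expe <- sum(obs) * stats::dbinom(0:2, 2, 0.3)
  stat <- sum((obs - expe)^2 / expe)
  expect_gt(stats::pchisq(stat, df = 2, lower.tail = FALSE), 0.001)
})

test_that("degenerate genotype arguments are rejected", {
  ped <- hand_pedigree()
  expect_error(simulate_genotypes(ped, 10, c(0, 0), seed = 1),
               class = "trajgwas_param_error")
  expect_error(simulate_genotypes(ped, 10, c(0.6, 0.6), seed = 1),
               class = "trajgwas_param_error")
})

test_that("scenario configuration validates its keys", {
  expect_error(scenario_config(nonsense_key = 1),
               class = "trajgwas_param_error")
  expect_error(scenario_config(class_props = c(0.5, 0.5)),
               class = "trajgwas_param_error")   # wrong length for 5 classes
  expect_error(scenario_config(k_true = 2, class_props = c(0.6, 0.5),
                               class_coefs = matrix(0, 2, 3)),
               class = "trajgwas_param_error")   # proportions exceed 1
})

test_that("noise-free phenotypes lie exactly on the class curves", {
  ped <- simulate_pedigree(3, 3, 4, seed = 6)
  sc <- scenario_config(residual_sd = 0, polygenic_var = 0, missing_rate = 0)
  sim <- simulate_phenotypes(ped, NULL, sc, seed = 7)
  ph <- sim$phenotypes
  cls <- sim$truth$true_class[match(ph$individual_id,
                                    sim$truth$individual_id)]
  tt <- (ph$age - 45) / 10
  cc <- attr(sim$truth, "class_coefs")
  mu <- cc[cls, 1] + cc[cls, 2] * tt + cc[cls, 3] * tt^2 +
    attr(sim$truth, "sex_effect") * (ph$sex == "male") -
    sc$med_effect * ph$med_use      # treated visits read lower
  expect_equal(ph$sbp, mu, tolerance = 1e-12)
  ## and the +15 correction restores them to the class curve exactly
  adj <- adjust_medication(ph, offset = sc$med_effect)
  expect_equal(adj$sbp, mu + sc$med_effect * ph$med_use, tolerance = 1e-12)
})

test_that("visit design matches the cohort template", {
  ped <- simulate_pedigree(10, 3, 5, seed = 8)
  sim <- simulate_phenotypes(ped, NULL, scenario_config(), seed = 9)
  ph <- sim$phenotypes
  nv <- table(ph$individual_id)
  expect_lte(max(nv), 4L)
  spans <- tapply(ph$age, ph$individual_id, function(a) diff(range(a)))
  expect_lte(max(spans), 17 + 1e-9)
  ## ages strictly increasing within individual
  expect_true(all(tapply(ph$age, ph$individual_id,
                         function(a) all(diff(sort(a)) > 0))))
  expect_true(all(ph$sbp > 0))
})

test_that("liability variance components match the generating ratio", {
  ## moment-matching over replicates: the realized polygenic share of the
  ## class liability should track the configured heritability
  ped <- simulate_pedigree(4, 3, 4, seed = 10)
  h2 <- 0.6
  sc <- scenario_config(liability_h2 = h2)
  ratios <- vapply(1:60, function(s) {
    tr <- simulate_phenotypes(ped, NULL, sc, seed = 100 + s)$truth
    env <- tr$liability - tr$liability_genetic
    var(tr$liability_genetic) / (var(tr$liability_genetic) + var(env))
  }, numeric(1))
  expect_equal(mean(ratios), h2, tolerance = 0.05)
})

test_that("marginal SBP tracks the mixture-weighted class mean", {
  ped <- simulate_pedigree(20, 3, 5.8, seed = 11)
  sc <- scenario_config()
  sim <- simulate_phenotypes(ped, NULL, sc, seed = 12)
  ## compare on the medication-corrected scale the analysis runs on
  ph <- adjust_medication(sim$phenotypes, offset = sc$med_effect)
  tt <- (ph$age - 45) / 10
  cc <- sc$class_coefs
  mix_mu <- as.vector(cbind(1, tt, tt^2) %*% t(cc) %*% sc$class_props) +
    sc$sex_effect * mean(ph$sex == "male")
  expect_lt(abs(mean(ph$sbp) - mean(mix_mu)), 2)
})

test_that("phenotype writers round-trip", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(co$ph_raw, path)
  back <- read_phenotypes(path)
  expect_equal(back$sbp, co$ph_raw$sbp, tolerance = 1e-10)
  expect_identical(back$med_use, co$ph_raw$med_use)
  expect_identical(back$individual_id, co$ph_raw$individual_id)
})
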