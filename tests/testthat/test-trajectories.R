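test_that("censored-normal log-density matches closed forms and integrates to 1", {
  ## standard normal at its mode
  expect_equal(censored_normal_loglik(0, 0, 1), -0.5 * log(2 * pi))
  ## mass at the lower bound: y = y_min = 0, mu = 0 -> log Phi(0)
  expect_equal(censored_normal_loglik(0, 0, 1, y_min = 0), log(0.5))
  ## upper bound mirror
  expect_equal(censored_normal_loglik(5, 5, 2, y_max = 5), log(0.5))
  ## total probability: point masses at the bounds + interior density
  y_min <- 80; y_max <- 250; mu <- 130; sigma <- 20
  interior <- stats::integrate(
    function(y) exp(censored_normal_loglik(y, mu, sigma, y_min, y_max)),
    y_min + 1e-9, y_max - 1e-9, rel.tol = 1e-10)$value
  mass <- exp(censored_normal_loglik(y_min, mu, sigma, y_min, y_max)) +
    exp(censored_normal_loglik(y_max, mu, sigma, y_min, y_max)) + interior
  expect_equal(mass, 1, tolerance = 1e-6)
  ## bad arguments
  expect_error(censored_normal_loglik(1, 0, -1), class = "trajgwas_param_error")
  expect_error(censored_normal_loglik(NA, 0, 1), class = "trajgwas_param_error")
  expect_error(censored_normal_loglik(1, 0, 1, 5, 2),
               class = "trajgwas_param_error")
})

test_that("a single-class fit equals pooled polynomial least squares", {
  co <- small_cohort()
  ph <- co$ph
  m1 <- fit_lcgm(ph, 1, covariates = "sex", seed = 1)
  tt <- (ph$age - 45) / 10
  X <- cbind(1, tt, tt^2,
             vapply(sort(unique(ph$visit)), function(v)
               (ph$sex == "male") * (ph$visit == v), numeric(nrow(ph))))
  ols <- stats::lm.fit(X, ph$sbp)$coefficients
  expect_lt(max(abs(c(m1$beta[[1]], unname(m1$gamma)) - ols)), 1e-6)
  ## EM trace is monotone
  expect_true(all(diff(m1$loglik_trace) >= -1e-9))
})

test_that("well-separated flat classes are recovered almost perfectly", {
  set.seed(3)
  n <- 400
  cls <- rep(1:2, each = n / 2)
  ph <- do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- sort(runif(3, 30, 60))
    visits_fixture(sprintf("x%04d", i), ages,
                   c(110, 170)[cls[i]] + rnorm(3, 0, 5))
  }))
  m <- fit_lcgm(ph, 2, order = 0, covariates = character(0), seed = 4)
  a <- assign_classes(m, ph)
  truth <- cls[match(a$individual_id, sprintf("x%04d", seq_len(n)))]
  acc <- max(mean(a$class == truth), mean(a$class == 3 - truth))
  expect_gte(acc, 0.95)
  expect_true(all(diff(m$loglik_trace) >= -1e-9))
  ## posterior rows sum to one
  expect_equal(unname(rowSums(as.matrix(a[, c("p1", "p2")]))), rep(1, n),
               tolerance = 1e-8)
})

test_that("the group-size feasibility rule blocks oversized K", {
  co <- small_cohort()
  ph50 <- co$ph[co$ph$individual_id %in%
                  unique(co$ph$individual_id)[1:50], ]
  expect_error(fit_lcgm(ph50, 3, seed = 1), class = "trajgwas_infeasible")
})

test_that("BIC selection returns one class for single-class data", {
  set.seed(5)
  ph <- do.call(rbind, lapply(1:150, function(i) {
    ages <- sort(runif(3, 30, 60))
    visits_fixture(sprintf("s%03d", i), ages,
                   120 + 0.5 * (ages - 45) + rnorm(3, 0, 8))
  }))
  sel <- select_num_classes(ph, 1:3, covariates = character(0), seed = 6)
  expect_identical(sel$K, 1L)
  tab <- attr(sel, "selection")
  expect_identical(tab$status[tab$K == 1], "ok")
})

test_that("solutions with a tiny class are excluded from selection", {
  ## two classes, 97:3 mixture -> the K = 2 solution has a group under 25
  set.seed(7)
  n <- 300
  cls <- c(rep(1, 291), rep(2, 9))
  ph <- do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- sort(runif(3, 30, 60))
    visits_fixture(sprintf("t%03d", i), ages,
                   c(120, 190)[cls[i]] + rnorm(3, 0, 6))
  }))
  sel <- select_num_classes(ph, 1:2, covariates = character(0), seed = 8)
  tab <- attr(sel, "selection")
  expect_identical(tab$status[tab$K == 2], "group_too_small")
  expect_identical(sel$K, 1L)
})

test_that("pruning drops a quadratic term from a linear class and then stops", {
  set.seed(9)
  n <- 260
  cls <- rep(1:2, each = n / 2)
  ph <- do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- sort(runif(3, 25, 65))
    tt <- (ages - 45) / 10
    mu <- if (cls[i] == 1) 115 + 4 * tt else 160 + 6 * tt + 9 * tt^2
    visits_fixture(sprintf("p%03d", i), ages, mu + rnorm(3, 0, 6))
  }))
  m <- fit_lcgm(ph, 2, order = 2, covariates = character(0), seed = 10)
  pruned <- prune_polynomial_orders(m, ph, alpha = 0.05)
  expect_identical(pruned$K, 2L)
  ## the low flat-linear class loses its quadratic term, the curved one keeps it
  expect_identical(pruned$orders[1], 1L)
  expect_identical(pruned$orders[2], 2L)
  ## fewer parameters, strictly smaller BIC penalty
  expect_lt(pruned$n_parameters, m$n_parameters)
  ## a model whose terms are all strongly significant is a fixed point
  again <- prune_polynomial_orders(pruned, ph, alpha = 0.05)
  expect_identical(again$orders, pruned$orders)
})

test_that("posterior assignment follows Bayes rule with ties to the lowest class", {
  ## two identical classes: posteriors split evenly, hard label = 1
  model <- structure(list(
    K = 2L, orders = c(0L, 0L), beta = list(130, 130),
    gamma = numeric(0), pi = c(0.5, 0.5), sigma = 10,
    bounds = c(-Inf, Inf), covariates = character(0), znames = character(0)),
    class = "trajectory_model")
  ph <- visits_fixture("a", c(40, 50), c(128, 131))
  a <- assign_classes(model, ph)
  expect_equal(unname(unlist(a[1, c("p1", "p2")])), c(0.5, 0.5))
  expect_identical(a$class, 1L)
  ## overwhelming likelihood ratio picks the favored class
  model$beta <- list(100, 131)
  a2 <- assign_classes(model, ph)
  expect_identical(a2$class, 2L)
})

test_that("relabeling classes leaves the likelihood and partition unchanged", {
  co <- small_cohort()
  m <- fit_lcgm(co$ph, 3, covariates = "sex", seed = 11)
  a <- assign_classes(m, co$ph)
  perm <- c(3L, 1L, 2L)
  mp <- m
  mp$beta <- m$beta[perm]; mp$pi <- m$pi[perm]; mp$orders <- m$orders[perm]
  ap <- assign_classes(mp, co$ph)
  ## same partition up to the label permutation (mp class k is m class perm[k])
  relabeled <- perm[ap$class]
  expect_identical(relabeled, a$class)
  ## mixture likelihood of any individual's series is permutation-invariant
  expect_equal(
    rowSums(sweep(as.matrix(a[, paste0("p", 1:3)]), 2, m$pi, "*")),
    rowSums(sweep(as.matrix(ap[, paste0("p", 1:3)]), 2, mp$pi, "*")),
    tolerance = 1e-12)
})

test_that("classes are ranked by ascending mean hypertensive years", {
  assign <- structure(
    data.frame(individual_id = sprintf("i%02d", 1:6),
               class = c(1L, 1L, 2L, 2L, 3L, 3L)),
    class = c("class_assignment", "data.frame"))
  hy <- setNames(c(12, 10, 0, 1, 5, 6), assign$individual_id)
  r <- rank_classes(assign, hy)
  ## class 2 (mean 0.5) -> rank 1, class 3 (5.5) -> rank 2, class 1 (11) -> 3
  expect_identical(attr(r, "rank_of_class"), c(3L, 1L, 2L))
  expect_identical(r$rank, c(3L, 3L, 1L, 1L, 2L, 2L))
  expect_setequal(unique(r$rank), 1:3)
  ## already-sorted means give the identity ranking
  hy2 <- setNames(c(0, 0, 2, 2, 5, 5), assign$individual_id)
  expect_identical(attr(rank_classes(assign, hy2), "rank_of_class"), 1:3)
})

test_that("coefficient recovery sharpens as the cohort grows", {
  sc <- scenario_config()
  rmse_at <- function(n_fam, seed) {
    ped <- simulate_pedigree(n_fam, 3, 5.8, seed = seed)
    sim <- simulate_phenotypes(ped, NULL, sc, seed = seed + 1)
    ph <- filter_individuals(adjust_medication(sim$phenotypes))$phenotypes
    m <- fit_lcgm(ph, 5, covariates = "sex", seed = seed + 2)
    est <- do.call(rbind, m$beta)
    sqrt(mean((est - sc$class_coefs)^2))
  }
  r_small <- mean(c(rmse_at(4, 20), rmse_at(4, 40)))
  r_large <- mean(c(rmse_at(20, 30), rmse_at(20, 50)))
  expect_lt(r_large, r_small)
  expect_lt(r_large, 3)
})

test_that("trajectory model JSON round-trips", {
  co <- small_cohort()
  m <- fit_lcgm(co$ph, 2, covariates = "sex", seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_trajectory_model(m, path)
  back <- read_trajectory_model(path)
  expect_equal(back$beta, m$beta, tolerance = 1e-12)
  expect_equal(back$pi, m$pi, tolerance = 1e-12)
  expect_equal(back$sigma, m$sigma, tolerance = 1e-12)
  a1 <- assign_classes(m, co$ph)
  a2 <- assign_classes(back, co$ph)
  expect_equal(a2$class, a1$class)
})
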