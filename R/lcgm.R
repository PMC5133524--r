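## Censored-normal latent-class growth model (LCGM), fitted by EM.
##
## The observation model: given class k, SBP at a visit is normal with mean
## polynomial_k(rescaled age) + per-visit covariate effects, SD sigma shared
## across classes, optionally censored at (y_min, y_max); repeated measures
## are independent given class.  Age is rescaled internally to
## t = (age - 45) / 10 for conditioning.

#' Censored-normal log-density
#'
#' Normal log-density with point masses at the censoring bounds: values at
#' or below `y_min` contribute `log P(Y <= y_min)` and values at or above
#' `y_max` contribute `log P(Y >= y_max)`; interior values contribute the
#' usual normal log-density.
#'
#' @param y observed values.
#' @param mu,sigma mean and SD of the underlying normal (`sigma > 0`).
#' @param y_min,y_max censoring bounds (`y_min < y_max`; infinite by
#'   default, which reduces to the plain normal log-density).
#' @return vector of log-densities.
#' @export
censored_normal_loglik <- function(y, mu, sigma, y_min = -Inf, y_max = Inf) {
  if (any(!is.finite(y)) || any(!is.finite(mu)))
    stop_param("y and mu must be finite")
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop_param("sigma must be positive and finite")
  if (!(y_min < y_max)) stop_param("y_min must be < y_max")
  n <- max(length(y), length(mu))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- stats::dnorm(y, mu, sigma, log = TRUE)
  lo <- y <= y_min
  hi <- y >= y_max
  if (any(lo))
    out[lo] <- stats::pnorm((y_min - mu[lo]) / sigma[lo], log.p = TRUE)
  if (any(hi))
    out[hi] <- stats::pnorm((y_max - mu[hi]) / sigma[hi],
                            log.p = TRUE, lower.tail = FALSE)
  out
}

## rescaled age used throughout the trajectory model
lcgm_rescale_age <- function(age) (age - 45) / 10

## Build the polynomial basis and per-visit covariate columns.
lcgm_design <- function(ph, covariates, znames = NULL) {
  t_sc <- lcgm_rescale_age(ph$age)
  B <- cbind(1, t_sc, t_sc^2)
  if (is.null(znames)) {
    visits <- sort(unique(ph$visit))
    Z <- NULL; nm <- character(0)
    for (cv in covariates) {
      v <- covariate_numeric(ph, cv)
      for (vis in visits) {
        Z <- cbind(Z, v * (ph$visit == vis))
        nm <- c(nm, paste0(cv, "_v", vis))
      }
    }
    if (is.null(Z)) Z <- matrix(0, nrow(ph), 0L) else colnames(Z) <- nm
  } else {
    ## rebuild to a stored column layout (e.g. when assigning new data)
    Z <- matrix(0, nrow(ph), length(znames),
                dimnames = list(NULL, znames))
    for (nm in znames) {
      parts <- regmatches(nm, regexec("^(.*)_v(\\d+)$", nm))[[1L]]
      v <- covariate_numeric(ph, parts[2L])
      Z[, nm] <- v * (ph$visit == as.integer(parts[3L]))
    }
  }
  list(B = B, Z = Z)
}

covariate_numeric <- function(ph, cv) {
  if (!cv %in% names(ph)) stop_param("covariate not in phenotypes: ", cv)
  v <- ph[[cv]]
  if (cv == "sex") as.numeric(v == "male") else as.numeric(v)
}

## Expanded design stacking one block of rows per class.
lcgm_bigX <- function(B, Z, orders) {
  N <- nrow(B); K <- length(orders); q <- ncol(Z)
  pk <- orders + 1L
  P <- sum(pk) + q
  X <- matrix(0, N * K, P)
  col0 <- cumsum(c(0L, pk))
  for (k in seq_len(K)) {
    rows <- (k - 1L) * N + seq_len(N)
    X[rows, col0[k] + seq_len(pk[k])] <- B[, seq_len(pk[k]), drop = FALSE]
    if (q) X[rows, P - q + seq_len(q)] <- Z
  }
  list(X = X, col0 = col0, pk = pk, P = P, q = q)
}

lcgm_mu <- function(B, Z, beta, gamma) {
  ## N x K matrix of class-conditional means
  K <- length(beta)
  base <- if (length(gamma)) drop(Z %*% gamma) else 0
  vapply(seq_len(K), function(k) {
    drop(B[, seq_along(beta[[k]]), drop = FALSE] %*% beta[[k]]) + base
  }, numeric(nrow(B)))
}

log_sum_exp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

## Core EM loop.  Returns NULL when a start collapses (empty class /
## singular M-step).
lcgm_em <- function(y, B, Z, id, n_ind, orders, init, bounds,
                    maxit = 500L, tol = 1e-8) {
  K <- length(orders)
  N <- length(y)
  bd <- lcgm_bigX(B, Z, orders)
  y_big <- rep(y, K)
  censored <- is.finite(bounds[1L]) || is.finite(bounds[2L])
  pi_k <- init$pi; beta <- init$beta; gamma <- init$gamma; sigma <- init$sigma
  theta <- c(unlist(beta), gamma)

  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    mu <- lcgm_mu(B, Z, beta, gamma)
    ll_obs <- vapply(seq_len(K), function(k)
      censored_normal_loglik(y, mu[, k], sigma, bounds[1L], bounds[2L]),
      numeric(N))
    li <- rowsum(ll_obs, id, reorder = TRUE)       # n_ind x K
    lk <- sweep(li, 2L, log(pi_k), "+")
    ll_i <- log_sum_exp_rows(lk)
    ll <- sum(ll_i)
    if (ll < ll_old - 1e-6)
      stop_invariant("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
    trace <- c(trace, ll)
    converged <- is.finite(ll_old) &&
      abs(ll - ll_old) / (abs(ll_old) + 1) < tol
    ll_old <- ll
    r <- exp(lk - ll_i)                            # responsibilities
    if (converged) break

    ## M-step
    cs <- colSums(r)
    if (any(cs < max(orders) + 2)) return(NULL)
    pi_k <- pmax(cs / n_ind, 1e-10); pi_k <- pi_k / sum(pi_k)
    w_big <- as.vector(r[id, ])
    if (!censored) {
      Xw <- bd$X * w_big
      th_new <- tryCatch(
        drop(solve(crossprod(Xw, bd$X), crossprod(Xw, y_big))),
        error = function(e) NULL)
      if (is.null(th_new) || anyNA(th_new)) return(NULL)
      resid <- y_big - drop(bd$X %*% th_new)
      sigma2 <- sum(w_big * resid^2) / N
      if (sigma2 <= 1e-12) return(NULL)
      theta <- th_new
      sigma <- sqrt(sigma2)
    } else {
      ## generalized EM: improve the expected censored log-likelihood
      negQ <- function(par) {
        s <- exp(par[length(par)])
        m <- drop(bd$X %*% par[-length(par)])
        -sum(w_big * censored_normal_loglik(y_big, m, s,
                                            bounds[1L], bounds[2L]))
      }
      par0 <- c(theta, log(sigma))
      opt <- stats::optim(par0, negQ, method = "BFGS",
                          control = list(maxit = 30L))
      if (opt$value <= negQ(par0)) {
        theta <- opt$par[-length(opt$par)]
        sigma <- exp(opt$par[length(opt$par)])
      }
    }
    beta <- split_theta(theta, bd)$beta
    gamma <- split_theta(theta, bd)$gamma
  }

  ## Wald covariance of the mean parameters at convergence (weighted
  ## least-squares approximation used for term pruning).
  w_big <- as.vector(r[id, ])
  XtWX <- crossprod(bd$X * sqrt(w_big))
  vcov_theta <- tryCatch(sigma^2 * solve(XtWX), error = function(e) NULL)

  list(pi = pi_k, beta = beta, gamma = gamma, sigma = sigma,
       loglik = ll_old, iterations = it, trace = trace, r = r,
       theta = theta, vcov_theta = vcov_theta, design = bd)
}

split_theta <- function(theta, bd) {
  K <- length(bd$pk)
  beta <- lapply(seq_len(K), function(k)
    theta[bd$col0[k] + seq_len(bd$pk[k])])
  gamma <- if (bd$q) theta[bd$P - bd$q + seq_len(bd$q)] else numeric(0)
  list(beta = beta, gamma = gamma)
}

## Per-individual OLS (intercept at t = 0, slope) features for starts.
individual_features <- function(y, t_sc, id) {
  f <- t(vapply(split(data.frame(y = y, t = t_sc), id), function(d) {
    if (nrow(d) < 2L || stats::var(d$t) == 0)
      return(c(mean(d$y), 0))
    sl <- stats::cov(d$t, d$y) / stats::var(d$t)
    c(mean(d$y) - sl * mean(d$t), sl)
  }, numeric(2L)))
  f
}

#' Fit a latent-class growth model
#'
#' Maximizes the censored-normal mixture likelihood by EM with a diverse
#' multistart: k-means clusters of per-individual (intercept, slope)
#' least-squares features, quantile slicing of the fitted individual
#' intercepts, random perturbations of both, and any supplied warm starts
#' (e.g. split solutions from a smaller class count).  Each start runs a
#' short EM; the best few are then run to full convergence and the best
#' final log-likelihood is kept.  The per-iteration log-likelihood is
#' checked to be non-decreasing, and classes are relabeled in increasing
#' order of fitted mean SBP at age 45.
#'
#' @param ph long phenotype data.frame, preprocessed so every individual has
#'   at least 2 visits.
#' @param K number of classes (must satisfy `K <= n_individuals / 25`, the
#'   smallest-group feasibility rule).
#' @param order polynomial degree in rescaled age, at most 2 (quadratic).
#' @param covariates character vector of covariate columns entering with one
#'   coefficient per visit index (default `"sex"`).
#' @param bounds censoring bounds `(y_min, y_max)`; the default
#'   `c(-Inf, Inf)` is the uncensored normal model.
#' @param seed integer seed controlling starts.
#' @param n_starts number of EM starts (default 10).
#' @param maxit,tol EM iteration cap and relative log-likelihood tolerance.
#' @param orders optional per-class polynomial degrees (overrides `order`),
#'   used when pruning terms class by class.
#' @param init optional warm-start parameter list (`pi`, `beta`, `gamma`,
#'   `sigma`); when given only one EM run is performed from it.
#' @param extra_inits optional list of additional warm-start parameter
#'   lists entered into the multistart pool.
#' @return a `trajectory_model`: class count `K`, per-class coefficients on
#'   the rescaled-age (`beta`) and raw-age (`beta_raw`) scales, per-visit
#'   covariate effects `gamma`, mixing proportions `pi`, residual SD
#'   `sigma`, censoring `bounds`, `loglik`, `bic` (log-likelihood minus half
#'   the parameter count times log n-individuals, so larger is better),
#'   `n_individuals`, and bookkeeping needed to assign new data.
#' @export
fit_lcgm <- function(ph, K, order = 2L, covariates = "sex",
                     bounds = c(-Inf, Inf), seed = 1L, n_starts = 10L,
                     maxit = 500L, tol = 1e-8, orders = NULL, init = NULL,
                     extra_inits = list()) {
  K <- assert_count(K, "K", min = 1L)
  if (is.null(orders)) {
    order <- assert_count(order, "order", min = 0L)
    if (order > 2L) stop_param("order must be <= 2")
    orders <- rep.int(order, K)
  }
  if (length(orders) != K || any(orders < 0L) || any(orders > 2L))
    stop_param("orders must give one degree (0..2) per class")
  if (length(bounds) != 2L || !(bounds[1L] < bounds[2L]))
    stop_param("bounds must be (y_min, y_max) with y_min < y_max")
  ph <- ph[order(ph$individual_id, ph$visit), , drop = FALSE]
  ids <- unique(ph$individual_id)
  n_ind <- length(ids)
  if (any(table(ph$individual_id) < 2L))
    stop_param("every individual needs >= 2 visits; run the preprocess ",
               "filters first")
  if (K > n_ind / 25)
    stop(errorCondition(
      paste0("K = ", K, " infeasible: the smallest-group rule (N > 25) ",
             "cannot hold with ", n_ind, " individuals"),
      class = c("trajgwas_infeasible", "error")))

  id <- match(ph$individual_id, ids)
  des <- lcgm_design(ph, covariates)
  y <- ph$sbp
  t_sc <- lcgm_rescale_age(ph$age)

  run_from_r <- function(r0, run_maxit = maxit, run_tol = tol) {
    ## one M-step from hard/soft responsibilities, then EM
    bd <- lcgm_bigX(des$B, des$Z, orders)
    w_big <- as.vector(r0[id, ])
    fit <- stats::lm.wfit(bd$X, rep(y, K), w_big)
    th <- fit$coefficients
    if (anyNA(th)) return(NULL)
    s2 <- sum(w_big * fit$residuals^2) / length(y)
    sp <- split_theta(th, bd)
    ini <- list(pi = pmax(colSums(r0) / n_ind, 1e-6),
                beta = sp$beta, gamma = sp$gamma,
                sigma = sqrt(max(s2, 1e-6)))
    ini$pi <- ini$pi / sum(ini$pi)
    lcgm_em(y, des$B, des$Z, id, n_ind, orders, ini, bounds,
            maxit = run_maxit, tol = run_tol)
  }
  run_from_r_partial <- function(r0) run_from_r(r0, 80L, 1e-6)

  soften <- function(a) {
    r0 <- matrix(0, n_ind, K)
    r0[cbind(seq_len(n_ind), a)] <- 1
    (r0 + 0.05) / (1 + 0.05 * K)   # keeps early M-steps well-conditioned
  }
  best <- NULL
  with_seed(seed, {
    if (!is.null(init)) {
      best <- lcgm_em(y, des$B, des$Z, id, n_ind, orders, init, bounds,
                      maxit = maxit, tol = tol)
      if (is.null(best)) stop_invariant("warm-started EM collapsed")
    } else if (K == 1L) {
      best <- run_from_r(matrix(1, n_ind, 1L))
    } else {
      ## Diverse short starts, then full convergence of the best few: the
      ## mixture surface has many poor local optima, and per-individual
      ## (intercept, slope) features are noisy with 2-4 visits, so k-means
      ## alone is an unreliable guide.
      feats <- individual_features(y, t_sc, id)
      km <- tryCatch(stats::kmeans(scale(feats), K, nstart = 5L),
                     error = function(e) NULL)
      assigns <- list()
      if (!is.null(km)) assigns[[length(assigns) + 1L]] <- km$cluster
      ## level-based quantile slicing of the fitted intercepts
      assigns[[length(assigns) + 1L]] <-
        as.integer(cut(rank(feats[, 1L], ties.method = "first"),
                       breaks = K, labels = FALSE))
      base <- assigns
      while (length(assigns) < n_starts) {
        a <- base[[1L + (length(assigns) %% length(base))]]
        flip <- stats::runif(n_ind) < 0.3
        a[flip] <- sample.int(K, sum(flip), replace = TRUE)
        assigns[[length(assigns) + 1L]] <- a
      }
      short <- list()
      for (a in assigns) {
        if (length(unique(a)) < K) a[sample.int(n_ind, K)] <- seq_len(K)
        res <- tryCatch(run_from_r_partial(soften(a)),
                        error = function(e) {
                          if (inherits(e, "trajgwas_invariant_error")) stop(e)
                          NULL
                        })
        if (!is.null(res)) short[[length(short) + 1L]] <- res
      }
      for (ei in extra_inits) {
        res <- tryCatch(
          lcgm_em(y, des$B, des$Z, id, n_ind, orders, ei, bounds,
                  maxit = 80L, tol = 1e-6),
          error = function(e) NULL)
        if (!is.null(res)) short[[length(short) + 1L]] <- res
      }
      if (length(short)) {
        ord <- order(vapply(short, `[[`, numeric(1L), "loglik"),
                     decreasing = TRUE)
        for (i in ord[seq_len(min(3L, length(ord)))]) {
          warm <- list(pi = short[[i]]$pi, beta = short[[i]]$beta,
                       gamma = short[[i]]$gamma, sigma = short[[i]]$sigma)
          res <- tryCatch(
            lcgm_em(y, des$B, des$Z, id, n_ind, orders, warm, bounds,
                    maxit = maxit, tol = tol),
            error = function(e) {
              if (inherits(e, "trajgwas_invariant_error")) stop(e)
              NULL
            })
          if (!is.null(res) &&
              (is.null(best) || res$loglik > best$loglik)) best <- res
        }
      }
    }
  })
  if (is.null(best))
    stop_invariant("all EM starts collapsed; data cannot support K = ", K)

  ## relabel classes by fitted mean at t = 0 (age 45)
  m0 <- vapply(best$beta, `[[`, numeric(1L), 1L)
  perm <- order(m0)
  pk_old <- orders + 1L
  col0_old <- cumsum(c(0L, pk_old))
  q_z <- ncol(des$Z)
  theta_idx <- c(unlist(lapply(perm, function(kk)
    col0_old[kk] + seq_len(pk_old[kk]))),
    sum(pk_old) + seq_len(q_z))
  if (!is.null(best$vcov_theta))
    best$vcov_theta <- best$vcov_theta[theta_idx, theta_idx, drop = FALSE]
  best$beta <- best$beta[perm]
  best$pi <- best$pi[perm]
  orders <- orders[perm]
  best$r <- best$r[, perm, drop = FALSE]

  q <- ncol(des$Z)
  p_free <- sum(orders + 1L) + q + (K - 1L) + 1L
  bic <- best$loglik - 0.5 * p_free * log(n_ind)
  beta_raw <- lapply(best$beta, raw_age_coefs)

  structure(list(
    K = K, orders = orders,
    beta = best$beta, beta_raw = beta_raw,
    gamma = stats::setNames(best$gamma, colnames(des$Z)),
    pi = best$pi, sigma = best$sigma, bounds = bounds,
    loglik = best$loglik, bic = bic, n_parameters = p_free,
    n_individuals = n_ind, n_obs = length(y),
    covariates = covariates, znames = colnames(des$Z),
    iterations = best$iterations, loglik_trace = best$trace,
    vcov_theta = best$vcov_theta, perm = perm,
    individual_ids = ids),
    class = "trajectory_model")
}

## Warm-start candidates for K classes from a fitted (K-1)-class model:
## each class in turn is split into two copies offset by +-0.7 sigma in
## the intercept, with its mixing mass halved.
split_inits <- function(model) {
  lapply(seq_len(model$K), function(c_) {
    beta <- model$beta
    off <- 0.7 * model$sigma
    b_lo <- beta[[c_]]; b_lo[1L] <- b_lo[1L] - off
    b_hi <- beta[[c_]]; b_hi[1L] <- b_hi[1L] + off
    beta <- append(beta[-c_], list(b_lo, b_hi))
    pi_k <- c(model$pi[-c_], rep(model$pi[c_] / 2, 2L))
    list(pi = pi_k / sum(pi_k), beta = beta,
         gamma = unname(model$gamma), sigma = model$sigma)
  })
}

## map coefficients on t = (age-45)/10 back to raw age
raw_age_coefs <- function(b) {
  b <- c(b, 0, 0)[1:3]
  c(intercept = b[1L] - 4.5 * b[2L] + 20.25 * b[3L],
    linear = b[2L] / 10 - 9 * b[3L] / 100,
    quadratic = b[3L] / 100)
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("trajectory_model: K =", x$K, " n =", x$n_individuals,
      " logLik =", format(x$loglik, digits = 8),
      " BIC =", format(x$bic, digits = 8), "\n")
  cat("  pi:", paste(format(x$pi, digits = 3), collapse = " "), "\n")
  cat("  sigma:", format(x$sigma, digits = 4), "\n")
  for (k in seq_len(x$K))
    cat(sprintf("  class %d (order %d): %s\n", k, x$orders[k],
                paste(format(x$beta[[k]], digits = 4), collapse = " ")))
  if (length(x$gamma))
    cat("  covariate effects:",
        paste(names(x$gamma), format(x$gamma, digits = 3),
              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Posterior class assignment
#'
#' Computes each individual's posterior class-membership probabilities by
#' Bayes' rule from the class-conditional likelihood of its full measurement
#' series and the mixing proportions, and hard-assigns the class with the
#' highest posterior (ties to the lowest class index).
#'
#' @param model a `trajectory_model`.
#' @param ph long phenotype data.frame.
#' @return a `class_assignment` data.frame: `individual_id`, `class`, and
#'   posterior columns `p1..pK`.
#' @export
assign_classes <- function(model, ph) {
  ph <- ph[order(ph$individual_id, ph$visit), , drop = FALSE]
  ids <- unique(ph$individual_id)
  id <- match(ph$individual_id, ids)
  des <- lcgm_design(ph, model$covariates, znames = model$znames)
  mu <- lcgm_mu(des$B, des$Z, model$beta, model$gamma)
  K <- model$K
  ll_obs <- vapply(seq_len(K), function(k)
    censored_normal_loglik(ph$sbp, mu[, k], model$sigma,
                           model$bounds[1L], model$bounds[2L]),
    numeric(nrow(ph)))
  li <- rowsum(ll_obs, id, reorder = TRUE)
  lk <- sweep(li, 2L, log(model$pi), "+")
  post <- exp(lk - log_sum_exp_rows(lk))
  hard <- max.col(post, ties.method = "first")
  out <- data.frame(individual_id = ids, class = hard,
                    stringsAsFactors = FALSE)
  post_df <- as.data.frame(post)
  names(post_df) <- paste0("p", seq_len(K))
  out <- cbind(out, post_df)
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Select the number of trajectory classes
#'
#' Fits the growth-mixture model for each class count in `k_range` in
#' ascending order — warm-starting each count with splits of every class of
#' the previous count's solution, alongside the standard multistart —
#' discards solutions in which any hard-assigned group has 25 or fewer
#' members (a practical interpretability rule), and returns the surviving
#' fit with the highest BIC, breaking ties toward fewer classes.
#'
#' @inheritParams fit_lcgm
#' @param k_range candidate class counts (default 1..6).
#' @param verbose print one line per K.
#' @return the selected `trajectory_model`, with attribute `selection` — a
#'   data.frame of per-K BIC, minimum group size and status.
#' @export
select_num_classes <- function(ph, k_range = 1:6, order = 2L,
                               covariates = "sex", bounds = c(-Inf, Inf),
                               seed = 1L, n_starts = 10L, min_group = 25L,
                               verbose = FALSE) {
  diag_rows <- list()
  fits <- list()
  prev <- NULL
  for (K in sort(k_range)) {
    splits <- if (!is.null(prev) && prev$K == K - 1L)
      split_inits(prev) else list()
    res <- tryCatch(
      fit_lcgm(ph, K, order = order, covariates = covariates,
               bounds = bounds, seed = stage_seed(seed, K),
               n_starts = n_starts, extra_inits = splits),
      trajgwas_infeasible = function(e) e,
      trajgwas_invariant_error = function(e) e)
    if (!inherits(res, "error")) prev <- res
    if (inherits(res, "error")) {
      diag_rows[[as.character(K)]] <- data.frame(
        K = K, bic = NA_real_, loglik = NA_real_, min_group = NA_integer_,
        status = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    grp <- table(factor(assign_classes(res, ph)$class, levels = seq_len(K)))
    status <- if (min(grp) <= min_group) "group_too_small" else "ok"
    if (status == "ok") fits[[as.character(K)]] <- res
    diag_rows[[as.character(K)]] <- data.frame(
      K = K, bic = res$bic, loglik = res$loglik,
      min_group = as.integer(min(grp)), status = status,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("K=%d  BIC=%.2f  min group=%d  %s",
                      K, res$bic, min(grp), status))
  }
  selection <- do.call(rbind, diag_rows)
  rownames(selection) <- NULL
  if (!length(fits))
    stop(errorCondition(
      paste0("no feasible class count in ", paste(range(k_range),
             collapse = ".."), "; per-K diagnostics attached"),
      class = c("trajgwas_infeasible", "error"),
      diagnostics = selection))
  bics <- vapply(fits, `[[`, numeric(1L), "bic")
  ks <- as.integer(names(fits))
  best_k <- ks[order(-bics, ks)][1L]
  out <- fits[[as.character(best_k)]]
  attr(out, "selection") <- selection
  out
}

#' Prune non-significant polynomial terms class by class
#'
#' After the class count is chosen with all classes at the same polynomial
#' order, the highest-order term of each class is Wald-tested; while any
#' class's top term is non-significant the least significant one is dropped
#' and the model refit (warm-started), until every retained term is
#' significant.  Intercepts are always retained.  The class count never
#' changes.
#'
#' @param model fitted `trajectory_model`.
#' @param ph the phenotype data it was fitted on.
#' @param alpha Wald significance level (default 0.05).
#' @return the pruned `trajectory_model`.
#' @export
prune_polynomial_orders <- function(model, ph, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  repeat {
    if (is.null(model$vcov_theta)) break
    orders <- model$orders
    bd <- lcgm_bigX(matrix(0, 1L, 3L),
                    matrix(0, 1L, length(model$znames)), orders)
    worst_p <- -Inf; worst_k <- 0L
    for (k in seq_len(model$K)) {
      if (orders[k] == 0L) next
      j <- bd$col0[k] + orders[k] + 1L      # top coefficient of class k
      se <- sqrt(model$vcov_theta[j, j])
      z <- model$beta[[k]][orders[k] + 1L] / se
      p <- 2 * stats::pnorm(-abs(z))
      if (p > alpha && p > worst_p) { worst_p <- p; worst_k <- k }
    }
    if (worst_k == 0L) break
    orders[worst_k] <- orders[worst_k] - 1L
    init <- list(pi = model$pi,
                 beta = lapply(seq_len(model$K), function(k)
                   model$beta[[k]][seq_len(orders[k] + 1L)]),
                 gamma = unname(model$gamma), sigma = model$sigma)
    model <- fit_lcgm(ph, model$K, covariates = model$covariates,
                      bounds = model$bounds, seed = 1L, orders = orders,
                      init = init)
  }
  model
}

#' Rank trajectory classes by cumulative hypertensive years
#'
#' Relabels classes 1..K in ascending order of the class mean of
#' per-individual cumulative hypertensive years, so rank 1 is the
#' lowest-risk trajectory and rank K the highest.  Ties are broken by the
#' class mean SBP at each individual's last visit.
#'
#' @param assign a `class_assignment`.
#' @param hy_years named vector of hypertensive years (see
#'   [cumulative_hypertensive_years()]).
#' @param ph optional phenotype data for the tie-break.
#' @return the assignment with columns `rank` (per individual) added, and
#'   attributes `rank_of_class` (permutation) and `class_hy_means`.
#' @export
rank_classes <- function(assign, hy_years, ph = NULL) {
  K <- max(assign$class)
  hy <- hy_years[assign$individual_id]
  means <- vapply(seq_len(K), function(k)
    mean(hy[assign$class == k]), numeric(1L))
  tie <- rep(0, K)
  if (!is.null(ph)) {
    ph <- ph[order(ph$individual_id, ph$visit), , drop = FALSE]
    last <- ph[!duplicated(ph$individual_id, fromLast = TRUE), ]
    last_sbp <- stats::setNames(last$sbp, last$individual_id)[
      assign$individual_id]
    tie <- vapply(seq_len(K), function(k)
      mean(last_sbp[assign$class == k]), numeric(1L))
  }
  ord <- order(means, tie)            # class indices from lowest risk up
  rank_of_class <- integer(K)
  rank_of_class[ord] <- seq_len(K)
  assign$rank <- rank_of_class[assign$class]
  attr(assign, "rank_of_class") <- rank_of_class
  attr(assign, "class_hy_means") <- means
  assign
}

#' Write a class assignment as CSV
#' @param assign a `class_assignment` (ranked or not).
#' @param path file path.
#' @export
write_assignment <- function(assign, path) {
  utils::write.csv(as.data.frame(assign), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a trajectory model to JSON
#' @param model a `trajectory_model`.
#' @param path file path.
#' @return `read_trajectory_model` returns the model.
#' @export
write_trajectory_model <- function(model, path) {
  x <- unclass(model)
  x$vcov_theta <- NULL
  x$loglik_trace <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_model
#' @export
read_trajectory_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_coef_list <- function(b) {
    ## equal-order classes simplify to a matrix, mixed orders to a list
    if (is.matrix(b)) b <- asplit(b, 1L)
    lapply(b, function(v) as.numeric(v[!is.na(v)]))
  }
  x$beta <- as_coef_list(x$beta)
  x$beta_raw <- as_coef_list(x$beta_raw)
  x$gamma <- stats::setNames(as.numeric(x$gamma), x$znames)
  x$bounds <- as.numeric(x$bounds)
  x$bounds[is.na(x$bounds)] <- c(-Inf, Inf)[is.na(x$bounds)]
  structure(x, class = "trajectory_model")
}
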