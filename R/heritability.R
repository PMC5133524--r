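## Pedigree-based variance-component heritability by REML.

#' Estimate narrow-sense heritability from a pedigree
#'
#' Fits the animal model `y = X b + g + e` with `cov(g) = 2 Phi sigma_g^2`
#' and i.i.d. residuals by restricted maximum likelihood.  The relationship
#' matrix `A = 2 Phi` is eigendecomposed once; the restricted likelihood is
#' then profiled over the total variance and maximized over
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` on [0, 1] by 1-D optimization.
#' The standard error comes from the observed information (numeric second
#' derivative of the profile restricted log-likelihood, delta-method exact
#' here since h2 is the optimized parameter), and the p-value for
#' `H0: sigma_g^2 = 0` from a likelihood-ratio test against the boundary
#' 50:50 mixture of a point mass at zero and a 1-df chi-square.
#'
#' @param trait named numeric vector (names = individual ids); NAs dropped.
#' @param covariates optional fixed-effect matrix or data.frame with rownames
#'   = individual ids; an intercept is always added.
#' @param phi kinship matrix covering all trait ids.
#' @param fix_h2 optionally fix h2 (e.g. 0 for the no-genetics model)
#'   instead of estimating it.
#' @return a `heritability_result`: `h2`, `se`, `sigma_g2`, `sigma_e2`,
#'   `loglik` (restricted, all constants included), `lrt`, `p_value`, `n`.
#' @export
estimate_h2 <- function(trait, covariates = NULL, phi, fix_h2 = NULL) {
  if (is.null(names(trait))) stop_param("trait must be named by individual id")
  trait <- trait[!is.na(trait)]
  ids <- names(trait)
  if (!all(ids %in% rownames(phi)))
    stop_invariant("trait ids missing from kinship matrix")
  n <- length(ids)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[ids, , drop = FALSE]
    else if (nrow(cv) != n) stop_param("covariates not aligned to trait")
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) stop_param("singular covariate matrix")
  p <- ncol(X)
  A <- 2 * phi[ids, ids]
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, trait))
  Xt <- crossprod(eg$vectors, X)

  ## full restricted log-likelihood profiled over the total variance
  reml_ll <- function(h2) {
    v <- h2 * d + (1 - h2)
    w <- 1 / v
    XtWX <- crossprod(Xt * w, Xt)
    b <- solve(XtWX, crossprod(Xt * w, yt))
    r <- yt - drop(Xt %*% b)
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi) + 1 + log(s2)) + sum(log(v)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1L])
  }

  if (is.null(fix_h2)) {
    opt <- stats::optimize(reml_ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand_h2 <- c(0, opt$maximum, 1)
    cand_ll <- c(reml_ll(0), opt$objective, reml_ll(1 - 1e-10))
    h2 <- cand_h2[which.max(cand_ll)]
    ll <- max(cand_ll)
  } else {
    h2 <- assert_scalar_number(fix_h2, "fix_h2", min = 0, max = 1)
    ll <- reml_ll(min(h2, 1 - 1e-10))
    opt <- NULL
  }

  v <- h2 * d + (1 - h2); w <- 1 / v
  XtWX <- crossprod(Xt * w, Xt)
  b <- solve(XtWX, crossprod(Xt * w, yt))
  s2 <- sum(w * (yt - drop(Xt %*% b))^2) / (n - p)
  sigma_g2 <- h2 * s2
  sigma_e2 <- (1 - h2) * s2

  ## observed-information SE on the h2 scale
  se <- NA_real_
  eps <- 1e-4
  lo <- max(h2 - eps, 0); hi <- min(h2 + eps, 1 - 1e-10)
  if (hi - lo > eps / 2) {
    mid <- (lo + hi) / 2
    curv <- (reml_ll(lo) - 2 * reml_ll(mid) + reml_ll(hi)) /
      (((hi - lo) / 2)^2)
    if (is.finite(curv) && curv < 0) se <- sqrt(-1 / curv)
  }

  lrt <- if (is.null(fix_h2)) max(2 * (ll - reml_ll(0)), 0) else NA_real_
  p_value <- if (is.na(lrt)) NA_real_
    else if (lrt <= 1e-12) 1
    else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  structure(list(h2 = h2, se = se, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 loglik = ll, lrt = lrt, p_value = p_value, n = n,
                 fixed_effects = stats::setNames(drop(b), colnames(X))),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("heritability_result: h2 = %.3f (SE %.3f), sigma_g2 = %.3f, ",
              x$h2, x$se, x$sigma_g2),
      sprintf("sigma_e2 = %.3f, LRT p = %.3g, n = %d\n",
              x$sigma_e2, x$p_value, x$n))
  invisible(x)
}
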