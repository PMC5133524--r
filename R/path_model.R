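## Lagged recursive path model of SBP across visits, used to screen which
## covariates should enter the trajectory model.  The system is
##   SBP_1 = a_1 + sum_c g_{c,1} cov_c + d_1 SNP + e_1
##   SBP_t = a_t + l_t SBP_{t-1} + sum_c g_{c,t} cov_c + d_t SNP + e_t
## estimated equation by equation (the system is recursive, so this is the
## maximum-likelihood fit), with family-clustered sandwich standard errors.

#' Reshape long phenotypes to one row per individual
#'
#' Produces columns `sbp_1..sbp_T` and `age_1..age_T` (by visit index) plus
#' the time-constant covariates.
#'
#' @param ph long phenotype data.frame.
#' @return wide data.frame keyed by `individual_id`.
#' @export
make_wide_phenotypes <- function(ph) {
  ids <- unique(ph$individual_id)
  visits <- sort(unique(ph$visit))
  first <- ph[!duplicated(ph$individual_id), ]
  wide <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  wide$family_id <- first$family_id[match(ids, first$individual_id)]
  wide$sex <- first$sex[match(ids, first$individual_id)]
  if ("smoking" %in% names(ph))
    wide$smoking <- first$smoking[match(ids, first$individual_id)]
  for (v in visits) {
    sub <- ph[ph$visit == v, ]
    wide[[paste0("sbp_", v)]] <- sub$sbp[match(ids, sub$individual_id)]
    wide[[paste0("age_", v)]] <- sub$age[match(ids, sub$individual_id)]
  }
  wide
}

#' Fit the lagged recursive path model for one SNP
#'
#' Fits the per-visit equations above by least squares on individuals with
#' complete data across all visits, using family-clustered sandwich
#' standard errors for all inference (equivalent to classical
#' heteroskedasticity-robust errors when all families are singletons).
#' Indirect covariate effects are reported as products of path coefficients
#' (covariate effect at the origin visit times the chain of lag
#' coefficients), with delta-method standard errors treating the recursive
#' equations as independent.
#'
#' A SNP is only analyzed when each of its genotype categories (0/1/2) has
#' at least `min_genotype_n` individuals; otherwise a classed condition
#' (`trajgwas_snp_skip`) is signalled so callers can skip it rather than
#' crash.
#'
#' @param wide wide per-visit table (see [make_wide_phenotypes()]).
#' @param snp optional named dosage vector (names = individual ids).
#' @param covariates covariate names; each is taken per visit from
#'   `<name>_<t>` when such a column exists (e.g. age), else from the
#'   time-constant column; `sex` is coded male = 1.
#' @param cluster name of the clustering column (default `family_id`).
#' @param min_genotype_n per-genotype minimum for SNP inclusion (default 30).
#' @return a `path_model_fit`: `coefficients` (data.frame: `equation` =
#'   visit, `term`, `estimate`, `se`, `p_value`), `indirect` (data.frame of
#'   indirect effects), log-likelihoods and parameter counts for the fitted,
#'   saturated and independence models, and `n` (complete cases).
#' @export
fit_lagged_path_model <- function(wide, snp = NULL,
                                  covariates = c("sex", "smoking"),
                                  cluster = "family_id",
                                  min_genotype_n = 30L) {
  visits <- sort(as.integer(sub("^sbp_", "",
                                grep("^sbp_", names(wide), value = TRUE))))
  if (length(visits) < 2L) stop_param("need >= 2 visit columns (sbp_t)")

  dat <- wide
  if (!is.null(snp)) {
    g <- snp[dat$individual_id]
    tab <- table(factor(round(g), levels = 0:2))
    if (any(tab < min_genotype_n))
      signal_snp_skip(paste0("genotype counts ",
                             paste(tab, collapse = "/"),
                             " below the per-genotype minimum of ",
                             min_genotype_n))
    dat$snp <- as.numeric(g)
  }
  cov_col <- function(cv, t) {
    per_t <- paste0(cv, "_", t)
    v <- if (per_t %in% names(dat)) dat[[per_t]] else dat[[cv]]
    if (is.null(v)) stop_param("covariate not found: ", cv)
    if (cv == "sex") as.numeric(v == "male") else as.numeric(v)
  }
  ## complete cases across every variable used anywhere in the system
  used <- do.call(cbind, c(
    lapply(visits, function(t) dat[[paste0("sbp_", t)]]),
    lapply(covariates, function(cv)
      do.call(cbind, lapply(visits, function(t) cov_col(cv, t)))),
    if (!is.null(snp)) list(dat$snp)))
  cc <- stats::complete.cases(used)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  if (n < 10L) stop_param("too few complete cases (", n, ")")
  cl <- dat[[cluster]]

  gauss_ll <- function(res) {
    s2 <- mean(res^2)           # ML variance
    -0.5 * length(res) * (log(2 * pi * s2) + 1)
  }
  fit_eq <- function(t, rhs_mat) {
    y <- dat[[paste0("sbp_", t)]]
    X <- cbind(`(Intercept)` = rep(1, n), rhs_mat)
    fit <- stats::lm.fit(X, y)
    keep <- !is.na(fit$coefficients)
    lmfit <- stats::lm(y ~ X[, keep, drop = FALSE] - 1)
    vc <- sandwich::vcovCL(lmfit, cluster = cl)
    est <- fit$coefficients[keep]
    se <- sqrt(diag(vc))
    list(terms = colnames(X)[keep], est = unname(est), se = unname(se),
         ll = gauss_ll(fit$residuals), p_mean = sum(keep))
  }

  coef_rows <- list(); ll_model <- 0; p_model <- 0
  lag_est <- stats::setNames(numeric(0), character(0))
  lag_se <- lag_est
  gamma_est <- list()
  for (t in visits) {
    rhs <- NULL; nms <- character(0)
    if (t > visits[1L]) {
      prev <- visits[which(visits == t) - 1L]
      rhs <- cbind(rhs, dat[[paste0("sbp_", prev)]])
      nms <- c(nms, "lag_sbp")
    }
    for (cv in covariates) { rhs <- cbind(rhs, cov_col(cv, t)); nms <- c(nms, cv) }
    if (!is.null(snp)) { rhs <- cbind(rhs, dat$snp); nms <- c(nms, "snp") }
    if (!is.null(rhs)) colnames(rhs) <- nms
    eq <- fit_eq(t, rhs)
    ll_model <- ll_model + eq$ll; p_model <- p_model + eq$p_mean + 1L
    coef_rows[[as.character(t)]] <- data.frame(
      equation = t, term = eq$terms, estimate = eq$est, se = eq$se,
      p_value = 2 * stats::pnorm(-abs(eq$est / eq$se)),
      stringsAsFactors = FALSE)
    if (t > visits[1L]) {
      lag_est[as.character(t)] <- eq$est[eq$terms == "lag_sbp"]
      lag_se[as.character(t)] <- eq$se[eq$terms == "lag_sbp"]
    }
    for (cv in covariates)
      gamma_est[[paste(cv, t)]] <-
        c(est = eq$est[eq$terms == cv], se = eq$se[eq$terms == cv])
  }
  coefficients <- do.call(rbind, coef_rows)
  rownames(coefficients) <- NULL

  ## saturated: each SBP_t on all earlier SBPs + all covariate columns + SNP
  ll_sat <- 0; p_sat <- 0
  for (t in visits) {
    rhs <- NULL
    earlier <- visits[visits < t]
    for (e in earlier) rhs <- cbind(rhs, dat[[paste0("sbp_", e)]])
    for (cv in covariates)
      for (tt in visits) rhs <- cbind(rhs, cov_col(cv, tt))
    if (!is.null(snp)) rhs <- cbind(rhs, dat$snp)
    X <- cbind(rep(1, n), rhs)
    fit <- stats::lm.fit(X, dat[[paste0("sbp_", t)]])
    ll_sat <- ll_sat + gauss_ll(fit$residuals)
    p_sat <- p_sat + sum(!is.na(fit$coefficients)) + 1L
  }
  ## independence baseline: intercept-only equations
  ll_indep <- 0
  for (t in visits)
    ll_indep <- ll_indep + gauss_ll(dat[[paste0("sbp_", t)]] -
                                      mean(dat[[paste0("sbp_", t)]]))
  p_indep <- 2L * length(visits)

  ## indirect effects: covariate at s propagated through the lag chain
  ind_rows <- list()
  for (cv in covariates) {
    for (s in visits[-length(visits)]) {
      g <- gamma_est[[paste(cv, s)]]
      if (is.null(g) || !length(g)) next
      eff <- g[["est"]]; v <- g[["se"]]^2
      for (t in visits[visits > s]) {
        l_e <- lag_est[as.character(t)]; l_s <- lag_se[as.character(t)]
        v <- v * l_e^2 + eff^2 * l_s^2      # first-order product variance
        eff <- eff * l_e
        se <- sqrt(v)
        ind_rows[[paste(cv, s, t)]] <- data.frame(
          covariate = cv, from = s, to = t, estimate = unname(eff),
          se = unname(se),
          p_value = 2 * stats::pnorm(-abs(eff / se)),
          stringsAsFactors = FALSE)
      }
    }
  }
  indirect <- if (length(ind_rows)) do.call(rbind, ind_rows) else
    data.frame(covariate = character(0), from = integer(0), to = integer(0),
               estimate = numeric(0), se = numeric(0), p_value = numeric(0))
  rownames(indirect) <- NULL

  structure(list(coefficients = coefficients, indirect = indirect,
                 loglik_model = ll_model, p_model = p_model,
                 loglik_sat = ll_sat, p_sat = p_sat,
                 loglik_indep = ll_indep, p_indep = p_indep,
                 n = n, visits = visits, covariates = covariates,
                 snp_used = !is.null(snp)),
            class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat("path_model_fit:", length(x$visits), "visit equations, n =", x$n, "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Fit indices for a path model
#'
#' Likelihood-ratio chi-squares against the saturated recursive system give
#' RMSEA, CFI and TLI; the model is flagged adequate when RMSEA < 0.06 and
#' both CFI and TLI are at least 0.95.
#'
#' @param fit a `path_model_fit`.
#' @param n sample size (defaults to the fit's complete-case count).
#' @return a `fit_indices` list: `rmsea`, `cfi`, `tli`, `chisq_model`,
#'   `df_model`, `model_ok`, `zero_df` (TRUE with a warning when the model
#'   is saturated so RMSEA is defined as 0).
#' @export
compute_fit_indices <- function(fit, n = fit$n) {
  chisq_m <- max(2 * (fit$loglik_sat - fit$loglik_model), 0)
  df_m <- fit$p_sat - fit$p_model
  chisq_i <- max(2 * (fit$loglik_sat - fit$loglik_indep), 0)
  df_i <- fit$p_sat - fit$p_indep
  zero_df <- df_m <= 0
  rmsea <- if (zero_df) {
    warning("model has zero degrees of freedom; RMSEA defined as 0")
    0
  } else sqrt(max(chisq_m - df_m, 0) / (df_m * n))
  denom <- max(chisq_i - df_i, chisq_m - df_m, 1e-12)
  cfi <- 1 - max(chisq_m - df_m, 0) / denom
  tli <- if (zero_df || df_i <= 0 || chisq_i / df_i <= 1) 1 else
    ((chisq_i / df_i) - (chisq_m / df_m)) / ((chisq_i / df_i) - 1)
  structure(list(rmsea = rmsea, cfi = cfi, tli = tli,
                 chisq_model = chisq_m, df_model = df_m,
                 chisq_indep = chisq_i, df_indep = df_i,
                 model_ok = rmsea < 0.06 && cfi >= 0.95 && tli >= 0.95,
                 zero_df = zero_df),
            class = "fit_indices")
}

#' Covariate-retention rule across SNP models
#'
#' A covariate is carried into the trajectory model only when its direct
#' effect is significant at `alpha` at `min_timepoints` or more visits in
#' each of at least `min_models` SNP models — evidence that it shapes SBP
#' consistently, not just in one genetic background.
#'
#' @param fits list of `path_model_fit` objects (one per SNP).
#' @param alpha significance level (default 0.05).
#' @param min_timepoints minimum significant visits per model (default 2).
#' @param min_models minimum qualifying SNP models (default 2).
#' @return character vector of retained covariate names (possibly empty).
#' @export
select_covariates <- function(fits, alpha = 0.05, min_timepoints = 2L,
                              min_models = 2L) {
  if (length(fits) < min_models)
    stop_param("need at least ", min_models, " SNP model fits")
  covs <- unique(unlist(lapply(fits, `[[`, "covariates")))
  retained <- character(0)
  for (cv in covs) {
    qualifying <- vapply(fits, function(f) {
      co <- f$coefficients
      sum(co$term == cv & co$p_value < alpha) >= min_timepoints
    }, logical(1L))
    if (sum(qualifying) >= min_models) retained <- c(retained, cv)
  }
  retained
}
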