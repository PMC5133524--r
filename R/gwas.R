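## Mixed-model genome-wide association on trajectory-class traits.

#' Build analysis traits from a ranked class assignment
#'
#' Produces the K-1 pairwise binary traits (rank-1 class as the referent,
#' coded 0; the comparison class coded 1; everyone else missing) and one
#' ordinal trait carrying the rank labels 1..K as numeric values.
#'
#' @param assign a ranked `class_assignment` (see [rank_classes()]).
#' @return a `trait_set`: named list with `pairwise` (list `pair2`..`pairK`
#'   of named 0/1 vectors) and `ordinal` (named numeric vector).
#' @export
build_traits <- function(assign) {
  if (!"rank" %in% names(assign))
    stop_param("assignment must be ranked first (rank_classes)")
  K <- max(assign$rank)
  if (K < 2L) stop_param("need at least 2 classes to build traits")
  ids <- assign$individual_id
  pairwise <- list()
  for (k in 2:K) {
    v <- rep(NA_real_, length(ids))
    v[assign$rank == 1L] <- 0
    v[assign$rank == k] <- 1
    pairwise[[paste0("pair", k)]] <- stats::setNames(v, ids)
  }
  structure(list(pairwise = pairwise,
                 ordinal = stats::setNames(as.numeric(assign$rank), ids)),
            class = "trait_set")
}

#' Mixed-model genome-wide association scan
#'
#' EMMAX-style two-stage testing: the polygenic variance fraction is
#' estimated once by REML under the null model (intercept + principal
#' components + optional covariates, no SNP); the phenotype, covariates and
#' genotypes are then rotated by the spectral transform of the relationship
#' matrix, which whitens the family covariance, and every SNP is tested by
#' ordinary least squares in the rotated space (generalized least squares in
#' the original space) with a Wald t-test.  Missing dosages are mean-imputed
#' per SNP; SNPs at or below the minor-allele-frequency floor, computed on
#' the analyzed subsample, are excluded.
#'
#' @param trait named numeric vector; NAs define the analyzed subsample.
#' @param gen `genotype_matrix`.
#' @param phi kinship matrix.
#' @param pcs optional `pc_result` (its first `n_pcs` score columns enter as
#'   fixed effects) or a plain score matrix with rownames.
#' @param covariates optional extra fixed-effect matrix (rownames = ids).
#' @param maf_min minor-allele-frequency floor; SNPs with MAF strictly
#'   greater than this are tested (default 0.01).
#' @param n_pcs how many PC columns to use (default 4).
#' @param gws,suggestive significance-tier thresholds passed to
#'   [flag_significance()].
#' @return an `assoc_table` data.frame: `chromosome`, `position`, `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf` (effect-allele frequency in the
#'   analyzed subsample), `beta`, `se`, `p_value`, `tier`; attribute `h2_null`
#'   holds the null-model heritability.
#' @export
run_mixed_gwa <- function(trait, gen, phi, pcs = NULL, covariates = NULL,
                          maf_min = 0.01, n_pcs = 4L,
                          gws = 1.3e-7, suggestive = 1.6e-6) {
  assert_scalar_number(maf_min, "maf_min", min = 0, max = 0.5)
  if (is.null(names(trait))) stop_param("trait must be named by individual id")
  trait <- trait[!is.na(trait)]
  ids <- names(trait)
  if (stats::var(trait) == 0) stop_param("trait is constant")
  if (!all(ids %in% rownames(gen$dosage)))
    stop_invariant("trait ids missing from genotype matrix")
  if (!all(ids %in% rownames(phi)))
    stop_invariant("trait ids missing from kinship matrix")
  n <- length(ids)

  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
    sc <- sc[ids, seq_len(min(n_pcs, ncol(sc))), drop = FALSE]
    X <- cbind(X, sc)
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[ids, , drop = FALSE]
    X <- cbind(X, cv)
  }

  ## stage 1: null-model variance components
  h2_null <- estimate_h2(trait, X[, -1L, drop = FALSE], phi)$h2
  A <- 2 * phi[ids, ids]
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  v <- h2_null * d + (1 - h2_null)
  Tr <- t(eg$vectors) / sqrt(v)       # whitening transform
  ys <- drop(Tr %*% trait)
  Xs <- Tr %*% X

  ## genotypes: analyzed subsample, mean imputation, MAF floor
  G <- gen$dosage[ids, , drop = FALSE]
  eaf <- colMeans(G, na.rm = TRUE) / 2
  if (anyNA(G)) {
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- (2 * eaf)[na_idx[, 2L]]
  }
  maf <- pmin(eaf, 1 - eaf)
  keep <- which(maf > maf_min)
  meta <- gen$snp_meta
  if (!length(keep)) {
    warning("all SNPs below the MAF floor; empty association table")
    out <- data.frame(chromosome = integer(0), position = integer(0),
                      snp_id = character(0), effect_allele = character(0),
                      other_allele = character(0), eaf = numeric(0),
                      beta = numeric(0), se = numeric(0),
                      p_value = numeric(0), tier = character(0))
    class(out) <- c("assoc_table", "data.frame")
    return(out)
  }
  Gs <- Tr %*% G[, keep, drop = FALSE]

  ## stage 2: GLS per SNP via residualization on the null covariates
  qrX <- qr(Xs)
  p <- qrX$rank
  yr <- qr.resid(qrX, ys)
  Gr <- qr.resid(qrX, Gs)
  gg <- colSums(Gr^2)
  gy <- colSums(Gr * yr)
  yy <- sum(yr^2)
  df <- n - p - 1L
  beta <- gy / gg
  rss <- pmax(yy - beta^2 * gg, 0)
  se <- sqrt(rss / df / gg)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  degenerate <- gg < 1e-10
  beta[degenerate] <- NA_real_; se[degenerate] <- NA_real_
  pval[degenerate] <- NA_real_

  out <- data.frame(
    chromosome = meta$chromosome[keep], position = meta$position[keep],
    snp_id = meta$snp_id[keep], effect_allele = meta$effect_allele[keep],
    other_allele = meta$other_allele[keep], eaf = unname(eaf[keep]),
    beta = unname(beta), se = unname(se), p_value = unname(pval),
    stringsAsFactors = FALSE)
  out <- flag_significance(out, gws = gws, suggestive = suggestive)
  attr(out, "h2_null") <- h2_null
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Assign significance tiers to association results
#'
#' Tiers follow the family-study genome-wide conventions: `gws` for
#' `p < 1.3e-7`, `suggestive` for `1.3e-7 <= p < 1.6e-6`, otherwise `none`.
#'
#' @param table data.frame with a `p_value` column.
#' @param gws,suggestive tier thresholds.
#' @return the table with a `tier` column.
#' @export
flag_significance <- function(table, gws = 1.3e-7, suggestive = 1.6e-6) {
  p <- table$p_value
  table$tier <- ifelse(is.na(p), "none",
                       ifelse(p < gws, "gws",
                              ifelse(p < suggestive, "suggestive", "none")))
  table
}

#' Genomic inflation factor and Q-Q coordinates
#'
#' `lambda` is the median of the 1-df chi-square quantile transform of the
#' p-values divided by the null median 0.4549...; values near 1 indicate no
#' systematic inflation.
#'
#' @param pvals vector of at least 100 p-values in (0, 1].
#' @return list with `lambda` and `qq`, a data.frame of expected vs observed
#'   -log10 p sorted for plotting.
#' @export
genomic_lambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) < 100L) stop_param("need at least 100 p-values")
  if (any(pvals <= 0 | pvals > 1)) stop_param("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  n <- length(pvals)
  qq <- data.frame(
    expected = -log10(stats::ppoints(n)),
    observed = -log10(sort(pvals)))
  list(lambda = lambda, qq = qq)
}

#' Write an association table as TSV
#'
#' Columns `CHR POS SNP EA OA EAF BETA SE P TIER`.
#'
#' @param table an `assoc_table`.
#' @param path file path.
#' @export
write_assoc_table <- function(table, path) {
  out <- data.frame(CHR = table$chromosome, POS = table$position,
                    SNP = table$snp_id, EA = table$effect_allele,
                    OA = table$other_allele, EAF = table$eaf,
                    BETA = table$beta, SE = table$se, P = table$p_value,
                    TIER = table$tier)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
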