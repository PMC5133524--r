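## LD pruning and founder-based principal components.

#' Greedy sliding-window LD pruning
#'
#' Standard PLINK-style pruning: SNPs are scanned chromosome by chromosome
#' in windows of `window` SNPs advanced by `step`; within a window, for any
#' pair of retained SNPs whose squared Pearson correlation of dosages
#' exceeds `r2_max`, the later SNP is dropped.  Correlations are computed on
#' the supplied dosage subsample (typically founders).
#'
#' @param gen `genotype_matrix`.
#' @param r2_max squared-correlation ceiling (default 0.2).
#' @param window window size in SNPs (>= 2, default 50).
#' @param step window increment in SNPs (default 5).
#' @param ids optional individual ids to compute correlations on (e.g.
#'   founders); default all.
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(gen, r2_max = 0.2, window = 50L, step = 5L, ids = NULL) {
  assert_scalar_number(r2_max, "r2_max", min = 0, max = 1)
  window <- assert_count(window, "window", min = 2L)
  step <- assert_count(step, "step", min = 1L)
  dos <- gen$dosage
  if (!is.null(ids)) dos <- dos[ids, , drop = FALSE]
  meta <- gen$snp_meta
  keep <- rep(TRUE, ncol(dos))
  for (chr in unique(meta$chromosome)) {
    snps <- which(meta$chromosome == chr)
    start <- 1L
    repeat {
      win <- snps[seq(start, min(start + window - 1L, length(snps)))]
      live <- win[keep[win]]
      if (length(live) >= 2L) {
        cm <- suppressWarnings(stats::cor(dos[, live, drop = FALSE]))
        cm[is.na(cm)] <- 0
        for (a in seq_len(length(live) - 1L)) {
          if (!keep[live[a]]) next
          bad <- which(cm[a, ]^2 > r2_max)
          bad <- bad[bad > a & keep[live[bad]]]
          if (length(bad)) keep[live[bad]] <- FALSE
        }
      }
      if (start + window - 1L >= length(snps)) break
      start <- start + step
    }
  }
  meta$snp_id[keep]
}

#' Principal components from unrelated founders
#'
#' Computes PCA loadings on founder genotypes only (founders are the
#' pedigree members with both parents missing, hence mutually unrelated up
#' to sampling), after centering each SNP at twice its founder allele
#' frequency and scaling by the binomial SD `sqrt(2 f (1 - f))`; all
#' individuals — founders and descendants — are then projected onto the
#' top-`m` loadings, giving ancestry covariates for the association model.
#'
#' @param gen `genotype_matrix`.
#' @param ped pedigree data.frame.
#' @param pruned SNP ids to use (typically from [ld_prune()]); default all.
#' @param m number of components (default 4).
#' @return a `pc_result`: `scores` (all individuals x m), `founder_scores`,
#'   `loadings` (SNP x m), `eigenvalues`, `snp_ids`, `center`, `scale`.
#' @export
founder_pca <- function(gen, ped, pruned = NULL, m = 4L) {
  m <- assert_count(m, "m", min = 1L)
  ped <- validate_pedigree(ped)
  fo <- intersect(founders(ped), rownames(gen$dosage))
  if (length(fo) < m)
    stop_param("fewer founders (", length(fo), ") than requested components")
  snps <- pruned %||% gen$snp_meta$snp_id
  dos <- gen$dosage[, snps, drop = FALSE]
  fdos <- dos[fo, , drop = FALSE]
  f <- colMeans(fdos, na.rm = TRUE) / 2
  poly <- f > 0 & f < 1
  if (!any(poly)) stop_param("no SNP polymorphic among founders")
  fdos <- fdos[, poly, drop = FALSE]
  dos <- dos[, poly, drop = FALSE]
  f <- f[poly]
  ctr <- 2 * f
  scl <- sqrt(2 * f * (1 - f))
  Zf <- sweep(sweep(fdos, 2L, ctr), 2L, scl, "/")
  Zf[is.na(Zf)] <- 0
  sv <- svd(Zf, nu = m, nv = m)
  if (ncol(sv$v) < m) stop_param("not enough variation for ", m, " components")
  loadings <- sv$v
  rownames(loadings) <- colnames(fdos)
  colnames(loadings) <- paste0("PC", seq_len(m))
  Za <- sweep(sweep(dos, 2L, ctr), 2L, scl, "/")
  Za[is.na(Za)] <- 0
  scores <- Za %*% loadings
  structure(list(scores = scores,
                 founder_scores = Zf %*% loadings,
                 loadings = loadings,
                 eigenvalues = sv$d[seq_len(m)]^2 / (length(fo) - 1L),
                 snp_ids = colnames(fdos), center = ctr, scale = scl),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat("pc_result:", ncol(x$scores), "components on", length(x$snp_ids),
      "SNPs;", nrow(x$scores), "individuals projected\n")
  invisible(x)
}

#' Write PC scores as CSV
#' @param pcs a `pc_result`.
#' @param path file path.
#' @export
write_pc_scores <- function(pcs, path) {
  utils::write.csv(
    data.frame(individual_id = rownames(pcs$scores), pcs$scores,
               check.names = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
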