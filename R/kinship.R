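#' Pedigree kinship matrix
#'
#' Computes the kinship coefficient \eqn{\Phi_{ij}} — the probability that a
#' randomly sampled allele from individual *i* is identical by descent to one
#' sampled from *j* — by the standard recursion over a pedigree sorted so
#' parents precede children: founders have \eqn{\Phi_{ii} = 1/2} and are
#' pairwise unrelated; for an individual *i* with parents *f*, *m*,
#' \eqn{\Phi_{ii} = (1 + \Phi_{fm})/2} and \eqn{\Phi_{ij} = (\Phi_{fj} +
#' \Phi_{mj})/2} for any *j* that is not a descendant of *i*.  The additive
#' relationship matrix used by the variance-component models is `2 * phi`.
#'
#' @param ped pedigree data.frame (see [simulate_pedigree()]).
#' @return symmetric numeric matrix with dimnames = individual ids, in
#'   parent-before-child order.
#' @export
kinship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)   # reorders parents first, errors on cycles
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  fa <- unname(idx[ped$father_id]); mo <- unname(idx[ped$mother_id])
  phi <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {            # founder
      phi[i, i] <- 0.5
    } else {
      j <- seq_len(i - 1L)
      phi[i, j] <- phi[j, i] <- 0.5 * (phi[fa[i], j] + phi[mo[i], j])
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
    }
  }
  phi
}

#' Monte-Carlo IBD kinship by gene dropping
#'
#' Independent check of [kinship_matrix()]: drops `n_drops` unlinked loci
#' with unique founder alleles through the pedigree and estimates
#' \eqn{\Phi_{ij}} as the observed probability that one random allele from
#' each individual is identical by descent.
#'
#' @param ped pedigree data.frame.
#' @param n_drops number of simulated loci.
#' @param seed integer seed.
#' @return estimated kinship matrix.
#' @export
kinship_gene_drop <- function(ped, n_drops = 1e4, seed = 1) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  fa <- unname(idx[ped$father_id]); mo <- unname(idx[ped$mother_id])
  with_seed(seed, {
    acc <- matrix(0, n, n)
    a1 <- integer(n); a2 <- integer(n)
    for (d in seq_len(n_drops)) {
      lab <- 0L
      for (i in seq_len(n)) {
        if (is.na(fa[i])) {
          a1[i] <- lab + 1L; a2[i] <- lab + 2L; lab <- lab + 2L
        } else {
          a1[i] <- if (stats::runif(1) < 0.5) a1[fa[i]] else a2[fa[i]]
          a2[i] <- if (stats::runif(1) < 0.5) a1[mo[i]] else a2[mo[i]]
        }
      }
      ## P(random allele of i IBD random allele of j) for this locus
      acc <- acc + 0.25 * ((outer(a1, a1, "==") + outer(a1, a2, "==")) +
                           (outer(a2, a1, "==") + outer(a2, a2, "==")))
    }
    out <- acc / n_drops
    dimnames(out) <- list(ped$individual_id, ped$individual_id)
    out
  })
}

#' Draw a polygenic vector with covariance `var * 2 * phi`
#' @noRd
draw_polygenic <- function(phi, var_g) {
  if (var_g <= 0) return(stats::setNames(rep(0, nrow(phi)), rownames(phi)))
  A <- 2 * phi
  L <- tryCatch(chol(A), error = function(e) chol(A + diag(1e-8, nrow(A))))
  stats::setNames(sqrt(var_g) * drop(crossprod(L, stats::rnorm(nrow(A)))),
                  rownames(phi))
}

#' Write / read kinship as lower-triangle TSV
#'
#' Columns `id1`, `id2`, `kinship`; one row per pair with `id1` index >=
#' `id2` index (diagonal included).
#'
#' @param phi kinship matrix.
#' @param path file path.
#' @return `write_kinship` returns `path` invisibly; `read_kinship` the
#'   matrix.
#' @export
write_kinship <- function(phi, path) {
  ids <- rownames(phi)
  lt <- which(lower.tri(phi, diag = TRUE), arr.ind = TRUE)
  utils::write.table(
    data.frame(id1 = ids[lt[, 1L]], id2 = ids[lt[, 2L]],
               kinship = phi[lt]),
    path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  ids <- unique(c(d$id1, d$id2))
  phi <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  phi[cbind(d$id1, d$id2)] <- d$kinship
  phi[cbind(d$id2, d$id1)] <- d$kinship
  phi
}
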