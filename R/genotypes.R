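#' Simulate genotypes by gene dropping through a pedigree
#'
#' For each biallelic autosomal SNP an effect-allele frequency is drawn
#' uniformly from `maf_range`; founders receive Hardy-Weinberg genotypes at
#' that frequency, and every non-founder receives one allele transmitted at
#' random from each parent, so the output is Mendelian-consistent by
#' construction.  SNPs monomorphic in the realized sample are redrawn
#' (a finite sample can fix or lose a rare allele even when the generating
#' frequency is polymorphic).
#'
#' @param ped pedigree data.frame (see [simulate_pedigree()]).
#' @param n_snps number of SNPs.
#' @param maf_range length-2 numeric, `0 < lo <= hi <= 0.5`.
#' @param seed integer seed.
#' @param n_chromosomes autosomes to spread SNPs across (default 22).
#' @return a `genotype_matrix`: list with `dosage` (individuals x SNPs
#'   integer matrix, effect-allele dosage 0/1/2) and `snp_meta`
#'   (data.frame: `snp_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf` where `eaf` is the realized sample frequency,
#'   i.e. mean dosage / 2).
#' @export
simulate_genotypes <- function(ped, n_snps, maf_range, seed,
                               n_chromosomes = 22L) {
  ped <- validate_pedigree(ped)
  if (nrow(ped) == 0L) stop_param("empty pedigree")
  n_snps <- assert_count(n_snps, "n_snps", min = 1L)
  if (length(maf_range) != 2L || !is.numeric(maf_range))
    stop_param("maf_range must be (lo, hi)")
  lo <- maf_range[1L]; hi <- maf_range[2L]
  if (!(lo > 0 && lo <= hi && hi <= 0.5))
    stop_param("maf_range must satisfy 0 < lo <= hi <= 0.5 ",
               "(lo = 0 would allow monomorphic SNPs)")
  seed <- assert_count(seed, "seed", min = 0L)

  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  fa <- unname(idx[ped$father_id]); mo <- unname(idx[ped$mother_id])
  is_founder <- is.na(fa) & is.na(mo)

  with_seed(seed, {
    freq <- stats::runif(n_snps, lo, hi)
    dos <- matrix(0L, n, n_snps,
                  dimnames = list(ped$individual_id, NULL))
    drop_once <- function(cols, f) {
      for (i in which(is_founder))
        dos[i, cols] <<- stats::rbinom(length(cols), 2L, f)
      for (i in which(!is_founder))   # parents precede children
        dos[i, cols] <<- stats::rbinom(length(cols), 1L, dos[fa[i], cols] / 2) +
          stats::rbinom(length(cols), 1L, dos[mo[i], cols] / 2)
    }
    drop_once(seq_len(n_snps), freq)
    ## redraw SNPs fixed in the realized sample
    for (rep in 1:25) {
      mono <- which(colSums(dos) == 0L | colSums(dos) == 2L * n)
      if (!length(mono)) break
      freq[mono] <- stats::runif(length(mono), lo, hi)
      drop_once(mono, freq[mono])
    }
    if (any(colSums(dos) == 0L | colSums(dos) == 2L * n))
      stop_invariant("could not obtain polymorphic SNPs; raise maf_range")

    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, n_snps, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), "")
    chr <- sort(rep_len(seq_len(n_chromosomes), n_snps))
    pos <- integer(n_snps)
    for (c_ in unique(chr)) {
      k <- sum(chr == c_)
      pos[chr == c_] <- cumsum(1L + stats::rpois(k, 9999L))
    }
    meta <- data.frame(
      snp_id = sprintf("snp%06d", seq_len(n_snps)),
      chromosome = chr, position = pos,
      effect_allele = unname(ea), other_allele = unname(oa),
      eaf = colMeans(dos) / 2,
      stringsAsFactors = FALSE)
    colnames(dos) <- meta$snp_id
    new_genotype_matrix(dos, meta)
  })
}

new_genotype_matrix <- function(dosage, snp_meta) {
  stopifnot(ncol(dosage) == nrow(snp_meta))
  structure(list(dosage = dosage, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  invisible(x)
}

#' Count Mendelian inconsistencies
#'
#' For every individual with two genotyped parents, a dosage is inconsistent
#' when it falls outside the range implied by obligate parental
#' transmissions (e.g. two `0` parents cannot produce a carrier).
#'
#' @param gen `genotype_matrix`.
#' @param ped pedigree data.frame aligned by individual id.
#' @return total count of (individual, SNP) violations.
#' @export
mendelian_errors <- function(gen, ped) {
  ped <- validate_pedigree(ped)
  dos <- gen$dosage[ped$individual_id, , drop = FALSE]
  idx <- stats::setNames(seq_len(nrow(ped)), ped$individual_id)
  fa <- unname(idx[ped$father_id]); mo <- unname(idx[ped$mother_id])
  kids <- which(!is.na(fa) & !is.na(mo))
  bad <- 0L
  for (i in kids) {
    fd <- dos[fa[i], ]; md <- dos[mo[i], ]; cd <- dos[i, ]
    lower <- (fd == 2L) + (md == 2L)
    upper <- 2L - (fd == 0L) - (md == 0L)
    ok <- is.na(cd) | is.na(fd) | is.na(md) | (cd >= lower & cd <= upper)
    bad <- bad + sum(!ok)
  }
  bad
}

#' Genotype quality-control filter
#'
#' Drops SNPs that are monomorphic, fail an exact-style Hardy-Weinberg
#' chi-square test among founders at `hwe_alpha`, or (when a pedigree is
#' supplied) show any Mendelian inconsistency — the standard cleaning
#' applied to family genotype panels before association analysis.
#'
#' @param gen `genotype_matrix`.
#' @param ped optional pedigree for the Mendelian check.
#' @param hwe_alpha significance level of the founder HWE test (default 1e-6;
#'   set to 0 to disable).
#' @return filtered `genotype_matrix` with an attribute `qc_removed`
#'   (data.frame `snp_id`, `reason`).
#' @export
qc_genotypes <- function(gen, ped = NULL, hwe_alpha = 1e-6) {
  dos <- gen$dosage
  n_obs <- colSums(!is.na(dos))
  p_hat <- colMeans(dos, na.rm = TRUE) / 2
  reason <- rep(NA_character_, ncol(dos))
  mono <- p_hat <= 0 | p_hat >= 1
  reason[mono] <- "monomorphic"
  if (hwe_alpha > 0) {
    sub <- if (!is.null(ped)) {
      fo <- intersect(founders(ped), rownames(dos))
      dos[fo, , drop = FALSE]
    } else dos
    pv <- hwe_pvalues(sub)
    reason[is.na(reason) & !is.na(pv) & pv < hwe_alpha] <- "hwe"
  }
  if (!is.null(ped)) {
    ## per-SNP Mendelian violations
    me <- mendelian_error_flags(gen, ped)
    reason[is.na(reason) & me] <- "mendelian"
  }
  keep <- is.na(reason)
  out <- new_genotype_matrix(dos[, keep, drop = FALSE],
                             gen$snp_meta[keep, , drop = FALSE])
  attr(out, "qc_removed") <- data.frame(
    snp_id = gen$snp_meta$snp_id[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

## chi-square HWE test per SNP on a dosage matrix (rows = individuals)
hwe_pvalues <- function(dos) {
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - p)^2; e1 <- 2 * n * p * (1 - p); e2 <- n * p^2
  stat <- (n0 - e0)^2 / pmax(e0, 1e-12) + (n1 - e1)^2 / pmax(e1, 1e-12) +
    (n2 - e2)^2 / pmax(e2, 1e-12)
  out <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out[n == 0 | p <= 0 | p >= 1] <- NA_real_
  out
}

mendelian_error_flags <- function(gen, ped) {
  ped <- validate_pedigree(ped)
  dos <- gen$dosage[ped$individual_id, , drop = FALSE]
  idx <- stats::setNames(seq_len(nrow(ped)), ped$individual_id)
  fa <- unname(idx[ped$father_id]); mo <- unname(idx[ped$mother_id])
  kids <- which(!is.na(fa) & !is.na(mo))
  flag <- rep(FALSE, ncol(dos))
  for (i in kids) {
    fd <- dos[fa[i], ]; md <- dos[mo[i], ]; cd <- dos[i, ]
    lower <- (fd == 2L) + (md == 2L)
    upper <- 2L - (fd == 0L) - (md == 0L)
    bad <- !(is.na(cd) | is.na(fd) | is.na(md)) & (cd < lower | cd > upper)
    flag <- flag | bad
  }
  flag
}

#' Write / read genotypes as PLINK PED/MAP text
#'
#' The MAP file has columns chromosome, SNP id, genetic distance (0) and
#' 1-based physical position; the PED file has the six FAM columns followed
#' by two allele characters per SNP (`0 0` for missing).  Dosage counts the
#' effect allele, which is written as the second allele of heterozygotes.
#'
#' @param gen `genotype_matrix`.
#' @param ped pedigree data.frame (provides the FAM columns).
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return `write_ped_map` returns the prefix invisibly;
#'   [read_genotypes()] reads the files back.
#' @export
write_ped_map <- function(gen, ped, prefix) {
  ped <- validate_pedigree(ped)
  meta <- gen$snp_meta
  utils::write.table(
    data.frame(meta$chromosome, meta$snp_id, 0, meta$position),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  dos <- gen$dosage[ped$individual_id, , drop = FALSE]
  n <- nrow(dos); p <- ncol(dos)
  a1 <- matrix(rep(meta$other_allele, each = n), n, p)
  a2 <- a1
  a1[dos >= 1L & !is.na(dos)] <-
    matrix(rep(meta$effect_allele, each = n), n, p)[dos >= 1L & !is.na(dos)]
  a2[dos == 2L & !is.na(dos)] <-
    matrix(rep(meta$effect_allele, each = n), n, p)[dos == 2L & !is.na(dos)]
  ## in PED convention write a1 a2 with effect allele counted; swap so the
  ## het is written "other effect"
  tmp <- a1; a1 <- a2; a2 <- tmp
  a1[is.na(dos)] <- "0"; a2[is.na(dos)] <- "0"
  geno <- matrix("", n, 2L * p)
  geno[, seq(1L, 2L * p, by = 2L)] <- a1
  geno[, seq(2L, 2L * p, by = 2L)] <- a2
  fam <- data.frame(
    fid = ped$family_id, iid = ped$individual_id,
    pat = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mat = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", 1L, 2L), phe = 0L)
  lines <- paste(fam$fid, fam$iid, fam$pat, fam$mat, fam$sex, fam$phe,
                 apply(geno, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write a minimal VCF v4.2 with GT genotypes
#'
#' @param gen `genotype_matrix`.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gen, path) {
  meta <- gen$snp_meta
  dos <- gen$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")),
             con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(dos))) {
    g <- ifelse(is.na(dos[, j]), "./.", gt[dos[, j] + 1L])
    writeLines(paste(c(meta$chromosome[j], meta$position[j], meta$snp_id[j],
                       meta$other_allele[j], meta$effect_allele[j],
                       ".", "PASS", ".", "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}
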