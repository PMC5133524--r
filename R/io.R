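## Genotype readers: PLINK PED/MAP text and VCF v4.2 (GT only).

#' Read genotypes from PLINK PED/MAP or VCF
#'
#' Dosages count the effect allele.  For VCF this is the ALT allele; for
#' PED/MAP (which carries no allele metadata) the effect allele of each SNP
#' is taken as the second allele of its first heterozygous genotype, falling
#' back to the rarer allele (ties broken to the lexicographically later
#' base) when no heterozygote is present — the convention [write_ped_map()]
#' uses, so a write/read round trip is the identity.  Missing genotypes
#' (`0 0` in PED, `./.` in VCF) stay missing.
#'
#' @param path for `ped_map`, the path prefix (reads `<path>.ped` and
#'   `<path>.map`); for `vcf`, the `.vcf` file.
#' @param format `"ped_map"` (default) or `"vcf"`.
#' @return a `genotype_matrix`; for `ped_map` an attribute `fam` holds the
#'   six pedigree columns.
#' @export
read_genotypes <- function(path, format = c("ped_map", "vcf")) {
  format <- match.arg(format)
  if (format == "ped_map") read_ped_map(path) else read_vcf(path)
}

read_ped_map <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path))
    stop_param("missing ", map_path, " or ", ped_path)
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chromosome", "snp_id", "cm",
                                         "position"))
  p <- nrow(map)
  lines <- readLines(ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 6L + 2L * p)
  if (length(bad))
    stop(errorCondition(
      paste0("PED line ", bad[1L], " has ", lengths(toks)[bad[1L]],
             " fields; expected ", 6L + 2L * p),
      class = c("trajgwas_format_error", "error")))
  n <- length(toks)
  tm <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  iid <- tm[, 2L]
  a1 <- tm[, 6L + seq(1L, 2L * p, by = 2L), drop = FALSE]
  a2 <- tm[, 6L + seq(2L, 2L * p, by = 2L), drop = FALSE]
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing))
    stop(errorCondition(
      paste0("half-missing genotype at PED line ",
             which(rowSums(half_missing) > 0)[1L]),
      class = c("trajgwas_format_error", "error")))
  dos <- matrix(NA_integer_, n, p, dimnames = list(iid, map$snp_id))
  ea <- character(p); oa <- character(p)
  for (j in seq_len(p)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- x1 != "0"
    alleles <- sort(unique(c(x1[obs], x2[obs])))
    if (length(alleles) > 2L)
      stop(errorCondition(
        paste0("SNP ", map$snp_id[j], " has ", length(alleles),
               " alleles in the PED file"),
        class = c("trajgwas_format_error", "error")))
    het <- obs & x1 != x2
    if (any(het)) {
      ea[j] <- x2[which(het)[1L]]
    } else if (length(alleles) == 2L) {
      cnt <- table(factor(c(x1[obs], x2[obs]), levels = alleles))
      ea[j] <- if (cnt[1L] < cnt[2L]) alleles[1L]
        else if (cnt[2L] < cnt[1L]) alleles[2L] else alleles[2L]
    } else ea[j] <- alleles[1L]
    oa[j] <- if (length(alleles) == 2L) setdiff(alleles, ea[j]) else "0"
    dos[obs, j] <- (x1[obs] == ea[j]) + (x2[obs] == ea[j])
  }
  meta <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                     position = map$position, effect_allele = ea,
                     other_allele = oa,
                     eaf = colMeans(dos, na.rm = TRUE) / 2,
                     stringsAsFactors = FALSE)
  out <- new_genotype_matrix(dos, meta)
  attr(out, "fam") <- data.frame(
    family_id = tm[, 1L], individual_id = iid,
    father_id = ifelse(tm[, 3L] == "0", NA_character_, tm[, 3L]),
    mother_id = ifelse(tm[, 4L] == "0", NA_character_, tm[, 4L]),
    sex = ifelse(tm[, 5L] == "1", "male", "female"),
    stringsAsFactors = FALSE)
  out
}

read_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")   # variants x samples
    dos <- t(matrix(gt_to_dosage(as.vector(gt)), nrow(gt), ncol(gt)))
    dimnames(dos) <- list(colnames(gt), rownames(gt))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    if (!length(hdr)) stop(errorCondition(
      "no #CHROM header line in VCF",
      class = c("trajgwas_format_error", "error")))
    cols <- strsplit(lines[hdr], "\t")[[1L]]
    body <- strsplit(lines[(hdr + 1L):length(lines)], "\t")
    bad <- which(lengths(body) != length(cols))
    if (length(bad)) stop(errorCondition(
      paste0("truncated VCF record at line ", hdr + bad[1L]),
      class = c("trajgwas_format_error", "error")))
    bm <- matrix(unlist(body), nrow = length(body), byrow = TRUE)
    fix <- data.frame(CHROM = bm[, 1L], POS = bm[, 2L], ID = bm[, 3L],
                      REF = bm[, 4L], ALT = bm[, 5L],
                      stringsAsFactors = FALSE)
    gtm <- bm[, 10:length(cols), drop = FALSE]   # records x samples
    dos <- t(matrix(gt_to_dosage(as.vector(gtm)), nrow(gtm), ncol(gtm)))
    dimnames(dos) <- list(cols[10:length(cols)], fix$ID)
  }
  meta <- data.frame(snp_id = colnames(dos),
                     chromosome = as.integer(fix$CHROM),
                     position = as.integer(fix$POS),
                     effect_allele = fix$ALT, other_allele = fix$REF,
                     eaf = colMeans(dos, na.rm = TRUE) / 2,
                     stringsAsFactors = FALSE)
  new_genotype_matrix(dos, meta)
}

gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  parts <- strsplit(gt[known], "[/|]")
  out[known] <- vapply(parts, function(a) sum(a == "1"), integer(1L))
  out
}
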