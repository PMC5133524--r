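## Shared fixtures, built in code.  Heavier cohorts are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## Three-generation hand-built family: founder couple f1/m1, their children
## c1 (marries founder s1) and c2, and grandchildren g1, g2 (children of
## c1 x s1).  c1 and c2 are full siblings; g1 and g2 full siblings.
hand_pedigree <- function() {
  data.frame(
    family_id = "F1",
    individual_id = c("f1", "m1", "c1", "c2", "s1", "g1", "g2"),
    father_id = c(NA, NA, "f1", "f1", NA, "c1", "c1"),
    mother_id = c(NA, NA, "m1", "m1", NA, "s1", "s1"),
    sex = c("male", "female", "male", "female", "female", "male", "female"),
    stringsAsFactors = FALSE)
}

## Unrelated singletons (identity-kinship settings).
singleton_pedigree <- function(n, prefix = "i") {
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  data.frame(family_id = ids, individual_id = ids,
             father_id = NA_character_, mother_id = NA_character_,
             sex = rep(c("male", "female"), length.out = n),
             stringsAsFactors = FALSE)
}

## A small analysis-ready cohort reused by several test files.
small_cohort <- function() {
  cached("small_cohort", {
    ped <- simulate_pedigree(8, 3, 5, seed = 42)
    gen <- simulate_genotypes(ped, 300, c(0.1, 0.5), seed = 43)
    sim <- simulate_phenotypes(ped, gen, scenario_config(), seed = 44)
    prep <- filter_individuals(adjust_medication(sim$phenotypes))
    list(ped = ped, gen = gen, truth = sim$truth, ph_raw = sim$phenotypes,
         ph = prep$phenotypes, report = prep$report,
         phi = kinship_matrix(ped))
  })
}

## Simple longitudinal fixture: visits at given ages, constant covariates.
visits_fixture <- function(id, ages, sbp, med = FALSE, sex = "male") {
  n <- length(ages)
  data.frame(family_id = "F1", individual_id = rep(id, n),
             visit = seq_len(n), age = ages, sbp = sbp,
             med_use = rep_len(med, n), sex = rep(sex, n),
             smoking = FALSE, stringsAsFactors = FALSE)
}

## Genotype matrix built directly from a dosage matrix.
geno_from_dosage <- function(dos, chromosome = NULL, position = NULL) {
  p <- ncol(dos)
  meta <- data.frame(
    snp_id = colnames(dos) %||% sprintf("s%04d", seq_len(p)),
    chromosome = chromosome %||% rep(1L, p),
    position = position %||% seq_len(p) * 1000L,
    effect_allele = rep("A", p), other_allele = rep("G", p),
    eaf = colMeans(dos, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE)
  colnames(dos) <- meta$snp_id
  trajgwas:::new_genotype_matrix(dos, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
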