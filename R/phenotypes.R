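## Scenario configuration and the longitudinal phenotype generator.

scenario_keys <- c(
  "name", "n_families", "n_generations", "mean_offspring", "n_snps",
  "maf_lo", "maf_hi", "k_true", "class_props", "class_coefs", "sex_effect",
  "residual_sd", "polygenic_var", "liability_h2", "med_slope", "med_center",
  "med_effect", "missing_rate", "n_visits", "baseline_age_min",
  "baseline_age_max",
  "gap_min", "gap_max", "span_max", "smoking_prev", "smoking_effect")

#' Simulation scenario configuration
#'
#' Builds the parameter set the phenotype generator runs on.  The default
#' (`"paper_mimic"`) emulates a family blood-pressure cohort: 20 extended
#' families of three generations (~950 members), five latent SBP trajectory
#' classes with well-separated quadratic age curves and mixing proportions
#' (0.40, 0.22, 0.18, 0.13, 0.07), a +5 mm Hg male sex effect, a polygenic
#' SBP component spread through the pedigree, visit-level measurement noise
#' of SD 10 mm Hg, up to 4 visits spanning at most 17 years, logistic
#' medication use calibrated to about 20 % of visit records (treated visits
#' observed `med_effect` = 15 mm Hg below the untreated pressure), and MCAR visit
#' deletion heavy enough that roughly three-quarters of members keep the two
#' visits required for analysis.
#'
#' Class polynomials are specified on the rescaled age `t = (age - 45) / 10`
#' as a `k_true x 3` matrix of (intercept, linear, quadratic) coefficients.
#'
#' @param ... overrides of the documented keys; unknown keys are rejected.
#' @return an object of class `scenario_config` (a named list).
#' @examples
#' sc <- scenario_config(missing_rate = 0)
#' sc$k_true
#' @export
scenario_config <- function(...) {
  cfg <- list(
    name = "paper_mimic",
    n_families = 20L, n_generations = 3L, mean_offspring = 5.8,
    n_snps = 2000L, maf_lo = 0.05, maf_hi = 0.5,
    k_true = 5L,
    class_props = c(0.40, 0.22, 0.18, 0.13, 0.07),
    class_coefs = matrix(c(108, 5, 1,
                           125, 8, 2,
                           140, 10, 3,
                           155, 14, 5,
                           175, 10, 8), 5L, 3L, byrow = TRUE),
    sex_effect = 5,
    residual_sd = 10,
    polygenic_var = 9,
    liability_h2 = 0.5,
    med_slope = 0.07, med_center = 171, med_effect = 15,
    missing_rate = 0.45,
    n_visits = 4L,
    baseline_age_min = 25, baseline_age_max = 60,
    gap_min = 4, gap_max = 6.5, span_max = 17,
    smoking_prev = 0.25, smoking_effect = 0)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), scenario_keys)
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop_param("unknown scenario keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  cfg$k_true <- assert_count(cfg$k_true, "k_true", min = 1L)
  if (length(cfg$class_props) != cfg$k_true)
    stop_param("class_props must have k_true entries")
  if (abs(sum(cfg$class_props) - 1) > 1e-8 || any(cfg$class_props <= 0))
    stop_param("class_props must be positive and sum to 1")
  ## flat configs carry class_coefs row-major (one class after another)
  cfg$class_coefs <- if (is.matrix(cfg$class_coefs))
    matrix(as.numeric(cfg$class_coefs), cfg$k_true, 3L)
  else matrix(as.numeric(cfg$class_coefs), cfg$k_true, 3L, byrow = TRUE)
  assert_scalar_number(cfg$residual_sd, "residual_sd", min = 0)
  assert_scalar_number(cfg$polygenic_var, "polygenic_var", min = 0)
  assert_scalar_number(cfg$liability_h2, "liability_h2", min = 0, max = 1)
  assert_scalar_number(cfg$med_effect, "med_effect", min = 0)
  assert_scalar_number(cfg$missing_rate, "missing_rate", min = 0, max = 1)
  if (cfg$gap_min > cfg$gap_max || cfg$gap_min <= 0)
    stop_param("gap range invalid")
  cfg$n_visits <- assert_count(cfg$n_visits, "n_visits", min = 2L)
  structure(cfg, class = "scenario_config")
}

#' Read / write a scenario as a flat key=value text file
#'
#' Vector values (`class_props`, `class_coefs`) are comma-separated;
#' `class_coefs` is stored row-major (one class after another).  Unknown
#' keys are rejected.
#'
#' @param path file path.
#' @param cfg a `scenario_config`.
#' @return `read_scenario_config` returns a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop_param("malformed key=value line in ", path)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  out <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    out[[keys[i]]] <- if (keys[i] == "name") v else
      as.numeric(strsplit(v, ",", fixed = TRUE)[[1L]])
  }
  do.call(scenario_config, out)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(cfg, path) {
  fmt <- function(v) paste(format(v, digits = 15, trim = TRUE), collapse = ",")
  keys <- intersect(scenario_keys, names(cfg))
  writeLines(vapply(keys, function(k) {
    v <- cfg[[k]]
    if (is.matrix(v)) v <- as.vector(t(v))
    paste0(k, " = ", if (is.character(v)) v else fmt(v))
  }, ""), path)
  invisible(path)
}

#' Simulate longitudinal SBP phenotypes over a pedigree
#'
#' Each individual is assigned a latent trajectory class by thresholding a
#' polygenic liability (`liability_h2` of its variance is additive-genetic,
#' spread through the pedigree by the kinship matrix), so class membership
#' is genuinely heritable.  Visit ages start at `Uniform(baseline_age_min,
#' baseline_age_max)` with gaps `Uniform(gap_min, gap_max)`, rescaled when
#' needed so the span never exceeds `span_max` years.  Noise-free SBP at a
#' visit is the class quadratic in rescaled age plus a male sex effect plus
#' an individual polygenic deviation.  Medication use is Bernoulli with
#' logistic probability in that noise-free untreated SBP; treated visits are
#' observed `med_effect` mm Hg lower (the treatment-induced bias the
#' +15 mm Hg analysis correction is designed to undo).  Observed SBP adds
#' N(0, residual_sd^2) visit noise, and whole visits are then deleted
#' completely at random at `missing_rate`.
#'
#' @param ped pedigree data.frame.
#' @param gen optional `genotype_matrix`; accepted for interface symmetry
#'   (the polygenic components are pedigree-based, not marker-based).
#' @param scenario a `scenario_config`.
#' @param seed integer seed.
#' @return list with `phenotypes` (long data.frame: `family_id`,
#'   `individual_id`, `visit`, `age`, `sbp`, `med_use`, `sex`, `smoking`)
#'   and `truth` (per-individual `true_class`, `polygenic_sbp`, `liability`;
#'   generating parameters attached as attributes `class_coefs`,
#'   `sex_effect`, `residual_sd`, `liability_h2`).
#' @export
simulate_phenotypes <- function(ped, gen = NULL, scenario = scenario_config(),
                                seed = 1L) {
  ped <- validate_pedigree(ped)
  if (!inherits(scenario, "scenario_config"))
    stop_param("scenario must be a scenario_config")
  sc <- validate_scenario(scenario)
  seed <- assert_count(seed, "seed", min = 0L)
  n <- nrow(ped)
  phi <- kinship_matrix(ped)

  with_seed(seed, {
    ## heritable class liability
    g_l <- draw_polygenic(phi, sc$liability_h2)
    liab <- g_l + stats::rnorm(n, 0, sqrt(1 - sc$liability_h2))
    cuts <- stats::qnorm(cumsum(sc$class_props))
    cuts[length(cuts)] <- Inf
    true_class <- findInterval(liab, c(-Inf, cuts[-length(cuts)]))
    ## polygenic SBP level
    g_sbp <- draw_polygenic(phi, sc$polygenic_var)
    smoking <- stats::runif(n) < sc$smoking_prev

    nv <- sc$n_visits
    base_age <- stats::runif(n, sc$baseline_age_min, sc$baseline_age_max)
    gaps <- matrix(stats::runif(n * (nv - 1L), sc$gap_min, sc$gap_max),
                   n, nv - 1L)
    span <- rowSums(gaps)
    over <- span > sc$span_max
    gaps[over, ] <- gaps[over, , drop = FALSE] * (sc$span_max / span[over])
    cum_gaps <- if (nv == 2L) gaps else t(apply(gaps, 1L, cumsum))
    ages <- cbind(base_age, base_age + cum_gaps)

    t_sc <- (ages - 45) / 10
    cc <- sc$class_coefs
    mu_class <- cc[true_class, 1L] + cc[true_class, 2L] * t_sc +
      cc[true_class, 3L] * t_sc^2
    latent <- mu_class + sc$sex_effect * (ped$sex == "male") + g_sbp +
      sc$smoking_effect * smoking
    ## medication uptake depends on the underlying (untreated) pressure;
    ## treated visits are observed lower by med_effect — the downward bias
    ## the downstream +15 mm Hg correction is designed to undo
    med <- matrix(stats::runif(n * nv), n, nv) <
      stats::plogis(sc$med_slope * (latent - sc$med_center))
    sbp <- latent - sc$med_effect * med +
      matrix(stats::rnorm(n * nv, 0, sc$residual_sd), n, nv)

    keep <- matrix(stats::runif(n * nv) >= sc$missing_rate, n, nv)
    ph <- data.frame(
      family_id = rep(ped$family_id, nv),
      individual_id = rep(ped$individual_id, nv),
      visit = rep(seq_len(nv), each = n),
      age = as.vector(ages),
      sbp = as.vector(sbp),
      med_use = as.vector(med),
      sex = rep(ped$sex, nv),
      smoking = rep(smoking, nv),
      stringsAsFactors = FALSE)
    ph <- ph[as.vector(keep), , drop = FALSE]
    ph <- ph[order(match(ph$individual_id, ped$individual_id), ph$visit), ,
             drop = FALSE]
    rownames(ph) <- NULL

    truth <- data.frame(
      individual_id = ped$individual_id,
      true_class = true_class,
      polygenic_sbp = unname(g_sbp),
      liability = unname(liab),
      liability_genetic = unname(g_l),
      stringsAsFactors = FALSE)
    attr(truth, "class_coefs") <- cc
    attr(truth, "sex_effect") <- sc$sex_effect
    attr(truth, "residual_sd") <- sc$residual_sd
    attr(truth, "liability_h2") <- sc$liability_h2
    list(phenotypes = ph, truth = truth)
  })
}

#' Write / read the long-format phenotype CSV
#'
#' Header `family_id,individual_id,visit,age,sbp,med_use,sex,smoking`;
#' booleans stored as 0/1.
#'
#' @param ph long phenotype data.frame.
#' @param path file path.
#' @return `read_phenotypes` returns the data.frame.
#' @export
write_phenotypes <- function(ph, path) {
  out <- ph[, c("family_id", "individual_id", "visit", "age", "sbp",
                "med_use", "sex", "smoking")]
  out$med_use <- as.integer(out$med_use)
  out$smoking <- as.integer(out$smoking)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "individual_id", "visit", "age", "sbp",
            "med_use", "sex", "smoking")
  if (!all(need %in% names(ph)))
    stop_param("phenotype file ", path, " lacks columns: ",
               paste(setdiff(need, names(ph)), collapse = ", "))
  ph$med_use <- as.logical(ph$med_use)
  ph$smoking <- as.logical(ph$smoking)
  ph
}
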