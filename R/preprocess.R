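## Phenotype corrections, inclusion filters, and hypertensive-year accrual.

#' Medication correction for systolic blood pressure
#'
#' Adds a fixed offset (default +15 mm Hg) to every SBP measurement taken
#' while on antihypertensive medication, the usual correction for the
#' treatment-induced downward bias of observed SBP.  Non-medicated records
#' are untouched and the input is not modified.
#'
#' @param ph long phenotype data.frame (see [simulate_phenotypes()]).
#' @param offset mm Hg to add to medicated records (>= 0).
#' @return the adjusted data.frame.
#' @examples
#' ph <- data.frame(individual_id = "a", visit = 1, age = 50,
#'                  sbp = 120, med_use = TRUE, sex = "male", smoking = FALSE)
#' adjust_medication(ph)$sbp  # 135
#' @export
adjust_medication <- function(ph, offset = 15) {
  assert_scalar_number(offset, "offset", min = 0)
  ph$sbp <- ph$sbp + offset * as.numeric(ph$med_use)
  ph
}

#' Apply the longitudinal inclusion filters
#'
#' Removes (a) individuals with fewer than 2 SBP measurements and
#' (b) individuals showing an extreme visit-to-visit SBP change: consecutive
#' within-individual differences are pooled across the whole sample, and any
#' individual with a difference more than `z_max` sample standard deviations
#' from the sample mean change is excluded.  The z-scores are computed once
#' on the input sample, without re-estimation after exclusions.
#'
#' @param ph long phenotype data.frame (medication adjustment already
#'   applied).
#' @param z_max absolute z-score cutoff for consecutive changes (default 3).
#' @return list with `phenotypes` (filtered) and `report` (a `filter_report`:
#'   `n_input`, `n_retained`, and an `exclusions` data.frame with
#'   `individual_id` and `reason` in `{"too_few_visits", "extreme_change"}`).
#' @export
filter_individuals <- function(ph, z_max = 3) {
  if (!is.data.frame(ph) || nrow(ph) == 0L) stop_param("empty phenotype table")
  assert_scalar_number(z_max, "z_max", min = 0)
  ph <- ph[order(ph$individual_id, ph$age), , drop = FALSE]
  ids <- unique(ph$individual_id)
  nv <- table(ph$individual_id)[ids]
  too_few <- ids[nv < 2L]

  same <- ph$individual_id[-1L] == ph$individual_id[-nrow(ph)]
  deltas <- diff(ph$sbp)[same]
  delta_id <- ph$individual_id[-1L][same]
  extreme <- character(0)
  if (length(deltas) >= 2L && stats::sd(deltas) > 0) {
    z <- (deltas - mean(deltas)) / stats::sd(deltas)
    extreme <- setdiff(unique(delta_id[abs(z) > z_max]), too_few)
  }
  excl <- rbind(
    data.frame(individual_id = too_few,
               reason = rep("too_few_visits", length(too_few)),
               stringsAsFactors = FALSE),
    data.frame(individual_id = extreme,
               reason = rep("extreme_change", length(extreme)),
               stringsAsFactors = FALSE))
  keep <- !(ph$individual_id %in% excl$individual_id)
  out <- ph[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(
    list(n_input = length(ids),
         n_retained = length(unique(out$individual_id)),
         exclusions = excl),
    class = "filter_report")
  list(phenotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "individuals in,", x$n_retained,
      "retained\n")
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}

#' Write a filter report as CSV
#' @param report a `filter_report`.
#' @param path file path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report$exclusions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative hypertensive years per individual
#'
#' An individual is hypertensive at a visit when the (unadjusted) SBP is at
#' or above `sbp_threshold` or the visit is medicated (treated hypertension
#' counts as hypertension).  Status is carried forward from each visit to
#' the next, so a hypertensive visit accrues the full interval until the
#' following visit and the last visit accrues nothing.
#'
#' @param ph long phenotype data.frame with raw (pre-offset) SBP; every
#'   individual must have >= 2 visits with strictly increasing ages.
#' @param sbp_threshold hypertension cutoff in mm Hg (default 140).
#' @param count_medication whether a medicated visit counts as hypertensive
#'   regardless of SBP (default TRUE).
#' @return named numeric vector of years, one entry per individual.
#' @examples
#' ph <- data.frame(individual_id = rep("a", 4), visit = 1:4,
#'                  age = c(40, 45, 50, 57), sbp = c(150, 150, 150, 150),
#'                  med_use = FALSE, sex = "male", smoking = FALSE)
#' cumulative_hypertensive_years(ph)  # 17
#' @export
cumulative_hypertensive_years <- function(ph, sbp_threshold = 140,
                                          count_medication = TRUE) {
  assert_scalar_number(sbp_threshold, "sbp_threshold", min = 0)
  ph <- ph[order(ph$individual_id, ph$visit), , drop = FALSE]
  res <- vapply(split(ph, ph$individual_id), function(d) {
    if (nrow(d) < 2L) stop_param("individual ", d$individual_id[1L],
                                 " has fewer than 2 visits")
    if (any(diff(d$age) <= 0))
      stop_invariant("ages not strictly increasing for ",
                     d$individual_id[1L])
    hyp <- d$sbp >= sbp_threshold
    if (count_medication) hyp <- hyp | d$med_use
    sum(diff(d$age)[hyp[-nrow(d)]])
  }, numeric(1L))
  res[unique(ph$individual_id)]
}
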