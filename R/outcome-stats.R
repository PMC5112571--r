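#' Read sonication records from CSV
#'
#' One row per sonication with at least `subject`, `total_dose`, and outcome
#' columns (`opening_volume_mm3`, `gd_delivered_nmol`,
#' `delivery_efficiency_pct`); optional logical `sham` and `calibration`
#' flags.
#'
#' @param path CSV file path.
#' @return Data frame of sonication records.
#' @export
read_sonication_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Linear regression of outcome on total cavitation dose
#'
#' Ordinary least squares of a BBB-opening outcome (opening volume,
#' delivered amount, or delivery efficiency) on the total cavitation dose
#' (SCDh + SCDu + ICD), pooled across subjects and per subject.  Sham and
#' calibration sonications are excluded by default.
#'
#' @param records Data frame of sonication records with columns
#'   `total_dose`, the outcome column, and optionally `subject`, `sham`,
#'   `calibration`.
#' @param outcome Outcome column: `"opening_volume_mm3"`,
#'   `"gd_delivered_nmol"` or `"delivery_efficiency_pct"` (or any numeric
#'   column name present in `records`).
#' @param include_sham Include sham-flagged records. Default FALSE.
#' @return List with `pooled` (slope, intercept, r_squared, p_value,
#'   slope_se, n) and `per_subject` (data frame of the same per subject;
#'   subjects with < 3 usable records are skipped).
#' @export
regress_dose_outcome <- function(records,
                                 outcome = c("opening_volume_mm3",
                                             "gd_delivered_nmol",
                                             "delivery_efficiency_pct"),
                                 include_sham = FALSE) {
  if (length(outcome) > 1L) outcome <- match.arg(outcome)
  stopifnot(is.data.frame(records), "total_dose" %in% names(records),
            outcome %in% names(records))
  keep <- is.finite(records$total_dose) & is.finite(records[[outcome]])
  if (!include_sham && "sham" %in% names(records))
    keep <- keep & !isTRUE_vec(records$sham)
  if ("calibration" %in% names(records))
    keep <- keep & !isTRUE_vec(records$calibration)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 3L)
    stop("degenerate-design: need >= 3 records with finite dose and outcome")
  if (stats::var(rec$total_dose) == 0)
    stop("degenerate-design: total cavitation dose has zero variance")

  fit_one <- function(df) {
    fit <- stats::lm(df[[outcome]] ~ df$total_dose)
    sm <- summary(fit)
    co <- sm$coefficients
    data.frame(slope = co[2, 1], intercept = co[1, 1],
               slope_se = co[2, 2],
               r_squared = sm$r.squared,
               p_value = co[2, 4], n = nrow(df))
  }
  pooled <- fit_one(rec)
  per_subject <- NULL
  if ("subject" %in% names(rec)) {
    per_subject <- do.call(rbind, lapply(split(rec, rec$subject), function(df) {
      if (nrow(df) < 3L || stats::var(df$total_dose) == 0) return(NULL)
      cbind(subject = df$subject[1], fit_one(df))
    }))
    rownames(per_subject) <- NULL
  }
  list(pooled = pooled, per_subject = per_subject, outcome = outcome)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) !is.na(x) & x
  else x %in% c("TRUE", "true", "1", 1)
}

#' Two-sample comparison of cavitation levels between outcome groups
#'
#' Two-tailed pooled-variance (Student's) t-test comparing, e.g., the
#' harmonic stable-cavitation dose between sonications that did and did not
#' produce a significant BBB opening.  Significance at p < 0.05.
#'
#' @param values Numeric vector (e.g. SCDh per sonication).
#' @param opened Logical vector splitting `values` into the two groups.
#' @return List with `t`, `p_value`, `df`, `mean_opened`, `mean_unopened`,
#'   `significant`.
#' @export
compare_groups <- function(values, opened) {
  stopifnot(is.numeric(values), length(values) == length(opened))
  opened <- as.logical(opened)
  ok <- is.finite(values) & !is.na(opened)
  v <- values[ok]; g <- opened[ok]
  if (sum(g) < 2L || sum(!g) < 2L)
    stop("insufficient-group: need >= 2 values per group")
  ht <- stats::t.test(v[g], v[!g], var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_opened = mean(v[g]), mean_unopened = mean(v[!g]),
       significant = ht$p.value < 0.05)
}

#' Simulate sonication records with a known dose-outcome relation
#'
#' Generates records whose outcome is `intercept + slope * total_dose +
#' Gaussian noise`, for validating the regression recovery and its null
#' behaviour.
#'
#' @param n Number of records.
#' @param slope,intercept True linear relation (slope 0 gives the null).
#' @param noise_sd Outcome noise standard deviation.
#' @param dose_range Range of total cavitation doses to draw from
#'   (uniform).
#' @param n_subjects Records are split evenly across this many subjects.
#' @param seed Integer seed.
#' @return Data frame with `subject`, `total_dose`,
#'   `opening_volume_mm3`, `sham`.
#' @export
simulate_dose_outcome <- function(n = 40, slope = 1, intercept = 0,
                                  noise_sd = 50, dose_range = c(50, 400),
                                  n_subjects = 3, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dose <- stats::runif(n, dose_range[1], dose_range[2])
  data.frame(
    subject = paste0("NHP", rep_len(seq_len(n_subjects), n)),
    total_dose = dose,
    opening_volume_mm3 = intercept + slope * dose + stats::rnorm(n, sd = noise_sd),
    sham = FALSE)
}

#' Write a statistics report as JSON
#'
#' @param regression Result of [regress_dose_outcome()].
#' @param comparison Optional result of [compare_groups()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(regression, comparison = NULL, path) {
  jsonlite::write_json(list(regression = regression, comparison = comparison),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
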