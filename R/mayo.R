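# Mayo imaging classification for ADPKD: prognostic subclasses 1A-1E from
# height-adjusted TKV and age, via the implied theoretical annual growth
# rate anchored at 150 ml/m at age zero. Atypical (class 2) morphology gets
# no subclass.

MAYO_BOUNDS <- c(`1A/1B` = 1.5, `1B/1C` = 3.0, `1C/1D` = 4.5, `1D/1E` = 6.0)

#' Mayo imaging class from HtTKV and age
#'
#' For typical (class 1, bilateral diffuse) morphology the estimated annual
#' growth rate is `r = (HtTKV / 150)^(1/age) - 1` (HtTKV in ml/m, theoretical
#' 150 ml/m at age 0); the subclass follows the thresholds
#' 1A < 1.5%, 1B 1.5-3%, 1C 3-4.5%, 1D 4.5-6%, 1E > 6% per year. Cases whose
#' rate falls within `boundary_tol_pct` percentage points of a threshold are
#' flagged borderline for manual reanalysis. Atypical morphology
#' (`typical = FALSE`) returns class 2 with no growth rate.
#'
#' @param htkv_ml_per_m height-adjusted TKV, ml per metre (> 0).
#' @param age_years age in years (> 0).
#' @param typical `TRUE` for class 1 morphology, `FALSE` for class 2.
#' @param boundary_tol_pct borderline flag tolerance, percentage points.
#' @return list with `value` ("1A".."1E" or "2"), `growth_rate_pct`
#'   (%/year, `NA` for class 2), `borderline` and `boundary` (which threshold
#'   was grazed, or `NA`).
#' @export
mayo_classify <- function(htkv_ml_per_m, age_years, typical = TRUE,
                          boundary_tol_pct = 0.1) {
  if (!is.numeric(htkv_ml_per_m) || htkv_ml_per_m <= 0)
    stop("HtTKV must be > 0 ml/m")
  if (!is.numeric(age_years) || age_years <= 0) stop("age must be > 0 years")
  if (!isTRUE(typical))
    return(list(value = "2", growth_rate_pct = NA_real_, borderline = FALSE,
                boundary = NA_character_))
  r <- ((htkv_ml_per_m / 150)^(1 / age_years) - 1) * 100
  cls <- c("1A", "1B", "1C", "1D", "1E")[findInterval(r, MAYO_BOUNDS) + 1L]
  dist <- abs(r - MAYO_BOUNDS)
  near <- which.min(dist)
  borderline <- unname(dist[near] <= boundary_tol_pct)
  list(value = cls, growth_rate_pct = r, borderline = borderline,
       boundary = if (borderline) names(MAYO_BOUNDS)[near] else NA_character_)
}

#' HtTKV at the Mayo class boundaries for a given age
#'
#' Closed form `150 * (1 + r_b)^age` for each growth-rate threshold `r_b`.
#'
#' @param age_years age in years.
#' @return named numeric vector of boundary HtTKV values (ml/m).
#' @export
mayo_boundaries_htkv <- function(age_years) {
  stopifnot(age_years > 0)
  vapply(MAYO_BOUNDS / 100, function(rb) 150 * (1 + rb)^age_years, numeric(1))
}

#' Classify a cohort table
#'
#' @param df data frame with columns `htkv`, `age` and optionally `typical`
#'   (default `TRUE`) and `patient_id`.
#' @param boundary_tol_pct passed to [mayo_classify()].
#' @return the input with `class`, `growth_rate_pct`, `borderline` and
#'   `boundary` columns appended.
#' @export
mayo_classify_cohort <- function(df, boundary_tol_pct = 0.1) {
  stopifnot(all(c("htkv", "age") %in% names(df)))
  typ <- if ("typical" %in% names(df)) as.logical(df$typical) else rep(TRUE, nrow(df))
  res <- lapply(seq_len(nrow(df)), function(i)
    mayo_classify(df$htkv[i], df$age[i], typ[i], boundary_tol_pct))
  df$class <- vapply(res, `[[`, character(1), "value")
  df$growth_rate_pct <- vapply(res, `[[`, numeric(1), "growth_rate_pct")
  df$borderline <- vapply(res, `[[`, logical(1), "borderline")
  df$boundary <- vapply(res, `[[`, character(1), "boundary")
  df
}

#' Misclassification table between two class assignments
#'
#' Counts each transition (e.g. "C to B") between the reference and test
#' class lists, in the style of a misclassification summary over a cohort.
#'
#' @param reference_classes,test_classes equal-length character vectors of
#'   Mayo classes ("1A".."1E" or "2").
#' @return list with `transitions` (named counts, only nonzero entries) and
#'   `total` misclassified.
#' @export
concordance_table <- function(reference_classes, test_classes) {
  if (length(reference_classes) != length(test_classes))
    stop("class lists must have equal length")
  mis <- reference_classes != test_classes
  lab <- function(x) sub("^1", "", x)
  trans <- paste(lab(reference_classes[mis]), "to", lab(test_classes[mis]))
  counts <- if (length(trans)) table(trans) else table(character(0))
  list(transitions = as.list(counts), total = sum(mis))
}
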