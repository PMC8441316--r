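#' Intensity category thresholds
#'
#' Three strictly increasing cutoffs defining the four ordered reporter
#' bins (none/very-low, low, medium, high). [default_thresholds()] derives
#' them as the quartiles of the day-1 control intensity distribution, the
#' packaged stand-in for visual-inspection binning.
#'
#' @param t1,t2,t3 strictly increasing non-negative cutoffs.
#' @return A `category_thresholds` object.
#' @export
category_thresholds <- function(t1, t2, t3) {
  if (!(t1 < t2 && t2 < t3)) stop("thresholds must be strictly increasing")
  structure(list(t1 = t1, t2 = t2, t3 = t3), class = "category_thresholds")
}

#' @rdname category_thresholds
#' @param trajectories tidy reporter data.frame (columns drug, day,
#'   intensity).
#' @param day reference day (default 1).
#' @export
default_thresholds <- function(trajectories, day = 1) {
  x <- trajectories$intensity[trajectories$drug == "control" &
                                trajectories$day == day]
  if (!length(x)) stop("no control observations at day ", day)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  category_thresholds(q[[1]], q[[2]], q[[3]])
}

#' Reporter intensity category labels, in order
#' @return Character vector of the four ordered bins.
#' @export
intensity_categories <- function() {
  c("none/very-low", "low", "medium", "high")
}

#' Bin reporter intensities into the four ordered categories
#'
#' Half-open binning: `[0, t1)` none/very-low, `[t1, t2)` low, `[t2, t3)`
#' medium, `[t3, Inf)` high — so an intensity exactly at a cutoff falls in
#' the upper bin. Monotone in intensity.
#'
#' @param intensity numeric vector, all >= 0.
#' @param thresholds a `category_thresholds`.
#' @return Ordered factor over [intensity_categories()].
#' @export
categorize_intensity <- function(intensity, thresholds) {
  stopifnot(inherits(thresholds, "category_thresholds"))
  if (any(intensity < 0)) stop("negative intensity")
  cuts <- c(-Inf, thresholds$t1, thresholds$t2, thresholds$t3, Inf)
  cut(intensity, breaks = cuts, labels = intensity_categories(),
      right = FALSE, ordered_result = TRUE)
}

#' Fit the linear decline of mean reporter intensity over adulthood
#'
#' Ordinary least squares of per-day mean intensity on day. Requires at
#' least 3 distinct days. Scale-equivariant: multiplying intensities by a
#' constant multiplies slope and intercept by it.
#'
#' @param mean_intensity per-day mean intensities.
#' @param days matching day values.
#' @return List with `slope` (intensity units/day), `intercept`,
#'   `r_squared`.
#' @export
fit_decline <- function(mean_intensity, days) {
  if (length(unique(days)) < 3) stop("need >= 3 distinct days")
  fit <- stats::lm(mean_intensity ~ days)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mean_intensity - mean(mean_intensity))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[["days"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = r2)
}

#' Standardized treated-vs-control effect on reporter intensity
#'
#' Effect size is the difference of arm means divided by the pooled SD;
#' positive values mean prolonged (higher) expression under treatment. The
#' p-value comes from a two-sided Wilcoxon-Mann-Whitney rank test, robust
#' to the skewed intensity distributions that categorical scoring implies.
#' A fully degenerate comparison (zero variance in both arms) returns
#' effect 0, p 1, `degenerate = TRUE`.
#'
#' @param treated,control numeric intensity vectors (>= 5 animals each).
#' @return List with `effect`, `p_value`, `degenerate`.
#' @export
prolongation_effect <- function(treated, control) {
  if (length(treated) < 5 || length(control) < 5) {
    stop("need >= 5 animals per arm")
  }
  v_t <- stats::var(treated); v_c <- stats::var(control)
  pooled <- sqrt(((length(treated) - 1) * v_t +
                    (length(control) - 1) * v_c) /
                   (length(treated) + length(control) - 2))
  if (pooled == 0) {
    return(list(effect = 0, p_value = 1, degenerate = TRUE))
  }
  p <- suppressWarnings(stats::wilcox.test(treated, control,
                                           exact = FALSE)$p.value)
  list(effect = (mean(treated) - mean(control)) / pooled,
       p_value = p, degenerate = FALSE)
}

#' Per-dose effects and dose selection for a reporter assay
#'
#' Computes the [prolongation_effect()] of every tested dose against the
#' control arm at the scoring day, BH-adjusts the p-values across doses,
#' and selects a dose by the rule of [select_dose()].
#'
#' @param trajectories tidy reporter data.frame (animal_id, day, drug, dose,
#'   intensity) with a `"control"` arm.
#' @param score_day adulthood day used for scoring (default 4).
#' @param alpha FDR level for dose eligibility.
#' @return List with `table` (data.frame dose/effect/p_value/q_value) and
#'   `selected_dose` (numeric or `NA`).
#' @export
dose_response <- function(trajectories, score_day = 4, alpha = 0.05) {
  ctrl <- trajectories$intensity[trajectories$drug == "control" &
                                   trajectories$day == score_day]
  doses <- sort(unique(trajectories$dose[trajectories$drug != "control"]))
  if (!length(doses)) stop("no treated dose present")
  res <- lapply(doses, function(d) {
    tr <- trajectories$intensity[trajectories$drug != "control" &
                                   trajectories$dose == d &
                                   trajectories$day == score_day]
    prolongation_effect(tr, ctrl)
  })
  tab <- data.frame(dose = doses,
                    effect = vapply(res, `[[`, numeric(1), "effect"),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"))
  adj <- bh_adjust(tab$p_value, alpha = alpha)
  tab$q_value <- adj$q_values
  list(table = tab, selected_dose = select_dose(tab, alpha = alpha))
}

#' Select the working dose from a dose-response table
#'
#' Among doses with `q_value <= alpha` and a positive effect, picks the one
#' with maximal effect; exact effect ties go to the lowest dose. Returns
#' `NA` when no dose qualifies. Never returns an untested dose, and raising
#' `alpha` never removes a previously eligible dose.
#'
#' @param dose_table data.frame with columns dose, effect, q_value.
#' @param alpha FDR level (default 0.05).
#' @return Selected dose (numeric) or `NA`.
#' @export
select_dose <- function(dose_table, alpha = 0.05) {
  stopifnot(all(c("dose", "effect", "q_value") %in% names(dose_table)))
  ok <- dose_table$q_value <= alpha & dose_table$effect > 0
  if (!any(ok)) return(NA_real_)
  cand <- dose_table[ok, , drop = FALSE]
  cand <- cand[order(-cand$effect, cand$dose), , drop = FALSE]
  cand$dose[[1]]
}

#' Per-day category distribution of a reporter experiment
#'
#' @param trajectories tidy reporter data.frame.
#' @param thresholds a `category_thresholds`; derived from day-1 controls
#'   when missing.
#' @return data.frame drug/dose/day/category/n.
#' @export
category_distribution <- function(trajectories, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- default_thresholds(trajectories)
  cat_col <- categorize_intensity(trajectories$intensity, thresholds)
  out <- as.data.frame(table(drug = trajectories$drug,
                             dose = trajectories$dose,
                             day = trajectories$day,
                             category = cat_col),
                       stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  out$dose <- as.numeric(out$dose)
  out$day <- as.numeric(out$day)
  out
}
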