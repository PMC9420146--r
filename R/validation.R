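#' Per-instar summary statistics
#'
#' Computes, for each instar in an assigned dataset, the count, mean,
#' standard deviation (sample, n - 1 denominator), standard error and
#' coefficient of variation of head-capsule width. These are the summary
#' rows from which the Brooks and Crosby growth indices are derived.
#'
#' @param data Data frame with a width column and an instar label column
#'   (e.g. from [assign_instars()]).
#' @param column Name of the width column, micrometres.
#' @param instar Name of the instar label column.
#' @return A tibble with one row per instar, ascending: `instar`, `n`,
#'   `mean`, `sd`, `se`, `cv` (percent). A single-observation instar gets
#'   `sd = 0`. An instar index with zero members is an error.
#' @export
instar_stats <- function(data, column = "hcw_um", instar = "instar") {
  stopifnot(is.data.frame(data), column %in% names(data),
            instar %in% names(data))
  lv <- sort(unique(data[[instar]]))
  if (length(lv) == 0L) stop("no instar labels present", call. = FALSE)
  expected <- seq.int(min(lv), max(lv))
  missing_lv <- setdiff(expected, lv)
  if (length(missing_lv) > 0L) {
    stop("instar(s) with zero members: ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::group_by(instar = .data[[instar]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[column]]),
      sd = stats::sd(.data[[column]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$instar) |>
    dplyr::mutate(
      sd = ifelse(.data$n == 1L, 0, .data$sd),
      se = .data$sd / sqrt(.data$n),
      cv = 100 * .data$sd / .data$mean
    )
}

#' Brooks' index: growth ratio between successive instars
#'
#' The ratio of the mean head-capsule width of instar n to that of instar
#' n - 1. Under Dyar's rule this ratio is approximately constant across
#' moults, typically between about 1.1 and 1.9 for insect larvae.
#'
#' @param mean_n Mean HCW of instar n, micrometres (> 0). Vectorised.
#' @param mean_prev Mean HCW of instar n - 1, micrometres (> 0).
#' @return `mean_n / mean_prev`.
#' @export
#' @examples
#' brooks_index(473.7, 365.0)   # 1.2978
brooks_index <- function(mean_n, mean_prev) {
  if (any(mean_n <= 0) || any(mean_prev <= 0)) {
    stop("means must be strictly positive", call. = FALSE)
  }
  mean_n / mean_prev
}

#' Crosby's index: relative change between successive Brooks indices
#'
#' Crosby's growth rule holds that consecutive growth ratios should be
#' nearly equal if no instar has been missed or split; the index is the
#' relative change `(b_n - b_{n-1}) / b_{n-1}` between successive Brooks
#' indices, and values small in magnitude (conventionally below 0.1)
#' support the instar partition.
#'
#' @param b_n Brooks index of instar n. Vectorised.
#' @param b_prev Brooks index of instar n - 1 (non-zero).
#' @return `(b_n - b_prev) / b_prev`.
#' @export
#' @examples
#' crosby_index(1.2202, 1.2978)   # -0.0598
crosby_index <- function(b_n, b_prev) {
  if (any(b_prev == 0)) stop("previous Brooks index must be non-zero", call. = FALSE)
  (b_n - b_prev) / b_prev
}

#' Validation report: statistics, growth indices and criteria verdicts
#'
#' Assembles the full per-instar validation table: summary statistics,
#' Brooks' index from the second instar onward, Crosby's index from the
#' third onward, and pass flags against the homogeneity (CV) and growth-
#' rule (Crosby) criteria.
#'
#' @inheritParams instar_stats
#' @param cv_threshold Coefficient-of-variation criterion, percent
#'   (default 15): each instar must have CV strictly below it.
#' @param crosby_threshold Crosby criterion (default 0.1): each Crosby
#'   index must be strictly below it in absolute value. The magnitude is
#'   used because a growth ratio deviating in either direction signals a
#'   missed or split instar.
#' @return An object of class `instar_validation`: a list with `stats`
#'   (the per-instar tibble with `brooks`, `crosby`, `cv_pass`,
#'   `crosby_pass` columns), `overall` (logical conjunction of all
#'   applicable verdicts), and the thresholds used.
#' @seealso [evaluate_criteria()] to re-judge an existing table under
#'   different thresholds.
#' @export
validate_instars <- function(data, column = "hcw_um", instar = "instar",
                             cv_threshold = 15, crosby_threshold = 0.1) {
  stats_tbl <- instar_stats(data, column = column, instar = instar)
  stats_tbl <- add_growth_indices(stats_tbl)
  evaluate_criteria(stats_tbl, cv_threshold = cv_threshold,
                    crosby_threshold = crosby_threshold)
}

# Append brooks (k-1 values, NA for the first instar) and crosby (k-2
# values, NA for the first two) columns to a per-instar stats tibble.
add_growth_indices <- function(stats_tbl) {
  m <- stats_tbl$mean
  k <- length(m)
  brooks <- c(NA_real_, if (k >= 2L) brooks_index(m[-1L], m[-k]))
  crosby <- rep(NA_real_, k)
  if (k >= 3L) {
    b <- brooks[-1L]
    crosby[3:k] <- crosby_index(b[-1L], b[-(k - 1L)])
  }
  dplyr::mutate(stats_tbl, brooks = brooks, crosby = crosby)
}

#' Judge instar criteria on a validation table
#'
#' Applies the two instar-number criteria to a per-instar table that
#' already carries `cv`, `brooks` and `crosby` columns (see
#' [validate_instars()]): the within-instar coefficient of variation must
#' be strictly below `cv_threshold` percent, and each Crosby index must be
#' strictly below `crosby_threshold` in absolute value. Both inequalities
#' are strict, so a CV of exactly 15 percent fails. Lowering either
#' threshold can only turn passes into fails, never the reverse.
#'
#' @param stats_tbl Per-instar tibble with `cv` and `crosby` columns.
#' @inheritParams validate_instars
#' @return An `instar_validation` object (see [validate_instars()]).
#' @export
evaluate_criteria <- function(stats_tbl, cv_threshold = 15,
                              crosby_threshold = 0.1) {
  stopifnot(is.data.frame(stats_tbl), cv_threshold > 0, crosby_threshold > 0)
  if (!"crosby" %in% names(stats_tbl)) stats_tbl <- add_growth_indices(stats_tbl)
  out <- dplyr::mutate(
    stats_tbl,
    cv_pass = .data$cv < cv_threshold,
    crosby_pass = ifelse(is.na(.data$crosby), NA,
                         abs(.data$crosby) < crosby_threshold)
  )
  overall <- all(out$cv_pass) && all(stats::na.omit(out$crosby_pass))
  structure(
    list(stats = out, overall = overall,
         cv_threshold = cv_threshold, crosby_threshold = crosby_threshold),
    class = "instar_validation"
  )
}

#' @export
print.instar_validation <- function(x, ...) {
  cat(sprintf("Instar validation (CV < %g%%, |Crosby| < %g): %s\n",
              x$cv_threshold, x$crosby_threshold,
              if (x$overall) "all criteria pass" else "criteria FAIL"))
  print(x$stats)
  invisible(x)
}

#' Dyar's-rule regression of log mean width on instar number
#'
#' Under Dyar's rule head-capsule width grows by a constant factor per
#' moult, so the natural logarithm of the mean HCW is linear in instar
#' number. This fits that line by ordinary least squares and reports the
#' slope (log growth ratio per instar), intercept, R-squared, and the
#' overall F statistic with its two-sided p-value on (1, k - 2) degrees of
#' freedom. With only k points the F test carries little information and is
#' reported for completeness, never used as a gate.
#'
#' @param means Ordered per-instar mean HCWs, micrometres, all positive.
#' @param instars Instar numbers; defaults to `1:length(means)`.
#' @return An object of class `dyar_regression`: `slope`, `intercept`,
#'   `r_squared`, `f_stat`, `p_value`, `n_points`, `growth_ratio`
#'   (`exp(slope)`), and the underlying `lm` fit.
#' @export
#' @examples
#' dyar_regression(c(365.0, 473.7, 578.0))
dyar_regression <- function(means, instars = seq_along(means)) {
  if (length(means) < 3L) {
    stop("Dyar regression needs at least 3 instars (got ", length(means),
         "); R-squared is degenerate on 2 points", call. = FALSE)
  }
  if (any(means <= 0)) stop("means must be strictly positive", call. = FALSE)
  stopifnot(length(instars) == length(means))
  df <- data.frame(ln_mean = log(means), instar = as.numeric(instars))
  fit <- stats::lm(ln_mean ~ instar, data = df)
  # an exactly geometric series is a legitimate input; summary.lm's
  # "essentially perfect fit" warning is noise there
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fstat <- unname(sm$fstatistic)
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = sm$r.squared,
      f_stat = fstat[1L],
      df = c(fstat[2L], fstat[3L]),
      p_value = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                 lower.tail = FALSE)),
      n_points = length(means),
      growth_ratio = exp(unname(stats::coef(fit)[2L])),
      model = fit
    ),
    class = "dyar_regression"
  )
}

#' @export
print.dyar_regression <- function(x, ...) {
  cat(sprintf(
    "Dyar's-rule regression: ln(mean HCW) = %.4f + %.4f * instar\n",
    x$intercept, x$slope))
  cat(sprintf("  growth ratio exp(slope) = %.4f\n", x$growth_ratio))
  cat(sprintf("  n = %d, R-squared = %.4f, F(%d, %d) = %.2f, p = %.4f\n",
              x$n_points, x$r_squared, x$df[1], x$df[2], x$f_stat,
              x$p_value))
  invisible(x)
}
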