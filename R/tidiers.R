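#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mixture
#'
#' One row per component: `component`, `weight`, `mean`, `sd`.
#'
#' @param x An `hcw_mixture`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hcw_mixture <- function(x, ...) {
  x$components
}

#' One-row model summary of a fitted mixture
#'
#' @param x An `hcw_mixture`.
#' @param ... Unused.
#' @return A tibble with `k`, `n`, `loglik`, `bic`, `converged`,
#'   `iterations`, `method`.
#' @export
glance.hcw_mixture <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, loglik = x$loglik, bic = x$bic,
                 converged = x$converged, iterations = x$iterations,
                 method = x$method)
}

#' Tidy a Dyar's-rule regression
#'
#' @param x A `dyar_regression`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.dyar_regression <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' One-row summary of a Dyar's-rule regression
#'
#' @param x A `dyar_regression`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `statistic` (F), `p.value`, `slope`,
#'   `growth_ratio`, `nobs`.
#' @export
glance.dyar_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, statistic = x$f_stat,
                 p.value = x$p_value, slope = x$slope,
                 growth_ratio = x$growth_ratio, nobs = x$n_points)
}

#' Tidy a full instar analysis
#'
#' The per-instar validation table: statistics, growth indices and
#' criteria verdicts.
#'
#' @param x An `instar_analysis`.
#' @param ... Unused.
#' @return A tibble, one row per instar.
#' @export
tidy.instar_analysis <- function(x, ...) {
  if (is.null(x$validation)) {
    stop("no validation table (status: ", x$status["validation"], ")",
         call. = FALSE)
  }
  x$validation$stats
}

#' One-row summary of a full instar analysis
#'
#' @param x An `instar_analysis`.
#' @param ... Unused.
#' @return A tibble with `selected_k`, `n`, `bic`, `overall_pass`,
#'   `dyar_r_squared`, `dyar_slope`.
#' @export
glance.instar_analysis <- function(x, ...) {
  tibble::tibble(
    selected_k = x$selected_k,
    n = x$provenance$n,
    bic = x$model$bic,
    overall_pass = if (is.null(x$validation)) NA else x$validation$overall,
    dyar_r_squared = if (is.null(x$dyar)) NA_real_ else x$dyar$r_squared,
    dyar_slope = if (is.null(x$dyar)) NA_real_ else x$dyar$slope
  )
}
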