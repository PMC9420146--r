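#' Configuration for an instar-determination analysis
#'
#' Collects every tunable of the pipeline in one validated list.
#'
#' @param k_min,k_max Range of component counts tried by BIC selection.
#' @param seed Integer seed for mixture initialisation.
#' @param bin_width Histogram bin width in micrometres, or `"auto"`
#'   (Freedman-Diaconis with a 5 micrometre floor).
#' @param cv_threshold Within-instar CV criterion, percent.
#' @param crosby_threshold Crosby-index magnitude criterion.
#' @param fit_mode `"em"` (maximum likelihood on raw widths, default) or
#'   `"histogram"` (least squares on binned counts).
#' @param boundary_mode `"weighted"` (default) or `"unweighted"` curves for
#'   the intersection boundaries.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(k_min = 1L, k_max = 5L, seed = 1L,
                            bin_width = "auto", cv_threshold = 15,
                            crosby_threshold = 0.1,
                            fit_mode = c("em", "histogram"),
                            boundary_mode = c("weighted", "unweighted")) {
  stopifnot(k_min >= 1L, k_min <= k_max, cv_threshold > 0,
            crosby_threshold > 0)
  structure(
    list(k_min = as.integer(k_min), k_max = as.integer(k_max),
         seed = as.integer(seed), bin_width = bin_width,
         cv_threshold = cv_threshold, crosby_threshold = crosby_threshold,
         fit_mode = match.arg(fit_mode),
         boundary_mode = match.arg(boundary_mode)),
    class = "analysis_config"
  )
}

#' Run the full instar-determination pipeline
#'
#' Executes, in order: BIC selection of the number of mixture components;
#' intersection boundaries between adjacent fitted curves; assignment of
#' every larva to an instar; per-instar statistics with Brooks'/Crosby's
#' indices and criteria verdicts; and the Dyar's-rule log-linear regression
#' of mean width on instar number. Stages are isolated: a failure downstream
#' (e.g. the regression needs at least 3 instars) records a skip reason and
#' keeps all earlier results.
#'
#' @param data Data frame of measurements (e.g. from [read_hcw_table()] or
#'   [simulate_hcw()]).
#' @param config An [analysis_config()].
#' @param column Name of the width column, micrometres.
#' @return An object of class `instar_analysis`: `selected_k`, `bic_table`,
#'   `model` (`hcw_mixture`), `boundaries` (tibble), `assignments`
#'   (input tibble plus `instar`), `validation` (`instar_validation`),
#'   `dyar` (`dyar_regression` or `NULL`), `histogram`, `status` (named
#'   character vector per stage: `"ok"` or the skip/error reason), and
#'   `provenance` (config, seed, n, package version, input source).
#' @export
#' @examples
#' d <- simulate_hcw(spec_from_table1(), seed = 1)
#' res <- run_analysis(d)
#' res$selected_k
run_analysis <- function(data, config = analysis_config(),
                         column = "hcw_um") {
  stopifnot(inherits(config, "analysis_config"), is.data.frame(data))
  status <- c(selection = "ok", boundaries = "ok", assignment = "ok",
              validation = "ok", dyar = "ok")
  histogram <- make_histogram(data, column = column,
                              bin_width = config$bin_width)
  model <- select_components(
    data, k_min = config$k_min, k_max = config$k_max, column = column,
    seed = config$seed, method = config$fit_mode
  )
  boundaries <- NULL; assignments <- NULL; validation <- NULL; dyar <- NULL
  if (model$k >= 2L) {
    boundaries <- tryCatch(
      intersection_boundaries(model,
                              weighted = config$boundary_mode == "weighted"),
      error = function(e) {
        status["boundaries"] <<- conditionMessage(e); NULL
      })
  } else {
    boundaries <- tibble::tibble(lower_instar = integer(), upper_instar = integer(),
                                 boundary_um = numeric())
    status["boundaries"] <- "skipped: k = 1, no boundaries"
  }
  if (!is.null(boundaries)) {
    assignments <- assign_instars(data, boundaries$boundary_um,
                                  column = column)
    validation <- tryCatch(
      validate_instars(assignments, column = column,
                       cv_threshold = config$cv_threshold,
                       crosby_threshold = config$crosby_threshold),
      error = function(e) {
        status["validation"] <<- conditionMessage(e); NULL
      })
  } else {
    status["assignment"] <- "skipped: no boundaries"
    status["validation"] <- "skipped: no boundaries"
  }
  if (!is.null(validation)) {
    dyar <- tryCatch(
      dyar_regression(validation$stats$mean, validation$stats$instar),
      error = function(e) {
        status["dyar"] <<- paste0("skipped: ", conditionMessage(e)); NULL
      })
  } else {
    status["dyar"] <- "skipped: no validation table"
  }
  structure(
    list(
      selected_k = model$k,
      bic_table = attr(model, "bic_table"),
      model = model,
      boundaries = boundaries,
      assignments = assignments,
      validation = validation,
      dyar = dyar,
      histogram = histogram,
      status = status,
      provenance = list(
        source = attr(data, "source") %||% "in-memory data frame",
        n = nrow(data), config = unclass(config), seed = config$seed,
        package_version = as.character(utils::packageVersion("instarmix"))
      )
    ),
    class = "instar_analysis"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.instar_analysis <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Serialise an analysis report
#'
#' @param report An `instar_analysis` from [run_analysis()].
#' @param format `"json"` (full precision, lossless round trip), `"tsv"`
#'   (the validation table, 4 decimal places), or `"text"` (a printed
#'   summary shaped like the per-instar table, 4 decimal places).
#' @param path Optional output file; when `NULL` the serialisation is
#'   returned as a character vector.
#' @return The serialised report (invisibly when written to `path`).
#' @export
render_report <- function(report, format = c("json", "tsv", "text"),
                          path = NULL) {
  stopifnot(inherits(report, "instar_analysis"))
  format <- match.arg(format)
  out <- switch(format,
    json = render_json(report),
    tsv = render_tsv(report),
    text = render_text(report)
  )
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

render_json <- function(report) {
  obj <- list(
    selected_k = report$selected_k,
    bic_table = report$bic_table,
    model = list(
      k = report$model$k,
      weights = report$model$components$weight,
      means = report$model$components$mean,
      sds = report$model$components$sd,
      loglik = report$model$loglik, bic = report$model$bic,
      converged = report$model$converged, method = report$model$method
    ),
    boundaries_um = report$boundaries$boundary_um %||% numeric(0),
    validation = if (!is.null(report$validation)) list(
      per_instar = report$validation$stats,
      overall_pass = report$validation$overall,
      cv_threshold = report$validation$cv_threshold,
      crosby_threshold = report$validation$crosby_threshold
    ),
    dyar = if (!is.null(report$dyar)) list(
      slope = report$dyar$slope, intercept = report$dyar$intercept,
      r_squared = report$dyar$r_squared, f_stat = report$dyar$f_stat,
      p_value = report$dyar$p_value, n_points = report$dyar$n_points,
      growth_ratio = report$dyar$growth_ratio
    ),
    status = as.list(report$status),
    provenance = report$provenance
  )
  as.character(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                                null = "null", pretty = TRUE))
}

render_tsv <- function(report) {
  if (is.null(report$validation)) {
    stop("no validation table to render (status: ",
         report$status["validation"], ")", call. = FALSE)
  }
  tb <- report$validation$stats
  num <- vapply(tb, is.numeric, logical(1)) & names(tb) != "instar" &
    names(tb) != "n"
  tb[num] <- lapply(tb[num], function(v) sprintf("%.4f", v))
  c(paste(names(tb), collapse = "\t"),
    apply(tb, 1L, paste, collapse = "\t"))
}

render_text <- function(report) {
  lines <- c(
    sprintf("Instar determination: %d instar(s) selected (BIC over k = %d..%d)",
            report$selected_k, min(report$bic_table$k),
            max(report$bic_table$k)),
    sprintf("  n = %d larvae, fit: %s%s", report$provenance$n,
            report$model$method,
            if (report$model$converged) "" else " [not converged]")
  )
  if (!is.null(report$boundaries) && nrow(report$boundaries) > 0) {
    lines <- c(lines, sprintf(
      "  boundaries (um): %s",
      paste(sprintf("%.4f", report$boundaries$boundary_um), collapse = ", ")))
  }
  if (!is.null(report$validation)) {
    st <- report$validation$stats
    lines <- c(lines, "", sprintf(
      "  %-6s %-5s %-14s %-8s %-8s %-8s", "instar", "n", "mean+/-SE (um)",
      "CV(%)", "Brooks", "Crosby"))
    for (i in seq_len(nrow(st))) {
      lines <- c(lines, sprintf(
        "  %-6d %-5d %7.1f +/- %-4.1f %-8.4f %-8s %-8s",
        st$instar[i], st$n[i], st$mean[i], st$se[i], st$cv[i],
        if (is.na(st$brooks[i])) "" else sprintf("%.4f", st$brooks[i]),
        if (is.na(st$crosby[i])) "" else sprintf("%.4f", st$crosby[i])))
    }
    lines <- c(lines, sprintf(
      "  criteria (CV < %g%%, |Crosby| < %g): %s",
      report$validation$cv_threshold, report$validation$crosby_threshold,
      if (report$validation$overall) "PASS" else "FAIL"))
  }
  if (!is.null(report$dyar)) {
    lines <- c(lines, sprintf(
      "  Dyar regression: slope = %.4f, R2 = %.4f, F = %.2f, p = %.4f",
      report$dyar$slope, report$dyar$r_squared, report$dyar$f_stat,
      report$dyar$p_value))
  }
  skipped <- report$status[report$status != "ok"]
  if (length(skipped) > 0) {
    lines <- c(lines, paste0("  [", names(skipped), "] ", skipped))
  }
  lines
}
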