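#' Specify a synthetic head-capsule-width mixture
#'
#' Describes a population of larvae as k normal components, one per instar,
#' each with a fixed individual count, a mean and an SD in micrometres, and
#' an optional hard truncation window for the observable widths.
#'
#' @param counts Integer count of individuals per component, each >= 1.
#' @param means Component means, micrometres, strictly increasing.
#' @param sds Component SDs, micrometres, all > 0.
#' @param truncation Optional `c(low, high)` window in micrometres;
#'   values are drawn inside it by rejection sampling.
#' @return An object of class `simulation_spec`.
#' @seealso [spec_from_table1()], [simulate_hcw()]
#' @export
simulation_spec <- function(counts, means, sds, truncation = NULL) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == length(means), length(means) == length(sds),
            all(counts >= 1L), all(sds > 0), all(means > 0))
  if (length(means) > 1L && any(diff(means) <= 0)) {
    stop("component means must be strictly increasing", call. = FALSE)
  }
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2L, truncation[1] < truncation[2])
  }
  structure(
    list(counts = counts, means = as.numeric(means), sds = as.numeric(sds),
         truncation = truncation, k = length(counts)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Synthetic HCW mixture spec: k =", x$k, ", n =", sum(x$counts), "\n")
  print(tibble::tibble(component = seq_len(x$k), count = x$counts,
                       mean = x$means, sd = x$sds))
  if (!is.null(x$truncation)) {
    cat("truncation:", x$truncation[1], "-", x$truncation[2], "um\n")
  }
  invisible(x)
}

#' Preset emulating the three-instar reference sample
#'
#' The published per-instar summary of the study sample (n = 401 larvae):
#' counts 65 / 145 / 191, mean head-capsule widths 365.0 / 473.7 / 578.0
#' micrometres, and coefficients of variation 5.30 / 5.26 / 4.38 percent.
#' Component SDs are derived as `cv * mean / 100` (19.345 / 24.9166 /
#' 25.3164 micrometres) and observable widths are truncated to the reported
#' 300-650 micrometre range. The raw individual measurements were never
#' deposited, so this preset is the synthetic stand-in used throughout the
#' recovery tests.
#'
#' @return A `simulation_spec` for the reference sample.
#' @export
#' @examples
#' sum(spec_from_table1()$counts)   # 401
spec_from_table1 <- function() {
  means <- c(365.0, 473.7, 578.0)
  cvs <- c(5.30, 5.26, 4.38)
  simulation_spec(
    counts = c(65L, 145L, 191L),
    means = means,
    sds = cvs * means / 100,
    truncation = c(300, 650)
  )
}

#' Simulate a labelled head-capsule-width dataset
#'
#' Draws exactly `counts[j]` widths from each normal component of a
#' [simulation_spec()], in ascending-mean order from a single seeded
#' pseudo-random stream, so identical spec + seed give identical output.
#' When a truncation window is set, out-of-window draws are rejected and
#' redrawn (not clipped), preserving within-window normality. Stratified
#' exact counts are the default; `multinomial = TRUE` instead draws the
#' per-component counts once from a multinomial with probabilities
#' proportional to `counts`.
#'
#' @param spec A `simulation_spec`.
#' @param seed Integer seed.
#' @param multinomial If `TRUE`, randomise per-component counts
#'   multinomially (total preserved) instead of using them exactly.
#' @return A tibble with columns `id` (character), `hcw_um` (double) and
#'   `true_instar` (integer, the generating component).
#' @export
#' @examples
#' d <- simulate_hcw(spec_from_table1(), seed = 1)
#' nrow(d)   # 401
simulate_hcw <- function(spec, seed = 1L, multinomial = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  counts <- spec$counts
  if (multinomial) {
    counts <- as.integer(stats::rmultinom(1, sum(spec$counts),
                                          spec$counts / sum(spec$counts)))
  }
  if (!is.null(spec$truncation)) {
    lo <- spec$truncation[1]; hi <- spec$truncation[2]
    inside <- stats::pnorm(hi, spec$means, spec$sds) -
      stats::pnorm(lo, spec$means, spec$sds)
    if (any(inside < 0.01)) {
      stop("truncation window (", lo, ", ", hi, ") excludes > 99% of the ",
           "mass of component(s) ", paste(which(inside < 0.01), collapse = ", "),
           "; rejection sampling would stall", call. = FALSE)
    }
  }
  vals <- purrr::map(seq_len(spec$k), function(j) {
    draw_truncated_normal(counts[j], spec$means[j], spec$sds[j],
                          spec$truncation)
  })
  tibble::tibble(
    id = sprintf("larva_%03d", seq_len(sum(counts))),
    hcw_um = unlist(vals),
    true_instar = rep(seq_len(spec$k), counts)
  )
}

# Exact-n rejection sampler from N(mean, sd) restricted to the window.
draw_truncated_normal <- function(n, mean, sd, truncation) {
  if (is.null(truncation)) return(stats::rnorm(n, mean, sd))
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(max(n, 32L), mean, sd)
    out <- c(out, d[d >= truncation[1] & d <= truncation[2]])
  }
  out[seq_len(n)]
}

#' Write a labelled synthetic dataset as a fixture CSV
#'
#' Writes columns `id`, `hcw_um`, `true_instar`, one header row; the file
#' round-trips through [read_hcw_table()].
#'
#' @param labelled Tibble from [simulate_hcw()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(labelled, path) {
  stopifnot(all(c("id", "hcw_um", "true_instar") %in% names(labelled)))
  write_hcw_table(labelled[, c("id", "hcw_um", "true_instar")], path)
  invisible(path)
}

#' Read or write a simulation spec as JSON
#'
#' @param spec A `simulation_spec`.
#' @param path File path.
#' @return `write_spec_json()` returns `path` invisibly;
#'   `read_spec_json()` returns a `simulation_spec`.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  jsonlite::write_json(
    list(counts = spec$counts, means = spec$means, sds = spec$sds,
         truncation = spec$truncation),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  simulation_spec(obj$counts, obj$means, obj$sds,
                  truncation = if (length(obj$truncation)) obj$truncation)
}
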