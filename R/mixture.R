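#' Fit a k-component normal mixture to head-capsule widths
#'
#' Maximum-likelihood fit of a univariate Gaussian mixture by
#' expectation-maximisation on the raw widths. Each fitted component is
#' interpreted as one larval instar: a weighted normal curve with its own
#' mean and standard deviation in micrometres.
#'
#' Initialisation places the k starting means at the k interior quantiles of
#' the data, with equal weights and a pooled starting SD. If a component SD
#' collapses to the 1 micrometre floor with vanishing weight (a degenerate
#' solution), the fit restarts with seeded jittered means, up to
#' `restarts` times. The EM log-likelihood is non-decreasing across
#' iterations; the full trace is kept for inspection.
#'
#' An alternative `method = "histogram"` mode reproduces curve fitting to
#' the binned frequency distribution: a sum of scaled Gaussians is fitted to
#' the bin counts by nonlinear least squares and the fitted amplitudes are
#' normalised to mixing weights. The default raw-likelihood mode is
#' bin-independent and statistically preferable.
#'
#' @param data Data frame of measurements.
#' @param k Number of mixture components (instars), `k >= 1`.
#' @param column Name of the width column, micrometres.
#' @param seed Integer seed controlling initialisation jitter; identical
#'   seeds give identical fits.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param sd_floor Lower bound on component SDs, micrometres.
#' @param restarts Maximum jittered re-initialisations on degeneracy.
#' @param method `"em"` (default, maximum likelihood on raw values) or
#'   `"histogram"` (least squares on binned counts).
#' @param bin_width Bin width for `method = "histogram"`; `"auto"` applies
#'   the Freedman-Diaconis rule.
#'
#' @return An object of class `hcw_mixture`: a list with `components` (a
#'   tibble of `component`, `weight`, `mean`, `sd`, sorted by ascending
#'   mean), `k`, `n`, `loglik`, `bic`, `converged`, `iterations`,
#'   `loglik_trace`, `method`, `seed`, and the data vector `x`.
#' @seealso [select_components()], [intersection_boundaries()], [tidy.hcw_mixture()]
#' @export
#' @examples
#' d <- simulate_hcw(simulation_spec(counts = c(50, 50),
#'                                   means = c(100, 500), sds = c(1, 1)),
#'                   seed = 1)
#' fit_mixture(d, k = 2, seed = 1)
fit_mixture <- function(data, k, column = "hcw_um", seed = 1L,
                        max_iter = 1000L, tol = 1e-8, sd_floor = 1,
                        restarts = 10L, method = c("em", "histogram"),
                        bin_width = "auto") {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  x <- data[[column]]
  if (is.null(x)) stop("column '", column, "' not found", call. = FALSE)
  n <- length(x)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (n < 3L * k) {
    stop("need at least 3 observations per component: n = ", n,
         " < 3k = ", 3L * k, call. = FALSE)
  }
  if (method == "histogram") {
    return(fit_mixture_histogram(x, k, seed = seed, bin_width = bin_width,
                                 sd_floor = sd_floor))
  }
  if (k == 1L) {
    # closed form: ML estimates are the sample mean and sample SD (ddof 0)
    mu <- mean(x)
    sdv <- sqrt(mean((x - mu)^2))
    ll <- sum(stats::dnorm(x, mu, max(sdv, sd_floor), log = TRUE))
    return(new_hcw_mixture(
      weight = 1, mean = mu, sd = max(sdv, sd_floor), n = n, loglik = ll,
      converged = TRUE, iterations = 0L, loglik_trace = ll,
      method = "em", seed = seed, x = x
    ))
  }

  set.seed(as.integer(seed))
  base_mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  pooled <- stats::sd(x) / k
  fit <- NULL
  for (attempt in seq_len(restarts + 1L)) {
    mu0 <- if (attempt == 1L) base_mu else
      sort(base_mu + stats::rnorm(k, 0, pooled))
    fit <- em_gaussian(x, k, mu0, rep(max(pooled, sd_floor), k),
                       rep(1 / k, k), max_iter, tol, sd_floor)
    if (!fit$degenerate) break
  }
  if (fit$degenerate) {
    stop("mixture fit degenerate after ", restarts,
         " restarts (component collapse); try a smaller k", call. = FALSE)
  }
  ord <- order(fit$mu)
  if (any(diff(fit$mu[ord]) <= 0)) {
    stop("fitted component means are tied; the data do not support k = ",
         k, " distinct components", call. = FALSE)
  }
  new_hcw_mixture(
    weight = fit$w[ord], mean = fit$mu[ord], sd = fit$sd[ord], n = n,
    loglik = fit$ll, converged = fit$converged, iterations = fit$iter,
    loglik_trace = fit$trace, method = "em", seed = seed, x = x
  )
}

# Plain EM for a univariate Gaussian mixture. Returns unsorted parameters,
# the log-likelihood trace, and a degeneracy flag (component weight ~ 0 or
# SD pinned at the floor while carrying < 2 expected members).
em_gaussian <- function(x, k, mu, sdv, w, max_iter, tol, sd_floor) {
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sdv[j]),
                   numeric(n))
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot))) {
      return(list(degenerate = TRUE))
    }
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(list(degenerate = TRUE))
    w <- nk / n
    mu <- colSums(r * x) / nk
    sdv <- pmax(sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk), sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  degenerate <- any(sdv <= sd_floor & colSums(r) < 2)
  list(mu = mu, sd = sdv, w = w, ll = trace[length(trace)], trace = trace,
       converged = converged, iter = iter, degenerate = degenerate)
}

# Histogram-mode fit: nonlinear least squares of sum_j A_j exp(-(x-m_j)^2 /
# (2 s_j^2)) against bin counts at bin midpoints, then weights ~ A_j s_j
# (area), normalised to 1. Mirrors amplitude-parameterised curve fitting to
# a frequency histogram.
fit_mixture_histogram <- function(x, k, seed, bin_width, sd_floor) {
  d <- tibble::tibble(hcw_um = x)
  h <- make_histogram(d, bin_width = bin_width)
  if (nrow(h) < 3L * k) {
    stop("histogram has ", nrow(h), " bins; too few to fit ", k,
         " components (need >= ", 3L * k, ")", call. = FALSE)
  }
  mu0 <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  s0 <- rep(stats::sd(x) / k, k)
  a0 <- rep(max(h$count), k) * 0.8
  par0 <- stats::setNames(
    c(a0, mu0, log(s0)),
    c(paste0("A", seq_len(k)), paste0("m", seq_len(k)), paste0("ls", seq_len(k)))
  )
  model_counts <- function(par, mid) {
    A <- par[seq_len(k)]
    m <- par[k + seq_len(k)]
    s <- exp(par[2L * k + seq_len(k)])
    rowSums(vapply(seq_len(k),
                   function(j) A[j] * exp(-(mid - m[j])^2 / (2 * s[j]^2)),
                   numeric(length(mid))))
  }
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) h$count - model_counts(par, h$mid),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- fit$par
  A <- pmax(p[seq_len(k)], 1e-12)
  m <- p[k + seq_len(k)]
  s <- pmax(exp(p[2L * k + seq_len(k)]), sd_floor)
  area <- A * s  # component area up to the common sqrt(2*pi) factor
  w <- area / sum(area)
  ord <- order(m)
  ll <- sum(log(rowSums(vapply(
    seq_len(k), function(j) w[j] * stats::dnorm(x, m[j], s[j]),
    numeric(length(x))
  ))))
  new_hcw_mixture(
    weight = w[ord], mean = m[ord], sd = s[ord], n = length(x), loglik = ll,
    converged = fit$info %in% 1:3, iterations = fit$niter,
    loglik_trace = ll, method = "histogram", seed = seed, x = x
  )
}

new_hcw_mixture <- function(weight, mean, sd, n, loglik, converged,
                            iterations, loglik_trace, method, seed, x) {
  k <- length(mean)
  stopifnot(abs(sum(weight) - 1) < 1e-8, all(sd > 0))
  structure(
    list(
      components = tibble::tibble(
        component = seq_len(k), weight = weight, mean = mean, sd = sd
      ),
      k = k, n = n, loglik = loglik,
      bic = -2 * loglik + (3 * k - 1) * log(n),
      converged = converged, iterations = iterations,
      loglik_trace = loglik_trace, method = method, seed = seed, x = x
    ),
    class = "hcw_mixture"
  )
}

#' @export
print.hcw_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%s): k = %d, n = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$method, x$k, x$n, x$loglik, x$bic,
              if (x$converged) "" else " [not converged]"))
  print(x$components)
  invisible(x)
}

#' Select the number of instars by BIC
#'
#' Fits mixtures for every component count in `k_min:k_max` and returns the
#' fit minimising the Bayesian information criterion, breaking ties toward
#' the smaller k. The per-k BIC table is attached so the automatic choice
#' can be compared with a visual peak count.
#'
#' @inheritParams fit_mixture
#' @param k_min,k_max Range of component counts to consider.
#' @param ... Passed on to [fit_mixture()].
#' @return The best `hcw_mixture`, with the comparison table (`k`,
#'   `loglik`, `bic`, `converged`, `error`) in attribute `bic_table`.
#' @export
select_components <- function(data, k_min = 1L, k_max = 5L,
                              column = "hcw_um", seed = 1L, ...) {
  stopifnot(k_min >= 1L, k_min <= k_max)
  ks <- seq.int(k_min, k_max)
  fits <- purrr::map(ks, function(k) {
    tryCatch(fit_mixture(data, k = k, column = column, seed = seed, ...),
             error = function(e) e)
  })
  tab <- tibble::tibble(
    k = ks,
    loglik = purrr::map_dbl(fits, ~ if (inherits(.x, "error")) NA_real_ else .x$loglik),
    bic = purrr::map_dbl(fits, ~ if (inherits(.x, "error")) NA_real_ else .x$bic),
    converged = purrr::map_lgl(fits, ~ !inherits(.x, "error") && .x$converged),
    error = purrr::map_chr(fits, ~ if (inherits(.x, "error")) conditionMessage(.x) else NA_character_)
  )
  ok <- which(!is.na(tab$bic))
  if (length(ok) == 0L) {
    stop("mixture fitting failed for every k in ", k_min, "..", k_max,
         ": ", tab$error[1], call. = FALSE)
  }
  # ties (within numerical noise) resolved toward smaller k
  best <- ok[which.min(tab$bic[ok] + 1e-9 * ks[ok])]
  out <- fits[[best]]
  attr(out, "bic_table") <- tab
  out
}

#' Weighted normal density contribution of one component
#'
#' The height of a single mixture component at `x`:
#' `weight * dnorm(x, mean, sd)`. Integrates to `weight` over the real line.
#'
#' @param x Width(s) in micrometres at which to evaluate.
#' @param weight Mixing weight in (0, 1].
#' @param mean,sd Component mean and SD, micrometres; `sd > 0`.
#' @return Numeric vector of densities.
#' @export
#' @examples
#' component_density(0, weight = 1, mean = 0, sd = 1)   # 0.3989423
component_density <- function(x, weight = 1, mean, sd) {
  stopifnot(sd > 0, weight > 0, weight <= 1)
  weight * stats::dnorm(x, mean, sd)
}

#' Instar boundaries at intersections of adjacent normal curves
#'
#' For each adjacent pair of fitted components, solves for the width at
#' which the two weighted normal curves cross, i.e. the x with
#' `w_i N(x | m_i, s_i) = w_j N(x | m_j, s_j)`, restricted to lie strictly
#' between the two means. That crossing is the dividing point between two
#' instars. On the log scale the equality is quadratic in x when the SDs
#' differ and linear when they are equal; of the candidate roots the one
#' strictly between the means is kept (if, despite the guard, both interior
#' roots occurred, the one nearer the midpoint would be kept).
#'
#' @param model A fitted `hcw_mixture` with `k >= 2`.
#' @param weighted If `TRUE` (default) the curves carry their mixing
#'   weights; if `FALSE` the intersection of the unweighted densities is
#'   used.
#' @return A tibble with one row per adjacent pair: `lower_instar`,
#'   `upper_instar`, `boundary_um`.
#' @export
intersection_boundaries <- function(model, weighted = TRUE) {
  stopifnot(inherits(model, "hcw_mixture"))
  if (model$k < 2L) {
    stop("boundaries require at least 2 components (k = ", model$k, ")",
         call. = FALSE)
  }
  comp <- model$components
  b <- purrr::map_dbl(seq_len(model$k - 1L), function(i) {
    gaussian_crossing(
      w1 = if (weighted) comp$weight[i] else 1,
      m1 = comp$mean[i], s1 = comp$sd[i],
      w2 = if (weighted) comp$weight[i + 1L] else 1,
      m2 = comp$mean[i + 1L], s2 = comp$sd[i + 1L],
      pair = c(i, i + 1L)
    )
  })
  tibble::tibble(
    lower_instar = seq_len(model$k - 1L),
    upper_instar = seq_len(model$k - 1L) + 1L,
    boundary_um = b
  )
}

# Crossing of two weighted normal densities, restricted to (m1, m2).
# log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
gaussian_crossing <- function(w1, m1, s1, w2, m2, s2, pair = c(1L, 2L)) {
  stopifnot(m1 < m2)
  c0 <- log(w1 / s1) - log(w2 / s2)
  if (isTRUE(all.equal(s1, s2))) {
    # linear: (m2 - m1) x = (m2^2 - m1^2)/2 - s^2 * c0
    x <- ((m2^2 - m1^2) / 2 - s1^2 * c0) / (m2 - m1)
    roots <- x
  } else {
    a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    b <- m1 / s1^2 - m2 / s2^2
    cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + c0
    disc <- b^2 - 4 * a * cc
    if (disc < 0) roots <- numeric(0)
    else roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 0L) {
    stop("no density crossing strictly between the means of components ",
         pair[1], " and ", pair[2], " (", round(m1, 1), " and ",
         round(m2, 1), " um); extreme weight imbalance -- consider ",
         "unweighted curves or a posterior-ratio boundary", call. = FALSE)
  }
  if (length(inside) > 1L) {
    inside <- inside[which.min(abs(inside - (m1 + m2) / 2))]
  }
  inside
}

#' Assign individuals to instars by boundary intervals
#'
#' Labels every measurement with its instar: value `v` belongs to instar `i`
#' when it falls in the half-open interval `(b_{i-1}, b_i]`, with implicit
#' outer boundaries at minus and plus infinity. A value exactly equal to a
#' boundary therefore joins the lower instar.
#'
#' @param data Data frame of measurements.
#' @param boundaries Numeric vector of strictly increasing boundaries in
#'   micrometres, or the tibble returned by [intersection_boundaries()].
#' @param column Name of the width column.
#' @return `data` with an integer `instar` column appended.
#' @export
assign_instars <- function(data, boundaries, column = "hcw_um") {
  stopifnot(is.data.frame(data))
  if (is.data.frame(boundaries)) boundaries <- boundaries$boundary_um
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) > 1L && any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  x <- data[[column]]
  inst <- findInterval(x, boundaries, left.open = TRUE) + 1L
  dplyr::mutate(tibble::as_tibble(data), instar = as.integer(inst))
}

#' Export a mixture model as JSON
#'
#' @param model A fitted `hcw_mixture`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_mixture_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "hcw_mixture"))
  obj <- list(
    k = model$k, weights = model$components$weight,
    means = model$components$mean, sds = model$components$sd,
    loglik = model$loglik, bic = model$bic, n = model$n,
    seed = model$seed, converged = model$converged, method = model$method
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Import a mixture model from JSON
#'
#' Rebuilds an `hcw_mixture` from [write_mixture_json()] output. The raw
#' data vector is not stored in the JSON, so plotting methods that need it
#' are unavailable on the imported object.
#'
#' @param path Path to a JSON file written by [write_mixture_json()].
#' @return An `hcw_mixture` object.
#' @export
read_mixture_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_hcw_mixture(
    weight = obj$weights, mean = obj$means, sd = obj$sds, n = obj$n,
    loglik = obj$loglik, converged = obj$converged, iterations = NA_integer_,
    loglik_trace = obj$loglik, method = obj$method, seed = obj$seed,
    x = numeric(0)
  )
}
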