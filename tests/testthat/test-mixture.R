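test_that("a one-component fit is the closed-form normal MLE", {
  x <- c(310, 355, 402, 498, 510, 623)
  m <- fit_mixture(hcw_tbl(x), k = 1)
  expect_equal(m$components$mean, mean(x))
  expect_equal(m$components$sd, sqrt(mean((x - mean(x))^2)))  # ddof 0
  expect_equal(m$components$weight, 1)
  expect_true(m$converged)
})

test_that("well-separated clusters are recovered almost exactly", {
  d <- two_cluster_data(seed = 1)
  m <- fit_mixture(d, k = 2, seed = 1)
  expect_lt(abs(m$components$mean[1] - 100), 1)
  expect_lt(abs(m$components$mean[2] - 500), 1)
  expect_lt(max(abs(m$components$weight - 0.5)), 0.02)
})

test_that("the three-instar preset is recovered by a k = 3 fit", {
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, seed = 1)
  truth <- c(365.0, 473.7, 578.0)
  expect_true(all(abs(m$components$mean / truth - 1) < 0.02))
  expect_true(all(diff(m$components$mean) > 0))
  expect_equal(sum(m$components$weight), 1, tolerance = 1e-8)
})

test_that("EM agrees with an independent mixture fitter on the preset", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, seed = 1)
  ref <- mclust::Mclust(d$hcw_um, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(unname(ref$parameters$mean)), m$components$mean,
               tolerance = 1e-3)
  expect_equal(m$loglik, ref$loglik, tolerance = 1e-4)
})

test_that("EM log-likelihood never decreases across iterations", {
  for (seed in 1:4) {
    d <- simulate_hcw(spec_from_table1(), seed = seed)
    for (k in 2:4) {
      m <- fit_mixture(d, k = k, seed = seed)
      expect_true(all(diff(m$loglik_trace) >= -1e-6),
                  info = sprintf("seed %d, k %d", seed, k))
    }
  }
})

test_that("fits demand at least three observations per component", {
  expect_error(fit_mixture(hcw_tbl(c(300, 400, 500)), k = 2), "3k")
  expect_error(fit_mixture(hcw_tbl(300), k = 0), "at least 1")
})

test_that("BIC selection finds the generating component count", {
  d1 <- simulate_hcw(simulation_spec(100, 400, 2), seed = 2)
  s1 <- select_components(d1, k_min = 1, k_max = 4, seed = 2)
  expect_equal(s1$k, 1L)

  s2 <- select_components(two_cluster_data(seed = 1), k_min = 1, k_max = 4)
  expect_equal(s2$k, 2L)

  d3 <- simulate_hcw(spec_from_table1(), seed = 1)
  s3 <- select_components(d3, k_min = 1, k_max = 5, seed = 1)
  expect_equal(s3$k, 3L)
  tab <- attr(s3, "bic_table")
  expect_equal(tab$k, 1:5)
  expect_equal(tab$bic[3], min(tab$bic, na.rm = TRUE))
})

test_that("weighted component density matches the closed form", {
  expect_equal(component_density(0, 1, 0, 1), 0.3989423, tolerance = 1e-6)
  expect_equal(component_density(0, 0.5, 0, 1), 0.1994711, tolerance = 1e-6)
  expect_equal(component_density(365, 1, 365, 19.35),
               1 / (19.35 * sqrt(2 * pi)))
  expect_equal(component_density(c(-1, 1), 0.3, 0, 1),
               0.3 * dnorm(c(-1, 1)))
  expect_error(component_density(0, 1, 0, -1))
})

test_that("equal-spread equal-weight curves cross at the midpoint", {
  m <- pair_model(0.5, 100, 10, 200, 10)
  b <- intersection_boundaries(m)
  expect_equal(b$boundary_um, 150)
  expect_equal(b$lower_instar, 1L)
  expect_equal(b$upper_instar, 2L)
})

test_that("the analytic crossing matches a dense grid search", {
  m <- pair_model(0.5, 365, 19.34, 473.7, 24.92)
  b <- intersection_boundaries(m)$boundary_um
  oracle <- grid_crossings(0.5, 365, 19.34, 0.5, 473.7, 24.92)
  expect_equal(length(oracle), 1L)
  expect_lt(abs(b - oracle), 0.1)
})

test_that("unweighted boundaries ignore the mixing weights", {
  m <- pair_model(0.9, 100, 10, 200, 10)
  expect_equal(intersection_boundaries(m, weighted = FALSE)$boundary_um, 150)
  expect_lt(intersection_boundaries(m, weighted = TRUE)$boundary_um, 150 + 1e-9)
})

test_that("a missing interior crossing raises the documented error", {
  # the heavy narrow component dominates everywhere between the means
  m <- pair_model(0.999, 100, 30, 102, 0.5)
  expect_error(intersection_boundaries(m), "no density crossing")
})

test_that("boundaries from a fitted preset model interleave the means", {
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, seed = 1)
  b <- intersection_boundaries(m)
  mu <- m$components$mean
  expect_equal(nrow(b), 2L)
  expect_true(b$boundary_um[1] > mu[1] && b$boundary_um[1] < mu[2])
  expect_true(b$boundary_um[2] > mu[2] && b$boundary_um[2] < mu[3])
  expect_error(intersection_boundaries(fit_mixture(d, k = 1)), "at least 2")
})

test_that("instar assignment follows open-left/closed-right intervals", {
  d <- hcw_tbl(c(365, 474, 578))
  a <- assign_instars(d, c(420, 530))
  expect_equal(a$instar, c(1L, 2L, 3L))
  # a value exactly on a boundary joins the lower instar
  expect_equal(assign_instars(hcw_tbl(420), c(420, 530))$instar, 1L)
  expect_equal(assign_instars(hcw_tbl(420.0001), c(420, 530))$instar, 2L)
  expect_error(assign_instars(d, c(530, 420)), "strictly increasing")
})

test_that("every individual receives exactly one instar label", {
  for (seed in 1:5) {
    d <- simulate_hcw(spec_from_table1(), seed = seed)
    m <- fit_mixture(d, k = 3, seed = seed)
    a <- assign_instars(d, intersection_boundaries(m))
    expect_equal(nrow(a), 401L)
    expect_false(any(is.na(a$instar)))
    expect_equal(sum(table(a$instar)), 401)
  }
})

test_that("preset assignment counts are close to the generating counts", {
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, seed = 1)
  a <- assign_instars(d, intersection_boundaries(m))
  counts <- as.integer(table(a$instar))
  # misclassification happens only near boundaries; tails there are thin
  expect_true(all(abs(counts - c(65, 145, 191)) <= 12))
})

test_that("histogram-mode fitting recovers the same structure", {
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, method = "histogram")
  expect_equal(m$method, "histogram")
  truth <- c(365.0, 473.7, 578.0)
  expect_true(all(abs(m$components$mean / truth - 1) < 0.03))
  expect_equal(sum(m$components$weight), 1, tolerance = 1e-8)
})

test_that("identical seeds give identical fits", {
  d <- simulate_hcw(spec_from_table1(), seed = 4)
  m1 <- fit_mixture(d, k = 3, seed = 9)
  m2 <- fit_mixture(d, k = 3, seed = 9)
  expect_identical(m1$components, m2$components)
  expect_identical(m1$loglik, m2$loglik)
})

test_that("mixture models round-trip through JSON export", {
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_mixture_json(m, f)
  m2 <- read_mixture_json(f)
  expect_equal(m2$components, m$components)
  expect_equal(m2$loglik, m$loglik)
  expect_equal(m2$k, 3L)
})

test_that("tidy and glance summarise a fit", {
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, seed = 1)
  td <- tidy(m)
  expect_equal(names(td), c("component", "weight", "mean", "sd"))
  expect_equal(nrow(td), 3L)
  gl <- glance(m)
  expect_equal(gl$k, 3L)
  expect_equal(gl$n, 401L)
  expect_equal(gl$bic, -2 * m$loglik + 8 * log(401))
})
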