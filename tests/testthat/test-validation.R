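test_that("per-instar statistics match hand arithmetic", {
  d <- tibble::tibble(hcw_um = c(10, 10, 10), instar = 1L)
  st <- instar_stats(d)
  expect_equal(st$mean, 10)
  expect_equal(st$sd, 0)
  expect_equal(st$cv, 0)

  d2 <- tibble::tibble(hcw_um = c(360, 370), instar = 1L)
  st2 <- instar_stats(d2)
  expect_equal(st2$mean, 365)
  expect_equal(round(st2$sd, 4), 7.0711)       # sample SD, n - 1
  expect_equal(round(st2$cv, 4), 1.9373)
  expect_equal(st2$se, st2$sd / sqrt(2))
})

test_that("an instar with zero members is an error", {
  d <- tibble::tibble(hcw_um = c(300, 600), instar = c(1L, 3L))
  expect_error(instar_stats(d), "zero members: 2")
})

test_that("Brooks' index reproduces the published growth ratios", {
  expect_equal(round(brooks_index(473.7, 365.0), 4), 1.2978)
  expect_equal(round(brooks_index(578.0, 473.7), 4), 1.2202)
  expect_equal(brooks_index(42, 42), 1)
  expect_error(brooks_index(-1, 2), "positive")
})

test_that("Brooks' indices telescope across any chain of instars", {
  set.seed(1)
  for (i in 1:20) {
    abc <- sort(runif(3, 100, 700))
    expect_equal(brooks_index(abc[3], abc[2]) * brooks_index(abc[2], abc[1]),
                 abc[3] / abc[1])
  }
})

test_that("Crosby's index reproduces the published value", {
  expect_equal(round(crosby_index(1.2202, 1.2978), 4), -0.0598)
  expect_equal(crosby_index(1.3, 1.3), 0)
  expect_equal(crosby_index(1.3, 1.0), 0.3)
  expect_error(crosby_index(1, 0), "non-zero")
})

test_that("Crosby's index is invariant to rescaling both growth ratios", {
  set.seed(2)
  for (i in 1:20) {
    b <- runif(2, 1.05, 1.9)
    s <- runif(1, 0.5, 3)
    expect_equal(crosby_index(s * b[2], s * b[1]), crosby_index(b[2], b[1]))
  }
})

test_that("criteria verdicts use strict inequalities on CV and |Crosby|", {
  tab <- tibble::tibble(
    instar = 1:3, n = c(65L, 145L, 191L),
    mean = c(365.0, 473.7, 578.0), sd = NA_real_, se = NA_real_,
    cv = c(5.30, 5.26, 4.38)
  )
  v <- evaluate_criteria(tab)
  expect_true(v$overall)
  expect_true(all(v$stats$cv_pass))
  expect_equal(round(v$stats$crosby[3], 4), -0.0598)
  expect_true(v$stats$crosby_pass[3])

  # CV exactly at the threshold fails
  tab15 <- dplyr::mutate(tab, cv = c(5, 15, 5))
  expect_false(evaluate_criteria(tab15)$overall)

  # a Crosby index of -0.15 fails on magnitude
  tabneg <- dplyr::mutate(tab, mean = c(365, 365 * 1.3, 365 * 1.3 * 1.105))
  vneg <- evaluate_criteria(tabneg)
  expect_equal(vneg$stats$crosby[3], -0.15)
  expect_false(vneg$overall)
})

test_that("lowering thresholds never converts a fail into a pass", {
  set.seed(3)
  for (i in 1:20) {
    means <- sort(runif(3, 200, 700))
    tab <- tibble::tibble(instar = 1:3, n = 10L, mean = means,
                          sd = NA_real_, se = NA_real_,
                          cv = runif(3, 0, 30))
    hi <- evaluate_criteria(tab, cv_threshold = 15, crosby_threshold = 0.1)
    lo <- evaluate_criteria(tab, cv_threshold = 10, crosby_threshold = 0.05)
    expect_true(all(which(lo$stats$cv_pass) %in% which(hi$stats$cv_pass)))
    expect_true(!lo$overall || hi$overall)
  }
})

test_that("Dyar regression matches a closed-form OLS oracle", {
  means <- c(365.0, 473.7, 578.0)
  r <- dyar_regression(means)
  oracle <- ols_oracle(1:3, log(means))
  expect_equal(r$slope, oracle$slope)
  expect_equal(r$intercept, oracle$intercept)
  expect_equal(r$r_squared, oracle$r_squared)
  expect_equal(round(r$slope, 4), 0.2298)
  expect_equal(round(r$r_squared, 3), 0.994)
  expect_equal(unname(r$df), c(1, 1))
})

test_that("exactly geometric means give a perfect Dyar fit", {
  r <- dyar_regression(c(100, 130, 169))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, log(1.3))
  expect_equal(r$growth_ratio, 1.3)

  set.seed(4)
  for (i in 1:10) {
    ratio <- runif(1, 1.1, 1.6)
    m0 <- runif(1, 200, 400)
    k <- sample(3:6, 1)
    r2 <- dyar_regression(m0 * ratio^(0:(k - 1)))
    expect_equal(r2$r_squared, 1)
    expect_equal(r2$slope, log(ratio))
  }
})

test_that("Dyar regression refuses fewer than three instars", {
  expect_error(dyar_regression(c(365, 473.7)), "at least 3")
  expect_error(dyar_regression(c(-1, 2, 3)), "positive")
})

test_that("validate_instars ties the pieces together on real assignments", {
  d <- simulate_hcw(spec_from_table1(), seed = 1)
  m <- fit_mixture(d, k = 3, seed = 1)
  a <- assign_instars(d, intersection_boundaries(m))
  v <- validate_instars(a)
  expect_s3_class(v, "instar_validation")
  expect_equal(nrow(v$stats), 3L)
  expect_true(v$overall)
  expect_true(all(v$stats$cv < 15))
  expect_equal(sum(!is.na(v$stats$brooks)), 2L)
  expect_equal(sum(!is.na(v$stats$crosby)), 1L)
  expect_true(all(na.omit(v$stats$brooks) > 1))
})

test_that("tidy and glance summarise a Dyar regression", {
  r <- dyar_regression(c(365.0, 473.7, 578.0))
  td <- tidy(r)
  expect_equal(nrow(td), 2L)
  expect_equal(td$estimate[2], r$slope)
  gl <- glance(r)
  expect_equal(gl$r.squared, r$r_squared)
  expect_equal(gl$nobs, 3L)
})
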