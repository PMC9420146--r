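# Shared fixtures and independent oracles.

hcw_tbl <- function(values) tibble::tibble(hcw_um = as.numeric(values))

# Two well-separated clusters at 100 and 500 um, 50 points each.
two_cluster_data <- function(seed = 1) {
  simulate_hcw(simulation_spec(counts = c(50, 50), means = c(100, 500),
                               sds = c(1, 1)), seed = seed)
}

# Independent oracle for the weighted-density crossing: dense grid search
# over (m1, m2) at `res` um resolution, returning every sign-change
# location of w1*N(x|m1,s1) - w2*N(x|m2,s2).
grid_crossings <- function(w1, m1, s1, w2, m2, s2, res = 0.01) {
  xs <- seq(m1, m2, by = res)
  g <- w1 * dnorm(xs, m1, s1) - w2 * dnorm(xs, m2, s2)
  flip <- which(g[-1] * g[-length(g)] <= 0)
  (xs[flip] + xs[flip + 1]) / 2
}

# Build a two-component mixture object with prescribed parameters so the
# boundary solver can be exercised on arbitrary (valid) component pairs.
pair_model <- function(w1, m1, s1, m2, s2) {
  d <- hcw_tbl(c(rep(m1, 3), rep(m2, 3)))
  m <- fit_mixture(d, k = 1)
  m$components <- tibble::tibble(
    component = 1:2, weight = c(w1, 1 - w1), mean = c(m1, m2),
    sd = c(s1, s2)
  )
  m$k <- 2L
  m
}

# Closed-form simple-OLS slope and R^2, independent of lm().
ols_oracle <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  r2 <- 1 - sum((y - ic - sl * x)^2) / sum((y - mean(y))^2)
  list(slope = sl, intercept = ic, r_squared = r2)
}
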