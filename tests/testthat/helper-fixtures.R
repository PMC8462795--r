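# Shared fixtures: small simulated recordings and quick fits.

paper_params <- function(b = 4.0, k = 0.93) {
  crhr_params(73.5, b, 3.3, 0.32, 6.9, k)
}

# one preprocessed 2-day window from a short simulated recording
quick_window <- function(seed, params = paper_params(), n_days = 3, ...) {
  sim <- crhr_simulate(sim_config(params = params, n_days = n_days,
                                  seed = seed, ...))
  prep <- crhr_preprocess(sim$records)
  list(window = prep$windows[[1]], sim = sim, prep = prep)
}

# random gappy observation series drawn straight from the model
random_gap_series <- function(n, params, seed) {
  set.seed(seed)
  gaps <- sample(1:20, n - 1, replace = TRUE,
                 prob = c(0.7, rep(0.3 / 19, 19)))
  t <- cumsum(c(0, gaps)) / 12
  x <- rexp(n, 1 / 10)
  p <- as.numeric(unclass(params))
  mu <- mean_hr(params, t, x)
  vstat <- p[5]^2 / (1 - p[6]^2)
  r <- numeric(n)
  r[1] <- rnorm(1, 0, sqrt(vstat))
  if (n > 1) {
    kg <- p[6]^gaps
    for (i in 2:n) r[i] <- kg[i - 1] * r[i - 1] +
        rnorm(1, 0, sqrt(vstat * (1 - kg[i - 1]^2)))
  }
  gap_series(t, mu + r, x)
}

# dense multivariate-normal log-likelihood oracle for the AR(1) model
dense_mvn_loglik <- function(params, obs) {
  p <- as.numeric(unclass(params))
  t <- obs$t; n <- nrow(obs)
  g <- round(abs(outer(t, t, "-")) * 12)
  Sg <- p[5]^2 * p[6]^g / (1 - p[6]^2)
  r <- obs$hr - mean_hr(params, t, obs$steps_per_min)
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(Sg)$modulus +
                       t(r) %*% solve(Sg, r)))
}

# inverse-variance weighted Pearson correlation
weighted_cor <- function(x, y, w) {
  ok <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  x <- x[ok]; y <- y[ok]; w <- w[ok] / sum(w[ok])
  mx <- sum(w * x); my <- sum(w * y)
  sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# circular coverage: is `truth` inside the arc from lo to hi (going forward)?
arc_covers <- function(lo, hi, truth) {
  wrap_hours(truth - lo) <= wrap_hours(hi - lo)
}
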