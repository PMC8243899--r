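# Trajectory-model core: polynomial curves, likelihood against a brute-force
# oracle, E/M steps against closed forms, full EM behaviour and determinism.

test_that("polynomial means evaluate exactly", {
  s <- time_grid(60)
  expect_equal(poly_mean(3.2, s), rep(3.2, 60))            # intercept only
  expect_equal(poly_mean(c(0, 1), -1), -1)                 # identity line
  # Horner-scheme hand evaluation of 1 + 2s + 3s^2 at s = 0.5
  expect_equal(poly_mean(c(1, 2, 3), 0.5), 1 + 0.5 * (2 + 0.5 * 3))
  expect_error(poly_mean(rep(1, 7), 0), "order")
  expect_error(poly_mean(1, 2), "\\|s\\| <= 1")
})

test_that("time grid is a strictly monotone map into [-1, 0]", {
  s <- time_grid(60)
  expect_equal(s[1], 0)
  expect_equal(s[60], -1)
  expect_true(all(diff(s) < 0))
  expect_true(all(abs(s) <= 1))
})

test_that("mixture log-likelihood matches the brute-force oracle", {
  # density at its mode: G = 1, one patient, one month, y = mu
  p1 <- list(pi = 1, beta = list(2), sigma = 0.7)
  Y1 <- matrix(2, 1, 1)
  expect_equal(gbtm_loglik(p1, Y1, time = 0), log(1 / (0.7 * sqrt(2 * pi))))

  # random micro-instances: n <= 5, T <= 3, G <= 3
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(1:5, 1); Tn <- sample(1:3, 1); G <- sample(1:3, 1)
    s <- sort(stats::runif(Tn, -1, 0), decreasing = TRUE)
    pi <- as.numeric(stats::rgamma(G, 2)); pi <- pi / sum(pi)
    beta <- lapply(seq_len(G), function(g)
      stats::rnorm(sample(1:4, 1), 0, 1))
    sigma <- stats::runif(1, 0.3, 2)
    Y <- matrix(stats::rnorm(n * Tn, 0, 2), n, Tn)
    params <- list(pi = pi, beta = beta, sigma = sigma)
    expect_equal(gbtm_loglik(params, Y, time = s),
                 brute_loglik(pi, beta, sigma, Y, s), tolerance = 1e-10)
    # duplicating every patient doubles the log-likelihood exactly
    expect_equal(gbtm_loglik(params, rbind(Y, Y), time = s),
                 2 * gbtm_loglik(params, Y, time = s), tolerance = 1e-10)
  }
  expect_error(gbtm_loglik(p1, matrix(NA_real_, 1, 1)), "non-finite")
})

test_that("E step follows Bayes' rule", {
  s <- c(0, -0.5)
  # symmetric curves and weights: all posteriors 1/2
  params <- list(pi = c(0.5, 0.5), beta = list(1, 1), sigma = 1)
  P <- gbtm_estep(params, matrix(stats::rnorm(6), 3, 2), time = s)
  expect_equal(P, matrix(0.5, 3, 2), ignore_attr = TRUE)
  # pi = (1, 0): posterior column 2 all zeros
  params2 <- list(pi = c(1, 0), beta = list(1, 2), sigma = 1)
  P2 <- gbtm_estep(params2, matrix(stats::rnorm(6), 3, 2), time = s)
  expect_equal(P2[, 2], rep(0, 3))
  # hand Bayes computation, 2 patients x 2 months x 2 groups
  params3 <- list(pi = c(0.3, 0.7), beta = list(0, 1), sigma = 0.8)
  Y <- matrix(c(0.2, 1.1, -0.4, 0.9), 2, 2)
  lik <- function(y, mu) prod(stats::dnorm(y, mu, 0.8))
  P3 <- gbtm_estep(params3, Y, time = s)
  for (i in 1:2) {
    a <- 0.3 * lik(Y[i, ], c(0, 0)); b <- 0.7 * lik(Y[i, ], c(1, 1))
    expect_equal(P3[i, ], c(a, b) / (a + b), tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(P3) - 1) < 1e-12))
})

test_that("M step solves the weighted least-squares problem", {
  set.seed(42)
  n <- 30; Tn <- 10
  s <- time_grid(Tn)
  Y <- matrix(stats::rnorm(n * Tn, 5, 1), n, Tn)
  # G = 1 reduces to ordinary least squares on the stacked data
  params <- gbtm_mstep(matrix(1, n, 1), Y, orders = 2)
  df <- data.frame(y = as.vector(Y), s = rep(s, each = n))
  ols <- stats::lm(y ~ s + I(s^2), data = df)
  expect_equal(params$beta[[1]], unname(stats::coef(ols)), tolerance = 1e-8)
  expect_equal(params$pi, 1)
  # sigma is the root mean squared residual (ML, divisor n*T)
  expect_equal(params$sigma,
               sqrt(sum(stats::resid(ols)^2) / (n * Tn)), tolerance = 1e-8)

  # degenerate 0/1 memberships reduce to separate per-group OLS fits
  grp <- rep(1:2, each = n / 2)
  post <- cbind(grp == 1, grp == 2) * 1
  Y2 <- Y; Y2[grp == 2, ] <- Y2[grp == 2, ] + 4
  p2 <- gbtm_mstep(post, Y2, orders = c(1, 1))
  for (g in 1:2) {
    dfg <- data.frame(y = as.vector(Y2[grp == g, ]), s = rep(s, each = n / 2))
    expect_equal(p2$beta[[g]], unname(stats::coef(stats::lm(y ~ s, dfg))),
                 tolerance = 1e-8)
  }
  # weighted normal-equation solution beats/equals a coarse grid search
  set.seed(7)
  w <- stats::runif(n); post3 <- cbind(w, 1 - w)
  p3 <- gbtm_mstep(post3, Y, orders = c(0, 0))
  sse <- function(m1, m2) {
    sum(w * rowSums((Y - m1)^2)) + sum((1 - w) * rowSums((Y - m2)^2))
  }
  best_grid <- min(outer(seq(3, 7, 0.05), seq(3, 7, 0.05), Vectorize(sse)))
  expect_lte(sse(p3$beta[[1]], p3$beta[[2]]), best_grid + 1e-8)
  expect_error(gbtm_mstep(matrix(1, 5, 1), Y[1:5, 1:3], orders = 5), "singular")
})

test_that("one-group intercept-only fit recovers mean and ML sigma exactly", {
  set.seed(3)
  Y <- matrix(stats::rnorm(50 * 12, 10, 2), 50, 12)
  fit <- gbtm(Y, groups = 1, orders = 0, n_restarts = 1, seed = 1)
  expect_equal(fit$beta[[1]], mean(Y), tolerance = 1e-9)
  expect_equal(fit$sigma, sqrt(mean((Y - mean(Y))^2)), tolerance = 1e-9)
  expect_equal(fit$pi, 1)
})

test_that("well-separated flat groups are recovered with binomial accuracy", {
  cfg <- flat_two_group_config(n = 200, levels = c(12, 8), sigma = 0.4,
                               weights = c(0.6, 0.4), seed = 31)
  co <- generate_cohort(cfg)
  lp <- log_transform(build_panel(co$claims, co$patients))
  fit <- gbtm(panel_matrix(lp, "total"), groups = 2, orders = 0,
              n_restarts = 3, seed = 2)
  pi_sorted <- sort(fit$pi, decreasing = TRUE)
  expect_lt(abs(pi_sorted[1] - 0.6), 3 * sqrt(0.6 * 0.4 / 200))
  ints <- sort(vapply(fit$beta, `[`, numeric(1), 1), decreasing = TRUE)
  n_hi <- round(200 * pi_sorted[1])
  expect_lt(abs(ints[1] - 12), 4 * 0.4 / sqrt(60 * n_hi) + 0.02)
  expect_lt(abs(ints[2] - 8), 4 * 0.4 / sqrt(60 * (200 - n_hi)) + 0.02)
})

test_that("the likelihood is invariant to permuting group labels", {
  set.seed(11)
  Y <- matrix(stats::rnorm(20 * 5, 3, 1), 20, 5)
  params <- list(pi = c(0.2, 0.5, 0.3),
                 beta = list(c(1, 0.5), 3, c(5, -1, 2)), sigma = 1.1)
  perm <- c(3, 1, 2)
  params_p <- list(pi = params$pi[perm], beta = params$beta[perm], sigma = 1.1)
  expect_equal(gbtm_loglik(params, Y), gbtm_loglik(params_p, Y))
})

test_that("modal assignment breaks ties toward the lowest group index", {
  expect_equal(assign_groups(matrix(c(0.2, 0.8), 1)), 2L)
  expect_equal(assign_groups(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(5)
  P <- matrix(stats::runif(60), 20, 3)
  P <- P / rowSums(P)
  scan <- apply(P, 1, function(r) which(r == max(r))[1])
  expect_equal(assign_groups(P), as.integer(scan))
})

test_that("EM is monotone, reaches a fixed point, and is seed-deterministic", {
  cfg <- flat_two_group_config(n = 120, levels = c(11, 9), sigma = 0.8,
                               seed = 13)
  co <- generate_cohort(cfg)
  Y <- panel_matrix(log_transform(build_panel(co$claims, co$patients)), "total")
  fit <- gbtm(Y, groups = 2, orders = 1, n_restarts = 4, seed = 99, tol = 1e-10)
  # monotone trace
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  # fixed point: one further EM cycle barely moves the log-likelihood
  post <- gbtm_estep(coef(fit), Y)
  params2 <- gbtm_mstep(post, Y, orders = fit$orders)
  expect_lt(abs(gbtm_loglik(params2, Y) - fit$loglik), 1e-4)
  # determinism
  fit2 <- gbtm(Y, groups = 2, orders = 1, n_restarts = 4, seed = 99, tol = 1e-10)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$assignment, fit2$assignment)
  expect_equal(fit$loglik, fit2$loglik)
})

test_that("fitted curves recover the generator truth on the calibrated cohort", {
  co <- generate_cohort(default_calibration("total", n_patients = 2000, seed = 8))
  Y <- panel_matrix(log_transform(build_panel(co$claims, co$patients)), "total")
  fit <- gbtm(Y, groups = 6, orders = 5, n_restarts = 5, seed = 4)
  truth <- calibration_truth_fit("total")
  M_fit <- predict(fit, type = "curves")
  M_true <- vapply(truth$beta, function(b) poly_mean(b, truth$time), numeric(60))
  # optimal label matching: exhaustive over the 720 permutations
  D <- vapply(seq_len(6), function(g)
    colMeans((M_fit - M_true[, g])^2), numeric(6))   # fitted x truth
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  costs <- vapply(perms(1:6), function(p) sum(D[cbind(p, 1:6)]), numeric(1))
  best <- perms(1:6)[[which.min(costs)]]
  for (g in seq_len(6))
    expect_lt(max(abs(M_fit[, best[g]] - M_true[, g])), 0.5)
})

test_that("the censored-normal variant runs and stays monotone", {
  set.seed(17)
  n <- 150; Tn <- 20
  mu <- 0.8
  Y <- matrix(stats::rnorm(n * Tn, mu, 1), n, Tn)
  Y[Y < 0] <- 0   # left-censor at zero
  fit <- gbtm(Y, groups = 1, orders = 0, censored = TRUE, n_restarts = 1,
              seed = 1, max_iter = 300)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  # censored fit should sit nearer the latent mean than the naive zero-coded fit
  naive <- mean(Y)
  expect_lt(abs(fit$beta[[1]][1] - mu), abs(naive - mu))
})
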