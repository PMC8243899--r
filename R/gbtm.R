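# Group-based trajectory model: finite mixture of polynomial mean curves with
# Gaussian errors on the log-expenditure scale, fitted by EM.
#
# Model: patient i with observations y_i1..y_iT at scaled times s_1..s_T
# belongs to latent group g with probability pi_g; within group g,
#   y_it ~ N(beta_g(s_t), sigma^2) independently over t,
# beta_g a polynomial of order p_g <= 5 and sigma shared across groups and
# months. The per-patient likelihood is sum_g pi_g * prod_t phi(...), and the
# scaled time s = -(m - 1)/(T - 1) maps month-before-death index m (1 = death
# month) into [-1, 0] so that quintic terms stay well conditioned.

#' Death-anchored scaled time grid
#'
#' Maps month indices 1..T (1 = month of death, T = earliest) to the scaled
#' time covariate s = -(m - 1) / (T - 1), so s = 0 at death and s = -1 at the
#' start of the observation window.
#'
#' @param T_months Number of months in the panel.
#' @return Numeric vector of length \code{T_months}.
#' @export
time_grid <- function(T_months) {
  -(seq_len(T_months) - 1) / (T_months - 1)
}

#' Evaluate a polynomial mean curve
#'
#' @param beta Coefficient vector, constant term first; length 1..6
#'   (intercept-only up to quintic).
#' @param s Scaled times in [-1, 0] (any values with |s| <= 1 are accepted).
#' @return Numeric vector of mean log-expenditures at \code{s}.
#' @export
poly_mean <- function(beta, s) {
  if (length(beta) < 1L || length(beta) > 6L)
    stop("polynomial order must be between 0 and 5", call. = FALSE)
  if (any(abs(s) > 1 + 1e-9))
    stop("scaled times must satisfy |s| <= 1", call. = FALSE)
  drop(outer(s, seq_along(beta) - 1L, `^`) %*% beta)
}

# validate a params list(pi, beta, sigma)
.check_params <- function(params, G = NULL) {
  if (!all(c("pi", "beta", "sigma") %in% names(params)))
    stop("params must have components pi, beta, sigma", call. = FALSE)
  if (!is.null(G) && length(params$pi) != G)
    stop("params$pi has wrong length", call. = FALSE)
  if (abs(sum(params$pi) - 1) > 1e-10 || any(params$pi < -1e-12))
    stop("mixture weights must lie on the simplex", call. = FALSE)
  if (params$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (any(lengths(params$beta) > 6L))
    stop("polynomial order must be at most 5", call. = FALSE)
  invisible(params)
}

# T x G matrix of group mean curves
.curve_matrix <- function(beta_list, s) {
  M <- vapply(beta_list, function(b) poly_mean(b, s), numeric(length(s)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(s))
  M
}

# n x G matrix of per-patient log joint densities under each group
# (uncensored normal likelihood); M is the T x G curve matrix
.logdens <- function(Y, M, sigma) {
  n <- nrow(Y); Tn <- ncol(Y)
  rss <- rowSums(Y^2) - 2 * (Y %*% M) +
    matrix(colSums(M^2), n, ncol(M), byrow = TRUE)
  -0.5 * Tn * log(2 * pi * sigma^2) - rss / (2 * sigma^2)
}

# censored variant: cells with y == 0 are treated as left-censored at 0,
# contributing log Phi((0 - mu)/sigma)
.logdens_censored <- function(Y, M, sigma, cens) {
  n <- nrow(Y); G <- ncol(M)
  out <- matrix(0, n, G)
  for (g in seq_len(G)) {
    mu <- M[, g]
    A <- stats::dnorm(sweep(Y, 2L, mu), sd = sigma, log = TRUE)
    B <- matrix(stats::pnorm(-mu / sigma, log.p = TRUE), n, ncol(Y), byrow = TRUE)
    out[, g] <- rowSums(ifelse(cens, B, A))
  }
  out
}

.logsumexp_rows <- function(L) {
  mx <- apply(L, 1L, max)
  mx + log(rowSums(exp(L - mx)))
}

#' Mixture log-likelihood of a trajectory model
#'
#' Total log-likelihood of the data under given parameters: for each patient,
#' the log of the mixture over groups of the product over months of normal
#' densities, computed in log space with per-group log-sum-exp.
#'
#' @param params List with \code{pi} (mixture weights on the simplex),
#'   \code{beta} (list of per-group polynomial coefficient vectors) and
#'   \code{sigma} (shared residual SD, > 0).
#' @param Y n x T matrix of log-scale expenditures (all entries finite).
#' @param time Optional scaled time vector (defaults to [time_grid()] on the
#'   panel width).
#' @return A single finite number.
#' @export
gbtm_loglik <- function(params, Y, time = NULL) {
  Y <- as.matrix(Y)
  if (any(!is.finite(Y))) stop("Y contains non-finite entries", call. = FALSE)
  .check_params(params)
  s <- if (is.null(time)) time_grid(ncol(Y)) else time
  M <- .curve_matrix(params$beta, s)
  L <- sweep(.logdens(Y, M, params$sigma), 2L, log(params$pi), `+`)
  sum(.logsumexp_rows(L))
}

#' E step: posterior group-membership probabilities
#'
#' Bayes-rule posteriors proportional to pi_g times the per-patient group
#' density, computed in log space and row-normalised.
#'
#' @inheritParams gbtm_loglik
#' @return n x G matrix whose rows sum to 1.
#' @export
gbtm_estep <- function(params, Y, time = NULL) {
  Y <- as.matrix(Y)
  .check_params(params)
  s <- if (is.null(time)) time_grid(ncol(Y)) else time
  M <- .curve_matrix(params$beta, s)
  lpi <- ifelse(params$pi > 0, log(params$pi), -Inf)
  L <- sweep(.logdens(Y, M, params$sigma), 2L, lpi, `+`)
  if (any(!is.finite(apply(L, 1L, max))))
    stop("degenerate parameters: a patient has zero density under every group",
         call. = FALSE)
  P <- exp(L - .logsumexp_rows(L))
  P / rowSums(P)
}

#' M step: weighted polynomial regressions and pooled variance
#'
#' Given posterior weights, each group's coefficients solve the
#' posterior-weighted least-squares polynomial regression of y on scaled
#' time; sigma^2 is the posterior-weighted mean squared residual pooled over
#' groups and months, and the mixture weights are the posterior column means.
#'
#' @param posterior n x G matrix with rows summing to 1.
#' @param Y n x T data matrix.
#' @param orders Integer vector (length G) of polynomial orders, each 0..5.
#' @param time Optional scaled time vector.
#' @return A params list (\code{pi}, \code{beta}, \code{sigma}).
#' @export
gbtm_mstep <- function(posterior, Y, orders, time = NULL) {
  Y <- as.matrix(Y)
  posterior <- as.matrix(posterior)
  n <- nrow(Y); Tn <- ncol(Y); G <- ncol(posterior)
  if (length(orders) == 1L) orders <- rep(orders, G)
  if (any(orders < 0L | orders > 5L))
    stop("polynomial orders must lie in 0..5", call. = FALSE)
  if (any(orders + 1L > Tn))
    stop("singular design: order ", max(orders), " needs more than ", Tn,
         " distinct months", call. = FALSE)
  if (max(abs(rowSums(posterior) - 1)) > 1e-6)
    stop("posterior rows must sum to 1", call. = FALSE)
  s <- if (is.null(time)) time_grid(Tn) else time
  wsum <- colSums(posterior)                 # effective group sizes
  Z <- crossprod(Y, posterior)               # T x G: sum_i w_ig y_it
  yy <- rowSums(Y^2)
  beta <- vector("list", G)
  rss <- numeric(G)
  for (g in seq_len(G)) {
    X <- outer(s, 0:orders[g], `^`)
    XtX <- crossprod(X) * wsum[g]
    Xty <- crossprod(X, Z[, g])
    b <- tryCatch(solve(XtX, Xty), error = function(e)
      stop("singular weighted design in group ", g, call. = FALSE))
    beta[[g]] <- drop(b)
    m <- drop(X %*% b)
    q <- yy - 2 * drop(Y %*% m) + sum(m^2)   # per-patient SSE about the curve
    rss[g] <- sum(posterior[, g] * q)
  }
  sigma <- sqrt(sum(rss) / (n * Tn))
  list(pi = wsum / n, beta = beta, sigma = sigma)
}

# M step for the censored-normal variant: censored cells are imputed with
# their truncated-normal conditional moments under the current parameters
# (standard tobit-EM update), then the weighted regressions proceed as usual.
.mstep_censored <- function(posterior, Y, orders, s, params, cens) {
  n <- nrow(Y); Tn <- ncol(Y); G <- ncol(posterior)
  M <- .curve_matrix(params$beta, s)
  sig <- params$sigma
  wsum <- colSums(posterior)
  beta <- vector("list", G)
  rss <- numeric(G)
  for (g in seq_len(G)) {
    mu <- matrix(M[, g], n, Tn, byrow = TRUE)
    a <- -mu / sig                            # standardised censoring point
    lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
    ey <- mu - sig * lam                      # E[y* | y* < 0]
    vy <- sig^2 * pmax(0, 1 - lam * (lam - a))
    Yg <- ifelse(cens, ey, Y)
    V <- ifelse(cens, vy, 0)
    X <- outer(s, 0:orders[g], `^`)
    XtX <- crossprod(X) * wsum[g]
    Xty <- crossprod(X, crossprod(Yg, posterior[, g]))
    b <- solve(XtX, Xty)
    beta[[g]] <- drop(b)
    mfit <- matrix(drop(X %*% b), n, Tn, byrow = TRUE)
    rss[g] <- sum(posterior[, g] * rowSums((Yg - mfit)^2 + V))
  }
  list(pi = wsum / n, beta = beta, sigma = sqrt(sum(rss) / (n * Tn)))
}

#' Modal group assignment
#'
#' Argmax of each posterior row; ties are broken toward the lowest group
#' index so assignment is deterministic.
#'
#' @param posterior n x G matrix of posterior probabilities.
#' @return Integer vector of group indices in 1..G.
#' @export
assign_groups <- function(posterior) {
  posterior <- as.matrix(posterior)
  max.col(posterior, ties.method = "first")
}

# initial hard partition for one restart: k-means on per-patient summary
# features -- overall mean, OLS slope, and means over the early / middle /
# late thirds of the window (the segment means discriminate rise timing,
# which a global slope cannot) -- jittered for restarts after the first
.init_partition <- function(Y, G, s, restart) {
  n <- nrow(Y); Tn <- ncol(Y)
  sc <- s - mean(s)
  feats <- cbind(rowMeans(Y), drop(Y %*% sc) / sum(sc^2))
  if (Tn >= 6L) {
    thirds <- split(seq_len(Tn), cut(seq_len(Tn), 3L, labels = FALSE))
    seg <- vapply(thirds, function(ix)
      rowMeans(Y[, ix, drop = FALSE]), numeric(n))
    feats <- cbind(feats, seg)
  }
  fs <- scale(feats)
  fs[!is.finite(fs)] <- 0
  if (restart > 1L) fs <- fs + stats::rnorm(length(fs), 0, 0.75)
  if (n <= G) return(seq_len(n) %% G + 1L)
  km <- tryCatch(
    stats::kmeans(fs, centers = G, nstart = if (restart == 1L) 5L else 2L,
                  iter.max = 50L),
    error = function(e) NULL)
  if (is.null(km)) sample.int(G, n, replace = TRUE) else km$cluster
}

#' Fit a group-based trajectory model
#'
#' Maximum-likelihood fit of the finite mixture of polynomial trajectories by
#' EM with multiple restarts. Restart 1 initialises from k-means on
#' per-patient (mean, OLS slope) features; later restarts jitter the features
#' before clustering. EM alternates [gbtm_estep()] and [gbtm_mstep()] until
#' the relative log-likelihood change falls below \code{tol} or
#' \code{max_iter} iterations; the log-likelihood is asserted nondecreasing
#' along the way, and the best converged restart is returned. Identical
#' inputs and seed reproduce an identical fit.
#'
#' @param y n x T numeric matrix of log-scale expenditures; column 1 is the
#'   month of death, column T the earliest month.
#' @param groups Number of latent groups G (n must be at least G).
#' @param orders Polynomial order(s), a scalar or length-G vector in 0..5.
#' @param time Optional scaled-time vector; defaults to [time_grid()].
#' @param n_restarts Number of EM restarts (default 10).
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change drops below \code{tol} (default 1e-8) or after
#'   \code{max_iter} (default 500) iterations.
#' @param censored If \code{TRUE}, zero cells of \code{y} are treated as
#'   left-censored at zero (censored-normal likelihood) instead of observed
#'   zeros. Off by default: the default model takes the zero-coded log
#'   transform literally.
#' @param seed RNG seed controlling the restarts (restored on exit).
#' @param verbose Print per-restart progress.
#' @return Object of class \code{"gbtm"}: parameter estimates (\code{pi},
#'   \code{beta}, \code{sigma}), \code{loglik}, \code{n_params} =
#'   (G-1) + sum(orders+1) + 1, posterior matrix, modal \code{assignment},
#'   convergence information and the log-likelihood trace of the winning
#'   restart.
#' @seealso [gbtm_grid()] for model selection, [adequacy_report()] for
#'   classification diagnostics.
#' @export
gbtm <- function(y, groups, orders = 2L, time = NULL, n_restarts = 10L,
                 max_iter = 500L, tol = 1e-8, censored = FALSE, seed = NULL,
                 verbose = FALSE) {
  Y <- as.matrix(y)
  if (any(!is.finite(Y))) stop("y contains non-finite entries", call. = FALSE)
  n <- nrow(Y); Tn <- ncol(Y)
  G <- as.integer(groups)
  if (n < G) stop("need at least as many patients as groups", call. = FALSE)
  if (length(orders) == 1L) orders <- rep(as.integer(orders), G)
  if (length(orders) != G) stop("'orders' must have length 1 or G", call. = FALSE)
  if (any(orders < 0L | orders > 5L))
    stop("polynomial orders must lie in 0..5", call. = FALSE)
  s <- if (is.null(time)) time_grid(Tn) else time
  cens <- if (censored) Y == 0 else NULL

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  best <- NULL
  restart_ll <- rep(NA_real_, n_restarts)
  for (r in seq_len(n_restarts)) {
    part <- .init_partition(Y, G, s, r)
    post <- matrix(0, n, G)
    post[cbind(seq_len(n), part)] <- 1
    post <- 0.95 * post + 0.05 / G            # soften the hard start
    fit <- tryCatch(
      .em_run(Y, post, orders, s, max_iter, tol, censored, cens),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) next
    restart_ll[r] <- fit$loglik
    if (verbose)
      message(sprintf("restart %d: loglik %.3f (%s, %d iter)", r, fit$loglik,
                      if (fit$converged) "converged" else "not converged",
                      fit$n_iter))
    better <- is.null(best) ||
      (fit$converged && !best$converged) ||
      (fit$converged == best$converged && fit$loglik > best$loglik)
    if (better) { best <- fit; best$restart_id <- r }
  }
  if (is.null(best)) {
    err <- simpleError("all EM restarts failed or diverged")
    err$restart_loglik <- restart_ll
    stop(err)
  }
  if (!best$converged)
    warning("no restart reached the convergence tolerance; returning the best run",
            call. = FALSE)

  post <- best$posterior
  structure(list(
    pi = best$params$pi, beta = best$params$beta, sigma = best$params$sigma,
    groups = G, orders = orders, time = s,
    loglik = best$loglik,
    n_params = (G - 1L) + sum(orders + 1L) + 1L,
    posterior = post,
    assignment = assign_groups(post),
    converged = best$converged, n_iter = best$n_iter,
    loglik_trace = best$trace,
    restart_id = best$restart_id, restart_loglik = restart_ll,
    nobs = n, n_months = Tn, censored = censored,
    seed = seed, call = match.call()
  ), class = "gbtm")
}

# one EM run from an initial posterior
.em_run <- function(Y, post, orders, s, max_iter, tol, censored, cens) {
  params <- gbtm_mstep(post, Y, orders, time = s)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    M <- .curve_matrix(params$beta, s)
    LD <- if (censored) .logdens_censored(Y, M, params$sigma, cens)
          else .logdens(Y, M, params$sigma)
    lpi <- ifelse(params$pi > 0, log(params$pi), -Inf)
    L <- sweep(LD, 2L, lpi, `+`)
    lse <- .logsumexp_rows(L)
    ll <- sum(lse)
    if (!is.finite(ll)) stop("log-likelihood diverged", call. = FALSE)
    if (ll < ll_old - 1e-6 * (abs(ll_old) + 1))
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    trace <- c(trace, ll)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) { converged <- TRUE }
    post <- exp(L - lse)
    post <- post / rowSums(post)
    if (converged || it >= max_iter) break
    params <- if (censored) .mstep_censored(post, Y, orders, s, params, cens)
              else gbtm_mstep(post, Y, orders, time = s)
    ll_old <- ll
  }
  list(params = params, posterior = post, loglik = ll, trace = trace,
       converged = converged, n_iter = it)
}
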