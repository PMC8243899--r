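# Model selection: BIC grid over group counts and polynomial orders, with the
# minimum-group-proportion admissibility rule.

#' Bayesian information criterion (trajectory-literature convention)
#'
#' BIC = loglik - 0.5 * k * log(n), with n the number of patients; higher is
#' better. This is the sign convention customary in the trajectory-modelling
#' literature (the negative of half the usual penalised deviance).
#'
#' @param object A fitted [gbtm()] model (anything with \code{loglik} and
#'   \code{n_params} components works).
#' @param n Sample size used in the penalty; defaults to the number of
#'   patients the model was fitted to.
#' @return A single number.
#' @export
gbtm_bic <- function(object, n = object$nobs) {
  if (is.null(n) || n < 1) stop("'n' must be at least 1", call. = FALSE)
  object$loglik - 0.5 * object$n_params * log(n)
}

#' Fit and compare a grid of candidate trajectory models
#'
#' Fits every combination of group count and common polynomial order, marks
#' as inadmissible any candidate whose smallest estimated group proportion
#' falls below \code{min_prop} (or that failed to converge), and selects the
#' admissible candidate with the best [gbtm_bic()]. With
#' \code{refine = TRUE}, the chosen model's per-group orders are then
#' greedily reduced one group at a time for as long as the BIC does not
#' worsen.
#'
#' @param y n x T log-scale data matrix (column 1 = death month).
#' @param groups Candidate group counts (default 2..8).
#' @param orders Candidate common polynomial orders (default 0..5).
#' @param min_prop Minimum admissible estimated group proportion
#'   (default 0.05).
#' @param n_restarts EM restarts per candidate (default 5).
#' @param seed Seed; each candidate gets a deterministic seed derived from
#'   it, so the whole grid is reproducible.
#' @param refine Greedy per-group order refinement of the winner.
#' @param verbose Print progress.
#' @param ... Passed to [gbtm()].
#' @return Object of class \code{"gbtm_grid"}: \code{grid} (one row per
#'   candidate: G, order, loglik, n_params, bic, min_prop, converged,
#'   admissible), \code{fits} (all fitted models), \code{best} (the chosen
#'   fit) and \code{best_index}.
#' @export
gbtm_grid <- function(y, groups = 2:8, orders = 0:5, min_prop = 0.05,
                      n_restarts = 5L, seed = 1L, refine = FALSE,
                      verbose = FALSE, ...) {
  y <- as.matrix(y)
  cand <- expand.grid(G = groups, order = orders)
  fits <- vector("list", nrow(cand))
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    G <- cand$G[i]; p <- cand$order[i]
    fit <- tryCatch(
      gbtm(y, groups = G, orders = p, n_restarts = n_restarts,
           seed = seed + 1000L * i, ...),
      warning = function(w) {
        f <- suppressWarnings(
          gbtm(y, groups = G, orders = p, n_restarts = n_restarts,
               seed = seed + 1000L * i, ...))
        f$converged <- FALSE
        f
      },
      error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      G = G, order = p,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      n_params = if (is.null(fit)) NA_integer_ else fit$n_params,
      bic = if (is.null(fit)) NA_real_ else gbtm_bic(fit),
      min_prop = if (is.null(fit)) NA_real_ else min(fit$pi),
      converged = !is.null(fit) && fit$converged
    )
    if (verbose && !is.null(fit))
      message(sprintf("G=%d order=%d: bic %.2f (min pi %.3f)", G, p,
                      rows[[i]]$bic, rows[[i]]$min_prop))
  }
  grid <- do.call(rbind, rows)
  grid$admissible <- grid$converged & !is.na(grid$min_prop) &
    grid$min_prop >= min_prop
  if (!any(grid$admissible)) {
    err <- simpleError("no admissible candidate in the selection grid")
    err$grid <- grid
    stop(err)
  }
  best_index <- which(grid$admissible)[which.max(grid$bic[grid$admissible])]
  best <- fits[[best_index]]
  if (refine) best <- .refine_orders(y, best, seed = seed, ...)
  structure(list(grid = grid, fits = fits, best = best,
                 best_index = best_index, min_prop = min_prop),
            class = "gbtm_grid")
}

# greedy per-group order reduction while the BIC does not worsen
.refine_orders <- function(y, fit, seed, ...) {
  repeat {
    improved <- FALSE
    for (g in seq_len(fit$groups)) {
      if (fit$orders[g] == 0L) next
      try_orders <- fit$orders
      try_orders[g] <- try_orders[g] - 1L
      cand <- tryCatch(
        suppressWarnings(gbtm(y, groups = fit$groups, orders = try_orders,
                              n_restarts = 3L, seed = seed + 7L * g, ...)),
        error = function(e) NULL)
      if (!is.null(cand) && gbtm_bic(cand) >= gbtm_bic(fit)) {
        fit <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  fit
}

#' @export
print.gbtm_grid <- function(x, ...) {
  g <- x$grid
  cat("Trajectory-model selection grid (", nrow(g), " candidates, ",
      sum(g$admissible), " admissible; min group proportion ",
      x$min_prop, ")\n", sep = "")
  b <- g[x$best_index, ]
  cat(sprintf("Chosen: G = %d, common order %d, BIC = %.2f\n",
              b$G, b$order, b$bic))
  invisible(x)
}
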