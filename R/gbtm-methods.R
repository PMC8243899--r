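# Standard S3 methods for fitted trajectory models.

#' @export
print.gbtm <- function(x, digits = 3L, ...) {
  cat("Group-based trajectory model (", x$groups, " groups, orders ",
      paste(x$orders, collapse = "/"), ")\n", sep = "")
  cat("  patients: ", x$nobs, "   months: ", x$n_months,
      "   log-likelihood: ", format(x$loglik, digits = 10), "\n", sep = "")
  cat("  mixture weights: ", paste(round(100 * x$pi, 1L), "%", sep = "",
                                   collapse = ", "), "\n", sep = "")
  cat("  residual SD (log scale): ", round(x$sigma, digits), "\n", sep = "")
  if (!x$converged) cat("  ** EM did not converge **\n")
  invisible(x)
}

#' @export
coef.gbtm <- function(object, ...) {
  list(pi = object$pi, beta = object$beta, sigma = object$sigma)
}

#' @export
logLik.gbtm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.gbtm <- function(object, ...) object$nobs

#' Predicted trajectory curves, posteriors or classes
#'
#' @param object A fitted [gbtm()] model.
#' @param newdata Optional n x T matrix of new log-scale observations
#'   (required for \code{type = "posterior"} or \code{"class"}).
#' @param months Month-before-death indices at which to evaluate the fitted
#'   curves (default the fitted grid).
#' @param type \code{"curves"} (T x G matrix of group mean curves),
#'   \code{"posterior"} or \code{"class"}.
#' @param ... Unused.
#' @export
predict.gbtm <- function(object, newdata = NULL,
                         months = seq_len(object$n_months),
                         type = c("curves", "posterior", "class"), ...) {
  type <- match.arg(type)
  if (type == "curves") {
    s <- -(months - 1) / (object$n_months - 1)
    M <- .curve_matrix(object$beta, s)
    dimnames(M) <- list(months, paste0("group", seq_len(object$groups)))
    return(M)
  }
  if (is.null(newdata))
    stop("'newdata' is required for posterior/class predictions", call. = FALSE)
  P <- gbtm_estep(coef(object), as.matrix(newdata), time = object$time)
  if (type == "posterior") P else assign_groups(P)
}

#' @export
fitted.gbtm <- function(object, ...) {
  # posterior-weighted mean curve per patient
  M <- .curve_matrix(object$beta, object$time)   # T x G
  object$posterior %*% t(M)
}

#' @export
residuals.gbtm <- function(object, y, ...) {
  if (missing(y))
    stop("supply the data matrix 'y' the model was fitted to", call. = FALSE)
  as.matrix(y) - fitted(object)
}

#' Simulate cohorts from a fitted trajectory model
#'
#' Parametric simulation: group labels are drawn from the fitted mixture
#' weights and observations from the fitted group curves plus Gaussian
#' noise. Used by the bootstrap confidence intervals for group proportions.
#'
#' @param object A fitted [gbtm()] model.
#' @param nsim Number of replicate datasets.
#' @param seed Optional RNG seed (restored on exit).
#' @param n Patients per replicate (default: as fitted).
#' @param ... Unused.
#' @return A list of \code{nsim} matrices, each with a \code{"group"}
#'   attribute holding the simulated labels.
#' @export
simulate.gbtm <- function(object, nsim = 1L, seed = NULL, n = object$nobs, ...) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  M <- .curve_matrix(object$beta, object$time)   # T x G
  Tn <- object$n_months
  lapply(seq_len(nsim), function(b) {
    g <- sample.int(object$groups, n, replace = TRUE, prob = object$pi)
    Y <- t(M)[g, , drop = FALSE] +
      matrix(stats::rnorm(n * Tn, 0, object$sigma), n, Tn)
    attr(Y, "group") <- g
    Y
  })
}

#' @export
summary.gbtm <- function(object, ...) {
  app <- avg_posterior_prob(object$posterior, object$assignment)
  assigned <- tabulate(object$assignment, nbins = object$groups) / object$nobs
  occ <- odds_correct_classification(app, object$pi)
  tab <- data.frame(group = seq_len(object$groups),
                    order = object$orders,
                    pi_hat = object$pi,
                    assigned = assigned,
                    APP = app, OCC = occ)
  structure(list(model = object, table = tab), class = "summary.gbtm")
}

#' @export
print.summary.gbtm <- function(x, digits = 3L, ...) {
  print(x$model)
  cat("\nClassification diagnostics:\n")
  tab <- x$table
  tab$pi_hat <- round(tab$pi_hat, digits)
  tab$assigned <- round(tab$assigned, digits)
  tab$APP <- round(tab$APP, digits)
  tab$OCC <- round(tab$OCC, 1L)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot fitted trajectories against observed group means
#'
#' Draws the fitted polynomial mean curves (lines) and, when the data matrix
#' is supplied, the observed per-assigned-group monthly means (points),
#' against months before death (death at the right edge).
#'
#' @param x A fitted [gbtm()] model.
#' @param y Optional n x T data matrix (the fitting data) for observed means.
#' @param labels Optional group labels for the legend.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gbtm <- function(x, y = NULL, labels = NULL, ...) {
  Tn <- x$n_months
  mb <- Tn:1                                  # plotting order: past -> death
  M <- .curve_matrix(x$beta, x$time)          # rows = month index 1..T
  graphics::matplot(-(mb), M[mb, ], type = "l", lty = 1L, lwd = 2L,
                    col = seq_len(x$groups),
                    xlab = "months before death",
                    ylab = "mean log expenditure", ...)
  if (!is.null(y)) {
    y <- as.matrix(y)
    for (g in seq_len(x$groups)) {
      rows <- x$assignment == g
      if (!any(rows)) next
      obs <- colMeans(y[rows, , drop = FALSE])
      graphics::points(-(mb), obs[mb], col = g, pch = 1L, cex = 0.5)
    }
  }
  leg <- if (is.null(labels)) paste0("group ", seq_len(x$groups)) else labels
  graphics::legend("topleft", bty = "n", lty = 1L, col = seq_len(x$groups),
                   legend = sprintf("%s (%.1f%%)", leg, 100 * x$pi), cex = 0.8)
  invisible(x)
}
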