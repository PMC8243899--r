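# Classification adequacy diagnostics: average posterior probability of
# assignment (APP), odds of correct classification (OCC), agreement between
# estimated and assigned proportions, and bootstrap confidence intervals for
# the estimated proportions.

#' Average posterior probability of assignment (APP)
#'
#' For each group, the mean posterior membership probability among the
#' patients modally assigned to it. The customary adequacy threshold is
#' APP >= 0.7; chance level is 1/G.
#'
#' @param posterior n x G posterior matrix.
#' @param assignments Modal assignments (must equal the row-wise argmax of
#'   \code{posterior}).
#' @return Length-G vector; \code{NA} (with a \code{"empty_groups"}
#'   attribute) for groups with no assigned members.
#' @export
avg_posterior_prob <- function(posterior, assignments) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (!identical(as.integer(assignments), assign_groups(posterior)))
    stop("assignments are not the modal (argmax) classification of 'posterior'",
         call. = FALSE)
  app <- vapply(seq_len(G), function(g) {
    rows <- assignments == g
    if (!any(rows)) return(NA_real_)
    mean(posterior[rows, g])
  }, numeric(1L))
  empty <- which(!is.finite(app))
  if (length(empty)) attr(app, "empty_groups") <- empty
  app
}

#' Odds of correct classification (OCC)
#'
#' OCC_g = [APP_g / (1 - APP_g)] / [pi_g / (1 - pi_g)]: the odds of a correct
#' modal assignment relative to the odds under chance assignment at the
#' estimated group proportion. OCC = 1 means assignment is no better than
#' chance; the customary adequacy threshold is OCC >= 5. Boundary inputs
#' (APP or pi at 0/1) yield an \code{Inf}/0 sentinel rather than an error.
#'
#' @param app APP per group (vector).
#' @param pi_hat Estimated group proportions (vector, same length).
#' @return Length-G vector of positive odds ratios (possibly \code{Inf}).
#' @export
odds_correct_classification <- function(app, pi_hat) {
  if (length(app) != length(pi_hat))
    stop("'app' and 'pi_hat' must have the same length", call. = FALSE)
  odds <- function(p) p / (1 - p)
  out <- odds(app) / odds(pi_hat)
  out[pi_hat <= 0] <- Inf
  out
}

#' Bootstrap confidence intervals for group proportions
#'
#' Parametric bootstrap: \code{n_boot} replicate cohorts are simulated from
#' the fitted model; in each, the mixture weights are re-estimated by EM with
#' the group curves and residual SD frozen at their fitted values (so labels
#' cannot switch), and the percentile interval of the replicate weights is
#' returned per group.
#'
#' @param object A converged [gbtm()] fit.
#' @param level Confidence level (default 0.98).
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Optional RNG seed (restored on exit).
#' @return G x 2 matrix of lower/upper bounds, with the fitted proportions in
#'   attribute \code{"pi_hat"}.
#' @export
proportion_ci <- function(object, level = 0.98, n_boot = 500L, seed = NULL) {
  stopifnot(inherits(object, "gbtm"))
  if (!object$converged)
    stop("bootstrap requires a converged fit", call. = FALSE)
  G <- object$groups
  if (G == 1L) {
    out <- matrix(1, 1L, 2L, dimnames = list(NULL, c("lower", "upper")))
    attr(out, "pi_hat") <- 1
    return(out)
  }
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  M <- .curve_matrix(object$beta, object$time)
  n <- object$nobs; Tn <- object$n_months
  sig <- object$sigma
  reps <- matrix(NA_real_, n_boot, G)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    g <- sample.int(G, n, replace = TRUE, prob = object$pi)
    Y <- t(M)[g, , drop = FALSE] + matrix(stats::rnorm(n * Tn, 0, sig), n, Tn)
    LD <- .logdens(Y, M, sig)                  # fixed across pi iterations
    p <- object$pi
    ok <- TRUE
    for (it in 1:200) {
      L <- sweep(LD, 2L, ifelse(p > 0, log(p), -Inf), `+`)
      P <- exp(L - .logsumexp_rows(L))
      p_new <- colMeans(P / rowSums(P))
      if (any(!is.finite(p_new))) { ok <- FALSE; break }
      if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
      p <- p_new
    }
    if (ok) reps[b, ] <- p else fails <- fails + 1L
  }
  if (fails > 0.10 * n_boot)
    stop("bootstrap weight re-estimation failed in ", fails, " of ", n_boot,
         " replicates", call. = FALSE)
  a <- (1 - level) / 2
  out <- t(apply(reps, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  colnames(out) <- c("lower", "upper")
  attr(out, "pi_hat") <- object$pi
  out
}

#' Four-part classification adequacy report
#'
#' Assembles per group: estimated proportion, assigned (modal) proportion,
#' APP, OCC, a bootstrap confidence interval for the estimated proportion,
#' and pass flags for the customary criteria APP >= 0.7, OCC >= 5, and
#' |assigned - estimated| <= \code{closeness} (the raw difference is always
#' reported; the 0.05 default is this package's documented convention, since
#' "close" has no universal numeric definition).
#'
#' @param object A converged [gbtm()] fit.
#' @param level,n_boot,seed Passed to [proportion_ci()].
#' @param closeness Proportion-agreement flag threshold (default 0.05).
#' @param ci Set \code{FALSE} to skip the bootstrap interval.
#' @return Object of class \code{"gbtm_adequacy"}: a per-group data frame
#'   plus an overall \code{pass} flag.
#' @export
adequacy_report <- function(object, level = 0.98, n_boot = 500L, seed = NULL,
                            closeness = 0.05, ci = TRUE) {
  stopifnot(inherits(object, "gbtm"))
  if (!object$converged)
    stop("adequacy diagnostics require a converged fit", call. = FALSE)
  app <- avg_posterior_prob(object$posterior, object$assignment)
  assigned <- tabulate(object$assignment, nbins = object$groups) / object$nobs
  occ <- odds_correct_classification(app, object$pi)
  tab <- data.frame(
    group = seq_len(object$groups),
    pi_hat = object$pi, assigned = assigned,
    diff = abs(assigned - object$pi),
    APP = as.numeric(app), OCC = occ,
    app_ok = !is.na(app) & app >= 0.7,
    occ_ok = is.finite(occ) & occ >= 5 | is.infinite(occ),
    prop_ok = abs(assigned - object$pi) <= closeness
  )
  if (ci) {
    bounds <- proportion_ci(object, level = level, n_boot = n_boot, seed = seed)
    tab$ci_lower <- bounds[, "lower"]
    tab$ci_upper <- bounds[, "upper"]
  }
  structure(list(table = tab, closeness = closeness, level = level,
                 pass = all(tab$app_ok & tab$occ_ok & tab$prop_ok)),
            class = "gbtm_adequacy")
}

#' @export
print.gbtm_adequacy <- function(x, digits = 3L, ...) {
  cat("Classification adequacy (", if (x$pass) "PASS" else "FAIL",
      "): APP >= 0.7, OCC >= 5, |assigned - estimated| <= ",
      x$closeness, "\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], function(z) round(z, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Heuristic trajectory labels
#'
#' Names each fitted group with the vocabulary customary for end-of-life
#' spending trajectories, by a deterministic rule on the fitted curve:
#' a curve whose total range is below \code{flat_range} is "persistent", and
#' is called high / medium-to-high / low by where its late-window mean sits
#' within the span of all fitted values (top 15\%, middle, bottom 45\%).
#' A rising curve is classified by the month (counting back from death) at
#' which it first crosses the midpoint of its own range: crossing 37+ months
#' before death is "early rise then high persistent", 15-36 months
#' "progressive increase", 7-14 months "late rise", and 6 or fewer
#' "low persistent then very late rise".
#'
#' @param object A fitted [gbtm()] model.
#' @param flat_range Log-scale range below which a curve counts as flat
#'   (default 0.8).
#' @param late_window Month indices of the late window (default 1:12).
#' @return Character vector of group labels.
#' @export
label_trajectories <- function(object, flat_range = 0.8, late_window = 1:12) {
  stopifnot(inherits(object, "gbtm"))
  M <- .curve_matrix(object$beta, object$time)    # T x G, row 1 = death
  rng_all <- range(M)
  span <- max(diff(rng_all), 1e-9)
  vapply(seq_len(object$groups), function(g) {
    v <- M[, g]
    rg <- max(v) - min(v)
    if (rg < flat_range) {
      q <- (mean(v[late_window]) - rng_all[1]) / span
      if (q >= 0.85) return("high persistent")
      if (q >= 0.45) return("medium-to-high persistent")
      return("low persistent")
    }
    mid <- (max(v) + min(v)) / 2
    mc <- max(which(v >= mid))    # furthest-from-death month at/above midpoint
    if (mc >= 37L) "early rise then high persistent"
    else if (mc >= 15L) "progressive increase"
    else if (mc >= 7L) "late rise"
    else "low persistent then very late rise"
  }, character(1L))
}
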