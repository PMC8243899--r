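# Association between trajectory membership and patient factors:
# multinomial logistic regression against the high-persistent reference
# group, reported as odds ratios with Wald 95% confidence intervals.

#' Build the covariate design for the association models
#'
#' Model 1 uses age, sex and every binary disease (\code{dx_*}) and service
#' (\code{svc_*}) flag; Model 2 replaces the individual disease flags by the
#' disease count (sum of the \code{dx_*} flags). Constant columns are dropped
#' with a warning (they carry no information and break the fit).
#'
#' @param patients Patient table with \code{age}, \code{sex} and \code{dx_*}
#'   / \code{svc_*} flag columns (all flags 0/1, no missing values).
#' @param model 1 (or \code{"diseases"}) / 2 (or \code{"count"}).
#' @return List with \code{X} (numeric matrix including an intercept column)
#'   and \code{terms} (covariate names).
#' @export
build_design <- function(patients, model = 1) {
  model <- if (is.character(model)) match.arg(model, c("diseases", "count"))
           else c("diseases", "count")[as.integer(model)]
  need <- c("age", "sex")
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("patients table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dx <- grep("^dx_", names(patients), value = TRUE)
  svc <- grep("^svc_", names(patients), value = TRUE)
  if (!length(dx) || !length(svc))
    stop("patients table needs dx_* disease flags and svc_* service flags",
         call. = FALSE)
  flag_cols <- c(svc, dx)
  flags <- as.matrix(patients[flag_cols])
  if (any(is.na(flags)) || any(is.na(patients$age))) {
    bad <- patients$patient_id[rowSums(is.na(patients[c("age", flag_cols)])) > 0]
    stop("missing covariate values for patient(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (!all(flags %in% c(0, 1)))
    stop("disease/service flags must be binary 0/1", call. = FALSE)
  male <- as.numeric(patients$sex == "male")
  X <- if (model == "diseases") {
    cbind(`(Intercept)` = 1, age = patients$age, male = male,
          as.matrix(patients[svc]), as.matrix(patients[dx]))
  } else {
    cbind(`(Intercept)` = 1, age = patients$age, male = male,
          as.matrix(patients[svc]),
          n_diseases = rowSums(as.matrix(patients[dx])))
  }
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, function(z) stats::var(z) > 0))
  if (!all(keep)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  list(X = X, terms = colnames(X)[-1L], model = model)
}

#' Multinomial logistic regression of trajectory membership
#'
#' Fits trajectory group on patient factors by maximum-likelihood multinomial
#' logit, against a reference group (by default the group labelled
#' \code{"high persistent"}; the largest group when labels are not supplied).
#' Coefficients are reported as odds ratios with Wald 95% confidence
#' intervals (exp(coefficient +/- z SE)) and two-tailed p-values.
#'
#' @param patients Patient table (see [build_design()]).
#' @param assignment Trajectory group per patient, in patient-table order.
#' @param model 1 (age, sex, services, 21 diseases) or 2 (age, sex, services,
#'   disease count).
#' @param labels Optional character labels per group (e.g. from
#'   [label_trajectories()]); used to name the outcomes and pick the
#'   reference.
#' @param reference Reference outcome level; default the group labelled
#'   "high persistent", else the largest group.
#' @return Object of class \code{"trajectory_assoc"} with coefficient, SE,
#'   odds-ratio, CI and p-value matrices ((G-1) outcomes x covariates),
#'   fitted class probabilities, and fit metadata.
#' @export
fit_trajectory_multinom <- function(patients, assignment, model = 1,
                                    labels = NULL, reference = NULL) {
  if (length(assignment) != nrow(patients))
    stop("'assignment' must have one entry per patient", call. = FALSE)
  des <- build_design(patients, model)
  grp <- if (!is.null(labels)) {
    lv <- make.unique(labels)
    factor(lv[assignment], levels = lv)
  } else factor(assignment)
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L)
    stop("need at least two outcome groups", call. = FALSE)
  if (is.null(reference)) {
    hp <- grep("^high persistent", levels(grp), value = TRUE)
    reference <- if (length(hp)) hp[1L] else names(which.max(table(grp)))
  }
  if (!reference %in% levels(grp))
    stop("reference group '", reference, "' not present in outcomes", call. = FALSE)
  grp <- stats::relevel(grp, ref = reference)

  dat <- data.frame(.group = grp, des$X[, -1L, drop = FALSE],
                    check.names = FALSE)
  fml <- stats::as.formula(paste(".group ~",
                                 paste(sprintf("`%s`", des$terms), collapse = " + ")))
  fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 1000L,
                        Hess = TRUE, MaxNWts = 5000L)
  if (fit$convergence != 0)
    stop("multinomial logistic regression did not converge", call. = FALSE)

  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L,
                                     dimnames = list(levels(grp)[2L], names(co)))
  V <- tryCatch(stats::vcov(fit), error = function(e)
    stop("Hessian not invertible (possible complete separation)", call. = FALSE))
  se <- matrix(sqrt(diag(V)), nrow = nrow(co), byrow = TRUE,
               dimnames = dimnames(co))
  if (any(abs(co[, colnames(co) != "(Intercept)", drop = FALSE]) > 15)) {
    bad <- colnames(co)[colSums(abs(co) > 15) > 0]
    bad <- setdiff(bad, "(Intercept)")
    if (length(bad))
      stop("apparent complete separation for covariate(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  structure(list(
    coef = co, se = se,
    or = exp(co), ci_lower = exp(co - z * se), ci_upper = exp(co + z * se),
    p = 2 * stats::pnorm(-abs(co / se)),
    reference = reference, model = des$model, terms = des$terms,
    loglik = -fit$value,  # nnet minimises the negative log-likelihood
    converged = TRUE,
    fitted_prob = stats::fitted(fit),
    n = nrow(patients)
  ), class = "trajectory_assoc")
}

#' Odds-ratio table
#'
#' One row per covariate and non-reference outcome group with the odds ratio
#' (2 decimals), Wald 95% CI and p-value, plus a formatted
#' \code{"OR (lower-upper)"} string.
#'
#' @param result A [fit_trajectory_multinom()] result.
#' @return Data frame with columns \code{outcome_group}, \code{term},
#'   \code{or}, \code{ci_lower}, \code{ci_upper}, \code{p},
#'   \code{formatted}.
#' @export
or_table <- function(result) {
  stopifnot(inherits(result, "trajectory_assoc"))
  terms <- setdiff(colnames(result$coef), "(Intercept)")
  out <- do.call(rbind, lapply(rownames(result$coef), function(gname) {
    data.frame(
      outcome_group = gname, term = terms,
      or = round(result$or[gname, terms], 2L),
      ci_lower = round(result$ci_lower[gname, terms], 2L),
      ci_upper = round(result$ci_upper[gname, terms], 2L),
      p = result$p[gname, terms],
      stringsAsFactors = FALSE
    )
  }))
  out$formatted <- sprintf("%.2f (%.2f-%.2f)", out$or, out$ci_lower, out$ci_upper)
  rownames(out) <- NULL
  attr(out, "reference") <- result$reference
  out
}

#' @export
print.trajectory_assoc <- function(x, ...) {
  cat("Multinomial logistic regression of trajectory membership (model ",
      x$model, ")\n", sep = "")
  cat("  reference group: ", x$reference, "   n = ", x$n,
      "   log-likelihood: ", format(x$loglik, digits = 8), "\n", sep = "")
  cat("  outcomes: ", paste(rownames(x$coef), collapse = ", "), "\n", sep = "")
  invisible(x)
}
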