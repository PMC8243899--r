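# Death-anchored expenditure panels.
#
# Claims are billed by calendar month, so the panel bins amounts by the
# number of calendar months between the billing month and the death month:
# month index 1 is the month of death, month index `window` the earliest.

.panel_categories <- function() {
  c(eol_categories(), "medical", "long_term_care", "total")
}

#' Build a death-anchored expenditure panel from long-format claims
#'
#' Aggregates claim amounts into a patients x months x categories array
#' anchored at each patient's death month: a claim billed in the death month
#' lands in month index 1, one billed m calendar months earlier in month
#' index m + 1. Claims billed after the death month or more than
#' \code{window_months} before it are dropped. Patients with no claims keep a
#' row of zeros (zero-cost decedents stay in the cohort), and the aggregate
#' categories \code{medical} (= inpatient + outpatient),
#' \code{long_term_care} (= institutional + home) and \code{total}
#' (= medical + long_term_care) are materialised so the additivity identities
#' hold exactly in every cell.
#'
#' @param claims Data frame with columns \code{patient_id},
#'   \code{billing_month} ("YYYY-MM"), \code{category} (one of
#'   [eol_categories()]) and \code{amount_yen} (or \code{amount}).
#' @param patients Data frame with \code{patient_id} and \code{death_date}
#'   (ISO date or "YYYY-MM"); every claim's patient must appear here.
#' @param window_months Panel length in months before death (default 60).
#' @return An object of class \code{"expenditure_panel"}: a list with
#'   \code{values} (n x window x 7 array), \code{patient_ids}, \code{unit}
#'   ("yen") and \code{window}.
#' @export
build_panel <- function(claims, patients, window_months = 60L) {
  Tm <- as.integer(window_months)
  amt_col <- if ("amount_yen" %in% names(claims)) "amount_yen" else "amount"
  if (!all(c("patient_id", "billing_month", "category", amt_col) %in% names(claims)))
    stop("claims must have columns patient_id, billing_month, category, amount_yen",
         call. = FALSE)
  ids <- as.character(patients$patient_id)
  if (anyDuplicated(ids))
    stop("duplicated patient ids in 'patients'", call. = FALSE)
  unknown <- setdiff(unique(as.character(claims$patient_id)), ids)
  if (length(unknown))
    stop("claims reference unknown patient id(s): ",
         paste(utils::head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) ", ..." else "", call. = FALSE)
  amt <- claims[[amt_col]]
  if (any(!is.finite(amt)) || any(amt < 0))
    stop("claim amounts must be finite and non-negative", call. = FALSE)
  bad_cat <- setdiff(unique(as.character(claims$category)), eol_categories())
  if (length(bad_cat))
    stop("unknown claim categor(ies): ", paste(bad_cat, collapse = ", "), call. = FALSE)

  death_ym <- .ym_to_int(substr(as.character(patients$death_date), 1L, 7L))
  names(death_ym) <- ids

  pidx <- match(as.character(claims$patient_id), ids)
  m <- death_ym[pidx] - .ym_to_int(as.character(claims$billing_month)) + 1L
  keep <- m >= 1L & m <= Tm
  cidx <- match(as.character(claims$category), eol_categories())

  n <- length(ids)
  vals <- array(0, dim = c(n, Tm, 7L),
                dimnames = list(ids, NULL, .panel_categories()))
  if (any(keep)) {
    # accumulate with a linear index into the n x Tm x 4 block
    lin <- pidx[keep] + (m[keep] - 1L) * n + (cidx[keep] - 1L) * (n * Tm)
    agg <- rowsum(amt[keep], lin)
    block <- array(0, dim = c(n, Tm, 4L))
    block[as.integer(rownames(agg))] <- agg[, 1L]
    vals[, , 1:4] <- block
  }
  vals[, , "medical"] <- vals[, , "inpatient"] + vals[, , "outpatient"]
  vals[, , "long_term_care"] <- vals[, , "ltc_institutional"] + vals[, , "ltc_home"]
  vals[, , "total"] <- vals[, , "medical"] + vals[, , "long_term_care"]

  structure(list(values = vals, patient_ids = ids, unit = "yen", window = Tm),
            class = "expenditure_panel")
}

#' @export
print.expenditure_panel <- function(x, ...) {
  cat("Death-anchored expenditure panel: ", length(x$patient_ids),
      " patients x ", x$window, " months (unit: ", x$unit, ")\n", sep = "")
  invisible(x)
}

#' Natural-log transform of an expenditure panel
#'
#' Applies the elementwise natural log used for trajectory modelling, coding
#' zero amounts as zero on the log scale (so a 1-unit amount, whose log is
#' also 0, collides with the zero code by construction). Aggregate-category
#' additivity does not survive this transform and is not asserted afterwards.
#'
#' @param panel An [build_panel()] object with non-negative amounts.
#' @return An object of class \code{"log_panel"} with the same shape.
#' @export
log_transform <- function(panel) {
  stopifnot(inherits(panel, "expenditure_panel"))
  v <- panel$values
  if (any(v < 0)) stop("negative amounts cannot be log-transformed", call. = FALSE)
  lv <- v
  pos <- v > 0
  lv[pos] <- log(v[pos])
  structure(list(values = lv, patient_ids = panel$patient_ids,
                 unit = paste0("log_", panel$unit), window = panel$window),
            class = "log_panel")
}

#' @export
print.log_panel <- function(x, ...) {
  cat("Log-scale expenditure panel: ", length(x$patient_ids),
      " patients x ", x$window, " months (unit: ", x$unit, ")\n", sep = "")
  invisible(x)
}

#' Extract one category of a log panel as a fitting matrix
#'
#' @param panel A \code{log_panel} (or \code{expenditure_panel}).
#' @param category One of the seven panel categories, e.g. \code{"total"}.
#' @return An n x window numeric matrix (rows named by patient id); column
#'   t holds month index t, i.e. column 1 is the death month.
#' @export
panel_matrix <- function(panel, category = "total") {
  stopifnot(inherits(panel, c("expenditure_panel", "log_panel")))
  category <- match.arg(category, .panel_categories())
  panel$values[, , category]
}

#' Convert yen amounts to US dollars
#'
#' Fixed-rate conversion used for reporting (purchasing-power-parity rate,
#' default 92 yen per dollar). Accepts a numeric vector/array or a panel.
#'
#' @param x Numeric amounts in yen, or an \code{expenditure_panel}.
#' @param rate_yen_per_usd Positive exchange rate (yen per dollar).
#' @return Same shape as the input, in dollars; for a panel, the unit tag
#'   becomes \code{"usd"}.
#' @export
to_usd <- function(x, rate_yen_per_usd = 92) {
  if (!is.numeric(rate_yen_per_usd) || length(rate_yen_per_usd) != 1L ||
      rate_yen_per_usd <= 0)
    stop("'rate_yen_per_usd' must be a single positive number", call. = FALSE)
  if (inherits(x, "expenditure_panel")) {
    if (x$unit != "yen") stop("panel is not in yen", call. = FALSE)
    x$values <- x$values / rate_yen_per_usd
    x$unit <- "usd"
    return(x)
  }
  x / rate_yen_per_usd
}

#' Descriptive summary of per-patient expenditures
#'
#' Per-patient totals over trailing windows (by default the last 60 and last
#' 12 months before death) summarised per category with the sample (n-1)
#' standard deviation, plus the count of patients whose window total is zero.
#'
#' @param object An \code{expenditure_panel}.
#' @param windows Integer vector of trailing window lengths in months.
#' @param ... Unused.
#' @return Data frame with columns \code{category}, \code{window_months},
#'   \code{mean}, \code{sd}, \code{min}, \code{max}, \code{n_zero}.
#' @export
summary.expenditure_panel <- function(object, windows = c(60L, 12L), ...) {
  panel_summary(object, windows)
}

#' @rdname summary.expenditure_panel
#' @param panel An \code{expenditure_panel}.
#' @export
panel_summary <- function(panel, windows = c(60L, 12L)) {
  stopifnot(inherits(panel, "expenditure_panel"))
  if (length(panel$patient_ids) == 0L)
    stop("empty panel: no patients to summarise", call. = FALSE)
  if (any(windows < 1L | windows > panel$window))
    stop("windows must lie in 1..", panel$window, call. = FALSE)
  cats <- .panel_categories()
  out <- do.call(rbind, lapply(windows, function(w) {
    do.call(rbind, lapply(cats, function(cc) {
      tot <- rowSums(panel$values[, seq_len(w), cc, drop = FALSE])
      data.frame(category = cc, window_months = as.integer(w),
                 mean = mean(tot), sd = stats::sd(tot),
                 min = min(tot), max = max(tot),
                 n_zero = sum(tot == 0), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Expenditure concentration (Pareto) curve
#'
#' Sorts per-patient window totals in descending order and returns the
#' cumulative share of the grand total held by the top k patients, together
#' with, for each query share q, the smallest rank whose cumulative share
#' reaches q and its percentile rank 100 k / n.
#'
#' @param totals Non-negative per-patient totals (not all zero).
#' @param query_shares Cumulative shares to locate (default 10% and 50%).
#' @return List of class \code{"pareto_curve"} with \code{curve} (data frame
#'   \code{rank}, \code{cumulative_share}) and \code{queries} (data frame
#'   \code{share}, \code{rank}, \code{percentile}).
#' @export
pareto_curve <- function(totals, query_shares = c(0.10, 0.50)) {
  totals <- as.numeric(totals)
  if (length(totals) < 1L || any(!is.finite(totals)) || any(totals < 0))
    stop("'totals' must be non-negative finite values", call. = FALSE)
  gs <- sum(totals)
  if (gs == 0) stop("all totals are zero; cumulative shares undefined", call. = FALSE)
  srt <- sort(totals, decreasing = TRUE)
  share <- cumsum(srt) / gs
  n <- length(totals)
  q <- vapply(query_shares, function(qq) {
    k <- which(share >= qq - 1e-12)[1L]
    c(rank = k, percentile = round(100 * k / n, 1L))
  }, numeric(2L))
  structure(list(
    curve = data.frame(rank = seq_len(n), cumulative_share = share),
    queries = data.frame(share = query_shares, rank = q["rank", ],
                         percentile = q["percentile", ])
  ), class = "pareto_curve")
}

#' @export
print.pareto_curve <- function(x, ...) {
  n <- nrow(x$curve)
  cat("Expenditure concentration over", n, "patients\n")
  print(x$queries, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pareto_curve <- function(x, ...) {
  graphics::plot(x$curve$rank, 100 * x$curve$cumulative_share, type = "l",
                 xlab = "patient rank (most expensive first)",
                 ylab = "cumulative share of spending (%)", ...)
  invisible(x)
}

#' Per-group monthly mean expenditure curves
#'
#' Arithmetic mean expenditure per month within each assignment group, for
#' every panel category; the observed counterpart of the fitted trajectory
#' curves. Groups with zero members are flagged in the
#' \code{"empty_groups"} attribute and omitted from the result.
#'
#' @param panel An \code{expenditure_panel} or \code{log_panel}.
#' @param assignments Group label per patient, in panel patient order (or
#'   named by patient id).
#' @return Long data frame: \code{category}, \code{group},
#'   \code{month_index} (1 = death month), \code{mean}, \code{n}.
#' @export
monthly_trend <- function(panel, assignments) {
  stopifnot(inherits(panel, c("expenditure_panel", "log_panel")))
  ids <- panel$patient_ids
  if (!is.null(names(assignments))) {
    miss <- setdiff(ids, names(assignments))
    if (length(miss)) stop("assignments missing for patient(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    assignments <- assignments[ids]
  } else if (length(assignments) != length(ids)) {
    stop("assignments must cover all ", length(ids), " panel patients", call. = FALSE)
  }
  grp <- if (is.factor(assignments)) assignments else factor(assignments)
  counts <- table(grp)
  empty <- names(counts)[counts == 0L]
  cats <- .panel_categories()
  out <- do.call(rbind, lapply(cats, function(cc) {
    mat <- panel$values[, , cc, drop = FALSE][, , 1L]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(ids))
    do.call(rbind, lapply(levels(grp)[counts > 0L], function(g) {
      rows <- grp == g
      data.frame(category = cc, group = g,
                 month_index = seq_len(panel$window),
                 mean = colMeans(mat[rows, , drop = FALSE]),
                 n = sum(rows), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "empty_groups") <- empty
  out
}
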