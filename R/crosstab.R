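# Cross-tabulation of trajectory assignments across expenditure categories.

#' Cross-tabulate two trajectory assignments
#'
#' Counts patients by their combination of trajectory group in two
#' expenditure categories (e.g. total vs long-term care), with row, column
#' and grand totals. Both assignment vectors must cover the same patients:
#' when named, they are aligned by name; otherwise they must have equal
#' length and order.
#'
#' @param assign_a,assign_b Group assignments (vectors or factors, optionally
#'   named by patient id).
#' @param a_name,b_name Dimension labels for printing.
#' @return Object of class \code{"trajectory_crosstab"}: \code{counts}
#'   matrix, \code{row_totals}, \code{col_totals}, \code{grand}.
#' @export
cross_tabulate <- function(assign_a, assign_b, a_name = "category A",
                           b_name = "category B") {
  if (!is.null(names(assign_a)) && !is.null(names(assign_b))) {
    if (!setequal(names(assign_a), names(assign_b)))
      stop("the two assignments cover different patient sets", call. = FALSE)
    assign_b <- assign_b[names(assign_a)]
  } else if (length(assign_a) != length(assign_b)) {
    stop("assignments differ in length and carry no patient names to align by",
         call. = FALSE)
  }
  counts <- table(A = factor(assign_a), B = factor(assign_b))
  counts <- unclass(counts)
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand = sum(counts),
                 a_name = a_name, b_name = b_name),
            class = "trajectory_crosstab")
}

#' @export
print.trajectory_crosstab <- function(x, ...) {
  cat("Trajectory cross-tabulation: ", x$a_name, " (rows) x ", x$b_name,
      " (columns), n = ", x$grand, "\n", sep = "")
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.trajectory_crosstab <- function(x, ...) {
  df <- as.data.frame.table(as.table(x$counts), stringsAsFactors = FALSE)
  names(df) <- c("group_a", "group_b", "count")
  df
}
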