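#' Fold-enhancement of trafficking
#'
#' Ratio of treated to untreated cell-surface expression (both as % of the
#' same control). Scale-invariant; the input to the folding-equilibrium
#' energy model ([dg_from_fold()]).
#'
#' @param treated CSE with treatment (e.g. + E-4031), % of control.
#' @param untreated CSE without treatment, % of control; must be > 0.
#' @return Dimensionless fold.
#' @export
#' @examples
#' fold_enhancement(38.2, 2.2)  # ~17.4-fold rescue
fold_enhancement <- function(treated, untreated) {
  if (any(!is.finite(untreated)) || any(untreated <= 0)) {
    stop("untreated CSE must be > 0 to form a fold-enhancement")
  }
  treated / untreated
}

#' Ordinary least-squares regression of drug rescue on WT rescue
#'
#' Fits `homo_e4031_cse ~ wt_rescue_cse` (rescue by the pharmacological
#' chaperone against rescue by co-expression with WT subunits, both as % of
#' WT CSE) over the variants not excluded. Used to ask whether inherent
#' "rescuability" of a variant measured by WT co-assembly predicts
#' pharmacological rescue.
#'
#' @param records Wide rescue table (e.g. [herg_table1()] or
#'   [build_rescue_table()] output).
#' @param exclude Variant labels left out of the fit. The study design
#'   excludes the pore variant L615F (an outlier with impaired drug binding)
#'   and the WT reference row.
#' @param x_col,y_col Column names for the x and y variables.
#' @return An object of class `rescue_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n_points`, `included_variants`, `excluded_variants`.
#' @export
fit_rescue_regression <- function(records, exclude = c("WT", "L615F"),
                                  x_col = "wt_rescue_cse",
                                  y_col = "homo_e4031_cse") {
  if (!all(c("variant", x_col, y_col) %in% names(records))) {
    stop("records must have columns variant, ", x_col, ", ", y_col)
  }
  keep <- !(records$variant %in% exclude) &
    is.finite(records[[x_col]]) & is.finite(records[[y_col]])
  x <- records[[x_col]][keep]
  y <- records[[y_col]][keep]
  if (length(x) < 3L) stop("need >= 3 points for the regression")
  if (stats::var(x) == 0) stop("zero variance in x; cannot fit")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = length(x),
         included_variants = records$variant[keep],
         excluded_variants = intersect(exclude, records$variant)),
    class = "rescue_fit"
  )
}

#' @export
print.rescue_fit <- function(x, ...) {
  cat(sprintf("<rescue_fit> y = %.3fx %+.3f, R^2 = %.3f (n = %d; excluded: %s)\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              paste(x$excluded_variants, collapse = ", ")))
  invisible(x)
}

#' Extremes of a rescue-table column
#'
#' @param records Wide rescue table.
#' @param column Column name (e.g. `"total_coexpr_cse"`).
#' @return List with `min` and `max`, each `(variant, value)`; ties are
#'   reported in label order (first label wins).
#' @export
table_extremes <- function(records, column) {
  if (!column %in% names(records)) stop("no column '", column, "' in records")
  v <- records[[column]]
  keep <- is.finite(v)
  if (!any(keep)) stop("no finite values in column '", column, "'")
  lab <- records$variant[keep]
  v <- v[keep]
  list(min = list(variant = lab[which.min(v)], value = min(v)),
       max = list(variant = lab[which.max(v)], value = max(v)))
}

# Background-subtract an On-Cell summary and return means/sems keyed by id.
.adjusted_lookup <- function(summary, background_id) {
  adj <- background_subtract(summary, background_id)
  list(mean = stats::setNames(adj$mean, adj$condition_id),
       sem = stats::setNames(adj$sem, adj$condition_id))
}

# One control-scaled percentage column with first-order SEM propagation.
.pct_col <- function(adj, cond_ids, control_id, column_label) {
  if (!control_id %in% names(adj$mean)) {
    stop("missing control '", control_id, "' for column ", column_label)
  }
  ctrl <- adj$mean[[control_id]]
  ctrl_sem <- adj$sem[[control_id]]
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control '", control_id, "' is not positive for column ",
         column_label)
  }
  res <- lapply(cond_ids, function(id) {
    if (!id %in% names(adj$mean)) return(list(percent = NA_real_,
                                              sem = NA_real_))
    percent_of_control(adj$mean[[id]], ctrl, adj$sem[[id]], ctrl_sem)
  })
  list(value = vapply(res, `[[`, numeric(1), "percent"),
       sem = vapply(res, `[[`, numeric(1), "sem"))
}

#' Assemble the per-variant rescue table from experiment summaries
#'
#' Combines On-Cell condition summaries from the four experiment designs
#' into the per-variant table of background-subtracted, control-scaled
#' cell-surface expression percentages:
#' homozygous CSE and CSE + E-4031 (fig5 design; HA-WT alone = 100), total
#' co-expression CSE (fig2; HA-WT alone = 100), residual HA-WT CSE under
#' untagged-variant co-expression and variant rescue by untagged WT (fig3 /
#' fig4; HA-WT + un-WT = 100). Condition ids must follow the
#' [builtin_designs()] naming convention.
#'
#' @param summaries Named list of On-Cell condition summaries
#'   ([summarize_conditions()]) with entries `fig2`, `fig3`, `fig4`, `fig5`.
#'   Any subset may be supplied; absent designs yield `NA` columns.
#' @param variants Variant labels (default the ten study variants).
#' @param background_id Background condition id present in every summary
#'   (default `"empty"`).
#' @return Wide rescue table: one row per variant plus a `WT` reference row,
#'   columns as in [herg_table1()] (without `mave_cse`), with `_sem`
#'   companions propagated to first order.
#' @export
build_rescue_table <- function(summaries, variants = herg_study_variants(),
                               background_id = "empty") {
  out <- data.frame(variant = c("WT", variants), stringsAsFactors = FALSE)
  blank <- rep(NA_real_, nrow(out))
  cols <- c("homo_cse", "homo_e4031_cse", "total_coexpr_cse",
            "wt_residual_cse", "wt_rescue_cse")
  for (cl in cols) {
    out[[cl]] <- blank
    out[[paste0(cl, "_sem")]] <- blank
  }

  if (!is.null(summaries$fig5)) {
    adj <- .adjusted_lookup(summaries$fig5, background_id)
    homo <- .pct_col(adj, c("HA-WT", paste0("HA-", variants)), "HA-WT",
                     "homo_cse")
    out$homo_cse <- homo$value
    out$homo_cse_sem <- homo$sem
    drug <- .pct_col(adj, c("HA-WT+E4031", paste0("HA-", variants, "+E4031")),
                     "HA-WT", "homo_e4031_cse")
    out$homo_e4031_cse <- drug$value
    out$homo_e4031_cse_sem <- drug$sem
  }
  if (!is.null(summaries$fig2)) {
    adj <- .adjusted_lookup(summaries$fig2, background_id)
    co <- .pct_col(adj, c("HA-WT", paste0("HA-WT+HA-", variants)), "HA-WT",
                   "total_coexpr_cse")
    out$total_coexpr_cse <- co$value
    out$total_coexpr_cse_sem <- co$sem
  }
  if (!is.null(summaries$fig3)) {
    adj <- .adjusted_lookup(summaries$fig3, background_id)
    dn <- .pct_col(adj, c("HA-WT+un-WT", paste0("HA-WT+un-", variants)),
                   "HA-WT+un-WT", "wt_residual_cse")
    out$wt_residual_cse <- dn$value
    out$wt_residual_cse_sem <- dn$sem
  }
  if (!is.null(summaries$fig4)) {
    adj <- .adjusted_lookup(summaries$fig4, background_id)
    rs <- .pct_col(adj, c("HA-WT+un-WT", paste0("HA-", variants, "+un-WT")),
                   "HA-WT+un-WT", "wt_rescue_cse")
    out$wt_rescue_cse <- rs$value
    out$wt_rescue_cse_sem <- rs$sem
  }
  out
}
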