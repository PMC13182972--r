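#' Normalize a plate by the sum of its 800-channel signal
#'
#' Implements the normalization-by-sum quantification used for On-Cell /
#' In-Cell western plates. Per well, the 800-channel (antibody) intensity is
#' divided by the 700-channel (cell stain) intensity to correct for cell
#' number; duplicate technical-replicate wells of each condition are
#' averaged; each condition mean is then divided by the total summed raw
#' 800-channel signal of the plate. The last step makes the values
#' dimensionless, invariant to the 800-channel gain, and of the order 1e-8
#' seen on the figure axes of plate-assay studies.
#'
#' @param plate An [assay_plate()].
#' @param denominator `"raw_ch800"` (default; sum of raw 800-channel
#'   intensities over all wells of the plate, empty-vector wells included) or
#'   `"mean_ratio"` (sum of the per-condition duplicate-averaged ratios; an
#'   alternative reading of "total summed signal", provided for comparison).
#' @param include_empty Should background (empty-vector) wells enter the
#'   denominator sum? Default `TRUE`.
#' @return data.frame with columns `condition_id`, `repeat_index`, `value`
#'   (normalized arbitrary fluorescence), one row per condition.
#' @export
normalize_plate <- function(plate,
                            denominator = c("raw_ch800", "mean_ratio"),
                            include_empty = TRUE) {
  stopifnot(inherits(plate, "assay_plate"))
  denominator <- match.arg(denominator)
  w <- plate$wells
  if (any(w$ch700 <= 0)) {
    stop("ch700 must be > 0 in every well; offending well(s): ",
         paste(w$well[w$ch700 <= 0], collapse = ", "))
  }
  conds <- unique(w$condition_id)
  if (length(conds) == 0L) stop("plate has no wells")
  ratio <- w$ch800 / w$ch700
  mean_ratio <- vapply(conds, function(id) {
    mean(ratio[w$condition_id == id])
  }, numeric(1))

  in_sum <- rep(TRUE, nrow(w))
  if (!include_empty && !is.null(plate$design)) {
    herg <- vapply(conds, function(id) {
      condition_composition(plate$design, id)$herg_mass > 0
    }, logical(1))
    in_sum <- w$condition_id %in% conds[herg]
  }
  s <- if (denominator == "raw_ch800") {
    sum(w$ch800[in_sum])
  } else {
    sum(mean_ratio[if (!include_empty && !is.null(plate$design)) {
      vapply(conds, function(id) {
        condition_composition(plate$design, id)$herg_mass > 0
      }, logical(1))
    } else rep(TRUE, length(conds))])
  }
  if (!is.finite(s) || s <= 0) stop("plate 800-channel sum is not positive")
  data.frame(condition_id = conds,
             repeat_index = plate$repeat_index,
             value = unname(mean_ratio) / s,
             stringsAsFactors = FALSE)
}

#' Aggregate normalized values over independent repeats
#'
#' @param values data.frame of normalized values (`condition_id`,
#'   `repeat_index`, `value`), typically several [normalize_plate()] outputs
#'   row-bound together.
#' @return data.frame with one row per condition: `condition_id`, `mean`,
#'   `sem` (sample SD over repeats divided by sqrt(n); `NA` with a warning
#'   when only one repeat is available), `n`.
#' @export
summarize_conditions <- function(values) {
  req <- c("condition_id", "repeat_index", "value")
  if (!all(req %in% names(values))) {
    stop("`values` must have columns ", paste(req, collapse = ", "))
  }
  conds <- unique(values$condition_id)
  out <- do.call(rbind, lapply(conds, function(id) {
    v <- values$value[values$condition_id == id]
    n <- length(v)
    sem <- if (n >= 2L) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(condition_id = id, mean = mean(v), sem = sem, n = n,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n < 2L)) {
    warning("SEM undefined for condition(s) with a single repeat: ",
            paste(out$condition_id[out$n < 2L], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Subtract the background (empty-vector) level from condition summaries
#'
#' Operates on repeat-aggregated means; SEMs are combined in quadrature.
#' Negative adjusted means are reported as-is with a warning (they occur when
#' a condition's signal is indistinguishable from background).
#'
#' @param summary Condition summary data.frame ([summarize_conditions()]).
#' @param background Either the `condition_id` of the background condition
#'   within `summary` (default `"empty"`) or a one-row summary data.frame.
#' @return `summary` with `mean` background-subtracted, a `sem` combining
#'   both uncertainties, and the background row removed when it came from
#'   within `summary`.
#' @export
background_subtract <- function(summary, background = "empty") {
  if (is.character(background)) {
    row <- summary[summary$condition_id == background, ]
    if (nrow(row) != 1L) {
      stop("background condition '", background, "' not found in summary")
    }
    bg_mean <- row$mean
    bg_sem <- row$sem
    summary <- summary[summary$condition_id != background, , drop = FALSE]
  } else {
    if (!is.data.frame(background) || nrow(background) != 1L) {
      stop("`background` must be a condition id or a one-row summary")
    }
    bg_mean <- background$mean
    bg_sem <- background$sem
  }
  summary$mean <- summary$mean - bg_mean
  summary$sem <- sqrt(summary$sem^2 + bg_sem^2)
  if (any(summary$mean < 0)) {
    warning("background-subtracted mean negative for condition(s): ",
            paste(summary$condition_id[summary$mean < 0], collapse = ", "))
  }
  summary
}

#' Express an adjusted mean as a percentage of a control
#'
#' @param adjusted Background-subtracted mean (scalar or vector).
#' @param control_adjusted Background-subtracted control mean; must be > 0.
#' @param sem,control_sem Optional SEMs; when both given, the SEM of the
#'   percentage is propagated to first order:
#'   `p * sqrt((sem/adjusted)^2 + (control_sem/control)^2)`.
#' @return Percentage (100 = control), or a list `(percent, sem)` when SEMs
#'   are supplied.
#' @export
percent_of_control <- function(adjusted, control_adjusted,
                               sem = NULL, control_sem = NULL) {
  if (!is.finite(control_adjusted) || control_adjusted <= 0) {
    stop("control mean must be > 0 to form a percentage")
  }
  p <- 100 * adjusted / control_adjusted
  if (is.null(sem) || is.null(control_sem)) return(p)
  rel <- sqrt(ifelse(adjusted != 0, (sem / adjusted)^2, 0) +
                (control_sem / control_adjusted)^2)
  list(percent = p, sem = abs(p) * rel)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Ordinary one-way ANOVA across all groups followed by unconditional
#' pairwise two-sided t comparisons on the pooled within-group variance
#' (residual df = N - k), for an explicitly declared comparison family.
#' Raw p values are Bonferroni-adjusted by the family size and capped at 1.
#' The family is explicit — typically each condition against its design's
#' control — never all pairs by default. Zero-variance degenerate data give
#' p = 1 with a warning rather than an error.
#'
#' @param groups Named list of numeric vectors (per-condition repeat
#'   values), each of length >= 2.
#' @param family data.frame with columns `condition`, `reference` declaring
#'   the comparisons.
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame with one row per comparison: `condition`, `reference`,
#'   `estimate` (difference of means), `raw_p`, `adjusted_p`, `significant`.
#'   The omnibus ANOVA statistics are attached as attributes `anova_f` and
#'   `anova_p`.
#' @export
anova_bonferroni <- function(groups, family, alpha = 0.05) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2L) {
    stop("`groups` must be a named list of >= 2 numeric vectors")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs >= 2 values")
  }
  if (!all(c("condition", "reference") %in% names(family))) {
    stop("`family` must have columns condition, reference")
  }
  unknown <- setdiff(c(family$condition, family$reference), names(groups))
  if (length(unknown)) {
    stop("family references unknown condition(s): ",
         paste(unique(unknown), collapse = ", "))
  }

  n_i <- vapply(groups, length, integer(1))
  m_i <- vapply(groups, mean, numeric(1))
  n_tot <- sum(n_i)
  k <- length(groups)
  grand <- sum(n_i * m_i) / n_tot
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- k - 1L
  df_w <- n_tot - k
  if (ss_within <= 0) {
    warning("zero within-group variance; ANOVA degenerate, p set to 1")
    f_stat <- if (ss_between > 0) Inf else 0
    p_anova <- 1
    mse <- 0
  } else {
    mse <- ss_within / df_w
    f_stat <- (ss_between / df_b) / mse
    p_anova <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  }

  m <- nrow(family)
  out <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- family$condition[i]
    b <- family$reference[i]
    est <- m_i[[a]] - m_i[[b]]
    if (mse <= 0) {
      raw <- 1
    } else {
      t_stat <- est / sqrt(mse * (1 / n_i[[a]] + 1 / n_i[[b]]))
      raw <- 2 * stats::pt(abs(t_stat), df_w, lower.tail = FALSE)
    }
    data.frame(condition = a, reference = b, estimate = est, raw_p = raw,
               adjusted_p = min(1, raw * m), stringsAsFactors = FALSE)
  }))
  out$significant <- out$adjusted_p < alpha
  attr(out, "anova_f") <- f_stat
  attr(out, "anova_p") <- p_anova
  out
}
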