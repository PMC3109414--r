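## Per-biomarker orchestration: combine level and slope change-points,
## side-specific validation statistics, nested model comparison, and the
## demographics summary.

#' Combine level and slope change-points
#'
#' The working change-point is the arithmetic mean of the level and slope
#' change-points. If one component is missing (a no-change-point flag
#' upstream) the combination falls back to the available one and is flagged.
#'
#' @param level_cp,slope_cp change-points on the CAMCOG scale (either may be
#'   `NA`).
#' @return list of class `changepoint_estimate`: `level`, `slope`,
#'   `combined`, `fallback` flag.
#' @export
combine_changepoints <- function(level_cp, slope_cp) {
  if (is.na(level_cp) && is.na(slope_cp))
    stop("both change-point components are missing", call. = FALSE)
  fallback <- is.na(level_cp) || is.na(slope_cp)
  combined <- if (fallback) {
    if (is.na(level_cp)) slope_cp else level_cp
  } else {
    (level_cp + slope_cp) / 2
  }
  structure(list(level = level_cp, slope = slope_cp, combined = combined,
                 fallback = fallback),
            class = "changepoint_estimate")
}

.stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Side-specific statistics around a change-point
#'
#' Splits a biomarker at the change-point score (above means strictly
#' greater, the boundary joins "below") and computes, per side, the number
#' of observations, the median and variance of the biomarker, Spearman's rho
#' with CAMCOG and the MM-regression slope with its t statistic; and,
#' between sides, the Wilcoxon-Mann-Whitney p for a median difference and
#' the variance-ratio F test. A side with fewer than `min_n` complete
#' observations is flagged and the between-side tests are suppressed.
#'
#' @param table cohort table.
#' @param biomarker biomarker column name.
#' @param cp change-point score, or a `changepoint_estimate` (its `combined`
#'   value is used).
#' @param min_n minimum complete observations per side.
#' @return list of class `side_stats`: `sides` (data.frame with one row per
#'   side), `wmw_p`, `variance_f`, `variance_df`, `variance_p`,
#'   `suppressed` flag.
#' @export
side_statistics <- function(table, biomarker, cp, min_n = 3) {
  if (inherits(cp, "changepoint_estimate")) cp <- cp$combined
  ok <- is.finite(table$camcog) & is.finite(table[[biomarker]])
  camcog <- table$camcog[ok]; y <- table[[biomarker]][ok]
  above <- camcog > cp

  one_side <- function(sel, label) {
    xs <- camcog[sel]; ys <- y[sel]
    if (length(ys) < min_n || length(unique(xs)) < 2)
      return(data.frame(side = label, n = length(ys), median = NA_real_,
                        variance = NA_real_, rho = NA_real_,
                        slope = NA_real_, t = NA_real_, df = NA_integer_,
                        rho_p = NA_real_, slope_p = NA_real_,
                        flagged = TRUE))
    fit <- mm_regression(xs, ys)
    rho <- spearman_rho(xs, ys)
    nn <- length(ys)
    # large-sample t approximation for Spearman's rho
    rho_t <- rho * sqrt((nn - 2) / (1 - rho^2))
    data.frame(side = label, n = nn, median = stats::median(ys),
               variance = stats::var(ys), rho = rho,
               slope = unname(fit$coefficients["slope"]),
               t = unname(fit$t["slope"]), df = fit$df,
               rho_p = 2 * stats::pt(abs(rho_t), nn - 2, lower.tail = FALSE),
               slope_p = 2 * stats::pt(abs(fit$t["slope"]), fit$df,
                                       lower.tail = FALSE),
               flagged = FALSE)
  }
  sides <- rbind(one_side(above, "above"), one_side(!above, "below"))
  suppressed <- any(sides$flagged)
  wmw_p <- variance_f <- variance_p <- NA_real_
  variance_df <- c(NA_integer_, NA_integer_)
  if (!suppressed) {
    wmw <- mann_whitney(y[above], y[!above])
    vr <- variance_ratio_test(y[above], y[!above])
    wmw_p <- wmw$p_value
    variance_f <- vr$statistic; variance_df <- vr$df
    variance_p <- vr$p_value
  }
  structure(list(biomarker = biomarker, changepoint = cp, sides = sides,
                 wmw_p = wmw_p, variance_f = variance_f,
                 variance_df = variance_df, variance_p = variance_p,
                 suppressed = suppressed),
            class = "side_stats")
}

#' Segmented versus single-line model comparison
#'
#' Nested least-squares F test of a two-regime linear fit (independent lines
#' above and below the change-point, 4 parameters) against a single global
#' line (2 parameters): `F = ((RSS0 - RSS1)/2) / (RSS1/(n - 4))` on
#' (2, n - 4) df. Least squares (not MM) is used so the nested-F
#' distribution theory applies.
#'
#' @param table cohort table.
#' @param biomarker biomarker column.
#' @param cp change-point score.
#' @return list of class `model_comparison`: `rss_linear`, `rss_segmented`,
#'   `f`, `df`, `p_value`, `infinite` flag (exact two-regime fit).
#' @export
segmented_vs_linear <- function(table, biomarker, cp) {
  if (inherits(cp, "changepoint_estimate")) cp <- cp$combined
  ok <- is.finite(table$camcog) & is.finite(table[[biomarker]])
  x <- table$camcog[ok]; y <- table[[biomarker]][ok]
  above <- x > cp
  if (sum(above) < 3 || sum(!above) < 3)
    stop("need at least 3 observations on each side", call. = FALSE)
  n <- length(y)
  rss_of <- function(xx, yy) {
    if (length(unique(xx)) < 2) return(sum((yy - mean(yy))^2))
    b <- .wls(xx, yy, rep(1, length(xx)))
    sum((yy - b[1] - b[2] * xx)^2)
  }
  rss0 <- rss_of(x, y)
  rss1 <- rss_of(x[above], y[above]) + rss_of(x[!above], y[!above])
  if (rss1 <= .Machine$double.eps * max(rss0, 1))
    return(structure(list(rss_linear = rss0, rss_segmented = rss1,
                          f = Inf, df = c(2L, n - 4L), p_value = 0,
                          infinite = TRUE),
                     class = "model_comparison"))
  f <- ((rss0 - rss1) / 2) / (rss1 / (n - 4))
  structure(list(rss_linear = rss0, rss_segmented = rss1, f = f,
                 df = c(2L, n - 4L),
                 p_value = stats::pf(f, 2, n - 4, lower.tail = FALSE),
                 infinite = FALSE),
            class = "model_comparison")
}

#' Full change-point analysis of one biomarker
#'
#' Runs the whole per-biomarker workflow: structural-change F scan and
#' RSS breakpoint (level change-point), tie-splitting segmentation resampler
#' (slope change-point), their combination, side statistics, the
#' segmented-versus-linear comparison and a robust lowess reference curve;
#' optionally builds the four-model overlay figure.
#'
#' @param table cohort table.
#' @param biomarker biomarker column name.
#' @param trim trimming fraction for the F scan.
#' @param n_perm permutations for the scan p-value.
#' @param repetitions tie-splitting repetitions for the slope change-point.
#' @param seed master seed driving all resampling.
#' @param schedule escalation schedule.
#' @param span lowess span.
#' @param make_figure build the ggplot overlay (set `FALSE` in bulk runs).
#' @return list of class `biomarker_result` with elements `biomarker`,
#'   `scan`, `level_cp`, `slope_cp`, `changepoint`
#'   (`changepoint_estimate`), `side_stats`, `model_comparison`, `lowess`
#'   (data.frame of `camcog`, `fit`), `figure` (a ggplot or `NULL`),
#'   `flags` (character vector of everything flagged along the way).
#' @export
run_biomarker <- function(table, biomarker, trim = 0.15, n_perm = 200,
                          repetitions = 1000, seed = 1,
                          schedule = NULL, span = 2/3,
                          make_figure = TRUE) {
  stopifnot(biomarker %in% names(table))
  ok <- is.finite(table$camcog) & is.finite(table[[biomarker]])
  camcog <- table$camcog[ok]; y <- table[[biomarker]][ok]
  flags <- character(0)

  scan <- fstat_scan(camcog, y, trim = trim, n_perm = n_perm, seed = seed)
  bp <- rss_breakpoint(camcog, y)
  slope <- slope_changepoint(camcog, y, repetitions = repetitions,
                             master_seed = seed, schedule = schedule)
  if (slope$failed) flags <- c(flags, "slope change-point analysis failed")
  cp <- combine_changepoints(bp$camcog, slope$median)
  if (cp$fallback) flags <- c(flags, "change-point fallback to one component")

  ss <- side_statistics(table, biomarker, cp)
  if (ss$suppressed) flags <- c(flags, "side below minimum n")
  mc <- segmented_vs_linear(table, biomarker, cp$combined)
  if (mc$infinite) flags <- c(flags, "exact segmented fit (infinite F)")
  lw <- data.frame(camcog = camcog, fit = lowess_fit(camcog, y, span = span))
  lw <- lw[order(lw$camcog), ]

  res <- structure(list(biomarker = biomarker, scan = scan,
                        level_cp = bp$camcog, slope_cp = slope$median,
                        changepoint = cp, slope_result = slope,
                        side_stats = ss, model_comparison = mc,
                        lowess = lw, figure = NULL, flags = flags,
                        n = length(y), seed = seed),
                   class = "biomarker_result")
  if (make_figure) res$figure <- plot_biomarker_fit(table, biomarker, res)
  res
}

#' Flat machine-readable record of a biomarker result
#'
#' @param result a `biomarker_result`.
#' @return named list of plain scalars/vectors, suitable for JSON export.
#' @export
biomarker_record <- function(result) {
  ss <- result$side_stats$sides
  list(biomarker = result$biomarker,
       n = result$n,
       level_changepoint = result$level_cp,
       slope_changepoint = result$slope_cp,
       combined_changepoint = result$changepoint$combined,
       sup_f = result$scan$sup_f,
       scan_p = result$scan$p_value,
       segmented_f = result$model_comparison$f,
       segmented_df = result$model_comparison$df,
       segmented_p = result$model_comparison$p_value,
       median_above = ss$median[ss$side == "above"],
       median_below = ss$median[ss$side == "below"],
       variance_above = ss$variance[ss$side == "above"],
       variance_below = ss$variance[ss$side == "below"],
       rho_above = ss$rho[ss$side == "above"],
       rho_below = ss$rho[ss$side == "below"],
       slope_above = ss$slope[ss$side == "above"],
       slope_below = ss$slope[ss$side == "below"],
       t_above = ss$t[ss$side == "above"],
       t_below = ss$t[ss$side == "below"],
       wmw_p = result$side_stats$wmw_p,
       variance_f = result$side_stats$variance_f,
       variance_p = result$side_stats$variance_p,
       flags = result$flags)
}

#' Side-statistics summary table across biomarkers
#'
#' Renders the side statistics of several biomarker results in the classic
#' wide layout: one column pair (Above, Below) per biomarker and rows for
#' Median, Variance, Spearman's rho and Robust slope, with two-level
#' significance stars (`*` p < 0.05, `**` p < 0.01) attached to the rendered
#' values; unrounded p-values remain available in each result.
#'
#' @param results list of `biomarker_result` objects.
#' @return data.frame with a `parameter` column and Above/Below columns per
#'   biomarker.
#' @export
summary_table <- function(results) {
  out <- data.frame(parameter = c("Change-point", "Median", "Variance",
                                  "Spearman's rho", "Robust slope"))
  for (res in results) {
    ss <- res$side_stats$sides
    ab <- ss[ss$side == "above", ]; be <- ss[ss$side == "below", ]
    wmw_star <- .stars(res$side_stats$wmw_p)
    var_star <- .stars(res$side_stats$variance_p)
    col_ab <- c(sprintf("%.1f", res$changepoint$combined),
                sprintf("%.0f", ab$median),
                sprintf("%.0f", ab$variance),
                paste0(sprintf("%.2f", ab$rho), .stars(ab$rho_p)),
                paste0(signif(ab$slope, 3), .stars(ab$slope_p)))
    col_be <- c("",
                paste0(sprintf("%.0f", be$median), wmw_star),
                paste0(sprintf("%.0f", be$variance), var_star),
                paste0(sprintf("%.2f", be$rho), .stars(be$rho_p)),
                paste0(signif(be$slope, 3), .stars(be$slope_p)))
    out[[paste0(res$biomarker, "_above")]] <- col_ab
    out[[paste0(res$biomarker, "_below")]] <- col_be
  }
  out
}

.fmt_med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%g (%g-%g)", q[2], q[1], q[3])
}

#' Demographic comparison of the diagnostic groups
#'
#' Per group: gender counts and median (IQR) summaries of age, MMSE and
#' CAMCOG; between groups: Wilcoxon-Mann-Whitney p-values for the continuous
#' contrasts and both the Fisher exact and Pearson chi-square p for gender.
#'
#' @param table cohort table with both groups present.
#' @return list of class `demographics`: `summary` (data.frame, one row per
#'   group), `p_values` (named: age, mmse, camcog, gender_fisher,
#'   gender_chisq), `flagged` (TRUE when a group is missing, in which case
#'   only the partial summary is returned).
#' @export
demographics_table <- function(table) {
  groups <- levels(table$group)
  present <- groups[groups %in% unique(as.character(table$group))]
  rows <- lapply(present, function(g) {
    sub <- table[table$group == g, ]
    data.frame(group = g,
               gender = sprintf("%dF: %dM", sum(sub$gender == "F"),
                                sum(sub$gender == "M")),
               age = .fmt_med_iqr(sub$age),
               mmse = .fmt_med_iqr(sub$mmse),
               camcog = .fmt_med_iqr(sub$camcog))
  })
  summary <- do.call(rbind, rows)
  if (length(present) < 2) {
    return(structure(list(summary = summary, p_values = NULL,
                          flagged = TRUE), class = "demographics"))
  }
  a <- table[table$group == groups[1], ]
  b <- table[table$group == groups[2], ]
  gender_tab <- rbind(c(sum(a$gender == "F"), sum(a$gender == "M")),
                      c(sum(b$gender == "F"), sum(b$gender == "M")))
  cat_res <- categorical_tests(gender_tab)
  p_values <- c(age = mann_whitney(a$age, b$age)$p_value,
                mmse = mann_whitney(a$mmse, b$mmse)$p_value,
                camcog = mann_whitney(a$camcog, b$camcog)$p_value,
                gender_fisher = cat_res$fisher_p,
                gender_chisq = cat_res$chisq_p)
  structure(list(summary = summary, p_values = p_values, flagged = FALSE),
            class = "demographics")
}
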