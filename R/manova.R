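## Omnibus multivariate inflection tests: the four biomarkers regressed
## jointly on covariates and CAMCOG, with a level-shift indicator and a
## hinge (slope-change) term at a configurable inflection score.

#' Design matrix with an inflection at a CAMCOG score
#'
#' Builds the multivariate regression design: intercept, age, gender
#' (indicator for male, reference female), storage time, assay-group
#' indicators (reference group 1), the CAMCOG score, a level-shift indicator
#' `1[camcog < inflect_at]`, and the hinge term
#' `(camcog - inflect_at) * 1[camcog < inflect_at]` encoding a slope change
#' below the inflection. The boundary score belongs to the upper regime.
#' Rows with any missing response or covariate are dropped listwise.
#'
#' @param table cohort table (see [generate_cohort()]).
#' @param inflect_at inflection on the CAMCOG total-score scale, default 89;
#'   must lie strictly inside the observed score range.
#' @param responses biomarker columns to model jointly; default all.
#' @return list of class `inflection_design`: `X` (design matrix), `Y`
#'   (response matrix), `inflect_at`, `rows` (row indices of `table` kept),
#'   `collinear` flag (indicator/hinge columns identically zero).
#' @export
design_with_inflection <- function(table, inflect_at = 89,
                                   responses = biomarker_names(table)) {
  if (inflect_at <= 0 || inflect_at >= 107)
    stop("inflect_at must lie inside (0, 107)", call. = FALSE)
  stopifnot(length(responses) >= 1, all(responses %in% names(table)))
  Y <- as.matrix(table[, responses, drop = FALSE])
  covars <- table[, c("age", "gender", "storage_time", "assay_group",
                      "camcog")]
  keep <- stats::complete.cases(Y) & stats::complete.cases(covars)
  Y <- Y[keep, , drop = FALSE]
  covars <- covars[keep, , drop = FALSE]
  rng <- range(covars$camcog)
  if (inflect_at < rng[1] || inflect_at > rng[2])
    stop(sprintf("inflection %g outside observed CAMCOG range [%g, %g]",
                 inflect_at, rng[1], rng[2]), call. = FALSE)
  below <- as.numeric(covars$camcog < inflect_at)
  hinge <- (covars$camcog - inflect_at) * below
  ag <- factor(covars$assay_group)
  X <- cbind(intercept = 1,
             age = covars$age,
             genderM = as.numeric(covars$gender == "M"),
             storage_time = covars$storage_time)
  if (nlevels(ag) > 1) {
    dummies <- stats::model.matrix(~ ag)[, -1, drop = FALSE]
    colnames(dummies) <- paste0("assay", levels(ag)[-1])
    X <- cbind(X, dummies)
  }
  X <- cbind(X, camcog = covars$camcog, below = below, hinge = hinge)
  structure(list(X = X, Y = Y, inflect_at = inflect_at,
                 rows = which(keep),
                 collinear = all(below == 0) || all(below == 1)),
            class = "inflection_design")
}

#' Multivariate test of a single design term (Wilks lambda)
#'
#' Fits the multivariate linear model of the responses on the design and
#' tests one single-df coefficient across all responses. With hypothesis and
#' error cross-product matrices H and E, Wilks \eqn{\Lambda = det(E) /
#' det(E + H)}; for a single-df hypothesis this converts exactly to
#' \eqn{F = (1 - \Lambda)/\Lambda \cdot (v_e - m + 1)/m} on
#' \eqn{(m, v_e - m + 1)} df, where m is the number of responses and
#' \eqn{v_e = n - rank(X)}. Degrees of freedom always reflect the realized
#' complete-case n.
#'
#' @param design an [design_with_inflection()] result (or any list with
#'   matrices `X` and `Y`).
#' @param term design column to test: `"below"` (level shift), `"hinge"`
#'   (slope change), or any column name of `X`.
#' @return object of class `manova_result`: `term`, `wilks`, `f`, `df`
#'   (numerator, denominator), `p_value`, `coefficients` (per-response
#'   estimates of the tested term), `n`.
#' @export
manova_term_test <- function(design, term) {
  X <- design$X; Y <- as.matrix(design$Y)
  stopifnot(is.matrix(X), nrow(X) == nrow(Y))
  if (!term %in% colnames(X))
    stop(sprintf("term '%s' is not a design column", term), call. = FALSE)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (n <= p + m)
    stop("too few complete cases for the design and responses",
         call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrx, Y)
  R <- Y - X %*% B
  E <- crossprod(R)
  xtx_inv <- chol2inv(qr.R(qrx))       # (X'X)^{-1} in pivoted order
  # undo pivoting
  piv <- qrx$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  j <- match(term, colnames(X))
  v <- B[j, ]                          # tested coefficient across responses
  Mjj <- xtx_inv[j, j]
  H <- tcrossprod(v) / Mjj
  lambda <- det(E) / det(E + H)
  ve <- n - qrx$rank
  df2 <- ve - m + 1
  if (df2 <= 0) stop("not enough error degrees of freedom", call. = FALSE)
  f <- (1 - lambda) / lambda * df2 / m
  p_value <- stats::pf(f, m, df2, lower.tail = FALSE)
  structure(list(term = term, wilks = lambda, f = f, df = c(m, df2),
                 p_value = p_value, coefficients = v, n = n),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "MANOVA term '%s': Wilks lambda = %.4f, F = %.3f on %d/%d df, p = %.4g (n = %d)\n",
    x$term, x$wilks, x$f, x$df[1], x$df[2], x$p_value, x$n))
  invisible(x)
}

#' Omnibus inflection tests for level shift and slope change
#'
#' Convenience wrapper running [manova_term_test()] for the level-shift
#' indicator and the hinge term of an inflection design.
#'
#' @inheritParams design_with_inflection
#' @return list with elements `levels` and `slopes`, each a
#'   `manova_result`, plus the `design`.
#' @export
inflection_manova <- function(table, inflect_at = 89,
                              responses = biomarker_names(table)) {
  design <- design_with_inflection(table, inflect_at, responses)
  if (design$collinear)
    stop("inflection design is collinear: no observations on one side",
         call. = FALSE)
  list(levels = manova_term_test(design, "below"),
       slopes = manova_term_test(design, "hinge"),
       design = design)
}
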