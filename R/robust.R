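## Elementary robust / rank statistics used throughout the change-point
## analyses. Everything here is implemented directly (the analyses are about
## these procedures); base-R counterparts appear only as oracles in tests.

# Tukey bisquare rho, normalized so rho(Inf) = 1.
.bisquare_rho <- function(u, c) {
  v <- pmin(1, abs(u / c))
  1 - (1 - v^2)^3
}

# psi = d/du of the unnormalized bisquare objective; weights psi(u)/u in [0,1].
.bisquare_w <- function(u, c) {
  v <- u / c
  ifelse(abs(v) < 1, (1 - v^2)^2, 0)
}

.bisquare_psi <- function(u, c) u * .bisquare_w(u, c)

.bisquare_dpsi <- function(u, c) {
  v <- u / c
  ifelse(abs(v) < 1, (1 - v^2) * (1 - 5 * v^2), 0)
}

# M-scale of residuals: solve mean(rho(r/s)) = b for s, bisquare tuning c.
# Fixed-point iteration on s^2; b = 0.5 with c = 1.548 gives breakdown 0.5
# and consistency at the normal.
.m_scale <- function(r, c = 1.548, b = 0.5, tol = 1e-10, max_iter = 200) {
  r <- r[is.finite(r)]
  if (all(abs(r) < .Machine$double.eps)) return(0)
  s <- stats::median(abs(r)) / 0.6745
  if (s == 0) s <- mean(abs(r))
  for (i in seq_len(max_iter)) {
    m <- mean(.bisquare_rho(r / s, c))
    s_new <- s * sqrt(m / b)
    if (abs(s_new - s) < tol * s) return(s_new)
    s <- s_new
  }
  s
}

# one weighted least-squares step for y ~ 1 + x
.wls <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0) return(NULL)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  c(ybar - slope * xbar, slope)
}

#' MM-estimation robust simple linear regression
#'
#' Two-stage MM estimate of `y ~ x`: a high-breakdown S-estimate (Tukey
#' bisquare, tuning 1.548, breakdown point 0.5) obtained from random
#' elemental two-point candidates refined by iteratively reweighted least
#' squares that re-minimizes the M-scale, followed by an efficient M-step
#' (Tukey bisquare, tuning 4.685, 95\% relative efficiency at the normal)
#' holding the S-scale fixed. Standard errors use the standard asymptotic
#' M-estimator covariance; t statistics use df = n - 2.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must not be
#'   constant.
#' @param n_candidates number of random elemental starts for the S-stage.
#' @param max_iter,tol IRLS iteration cap and relative convergence tolerance.
#' @param seed optional seed for the elemental subsampling (fixed internally
#'   by default so fits are deterministic).
#' @return object of class `robust_fit`: `coefficients` (intercept, slope),
#'   `scale`, `weights` (final bisquare weights in \[0,1\]), `se`,
#'   `t` (the reported "rlm t" is `t["slope"]`), `df`, `converged`.
#' @export
mm_regression <- function(x, y, n_candidates = 50, max_iter = 200,
                          tol = 1e-8, seed = 173) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate design: x is constant", call. = FALSE)

  ls <- .wls(x, y, rep(1, n))
  r_ls <- y - ls[1] - ls[2] * x
  y_scale <- max(abs(y), 1)
  if (max(abs(r_ls)) < 1e-12 * y_scale) {
    # exact linear data: LS is the MM fit, zero scale
    out <- list(coefficients = c(intercept = ls[1], slope = ls[2]),
                scale = 0, weights = rep(1, n),
                se = c(intercept = 0, slope = 0),
                t = c(intercept = NA_real_, slope = NA_real_),
                df = n - 2L, converged = TRUE, n = n)
    class(out) <- "robust_fit"
    return(out)
  }

  # --- S-stage: elemental candidates + LS, scored by M-scale
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  cand <- list(ls)
  for (k in seq_len(n_candidates)) {
    ij <- sample.int(n, 2)
    dx <- x[ij[2]] - x[ij[1]]
    if (dx == 0) next
    sl <- (y[ij[2]] - y[ij[1]]) / dx
    cand[[length(cand) + 1]] <- c(y[ij[1]] - sl * x[ij[1]], sl)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  scales <- vapply(cand, function(b) .m_scale(y - b[1] - b[2] * x),
                   numeric(1))
  keep <- order(scales)[seq_len(min(5, length(cand)))]
  best <- NULL; best_scale <- Inf
  for (k in keep) {
    b <- cand[[k]]; s <- scales[k]
    for (it in seq_len(30)) {       # I-steps: reweight and rescale
      r <- y - b[1] - b[2] * x
      w <- .bisquare_w(r / s, 1.548)
      if (sum(w > 0) < 3) break
      b_new <- .wls(x, y, w)
      if (is.null(b_new)) break
      s <- .m_scale(y - b_new[1] - b_new[2] * x)
      if (max(abs(b_new - b)) < tol * max(1, max(abs(b)))) { b <- b_new; break }
      b <- b_new
    }
    if (s < best_scale) { best <- b; best_scale <- s }
  }
  s_hat <- best_scale
  if (!is.finite(s_hat) || s_hat <= 0)
    s_hat <- stats::median(abs(r_ls)) / 0.6745

  # --- M-stage at 95% efficiency, scale fixed
  b <- best
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - b[1] - b[2] * x
    w <- .bisquare_w(r / s_hat, 4.685)
    if (sum(w > 0) < 3) break
    b_new <- .wls(x, y, w)
    if (is.null(b_new)) break
    if (max(abs(b_new - b) / pmax(1e-10, abs(b))) < tol) {
      b <- b_new; converged <- TRUE; break
    }
    b <- b_new
  }
  if (!converged)
    warning("MM regression IRLS did not converge; returning last iterate")

  r <- y - b[1] - b[2] * x
  u <- r / s_hat
  w <- .bisquare_w(u, 4.685)
  psi <- .bisquare_psi(u, 4.685)
  dpsi <- .bisquare_dpsi(u, 4.685)
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  kappa <- (sum(psi^2) / (n - 2)) / (mean(dpsi)^2)
  xtx_inv <- rbind(c(1 / n + xbar^2 / sxx, -xbar / sxx),
                   c(-xbar / sxx, 1 / sxx))
  se <- s_hat * sqrt(kappa * diag(xtx_inv))
  tt <- ifelse(se > 0, b / se, NA_real_)

  out <- list(coefficients = c(intercept = b[1], slope = b[2]),
              scale = s_hat, weights = w,
              se = c(intercept = se[1], slope = se[2]),
              t = c(intercept = tt[1], slope = tt[2]),
              df = n - 2L, converged = converged, n = n)
  class(out) <- "robust_fit"
  out
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("Robust MM regression (n = %d)\n", x$n))
  cat(sprintf("  intercept %.4g (se %.3g), slope %.4g (se %.3g)\n",
              x$coefficients[1], x$se[1], x$coefficients[2], x$se[2]))
  cat(sprintf("  slope t = %.3g on %d df; scale = %.4g%s\n",
              x$t[2], x$df, x$scale,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Robust locally weighted regression (lowess)
#'
#' Locally weighted linear regression with tricube neighbourhood weights and
#' bisquare robustifying iterations on the residuals, evaluated at each
#' observed `x`. This is the "model-free" reference curve the change-point
#' fits are compared against.
#'
#' @param x,y numeric vectors, n >= 5.
#' @param span fraction of the data in each local window, in (0, 1\].
#' @param iterations number of robustifying reweighting passes.
#' @return numeric vector of fitted values, one per observation (input
#'   order).
#' @export
lowess_fit <- function(x, y, span = 2/3, iterations = 3) {
  n <- length(x)
  if (n < 5 || length(y) != n)
    stop("need at least 5 (x, y) pairs", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  k <- ceiling(span * n)
  if (k < 2)
    stop("span too small: local window must contain at least 2 points",
         call. = FALSE)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  rw <- rep(1, n)
  fit <- numeric(n)
  for (pass in seq_len(iterations + 1)) {
    for (i in seq_len(n)) {
      d <- abs(xs - xs[i])
      idx <- order(d)[seq_len(k)]
      h <- max(d[idx])
      w <- if (h > 0) (1 - pmin(1, d[idx] / h)^3)^3 else rep(1, k)
      w <- w * rw[idx]
      if (sum(w > 0) < 2 || sum(w) == 0) {
        fit[i] <- sum(rw[idx] * ys[idx]) / max(sum(rw[idx]), 1e-12)
        next
      }
      b <- .wls(xs[idx], ys[idx], w)
      fit[i] <- if (is.null(b)) sum(w * ys[idx]) / sum(w)
        else b[1] + b[2] * xs[i]
    }
    if (pass > iterations) break
    res <- ys - fit
    m <- stats::median(abs(res))
    if (m == 0) break
    rw <- .bisquare_w(res / (6 * m), 1)
  }
  out <- numeric(n)
  out[ord] <- fit
  out
}

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y numeric vectors, n >= 3.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined: a variable is constant", call. = FALSE)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Wilcoxon-Mann-Whitney two-sample rank test
#'
#' U statistic for sample `a` (number of pairs where `a` precedes `b`, ties
#' counted one half). The two-sided p-value is exact by full enumeration of
#' all group assignments when the combined sample size is at most
#' `exact_cap`, otherwise a normal approximation with tie correction and a
#' continuity correction is used.
#'
#' @param a,b non-empty numeric samples.
#' @param exact_cap largest combined n for which the exact distribution is
#'   enumerated.
#' @return list of class `rank_test`: `statistic` (U for `a`), `p_value`
#'   (two-sided), `method` (`"exact"` or `"normal-approximation"`).
#' @export
mann_whitney <- function(a, b, exact_cap = 12) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (N <= exact_cap) {
    # exact permutation distribution of the rank sum over all C(N, na)
    # assignments, by dynamic programming over the (doubled, so integer)
    # mid-ranks; handles ties exactly
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
    # counts[j + 1, s + 1] = number of j-subsets of the ranks seen so far
    # with doubled-rank sum s
    counts <- matrix(0, nrow = na + 1, ncol = smax + 1)
    counts[1, 1] <- 1
    for (ri in r2) {
      for (j in rev(seq_len(na))) {
        nz <- which(counts[j, ] > 0)
        if (length(nz) == 0) next
        tgt <- nz + ri
        keep <- tgt <= smax + 1
        counts[j + 1, tgt[keep]] <- counts[j + 1, tgt[keep]] +
          counts[j, nz[keep]]
      }
    }
    total <- choose(N, na)
    sums <- (seq_len(smax + 1) - 1) / 2            # back to rank scale
    us <- sums - na * (na + 1) / 2
    w <- counts[na + 1, ]
    dev_obs <- abs(u_obs - mu)
    p <- sum(w[abs(us - mu) >= dev_obs - 1e-9]) / total
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_adj <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_adj)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal-approximation"
  }
  structure(list(statistic = u_obs, p_value = p, method = method,
                 n = c(na, nb)), class = "rank_test")
}

#' Variance-ratio F test
#'
#' F is the larger sample variance over the smaller, with degrees of freedom
#' ordered to match numerator/denominator; the two-sided p doubles the upper
#' tail and caps at 1.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @return list: `statistic`, `df` (numerator, denominator), `p_value`,
#'   `infinite` flag when the smaller variance is zero.
#' @export
variance_ratio_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va >= vb) {
    num <- va; den <- vb; df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    num <- vb; den <- va; df <- c(length(b) - 1L, length(a) - 1L)
  }
  if (den == 0) {
    return(list(statistic = Inf, df = df, p_value = 0, infinite = TRUE))
  }
  f <- num / den
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(statistic = f, df = df, p_value = p, infinite = FALSE)
}

#' Pearson chi-square and Fisher exact tests for a 2x2 table
#'
#' Pearson's chi-square without continuity correction, and the two-sided
#' Fisher exact p summing all hypergeometric outcomes (given the margins) no
#' more probable than the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `chisq` (statistic), `chisq_p`, `fisher_p`.
#' @export
categorical_tests <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a row or column is all zero", call. = FALSE)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  chisq <- sum((tab - expd)^2 / expd)
  chisq_p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  m <- colSums(tab)[1]; k <- rowSums(tab)[1]
  lo <- max(0, k - (n - m)); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n - m, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n - m, k)
  fisher_p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(chisq = chisq, chisq_p = chisq_p, fisher_p = fisher_p)
}
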