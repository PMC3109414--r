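## Level change-point detection: structural-change F scan and single
## RSS-minimizing breakpoint along the CAMCOG axis. The regime model is the
## linear regression of the biomarker on CAMCOG (intercept and slope per
## regime); a constant-per-regime variant is available for pure level-step
## analyses and underlies chow_f.

# prefix-sum bundle over the ordered sample
.prefix <- function(x, y) {
  list(sx = c(0, cumsum(x)), sxx = c(0, cumsum(x^2)),
       sy = c(0, cumsum(y)), syy = c(0, cumsum(y^2)),
       sxy = c(0, cumsum(x * y)))
}

# RSS of a least-squares line (or of the mean under the constant model) on
# positions a..b, vectorized over a/b, from prefix sums
.range_rss <- function(ps, a, b, model) {
  n <- b - a + 1
  sy <- ps$sy[b + 1] - ps$sy[a]
  syy <- ps$syy[b + 1] - ps$syy[a]
  rss0 <- pmax(0, syy - sy^2 / n)
  if (model == "constant") return(rss0)
  sx <- ps$sx[b + 1] - ps$sx[a]
  sxx <- ps$sxx[b + 1] - ps$sxx[a]
  sxy <- ps$sxy[b + 1] - ps$sxy[a]
  sxx_c <- pmax(0, sxx - sx^2 / n)
  sxy_c <- sxy - sx * sy / n
  # all-tied x within the segment: fall back to the mean-only RSS there
  pmax(0, rss0 - ifelse(sxx_c > 0, sxy_c^2 / sxx_c, 0))
}

# split RSS for every left-segment size in idx
.split_rss <- function(ps, n, idx, model) {
  .range_rss(ps, rep(1L, length(idx)), idx, model) +
    .range_rss(ps, idx + 1L, rep(n, length(idx)), model)
}

.model_k <- function(model) if (model == "constant") 1L else 2L

# admissible split positions: under the linear model each regime must span
# at least `min_distinct` distinct predictor values, the standard regularity
# condition for fitting a line per regime (a regime confined to one or two
# tied scores would otherwise soak up RSS by overfitting)
.admissible_idx <- function(cs, lo, hi, model, min_distinct = 3L) {
  idx <- lo:hi
  if (model == "constant") return(idx)
  n <- length(cs)
  n_dist_left <- cumsum(c(TRUE, cs[-1] != cs[-n]))
  n_dist_right <- rev(cumsum(c(TRUE, rev(cs)[-1] != rev(cs)[-n])))
  keep <- n_dist_left[idx] >= min_distinct &
    n_dist_right[idx + 1L] >= min_distinct
  idx[keep]
}

#' Chow-type F statistic for a level shift
#'
#' Compares a single common mean against separate means on each side of a
#' split: `F = (RSS_pooled - RSS_split) / (RSS_split / (n - 2))` with one
#' parameter (the mean) per regime. A perfect separation (zero within-side
#' variance with distinct means) yields an infinite F, flagged rather than
#' raised.
#'
#' @param y_left,y_right numeric vectors, each with at least 2 observations.
#' @return list: `statistic`, `rss_pooled`, `rss_split`, `infinite` flag.
#' @export
chow_f <- function(y_left, y_right) {
  y_left <- y_left[is.finite(y_left)]; y_right <- y_right[is.finite(y_right)]
  if (length(y_left) < 2 || length(y_right) < 2)
    stop("each side needs at least 2 observations", call. = FALSE)
  n <- length(y_left) + length(y_right)
  y <- c(y_left, y_right)
  rss_pooled <- sum((y - mean(y))^2)
  rss_split <- sum((y_left - mean(y_left))^2) +
    sum((y_right - mean(y_right))^2)
  if (rss_split <= .Machine$double.eps * max(rss_pooled, 1)) {
    if (rss_pooled <= .Machine$double.eps)
      return(list(statistic = 0, rss_pooled = rss_pooled,
                  rss_split = rss_split, infinite = FALSE))
    return(list(statistic = Inf, rss_pooled = rss_pooled,
                rss_split = rss_split, infinite = TRUE))
  }
  f <- (rss_pooled - rss_split) / (rss_split / (n - 2))
  list(statistic = f, rss_pooled = rss_pooled, rss_split = rss_split,
       infinite = FALSE)
}

#' Structural-change F scan along the CAMCOG axis
#'
#' Orders observations by CAMCOG (ties keep input order) and evaluates, at
#' every admissible split inside the trimmed interior, the F statistic
#' comparing one regression fitted to the whole sample against separate
#' regressions per regime: `F = ((RSS_pooled - RSS_split)/k) /
#' (RSS_split/(n - 2k))` with `k` parameters per regime (2 for the default
#' linear model, 1 for the constant model, where the statistic is exactly
#' [chow_f()]). The supremum F gets a permutation p-value: residuals of the
#' pooled fit are permuted, re-attached to the pooled fitted values, and the
#' scan is repeated.
#'
#' @param camcog numeric vector of scores.
#' @param y numeric responses, same length, n >= 10.
#' @param trim trimming fraction per side, in (0, 0.5).
#' @param n_perm number of permutations for the p-value.
#' @param seed seed for the permutations.
#' @param model `"linear"` (intercept and slope per regime) or `"constant"`
#'   (mean per regime).
#' @return object of class `fstat_scan`: `positions` (left-segment sizes),
#'   `camcog_at` (score of the last left-regime observation at each
#'   candidate), `f` (statistics), `sup_f`, `camcog` (argmax position mapped
#'   to a score), `p_value`, `model`.
#' @export
fstat_scan <- function(camcog, y, trim = 0.15, n_perm = 1000, seed = 1,
                       model = c("linear", "constant")) {
  model <- match.arg(model)
  ok <- is.finite(camcog) & is.finite(y)
  camcog <- camcog[ok]; y <- y[ok]
  n <- length(y)
  if (n < 10) stop("need at least 10 complete observations", call. = FALSE)
  if (trim <= 0 || trim >= 0.5) stop("trim must lie in (0, 0.5)",
                                     call. = FALSE)
  k <- .model_k(model)
  ord <- order(camcog)          # stable: ties keep input order
  cs <- camcog[ord]; ys <- y[ord]
  lo <- max(k + 1L, as.integer(ceiling(trim * n)))
  hi <- min(n - k - 1L, as.integer(floor((1 - trim) * n)))
  if (lo > hi) stop("no admissible split candidates after trimming",
                    call. = FALSE)
  idx <- .admissible_idx(cs, lo, hi, model)
  if (length(idx) == 0)
    stop("no admissible split candidates after trimming", call. = FALSE)

  scan_once <- function(yy) {
    ps <- .prefix(cs, yy)
    rss_p <- .range_rss(ps, 1L, n, model)
    rss_s <- .split_rss(ps, n, idx, model)
    f <- ifelse(rss_s <= .Machine$double.eps * max(rss_p, 1),
                ifelse(rss_p <= .Machine$double.eps, 0, Inf),
                ((rss_p - rss_s) / k) / (rss_s / (n - 2 * k)))
    list(f = f, rss_p = rss_p)
  }
  obs <- scan_once(ys)
  sup_f <- max(obs$f)
  arg <- idx[which.max(obs$f)]

  p_value <- NA_real_
  if (n_perm > 0) {
    # permute residuals of the pooled fit: the null keeps one global model
    ps <- .prefix(cs, ys)
    if (model == "constant") {
      fitted <- rep(mean(ys), n)
    } else {
      sxx_c <- sum((cs - mean(cs))^2)
      b1 <- if (sxx_c > 0) sum((cs - mean(cs)) * (ys - mean(ys))) / sxx_c
            else 0
      fitted <- mean(ys) + b1 * (cs - mean(cs))
    }
    resid <- ys - fitted
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      yp <- fitted + resid[sample.int(n)]
      if (max(scan_once(yp)$f) >= sup_f) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (1 + n_perm)
  }
  structure(list(positions = idx, camcog_at = cs[idx], f = obs$f,
                 sup_f = sup_f, camcog = cs[arg], position = arg,
                 p_value = p_value, n = n, trim = trim, model = model),
            class = "fstat_scan")
}

#' @export
print.fstat_scan <- function(x, ...) {
  cat(sprintf(
    "Structural-change scan (%s model, n = %d, trim %.2f): sup F = %.3f at CAMCOG %g",
    x$model, x$n, x$trim, x$sup_f, x$camcog))
  if (!is.na(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' RSS-minimizing single breakpoint
#'
#' Exhaustive search over all admissible single splits of the
#' CAMCOG-ordered sequence, minimizing the total within-regime residual sum
#' of squares — by default of the linear regression of the biomarker on
#' CAMCOG per regime, optionally of the constant (mean per regime) model.
#' RSS ties are broken toward the split whose CAMCOG value is nearest the
#' sample median score. The breakpoint is reported as the CAMCOG value of
#' the last observation of the left regime.
#'
#' @param camcog numeric scores.
#' @param y numeric responses.
#' @param min_seg minimum observations per regime; default
#'   `max(5, ceiling(0.15 * n))`.
#' @param model `"linear"` or `"constant"`, as in [fstat_scan()].
#' @return list: `position` (left-segment size in the ordered sample),
#'   `camcog`, `rss`, `model`.
#' @export
rss_breakpoint <- function(camcog, y, min_seg = NULL,
                           model = c("linear", "constant")) {
  model <- match.arg(model)
  ok <- is.finite(camcog) & is.finite(y)
  camcog <- camcog[ok]; y <- y[ok]
  n <- length(y)
  if (is.null(min_seg)) min_seg <- max(5L, as.integer(ceiling(0.15 * n)))
  min_seg <- max(.model_k(model) + 1L, as.integer(min_seg))
  if (n < 2 * min_seg)
    stop("need at least 2 * min_seg observations", call. = FALSE)
  ord <- order(camcog)
  cs <- camcog[ord]; ys <- y[ord]
  idx <- .admissible_idx(cs, min_seg, n - min_seg, model)
  if (length(idx) == 0)
    stop("no admissible split candidates", call. = FALSE)
  ps <- .prefix(cs, ys)
  rss <- .split_rss(ps, n, idx, model)
  best <- min(rss)
  tied <- idx[rss <= best + 1e-9 * max(best, 1)]
  med <- stats::median(cs)
  pos <- tied[which.min(abs(cs[tied] - med))]
  list(position = pos, camcog = cs[pos], rss = rss[idx == pos][1],
       model = model)
}
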