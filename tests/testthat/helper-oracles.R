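# Independent naive oracles used across the suite. These deliberately share
# no code with the package: plain loops and textbook formulas only.

# breakpoint by brute force: try every admissible split of the ordered data,
# fit each regime by lm (or its mean), keep the minimum-RSS split, breaking
# ties toward the split whose score is nearest the sample median
naive_breakpoint <- function(camcog, y, min_seg, model = "linear") {
  ord <- order(camcog)
  cs <- camcog[ord]; ys <- y[ord]
  n <- length(ys)
  side_rss <- function(xx, yy) {
    if (model == "constant" || length(unique(xx)) < 2)
      return(sum((yy - mean(yy))^2))
    f <- stats::lm.fit(cbind(1, xx), yy)
    sum(f$residuals^2)
  }
  best_rss <- Inf; best_pos <- NA_integer_
  med <- stats::median(cs)
  for (i in min_seg:(n - min_seg)) {
    if (model == "linear" &&
        (length(unique(cs[1:i])) < 3 || length(unique(cs[(i + 1):n])) < 3))
      next
    rss <- side_rss(cs[1:i], ys[1:i]) + side_rss(cs[(i + 1):n], ys[(i + 1):n])
    if (is.infinite(best_rss) || rss < best_rss - 1e-9 * max(best_rss, 1)) {
      best_rss <- rss; best_pos <- i
    } else if (rss <= best_rss + 1e-9 * max(best_rss, 1)) {
      if (abs(cs[i] - med) < abs(cs[best_pos] - med)) {
        best_rss <- min(best_rss, rss); best_pos <- i
      }
    }
  }
  list(position = best_pos, camcog = cs[best_pos])
}

# exact two-sided Mann-Whitney p by recursive enumeration of rank-sum
# distributions over all assignments (positions chosen via combinations)
enumerate_wmw <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(id) sum(r[id]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  ids <- utils::combn(na + nb, na)
  us <- apply(ids, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small cohort used by many tests
make_cohort <- function(seed = 1, n_control = 95, n_ad = 97,
                        cfgs = default_scenarios()) {
  generate_cohort(cfgs, n_control, n_ad, seed = seed)
}
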